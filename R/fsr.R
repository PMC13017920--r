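#' Time-weighted average precursor enrichment over an incorporation window
#'
#' The precursor-product model needs the average precursor enrichment over
#' the labelling interval. Sampling is non-uniform, so the default is the
#' time-weighted trapezoid mean of the points falling inside `[t1, t2]`;
#' `method = "arithmetic"` gives the plain mean for sensitivity checks.
#' A single point inside the window is returned as-is.
#'
#' @param time Sample times, min.
#' @param ttr Precursor enrichment (TTR) at those times.
#' @param t1,t2 Window bounds in min, `t2 > t1`.
#' @param method `"trapezoid"` (default) or `"arithmetic"`.
#' @return Average precursor enrichment (TTR).
#' @examples
#' precursor_average(c(0, 60, 120), c(0.02, 0.04, 0.04), 0, 120) # 0.035
#' @export
precursor_average <- function(time, ttr, t1, t2,
                              method = c("trapezoid", "arithmetic")) {
  method <- match.arg(method)
  if (t2 <= t1) {
    stop("precursor_average: window must have t2 > t1", call. = FALSE)
  }
  keep <- !is.na(ttr) & time >= t1 & time <= t2
  t <- time[keep]
  y <- ttr[keep]
  if (length(t) == 0) {
    stop("precursor_average: no precursor samples inside [", t1, ", ", t2, "]",
         call. = FALSE)
  }
  if (length(t) == 1) {
    return(y)
  }
  o <- order(t)
  t <- t[o]; y <- y[o]
  if (method == "arithmetic") {
    mean(y)
  } else {
    pracma::trapz(t, y) / (t[length(t)] - t[1])
  }
}

#' Fractional synthesis rate (precursor-product model)
#'
#' \deqn{FSR = 100 \times \frac{E_{protein,2} - E_{protein,1}}
#'   {\bar E_{precursor} \times (t_2 - t_1)}}
#' with time in hours (`"per_hour"`, muscle convention) or days
#' (`"per_day"`, plasma-protein convention). Times are supplied in
#' minutes.
#'
#' @param e_protein_1,e_protein_2 Protein-bound enrichment (TTR) at the
#'   start and end of the incorporation window.
#' @param t1,t2 Window bounds, min.
#' @param precursor Average precursor enrichment over the window (see
#'   [precursor_average()]); must be > 0.
#' @param timescale `"per_hour"` or `"per_day"`.
#' @return FSR in %/h or %/day.
#' @examples
#' fsr(0, 0.00026, 0, 390, precursor = 0.04) # 0.1 %/h
#' @export
fsr <- function(e_protein_1, e_protein_2, t1, t2, precursor,
                timescale = c("per_hour", "per_day")) {
  timescale <- match.arg(timescale)
  if (any(t2 <= t1)) {
    stop("fsr: incorporation window must have t2 > t1", call. = FALSE)
  }
  if (any(!is.finite(precursor)) || any(precursor <= 0)) {
    stop("fsr: precursor enrichment must be > 0", call. = FALSE)
  }
  denom_minutes <- t2 - t1
  dt <- switch(timescale,
               per_hour = denom_minutes / 60,
               per_day = denom_minutes / 1440)
  100 * (e_protein_2 - e_protein_1) / (precursor * dt)
}

#' Mixed-muscle protein fractional synthesis rate from paired biopsies
#'
#' Applies the precursor-product model between the two biopsies (taken at
#' -30 and 360 min in the study design). The precursor is the muscle
#' free-pool pooled phenylalanine enrichment (D5 + D7 + D8) when the
#' biopsy table carries `free_pool_ttr`; otherwise the plasma pooled
#' series (`precursor_series`) is used.
#'
#' @param biopsy Tibble with `time`, `protein_bound_ttr`, and optionally
#'   `free_pool_ttr`; exactly two rows are used (first and last time).
#' @param precursor_series Optional tibble with `time`, `ttr` (plasma
#'   pooled phenylalanine enrichment, e.g. `pooled_ttr(e, "phe_all")`).
#' @param method Passed to [precursor_average()].
#' @return One-row tibble: `t1`, `t2`, `precursor`, `fsr_pct_h`.
#' @export
muscle_fsr <- function(biopsy, precursor_series = NULL,
                       method = "trapezoid") {
  biopsy <- dplyr::arrange(biopsy, .data$time)
  if (nrow(biopsy) < 2) {
    stop("muscle_fsr: need two biopsies", call. = FALSE)
  }
  b1 <- biopsy[1, ]
  b2 <- biopsy[nrow(biopsy), ]
  if ("free_pool_ttr" %in% names(biopsy) && !anyNA(biopsy$free_pool_ttr)) {
    prec <- precursor_average(biopsy$time, biopsy$free_pool_ttr,
                              b1$time, b2$time, method = method)
  } else if (!is.null(precursor_series)) {
    prec <- precursor_average(precursor_series$time, precursor_series$ttr,
                              b1$time, b2$time, method = method)
  } else {
    stop("muscle_fsr: need free_pool_ttr in the biopsy table or a precursor_series",
         call. = FALSE)
  }
  tibble::tibble(
    t1 = b1$time, t2 = b2$time, precursor = prec,
    fsr_pct_h = fsr(b1$protein_bound_ttr, b2$protein_bound_ttr,
                    b1$time, b2$time, prec, timescale = "per_hour")
  )
}

#' Plasma-protein fractional synthesis rate over postprandial windows
#'
#' Computes the precursor-product FSR of total plasma proteins for a set
#' of incorporation windows all starting at `t_start` (meal ingestion by
#' default) and ending at the sampling times of the protein-bound series
#' (60, 120, 240, 360 min in the study design). The precursor is the
#' plasma enrichment of the matching label channel: the infused D8+D7
#' pool for tracer-based FSR, or the meal D5 label for the meal-derived
#' variant.
#'
#' @param protein_ttr Tibble with `time`, `ttr`: protein-bound enrichment
#'   of plasma proteins, including a row at `t_start`.
#' @param precursor_series Tibble with `time`, `ttr`: free plasma
#'   enrichment of the same label.
#' @param windows_end Window end times, min.
#' @param t_start Common window start, min (default 0).
#' @param timescale Passed to [fsr()] (default `"per_day"`).
#' @param method Passed to [precursor_average()].
#' @return Tibble with one row per window: `t1`, `t2`, `precursor`, `fsr`.
#' @export
plasma_protein_fsr <- function(protein_ttr, precursor_series,
                               windows_end = c(60, 120, 240, 360),
                               t_start = 0,
                               timescale = "per_day",
                               method = "trapezoid") {
  e0 <- protein_ttr$ttr[protein_ttr$time == t_start]
  if (length(e0) != 1) {
    stop("plasma_protein_fsr: protein_ttr needs exactly one row at t_start = ",
         t_start, call. = FALSE)
  }
  purrr::map_dfr(windows_end, function(te) {
    e2 <- protein_ttr$ttr[protein_ttr$time == te]
    if (length(e2) != 1) {
      stop("plasma_protein_fsr: protein_ttr has no sample at ", te, " min",
           call. = FALSE)
    }
    prec <- precursor_average(precursor_series$time, precursor_series$ttr,
                              t_start, te, method = method)
    tibble::tibble(
      t1 = t_start, t2 = te, precursor = prec,
      fsr = fsr(e0, e2, t_start, te, prec, timescale = timescale)
    )
  })
}
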