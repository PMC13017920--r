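#' Net arteriovenous balance across a tissue bed
#'
#' In `"flow"` mode (leg, femoral vein) the net balance is
#' `(Ca - Cv) * flow / lean_mass`, in umol/min/kg lean mass; positive
#' values indicate net uptake. In `"difference"` mode (adipose, epigastric
#' vein, where flow is unavailable) the plain concentration difference
#' `Ca - Cv` in umol/L is returned.
#'
#' @param ca,cv Arterial and venous plasma concentrations, umol/L.
#' @param flow Arterial blood flow, L/min (required in `"flow"` mode).
#' @param lean_mass Lean mass, kg (required in `"flow"` mode).
#' @param mode `"flow"` or `"difference"`.
#' @return Net balance (see Details for units by mode).
#' @examples
#' net_balance(60, 55, flow = 0.3, lean_mass = 50) # 0.03
#' net_balance(60, 55, mode = "difference")        # 5
#' @export
net_balance <- function(ca, cv, flow = NULL, lean_mass = NULL,
                        mode = c("flow", "difference")) {
  mode <- match.arg(mode)
  if (mode == "difference") {
    return(ca - cv)
  }
  if (is.null(flow) || anyNA(flow)) {
    stop("net_balance: flow mode requires blood flow at every timepoint",
         call. = FALSE)
  }
  if (is.null(lean_mass) || any(lean_mass <= 0)) {
    stop("net_balance: flow mode requires a positive lean_mass", call. = FALSE)
  }
  if (any(flow <= 0)) {
    stop("net_balance: blood flow must be positive", call. = FALSE)
  }
  (ca - cv) * flow / lean_mass
}

#' Fractional extraction of tracer across a tissue bed
#'
#' `FE = (Ca*Ea - Cv*Ev) / (Ca*Ea)`: the fraction of arterially delivered
#' tracer not returned in the vein. Dimensionless; multiply by 100 for %.
#'
#' @param ca,cv Arterial and venous concentrations, umol/L.
#' @param ea,ev Arterial and venous enrichments (TTR).
#' @return Fractional extraction (dimensionless).
#' @examples
#' fractional_extraction(60, 0.055, 57, 0.050) # 0.13636...
#' @export
fractional_extraction <- function(ca, ea, cv, ev) {
  denom <- ca * ea
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    stop("fractional_extraction: arterial tracer flux Ca*Ea must be > 0",
         call. = FALSE)
  }
  (denom - cv * ev) / denom
}

#' Tissue tracer uptake
#'
#' `uptake = FE * Ca * flow / lean_mass`. For phenylalanine across the leg
#' this estimates muscle protein synthesis in the two-pool model.
#'
#' @param fe Fractional extraction from [fractional_extraction()].
#' @param ca Arterial concentration, umol/L.
#' @param flow Arterial blood flow, L/min.
#' @param lean_mass Lean mass, kg.
#' @return Uptake, umol/min/kg lean mass.
#' @export
uptake_rate <- function(fe, ca, flow, lean_mass) {
  if (is.null(flow) || anyNA(flow) || any(flow <= 0)) {
    stop("uptake_rate: requires positive blood flow", call. = FALSE)
  }
  if (is.null(lean_mass) || any(lean_mass <= 0)) {
    stop("uptake_rate: requires positive lean_mass", call. = FALSE)
  }
  fe * ca * flow / lean_mass
}

#' Tissue tracee release
#'
#' `release = uptake - net_balance`. For phenylalanine across the leg this
#' estimates muscle protein degradation in the two-pool model.
#'
#' @param uptake Uptake from [uptake_rate()], umol/min/kg lean mass.
#' @param net_balance Net balance in the same units.
#' @return Release, umol/min/kg lean mass.
#' @export
release_rate <- function(uptake, net_balance) {
  uptake - net_balance
}

#' Two-pool arteriovenous balance pipeline
#'
#' Computes per-timepoint net balance, fractional extraction, uptake, and
#' release for every analyte available at both sites of a tissue bed. With
#' blood flow (`mode = "flow"`: leg via the femoral vein) results are in
#' umol/min/kg lean mass; without flow (`mode = "difference"`: adipose via
#' the epigastric vein) only concentration-difference net balances
#' (umol/L) are returned. Uptake and release additionally require matching
#' arterial and venous enrichment series and are reported for the channels
#' in `channels`. Flow is linearly interpolated to the blood-sample times
#' (constant extension at the ends, covering the unmeasured baseline).
#'
#' @param arterial,venous Tibbles with `time`, `analyte`, `concentration`
#'   (umol/L) for the two sites. The venous series must sample the same
#'   times as the arterial series.
#' @param flow Tibble with `time`, `flow` (L/min); required in flow mode.
#' @param lean_mass Lean mass, kg; required in flow mode.
#' @param arterial_enrichments,venous_enrichments Optional tibbles with
#'   `time`, `analyte`, `isotopologue`, `ttr` for fractional extraction.
#' @param channels Pooled-TTR channels (see [pooled_ttr()]) for which
#'   extraction/uptake/release are computed (default `"phe_d8d7"`).
#' @param mode `"flow"` or `"difference"`.
#'
#' @return A tibble of class `av_balance_result`: `time`, `analyte`,
#'   `ca`, `cv`, `net_balance`, and (flow mode, labelled channels)
#'   `fractional_extraction`, `uptake`, `release`.
#' @export
av_balance <- function(arterial, venous, flow = NULL, lean_mass = NULL,
                       arterial_enrichments = NULL, venous_enrichments = NULL,
                       channels = "phe_d8d7",
                       mode = c("flow", "difference")) {
  mode <- match.arg(mode)
  a <- dplyr::select(arterial, dplyr::all_of(c("time", "analyte", "concentration")))
  v <- dplyr::select(venous, dplyr::all_of(c("time", "analyte", "concentration")))
  merged <- dplyr::inner_join(a, v, by = c("time", "analyte"),
                              suffix = c("_a", "_v"))
  orphans <- setdiff(union(a$time, v$time), merged$time)
  if (length(orphans) > 0) {
    stop("av_balance: arterial and venous series are misaligned at time(s) ",
         paste(sort(orphans), collapse = ", "), call. = FALSE)
  }
  merged <- dplyr::rename(merged, ca = "concentration_a", cv = "concentration_v")

  if (mode == "difference") {
    out <- merged |>
      dplyr::mutate(
        net_balance = net_balance(.data$ca, .data$cv, mode = "difference"),
        fractional_extraction = NA_real_,
        uptake = NA_real_,
        release = NA_real_
      )
    return(structure(dplyr::arrange(out, .data$analyte, .data$time),
                     class = c("av_balance_result", class(out)),
                     mode = mode, units = "umol/L"))
  }

  if (is.null(flow)) {
    stop("av_balance: flow mode requires a blood-flow series", call. = FALSE)
  }
  fl <- stats::approx(flow$time, flow$flow, xout = merged$time, rule = 2)$y
  out <- merged |>
    dplyr::mutate(
      flow = fl,
      net_balance = net_balance(.data$ca, .data$cv, .data$flow, lean_mass),
      fractional_extraction = NA_real_,
      uptake = NA_real_, release = NA_real_
    )

  if (!is.null(arterial_enrichments) && !is.null(venous_enrichments)) {
    for (ch in channels) {
      ana <- .ttr_channels[[ch]]$analyte
      ea <- pooled_ttr(arterial_enrichments, ch)
      ev <- pooled_ttr(venous_enrichments, ch)
      ee <- dplyr::inner_join(
        dplyr::select(ea, dplyr::all_of(c("time", "ttr"))),
        dplyr::select(ev, dplyr::all_of(c("time", "ttr"))),
        by = "time", suffix = c("_a", "_v")
      )
      idx <- which(out$analyte == ana & out$time %in% ee$time)
      ee <- ee[match(out$time[idx], ee$time), ]
      fe <- fractional_extraction(out$ca[idx], ee$ttr_a, out$cv[idx], ee$ttr_v)
      up <- uptake_rate(fe, out$ca[idx], out$flow[idx], lean_mass)
      out$fractional_extraction[idx] <- fe
      out$uptake[idx] <- up
      out$release[idx] <- release_rate(up, out$net_balance[idx])
    }
  }
  structure(dplyr::arrange(out, .data$analyte, .data$time),
            class = c("av_balance_result", class(out)),
            mode = mode, units = "umol/min/kg LM", lean_mass = lean_mass)
}
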