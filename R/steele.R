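#' Non-steady-state rate of appearance (Steele single-pool estimator)
#'
#' Single-pool isotope-dilution estimator evaluated on a pair of consecutive
#' samples: the tracee appearance rate is the infusion rate minus the
#' pool-enrichment drift term, divided by the mean enrichment,
#' \deqn{R_a = \frac{F - pV \bar C \, (E_2-E_1)/(t_2-t_1)}{(E_1+E_2)/2}.}
#' The estimate is attached to the pair midpoint time `(t1 + t2) / 2`.
#'
#' All arguments are vectorised over pairs.
#'
#' @param f Tracer infusion rate, umol/kg lean mass/min.
#' @param pv_eff Effective pool volume, L/kg lean mass
#'   (see [effective_pool_volume()]).
#' @param t1,t2 Sample times in min, `t2 > t1`.
#' @param c1,c2 Tracee (unlabelled) plasma concentrations, umol/L.
#' @param e1,e2 Pooled tracer enrichments (TTR) at `t1` and `t2`.
#'
#' @return Total rate of appearance, umol/kg lean mass/min.
#' @examples
#' steele_ra(0.07, 0.19, 0, 10, 55, 60, 0.060, 0.055) # 1.3124
#' @export
steele_ra <- function(f, pv_eff, t1, t2, c1, c2, e1, e2) {
  if (any(t2 <= t1)) {
    stop("steele_ra: sample pairs must have t2 > t1", call. = FALSE)
  }
  ebar <- (e1 + e2) / 2
  if (any(!is.finite(ebar)) || any(ebar <= 0)) {
    stop("steele_ra: degenerate mean enrichment (must be > 0)", call. = FALSE)
  }
  cbar <- (c1 + c2) / 2
  (f - pv_eff * cbar * (e2 - e1) / (t2 - t1)) / ebar
}

#' Non-steady-state rate of disappearance
#'
#' \deqn{R_d = R_a - pV \, (C_2-C_1)/(t_2-t_1).}
#' Under constant concentration `Rd = Ra`; a falling pool raises `Rd`
#' above `Ra`.
#'
#' @param ra_total Total rate of appearance from [steele_ra()].
#' @inheritParams steele_ra
#' @return Total rate of disappearance, umol/kg lean mass/min.
#' @export
steele_rd <- function(ra_total, pv_eff, t1, t2, c1, c2) {
  if (any(t2 <= t1)) {
    stop("steele_rd: sample pairs must have t2 > t1", call. = FALSE)
  }
  ra_total - pv_eff * (c2 - c1) / (t2 - t1)
}

#' Meal-derived (oral) rate of appearance from the meal label
#'
#' The appearance of meal protein-derived phenylalanine is identified by
#' the ring-D5 label incorporated in the meal casein:
#' \deqn{R_{a,oral} = \frac{R_{a,total}\,\bar E_{D5} +
#'   pV \bar C\,(E_{D5,2}-E_{D5,1})/(t_2-t_1)}{r}}
#' (`mode = "corrected"`, default), where `r` is the D5:tracee ratio in the
#' meal protein. `mode = "printed"` evaluates the pool-drift term without
#' the concentration factor, i.e. `pV * dE/dt` alone, reproducing the
#' typeset form of the source equation for comparison; it is not
#' dimensionally consistent and is not the default. Negative estimates
#' (possible under measurement noise) are clipped to zero with a warning.
#'
#' @param ra_total Total rate of appearance at the same midpoints.
#' @param e5_1,e5_2 D5-phenylalanine enrichment (TTR) at `t1`, `t2`.
#' @param r Ratio of D5-phenylalanine to unlabelled phenylalanine in the
#'   meal protein (0 < r).
#' @param mode `"corrected"` (default) or `"printed"`.
#' @inheritParams steele_ra
#' @return Oral rate of appearance, umol/kg lean mass/min.
#' @examples
#' # steady-state label: derivative term vanishes, both modes agree
#' oral_ra(1.8, 0.19, 0, 10, 70, 70, 0.0125, 0.0125, r = 0.05) # 0.45
#' @export
oral_ra <- function(ra_total, pv_eff, t1, t2, c1, c2, e5_1, e5_2, r,
                    mode = c("corrected", "printed")) {
  mode <- match.arg(mode)
  if (length(r) != 1 || !is.finite(r) || r <= 0) {
    stop("oral_ra: meal labelling ratio r must be a single positive number",
         call. = FALSE)
  }
  if (any(t2 <= t1)) {
    stop("oral_ra: sample pairs must have t2 > t1", call. = FALSE)
  }
  ebar5 <- (e5_1 + e5_2) / 2
  dedt <- (e5_2 - e5_1) / (t2 - t1)
  pool <- if (mode == "corrected") pv_eff * (c1 + c2) / 2 * dedt else pv_eff * dedt
  out <- (ra_total * ebar5 + pool) / r
  n_neg <- sum(out < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning("oral_ra: ", n_neg, " negative estimate(s) clipped to zero",
            call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Endogenous rate of appearance (whole-body proteolysis)
#'
#' Phenylalanine is essential, so its only endogenous source is protein
#' degradation: `Ra_endo = Ra_total - Ra_oral` (`mode = "simple"`,
#' default). `mode = "subtract_tracer"` additionally removes the tracer
#' infusion rate `f` for analyses that count the infusate as part of total
#' appearance. Negative values are clipped to zero with a warning.
#'
#' @param ra_total,ra_oral Appearance rates on a common midpoint grid.
#' @param f Tracer infusion rate (required for `"subtract_tracer"`).
#' @param mode `"simple"` (default) or `"subtract_tracer"`.
#' @return Endogenous rate of appearance, umol/kg lean mass/min.
#' @export
endogenous_ra <- function(ra_total, ra_oral, f = NULL,
                          mode = c("simple", "subtract_tracer")) {
  mode <- match.arg(mode)
  out <- ra_total - ra_oral
  if (mode == "subtract_tracer") {
    if (is.null(f)) {
      stop("endogenous_ra: mode 'subtract_tracer' requires the infusion rate f",
           call. = FALSE)
    }
    out <- out - f
  }
  n_neg <- sum(out < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning("endogenous_ra: ", n_neg, " negative estimate(s) clipped to zero",
            call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Phenylalanine hydroxylation rate
#'
#' The first, rate-limiting step of phenylalanine oxidation is its
#' hydroxylation to tyrosine. D7-/D6-tyrosine appear only from
#' hydroxylation of the D8-/D7-phenylalanine tracer, so
#' \deqn{Hydrox = R_{a,D2tyr} \times \frac{E_{D7D6,tyr}}{\bar E_{D8D7,phe}}.}
#'
#' @param ra_tyr_d2 Tyrosine rate of appearance from [steele_ra()] on the
#'   D2-tyrosine channel, umol/kg lean mass/min.
#' @param e_tyr_d7d6 Pooled D7+D6 tyrosine enrichment (TTR), typically the
#'   pair mean.
#' @param e_phe_1,e_phe_2 Pooled D8+D7 phenylalanine enrichment at the two
#'   samples of the pair.
#' @return Hydroxylation rate, umol/kg lean mass/min.
#' @examples
#' hydroxylation_rate(0.55, 0.004, 0.055, 0.055) # 0.04
#' @export
hydroxylation_rate <- function(ra_tyr_d2, e_tyr_d7d6, e_phe_1, e_phe_2) {
  ebar_phe <- (e_phe_1 + e_phe_2) / 2
  if (any(!is.finite(ebar_phe)) || any(ebar_phe <= 0)) {
    stop("hydroxylation_rate: degenerate phenylalanine enrichment (must be > 0)",
         call. = FALSE)
  }
  ra_tyr_d2 * e_tyr_d7d6 / ebar_phe
}

#' Whole-body protein synthesis rate from phenylalanine disposal
#'
#' Assuming protein synthesis and hydroxylation are the only disposal
#' routes: `synthesis = Rd_total - hydroxylation`. Negative values (noise
#' or degenerate inputs) are kept but flagged with a warning.
#'
#' @param rd_total Total rate of disappearance, umol/kg lean mass/min.
#' @param hydroxylation Hydroxylation rate on the same grid.
#' @return Protein synthesis rate, umol phenylalanine/kg lean mass/min.
#' @export
protein_synthesis_rate <- function(rd_total, hydroxylation) {
  out <- rd_total - hydroxylation
  n_neg <- sum(out < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning("protein_synthesis_rate: ", n_neg,
            " negative value(s); hydroxylation exceeded disposal", call. = FALSE)
  }
  out
}

#' Convert a phenylalanine flux to grams of protein per day
#'
#' Divides by the average phenylalanine content of mixed protein and scales
#' minutes to days: `rate * minutes_per_day / phe_per_gram_protein`.
#'
#' @param rate Flux in umol phenylalanine/kg lean mass/min.
#' @param constants A [kinetics_constants()] object.
#' @return Flux in g protein/day/kg lean mass.
#' @examples
#' to_grams_per_day(273 / 1440) # exactly 1
#' @export
to_grams_per_day <- function(rate, constants = kinetics_constants()) {
  rate * constants$minutes_per_day / constants$phe_per_gram_protein
}

#' Net whole-body protein gain
#'
#' `net gain = synthesis - degradation` (positive when anabolic); net
#' protein loss as conventionally reported is its negation.
#'
#' @param synthesis_g_day,degradation_g_day Rates in g/day/kg lean mass.
#' @return Net gain in g/day/kg lean mass.
#' @export
net_protein_gain <- function(synthesis_g_day, degradation_g_day) {
  synthesis_g_day - degradation_g_day
}

#' Systemic appearance of the meal label and first-pass extraction
#'
#' Integrates the oral rate of appearance over the postprandial window and
#' expresses it as a percentage of the phenylalanine ingested; the
#' complement estimates first-pass splanchnic extraction. If the supplied
#' series does not start at the beginning of the window a zero-appearance
#' point is prepended there (no meal label is in blood at ingestion); if it
#' ends early the last value is carried to the end of the window.
#'
#' @param time Midpoint times, min.
#' @param oral_ra Oral rate of appearance, umol/kg lean mass/min.
#' @param meal A [meal_spec()] (uses `total_phe_ingested`, umol).
#' @param lean_mass Lean mass, kg.
#' @param window Integration window in min (default `c(0, 360)`).
#'
#' @return A tibble with `appearance_pct`, `first_pass_pct`, and the
#'   integrated appearance `auc_umol_kg` (umol/kg lean mass).
#' @export
splanchnic_appearance <- function(time, oral_ra, meal, lean_mass,
                                  window = c(0, 360)) {
  stopifnot(inherits(meal, "meal_spec"))
  if (meal$total_phe_ingested <= 0) {
    stop("splanchnic_appearance: total_phe_ingested must be positive", call. = FALSE)
  }
  keep <- time >= window[1] & time <= window[2] & !is.na(oral_ra)
  t <- time[keep]
  y <- oral_ra[keep]
  if (length(t) < 1) {
    stop("splanchnic_appearance: no oral Ra values inside the window", call. = FALSE)
  }
  o <- order(t)
  t <- t[o]; y <- y[o]
  if (t[1] > window[1]) { t <- c(window[1], t); y <- c(0, y) }
  if (t[length(t)] < window[2]) { t <- c(t, window[2]); y <- c(y, y[length(y)]) }
  auc <- pracma::trapz(t, y)
  pct <- 100 * auc * lean_mass / meal$total_phe_ingested
  tibble::tibble(
    appearance_pct = pct,
    first_pass_pct = 100 - pct,
    auc_umol_kg = auc
  )
}

# consecutive-pair layout of a sampled channel table: one row per adjacent
# pair of non-missing samples, with midpoint timestamp
.pairwise <- function(df) {
  df <- dplyr::arrange(df, .data$time)
  n <- nrow(df)
  if (n < 2) {
    stop("kinetics: need at least 2 samples to form pairs", call. = FALSE)
  }
  tibble::tibble(
    t1 = df$time[-n], t2 = df$time[-1],
    midpoint = (df$time[-n] + df$time[-1]) / 2
  ) |>
    dplyr::bind_cols(
      stats::setNames(df[-n, setdiff(names(df), "time"), drop = FALSE],
                      paste0(setdiff(names(df), "time"), "_1")),
      stats::setNames(df[-1, setdiff(names(df), "time"), drop = FALSE],
                      paste0(setdiff(names(df), "time"), "_2"))
    )
}

#' Whole-body postprandial kinetics pipeline
#'
#' Runs the complete non-steady-state isotope-dilution calculus on one
#' subject-visit arterial series: total phenylalanine and tyrosine rates of
#' appearance and disappearance, meal-derived and endogenous appearance,
#' hydroxylation, protein synthesis, and the gram-per-day conversions, all
#' evaluated on consecutive sample pairs and timestamped at pair midpoints.
#' The fasting pair (-60, -30) yields the baseline midpoint at -45 min.
#'
#' @param concentrations Tibble with columns `time`, `analyte`
#'   (`"phe"`, `"tyr"`), `concentration` (umol/L) for the arterial site.
#' @param enrichments Tibble with columns `time`, `analyte`,
#'   `isotopologue`, `ttr` for the arterial site. If `background_correct`
#'   is `TRUE` the table must include the pre-infusion sample at
#'   `reference_time`.
#' @param subject List or one-row data frame with `body_weight` and
#'   `lean_mass` (kg).
#' @param protocol_phe,protocol_tyr [tracer_protocol()] objects.
#' @param meal A [meal_spec()].
#' @param constants A [kinetics_constants()].
#' @param oral_mode Passed to [oral_ra()].
#' @param endo_mode Passed to [endogenous_ra()].
#' @param background_correct Subtract the background sample first
#'   (default `TRUE`); set `FALSE` for pre-corrected enrichments.
#' @param reference_time Background sample time (default -150).
#'
#' @return A tibble of class `kinetics_result`: one row per midpoint with
#'   columns `t1`, `t2`, `midpoint`, `phase`, `ra_total`, `rd_total`,
#'   `ra_oral`, `ra_endo`, `hydroxylation`, `synthesis`, `ra_total_tyr`,
#'   `synthesis_g_day`, `degradation_g_day`, `net_gain_g_day`. Attributes
#'   carry the subject, infusion rates and modes.
#' @export
wholebody_kinetics <- function(concentrations, enrichments, subject,
                               protocol_phe, protocol_tyr, meal,
                               constants = kinetics_constants(),
                               oral_mode = c("corrected", "printed"),
                               endo_mode = c("simple", "subtract_tracer"),
                               background_correct = TRUE,
                               reference_time = -150) {
  oral_mode <- match.arg(oral_mode)
  endo_mode <- match.arg(endo_mode)
  subject <- as.list(subject)
  pv_eff <- effective_pool_volume(subject$body_weight, subject$lean_mass, constants)
  f_phe <- protocol_infusion_rate(protocol_phe, subject$lean_mass)
  f_tyr <- protocol_infusion_rate(protocol_tyr, subject$lean_mass)

  if (background_correct) {
    enrichments <- correct_background(enrichments, reference_time = reference_time)
  } else {
    enrichments <- dplyr::filter(enrichments, .data$time != reference_time)
  }

  chan <- function(channel) pooled_ttr(enrichments, channel)
  conc_of <- function(a) {
    sel <- concentrations$analyte == a &
      concentrations$time != reference_time &
      !is.na(concentrations$concentration)
    concentrations[sel, c("time", "concentration")]
  }
  assemble <- function(cc, ch1, ch2, name2) {
    tt <- sort(intersect(intersect(cc$time, ch1$time), ch2$time))
    out <- tibble::tibble(
      time = tt,
      concentration = cc$concentration[match(tt, cc$time)],
      ttr = ch1$ttr[match(tt, ch1$time)]
    )
    out[[name2]] <- ch2$ttr[match(tt, ch2$time)]
    out[stats::complete.cases(out), ]
  }
  phe <- assemble(conc_of("phe"), chan("phe_d8d7"), chan("phe_d5"), "ttr_d5")
  tyr <- assemble(conc_of("tyr"), chan("tyr_d2"), chan("tyr_d7d6"), "ttr_d7d6")

  pp <- .pairwise(phe)
  pt <- .pairwise(tyr)
  common <- intersect(pp$midpoint, pt$midpoint)
  if (length(common) < 1) {
    stop("wholebody_kinetics: phenylalanine and tyrosine series share no midpoints",
         call. = FALSE)
  }
  pp <- dplyr::filter(pp, .data$midpoint %in% common)
  pt <- dplyr::filter(pt, .data$midpoint %in% common)

  ra_total <- steele_ra(f_phe, pv_eff, pp$t1, pp$t2,
                        pp$concentration_1, pp$concentration_2,
                        pp$ttr_1, pp$ttr_2)
  rd_total <- steele_rd(ra_total, pv_eff, pp$t1, pp$t2,
                        pp$concentration_1, pp$concentration_2)
  raw_oral <- oral_ra(ra_total, pv_eff, pp$t1, pp$t2,
                      pp$concentration_1, pp$concentration_2,
                      pp$ttr_d5_1, pp$ttr_d5_2,
                      r = meal$d5_to_tracee_ratio_r, mode = oral_mode)
  ra_endo <- endogenous_ra(ra_total, raw_oral, f = f_phe, mode = endo_mode)
  ra_tyr <- steele_ra(f_tyr, pv_eff, pt$t1, pt$t2,
                      pt$concentration_1, pt$concentration_2,
                      pt$ttr_1, pt$ttr_2)
  hydrox <- hydroxylation_rate(ra_tyr,
                               (pt$ttr_d7d6_1 + pt$ttr_d7d6_2) / 2,
                               pp$ttr_1, pp$ttr_2)
  synth <- protein_synthesis_rate(rd_total, hydrox)
  synth_g <- to_grams_per_day(synth, constants)
  degr_g <- to_grams_per_day(ra_endo, constants)

  out <- tibble::tibble(
    t1 = pp$t1, t2 = pp$t2, midpoint = pp$midpoint,
    phase = dplyr::case_when(
      pp$t2 <= 0 ~ "fasting",
      pp$t1 < 0 ~ "transition",
      TRUE ~ "postprandial"
    ),
    ra_total = ra_total, rd_total = rd_total,
    ra_oral = raw_oral, ra_endo = ra_endo,
    hydroxylation = hydrox, synthesis = synth,
    ra_total_tyr = ra_tyr,
    synthesis_g_day = synth_g,
    degradation_g_day = degr_g,
    net_gain_g_day = net_protein_gain(synth_g, degr_g)
  )
  structure(out,
            class = c("kinetics_result", class(out)),
            subject = subject,
            f_phe = f_phe, f_tyr = f_tyr, pv_eff = pv_eff,
            meal = meal,
            oral_mode = oral_mode, endo_mode = endo_mode)
}
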