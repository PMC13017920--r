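#' Physiological and unit constants for tracer kinetics
#'
#' Bundles the constants shared by every kinetic equation in the package:
#' the Steele pool fraction, the phenylalanine content of mixed protein used
#' to convert phenylalanine fluxes to protein mass, and the unit-conversion
#' factors of the insulin-sensitivity indices.
#'
#' @param pool_fraction_pv Effective fraction of the distribution volume
#'   assumed to exchange rapidly, in L per kg *body weight* (default 0.125).
#' @param phe_per_gram_protein Average phenylalanine content of mixed body
#'   protein, in umol phenylalanine per g protein (default 273).
#' @param homa_denominator HOMA-IR normalisation constant (default 22.5).
#' @param insulin_conversion pmol/L per uU/mL (default 7.18).
#' @param glucose_conversion mg/dL per mmol/L (default 18).
#' @param minutes_per_day Minutes in a day (default 1440).
#'
#' @return A list of class `kinetics_constants`.
#' @examples
#' kinetics_constants()
#' @export
kinetics_constants <- function(pool_fraction_pv = 0.125,
                               phe_per_gram_protein = 273,
                               homa_denominator = 22.5,
                               insulin_conversion = 7.18,
                               glucose_conversion = 18,
                               minutes_per_day = 1440) {
  out <- list(
    pool_fraction_pv = pool_fraction_pv,
    phe_per_gram_protein = phe_per_gram_protein,
    homa_denominator = homa_denominator,
    insulin_conversion = insulin_conversion,
    glucose_conversion = glucose_conversion,
    minutes_per_day = minutes_per_day
  )
  bad <- names(out)[!vapply(out, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    stop("kinetics_constants: all constants must be single positive numbers; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(out, class = "kinetics_constants")
}

#' Blood-sampling time grid of the study design
#'
#' Times are minutes relative to meal ingestion (meal at 0). The -150 min
#' sample precedes the tracer prime and measures background enrichment;
#' -60 and -30 min are the fasting samples; 10..360 min are postprandial.
#'
#' @return Integer vector of sampling times in minutes.
#' @export
study_grid <- function() {
  c(-150L, -60L, -30L, 10L, 20L, 30L, 40L, 50L, 60L, 90L, 120L, 180L, 240L, 300L, 360L)
}

#' Effective pool volume per kg lean mass
#'
#' The pool fraction is defined per kg body weight while all fluxes are
#' normalised to lean mass; multiplying by body weight over lean mass puts
#' the Steele pool term on the same per-kg-lean-mass scale as the fluxes.
#'
#' @param body_weight Body weight in kg.
#' @param lean_mass Lean (fat-free) mass in kg; must satisfy
#'   `0 < lean_mass <= body_weight`.
#' @param constants A [kinetics_constants()] object.
#'
#' @return Effective pool volume in L per kg lean mass
#'   (`pool_fraction_pv * body_weight / lean_mass`).
#' @examples
#' effective_pool_volume(76, 50) # 0.19
#' @export
effective_pool_volume <- function(body_weight, lean_mass,
                                  constants = kinetics_constants()) {
  if (any(!is.finite(body_weight)) || any(body_weight <= 0)) {
    stop("effective_pool_volume: body_weight must be positive", call. = FALSE)
  }
  if (any(!is.finite(lean_mass)) || any(lean_mass <= 0)) {
    stop("effective_pool_volume: lean_mass must be positive", call. = FALSE)
  }
  if (any(lean_mass > body_weight)) {
    stop("effective_pool_volume: lean_mass cannot exceed body_weight", call. = FALSE)
  }
  constants$pool_fraction_pv * body_weight / lean_mass
}

#' Actual tracer infusion rate from infusate concentration and pump flow
#'
#' The delivered rate is reconstructed from the measured infusate
#' concentration and the pump flow rather than taken from the nominal
#' protocol, then normalised to lean mass.
#'
#' @param infusate_concentration Tracer concentration in the infusate,
#'   umol/mL.
#' @param pump_flow Pump flow rate, mL/min.
#' @param lean_mass Lean mass, kg.
#'
#' @return Infusion rate F in umol per kg lean mass per min.
#' @examples
#' actual_infusion_rate(30, 0.14, 60) # 0.07
#' @export
actual_infusion_rate <- function(infusate_concentration, pump_flow, lean_mass) {
  if (any(!is.finite(lean_mass)) || any(lean_mass <= 0)) {
    stop("actual_infusion_rate: lean_mass must be positive", call. = FALSE)
  }
  if (any(infusate_concentration < 0) || any(pump_flow < 0)) {
    stop("actual_infusion_rate: concentration and flow must be non-negative", call. = FALSE)
  }
  infusate_concentration * pump_flow / lean_mass
}

#' Tracer protocol description
#'
#' @param tracer_id `"phe_d8"` or `"tyr_d2"`.
#' @param prime Priming bolus, umol per kg lean mass.
#' @param continuous_rate_nominal Nominal continuous rate, umol/kg lean
#'   mass/min.
#' @param infusate_concentration Measured infusate concentration, umol/mL
#'   (optional; used by [actual_infusion_rate()]).
#' @param pump_flow Pump flow, mL/min (optional).
#'
#' @return A list of class `tracer_protocol`.
#' @export
tracer_protocol <- function(tracer_id = c("phe_d8", "tyr_d2"),
                            prime,
                            continuous_rate_nominal,
                            infusate_concentration = NA_real_,
                            pump_flow = NA_real_) {
  tracer_id <- match.arg(tracer_id)
  stopifnot(prime >= 0, continuous_rate_nominal >= 0)
  if (!is.na(infusate_concentration) && infusate_concentration < 0) {
    stop("tracer_protocol: infusate_concentration must be >= 0", call. = FALSE)
  }
  if (!is.na(pump_flow) && pump_flow < 0) {
    stop("tracer_protocol: pump_flow must be >= 0", call. = FALSE)
  }
  structure(list(
    tracer_id = tracer_id,
    prime = prime,
    continuous_rate_nominal = continuous_rate_nominal,
    infusate_concentration = infusate_concentration,
    pump_flow = pump_flow
  ), class = "tracer_protocol")
}

#' Infusion rate for a subject under a protocol
#'
#' Uses the measured infusate concentration and pump flow when both are
#' available, otherwise falls back to the nominal continuous rate.
#'
#' @param protocol A [tracer_protocol()].
#' @param lean_mass Lean mass, kg.
#' @return Rate in umol/kg lean mass/min.
#' @export
protocol_infusion_rate <- function(protocol, lean_mass) {
  stopifnot(inherits(protocol, "tracer_protocol"))
  if (!is.na(protocol$infusate_concentration) && !is.na(protocol$pump_flow)) {
    actual_infusion_rate(protocol$infusate_concentration, protocol$pump_flow, lean_mass)
  } else {
    protocol$continuous_rate_nominal
  }
}

#' Meal composition and labelling
#'
#' @param casein_grams Grams of intrinsically labelled casein in the meal.
#' @param d5_to_tracee_ratio_r Ratio r of ring-D5-phenylalanine to unlabelled
#'   phenylalanine in the meal protein (0 < r < 1).
#' @param total_phe_ingested Total phenylalanine ingested, umol.
#' @param energy_kcal Meal energy, kcal.
#' @param volume_ml Meal volume, mL.
#' @param ingestion_time Minute of ingestion (0 by convention).
#'
#' @return A list of class `meal_spec`.
#' @export
meal_spec <- function(casein_grams = 26,
                      d5_to_tracee_ratio_r = 0.08,
                      total_phe_ingested = 7900,
                      energy_kcal = 631,
                      volume_ml = 400,
                      ingestion_time = 0) {
  if (!(d5_to_tracee_ratio_r > 0 && d5_to_tracee_ratio_r < 1)) {
    stop("meal_spec: d5_to_tracee_ratio_r must lie in (0, 1)", call. = FALSE)
  }
  if (total_phe_ingested <= 0) {
    stop("meal_spec: total_phe_ingested must be positive", call. = FALSE)
  }
  structure(list(
    casein_grams = casein_grams,
    d5_to_tracee_ratio_r = d5_to_tracee_ratio_r,
    total_phe_ingested = total_phe_ingested,
    energy_kcal = energy_kcal,
    volume_ml = volume_ml,
    ingestion_time = ingestion_time
  ), class = "meal_spec")
}

# Isotopologue channels used throughout: the transamination product D7-phe is
# pooled with the infused D8-phe, and D7-/D6-tyrosine (hydroxylation products
# of D8-/D7-phe) are pooled likewise. phe_all is the FSR precursor channel.
.ttr_channels <- list(
  phe_d8d7 = list(analyte = "phe", isotopologues = c("d8", "d7")),
  phe_d5   = list(analyte = "phe", isotopologues = "d5"),
  phe_all  = list(analyte = "phe", isotopologues = c("d5", "d7", "d8")),
  tyr_d2   = list(analyte = "tyr", isotopologues = "d2"),
  tyr_d7d6 = list(analyte = "tyr", isotopologues = c("d7", "d6"))
)

#' Pooled tracer-to-tracee ratio for a measurement channel
#'
#' Sums the isotopologue TTRs that are analysed jointly: D8 + D7
#' phenylalanine (`"phe_d8d7"`), D7 + D6 tyrosine (`"tyr_d7d6"`), the
#' meal label D5 phenylalanine (`"phe_d5"`), the infused D2 tyrosine
#' (`"tyr_d2"`), and the D5 + D7 + D8 phenylalanine precursor pool
#' (`"phe_all"`).
#'
#' @param enrichments A data frame with columns `time`, `analyte`,
#'   `isotopologue`, `ttr` (other columns such as `subject_id`, `visit`,
#'   `site` are carried through as grouping keys).
#' @param channel One of `"phe_d8d7"`, `"phe_d5"`, `"phe_all"`,
#'   `"tyr_d2"`, `"tyr_d7d6"`.
#'
#' @return A tibble with the grouping keys, `time`, and the pooled `ttr`.
#'   An error is raised if a required isotopologue is absent or missing
#'   (TTRs are never silently zero-filled).
#' @examples
#' e <- tibble::tibble(time = c(10, 10), analyte = "phe",
#'                     isotopologue = c("d8", "d7"), ttr = c(0.05, 0.005))
#' pooled_ttr(e, "phe_d8d7")
#' @export
pooled_ttr <- function(enrichments, channel) {
  if (!channel %in% names(.ttr_channels)) {
    stop("pooled_ttr: unknown channel '", channel, "'; choose one of ",
         paste(names(.ttr_channels), collapse = ", "), call. = FALSE)
  }
  need <- c("time", "analyte", "isotopologue", "ttr")
  miss <- setdiff(need, names(enrichments))
  if (length(miss) > 0) {
    stop("pooled_ttr: enrichment table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ch <- .ttr_channels[[channel]]
  keys <- setdiff(names(enrichments), c("isotopologue", "ttr"))
  sub <- dplyr::filter(enrichments,
                       .data$analyte == ch$analyte,
                       .data$isotopologue %in% ch$isotopologues)
  if (nrow(sub) == 0) {
    stop("pooled_ttr: no '", ch$analyte, "' rows with isotopologue(s) ",
         paste(ch$isotopologues, collapse = "+"), " for channel '", channel, "'",
         call. = FALSE)
  }
  out <- sub |>
    dplyr::summarise(
      n_iso = dplyr::n_distinct(.data$isotopologue),
      any_na = anyNA(.data$ttr),
      ttr = sum(.data$ttr),
      .by = dplyr::all_of(keys)
    )
  if (any(out$n_iso != length(ch$isotopologues)) || any(out$any_na)) {
    bad <- out$time[out$n_iso != length(ch$isotopologues) | out$any_na]
    stop("pooled_ttr: channel '", channel, "' has missing isotopologue TTRs at time(s) ",
         paste(utils::head(unique(bad), 5), collapse = ", "), call. = FALSE)
  }
  dplyr::select(out, -dplyr::all_of(c("n_iso", "any_na")))
}

#' Subtract background (natural-abundance) enrichment
#'
#' Subtracts the enrichment measured in the pre-infusion background sample
#' from every TTR of the same isotopologue. By default the background is
#' the -150 min sample, taken once per subject-visit (the sampling site of
#' the background draw differs from the later sites, so the reference is
#' matched on analyte and isotopologue only within subject and visit); set
#' `by` to also match on `site`. If enrichments were already
#' background-corrected upstream, simply do not call this function.
#'
#' @param enrichments Data frame with columns `time`, `analyte`,
#'   `isotopologue`, `ttr` and optionally `subject_id`, `visit`, `site`.
#' @param reference_time Time of the background sample (default -150).
#' @param by Character vector of columns (besides `analyte` and
#'   `isotopologue`) defining which rows share one background sample.
#'
#' @return The input with `ttr` background-subtracted and the reference
#'   rows removed.
#' @export
correct_background <- function(enrichments, reference_time = -150,
                               by = intersect(c("subject_id", "visit"),
                                              names(enrichments))) {
  keys <- c(by, "analyte", "isotopologue")
  is_ref <- enrichments$time == reference_time
  if (!any(is_ref)) {
    stop("correct_background: no background sample at time ", reference_time,
         call. = FALSE)
  }
  key_of <- function(df) do.call(paste, c(df[keys], sep = "\r"))
  ref <- enrichments[is_ref, ]
  bg <- tapply(ref$ttr, key_of(ref), mean)
  out <- enrichments[!is_ref, ]
  adj <- as.vector(bg[key_of(out)])
  adj[is.na(adj)] <- 0
  out$ttr <- out$ttr - adj
  out
}
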