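#' HOMA-IR insulin-resistance index
#'
#' `HOMA-IR = glucose * insulin / (22.5 * 7.18)` with fasting glucose in
#' mmol/L and fasting insulin in pmol/L (7.18 converts pmol/L to uU/mL).
#'
#' @param fasting_glucose Fasting glucose, mmol/L.
#' @param fasting_insulin Fasting insulin, pmol/L.
#' @param constants A [kinetics_constants()] object.
#' @return HOMA-IR (dimensionless).
#' @examples
#' homa_ir(5.30, 31.6) # 1.0367
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin,
                    constants = kinetics_constants()) {
  if (any(fasting_glucose <= 0) || any(fasting_insulin <= 0)) {
    stop("homa_ir: fasting glucose and insulin must be positive", call. = FALSE)
  }
  fasting_glucose * fasting_insulin /
    (constants$homa_denominator * constants$insulin_conversion)
}

#' Matsuda whole-body insulin-sensitivity index
#'
#' \deqn{Matsuda = \frac{10000}{\sqrt{(G_f \times 18)(I_f / 7.18)
#'   (\bar G \times 18)(\bar I / 7.18)}}}
#' with glucose in mmol/L (x18 to mg/dL) and insulin in pmol/L (/7.18 to
#' uU/mL). Post-meal means are taken over the supplied 0-120 min series;
#' because sampling is non-uniform the default is the time-weighted
#' trapezoid mean (`mean_method = "arithmetic"` for the plain mean).
#'
#' @param fasting_glucose,fasting_insulin Fasting values, mmol/L and pmol/L.
#' @param time Post-meal sample times, min (values outside 0-120 are
#'   dropped).
#' @param glucose,insulin Post-meal series at `time`, mmol/L and pmol/L.
#' @param constants A [kinetics_constants()] object.
#' @param mean_method `"trapezoid"` (default) or `"arithmetic"`.
#' @return Matsuda index (dimensionless).
#' @examples
#' matsuda(5.0, 36, c(0, 120), c(7, 7), c(180, 180)) # 8.376
#' @export
matsuda <- function(fasting_glucose, fasting_insulin, time, glucose, insulin,
                    constants = kinetics_constants(),
                    mean_method = c("trapezoid", "arithmetic")) {
  mean_method <- match.arg(mean_method)
  if (fasting_glucose <= 0 || fasting_insulin <= 0) {
    stop("matsuda: fasting glucose and insulin must be positive", call. = FALSE)
  }
  keep <- time >= 0 & time <= 120 & !is.na(glucose) & !is.na(insulin)
  t <- time[keep]
  if (length(t) < 1 || any(glucose[keep] <= 0) || any(insulin[keep] <= 0)) {
    stop("matsuda: need positive glucose/insulin samples inside 0-120 min",
         call. = FALSE)
  }
  avg <- function(y) {
    if (length(t) == 1 || mean_method == "arithmetic") {
      mean(y)
    } else {
      o <- order(t)
      pracma::trapz(t[o], y[keep][o]) / (max(t) - min(t))
    }
  }
  g_mean <- avg(glucose[keep])
  i_mean <- avg(insulin[keep])
  gc <- constants$glucose_conversion
  ic <- constants$insulin_conversion
  10000 / sqrt((fasting_glucose * gc) * (fasting_insulin / ic) *
                 (g_mean * gc) * (i_mean / ic))
}

#' Trapezoid area under the curve with missing-value imputation
#'
#' Computes the trapezoid AUC of a time series over a range. Interior
#' missing values are linearly interpolated first
#' (`imputation = "linear"`); leading or trailing missing values inside
#' the range are an error (no extrapolation). `kind = "incremental"`
#' subtracts a baseline value (see [baseline_summary()]) before
#' integrating, so a series constantly at baseline has incremental AUC 0.
#'
#' @param time Sample times, min.
#' @param value Values at `time` (may contain `NA`).
#' @param range Integration range `c(lo, hi)`; defaults to the full time
#'   range.
#' @param imputation `"linear"` (default) or `"none"` (any `NA` in range
#'   is an error).
#' @param kind `"total"` (default) or `"incremental"`.
#' @param baseline Baseline value to subtract for `kind = "incremental"`.
#' @return The AUC (value x min).
#' @examples
#' auc_trapezoid(c(0, 60, 120, 180), c(0, 1, 1, 0)) # 120
#' auc_trapezoid(c(0, 60, 120), c(0, NA, 2))        # 120
#' @export
auc_trapezoid <- function(time, value, range = NULL,
                          imputation = c("linear", "none"),
                          kind = c("total", "incremental"),
                          baseline = NULL) {
  imputation <- match.arg(imputation)
  kind <- match.arg(kind)
  o <- order(time)
  time <- time[o]; value <- value[o]
  if (is.null(range)) range <- range(time)
  keep <- time >= range[1] & time <= range[2]
  t <- time[keep]; y <- value[keep]
  if (sum(!is.na(y)) < 2) {
    stop("auc_trapezoid: need at least 2 non-missing points in range",
         call. = FALSE)
  }
  if (anyNA(y)) {
    if (imputation == "none") {
      stop("auc_trapezoid: missing values present and imputation = 'none'",
           call. = FALSE)
    }
    if (is.na(y[1]) || is.na(y[length(y)])) {
      stop("auc_trapezoid: leading/trailing missing values in range; ",
           "linear imputation does not extrapolate", call. = FALSE)
    }
    y <- as.numeric(zoo::na.approx(zoo::zoo(y, t)))
  }
  if (kind == "incremental") {
    if (is.null(baseline)) {
      stop("auc_trapezoid: incremental AUC requires a baseline value",
           call. = FALSE)
    }
    y <- y - baseline
  }
  pracma::trapz(t, y)
}

#' Baseline value under the study's summarisation conventions
#'
#' Pre-meal baselines differ by quantity: amino-acid concentrations are
#' averaged over the -60 and -30 min samples, pair-midpoint kinetics use
#' the -45 min midpoint, and hormones use the -30 min sample.
#'
#' @param time Sample (or midpoint) times, min.
#' @param value Values at `time`.
#' @param quantity_kind `"concentration"`, `"kinetics"`, or `"hormone"`.
#' @return The baseline value.
#' @examples
#' baseline_summary(c(-60, -30, 10), c(100, 110, 150), "concentration") # 105
#' @export
baseline_summary <- function(time, value,
                             quantity_kind = c("concentration", "kinetics",
                                               "hormone")) {
  quantity_kind <- match.arg(quantity_kind)
  pick <- function(at) {
    v <- value[time == at]
    if (length(v) != 1 || is.na(v)) {
      stop("baseline_summary: required pre-meal value at ", at,
           " min is missing", call. = FALSE)
    }
    v
  }
  switch(quantity_kind,
         concentration = (pick(-60) + pick(-30)) / 2,
         kinetics = pick(-45),
         hormone = pick(-30))
}
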