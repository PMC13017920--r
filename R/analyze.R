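#' Run the full analysis battery on one simulated subject-visit
#'
#' Convenience wrapper used for parameter-recovery studies and worked
#' examples: feeds a [simulate_subject()] dataset through
#' [wholebody_kinetics()], [av_balance()] (leg, flow mode; adipose,
#' difference mode), [muscle_fsr()], [plasma_protein_fsr()],
#' [splanchnic_appearance()], and the insulin indices.
#'
#' @param subj A `synthetic_subject`.
#' @param oral_mode,endo_mode Passed to [wholebody_kinetics()].
#' @param constants A [kinetics_constants()].
#' @return A list with elements `wholebody` (a `kinetics_result`),
#'   `splanchnic`, `leg` and `adipose` (`av_balance_result`s),
#'   `muscle_fsr`, `plasma_fsr` (infused channel), `plasma_fsr_meal`,
#'   and `indices` (HOMA-IR and Matsuda).
#' @export
analyze_subject <- function(subj, oral_mode = "corrected",
                            endo_mode = "simple",
                            constants = kinetics_constants()) {
  stopifnot(inherits(subj, "synthetic_subject"))
  lm <- subj$subject$lean_mass
  site <- function(df, s) dplyr::filter(df, .data$site %in% s) |>
    dplyr::select(-dplyr::all_of("site"))

  art_conc <- site(subj$concentrations, "artery")
  art_enr_bg <- site(subj$enrichments, c("artery", "antecubital"))
  wb <- wholebody_kinetics(
    art_conc, art_enr_bg, as.list(subj$subject),
    subj$protocols$phe, subj$protocols$tyr, subj$meal,
    constants = constants, oral_mode = oral_mode, endo_mode = endo_mode
  )
  post <- dplyr::filter(wb, .data$midpoint > 0)
  spl <- splanchnic_appearance(post$midpoint, post$ra_oral, subj$meal, lm)

  enr_cor <- correct_background(subj$enrichments)
  leg <- av_balance(
    art_conc, site(subj$concentrations, "femoral_vein"),
    flow = subj$flow, lean_mass = lm,
    arterial_enrichments = dplyr::filter(enr_cor, .data$site == "artery"),
    venous_enrichments = dplyr::filter(enr_cor, .data$site == "femoral_vein"),
    channels = "phe_d8d7", mode = "flow"
  )
  adipose <- av_balance(
    art_conc, site(subj$concentrations, "epigastric_vein"),
    mode = "difference"
  )

  prec_all <- enr_cor |>
    dplyr::filter(.data$site == "artery") |>
    pooled_ttr("phe_all")
  mfsr <- muscle_fsr(subj$biopsy, precursor_series = prec_all)

  prec_inf <- enr_cor |>
    dplyr::filter(.data$site == "artery") |>
    pooled_ttr("phe_d8d7")
  prec_meal <- enr_cor |>
    dplyr::filter(.data$site == "artery") |>
    pooled_ttr("phe_d5")
  pp <- subj$plasma_protein
  pfsr <- plasma_protein_fsr(dplyr::filter(pp, .data$channel == "infused"),
                             prec_inf)
  pfsr_meal <- plasma_protein_fsr(dplyr::filter(pp, .data$channel == "meal"),
                                  prec_meal)

  horm <- subj$hormones
  gl <- dplyr::filter(horm, .data$analyte == "glucose")
  ins <- dplyr::filter(horm, .data$analyte == "insulin")
  gf <- gl$concentration[gl$time == -150]
  insf <- ins$concentration[ins$time == -150]
  gl_post <- dplyr::filter(gl, .data$time >= 0, .data$time <= 120)
  ins_post <- dplyr::filter(ins, .data$time >= 0, .data$time <= 120)
  indices <- tibble::tibble(
    homa_ir = homa_ir(gf, insf, constants),
    matsuda = matsuda(gf, insf, gl_post$time, gl_post$concentration,
                      ins_post$concentration, constants)
  )

  list(wholebody = wb, splanchnic = spl, leg = leg, adipose = adipose,
       muscle_fsr = mfsr, plasma_fsr = pfsr, plasma_fsr_meal = pfsr_meal,
       indices = indices)
}
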