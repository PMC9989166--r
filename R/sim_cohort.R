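#' Parameters for the synthetic cohort-table generator
#'
#' Emulates a longitudinal aggression study: two mouse lines (a
#' senescence-accelerated line, SAMP8, and its resistant control, SAMR1)
#' tested monthly, with a final-age treatment cross-over in which every animal
#' is tested under both vehicle and drug. Effects are additive on the log
#' scale of attack duration; exact zeros (sessions without any attack) are
#' injected with a configurable probability.
#'
#' @param n_per_genotype animals per line (>= 2).
#' @param ages_months test ages; the last age carries the cross-over.
#' @param genotype_effect additive log-scale shift for SAMP8 at ages >=
#'   `onset_age_months`.
#' @param onset_age_months age at which the genotype effect switches on.
#' @param treatment_effect additive log-scale shift under drug (negative =
#'   drug reduces attack duration).
#' @param baseline_log log-scale baseline of attack duration (log seconds).
#' @param subject_sd between-subject sd (log scale).
#' @param residual_sd within-subject session-to-session sd (log scale).
#' @param zero_prob probability any single session scores exactly 0 s.
#' @param crossover_age_months age tested under both vehicle and drug;
#'   defaults to the last entry of `ages_months`. Other ages are untreated.
#' @param seed random seed.
#' @return A list of class `sim_cohort_params`.
#' @export
sim_cohort_params <- function(n_per_genotype = 18L, ages_months = 4:7,
                              genotype_effect = 0.8, onset_age_months = 5L,
                              treatment_effect = -1.2, baseline_log = log(15),
                              subject_sd = 0.6, residual_sd = 0.5,
                              zero_prob = 0.1,
                              crossover_age_months = NULL, seed = 1L) {
  p <- list(n_per_genotype = as.integer(n_per_genotype),
            ages_months = as.integer(ages_months),
            genotype_effect = genotype_effect,
            onset_age_months = as.integer(onset_age_months),
            treatment_effect = treatment_effect,
            baseline_log = baseline_log,
            subject_sd = subject_sd, residual_sd = residual_sd,
            zero_prob = zero_prob,
            crossover_age_months =
              as.integer(crossover_age_months %||% max(ages_months)),
            seed = seed)
  if (p$n_per_genotype < 2L)
    stop_invalid("n_per_genotype must be >= 2")
  check_number(p$subject_sd, "subject_sd", min = 0)
  check_number(p$residual_sd, "residual_sd", min = 0)
  check_number(p$zero_prob, "zero_prob", min = 0, max = 1)
  if (!length(p$ages_months)) stop_invalid("ages_months must be non-empty")
  class(p) <- "sim_cohort_params"
  p
}

#' Simulate a long-format cohort table of attack durations
#'
#' One row per animal x age x treatment session. At the cross-over age every
#' animal contributes a vehicle and a drug session; at other ages a single
#' untreated session (`treatment = "none"`). Durations are lognormal with the
#' configured genotype/treatment shifts, clamped to the 600 s session length,
#' with exact zeros injected at rate `zero_prob`.
#'
#' @param params a [sim_cohort_params()] object.
#' @return A data frame of class `cohort_table` with columns `animal_id`,
#'   `genotype`, `age_months`, `treatment`, `session`, `attack_duration_s`.
#' @examples
#' head(simulate_cohort(sim_cohort_params(n_per_genotype = 4)))
#' @export
simulate_cohort <- function(params = sim_cohort_params()) {
  p <- params
  if (!inherits(p, "sim_cohort_params")) stop_invalid("invalid params object")
  with_seed(p$seed, {
    genos <- c("SAMR1", "SAMP8")
    ids <- unlist(lapply(genos, function(g)
      sprintf("%s_%02d", g, seq_len(p$n_per_genotype))))
    geno_of <- rep(genos, each = p$n_per_genotype)
    subj_int <- stats::rnorm(length(ids), 0, p$subject_sd)

    rows <- list()
    for (a in p$ages_months) {
      trts <- if (a == p$crossover_age_months) c("vehicle", "drug") else "none"
      for (tr in trts) {
        mu <- p$baseline_log +
          ifelse(geno_of == "SAMP8" & a >= p$onset_age_months,
                 p$genotype_effect, 0) +
          if (tr == "drug") p$treatment_effect else 0
        val <- exp(mu + subj_int + stats::rnorm(length(ids), 0, p$residual_sd))
        val <- pmin(val, 600)
        if (p$zero_prob > 0)
          val[stats::runif(length(val)) < p$zero_prob] <- 0
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = ids, genotype = geno_of, age_months = a,
          treatment = tr,
          session = if (tr == "none") sprintf("m%d", a)
                    else sprintf("m%d_%s", a, tr),
          attack_duration_s = val)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
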