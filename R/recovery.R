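#' Cooperativity (Log alpha-beta) parameter-recovery study
#'
#' Simulates seeded concentration--response surfaces from the operational
#' model parameterised by the reference pharmacology of an agonist
#' (vehicle potency and composite cooperativity; see
#' [reference_operational_pars()]), fits each dataset globally with the
#' default constraint set (`n = 1`, `logalpha = 0`), and returns the
#' per-dataset cooperativity estimates (mean over replicate fits).
#'
#' @param agonist reference agonist name (`"adenosine"`, `"NECA"`,
#'   `"CPA"`, `"BnOCPA"`).
#' @param n_seeds number of simulated datasets.
#' @param n_replicates replicates per dataset.
#' @param noise_sd response noise sd (0--100 normalized scale).
#' @param seed master seed; per-dataset seeds are drawn from it.
#' @return list with `estimates` (per-seed Logab), `median`, `truth`.
#' @export
logab_recovery_study <- function(agonist, n_seeds = 25L, n_replicates = 4L,
                                 noise_sd = 5, seed = 1L) {
  pars <- reference_operational_pars(agonist)
  set.seed(seed)
  dataset_seeds <- sample.int(1000000L, n_seeds)
  est <- vapply(dataset_seeds, function(s) {
    d <- gen_dose_response(pars, n_replicates = n_replicates,
                           noise_sd = noise_sd, seed = s, agonist = agonist)
    fit_operational_allosterism(d)$summary$logab
  }, numeric(1L))
  list(estimates = est, median = median(est), truth = pars$logab)
}

#' Potency (pEC50) parameter-recovery study
#'
#' Simulates seeded single-curve datasets from the unit-slope logistic
#' and refits them, returning the per-dataset potency estimates (mean
#' over replicate fits).
#'
#' @param pec50 generating potency (-log10 molar).
#' @param agonist_conc concentration grid (molar).
#' @param n_seeds,n_replicates,noise_sd,seed as in
#'   [logab_recovery_study()].
#' @param top,bottom generating asymptotes.
#' @return list with `estimates`, `median`, `truth`.
#' @export
pec50_recovery_study <- function(pec50, agonist_conc = 10^seq(-12, -6),
                                 n_seeds = 25L, n_replicates = 4L,
                                 noise_sd = 5, seed = 1L, top = 100,
                                 bottom = 0) {
  set.seed(seed)
  dataset_seeds <- sample.int(1000000L, n_seeds)
  est <- vapply(dataset_seeds, function(s) {
    d <- gen_logistic_dose_response(pec50, agonist_conc, top = top,
                                    bottom = bottom,
                                    n_replicates = n_replicates,
                                    noise_sd = noise_sd, seed = s)
    fit_logistic3(d)$summary$pec50
  }, numeric(1L))
  list(estimates = est, median = median(est), truth = pec50)
}
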