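#' Published reference pharmacology of A1R agonists with MIPS521
#'
#' Reference potency and cooperativity estimates for adenosine A1 receptor
#' orthosteric agonists modulated by the positive allosteric modulator
#' MIPS521: vehicle-condition pEC50 and composite cooperativity
#' Log(alpha*beta) from cAMP accumulation assays (mean +/- SEM of n = 4),
#' and pEC50 of Goa/Gob G protein dissociation (TRUPATH BRET2) with
#' vehicle or 10 nM MIPS521. These values parameterise the synthetic
#' generators in recovery studies.
#'
#' @return data frame with columns `assay` (`"cAMP"`, `"TRUPATH-Goa"`,
#'   `"TRUPATH-Gob"`), `agonist`, `modulator_conc` (molar, 0 = vehicle),
#'   `pec50`, `pec50_sem`, `logab`, `logab_sem` (cooperativity only for
#'   cAMP rows).
#' @export
a1r_reference_pharmacology <- function() {
  rbind(
    data.frame(assay = "cAMP",
               agonist = c("adenosine", "NECA", "CPA", "BnOCPA"),
               modulator_conc = 0,
               pec50 = c(7.85, 8.31, 8.56, 7.76),
               pec50_sem = c(0.07, 0.17, 0.09, 0.13),
               logab = c(1.30, 1.17, 1.35, 1.57),
               logab_sem = c(0.29, 0.19, 0.06, 0.28)),
    data.frame(assay = rep(c("TRUPATH-Goa", "TRUPATH-Gob"), each = 4L),
               agonist = rep(c("adenosine", "adenosine",
                               "BnOCPA", "BnOCPA"), 2L),
               modulator_conc = rep(c(0, 1e-8), 4L),
               pec50 = c(7.63, 8.33, 7.40, 7.92,
                         7.09, 8.66, 7.81, 7.65),
               pec50_sem = c(0.30, 0.30, 0.11, 0.12,
                             0.38, 0.46, 0.08, 0.13),
               logab = NA_real_, logab_sem = NA_real_))
}

#' Generator truth derived from the reference pharmacology
#'
#' Builds an [operational_pars()] set whose vehicle potency and composite
#' cooperativity match a cAMP reference row. The remaining parameters are
#' not constrained by the reference table and are set to one fixed,
#' realistic regime: `Em = 100` (normalized scale), `tauA = 3` (so the
#' vehicle curve plateaus at 75% of system maximum and
#' `pKA = pEC50 - log10(1 + tauA)`), modulator affinity `KB = 100 nM` and
#' weak direct agonism `tauB = 0.2`.
#'
#' @param agonist one of `"adenosine"`, `"NECA"`, `"CPA"`, `"BnOCPA"`.
#' @return an `operational_pars` list.
#' @export
reference_operational_pars <- function(agonist) {
  ref <- a1r_reference_pharmacology()
  row <- ref[ref$assay == "cAMP" & ref$agonist == agonist, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no cAMP reference row for agonist '", agonist, "'")
  tauA <- 3
  operational_pars(Em = 100, n = 1, tauA = tauA, tauB = 0.2,
                   pKA = row$pec50 - log10(1 + tauA), pKB = 7,
                   logab = row$logab, logalpha = 0)
}
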