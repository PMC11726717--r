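test_that("noiseless logistic data return the generating potency", {
  d <- gen_logistic_dose_response(8, n_replicates = 2, noise_sd = 0, seed = 1)
  fit <- fit_logistic3(d)
  expect_equal(fit$summary$pec50, 8, tolerance = 1e-4)
  expect_equal(fit$replicates$pec50, c(8, 8), tolerance = 1e-4)
  expect_true(all(fit$replicates$in_span))
})

test_that("constant responses are rejected as unidentifiable", {
  d <- gen_logistic_dose_response(8, n_replicates = 1, noise_sd = 0, seed = 1)
  d$response <- 42
  expect_error(fit_logistic3(d), "constant")
  d2 <- gen_logistic_dose_response(8, agonist_conc = 10^seq(-9, -7),
                                   n_replicates = 1, noise_sd = 0, seed = 1)
  expect_error(fit_logistic3(d2), "4 distinct")
})

test_that("logistic potency shifts by exactly 9 under M -> nM rescaling", {
  d <- gen_logistic_dose_response(8.2, n_replicates = 1, noise_sd = 0,
                                  seed = 2)
  d_nm <- d; d_nm$agonist_conc <- d$agonist_conc * 1e9
  f_m <- fit_logistic3(d)$summary$pec50
  f_nm <- fit_logistic3(d_nm)$summary$pec50
  expect_equal(f_m - f_nm, 9, tolerance = 1e-6)
})

test_that("operational model reduces to the agonism model at vehicle", {
  set.seed(71)
  for (k in 1:20) {
    pars <- operational_pars(Em = runif(1, 50, 150), n = runif(1, 0.5, 2),
                             tauA = 10^runif(1, -1, 2),
                             tauB = 10^runif(1, -2, 1),
                             pKA = runif(1, 6, 9), pKB = runif(1, 6, 8),
                             logab = runif(1, -1, 2))
    A <- 10^seq(-12, -5)
    tA <- pars$tauA * A
    KA <- 10^(-pars$pKA)
    agonism <- pars$Em * tA^pars$n / ((A + KA)^pars$n + tA^pars$n)
    full <- operational_response(A, 0, pars)
    expect_lt(max(abs(full - agonism) / agonism), 1e-12)
  }
})

test_that("noiseless surfaces return every free parameter", {
  pars <- operational_pars(Em = 100, tauA = 3, tauB = 0.2, pKA = 7.25,
                           pKB = 7, logab = 1.3)
  d <- gen_dose_response(pars, n_replicates = 1, noise_sd = 0, seed = 1)
  fit <- fit_operational_allosterism(d, per_replicate = FALSE)
  est <- fit$replicates
  expect_true(est$converged)
  for (p in c("Em", "tauA", "tauB", "pKA", "pKB"))
    expect_equal(est[[p]], pars[[p]], tolerance = 1e-3)
  expect_equal(est$logab, 1.3, tolerance = 1e-3)
})

test_that("null cooperativity is recovered as Logab = 0", {
  pars <- operational_pars(Em = 100, tauA = 3, tauB = 1e-8, pKA = 7.25,
                           pKB = 7, logab = 0)
  d <- gen_dose_response(pars, n_replicates = 1, noise_sd = 0, seed = 2)
  fit <- fit_operational_allosterism(d, per_replicate = FALSE)
  expect_equal(fit$summary$logab, 0, tolerance = 1e-3)
})

test_that("unit rescaling shifts pK values by 9 and leaves Logab fixed", {
  pars <- operational_pars(Em = 100, tauA = 3, tauB = 0.2, pKA = 7.25,
                           pKB = 7, logab = 1.3)
  d <- gen_dose_response(pars, n_replicates = 1, noise_sd = 0, seed = 3)
  d_nm <- d
  d_nm$agonist_conc <- d$agonist_conc * 1e9
  d_nm$modulator_conc <- d$modulator_conc * 1e9
  f_m <- fit_operational_allosterism(d, per_replicate = FALSE)$replicates
  f_nm <- fit_operational_allosterism(d_nm, per_replicate = FALSE)$replicates
  expect_equal(f_m$pKA - f_nm$pKA, 9, tolerance = 1e-3)
  expect_equal(f_m$pKB - f_nm$pKB, 9, tolerance = 1e-3)
  expect_equal(f_m$logab, f_nm$logab, tolerance = 1e-3)
})

test_that("aliased cooperativity constraints are rejected by name", {
  pars <- operational_pars()
  d <- gen_dose_response(pars, n_replicates = 1, noise_sd = 0, seed = 4)
  expect_error(fit_operational_allosterism(d, fixed = c(n = 1)),
               "alpha.*beta.*aliased|aliased")
  expect_error(
    fit_operational_allosterism(d[d$modulator_conc %in% c(0, 1e-7), ]),
    "3 modulator")
})

test_that("logab arithmetic and guards", {
  expect_equal(logab(10, 1), 1)
  expect_equal(logab(1, 1), 0)
  expect_equal(logab(2, 18.6), log10(37.2))
  expect_equal(logab(2, 18.6), 1.5705, tolerance = 1e-4)
  expect_error(logab(-1, 2), "positive")
})

test_that("median cooperativity error stays below the reference SEM", {
  study <- logab_recovery_study("adenosine", n_seeds = 100, seed = 7)
  ref <- a1r_reference_pharmacology()
  sem <- ref$logab_sem[ref$assay == "cAMP" & ref$agonist == "adenosine"]
  expect_lt(median(abs(study$estimates - study$truth)), sem)
})

test_that("Dunnett comparisons flag shifts and respect the raw-p bound", {
  set.seed(72)
  tab <- expand.grid(agonist = c("A1", "A2"),
                     modulator_conc = c(0, 1e-8, 1e-7),
                     replicate = 1:4, KEEP.OUT.ATTRS = FALSE)
  tab$pec50 <- 7.8 + rnorm(nrow(tab), sd = 0.1)
  # identical-to-control condition: adjusted p near 1
  cmp <- compare_conditions(tab, control = 0)
  expect_true(all(cmp$dunnett$p_adj >= cmp$dunnett$p_raw - 1e-12))
  expect_true(all(cmp$dunnett$p_adj > 0.05))
  # a 5-SD shift is detected
  tab2 <- tab
  sel <- tab2$agonist == "A1" & tab2$modulator_conc == 1e-7
  tab2$pec50[sel] <- tab2$pec50[sel] + 0.5
  cmp2 <- compare_conditions(tab2, control = 0)
  hit <- cmp2$dunnett[cmp2$dunnett$agonist == "A1" &
                        grepl("1e-07", cmp2$dunnett$contrast), ]
  expect_lt(hit$p_adj, 0.05)
  expect_match(hit$stars, "\\*")
  # single-replicate conditions are excluded with a warning
  tab3 <- rbind(tab, data.frame(agonist = "A1", modulator_conc = 1e-6,
                                replicate = 1, pec50 = 8))
  expect_warning(compare_conditions(tab3, control = 0), "single replicate")
})

test_that("Dunnett family-wise error stays near nominal under the null", {
  set.seed(73)
  fwe <- mean(vapply(1:100, function(i) {
    tab <- expand.grid(agonist = "A", modulator_conc = c(0, 1, 2, 3, 4),
                       replicate = 1:4, KEEP.OUT.ATTRS = FALSE)
    tab$pec50 <- rnorm(nrow(tab))
    cmp <- compare_conditions(tab, control = 0)
    any(cmp$dunnett$p_adj < 0.05)
  }, logical(1)))
  expect_lte(fwe, 0.07)
})
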