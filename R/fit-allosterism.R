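#' Globally fit the operational model of allosterism
#'
#' Fits the full agonist x modulator response surface (all modulator
#' concentrations simultaneously, vehicle included) by
#' Levenberg--Marquardt least squares, replicate by replicate, and
#' summarises the composite cooperativity Log(alpha*beta) across
#' replicates as mean +/- SEM.
#'
#' The default constraint set fixes the transducer slope `n = 1` and
#' `logalpha = 0`: functional data identify cooperativity only as the
#' product alpha*beta, so the model is parameterised in `logab` directly
#' and alpha/beta are split only under user-supplied constraints (e.g.
#' `fixed = c(logalpha = 0.3)` from binding data). Freeing `logalpha` and
#' `logab` together is rejected as unidentifiable.
#'
#' Starting values are derived from per-curve logistic fits (vehicle
#' potency, potency shift at the highest modulator concentration) with a
#' small multi-start grid over the agonist efficacy; the best
#' residual-sum-of-squares solution is kept.
#'
#' @param data an `allodyn_dose_response` for one agonist across
#'   modulator concentrations (vehicle rows have `modulator_conc = 0`).
#' @param fixed named vector of parameters held fixed, on the natural
#'   scale of [operational_pars()] names (`Em`, `n`, `tauA`, `tauB`,
#'   `pKA`, `pKB`, `logab`, `logalpha`).
#' @param per_replicate fit each replicate separately (the convention
#'   behind "mean +/- SEM of n = 4" tables); `FALSE` pools all rows into
#'   one fit.
#' @param start optional named overrides for starting values (natural
#'   scale).
#' @return an `allodyn_allostery_fit`: list with `replicates` (per-fit
#'   parameter estimates, `logab_se` from the fit covariance, `rss`,
#'   `converged`) and `summary` (`logab` mean, `logab_se` SEM across
#'   replicates -- or the fit SE for a single pooled fit -- and the
#'   agonist parameters).
#' @export
fit_operational_allosterism <- function(data,
                                        fixed = c(n = 1, logalpha = 0),
                                        per_replicate = TRUE,
                                        start = NULL) {
  data <- as_dose_response(as.data.frame(data))
  bvals <- sort(unique(data$modulator_conc))
  if (length(bvals) < 3L || bvals[1L] != 0)
    stop("need at least 3 modulator concentrations including vehicle (0)")
  par_names <- c("Em", "n", "tauA", "tauB", "pKA", "pKB", "logab", "logalpha")
  if (!all(names(fixed) %in% par_names))
    stop("unknown parameter(s) in constraints: ",
         paste(setdiff(names(fixed), par_names), collapse = ", "))
  free <- setdiff(par_names, names(fixed))
  if (all(c("logalpha", "logab") %in% free))
    stop("unidentifiable constraint set: alpha and beta are aliased ",
         "(functional data identify only the product alpha*beta); fix ",
         "'logalpha' (default 0) or 'logab'")
  reps <- if (per_replicate) sort(unique(data$replicate)) else list(NULL)
  fits <- lapply(reps, function(r) {
    d <- if (is.null(r)) data else data[data$replicate == r, , drop = FALSE]
    fit_surface(d, fixed, free, start, replicate = if (is.null(r)) NA else r)
  })
  reps_df <- do.call(rbind, fits)
  rownames(reps_df) <- NULL
  ok <- reps_df[reps_df$converged, , drop = FALSE]
  if (!nrow(ok)) stop("no operational-model fit converged")
  n_ok <- nrow(ok)
  summary <- data.frame(
    n = n_ok,
    logab = mean(ok$logab),
    logab_se = if (n_ok > 1L) sd(ok$logab) / sqrt(n_ok) else ok$logab_se,
    Em = mean(ok$Em), tauA = mean(ok$tauA), tauB = mean(ok$tauB),
    pKA = mean(ok$pKA), pKB = mean(ok$pKB))
  summary$label <- sprintf("%.2f ± %.2f", summary$logab, summary$logab_se)
  structure(list(replicates = reps_df, summary = summary, fixed = fixed),
            class = "allodyn_allostery_fit")
}

#' @export
print.allodyn_allostery_fit <- function(x, ...) {
  cat("<allodyn_allostery_fit> Log(alphabeta) = ", x$summary$label,
      " (n = ", x$summary$n, ")\n", sep = "")
  invisible(x)
}

# transformed parameter space: positive scale parameters fitted in log10
to_theta <- function(p) c(log10_Em = log10(p[["Em"]]), n = p[["n"]],
                          log10_tauA = log10(p[["tauA"]]),
                          log10_tauB = log10(max(p[["tauB"]], 1e-8)),
                          pKA = p[["pKA"]], pKB = p[["pKB"]],
                          logab = p[["logab"]], logalpha = p[["logalpha"]])

theta_names <- c(Em = "log10_Em", n = "n", tauA = "log10_tauA",
                 tauB = "log10_tauB", pKA = "pKA", pKB = "pKB",
                 logab = "logab", logalpha = "logalpha")

theta_to_pars <- function(theta) {
  operational_pars(Em = 10^theta[["log10_Em"]], n = theta[["n"]],
                   tauA = 10^theta[["log10_tauA"]],
                   tauB = 10^theta[["log10_tauB"]],
                   pKA = theta[["pKA"]], pKB = theta[["pKB"]],
                   logab = theta[["logab"]],
                   logalpha = theta[["logalpha"]])
}

fit_surface <- function(d, fixed, free, start, replicate) {
  base <- derive_starts(d)
  base[names(fixed)] <- fixed
  if (!is.null(start)) base[names(start)] <- start
  tau_grid <- if ("tauA" %in% free) c(base[["tauA"]], 0.5, 30) else base[["tauA"]]
  free_t <- unname(theta_names[free])
  best <- NULL
  for (tauA0 in tau_grid) {
    p0 <- base
    p0[["tauA"]] <- tauA0
    # keep the vehicle potency consistent with the trial efficacy
    if (!"pKA" %in% names(fixed))
      p0[["pKA"]] <- base[["vehicle_pec50"]] - log10(1 + tauA0)
    th0 <- to_theta(p0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = th0[free_t],
        fn = function(th) {
          full <- th0; full[free_t] <- th
          d$response - operational_response(d$agonist_conc,
                                            d$modulator_conc,
                                            theta_to_pars(full))
        },
        control = minpack.lm::nls.lm.control(maxiter = 400,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss, th0 = th0)
    }
  }
  if (is.null(best))
    return(data.frame(replicate = replicate, Em = NA, n = NA, tauA = NA,
                      tauB = NA, pKA = NA, pKB = NA, alpha = NA, beta = NA,
                      logab = NA, logab_se = NA, rss = NA,
                      converged = FALSE))
  th <- best$th0
  th[names(coef(best$fit))] <- coef(best$fit)
  pars <- theta_to_pars(th)
  se <- rep(NA_real_, length(free_t)); names(se) <- free_t
  sm <- tryCatch(summary(best$fit), error = function(e) NULL)
  if (!is.null(sm)) se[rownames(sm$coefficients)] <-
      sm$coefficients[, "Std. Error"]
  logab_se <- if ("logab" %in% free_t) unname(se["logab"]) else 0
  data.frame(replicate = replicate, Em = pars$Em, n = pars$n,
             tauA = pars$tauA, tauB = pars$tauB, pKA = pars$pKA,
             pKB = pars$pKB, alpha = 10^pars$logalpha,
             beta = 10^(pars$logab - pars$logalpha), logab = pars$logab,
             logab_se = logab_se, rss = best$rss,
             converged = best$fit$info %in% 1:4)
}

# data-driven starting values from per-curve logistic fits
derive_starts <- function(d) {
  veh <- d[d$modulator_conc == 0, , drop = FALSE]
  v <- fit_one_logistic(veh$agonist_conc, veh$response)
  bmax <- max(d$modulator_conc)
  hi <- d[d$modulator_conc == bmax, , drop = FALSE]
  h <- tryCatch(fit_one_logistic(hi$agonist_conc, hi$response),
                error = function(e) list(pec50 = NA))
  shift <- if (is.finite(h$pec50 %||% NA) && is.finite(v$pec50 %||% NA))
    max(h$pec50 - v$pec50, 0.05) else 1
  nz <- d$modulator_conc[d$modulator_conc > 0]
  tauA0 <- 3
  c(Em = max(max(d$response), v$top %||% max(d$response)) * 1.1,
    n = 1, tauA = tauA0, tauB = 0.2,
    pKA = (v$pec50 %||% 7) - log10(1 + tauA0),
    pKB = -log10(exp(mean(log(nz)))),
    logab = shift, logalpha = 0,
    vehicle_pec50 = v$pec50 %||% 7)
}
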