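#' Fit the 3-parameter logistic equation (Hill slope 1)
#'
#' Fits `response = bottom + (top - bottom) / (1 + 10^(-pEC50) / A)` to
#' each replicate of each group by Levenberg--Marquardt least squares and
#' summarises potency across replicates as mean +/- SEM, the form in which
#' concentration--response tables are conventionally reported.
#'
#' @param data an `allodyn_dose_response` (or compatible data frame).
#' @param group_cols columns defining fitting groups; the default fits
#'   each agonist x modulator-concentration curve separately.
#' @return an `allodyn_logistic_fit`: list with `replicates` (one row per
#'   group x replicate: `pec50`, `top`, `bottom`, `converged`, `in_span`)
#'   and `summary` (per group: `n`, `pec50`, `pec50_sem`, `label` as a
#'   "mean +/- SEM" string). Non-converged replicates are retained with
#'   `converged = FALSE` and excluded from summaries with a warning.
#' @export
fit_logistic3 <- function(data, group_cols = c("agonist", "modulator_conc")) {
  data <- as_dose_response(as.data.frame(data))
  g <- interaction(data[group_cols], drop = TRUE, lex.order = TRUE)
  rows <- list()
  for (lev in levels(g)) {
    d <- data[g == lev, , drop = FALSE]
    if (length(unique(d$agonist_conc)) < 4L)
      stop("group '", lev, "' has fewer than 4 distinct agonist ",
           "concentrations; the logistic is not identifiable")
    for (rep_id in sort(unique(d$replicate))) {
      dr <- d[d$replicate == rep_id, , drop = FALSE]
      fit <- fit_one_logistic(dr$agonist_conc, dr$response)
      span <- range(-log10(dr$agonist_conc))
      row <- cbind(d[1L, group_cols, drop = FALSE],
                   data.frame(replicate = rep_id, pec50 = fit$pec50,
                              top = fit$top, bottom = fit$bottom,
                              converged = fit$converged,
                              in_span = !is.na(fit$pec50) &&
                                fit$pec50 >= min(span) &&
                                fit$pec50 <= max(span)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  if (any(!reps$converged))
    warning(sum(!reps$converged), " replicate fit(s) did not converge; ",
            "excluded from summaries")
  if (any(reps$converged & !reps$in_span))
    warning("fitted EC50 outside the tested concentration span for ",
            sum(reps$converged & !reps$in_span), " replicate fit(s)")
  ok <- reps[reps$converged, , drop = FALSE]
  gs <- interaction(ok[group_cols], drop = TRUE, lex.order = TRUE)
  summ <- do.call(rbind, lapply(levels(gs), function(lev) {
    s <- ok[gs == lev, , drop = FALSE]
    cbind(s[1L, group_cols, drop = FALSE],
          data.frame(n = nrow(s), pec50 = mean(s$pec50),
                     pec50_sem = sd(s$pec50) / sqrt(nrow(s)),
                     top = mean(s$top), bottom = mean(s$bottom)))
  }))
  summ$label <- sprintf("%.2f ± %.2f", summ$pec50, summ$pec50_sem)
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ,
                 group_cols = group_cols),
            class = "allodyn_logistic_fit")
}

#' @export
print.allodyn_logistic_fit <- function(x, ...) {
  cat("<allodyn_logistic_fit> pEC50 (mean ± SEM across replicates):\n")
  print(x$summary[, c(x$group_cols, "n", "label")], row.names = FALSE)
  invisible(x)
}

# single-curve Levenberg-Marquardt fit; multi-start over pEC50
fit_one_logistic <- function(conc, resp) {
  if (sd(resp) == 0)
    stop("responses are constant: top and bottom are unidentifiable")
  if (abs(stats::cor(log10(conc), resp, method = "spearman")) < 0.3)
    warning("responses are not monotone in concentration; ",
            "logistic fit may be meaningless")
  lconc <- log10(conc)
  half <- (min(resp) + max(resp)) / 2
  p0 <- -lconc[which.min(abs(resp - half))]
  starts <- unique(c(p0, median(-lconc), p0 + 1, p0 - 1))
  best <- NULL
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ bottom + (top - bottom) / (1 + 10^(-pec50 - lconc)),
        start = list(bottom = min(resp), top = max(resp), pec50 = s),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best))
    return(list(pec50 = NA_real_, top = NA_real_, bottom = NA_real_,
                converged = FALSE))
  cf <- coef(best$fit)
  list(pec50 = unname(cf["pec50"]), top = unname(cf["top"]),
       bottom = unname(cf["bottom"]), converged = TRUE)
}
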