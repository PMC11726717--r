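#' Compare fitted parameters across conditions (ANOVA + Dunnett)
#'
#' Two-way analysis of variance of a per-replicate parameter (typically
#' pEC50) over agonist and modulator-concentration factors, followed by
#' Dunnett-style comparisons of every modulator level against the control
#' level within each agonist.
#'
#' @param tab per-replicate parameter table, e.g. the `replicates`
#'   element of [fit_logistic3()].
#' @param control control level of `modulator_col` (e.g. `0` for
#'   vehicle/DMSO).
#' @param value_col column analysed (default `"pec50"`).
#' @param agonist_col,modulator_col factor columns.
#' @return an `allodyn_comparison`: list with `anova` (the ANOVA table),
#'   `dunnett` (per comparison: estimate, SE, raw and Dunnett-adjusted p,
#'   significance stars) and `control`. Conditions with fewer than 2
#'   replicates are excluded with a warning.
#' @export
compare_conditions <- function(tab, control, value_col = "pec50",
                               agonist_col = "agonist",
                               modulator_col = "modulator_conc") {
  d <- as.data.frame(tab)
  stopifnot(all(c(value_col, agonist_col, modulator_col) %in% names(d)))
  d <- d[is.finite(d[[value_col]]), , drop = FALSE]
  d$.value <- d[[value_col]]
  d$.agonist <- factor(d[[agonist_col]])
  d$.modulator <- factor(d[[modulator_col]])
  cnt <- table(d$.agonist, d$.modulator)
  small <- cnt > 0 & cnt < 2
  if (any(small)) {
    warning(sum(small), " condition(s) with a single replicate excluded ",
            "from the comparison")
    for (i in which(small, arr.ind = TRUE)[, 1L]) {
      bad <- which(small[i, ])
      d <- d[!(d$.agonist == rownames(cnt)[i] &
                 d$.modulator %in% colnames(cnt)[bad]), , drop = FALSE]
    }
    d$.agonist <- droplevels(d$.agonist)
    d$.modulator <- droplevels(d$.modulator)
  }
  ctrl_lab <- as.character(control)
  if (!ctrl_lab %in% levels(d$.modulator))
    stop("control level '", ctrl_lab, "' not present in ", modulator_col)
  two_way <- nlevels(d$.agonist) > 1L
  model <- if (two_way) aov(.value ~ .agonist * .modulator, data = d)
           else aov(.value ~ .modulator, data = d)
  emm <- if (two_way)
    emmeans::emmeans(model, specs = ".modulator", by = ".agonist")
  else emmeans::emmeans(model, specs = ".modulator")
  ref <- match(ctrl_lab, levels(d$.modulator))
  ct <- emmeans::contrast(emm, method = "trt.vs.ctrl", ref = ref)
  adj <- as.data.frame(summary(ct))
  raw <- as.data.frame(summary(ct, adjust = "none"))
  dunnett <- data.frame(
    agonist = if (two_way) adj$.agonist else NA,
    contrast = adj$contrast, estimate = adj$estimate, se = adj$SE,
    df = adj$df, p_raw = raw$p.value,
    p_adj = pmax(adj$p.value, raw$p.value),
    stringsAsFactors = FALSE)
  dunnett$stars <- stars_for(dunnett$p_adj)
  structure(list(anova = as.data.frame(summary(model)[[1L]]),
                 dunnett = dunnett, control = ctrl_lab,
                 value_col = value_col),
            class = "allodyn_comparison")
}

stars_for <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}

#' @export
print.allodyn_comparison <- function(x, ...) {
  cat("<allodyn_comparison> ", x$value_col, " vs control '", x$control,
      "' (Dunnett-adjusted):\n", sep = "")
  print(x$dunnett[, c("agonist", "contrast", "estimate", "p_adj", "stars")],
        row.names = FALSE, digits = 3L)
  invisible(x)
}
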