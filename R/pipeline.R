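#' Validate a pipeline configuration
#'
#' Configuration is a YAML file (or equivalent list) with blocks:
#' `seed`, `output_dir`, `conditions` (each: `label`, `topology`,
#' optional `bw_map`, `replicas` as a list of DCD path vectors,
#' `selections` as named expressions), optional `metrics`
#' (`rmsd`/`rmsf`/`contacts` requests referencing named selections),
#' optional `network` (`params`, `communities`, `paths`
#' with `source`/`sink`/`tolerance`, `compare` pair of labels) and
#' optional `pharmacology` (`datasets`: `label`, `path`, `logistic`,
#' `allosterism`). All thresholds default to the package defaults
#' (4.5 A contact gate, 75% persistency, natural-log weights).
#'
#' @param config YAML path or list.
#' @return the validated config (list) with class `allodyn_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$conditions) && is.null(config$pharmacology))
    stop("config must declare 'conditions' and/or 'pharmacology'")
  labels <- vapply(config$conditions, function(x) x$label %||% "", "")
  if (length(labels) && (any(!nzchar(labels)) || anyDuplicated(labels)))
    stop("condition labels must be present and unique")
  for (cond in config$conditions) {
    if (is.null(cond$topology) || !file.exists(cond$topology))
      stop("condition '", cond$label, "': topology file missing")
    for (rep in cond$replicas) {
      missing <- rep[!file.exists(unlist(rep))]
      if (length(missing))
        stop("condition '", cond$label, "': trajectory file(s) missing: ",
             paste(missing, collapse = ", "))
    }
  }
  for (ds in config$pharmacology$datasets) {
    if (is.null(ds$path) || !file.exists(ds$path))
      stop("pharmacology dataset '", ds$label %||% "?", "': file missing")
  }
  cmp <- config$network$compare
  if (!is.null(cmp) && !all(unlist(cmp) %in% labels))
    stop("network compare references unknown condition label(s)")
  config$seed <- as.integer(config$seed %||% 1L)
  class(config) <- c("allodyn_config", "list")
  config
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order (trajectory IO,
#' then structural metrics, then network analysis per condition;
#' pharmacology independently), writes tidy CSV outputs under the
#' configured output directory and returns a run report. A failure inside
#' one condition block is caught and recorded without touching other
#' blocks. Reruns with an identical config and seed produce identical
#' outputs.
#'
#' @param config YAML path or list (see [validate_config()]).
#' @return an `allodyn_run_report`: per-condition metric tables, network
#'   summaries, pharmacology fits, `errors`, and provenance (config hash,
#'   seed, package version).
#' @export
run_pipeline <- function(config) {
  cfg_path <- if (is.character(config)) config else NULL
  config <- validate_config(config)
  set.seed(config$seed)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(conditions = list(), networks = list(),
                 pharmacology = list(), errors = list())
  nets <- list()
  for (cond in config$conditions) {
    res <- tryCatch(run_condition(cond, config, out_dir),
                    error = function(e)
                      structure(list(message = conditionMessage(e)),
                                class = "condition_error"))
    if (inherits(res, "condition_error")) {
      report$errors[[cond$label]] <- res$message
    } else {
      report$conditions[[cond$label]] <- res$tables
      if (!is.null(res$network)) nets[[cond$label]] <- res$network
    }
  }
  report$networks <- lapply(nets, function(n)
    list(edges = network_edges(n$network),
         communities = n$communities))
  cmp <- config$network$compare
  if (!is.null(cmp) && all(unlist(cmp) %in% names(nets))) {
    cmp <- unlist(cmp)
    diff <- compare_networks(nets[[cmp[1L]]]$network,
                             nets[[cmp[2L]]]$network)
    write.csv(diff, file.path(out_dir, "network_compare.csv"),
              row.names = FALSE)
    report$network_compare <- diff
  }
  for (ds in config$pharmacology$datasets) {
    res <- tryCatch(run_pharm(ds, out_dir),
                    error = function(e)
                      structure(list(message = conditionMessage(e)),
                                class = "condition_error"))
    if (inherits(res, "condition_error"))
      report$errors[[ds$label]] <- res$message
    else report$pharmacology[[ds$label]] <- res
  }
  cfg_hash <- if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path)) else {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(unclass(config), tmp)
    h <- unname(tools::md5sum(tmp)); unlink(tmp); h
  }
  report$provenance <- list(config_hash = cfg_hash, seed = config$seed,
                            package_version =
                              as.character(utils::packageVersion("allodyn")))
  class(report) <- "allodyn_run_report"
  report
}

run_condition <- function(cond, config, out_dir) {
  top <- read_topology(cond$topology, bw_map = cond$bw_map)
  trajs <- lapply(seq_along(cond$replicas), function(i)
    read_trajectory(unlist(cond$replicas[[i]]), top, replica = i))
  sels <- lapply(cond$selections, function(e) select_atoms(top, e))
  get_sel <- function(name) {
    if (is.null(name)) return(NULL)
    sels[[name]] %||% stop("unknown selection '", name, "' in condition '",
                           cond$label, "'")
  }
  tables <- list()
  met <- config$metrics
  if (!is.null(met$rmsd)) {
    series <- lapply(trajs, function(tr)
      rmsd_series(tr, analysis_sel = get_sel(met$rmsd$analysis),
                  fit_sel = get_sel(met$rmsd$fit)))
    tables$rmsd <- data.frame(
      replica = rep(seq_along(series),
                    vapply(series, function(s) length(s$values), 0L)),
      frame = unlist(lapply(series, function(s) seq_along(s$values))),
      rmsd = unlist(lapply(series, `[[`, "values")))
    tables$rmsd_summary <- format_mean_sd(unlist(lapply(series, `[[`,
                                                        "values")))
  }
  if (!is.null(met$rmsf)) {
    prof <- rmsf_profile(trajs, get_sel(met$rmsf$selection),
                         fit_sel = get_sel(met$rmsf$fit))
    tables$rmsf <- as.data.frame(prof)
  }
  network <- NULL
  if (!is.null(met$contacts) || !is.null(config$network)) {
    cpar <- met$contacts %||% list()
    sel_a <- get_sel(cpar$sel_a %||% names(sels)[1L])
    sel_b <- get_sel(cpar$sel_b %||% names(sels)[1L])
    contacts <- contact_persistency(trajs, sel_a, sel_b,
                                    cutoff = cpar$cutoff %||% 4.5,
                                    allow_overlap =
                                      isTRUE(cpar$allow_overlap) ||
                                      identical(sel_a$expression,
                                                sel_b$expression))
    tables$contacts <- as.data.frame(contacts)
    if (!is.null(config$network)) {
      np <- do.call(network_params, config$network$params %||% list())
      corr <- correlation_matrix(trajs, sel_a,
                                 fit_sel = get_sel(config$network$fit))
      net <- build_network(corr, contacts, np, condition = cond$label)
      comm <- if (isTRUE(config$network$communities))
        detect_communities(net)
      network <- list(network = net, communities = comm)
      write.csv(network_edges(net),
                file.path(out_dir, paste0(cond$label, "_edges.csv")),
                row.names = FALSE)
    }
  }
  for (nm in intersect(names(tables), c("rmsd", "rmsf", "contacts")))
    write.csv(tables[[nm]],
              file.path(out_dir, paste0(cond$label, "_", nm, ".csv")),
              row.names = FALSE)
  list(tables = tables, network = network)
}

run_pharm <- function(ds, out_dir) {
  data <- read_dose_response(ds$path)
  out <- list()
  if (isTRUE(ds$logistic %||% TRUE)) {
    fit <- fit_logistic3(data)
    out$logistic <- fit$summary
    write.csv(fit$summary,
              file.path(out_dir, paste0(ds$label, "_logistic.csv")),
              row.names = FALSE)
  }
  if (isTRUE(ds$allosterism)) {
    fit <- fit_operational_allosterism(data)
    out$allosterism <- fit$summary
    write.csv(fit$summary,
              file.path(out_dir, paste0(ds$label, "_allosterism.csv")),
              row.names = FALSE)
  }
  out
}

#' @export
print.allodyn_run_report <- function(x, ...) {
  cat("<allodyn_run_report> conditions: ",
      paste(names(x$conditions), collapse = ", "),
      if (length(x$pharmacology))
        paste0("; pharmacology: ", paste(names(x$pharmacology),
                                         collapse = ", ")),
      if (length(x$errors))
        paste0("; FAILED blocks: ", paste(names(x$errors), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
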