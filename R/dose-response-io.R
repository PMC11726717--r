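#' Read a concentration--response table
#'
#' Expects a CSV with columns `agonist`, `agonist_conc` (molar),
#' `modulator_conc` (molar, `0` meaning vehicle), `response` (assay units)
#' and `replicate`. This is the layout emitted by [gen_dose_response()] and
#' consumed by the fitting functions.
#'
#' @param path CSV file.
#' @return an `allodyn_dose_response` data frame with a logical `vehicle`
#'   column added.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("dose-response file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  as_dose_response(d)
}

#' Validate and type a concentration--response data frame
#'
#' @param d data frame with the five required columns (see
#'   [read_dose_response()]).
#' @return an `allodyn_dose_response` data frame.
#' @export
as_dose_response <- function(d) {
  req <- c("agonist", "agonist_conc", "modulator_conc", "response", "replicate")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("dose-response table is missing column(s): ",
         paste(miss, collapse = ", "))
  d$agonist_conc <- as.numeric(d$agonist_conc)
  d$modulator_conc <- as.numeric(d$modulator_conc)
  d$response <- as.numeric(d$response)
  if (anyNA(d$agonist_conc) || any(d$agonist_conc <= 0))
    stop("agonist_conc must be numeric and strictly positive (molar)")
  if (anyNA(d$modulator_conc) || any(d$modulator_conc < 0))
    stop("modulator_conc must be numeric and non-negative (molar, 0 = vehicle)")
  if (anyNA(d$response) || any(!is.finite(d$response)))
    stop("responses must be finite numbers")
  d$vehicle <- d$modulator_conc == 0
  class(d) <- c("allodyn_dose_response", "data.frame")
  d
}
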