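#' Read a per-patient trial CSV
#'
#' Reads and validates a trial dataset with the required columns
#' `patient_id`, `centre_id`, `arm`, `outcome` and any number of numeric
#' covariate columns. `arm` and `outcome` must be coded 0/1 (0 = control /
#' no event); offending rows are named in the error. Centre identifiers
#' are treated as opaque strings with no ordering semantics.
#'
#' @param path Path to a CSV file.
#' @return A `trial_dataset` data frame.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character",
                                      centre_id = "character"))
  if (nrow(d) == 0L) stop_data("empty trial file: ", path)
  req <- c("patient_id", "centre_id", "arm", "outcome")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop_data("missing required columns: ", paste(miss, collapse = ", "))
  }
  bad_arm <- which(!d$arm %in% c(0, 1))
  bad_out <- which(!d$outcome %in% c(0, 1))
  if (length(bad_arm) || length(bad_out)) {
    stop_data("non-binary values: ",
              if (length(bad_arm)) {
                paste0("arm rows [", toString(utils::head(bad_arm, 5)), "] ")
              } else "",
              if (length(bad_out)) {
                paste0("outcome rows [", toString(utils::head(bad_out, 5)), "]")
              } else "")
  }
  d$arm <- as.integer(d$arm)
  d$outcome <- as.integer(d$outcome)
  class(d) <- c("trial_dataset", "data.frame")
  d
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_trial_csv()]; columns are `patient_id`, `centre_id`,
#' `arm`, `outcome`, then one column per covariate.
#'
#' @param data A `trial_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trial_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a scenario results table to CSV
#'
#' Serialises the output of [run_grid()] / [run_scenario()] with the rate
#' columns both as display percentages rounded to one decimal
#' (`rejection_pct`, `convergence_pct`) and as full-precision proportions
#' (`rejection_rate`, `convergence_rate`), so the file is readable at a
#' glance yet reparses losslessly.
#'
#' @param table Data frame of scenario summaries.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_config("results table must be a non-empty data frame")
  }
  out <- as.data.frame(table)
  out$rejection_pct <- sprintf("%.1f", 100 * out$rejection_rate)
  out$convergence_pct <- sprintf("%.1f", 100 * out$convergence_rate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
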