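#' Monte-Carlo standard error of an estimated rate
#'
#' `sqrt(p (1 - p) / n)` for a proportion estimated from `n` independent
#' replicates.
#'
#' @param p Estimated rate in `[0, 1]`.
#' @param n Number of replicates.
#' @return Standard error on the proportion scale.
#' @examples
#' monte_carlo_se(0.05, 5000)  # about 0.003, i.e. 0.3 percentage points
#' @export
monte_carlo_se <- function(p, n) {
  if (any(p < 0 | p > 1) || any(n < 1)) {
    stop_config("p must lie in [0, 1] and n must be >= 1")
  }
  sqrt(p * (1 - p) / n)
}

#' Power lost by ignoring centre in the analysis
#'
#' When outcomes are clustered by centre with intraclass correlation `icc`
#' and the analysis ignores centre after centre-stratified randomisation,
#' the standard error of the treatment effect is inflated by
#' `(1 - icc)^(-1/2)`. For a trial designed to attain `design_power` at
#' two-sided level `alpha_level`, the attained power becomes
#' `Phi((z_{1-alpha/2} + z_{power}) * sqrt(1 - icc) - z_{1-alpha/2})`.
#' Returns the loss `(design_power - attained) * 100` in percentage points.
#'
#' @param icc Intraclass correlation in `[0, 1)`.
#' @param design_power Power the trial was designed for, default 0.8.
#' @param alpha_level Two-sided significance level, default 0.05.
#' @return Power reduction in percentage points.
#' @examples
#' power_reduction_unadjusted(0.01)  # ~0.4 percentage points
#' power_reduction_unadjusted(0.10)  # ~4.3
#' power_reduction_unadjusted(0.25)  # ~12.1
#' @export
power_reduction_unadjusted <- function(icc, design_power = 0.8,
                                       alpha_level = 0.05) {
  if (any(icc < 0 | icc >= 1)) stop_config("icc must lie in [0, 1)")
  if (design_power <= 0 || design_power >= 1 ||
      alpha_level <= 0 || alpha_level >= 1) {
    stop_config("design_power and alpha_level must lie strictly in (0, 1)")
  }
  za <- stats::qnorm(1 - alpha_level / 2)
  zb <- stats::qnorm(design_power)
  attained <- stats::pnorm((za + zb) * sqrt(1 - icc) - za)
  (design_power - attained) * 100
}

#' Summarise replicate estimates for one analysis method
#'
#' Aggregates per-replicate fits into the scenario-level performance
#' measures: the mean treatment effect (exponential of the mean log odds
#' ratio), the rejection rate (proportion with `p < 0.05`; the type I error
#' rate when the true odds ratio is 1, power otherwise), and the
#' convergence rate. Mean effect and rejection rate are computed over
#' converged replicates only; with no converged replicates they are `NA`.
#'
#' @param results Either a list of `estimate_result` objects or a data
#'   frame with columns `log_or`, `p_value`, `converged`.
#' @param truth True treatment log odds ratio of the generating scenario
#'   (0 for a null scenario).
#' @param alpha_level Significance threshold, default 0.05 (two-sided).
#' @return A one-row data frame of class `scenario_summary` with columns
#'   `mean_or`, `rejection_rate`, `convergence_rate`, `n_reps`,
#'   `mc_se_rejection`, `truth`.
#' @export
summarize_estimates <- function(results, truth = 0, alpha_level = 0.05) {
  if (is.data.frame(results)) {
    log_or <- results$log_or
    p <- results$p_value
    conv <- results$converged
  } else {
    log_or <- vapply(results, `[[`, numeric(1), "log_or")
    p <- vapply(results, `[[`, numeric(1), "p_value")
    conv <- vapply(results, `[[`, logical(1), "converged")
  }
  n <- length(conv)
  if (n < 1L) stop_config("need at least one replicate")
  nc <- sum(conv)
  rej <- if (nc > 0) mean(p[conv] < alpha_level) else NA_real_
  out <- data.frame(
    mean_or = if (nc > 0) exp(mean(log_or[conv])) else NA_real_,
    rejection_rate = rej,
    convergence_rate = nc / n,
    n_reps = n,
    mc_se_rejection = if (nc > 0) monte_carlo_se(rej, nc) else NA_real_,
    truth = truth
  )
  class(out) <- c("scenario_summary", "data.frame")
  out
}
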