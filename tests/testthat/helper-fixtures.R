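# Build a single-centre trial dataset from 2x2 cell counts
# (a = treated events, b = treated non-events, c = control events,
#  d = control non-events).
trial_from_2x2 <- function(a, b, c, d, centre_id = "C1") {
  n <- a + b + c + d
  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    centre_id = centre_id,
    arm = rep(c(1L, 0L), c(a + b, c + d)),
    outcome = c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("trial_dataset", "data.frame")
  out
}

# Stack several single-centre 2x2 tables into one multi-centre dataset.
trial_from_strata <- function(tables) {
  parts <- lapply(seq_along(tables), function(j) {
    t <- tables[[j]]
    trial_from_2x2(t[1], t[2], t[3], t[4], centre_id = sprintf("C%02d", j))
  })
  out <- do.call(rbind, parts)
  out$patient_id <- sprintf("P%04d", seq_len(nrow(out)))
  class(out) <- c("trial_dataset", "data.frame")
  out
}

# Quick generated multicentre dataset for estimator tests.
sim_trial <- function(n_total = 400, n_centres = 20, icc = 0.075,
                      control_rate = 0.3, beta = -0.5, block = 4,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- allocate_centres(n_total, n_centres, "even")
  arm <- stratified_permuted_blocks(sizes, block)
  pars <- generative_params(alpha = qlogis(control_rate), beta_treat = beta,
                            icc = icc)
  generate_trial(sizes, arm, pars)
}
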