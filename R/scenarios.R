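#' Define one simulation scenario
#'
#' A scenario fixes the trial design (centres, total size, patient
#' distribution, randomisation), the outcome model (ICC, control event
#' rate, treatment odds ratio), and the Monte-Carlo settings (methods,
#' replicates, seed). `run_scenario()` executes it end to end.
#'
#' @param n_centres Number of centres.
#' @param n_total Total number of patients.
#' @param icc Intraclass correlation of the centre effects.
#' @param distribution Patient distribution across centres, `"even"` or
#'   `"skewed"` (see [allocate_centres()]).
#' @param control_event_rate Control-arm event probability.
#' @param block_size Permuted-block length for stratified randomisation.
#' @param randomisation `"blocks"` (permuted blocks stratified by centre)
#'   or `"simple"`.
#' @param treatment_or True treatment odds ratio (1 for a null scenario).
#' @param methods Analysis methods to fit each replicate; any subset of
#'   `"unadjusted"`, `"fixed"`, `"random"`, `"gee-naive"`, `"gee-robust"`,
#'   `"mh"`.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param base_seed Base seed; replicate `r` of scenario `scenario_id`
#'   draws from an independent substream keyed by
#'   `(base_seed, scenario_id, r)`.
#' @param scenario_id Integer scenario identifier used in seed derivation.
#' @param design `"parametric"` (latent model without covariates) or
#'   `"mist2"` (the MIST2-like generator with covariate-adjusted analyses).
#' @param quad_points Quadrature nodes for the random-effects fit.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_centres, n_total, icc,
                            distribution = c("even", "skewed"),
                            control_event_rate = 0.5,
                            block_size = 4L,
                            randomisation = c("blocks", "simple"),
                            treatment_or = 1,
                            methods = c("unadjusted", "fixed", "random",
                                        "gee-naive", "gee-robust", "mh"),
                            n_reps = 1000L, base_seed = 1L,
                            scenario_id = 1L,
                            design = c("parametric", "mist2"),
                            quad_points = 12L) {
  distribution <- match.arg(distribution)
  randomisation <- match.arg(randomisation)
  design <- match.arg(design)
  methods <- match.arg(methods, several.ok = TRUE)
  check_count(n_centres, "n_centres")
  check_count(n_total, "n_total")
  check_count(n_reps, "n_reps")
  if (n_total < n_centres) {
    stop_config("n_total must be at least n_centres")
  }
  if (icc < 0 || icc >= 1) stop_config("icc must lie in [0, 1)")
  if (treatment_or <= 0) stop_config("treatment_or must be positive")
  structure(list(
    n_centres = as.integer(n_centres), n_total = as.integer(n_total),
    icc = icc, distribution = distribution,
    control_event_rate = control_event_rate,
    block_size = as.integer(block_size), randomisation = randomisation,
    treatment_or = treatment_or, methods = methods,
    n_reps = as.integer(n_reps), base_seed = as.integer(base_seed),
    scenario_id = as.integer(scenario_id), design = design,
    quad_points = as.integer(quad_points)
  ), class = "scenario_config")
}

#' Derive the seed of one replicate substream
#'
#' Maps `(base_seed, scenario_id, replicate)` to a deterministic seed below
#' 2^31 via a mixed congruential key, so replicates of different scenarios
#' never share a random stream within a run (keys are unique for replicate
#' indices below 16807) and results are order-deterministic regardless of
#' execution order.
#'
#' @param base_seed Run-level base seed.
#' @param scenario_id Scenario identifier.
#' @param replicate Replicate index (1-based).
#' @return Integer seed.
#' @export
replicate_seed <- function(base_seed, scenario_id, replicate) {
  as.integer(((base_seed %% 2147483647) * 48271 +
                scenario_id * 16807 + replicate) %% 2147483647)
}

# -------- scenario grids --------

#' Build the main 192-scenario factorial grid
#'
#' Full factorial over centres (5, 50, 100), total patients (200, 500,
#' 1000, 2000), ICC (0.025, 0.075), patient distribution (even, skewed),
#' control event rate (20%, 50%), and permuted-block size (4, 20):
#' 3 x 4 x 2 x 2 x 2 x 2 = 192 scenarios. Each is run twice in practice -
#' once at odds ratio 1 for the type I error rate and once at an
#' event-reducing odds ratio calibrated for 80% power (see [run_grid()]).
#'
#' @param n_reps Replicates per scenario.
#' @param base_seed Base seed shared by the grid.
#' @param methods Methods to fit (defaults to all).
#' @return List of [scenario_config()] objects with `scenario_id` 1..192.
#' @export
build_main_grid <- function(n_reps = 1000L, base_seed = 1L,
                            methods = c("unadjusted", "fixed", "random",
                                        "gee-naive", "gee-robust", "mh")) {
  g <- expand.grid(
    n_centres = c(5L, 50L, 100L),
    n_total = c(200L, 500L, 1000L, 2000L),
    icc = c(0.025, 0.075),
    distribution = c("even", "skewed"),
    control_event_rate = c(0.2, 0.5),
    block_size = c(4L, 20L),
    stringsAsFactors = FALSE
  )
  grid_to_configs(g, n_reps, base_seed, methods)
}

#' Build the large-ICC sensitivity grid (24 scenarios)
#'
#' ICC fixed at 0.25, control event rate 50%, even patient distribution;
#' centres (5, 50, 100) x total patients (200, 500, 1000, 2000) x block
#' size (4, 20) = 24 scenarios.
#'
#' @inheritParams build_main_grid
#' @return List of 24 [scenario_config()] objects.
#' @export
build_icc_sensitivity <- function(n_reps = 1000L, base_seed = 1L,
                                  methods = c("unadjusted", "fixed",
                                              "random", "gee-naive",
                                              "gee-robust", "mh")) {
  g <- expand.grid(
    n_centres = c(5L, 50L, 100L),
    n_total = c(200L, 500L, 1000L, 2000L),
    icc = 0.25,
    distribution = "even",
    control_event_rate = 0.5,
    block_size = c(4L, 20L),
    stringsAsFactors = FALSE
  )
  grid_to_configs(g, n_reps, base_seed, methods)
}

#' Build the robust-SE GEE sensitivity grid (12 scenarios)
#'
#' ICC 0.025, control event rate 50%, even distribution, block size 4;
#' centres (5, 50, 100) x total patients (200, 500, 1000, 2000) = 12
#' scenarios, analysed with the sandwich-SE GEE.
#'
#' @inheritParams build_main_grid
#' @return List of 12 [scenario_config()] objects.
#' @export
build_robust_gee_sensitivity <- function(n_reps = 1000L, base_seed = 1L) {
  g <- expand.grid(
    n_centres = c(5L, 50L, 100L),
    n_total = c(200L, 500L, 1000L, 2000L),
    icc = 0.025,
    distribution = "even",
    control_event_rate = 0.5,
    block_size = 4L,
    stringsAsFactors = FALSE
  )
  grid_to_configs(g, n_reps, base_seed, methods = "gee-robust")
}

#' Build the MIST2-like scenario pair
#'
#' Two scenarios over the MIST2-like generator: treatment odds ratio 1
#' (type I error) and 0.23 (power), ICC 0, simple randomisation, with all
#' analyses adjusted for the three baseline covariates and the
#' centre-unadjusted logistic model included as a sixth method. The
#' Mantel-Haenszel strata cross centre with pleural fluid dichotomised at
#' 30% and the two binary covariates.
#'
#' @inheritParams build_main_grid
#' @return List of 2 [scenario_config()] objects.
#' @export
build_mist2_grid <- function(n_reps = 1000L, base_seed = 1L) {
  lapply(seq_along(c(1, 0.23)), function(i) {
    scenario_config(
      n_centres = 11L, n_total = 190L, icc = 0,
      distribution = "even",   # unused: the mist2 design fixes its profile
      control_event_rate = 0.12, randomisation = "simple",
      treatment_or = c(1, 0.23)[i],
      methods = c("unadjusted", "fixed", "random", "gee-naive",
                  "gee-robust", "mh"),
      n_reps = n_reps, base_seed = base_seed, scenario_id = 900L + i,
      design = "mist2")
  })
}

grid_to_configs <- function(g, n_reps, base_seed, methods) {
  lapply(seq_len(nrow(g)), function(i) {
    scenario_config(
      n_centres = g$n_centres[i], n_total = g$n_total[i], icc = g$icc[i],
      distribution = g$distribution[i],
      control_event_rate = g$control_event_rate[i],
      block_size = g$block_size[i], randomisation = "blocks",
      treatment_or = 1, methods = methods, n_reps = n_reps,
      base_seed = base_seed, scenario_id = i)
  })
}

# -------- execution --------

#' Run one scenario end to end
#'
#' For each replicate: derives an independent substream from
#' `(base_seed, scenario_id, replicate)`, allocates patients to centres,
#' randomises arms, generates outcomes from the latent-logistic model, fits
#' every requested method, applies the convergence rules, and finally
#' aggregates per method with [summarize_estimates()]. Identical
#' configuration implies identical results.
#'
#' @param config A [scenario_config()].
#' @return Data frame with one row per method: scenario parameters plus
#'   `mean_or`, `rejection_rate`, `convergence_rate`, `n_reps`,
#'   `mc_se_rejection`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$design == "mist2") return(run_scenario_mist2(config))
  sizes <- allocate_centres(config$n_total, config$n_centres,
                            config$distribution)
  n <- sum(sizes)
  J <- length(sizes)
  centre <- rep.int(seq_len(J), sizes)
  alpha <- calibrate_alpha(config$control_event_rate)
  beta <- log(config$treatment_or)
  sigma <- icc_to_sigma(config$icc)
  methods <- config$methods
  want_gee <- any(c("gee-naive", "gee-robust") %in% methods)
  fit_m <- setdiff(methods, c("gee-naive", "gee-robust"))
  if (want_gee) fit_m <- c(fit_m, "gee")
  R <- config$n_reps
  store <- new_store(methods, R)
  for (r in seq_len(R)) {
    set.seed(replicate_seed(config$base_seed, config$scenario_id, r))
    arm <- if (config$randomisation == "blocks") {
      stratified_permuted_blocks(sizes, config$block_size)
    } else {
      simple_randomization(n)
    }
    u <- stats::rnorm(J, 0, sigma)
    y <- as.integer(alpha + beta * arm + u[centre] + stats::rlogis(n) > 0)
    for (m in fit_m) {
      if (m == "gee") {
        fits <- fit_gee_core(y, arm, centre, n_centres = J)
        if ("gee-naive" %in% methods) {
          store_rep(store[["gee-naive"]], r, fits$naive)
        }
        if ("gee-robust" %in% methods) {
          store_rep(store[["gee-robust"]], r, fits$robust)
        }
      } else {
        core <- switch(m,
          unadjusted = fit_unadjusted_core(y, arm),
          fixed = fit_fixed_core(y, arm, centre, n_centres = J),
          random = fit_random_core(y, arm, centre,
                                   quad_points = config$quad_points,
                                   n_centres = J),
          mh = fit_mh_core(y, arm, centre, n_strata = J))
        store_rep(store[[m]], r, core)
      }
    }
  }
  collect_summaries(store, config, truth = beta)
}

# per-method replicate stores are environments so store_rep fills them in
# place inside the replicate loop
new_store <- function(methods, R) {
  store <- lapply(methods, function(m) {
    e <- new.env(parent = emptyenv())
    e$log_or <- numeric(R)
    e$p <- numeric(R)
    e$conv <- logical(R)
    e
  })
  names(store) <- methods
  store
}

store_rep <- function(slot, r, core) {
  slot$log_or[r] <- if (is.null(core$log_or)) NA_real_ else core$log_or
  slot$p[r] <- if (is.null(core$p_value)) NA_real_ else core$p_value
  slot$conv[r] <- isTRUE(core$converged)
  invisible(slot)
}

collect_summaries <- function(store, config, truth) {
  rows <- lapply(names(store), function(m) {
    s <- store[[m]]
    sm <- summarize_estimates(
      data.frame(log_or = s$log_or, p_value = s$p, converged = s$conv),
      truth = truth)
    cbind(scenario_id = config$scenario_id, n_centres = config$n_centres,
          n_total = config$n_total, icc = config$icc,
          distribution = config$distribution,
          control_event_rate = config$control_event_rate,
          block_size = config$block_size,
          randomisation = config$randomisation,
          treatment_or = config$treatment_or,
          base_seed = config$base_seed, method = m, sm,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

run_scenario_mist2 <- function(config) {
  covs <- c("pleural_fluid", "purulence", "hospital_infection")
  methods <- config$methods
  R <- config$n_reps
  store <- new_store(methods, R)
  for (r in seq_len(R)) {
    set.seed(replicate_seed(config$base_seed, config$scenario_id, r))
    d <- generate_mist2_like(n_total = config$n_total,
                             treatment_or = config$treatment_or,
                             icc = config$icc)
    v <- trial_vectors(d, covs)
    gee_done <- FALSE
    for (m in methods) {
      core <- switch(m,
        unadjusted = fit_unadjusted_core(v$y, v$x, v$Z),
        fixed = fit_fixed_core(v$y, v$x, v$centre, v$Z, v$n_centres),
        random = {
          ord <- order(v$centre)
          fit_random_core(v$y[ord], v$x[ord], v$centre[ord],
                          v$Z[ord, , drop = FALSE],
                          quad_points = config$quad_points,
                          n_centres = v$n_centres)
        },
        `gee-naive` = , `gee-robust` = {
          if (!gee_done) {
            gee_fits <- fit_gee_core(v$y, v$x, v$centre, v$Z, v$n_centres)
            gee_done <- TRUE
          }
          if (m == "gee-naive") gee_fits$naive else gee_fits$robust
        },
        mh = {
          s <- build_strata(d, c("centre", covs),
                            cut_rules = list(pleural_fluid = 30))
          si <- as.integer(s)
          fit_mh_core(v$y, v$x, si, max(si))
        })
      store_rep(store[[m]], r, core)
    }
  }
  collect_summaries(store, config, truth = log(config$treatment_or))
}

#' Run a grid of scenarios
#'
#' Executes each scenario of a grid under either the null (odds ratio 1)
#' or the power setting, where the treatment odds ratio is re-calibrated
#' per scenario by [calibrate_effect()] to give 80% power at that sample
#' size and event rate. Power runs use a scenario-id offset so null and
#' power replicates never share random substreams.
#'
#' @param grid List of [scenario_config()]s from a grid builder.
#' @param effect `"null"` or `"power"`.
#' @param n_reps,base_seed,methods Optional overrides applied to every
#'   scenario.
#' @param target_power Power the effect is calibrated for (power runs).
#' @return Row-bound data frame of [run_scenario()] outputs with an
#'   `effect` column.
#' @export
run_grid <- function(grid, effect = c("null", "power"), n_reps = NULL,
                     base_seed = NULL, methods = NULL, target_power = 0.8) {
  effect <- match.arg(effect)
  out <- lapply(grid, function(cfg) {
    if (!is.null(n_reps)) cfg$n_reps <- as.integer(n_reps)
    if (!is.null(base_seed)) cfg$base_seed <- as.integer(base_seed)
    if (!is.null(methods)) cfg$methods <- methods
    if (effect == "power" && cfg$design == "parametric") {
      cfg$treatment_or <- exp(calibrate_effect(
        cfg$n_total, cfg$control_event_rate, target_power = target_power))
      cfg$scenario_id <- cfg$scenario_id + 1000L
    }
    run_scenario(cfg)
  })
  res <- do.call(rbind, out)
  cbind(effect = effect, res, stringsAsFactors = FALSE)
}
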