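# Internal fitting cores. These operate on bare vectors/matrices so the
# simulation engine can avoid data-frame overhead; the exported estimator
# functions in estimators.R are thin wrappers that validate a trial_dataset
# and delegate here. All cores return a list with elements
#   log_or, se, p_value, converged, failure_reason, n_included,
#   n_strata_included (+ method-specific extras)
# with the treatment coefficient always in column 2 of the design.

core_result <- function(log_or, se, optimiser_ok, n_included,
                        n_strata_included = NA_integer_, extra = NULL) {
  cc <- convergence_check(log_or, se, optimiser_ok)
  p <- if (cc$converged) 2 * stats::pnorm(-abs(log_or / se)) else NA_real_
  c(list(log_or = log_or, se = se, p_value = p, converged = cc$converged,
         failure_reason = cc$reason, n_included = n_included,
         n_strata_included = n_strata_included), extra)
}

core_failure <- function(reason, n_included = 0L) {
  list(log_or = NA_real_, se = NA_real_, p_value = NA_real_,
       converged = FALSE, failure_reason = reason,
       n_included = n_included, n_strata_included = NA_integer_)
}

# Wald variance of a logistic GLM, with the IRLS weights re-evaluated at
# the converged coefficients (glm.fit's stored weights lag one iteration);
# NULL when the weighted cross-product is numerically singular.
glm_vcov <- function(X, coef) {
  mu <- stats::plogis(drop(X %*% coef))
  XtWX <- crossprod(X * sqrt(mu * (1 - mu)))
  tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
}

fit_logistic <- function(X, y) {
  fit <- suppressWarnings(tryCatch(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 50L)),
    error = function(e) NULL))
  if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
  fit$coefficients <- unname(fit$coefficients)
  fit
}

fit_unadjusted_core <- function(y, x, Z = NULL) {
  X <- cbind(1, x, Z)
  dimnames(X) <- NULL
  fit <- fit_logistic(X, y)
  if (is.null(fit)) return(core_failure("optimiser-failure", length(y)))
  V <- glm_vcov(X, fit$coefficients)
  if (is.null(V)) return(core_failure("optimiser-failure", length(y)))
  core_result(fit$coefficients[2L], sqrt(V[2L, 2L]), fit$converged, length(y))
}

# Fixed-effects (centre-dummy) logistic regression. Centres in which all
# patients share one outcome or one arm carry no within-centre information
# and are removed before fitting, so they can be reported as excluded rather
# than surfacing as separation-driven non-convergence.
fit_fixed_core <- function(y, x, centre, Z = NULL, n_centres = max(centre)) {
  ev <- tabulate_sum(y, centre, n_centres)
  tr <- tabulate_sum(x, centre, n_centres)
  m <- tabulate(centre, n_centres)
  keep <- m > 0L & ev > 0L & ev < m & tr > 0L & tr < m
  if (!any(keep)) return(core_failure("non-estimable"))
  sel <- keep[centre]
  ys <- y[sel]; xs <- x[sel]
  Zs <- if (is.null(Z)) NULL else Z[sel, , drop = FALSE]
  kept <- which(keep)
  n_kept <- length(kept)
  if (n_kept == 1L) {
    D <- NULL  # single informative centre: reduces to the unadjusted model
  } else {
    ci <- match(centre[sel], kept)
    D <- matrix(0, length(ys), n_kept - 1L)
    nz <- ci > 1L
    D[cbind(which(nz), ci[nz] - 1L)] <- 1
  }
  X <- cbind(1, xs, Zs, D)
  dimnames(X) <- NULL
  fit <- fit_logistic(X, ys)
  if (is.null(fit)) {
    return(core_failure("optimiser-failure", sum(sel)))
  }
  V <- glm_vcov(X, fit$coefficients)
  if (is.null(V) || V[2L, 2L] < 0) {
    return(core_failure("optimiser-failure", sum(sel)))
  }
  core_result(fit$coefficients[2L], sqrt(V[2L, 2L]), fit$converged,
              sum(sel), n_kept)
}

tabulate_sum <- function(v, g, ng) {
  out <- numeric(ng)
  agg <- rowsum(v, g)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# Mantel-Haenszel over per-stratum 2x2 tables. `stratum` is an integer code
# 1..S. Non-informative strata (single arm or single outcome, i.e.
# a*d = b*c = 0) contribute nothing to the MH sums, the RBG variance, or the
# MH chi-square, and their patients are excluded from n_included.
fit_mh_core <- function(y, x, stratum, n_strata = max(stratum)) {
  a <- tabulate_sum(y * x, stratum, n_strata)
  b <- tabulate_sum((1 - y) * x, stratum, n_strata)
  cc <- tabulate_sum(y * (1 - x), stratum, n_strata)
  d <- tabulate_sum((1 - y) * (1 - x), stratum, n_strata)
  n <- a + b + cc + d
  info <- (a * d > 0) | (b * cc > 0)
  if (!any(info)) return(core_failure("non-estimable"))
  a <- a[info]; b <- b[info]; cc <- cc[info]; d <- d[info]; n <- n[info]
  R_j <- a * d / n
  S_j <- b * cc / n
  R <- sum(R_j); S <- sum(S_j)
  if (R == 0 || S == 0) {
    return(core_failure("non-estimable", as.integer(sum(n))))
  }
  log_or <- log(R / S)
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P_j <- (a + d) / n
  Q_j <- (b + cc) / n
  v <- sum(P_j * R_j) / (2 * R^2) +
    sum(P_j * S_j + Q_j * R_j) / (2 * R * S) +
    sum(Q_j * S_j) / (2 * S^2)
  se <- sqrt(v)
  cc_res <- convergence_check(log_or, se, TRUE)
  # Mantel-Haenszel chi-square (1 df, no continuity correction)
  E <- (a + b) * (a + cc) / n
  Vh <- (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
  stat <- sum(a - E)^2 / sum(Vh)
  p <- if (cc_res$converged) {
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else NA_real_
  list(log_or = log_or, se = se, p_value = p, converged = cc_res$converged,
       failure_reason = cc_res$reason, n_included = as.integer(sum(n)),
       n_strata_included = length(n), mh_chisq = stat)
}

# ---- Generalised estimating equations, exchangeable working correlation ----
#
# Fisher scoring on the quasi-score U(beta) = sum_j D_j' V_j^{-1} (y_j - mu_j)
# with V_j = A^{1/2} R(rho) A^{1/2}, exploiting the closed form
# R^{-1} = a I + b J with a = 1/(1-rho), b = -rho / ((1-rho)(1 + (m-1) rho)).
# rho is re-estimated each iteration from Pearson residual cross-products
# with a denominator corrected for the parameter count; the binomial scale
# is fixed at 1. Returns both the model-based (naive) and sandwich (robust)
# covariance of the coefficients.
gee_fit <- function(y, X, centre, n_centres = max(centre),
                    tol = 1e-8, maxit = 100L) {
  dimnames(X) <- NULL
  p <- ncol(X)
  m <- tabulate(centre, n_centres)
  pres <- m > 0L
  pair_den <- sum(m * (m - 1)) / 2 - p
  init <- fit_logistic(X, y)
  beta <- if (is.null(init)) numeric(p) else init$coefficients
  rho <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    A <- mu * (1 - mu)
    sA <- sqrt(pmax(A, 1e-12))
    tt <- (y - mu) / sA
    S1 <- tabulate_sum(tt, centre, n_centres)
    if (pair_den > 0) {
      S2 <- tabulate_sum(tt^2, centre, n_centres)
      rho <- sum(S1^2 - S2) / 2 / pair_den
      mmax <- max(m)
      if (mmax > 1L) {
        rho <- min(max(rho, -0.95 / (mmax - 1)), 0.95)
      } else {
        rho <- 0
      }
    }
    av <- 1 / (1 - rho)
    bv <- ifelse(m > 0L, -rho / ((1 - rho) * (1 + (m - 1L) * rho)), 0)
    G <- matrix(0, n_centres, p)
    agg <- rowsum(X * sA, centre)
    G[as.integer(rownames(agg)), ] <- agg
    U <- crossprod(X, sA * (av * tt)) + crossprod(G, bv * S1)
    B <- av * crossprod(X * sA) + crossprod(G, bv * G)
    delta <- tryCatch(solve(B, U), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      return(list(ok = FALSE))
    }
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged || any(!is.finite(beta))) return(list(ok = FALSE))
  # covariances at the solution
  eta <- drop(X %*% beta); mu <- stats::plogis(eta)
  A <- mu * (1 - mu); sA <- sqrt(pmax(A, 1e-12)); tt <- (y - mu) / sA
  S1 <- tabulate_sum(tt, centre, n_centres)
  av <- 1 / (1 - rho)
  bv <- ifelse(m > 0L, -rho / ((1 - rho) * (1 + (m - 1L) * rho)), 0)
  G <- matrix(0, n_centres, p)
  agg <- rowsum(X * sA, centre)
  G[as.integer(rownames(agg)), ] <- agg
  B <- av * crossprod(X * sA) + crossprod(G, bv * G)
  Binv <- tryCatch(solve(B), error = function(e) NULL)
  if (is.null(Binv)) return(list(ok = FALSE))
  # per-cluster score contributions g_j = D_j' V_j^{-1} (y_j - mu_j)
  gs <- matrix(0, n_centres, p)
  agg2 <- rowsum(X * (sA * av * tt), centre)
  gs[as.integer(rownames(agg2)), ] <- agg2
  gs <- gs + (bv * S1) * G
  M <- crossprod(gs)
  list(ok = TRUE, beta = beta, rho = rho,
       vcov_naive = Binv, vcov_robust = Binv %*% M %*% Binv)
}

fit_gee_core <- function(y, x, centre, Z = NULL, n_centres = max(centre),
                         tol = 1e-8, maxit = 100L) {
  X <- cbind(1, x, Z)
  fit <- gee_fit(y, X, centre, n_centres, tol = tol, maxit = maxit)
  if (!isTRUE(fit$ok)) {
    f <- core_failure("optimiser-failure", length(y))
    return(list(naive = f, robust = f))
  }
  b <- fit$beta[2L]
  list(
    naive = core_result(b, sqrt(fit$vcov_naive[2L, 2L]), TRUE, length(y),
                        extra = list(rho = fit$rho)),
    robust = core_result(b, sqrt(fit$vcov_robust[2L, 2L]), TRUE, length(y),
                         extra = list(rho = fit$rho))
  )
}

# ---- Random-effects (mixed) logistic regression via adaptive GHQ ----

gh_cache <- new.env(parent = emptyenv())

#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for the weight function `exp(-z^2)` computed by the
#' Golub-Welsch eigenvalue method.
#'
#' @param k Number of quadrature nodes.
#' @return List with `nodes` and `weights`, each length `k`.
#' @keywords internal
#' @export
gauss_hermite <- function(k) {
  key <- as.character(k)
  if (!is.null(gh_cache[[key]])) return(gh_cache[[key]])
  if (k == 1L) {
    out <- list(nodes = 0, weights = sqrt(pi))
  } else {
    i <- seq_len(k - 1)
    off <- sqrt(i / 2)
    Jm <- matrix(0, k, k)
    Jm[cbind(i, i + 1)] <- off
    Jm[cbind(i + 1, i)] <- off
    e <- eigen(Jm, symmetric = TRUE)
    ord <- order(e$values)
    out <- list(nodes = e$values[ord],
                weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
  }
  gh_cache[[key]] <- out
  out
}

# Maximise the AGQ marginal likelihood over (beta, sigma). Rows must be
# sorted by centre; `starts` are 0-based cluster offsets.
fit_random_core <- function(y, x, centre, Z = NULL, quad_points = 12L,
                            n_centres = max(centre)) {
  X <- cbind(1, x, Z)
  dimnames(X) <- NULL
  p <- ncol(X)
  starts <- c(0L, cumsum(tabulate(centre, n_centres)))
  starts <- unique(starts)  # drop empty clusters
  gh <- gauss_hermite(quad_points)
  storage.mode(X) <- "double"
  obj <- function(par) {
    val <- agq_nll(par, X, as.double(y), as.integer(starts),
                   gh$nodes, gh$weights)
    if (!is.finite(val)) 1e10 else val  # keep line searches warning-free
  }
  init <- fit_logistic(X, y)
  b0 <- if (is.null(init)) numeric(p) else unname(init$coefficients)
  fit <- tryCatch(
    stats::nlminb(c(b0, 0.5), obj, lower = c(rep(-Inf, p), 0),
                  control = list(rel.tol = 1e-10, iter.max = 200L)),
    error = function(e) NULL)
  if (!is.null(fit) && fit$convergence != 0) {
    # one restart from a boundary-adjacent start before declaring failure
    fit2 <- tryCatch(
      stats::nlminb(c(b0, 0.05), obj, lower = c(rep(-Inf, p), 0),
                    control = list(rel.tol = 1e-10, iter.max = 200L)),
      error = function(e) NULL)
    if (!is.null(fit2) &&
        (fit2$convergence == 0 || fit2$objective < fit$objective)) fit <- fit2
  }
  if (is.null(fit) || !is.finite(fit$objective)) {
    return(core_failure("optimiser-failure", length(y)))
  }
  par <- fit$par
  sigma_hat <- par[p + 1]
  se <- agq_wald_se(obj, par, p, sigma_hat)
  if (is.null(se)) return(core_failure("optimiser-failure", length(y)))
  core_result(par[2L], se, fit$convergence == 0, length(y),
              extra = list(sigma = sigma_hat, icc = sigma_to_icc(sigma_hat)))
}

# Wald SE of the treatment coefficient from a finite-difference Hessian of
# the negative log-likelihood. At a boundary solution (sigma ~ 0) the sigma
# row of the full Hessian is degenerate, so the fixed-effect block is used
# with sigma held at its estimate.
agq_wald_se <- function(obj, par, p, sigma_hat) {
  use_full <- sigma_hat > 1e-3
  H <- tryCatch({
    if (use_full) {
      stats::optimHess(par, obj)
    } else {
      stats::optimHess(par[seq_len(p)],
                       function(b) obj(c(b, sigma_hat)))
    }
  }, error = function(e) NULL)
  if (is.null(H)) return(NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) && use_full) {
    # near-singular full Hessian: retry the beta block
    H <- tryCatch(stats::optimHess(par[seq_len(p)],
                                   function(b) obj(c(b, sigma_hat))),
                  error = function(e) NULL)
    if (is.null(H)) return(NULL)
    V <- tryCatch(solve(H), error = function(e) NULL)
  }
  if (is.null(V) || !is.finite(V[2L, 2L]) || V[2L, 2L] < 0) return(NULL)
  sqrt(V[2L, 2L])
}
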