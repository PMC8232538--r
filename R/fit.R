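#' @name inference
#' @title Posterior inference by Polya-Gamma blocked Gibbs sampling
#'
#' @description
#' The logistic likelihood is augmented with Polya-Gamma latent
#' variables `omega_i ~ PG(1, eta_i)`, which renders every latent
#' Gaussian block (fixed effects, spline coefficients, spatial field,
#' household and community effects) conditionally Gaussian and every
#' variance parameter conditionally inverse-gamma.  Sum-to-zero
#' identifiability constraints on the spatial field and each smooth are
#' imposed by conditioning the Gaussian block draw on the constraint
#' ("conditioning by kriging").  The sampler is an implementation
#' choice: correctness is defined by agreement with brute-force
#' posteriors on small instances, which the test suite enforces.
NULL

#' Bernoulli log likelihood on the logit scale
#'
#' `sum(y * eta - log(1 + exp(eta)))`, evaluated overflow-safely for
#' `|eta|` up to several hundred.
#'
#' @param eta linear predictor values.
#' @param y binary outcomes (same length).
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(eta, y) {
  if (length(eta) != length(y)) {
    stop("eta and y have different lengths", call. = FALSE)
  }
  if (any(!y %in% c(0, 1))) stop("y must be binary", call. = FALSE)
  # log(1 + exp(eta)) = max(eta, 0) + log1p(exp(-|eta|))
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' Sampler settings
#'
#' @param iterations total Gibbs iterations (default 4000).
#' @param burnin discarded initial iterations (default 1000).
#' @param seed integer seed (required; reproducibility contract).
#' @return object of class `sar_engine`.
#' @export
sar_engine <- function(iterations = 4000, burnin = 1000, seed) {
  if (missing(seed)) stop("engine seed is required", call. = FALSE)
  stopifnot(iterations > burnin, burnin >= 0)
  structure(list(iterations = iterations, burnin = burnin, seed = seed),
            class = "sar_engine")
}

# draw from N(P^{-1} rhs, P^{-1}), optionally conditioned on a'theta = 0
draw_gaussian_block <- function(P, rhs, constraint = NULL) {
  ch <- chol(P)
  m <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  theta <- m + backsolve(ch, rnorm(length(rhs)))
  if (!is.null(constraint)) {
    h <- backsolve(ch, backsolve(ch, constraint, transpose = TRUE))
    theta <- theta - h * sum(constraint * theta) / sum(constraint * h)
  }
  as.numeric(theta)
}

# grouped sums of x by integer index (1..nlev); empty groups give 0
gsum <- function(x, idx, nlev) {
  out <- numeric(nlev)
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs))] <- rs
  out
}

#' Fit a structured additive logistic model
#'
#' Runs the blocked Polya-Gamma Gibbs sampler for the model defined by
#' `model` on women-level records, returning posterior summaries (mean,
#' sd, 2.5% and 97.5% quantiles) per parameter block, retained draws
#' for the blocks needed downstream, deviance draws for DIC, and basic
#' mixing diagnostics.
#'
#' @param records data frame with the outcome column, covariates and
#'   `region` / `cluster` / `household` id columns named in `model`.
#' @param graph a [region_graph()] covering every observed region; may
#'   be `NULL` for models with `spatial = FALSE`.
#' @param model a [sar_model()] specification.
#' @param engine a [sar_engine()] settings object.
#' @param outcome name of the binary outcome column
#'   (default `"sufficient"`).
#' @return object of class `sar_fit`.
#' @export
fit_sar <- function(records, graph, model, engine,
                    outcome = "sufficient") {
  stopifnot(inherits(model, "sar_model"), inherits(engine, "sar_engine"))
  if (isTRUE(model$spatial) && !inherits(graph, "region_graph")) {
    stop("a region_graph is required when the model has a spatial term",
         call. = FALSE)
  }
  if (!outcome %in% names(records)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  y <- records[[outcome]]
  if (any(is.na(y)) || any(!y %in% c(0, 1))) {
    stop("outcome must be complete and binary; apply ",
         "filter_complete_cases() first", call. = FALSE)
  }
  n <- length(y)
  pr <- model$priors

  # --- fixed-effect design (intercept always present) ---
  X <- encode_fixed(records, model$fixed)
  p <- ncol(X)
  P0 <- diag(rep(pr$fixed_prec, p), p)

  # --- smooth terms on unique covariate values ---
  sm <- list()
  for (s in model$smooths) {
    z <- records[[s$covariate]]
    if (is.null(z)) stop("smooth covariate '", s$covariate, "' missing",
                         call. = FALSE)
    uz <- sort(unique(z))
    iz <- match(z, uz)
    Bu <- build_spline_basis(uz, k = s$k, degree = s$degree)
    nobs_u <- tabulate(iz, nbins = length(uz))
    sm[[s$covariate]] <- list(
      uz = uz, iz = iz, Bu = Bu, nobs_u = nobs_u,
      K = rw2_penalty(s$k), k = s$k, degree = s$degree,
      knots = attr(Bu, "knots"),
      A = colSums(Bu * nobs_u)          # sum over observations
    )
  }

  # --- spatial structure ---
  use_sp <- isTRUE(model$spatial)
  if (use_sp) {
    ir <- match(records[[model$region]], graph$ids)
    if (any(is.na(ir))) {
      stop("records reference regions absent from the graph: ",
           paste(unique(records[[model$region]][is.na(ir)]), collapse = ", "),
           call. = FALSE)
    }
    R <- length(graph$ids)
    Q <- icar_precision(graph)
    rank_Q <- R - length(graph_components(graph))
  }

  # --- unstructured random effects ---
  use_re <- model$use_household
  if (use_re) {
    cl_lev <- unique(records[[model$cluster]])
    hh_lev <- unique(records[[model$household]])
    ic <- match(records[[model$cluster]], cl_lev)
    ih <- match(records[[model$household]], hh_lev)
    n_c <- length(cl_lev); n_h <- length(hh_lev)
  }

  set.seed(engine$seed)
  # state
  beta <- rep(0, p)
  theta <- lapply(sm, function(s) rep(0, s$k))
  if (use_sp) f <- rep(0, R)
  tau2_sm <- setNames(rep(0.1, length(sm)), names(sm))
  tau2_s <- 0.1
  if (use_re) {
    v <- rep(0, n_c); u <- rep(0, n_h)
    sig2_v <- 0.1; sig2_u <- 0.1
  }
  eta_fix <- as.numeric(X %*% beta)
  eta_sm <- lapply(sm, function(s) rep(0, n))
  eta_sp <- rep(0, n)
  eta_re <- rep(0, n)
  eta <- eta_fix + Reduce(`+`, eta_sm, rep(0, n)) + eta_sp + eta_re

  S <- engine$iterations - engine$burnin
  draws_fixed <- matrix(NA_real_, S, p, dimnames = list(NULL, colnames(X)))
  draws_theta <- lapply(sm, function(s) matrix(NA_real_, S, s$k))
  draws_spatial <- if (use_sp) {
    matrix(NA_real_, S, R, dimnames = list(NULL, graph$ids))
  }
  vn <- c(if (length(sm)) paste0("tau2_", names(sm)),
          if (use_sp) "tau2_spatial",
          if (use_re) c("sigma2_community", "sigma2_household"))
  draws_var <- matrix(NA_real_, S, length(vn), dimnames = list(NULL, vn))
  draws_dev <- numeric(S)
  eta_sum <- rep(0, n)
  kappa <- y - 0.5

  for (it in seq_len(engine$iterations)) {
    omega <- rpg_vec(eta)

    # fixed effects
    r <- kappa - omega * (eta - eta_fix)
    P <- crossprod(X, X * omega) + P0
    beta <- draw_gaussian_block(P, crossprod(X, r))
    eta <- eta - eta_fix
    eta_fix <- as.numeric(X %*% beta)
    eta <- eta + eta_fix

    # smooths
    for (j in seq_along(sm)) {
      s <- sm[[j]]
      r_u <- gsum(kappa - omega * (eta - eta_sm[[j]]), s$iz, length(s$uz))
      w_u <- gsum(omega, s$iz, length(s$uz))
      P <- crossprod(s$Bu, s$Bu * w_u) + s$K / tau2_sm[[j]]
      th <- draw_gaussian_block(P, crossprod(s$Bu, r_u), constraint = s$A)
      theta[[j]] <- th
      eta <- eta - eta_sm[[j]]
      eta_sm[[j]] <- as.numeric(s$Bu %*% th)[s$iz]
      eta <- eta + eta_sm[[j]]
      tau2_sm[[j]] <- 1 / rgamma(1, pr$a + (s$k - 2) / 2,
                                 pr$b + sum(th * (s$K %*% th)) / 2)
    }

    # spatial field
    if (use_sp) {
      r_r <- gsum(kappa - omega * (eta - eta_sp), ir, R)
      w_r <- gsum(omega, ir, R)
      P <- Q / tau2_s
      diag(P) <- diag(P) + w_r
      f <- draw_gaussian_block(P, r_r, constraint = rep(1, R))
      eta <- eta - eta_sp
      eta_sp <- f[ir]
      eta <- eta + eta_sp
      tau2_s <- 1 / rgamma(1, pr$a + rank_Q / 2,
                           pr$b + sum(f * (Q %*% f)) / 2)
    }

    # household / community effects (diagonal conditionals)
    if (use_re) {
      eta_v <- v[ic]; eta_u <- u[ih]
      r_c <- gsum(kappa - omega * (eta - eta_v), ic, n_c)
      w_c <- gsum(omega, ic, n_c) + 1 / sig2_v
      v <- r_c / w_c + rnorm(n_c) / sqrt(w_c)
      eta <- eta - eta_v + v[ic]
      sig2_v <- 1 / rgamma(1, pr$a + n_c / 2, pr$b + sum(v^2) / 2)

      r_h <- gsum(kappa - omega * (eta - eta_u), ih, n_h)
      w_h <- gsum(omega, ih, n_h) + 1 / sig2_u
      u <- r_h / w_h + rnorm(n_h) / sqrt(w_h)
      eta <- eta - eta_u + u[ih]
      sig2_u <- 1 / rgamma(1, pr$a + n_h / 2, pr$b + sum(u^2) / 2)
      eta_re <- v[ic] + u[ih]
    }

    if (it > engine$burnin) {
      sidx <- it - engine$burnin
      draws_fixed[sidx, ] <- beta
      for (j in seq_along(sm)) draws_theta[[j]][sidx, ] <- theta[[j]]
      if (use_sp) draws_spatial[sidx, ] <- f
      draws_var[sidx, ] <- c(if (length(sm)) tau2_sm,
                             if (use_sp) tau2_s,
                             if (use_re) c(sig2_v, sig2_u))
      draws_dev[sidx] <- -2 * log_likelihood(eta, y)
      eta_sum <- eta_sum + eta
    }
  }

  eta_mean <- eta_sum / S
  ess_fixed <- apply(draws_fixed, 2L, ess)
  min_ess <- min(ess_fixed,
                 if (use_sp) apply(draws_spatial, 2L, ess) else Inf)
  converged <- min_ess >= 30
  if (!converged) {
    warning("low effective sample size (min ", round(min_ess, 1),
            "); treat summaries with caution", call. = FALSE)
  }

  out <- list(
    level = model$level,
    model = model,
    graph = graph,
    summaries = list(
      fixed = summarize_draws(draws_fixed, colnames(X)),
      spatial = if (use_sp) summarize_draws(draws_spatial, graph$ids),
      variances = if (length(vn)) summarize_draws(draws_var, vn)
    ),
    draws = list(fixed = draws_fixed, theta = draws_theta,
                 spatial = draws_spatial, variances = draws_var,
                 deviance = draws_dev),
    smooth_info = sm,
    eta_mean = eta_mean,
    y = y,
    diagnostics = list(ess_fixed = ess_fixed, min_ess = min_ess,
                       converged = converged),
    engine = engine,
    fingerprint = data_fingerprint(y)
  )
  class(out) <- "sar_fit"
  out
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("sar_fit", x$level, "-", length(x$y), "observations,",
      if (!is.null(x$summaries$spatial)) {
        paste(nrow(x$summaries$spatial), "regions;")
      } else "no spatial term;",
      nrow(x$draws$fixed), "retained draws; min ESS",
      round(x$diagnostics$min_ess, 1), "\n")
  cat("\nFixed effects (logit scale):\n")
  print(round(x$summaries$fixed, 3))
  if (!is.null(x$summaries$variances)) {
    cat("\nVariance parameters:\n")
    print(round(x$summaries$variances, 4))
  }
  invisible(x)
}

#' Posterior odds-ratio summary of a coefficient
#'
#' Quantiles commute with the exponential transform, the mean does not:
#' with draws available the odds-ratio mean is the mean of the
#' exponentiated draws; from summaries alone the mean is `exp(mean)` and
#' flagged approximate.
#'
#' @param draws numeric vector of posterior coefficient draws, or `NULL`.
#' @param summary named vector/list with `mean`, `q2.5`, `q97.5`
#'   (used when `draws` is `NULL`).
#' @return list with `mean`, `q2.5`, `q97.5`, `approximate_mean`.
#' @export
posterior_transform_or <- function(draws = NULL, summary = NULL) {
  if (!is.null(draws)) {
    list(mean = mean(exp(draws)),
         q2.5 = as.numeric(quantile(exp(draws), 0.025, names = FALSE)),
         q97.5 = as.numeric(quantile(exp(draws), 0.975, names = FALSE)),
         approximate_mean = FALSE)
  } else if (!is.null(summary)) {
    list(mean = exp(summary[["mean"]]),
         q2.5 = exp(summary[["q2.5"]]),
         q97.5 = exp(summary[["q97.5"]]),
         approximate_mean = TRUE)
  } else {
    stop("either draws or summary must be supplied", call. = FALSE)
  }
}
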