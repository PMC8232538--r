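#' @name synthetic_data
#' @title DHS-like synthetic survey data with known ground truth
#'
#' @description
#' Restricted-access survey microdata cannot ship with the package, so
#' validation rests on a generator that emulates the structure of a
#' national women's health survey: regions on a contiguity graph,
#' clusters (communities) nested in regions, households nested in
#' clusters, categorical covariates drawn from realistic marginals,
#' metrical covariates (age, age at first birth, antenatal-care visits),
#' and a binary knowledge outcome produced by the structured additive
#' predictor with known fixed effects, smooth functions, ICAR spatial
#' field and household/community random effects.
NULL

#' Draw an intrinsic CAR (ICAR) spatial field
#'
#' Samples from the intrinsic Gaussian Markov random field with
#' precision `Q / tau2` (`Q` the graph Laplacian), made proper by
#' restriction to the sum-to-zero subspace: the constant null eigenvector
#' is removed and each remaining eigencomponent `l` is drawn
#' `N(0, tau2 / lambda_l)`.
#'
#' @param graph a connected [region_graph()].
#' @param tau2 positive conditional variance parameter.
#' @param seed optional integer seed.
#' @return named numeric vector of per-region values summing to zero.
#' @export
sample_icar_field <- function(graph, tau2, seed = NULL) {
  stopifnot(tau2 > 0)
  if (length(graph_components(graph)) > 1L) {
    stop("graph is disconnected; sample per component with a ",
         "sum-to-zero constraint in each connected component", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  Q <- icar_precision(graph)
  eg <- eigen(Q, symmetric = TRUE)
  R <- nrow(Q)
  lambda <- eg$values[seq_len(R - 1L)]   # positive eigenvalues
  z <- rnorm(R - 1L, sd = sqrt(tau2 / lambda))
  f <- as.numeric(eg$vectors[, seq_len(R - 1L), drop = FALSE] %*% z)
  setNames(f, graph$ids)
}

#' Default nonlinear truth: woman's current age
#'
#' Smooth effect rising with age to a peak at 35 years and declining
#' steeply afterwards (asymmetric Gaussian bump).  Values outside the
#' reproductive age range 15-49 are an error.
#'
#' @param age ages in years within `[15, 49]`.
#' @param amplitude peak height on the logit scale (default 0.8).
#' @param center_on optional age sample; if given, the function value is
#'   centered to mean zero over that sample.
#' @return numeric effect values.
#' @export
default_smooth_age <- function(age, amplitude = 0.8, center_on = NULL) {
  if (any(age < 15 | age > 49)) {
    stop("age outside the supported range [15, 49]", call. = FALSE)
  }
  shape <- function(a) {
    s <- ifelse(a <= 35, 8, 5)    # gradual rise, steep decline
    amplitude * exp(-0.5 * ((a - 35) / s)^2)
  }
  out <- shape(age)
  if (!is.null(center_on)) out <- out - mean(shape(center_on))
  out
}

#' Default nonlinear truth: age at first birth
#'
#' Flat at zero below 20 years, then increasing linearly: women who
#' start childbearing later have higher knowledge on the logit scale.
#'
#' @param z ages at first birth in years.
#' @param slope increase per year above 20 (default 0.04).
#' @param center_on optional sample for mean-zero centering.
#' @return numeric effect values.
#' @export
default_smooth_afb <- function(z, slope = 0.04, center_on = NULL) {
  shape <- function(a) slope * pmax(a - 20, 0)
  out <- shape(z)
  if (!is.null(center_on)) out <- out - mean(shape(center_on))
  out
}

#' Default nonlinear truth: number of antenatal-care visits
#'
#' Linear increase in knowledge with each additional ANC visit.
#'
#' @param z visit counts.
#' @param slope increase per visit (default 0.06).
#' @param center_on optional sample for mean-zero centering.
#' @return numeric effect values.
#' @export
default_smooth_anc <- function(z, slope = 0.06, center_on = NULL) {
  out <- slope * z
  if (!is.null(center_on)) out <- out - mean(slope * center_on)
  out
}

#' Default covariate level sets (reference level first)
#' @return named list of level vectors.
#' @export
default_fixed_levels <- function() {
  list(
    residence  = c("rural", "urban"),
    marital    = c("ever_married", "never_married"),
    religion   = c("others", "islam", "christians"),
    ethnicity  = c("others", "igbo", "yoruba", "hausa_fulani"),
    education  = c("none", "primary", "secondary", "higher"),
    wealth     = c("poorest", "poorer", "middle", "richer", "richest"),
    working    = c("unemployed", "employed"),
    newspaper  = c("no", "yes"),
    radio      = c("no", "yes"),
    television = c("no", "yes")
  )
}

#' Default covariate marginal probabilities
#'
#' National survey marginals for Nigerian women of reproductive age
#' (rural 58.0%, the three major ethnic groups 31.9/17.1/12.8%, 75.9%
#' ever married, newspaper readership 16.5%, and so on).
#'
#' @return named list of probability vectors aligned with
#'   [default_fixed_levels()].
#' @export
default_marginals <- function() {
  list(
    residence  = c(rural = 0.580, urban = 0.420),
    marital    = c(ever_married = 0.759, never_married = 0.241),
    religion   = c(others = 0.008, islam = 0.479, christians = 0.513),
    ethnicity  = c(others = 0.382, igbo = 0.171, yoruba = 0.128,
                   hausa_fulani = 0.319),
    education  = c(none = 0.320, primary = 0.152, secondary = 0.413,
                   higher = 0.115),
    wealth     = c(poorest = 0.170, poorer = 0.191, middle = 0.213,
                   richer = 0.222, richest = 0.204),
    working    = c(unemployed = 0.337, employed = 0.663),
    newspaper  = c(no = 0.835, yes = 0.165),
    radio      = c(no = 0.424, yes = 0.576),
    television = c(no = 0.474, yes = 0.526)
  )
}

#' Default true fixed effects (log odds ratios vs the reference level)
#' @return named list, one named vector of non-reference effects per
#'   covariate.
#' @export
default_truth_gamma <- function() {
  list(
    residence  = c(urban = log(1.061)),
    marital    = c(never_married = log(0.799)),
    religion   = c(islam = log(0.789), christians = log(0.785)),
    ethnicity  = c(igbo = log(1.052), yoruba = log(1.159),
                   hausa_fulani = log(1.043)),
    education  = c(primary = log(1.035), secondary = log(1.084),
                   higher = log(1.371)),
    wealth     = c(poorer = log(1.016), middle = log(0.996),
                   richer = log(1.067), richest = log(1.153)),
    working    = c(employed = log(0.873)),
    newspaper  = c(yes = log(0.967)),
    radio      = c(yes = log(0.947)),
    television = c(yes = log(0.818))
  )
}

#' Generator configuration
#'
#' @param n_women number of respondents.
#' @param graph_rows,graph_cols lattice dimensions of the default test
#'   geography (6 x 6 rook lattice, 36 regions).
#' @param clusters_per_region survey clusters (communities) per region.
#' @param marginals named list of covariate marginal probabilities; each
#'   vector must sum to 1.
#' @param gamma named list of true non-reference fixed effects.
#' @param beta0 intercept; `NULL` (default) solves for the value that
#'   gives `target_prevalence` on average given the marginals.
#' @param target_prevalence marginal outcome prevalence used when
#'   `beta0` is `NULL` (default 0.592).
#' @param smooths named list of truth functions of the metrical
#'   covariates (`age`, `age_first_birth`, `anc_visits`); each is
#'   centered over the sampled values before entering the predictor.
#'   Set to `list()` for no nonlinear effects.
#' @param tau2_spatial ICAR variance of the true spatial field
#'   (default 0.5); the field is drawn once per dataset.  `0` disables
#'   the spatial field.
#' @param spatial_field optional named per-region vector used as the true
#'   spatial field instead of drawing one (recovery experiments).
#' @param sd_household,sd_community standard deviations of iid household
#'   and community effects (default 0.3 each; `0` disables a term,
#'   giving an "M2-type" truth).
#' @return config list for [simulate_dataset()].
#' @export
sim_config <- function(n_women = 2000, graph_rows = 6, graph_cols = 6,
                       clusters_per_region = 8,
                       marginals = default_marginals(),
                       gamma = default_truth_gamma(),
                       beta0 = NULL, target_prevalence = 0.592,
                       smooths = list(age = default_smooth_age,
                                      age_first_birth = default_smooth_afb,
                                      anc_visits = default_smooth_anc),
                       tau2_spatial = 0.5, spatial_field = NULL,
                       sd_household = 0.3, sd_community = 0.3) {
  stopifnot(tau2_spatial >= 0, sd_household >= 0, sd_community >= 0)
  list(n_women = n_women, graph_rows = graph_rows, graph_cols = graph_cols,
       clusters_per_region = clusters_per_region, marginals = marginals,
       gamma = gamma, beta0 = beta0, target_prevalence = target_prevalence,
       smooths = smooths, tau2_spatial = tau2_spatial,
       spatial_field = spatial_field,
       sd_household = sd_household, sd_community = sd_community)
}

# age distribution: group shares 17.9/34.2/28.4/19.6% for <20, 20s, 30s, 40+
sample_ages <- function(n) {
  grp <- sample.int(4L, n, replace = TRUE,
                    prob = c(0.179, 0.342, 0.284, 0.196))
  lo <- c(15, 20, 30, 40)[grp]
  hi <- c(19, 29, 39, 49)[grp]
  lo + floor(runif(n) * (hi - lo + 1))
}

#' Simulate a hierarchical survey dataset from known truth
#'
#' Draws covariates from the configured marginals, assembles the
#' structured additive predictor
#' `eta = beta0 + x'gamma + sum_j f_j(z_j) + f_s(region) + v_cluster +
#' u_household`, and samples `sufficient ~ Bernoulli(plogis(eta))`.
#' The five knowledge responses are then filled in consistently with the
#' composite outcome (all "yes" iff sufficient).
#'
#' @param config a [sim_config()] list.
#' @param seed integer seed; the same config and seed reproduce the
#'   dataset bit for bit.
#' @return object of class `sar_sim`: `records` (data frame), `graph`,
#'   `truth` (intercept, gamma, spatial field, smooth values, effect
#'   draws), `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  for (cv in names(config$marginals)) {
    p <- config$marginals[[cv]]
    if (abs(sum(p) - 1) > 1e-8) {
      stop("marginals for '", cv, "' sum to ", sum(p), ", not 1", call. = FALSE)
    }
  }
  set.seed(seed)
  n <- config$n_women
  graph <- make_lattice_graph(config$graph_rows, config$graph_cols)
  R <- length(graph$ids)

  # nesting: region -> clusters -> households -> women
  region_idx <- sample.int(R, n, replace = TRUE)
  region <- graph$ids[region_idx]
  cluster_no <- sample.int(config$clusters_per_region, n, replace = TRUE)
  cluster <- paste0(region, "_c", cluster_no)
  # group women within a cluster into households of size 1 (80%) or 2
  household <- character(n)
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    sizes <- integer(0)
    while (sum(sizes) < length(idx)) {
      sizes <- c(sizes, if (runif(1) < 0.8) 1L else 2L)
    }
    hh <- rep(seq_along(sizes), times = sizes)[seq_along(idx)]
    household[idx] <- paste0(cl, "_h", hh)
  }

  records <- data.frame(region = region, cluster = cluster,
                        household = household,
                        stringsAsFactors = FALSE)
  for (cv in names(config$marginals)) {
    p <- config$marginals[[cv]]
    records[[cv]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  records$age <- sample_ages(n)
  afb <- pmin(records$age, pmax(12, round(rnorm(n, 20, 4))))
  records$age_first_birth <- pmin(afb, 35)
  records$anc_visits <- pmin(rpois(n, 4), 20L)

  # fixed-effect part
  gamma_flat <- numeric(0)
  eta_fix <- numeric(n)
  for (cv in names(config$gamma)) {
    g <- config$gamma[[cv]]
    for (l in names(g)) {
      gamma_flat[paste0(cv, ":", l)] <- g[[l]]
      eta_fix <- eta_fix + g[[l]] * (records[[cv]] == l)
    }
  }
  beta0 <- config$beta0
  if (is.null(beta0)) {
    # expected fixed-effect contribution under the marginals
    e_fix <- 0
    for (cv in names(config$gamma)) {
      g <- config$gamma[[cv]]
      e_fix <- e_fix + sum(g * config$marginals[[cv]][names(g)])
    }
    beta0 <- qlogis(config$target_prevalence) - e_fix
  }

  # centered smooth contributions
  smooth_vals <- list()
  eta_smooth <- numeric(n)
  for (cv in names(config$smooths)) {
    f <- config$smooths[[cv]]
    z <- records[[cv]]
    v <- f(z, center_on = z)
    smooth_vals[[cv]] <- v
    eta_smooth <- eta_smooth + v
  }

  spatial <- if (!is.null(config$spatial_field)) {
    fld <- config$spatial_field
    if (!all(graph$ids %in% names(fld))) {
      stop("spatial_field must name every region", call. = FALSE)
    }
    fld[graph$ids]
  } else if (config$tau2_spatial > 0) {
    sample_icar_field(graph, config$tau2_spatial)
  } else {
    setNames(rep(0, R), graph$ids)
  }
  v_cl <- setNames(rnorm(length(unique(cluster)), 0, config$sd_community),
                   unique(cluster))
  u_hh <- setNames(rnorm(length(unique(household)), 0, config$sd_household),
                   unique(household))

  eta <- beta0 + eta_fix + eta_smooth + spatial[region] +
    v_cl[cluster] + u_hh[household]
  y <- rbinom(n, 1L, plogis(eta))

  # knowledge responses consistent with the composite outcome
  qs <- knowledge_questions()
  resp <- matrix(1L, n, length(qs), dimnames = list(NULL, qs))
  insuff <- which(y == 0L)
  p_no <- c(heard_hiv = 0.999, mtct_pregnancy = 0.60, mtct_delivery = 0.70,
            mtct_breastfeeding = 0.90, knows_pmtct_drugs = 0.75)
  for (q in qs) {
    resp[insuff, q] <- rbinom(length(insuff), 1L, p_no[[q]])
  }
  all_yes <- insuff[rowSums(resp[insuff, , drop = FALSE]) == length(qs)]
  resp[all_yes, "knows_pmtct_drugs"] <- 0L
  records <- cbind(records, as.data.frame(resp))
  records$sufficient <- y

  truth <- list(beta0 = beta0, gamma = gamma_flat, spatial = spatial,
                smooth_values = smooth_vals, smooths = config$smooths,
                tau2_spatial = config$tau2_spatial,
                sd_household = config$sd_household,
                sd_community = config$sd_community,
                cluster_effects = v_cl, household_effects = u_hh,
                eta = eta)
  structure(list(records = records, graph = graph, truth = truth,
                 config = config, seed = seed),
            class = "sar_sim")
}

#' @export
print.sar_sim <- function(x, ...) {
  cat("sar_sim:", nrow(x$records), "women,",
      length(x$graph$ids), "regions,",
      length(unique(x$records$cluster)), "clusters,",
      length(unique(x$records$household)), "households; prevalence",
      round(mean(x$records$sufficient), 3), "\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `women.csv` (one row per respondent), `neighbors.txt` (the
#' region graph as a neighbour list) and `truth.yaml` (ground-truth
#' parameters for later recovery checks).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  women <- file.path(dir, "women.csv")
  nbfile <- file.path(dir, "neighbors.txt")
  truthfile <- file.path(dir, "truth.yaml")
  write.csv(sim$records, women, row.names = FALSE)
  write_neighbor_list(sim$graph, nbfile)
  truth <- sim$truth
  yaml::write_yaml(list(
    seed = sim$seed,
    beta0 = truth$beta0,
    gamma = as.list(truth$gamma),
    tau2_spatial = truth$tau2_spatial,
    sd_household = truth$sd_household,
    sd_community = truth$sd_community,
    spatial = as.list(truth$spatial)
  ), truthfile)
  invisible(c(women = women, neighbors = nbfile, truth = truthfile))
}
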