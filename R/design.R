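#' @name design
#' @title Structured additive design components
#'
#' @description
#' The linear predictor of the model is
#' \deqn{\eta_i = x_i'\beta + \sum_j f_j(z_{ij}) + f_{s}(s_i) + v_{c(i)} + u_{h(i)}}
#' with dummy-coded fixed effects, penalized B-spline smooths `f_j` of
#' metrical covariates under a second-order random-walk (RW2) prior, an
#' intrinsic CAR spatial field `f_s` over regions, and community/household
#' random effects.  This file builds the deterministic pieces: design
#' matrices, spline bases, penalty and precision matrices, and the model
#' and prior specifications (M1: spatial only; M2: adds fixed effects and
#' smooths; M3: adds household and community effects).
NULL

#' Dummy-code categorical covariates
#'
#' Builds the fixed-effect design matrix: one intercept column plus one
#' 0/1 indicator per non-reference level of each covariate.  The first
#' level of each declared level set is the reference.
#'
#' @param records data frame of respondent records.
#' @param spec named list; `spec[[covariate]]` is the full level vector
#'   with the reference level first.
#' @return numeric matrix with columns `(Intercept)` and
#'   `<covariate>:<level>`.
#' @export
encode_fixed <- function(records, spec) {
  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  for (cv in names(spec)) {
    lv <- spec[[cv]]
    if (!cv %in% names(records)) {
      stop("fixed covariate '", cv, "' not in records", call. = FALSE)
    }
    v <- as.character(records[[cv]])
    bad <- which(!v %in% lv)
    if (length(bad) > 0) {
      stop("record ", bad[[1]], ": covariate '", cv,
           "' has unseen level '", v[bad[[1]]], "'", call. = FALSE)
    }
    for (l in lv[-1]) cols[[paste0(cv, ":", l)]] <- as.numeric(v == l)
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  mat
}

#' Equidistant B-spline basis
#'
#' Basis of `k` B-splines of the given degree on equally spaced knots
#' spanning the observed range (Eilers-Marx P-spline construction, so
#' rows sum to one on the data range).
#'
#' @param z metrical covariate values (at least 4 distinct values).
#' @param k number of basis functions (coefficients); `k >= degree + 2`.
#' @param degree spline degree (3 = cubic; 0 gives histogram indicators).
#' @return matrix with `length(z)` rows and `k` columns; the knot vector
#'   is stored in attribute `knots`, the degree in `degree`.
#' @export
build_spline_basis <- function(z, k = 20, degree = 3) {
  if (length(unique(z)) < 4L) {
    stop("covariate has fewer than 4 distinct values; ",
         "use a linear (fixed) term instead of a smooth", call. = FALSE)
  }
  if (k < degree + 2) stop("need k >= degree + 2", call. = FALSE)
  a <- min(z); b <- max(z)
  nseg <- k - degree
  idx <- (-degree):(nseg + degree)
  knots <- a + (b - a) * idx / nseg
  knots[idx == 0] <- a       # boundary knots exact so evaluation at the
  knots[idx == nseg] <- b    # data range never falls outside the basis

  B <- splines::splineDesign(knots, z, ord = degree + 1, outer.ok = FALSE)
  attr(B, "knots") <- knots
  attr(B, "degree") <- degree
  B
}

#' Second-order random-walk penalty matrix
#'
#' `K = D2' D2` with `D2` the `(k-2) x k` second-difference operator,
#' the penalty implied by the RW2 prior
#' `beta_t = 2 beta_{t-1} - beta_{t-2} + u_t`, `u_t ~ N(0, tau2)`.
#' `K` annihilates constant and linear coefficient sequences and has
#' rank `k - 2`.
#'
#' @param k coefficient count, at least 3.
#' @return `k x k` symmetric positive semidefinite matrix.
#' @export
rw2_penalty <- function(k) {
  if (k < 3L) stop("RW2 penalty needs at least 3 coefficients", call. = FALSE)
  D2 <- diff(diag(k), differences = 2)
  crossprod(D2)
}

#' Smooth-term specification
#'
#' @param covariate name of the metrical covariate column.
#' @param k number of B-spline coefficients (default 20).
#' @param degree spline degree (default cubic).
#' @return object of class `sar_smooth`.
#' @export
sar_smooth <- function(covariate, k = 20, degree = 3) {
  structure(list(covariate = covariate, k = k, degree = degree),
            class = "sar_smooth")
}

#' Prior configuration
#'
#' Vague zero-mean normal priors for the intercept and fixed effects,
#' and a weakly informative inverse-gamma `IG(a, b)` hyperprior for
#' every variance parameter (smooth, spatial, household, community).
#'
#' @param a,b inverse-gamma shape and scale, both positive
#'   (default 0.001 each).
#' @param fixed_prec prior precision of fixed effects (default 1e-6).
#' @return object of class `sar_priors`.
#' @export
sar_priors <- function(a = 0.001, b = 0.001, fixed_prec = 1e-6) {
  stopifnot(a > 0, b > 0, fixed_prec > 0)
  structure(list(a = a, b = b, fixed_prec = fixed_prec),
            class = "sar_priors")
}

#' Model specification for the M1/M2/M3 ladder
#'
#' `M1` contains the intercept and the ICAR spatial field only; `M2`
#' adds the fixed effects and the smooth terms; `M3` adds household and
#' community random effects.  The ladder is nested by construction.
#'
#' @param level one of `"M1"`, `"M2"`, `"M3"`.
#' @param fixed named list of level vectors (reference first), as for
#'   [encode_fixed()]; used by M2/M3.
#' @param smooths list of [sar_smooth()] terms; used by M2/M3.
#' @param priors a [sar_priors()] object.
#' @param region,cluster,household id column names in the data.
#' @param spatial logical; drop the spatial field entirely when `FALSE`
#'   (outside the M1-M3 ladder; used for reduced models and validation
#'   against analytically tractable posteriors).
#' @return object of class `sar_model`.
#' @export
sar_model <- function(level = c("M3", "M2", "M1"), fixed = list(),
                      smooths = list(), priors = sar_priors(),
                      region = "region", cluster = "cluster",
                      household = "household", spatial = TRUE) {
  level <- match.arg(level)
  if (length(smooths) > 0 && !all(vapply(smooths, inherits, TRUE, "sar_smooth"))) {
    stop("smooths must be a list of sar_smooth() terms", call. = FALSE)
  }
  structure(list(
    level = level,
    fixed = if (level == "M1") list() else fixed,
    smooths = if (level == "M1") list() else smooths,
    spatial = spatial,
    use_household = level == "M3",
    use_community = level == "M3",
    priors = priors,
    region = region, cluster = cluster, household = household
  ), class = "sar_model")
}

#' @export
print.sar_model <- function(x, ...) {
  cat("sar_model", x$level, "- fixed:",
      if (length(x$fixed)) paste(names(x$fixed), collapse = ", ") else "(none)",
      "| smooths:",
      if (length(x$smooths)) paste(vapply(x$smooths, `[[`, "", "covariate"),
                                   collapse = ", ") else "(none)",
      "| household/community:", x$use_household, "\n")
  invisible(x)
}
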