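#' @name reporting
#' @title Odds-ratio tables, significance maps and smooth curves
#'
#' @description
#' The reporting surfaces of an analysis: a posterior odds-ratio table
#' grouped by covariate with reference rows printed as 1/1/1; a
#' per-region three-way significance classification of the spatial
#' field (95% credible interval above zero, below zero, or covering
#' zero), joinable to any cartographic boundary file; and posterior-mean
#' smooth-effect curves flanked by 95% credible bands.
NULL

#' Classify regions by spatial-effect significance
#'
#' A region is `higher` when the 2.5% quantile of its spatial effect
#' exceeds 0, `lower` when the 97.5% quantile is below 0, and
#' `not_significant` otherwise; judged on the linear-predictor scale.
#'
#' @param fitted a [fit_sar()] result with spatial summaries.
#' @return data frame of class `sar_sigmap` with columns `region`,
#'   `mean`, `q2.5`, `q97.5`, `classification`.
#' @export
classify_regions <- function(fitted) {
  stopifnot(inherits(fitted, "sar_fit"))
  sp <- fitted$summaries$spatial
  if (is.null(sp)) stop("fitted model has no spatial summaries", call. = FALSE)
  if (any(is.na(sp$mean))) {
    stop("spatial summaries contain missing regions", call. = FALSE)
  }
  cls <- ifelse(sp$q2.5 > 0, "higher",
                ifelse(sp$q97.5 < 0, "lower", "not_significant"))
  out <- data.frame(region = rownames(sp), mean = sp$mean,
                    q2.5 = sp$q2.5, q97.5 = sp$q97.5,
                    classification = cls, row.names = NULL)
  class(out) <- c("sar_sigmap", class(out))
  out
}

#' Posterior odds-ratio table for the fixed effects
#'
#' Rows are grouped by covariate; the reference level of each covariate
#' is printed as 1/1/1.  Odds-ratio means are computed from the
#' exponentiated posterior draws (see [posterior_transform_or()]).
#'
#' @param fitted a [fit_sar()] result.
#' @param group optional respondent-group label column.
#' @return data frame with columns `covariate`, `level`, `mean`,
#'   `q2.5`, `q97.5` (and `group` if given); the intercept row keeps its
#'   exponentiated summary.
#' @export
or_table <- function(fitted, group = NULL) {
  stopifnot(inherits(fitted, "sar_fit"))
  draws <- fitted$draws$fixed
  spec <- fitted$model$fixed
  rows <- list()
  orx <- posterior_transform_or(draws[, "(Intercept)"])
  rows[[1]] <- data.frame(covariate = "(Intercept)", level = "",
                          mean = orx$mean, q2.5 = orx$q2.5, q97.5 = orx$q97.5)
  for (cv in names(spec)) {
    lv <- spec[[cv]]
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cv, level = lv[[1]], mean = 1, q2.5 = 1, q97.5 = 1)
    for (l in lv[-1]) {
      cl <- paste0(cv, ":", l)
      orx <- posterior_transform_or(draws[, cl])
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, level = l,
        mean = orx$mean, q2.5 = orx$q2.5, q97.5 = orx$q97.5)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(group)) out$group <- group
  rownames(out) <- NULL
  out
}

#' Posterior smooth-effect curve with 95% credible band
#'
#' Evaluates the fitted smooth of a metrical covariate on a grid
#' covering the observed range: posterior mean and pointwise 2.5%/97.5%
#' quantiles of the curve.
#'
#' @param fitted a [fit_sar()] result.
#' @param covariate name of a covariate modelled with a smooth term.
#' @param grid evaluation points; defaults to the observed unique values.
#' @return data frame of class `sar_curve` with columns `x`, `mean`,
#'   `lower`, `upper`.
#' @export
smooth_report <- function(fitted, covariate, grid = NULL) {
  stopifnot(inherits(fitted, "sar_fit"))
  j <- match(covariate, names(fitted$smooth_info))
  if (is.na(j)) {
    stop("covariate '", covariate, "' is not modelled with a smooth term",
         call. = FALSE)
  }
  info <- fitted$smooth_info[[j]]
  if (is.null(grid)) grid <- info$uz
  if (any(grid < min(info$uz) | grid > max(info$uz))) {
    stop("grid extends beyond the observed covariate range", call. = FALSE)
  }
  Bg <- splines::splineDesign(info$knots, grid, ord = info$degree + 1)
  curves <- fitted$draws$theta[[j]] %*% t(Bg)   # draws x grid
  out <- data.frame(
    x = grid,
    mean  = colMeans(curves),
    lower = apply(curves, 2L, quantile, probs = 0.025, names = FALSE),
    upper = apply(curves, 2L, quantile, probs = 0.975, names = FALSE)
  )
  class(out) <- c("sar_curve", class(out))
  out
}
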