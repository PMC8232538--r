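#' @name model_selection
#' @title DIC model comparison
#'
#' @description
#' The deviance information criterion is `DIC = Dbar + pD`, where `Dbar`
#' is the posterior mean deviance, `Dhat` the deviance at a plug-in
#' estimate, and `pD = Dbar - Dhat` the effective number of parameters.
#' `Dhat` is evaluated at the posterior mean of the *linear predictor*
#' (not of the parameters): under sum-to-zero constraints and latent
#' Gaussian blocks this plug-in is always well defined, and it is the
#' common convention for latent Gaussian models.  DIC variants differ in
#' this choice, so it is stated prominently here.
NULL

#' Bernoulli deviance
#'
#' `-2 * log_likelihood(eta, y)`.
#'
#' @inheritParams log_likelihood
#' @return scalar deviance.
#' @export
deviance_binary <- function(eta, y) {
  -2 * log_likelihood(eta, y)
}

#' Deviance information criterion of a fitted model
#'
#' @param fitted a [fit_sar()] result carrying deviance draws and the
#'   posterior-mean predictor.
#' @return object of class `sar_dic` with `Dbar`, `Dhat`, `pD`, `DIC`,
#'   `model` (label) and the data fingerprint.
#' @export
dic <- function(fitted) {
  stopifnot(inherits(fitted, "sar_fit"))
  dev <- fitted$draws$deviance
  if (is.null(dev) || length(dev) == 0L) {
    stop("fitted model carries no deviance draws", call. = FALSE)
  }
  Dbar <- mean(dev)
  Dhat <- deviance_binary(fitted$eta_mean, fitted$y)
  pD <- Dbar - Dhat
  structure(list(Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD,
                 model = fitted$level, fingerprint = fitted$fingerprint),
            class = "sar_dic")
}

#' @export
print.sar_dic <- function(x, ...) {
  cat(sprintf("%s: DIC %.2f (Dbar %.2f, Dhat %.2f, pD %.2f)\n",
              x$model, x$DIC, x$Dbar, x$Dhat, x$pD))
  invisible(x)
}

#' Rank models by DIC
#'
#' Models must have been fitted to the same data (checked by a content
#' fingerprint).  Lower DIC is better; ties are broken in favour of the
#' model with fewer effective parameters `pD`.
#'
#' @param results list of [dic()] results (at least two).
#' @param group optional respondent-group label attached to every row.
#' @return data frame sorted by ascending DIC with columns `model`,
#'   `Dbar`, `Dhat`, `pD`, `DIC`, `best` and optionally `group`.
#' @export
compare_models <- function(results, group = NULL) {
  if (length(results) < 2L) stop("need at least two models", call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "sar_dic")))
  fps <- vapply(results, `[[`, "", "fingerprint")
  if (length(unique(fps)) != 1L) {
    stop("models were fitted to different data; DIC values are not ",
         "comparable", call. = FALSE)
  }
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(model = r$model, Dbar = r$Dbar, Dhat = r$Dhat,
               pD = r$pD, DIC = r$DIC)
  }))
  tab <- tab[order(tab$DIC, tab$pD), , drop = FALSE]
  tab$best <- seq_len(nrow(tab)) == 1L
  if (!is.null(group)) tab$group <- group
  rownames(tab) <- NULL
  tab
}
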