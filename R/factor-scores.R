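#' Regression-method factor-score weights
#'
#' For a fitted latent-variable model, the regression (Thomson) weights
#' are \eqn{W = \Sigma(\hat\theta)^{-1}\,C_{x\eta}}, where
#' \eqn{C_{x\eta} = \mathrm{Cov}(x, \eta)} is the model-implied
#' covariance between indicators and factors (for a simple factor model,
#' \eqn{C_{x\eta} = \hat\Lambda\hat\Phi}). Composite scores are
#' \eqn{W^\top (x - \hat\mu)}.
#'
#' @param fit a converged \code{"semfit"} with at least one latent factor.
#' @param group group index for multi-group fits (weights per group).
#' @return matrix (indicators x factors) of score weights.
#' @export
factor_score_weights <- function(fit, group = 1L) {
  stopifnot(inherits(fit, "semfit"))
  if (!length(fit$spec$latents)) stop("model has no latent factors")
  mom <- fit$moments[[group]]
  model <- fit$model
  lat_idx <- length(fit$spec$observed) + seq_along(fit$spec$latents)
  Cxe <- mom$V[model$obs_idx, lat_idx, drop = FALSE]
  Sinv <- tryCatch(solve(mom$Sigma), error = function(e)
    stop("implied covariance is singular; cannot compute score weights"))
  W <- Sinv %*% Cxe
  dimnames(W) <- list(fit$spec$observed, fit$spec$latents)
  W
}

#' Factor determinacy (Grice)
#'
#' The correlation between each latent factor and its regression-method
#' factor-score estimate,
#' \eqn{\rho_j = \sqrt{[C_{x\eta}^\top \Sigma^{-1} C_{x\eta}]_{jj} /
#' \Phi_{jj}}}. Values of 0.80 and above are conventionally acceptable
#' for using composite scores in further modeling.
#'
#' @inheritParams factor_score_weights
#' @return named numeric vector of determinacies in [0, 1].
#' @export
factor_determinacy <- function(fit, group = 1L) {
  stopifnot(inherits(fit, "semfit"))
  if (!length(fit$spec$latents)) stop("model has no latent factors")
  mom <- fit$moments[[group]]
  model <- fit$model
  lat_idx <- length(fit$spec$observed) + seq_along(fit$spec$latents)
  Cxe <- mom$V[model$obs_idx, lat_idx, drop = FALSE]
  Phi <- mom$V[lat_idx, lat_idx, drop = FALSE]
  Sinv <- solve(mom$Sigma)
  rho2 <- diag(t(Cxe) %*% Sinv %*% Cxe) / diag(Phi)
  stats::setNames(sqrt(pmin(pmax(rho2, 0), 1)), fit$spec$latents)
}

#' Compute composite factor scores
#'
#' Applies regression-method weights to (centered) observed data. Rows
#' with missing indicator values are scored from the weights implied by
#' their observed sub-vector — the weight system is re-solved on the
#' observed submatrix per missing-data pattern, which is the proper
#' renormalization — and the affected row count is reported via
#' \code{attr(, "n_partial")}.
#'
#' @param fit a converged \code{"semfit"}.
#' @param newdata data.frame with the indicator columns; defaults to the
#'   fitting data.
#' @param group group index whose weights/means to use.
#' @return matrix (rows x factors) of composite scores.
#' @export
factor_scores <- function(fit, newdata = NULL, group = 1L) {
  stopifnot(inherits(fit, "semfit"))
  obs <- fit$spec$observed
  Y <- if (is.null(newdata)) fit$data[[group]] else {
    miss <- setdiff(obs, names(newdata))
    if (length(miss)) stop("newdata lacks indicator(s): ",
                           paste(miss, collapse = ", "))
    as.matrix(as.data.frame(lapply(newdata[obs], as.numeric)))
  }
  mom <- fit$moments[[group]]
  model <- fit$model
  lat_idx <- length(obs) + seq_along(fit$spec$latents)
  Cxe <- mom$V[model$obs_idx, lat_idx, drop = FALSE]
  mu <- if (fit$meanstructure) mom$mu else
    colMeans(fit$data[[group]], na.rm = TRUE)

  scores <- matrix(NA_real_, nrow(Y), length(fit$spec$latents),
                   dimnames = list(NULL, fit$spec$latents))
  obs_mask <- !is.na(Y)
  key <- apply(obs_mask, 1L, function(z) paste(which(z), collapse = ","))
  n_partial <- 0L
  for (k in unique(key)) {
    rows <- which(key == k)
    ji <- which(obs_mask[rows[1], ])
    if (!length(ji)) next
    if (length(ji) < length(obs)) n_partial <- n_partial + length(rows)
    Wk <- solve(mom$Sigma[ji, ji, drop = FALSE], Cxe[ji, , drop = FALSE])
    dev <- sweep(Y[rows, ji, drop = FALSE], 2L, mu[ji])
    scores[rows, ] <- dev %*% Wk
  }
  attr(scores, "n_partial") <- n_partial
  scores
}
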