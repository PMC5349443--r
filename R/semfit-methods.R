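#' @export
print.semfit <- function(x, ...) {
  cat("semfit (", toupper(x$estimator), "): ",
      length(x$spec$observed), " observed, ",
      length(x$spec$latents), " latent, ",
      x$fit$npar, " free parameters",
      if (x$fit$ngroups > 1) paste0(", ", x$fit$ngroups, " groups"), "\n",
      sep = "")
  cat(sprintf("  chi-square = %.3f (df = %d), N = %d\n",
              x$fit$chi2, x$fit$df, x$fit$N))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (length(x$heywood))
    cat("  note: variance(s) at boundary:",
        paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a covariance-structure fit
#'
#' @param object a \code{"semfit"}.
#' @param ... unused.
#' @return the object, invisibly; prints estimates and fit indices.
#' @export
summary.semfit <- function(object, ...) {
  print(object)
  f <- object$fit
  if (!is.na(f$cmin_df))
    cat(sprintf("  CMIN/DF = %.3f, CFI = %.3f, RMSEA = %.3f\n",
                f$cmin_df, f$cfi, f$rmsea))
  cat("\nParameter estimates:\n")
  tab <- object$ptable
  tab <- tab[order(tab$group, match(tab$op, c("=~", "~", "~~", "~1"))), ]
  out <- data.frame(parameter = tab$pname, group = tab$group,
                    estimate = round(tab$est, 4),
                    se = round(tab$se, 4), z = round(tab$z, 2),
                    p = signif(tab$pvalue, 3))
  out$se[tab$fixed] <- NA
  print(out, row.names = FALSE)
  invisible(object)
}

#' @export
coef.semfit <- function(object, ...) object$theta

#' @export
vcov.semfit <- function(object, ...) object$vcov

#' @export
logLik.semfit <- function(object, ...) {
  structure(object$fit$logLik, df = object$fit$npar,
            nobs = object$fit$N, class = "logLik")
}

#' @export
nobs.semfit <- function(object, ...) object$fit$N

#' Model-implied covariance (and means)
#'
#' @param object a \code{"semfit"}.
#' @param ... unused.
#' @return for single-group fits, list with \code{Sigma} and \code{mu};
#'   a list of such lists otherwise.
#' @export
fitted.semfit <- function(object, ...) {
  out <- lapply(object$moments, function(m)
    list(Sigma = m$Sigma, mu = if (object$meanstructure) m$mu else NULL))
  if (length(out) == 1L) out[[1]] else out
}

#' Extract one estimate (with SE and p) from a fit
#'
#' Convenience accessor for a parameter by its name \code{"lhs op rhs"}
#' as shown in the parameter table, e.g. \code{"deq_w2 ~ apoe"}.
#'
#' @param fit a \code{"semfit"}.
#' @param pname parameter name.
#' @param group group index.
#' @return one-row data.frame: est, se, z, pvalue.
#' @export
parameter <- function(fit, pname, group = 1L) {
  stopifnot(inherits(fit, "semfit"))
  i <- which(fit$ptable$pname == pname & fit$ptable$group == group)
  if (!length(i)) stop("no such parameter: ", pname)
  fit$ptable[i, c("est", "se", "z", "pvalue")]
}

#' Standardized parameter solution
#'
#' Rescales paths, loadings and covariances by model-implied standard
#' deviations so estimates are on the correlation scale.
#'
#' @param fit a \code{"semfit"}.
#' @param group group index.
#' @return the parameter table with an added \code{std} column (and
#'   delta-method standardized \code{std_se} where available).
#' @export
standardized <- function(fit, group = 1L) {
  stopifnot(inherits(fit, "semfit"))
  mom <- fit$moments[[group]]
  vars <- fit$model$vars
  sdv <- sqrt(pmax(diag(mom$V), 0))
  names(sdv) <- vars
  tab <- fit$ptable[fit$ptable$group == group, ]
  std <- tab$est
  for (r in seq_len(nrow(tab))) {
    l <- tab$lhs[r]; rr <- tab$rhs[r]; op <- tab$op[r]
    if (op == "=~") std[r] <- tab$est[r] * sdv[l] / sdv[rr]
    else if (op == "~") std[r] <- tab$est[r] * sdv[rr] / sdv[l]
    else if (op == "~~" && l != rr)
      std[r] <- tab$est[r] / (sdv[l] * sdv[rr])
    else if (op == "~~") std[r] <- 1
    else std[r] <- NA_real_
  }
  tab$std <- std
  tab$std_se <- tab$se * ifelse(is.na(std) | tab$est == 0, NA,
                                abs(std / tab$est))
  tab
}
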