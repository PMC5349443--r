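#' Incremental and absolute fit indices
#'
#' Computes CMIN/DF, CFI and RMSEA from a model chi-square and the
#' chi-square of the independence (null) model fit to the same data:
#' \deqn{CFI = 1 - \frac{\max(\chi^2 - df, 0)}
#'   {\max(\chi^2_0 - df_0, \chi^2 - df, 0)}, \quad
#'   RMSEA = \sqrt{\frac{\max(\chi^2 - df, 0)}{df\,(N-1)}}}
#' Conventional reading: CMIN/DF below 5 adequate, CFI of 0.95+ good,
#' RMSEA at or below 0.05 a close fit.
#'
#' @param chi2,df model chi-square and degrees of freedom.
#' @param chi2_null,df_null independence-model chi-square and df. May be
#'   omitted, in which case CFI is \code{NA}.
#' @param n total sample size.
#' @return named numeric vector \code{c(cmin_df, cfi, rmsea)}. All three
#'   are \code{NA} when \code{df == 0} (indices undefined for a
#'   saturated model).
#' @examples
#' fit_indices(84.80, 11, chi2_null = 3300, df_null = 21, n = 3381)
#' @export
fit_indices <- function(chi2, df, chi2_null = NA, df_null = NA, n) {
  if (df == 0)
    return(c(cmin_df = NA_real_, cfi = NA_real_, rmsea = NA_real_))
  cmin_df <- chi2 / df
  num <- max(chi2 - df, 0)
  cfi <- if (is.na(chi2_null)) NA_real_ else {
    den <- max(chi2_null - df_null, num, 0)
    if (den == 0) 1 else 1 - num / den
  }
  cfi <- if (!is.na(cfi)) min(max(cfi, 0), 1) else cfi
  rmsea <- sqrt(num / (df * (n - 1)))
  c(cmin_df = cmin_df, cfi = cfi, rmsea = rmsea)
}

#' Chi-square difference test between nested fits
#'
#' Compares a constrained model against the model it nests in:
#' \eqn{\Delta\chi^2 = \chi^2_c - \chi^2_f} on
#' \eqn{\Delta df = df_c - df_f} degrees of freedom, with the upper-tail
#' chi-square p-value. Used for measurement-invariance and split-half
#' replication tests: a non-significant difference means the constraints
#' (e.g. equal mediation paths across random halves) do not worsen fit.
#'
#' @param fit_constrained,fit_free \code{"semfit"} objects on the same
#'   data, the first nested in the second.
#' @return list with \code{chi2_diff}, \code{df_diff}, \code{pvalue},
#'   and \code{flagged} (TRUE when the difference is negative, an
#'   estimation problem).
#' @export
chi2_diff_test <- function(fit_constrained, fit_free) {
  stopifnot(inherits(fit_constrained, "semfit"), inherits(fit_free, "semfit"))
  if (fit_constrained$fit$N != fit_free$fit$N ||
      fit_constrained$fit$ngroups != fit_free$fit$ngroups)
    stop("fits are not on the same data/groups; not nested")
  d_df <- fit_constrained$fit$df - fit_free$fit$df
  if (d_df < 0)
    stop("first fit has fewer df than second; models not nested as given")
  d_chi2 <- fit_constrained$fit$chi2 - fit_free$fit$chi2
  flagged <- d_chi2 < -1e-6
  p <- if (d_df == 0) 1 else
    stats::pchisq(max(d_chi2, 0), d_df, lower.tail = FALSE)
  list(chi2_diff = d_chi2, df_diff = d_df, pvalue = p, flagged = flagged)
}

#' @export
anova.semfit <- function(object, ..., test = TRUE) {
  fits <- list(object, ...)
  if (length(fits) != 2L) stop("supply exactly two nested fits")
  o <- order(vapply(fits, function(f) f$fit$df, 0), decreasing = TRUE)
  res <- chi2_diff_test(fits[[o[1]]], fits[[o[2]]])
  out <- data.frame(
    df = c(fits[[o[2]]]$fit$df, fits[[o[1]]]$fit$df),
    chi2 = c(fits[[o[2]]]$fit$chi2, fits[[o[1]]]$fit$chi2),
    chi2_diff = c(NA, res$chi2_diff),
    df_diff = c(NA, res$df_diff),
    pvalue = c(NA, res$pvalue))
  rownames(out) <- c("free", "constrained")
  class(out) <- c("anova", "data.frame")
  out
}
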