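#' Construct the latent dementia phenotype and its cognitive residual
#'
#' Fits a bifactor measurement model to the wave-2 indicators: the
#' dementia factor \code{deq} loads on all five indicators (four
#' cognitive tests plus the functional IADL scale) and captures the
#' cognitive correlates of functional status; the orthogonal residual
#' factor \code{gprime} loads on the cognitive tests only, absorbing
#' general cognitive variance unrelated to everyday function. Factors
#' are identified by fixed unit variances, indicators are standardized
#' before fitting, and no covariates enter this construction step.
#' Regression-method factor weights are applied to the wave-2 data to
#' produce per-subject composite scores, oriented so a higher
#' \code{deq} score means better function/cognition.
#'
#' @param cohort cohort data.frame (one row per subject-wave) containing
#'   the indicator columns, \code{subject}, \code{wave},
#'   \code{diagnosis} and \code{CDR_SB}.
#' @param indicators names of the five indicator columns; the last is
#'   the functional indicator carrying no \code{gprime} loading.
#' @param wave which wave to construct the phenotype in.
#' @param residual_cov optional character vector of indicator pairs
#'   (\code{"A ~~ B"}) freed as residual covariances.
#' @param missing passed to \code{\link{sem_fit}}.
#' @param validate logical; attach AUC (AD vs NC, complete cases) and
#'   CDR correlation validation.
#' @return object of class \code{"delta_model"}: \code{fit},
#'   \code{weights}, \code{scores} (subject, deq, gprime),
#'   \code{determinacy}, \code{validation}, \code{flipped}.
#' @export
build_deq <- function(cohort,
                      indicators = c("LMII", "VRI", "COWA", "DST", "IADL"),
                      wave = 2L, residual_cov = NULL,
                      missing = "auto", validate = TRUE) {
  miss <- setdiff(c(indicators, "subject", "wave"), names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  w2 <- cohort[cohort$wave == wave, , drop = FALSE]
  if (!nrow(w2)) stop("no rows for wave ", wave)
  if (anyDuplicated(w2$subject))
    stop("a subject appears more than once in wave ", wave)

  cog <- indicators[-length(indicators)]
  X <- w2[indicators]
  X[] <- lapply(X, function(x) as.numeric(scale(x)))

  model <- paste0(
    "deq =~ ", paste(indicators, collapse = " + "), "\n",
    "gprime =~ ", paste(cog, collapse = " + "), "\n",
    "deq ~~ 0*gprime")
  if (!is.null(residual_cov))
    model <- paste(c(model, residual_cov), collapse = "\n")
  spec <- sem_spec(model, std_lv = TRUE)
  fit <- sem_fit(spec, X, missing = missing)
  if (!fit$converged)
    warning("bifactor fit did not converge; results are flagged")

  # resolve the sign indeterminacy of each factor: orient so the average
  # loading is positive (higher score = better performance)
  flipped <- logical(2); names(flipped) <- c("deq", "gprime")
  for (f in names(flipped)) {
    rows <- fit$ptable$op == "=~" & fit$ptable$lhs == f
    if (mean(fit$ptable$est[rows]) < 0) flipped[f] <- TRUE
  }

  W <- factor_score_weights(fit)
  det <- factor_determinacy(fit)
  sc <- factor_scores(fit, X)
  for (f in names(flipped)) if (flipped[f]) {
    W[, f] <- -W[, f]; sc[, f] <- -sc[, f]
  }
  scores <- data.frame(subject = w2$subject, deq = sc[, "deq"],
                       gprime = sc[, "gprime"])
  attr(scores, "n_partial") <- attr(sc, "n_partial")

  validation <- NULL
  if (validate && all(c("diagnosis", "CDR_SB") %in% names(w2))) {
    validation <- list()
    if (all(c("AD", "NC") %in% w2$diagnosis)) {
      cc <- stats::complete.cases(X)
      validation$auc_deq <- validate_auc(scores$deq[cc], w2$diagnosis[cc])
      validation$auc_gprime <- validate_auc(scores$gprime[cc],
                                            w2$diagnosis[cc])
    }
    validation$cdr <- tryCatch(validate_cdr(scores$deq, w2$CDR_SB),
                               error = function(e) NULL)
  }

  structure(list(fit = fit, weights = W, scores = scores,
                 determinacy = det, validation = validation,
                 flipped = flipped, indicators = indicators, wave = wave),
            class = "delta_model")
}

#' @export
print.delta_model <- function(x, ...) {
  cat("delta_model (wave", x$wave, "bifactor):",
      nrow(x$scores), "subjects scored\n")
  cat(sprintf("  chi-square = %.2f (df = %d)", x$fit$fit$chi2, x$fit$fit$df))
  if (!is.na(x$fit$fit$cfi))
    cat(sprintf(", CFI = %.3f, RMSEA = %.3f",
                x$fit$fit$cfi, x$fit$fit$rmsea))
  cat("\n  determinacy: deq =", round(x$determinacy["deq"], 3),
      ", gprime =", round(x$determinacy["gprime"], 3), "\n")
  if (!is.null(x$validation$auc_deq))
    cat(sprintf("  AUC (AD vs NC): deq = %.3f (%.3f-%.3f), gprime = %.3f\n",
                x$validation$auc_deq$auc, x$validation$auc_deq$ci[1],
                x$validation$auc_deq$ci[2], x$validation$auc_gprime$auc))
  if (!is.null(x$validation$cdr))
    cat(sprintf("  r(deq, CDR-SB) = %.3f\n", x$validation$cdr$r))
  invisible(x)
}

#' AUC for case/control discrimination by a composite score
#'
#' Mann-Whitney AUC for the AD-versus-NC contrast (MCI excluded), with
#' the normal-approximation confidence interval of Hanley & McNeil. The
#' orientation is chosen so that worse (lower) scores indicate cases,
#' hence the reported AUC is at least 0.5; whether it was flipped is
#' returned.
#'
#' @param scores numeric vector of composite scores.
#' @param diagnosis character/factor with levels including the case and
#'   control labels.
#' @param case,control labels of the contrasted classes.
#' @param conf confidence level.
#' @return list: \code{auc}, \code{ci}, \code{n_case}, \code{n_control},
#'   \code{flipped}.
#' @export
validate_auc <- function(scores, diagnosis, case = "AD", control = "NC",
                         conf = 0.95) {
  keep <- diagnosis %in% c(case, control) & !is.na(scores)
  x <- scores[keep]; g <- diagnosis[keep]
  n1 <- sum(g == case); n0 <- sum(g == control)
  if (n1 == 0 || n0 == 0)
    stop("need at least one ", case, " and one ", control, " subject")
  r <- rank(x)
  # P(control score > case score), ties counted half
  auc <- (sum(r[g == control]) - n0 * (n0 + 1) / 2) / (n0 * n1)
  flipped <- auc < 0.5
  if (flipped) auc <- 1 - auc
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n0 * n1)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(max(v, 0)), 0), 1)
  list(auc = auc, ci = ci, n_case = n1, n_control = n0, flipped = flipped)
}

#' Correlation of a composite score with dementia severity
#'
#' Pearson correlation between the phenotype score and the CDR sum of
#' boxes, with a two-sided test.
#'
#' @param scores,cdr paired numeric vectors.
#' @return list: \code{r}, \code{pvalue}, \code{n}.
#' @export
validate_cdr <- function(scores, cdr) {
  keep <- !is.na(scores) & !is.na(cdr)
  if (stats::sd(scores[keep]) == 0 || stats::sd(cdr[keep]) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(scores[keep], cdr[keep])
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = sum(keep))
}
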