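#' Default covariate adjustment set
#'
#' The seven covariates every observed variable except APOE is adjusted
#' for in the structural models.
#' @return character vector of column names.
#' @export
delta_covariates <- function() {
  c("age", "education", "ethnicity", "gender", "GDS", "HCY", "HgbA1c")
}

# Assemble the analysis table for base/mediation models: baseline (wave-1)
# APOE and covariates joined to the wave-2 composite scores, all columns
# standardized so path estimates are on the correlation scale.
assemble_model_data <- function(cohort, scores,
                                covariates = delta_covariates()) {
  miss <- setdiff(c("subject", "wave", "APOE", covariates), names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  w1 <- cohort[cohort$wave == 1L, c("subject", "APOE", covariates)]
  d <- merge(scores, w1, by = "subject", sort = TRUE)
  out <- data.frame(subject = d$subject)
  out$deq <- as.numeric(scale(d$deq))
  if (!is.null(d$gprime)) out$gprime <- as.numeric(scale(d$gprime))
  out$apoe <- as.numeric(scale(as.numeric(d$APOE)))
  for (cv in covariates) out[[cv]] <- as.numeric(scale(as.numeric(d[[cv]])))
  out
}

#' Fit the base model: APOE's direct association with the phenotype
#'
#' Regresses the wave-2 \code{deq} composite (and separately the
#' \code{gprime} composite) on baseline APOE e4 carrier status with the
#' full covariate set adjusted by simultaneous paths. All variables are
#' standardized, so the APOE path is on the correlation scale. When the
#' \code{gprime} path is non-significant it is flagged for dropping from
#' downstream mediation screening, mirroring the analysis sequence in
#' which only the dementia-specific factor carries the APOE signal.
#'
#' @param cohort cohort data.frame (subject-wave rows).
#' @param scores data.frame \code{subject}, \code{deq}, \code{gprime}
#'   from \code{\link{build_deq}}.
#' @param covariates adjustment set; defaults to
#'   \code{\link{delta_covariates}()}.
#' @param alpha significance level for the drop decision.
#' @return object of class \code{"base_model"}: per-outcome APOE path
#'   (est, se, z, pvalue), fits, and \code{drop_gprime}.
#' @export
fit_base_model <- function(cohort, scores, covariates = delta_covariates(),
                           alpha = 0.05) {
  d <- assemble_model_data(cohort, scores, covariates)
  rhs <- paste(c("apoe", covariates), collapse = " + ")
  fit_deq <- sem_fit(sem_spec(paste("deq ~", rhs)),
                     d, missing = "auto")
  path_deq <- parameter(fit_deq, "deq ~ apoe")
  out <- list(deq = path_deq, fit_deq = fit_deq,
              covariates = covariates, n = nrow(d))
  if (!is.null(d$gprime)) {
    fit_g <- sem_fit(sem_spec(paste("gprime ~", rhs)),
                     d, missing = "auto")
    out$gprime <- parameter(fit_g, "gprime ~ apoe")
    out$fit_gprime <- fit_g
    out$drop_gprime <- out$gprime$pvalue >= alpha
  }
  class(out) <- "base_model"
  out
}

#' @export
print.base_model <- function(x, ...) {
  cat("base_model (n =", x$n, "):\n")
  cat(sprintf("  APOE -> deq    : %.3f (SE %.3f), p = %.3g\n",
              x$deq$est, x$deq$se, x$deq$pvalue))
  if (!is.null(x$gprime))
    cat(sprintf("  APOE -> gprime : %.3f (SE %.3f), p = %.3g%s\n",
                x$gprime$est, x$gprime$se, x$gprime$pvalue,
                if (isTRUE(x$drop_gprime)) "  [dropped downstream]" else ""))
  invisible(x)
}

#' Product-of-coefficients mediation effect (Sobel test)
#'
#' Computes the indirect effect as the product of the exposure ->
#' mediator path (\code{c}) and the mediator -> outcome path (\code{b}),
#' its delta-method z statistic
#' \deqn{z = \frac{b\,c}{\sqrt{b^2 se_c^2 + c^2 se_b^2}},}
#' the two-sided normal p-value, and the proportion mediated
#' \eqn{bc / (bc + a)} expressed as a percentage. The proportion is only
#' reported when the indirect effect and the total effect share a sign;
#' otherwise it is \code{NA} and flagged.
#'
#' @param b,se_b mediator -> outcome path and its SE.
#' @param c_,se_c exposure -> mediator path and its SE.
#' @param a_direct direct exposure -> outcome path from the same model.
#' @return list: \code{indirect}, \code{sobel_z}, \code{pvalue},
#'   \code{proportion} (percent), \code{flagged}.
#' @examples
#' mediation_effect(b = 0.15, se_b = 0.02, c_ = -0.15, se_c = 0.02,
#'                  a_direct = -0.23)
#' @export
mediation_effect <- function(b, se_b, c_, se_c, a_direct) {
  stopifnot(is.finite(b), is.finite(c_), is.finite(se_b), is.finite(se_c))
  indirect <- b * c_
  den <- sqrt(b^2 * se_c^2 + c_^2 * se_b^2)
  z <- if (den == 0) 0 else indirect / den
  p <- 2 * stats::pnorm(-abs(z))
  total <- indirect + a_direct
  flagged <- FALSE
  proportion <- NA_real_
  if (total == 0) {
    flagged <- TRUE
  } else if (indirect == 0) {
    proportion <- 0
  } else if (sign(indirect) != sign(total)) {
    flagged <- TRUE
  } else {
    proportion <- 100 * indirect / total
  }
  list(indirect = indirect, sobel_z = z, pvalue = p,
       proportion = proportion, flagged = flagged)
}

#' Fit the longitudinal mediation model for one analyte
#'
#' Simultaneous structural equations on standardized variables:
#' \preformatted{  analyte_w1 ~ apoe (path c) + covariates
#'   deq_w2     ~ apoe (path a) + analyte_w1 (path b) + covariates}
#' with the exposure and covariates correlating freely. With
#' \code{adjust = "residualize"}, outcome and analyte are residualized
#' on the covariates first and a three-variable model is fit instead.
#' Estimation is by FIML whenever cells are missing.
#'
#' @param cohort,scores as in \code{\link{fit_base_model}}.
#' @param analyte numeric vector of QC-standardized wave-1 analyte
#'   values, aligned to \code{analyte_subjects}.
#' @param analyte_subjects subject ids for \code{analyte}.
#' @param name analyte label carried into the result.
#' @param covariates adjustment set.
#' @param adjust \code{"paths"} (simultaneous adjustment inside the
#'   model, the default) or \code{"residualize"}.
#' @param se logical; compute standard errors.
#' @return object of class \code{"mediation_fit"}: paths \code{a},
#'   \code{b}, \code{c} (est, se, z, pvalue), the
#'   \code{\link{mediation_effect}} block, fit indices and the
#'   underlying \code{"semfit"}.
#' @export
fit_mediation_model <- function(cohort, scores, analyte, analyte_subjects,
                                name = "analyte",
                                covariates = delta_covariates(),
                                adjust = c("paths", "residualize"),
                                se = TRUE) {
  adjust <- match.arg(adjust)
  if (stats::sd(analyte, na.rm = TRUE) == 0 || all(is.na(analyte)))
    stop("analyte '", name, "' is constant; mediation model undefined")
  d <- assemble_model_data(cohort, scores, covariates)
  d$analyte <- as.numeric(scale(analyte[match(d$subject,
                                              analyte_subjects)]))
  if (adjust == "residualize") {
    for (v in c("deq", "analyte")) {
      fml <- stats::as.formula(paste(v, "~",
                                     paste(covariates, collapse = "+")))
      r <- stats::resid(stats::lm(fml, data = d,
                                  na.action = stats::na.exclude))
      d[[v]] <- as.numeric(scale(r))
    }
    model <- "analyte ~ apoe\n deq ~ apoe + analyte"
  } else {
    rhs <- paste(covariates, collapse = " + ")
    model <- paste0("analyte ~ apoe + ", rhs, "\n",
                    "deq ~ apoe + analyte + ", rhs)
  }
  fit <- sem_fit(sem_spec(model), d, missing = "auto", se = se)
  path_a <- parameter(fit, "deq ~ apoe")
  path_b <- parameter(fit, "deq ~ analyte")
  path_c <- parameter(fit, "analyte ~ apoe")
  eff <- mediation_effect(b = path_b$est, se_b = path_b$se,
                          c_ = path_c$est, se_c = path_c$se,
                          a_direct = path_a$est)
  structure(list(analyte = name, a = path_a, b = path_b, c = path_c,
                 effect = eff, fit = fit, n = nrow(d),
                 adjust = adjust), class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("mediation_fit:", x$analyte, "(n =", x$n, ")\n")
  cat(sprintf("  a (APOE->deq | analyte): %.3f (p = %.3g)\n",
              x$a$est, x$a$pvalue))
  cat(sprintf("  b (analyte->deq)       : %.3f (p = %.3g)\n",
              x$b$est, x$b$pvalue))
  cat(sprintf("  c (APOE->analyte)      : %.3f (p = %.3g)\n",
              x$c$est, x$c$pvalue))
  cat(sprintf("  indirect = %.4f, Sobel z = %.2f (p = %.3g)",
              x$effect$indirect, x$effect$sobel_z, x$effect$pvalue))
  if (!is.na(x$effect$proportion))
    cat(sprintf(", proportion mediated = %.1f%%", x$effect$proportion))
  cat("\n")
  invisible(x)
}

#' Split-half replication of a mediation model
#'
#' Randomly splits the cohort into two halves (odd subject out to group
#' 1), fits the mediation model simultaneously in both groups with
#' paths a, b, c free, refits with the three paths constrained equal
#' across groups, and compares fit by the chi-square difference test
#' (3 df). A non-significant difference (p > 0.05) means the mediation
#' structure replicates across the halves; the mediation effect is
#' recomputed from the constrained fit.
#'
#' @inheritParams fit_mediation_model
#' @param seed RNG seed for the split; the same seed reproduces the
#'   same split exactly.
#' @param alpha replication level.
#' @return list: \code{chi2_diff}, \code{df_diff}, \code{pvalue},
#'   \code{replicates}, \code{effect} (constrained-fit mediation block),
#'   \code{n_groups}.
#' @export
split_half_replicate <- function(cohort, scores, analyte, analyte_subjects,
                                 name = "analyte",
                                 covariates = delta_covariates(),
                                 seed = 42L, alpha = 0.05, se = TRUE) {
  d <- assemble_model_data(cohort, scores, covariates)
  if (nrow(d) < 100L) stop("need at least 100 subjects for a split-half fit")
  d$analyte <- as.numeric(scale(analyte[match(d$subject,
                                              analyte_subjects)]))
  set.seed(as.integer(seed))
  perm <- sample.int(nrow(d))
  half <- integer(nrow(d))
  half[perm] <- rep(1:2, c(ceiling(nrow(d) / 2), floor(nrow(d) / 2)))
  d$half <- half

  rhs <- paste(covariates, collapse = " + ")
  model <- paste0("analyte ~ apoe + ", rhs, "\n",
                  "deq ~ apoe + analyte + ", rhs)
  spec <- sem_spec(model)
  paths <- c("deq ~ apoe", "deq ~ analyte", "analyte ~ apoe")
  fit_free <- sem_fit(spec, d, group = "half", missing = "auto", se = FALSE)
  fit_con <- sem_fit(spec, d, group = "half", missing = "auto",
                     constrain = paths, se = se)
  test <- chi2_diff_test(fit_con, fit_free)

  pa <- parameter(fit_con, "deq ~ apoe")
  pb <- parameter(fit_con, "deq ~ analyte")
  pc_ <- parameter(fit_con, "analyte ~ apoe")
  eff <- if (se)
    mediation_effect(b = pb$est, se_b = pb$se, c_ = pc_$est,
                     se_c = pc_$se, a_direct = pa$est)
  else list(indirect = pb$est * pc_$est, sobel_z = NA_real_,
            pvalue = NA_real_, proportion = NA_real_, flagged = FALSE)
  list(analyte = name, chi2_diff = test$chi2_diff,
       df_diff = test$df_diff, pvalue = test$pvalue,
       replicates = test$pvalue > alpha & !test$flagged,
       flagged = test$flagged, effect = eff,
       n_groups = as.integer(table(d$half)))
}

#' Screen an analyte panel for mediators of the APOE effect
#'
#' Fits the longitudinal mediation model for every QC-passed analyte
#' and sorts the panel into three classes: \emph{mediator} (both the
#' analyte -> deq path b and the APOE -> analyte path c significant),
#' \emph{APOE-independent delta biomarker} (path b significant only),
#' and \emph{unrelated} (neither). Class membership is decided at
#' \code{screen_alpha}; the stricter multiple-comparison gate
#' (\code{gate}, a fixed threshold rather than alpha/m, with the panel
#' size logged for transparency) sets the \code{survives_bonferroni}
#' flag, so near-miss mediators remain visible in the mediator table.
#' Mediators are split-half replicated by default.
#'
#' @param cohort,scores as in \code{\link{fit_base_model}}.
#' @param panel a \code{"panel_qc"} object, or a numeric matrix of
#'   standardized analytes with subjects as rows (then
#'   \code{subjects} must be given).
#' @param gate Bonferroni-style significance gate (fixed threshold).
#' @param screen_alpha class-membership level; the effective class gate
#'   is \code{max(gate, screen_alpha)}, so a vacuous \code{gate = 1}
#'   classifies every analyte with nonzero paths as mediator.
#' @param covariates adjustment set.
#' @param adjust covariate adjustment mode, see
#'   \code{\link{fit_mediation_model}}.
#' @param replicate \code{"mediators"} (split-half replicate analytes
#'   classified mediator), \code{"all"}, or \code{"none"}.
#' @param seed seed for the replication split.
#' @param subjects subject ids when \code{panel} is a bare matrix.
#' @return object of class \code{"mediation_screen"}: \code{results}
#'   (one row per analyte), \code{tables} (the three class tables),
#'   call metadata.
#' @export
screen_panel <- function(cohort, scores, panel, gate = 0.001,
                         screen_alpha = 0.05,
                         covariates = delta_covariates(),
                         adjust = c("paths", "residualize"),
                         replicate = c("mediators", "all", "none"),
                         seed = 42L, subjects = NULL) {
  adjust <- match.arg(adjust)
  replicate <- match.arg(replicate)
  if (inherits(panel, "panel_qc")) {
    values <- panel$values; subjects <- panel$subject
  } else {
    values <- as.matrix(panel)
    if (is.null(subjects)) stop("subjects must accompany a bare matrix")
  }
  if (!ncol(values)) stop("empty analyte panel")
  alpha_class <- max(gate, screen_alpha)

  rows <- vector("list", ncol(values))
  for (j in seq_len(ncol(values))) {
    an <- colnames(values)[j]
    mf <- fit_mediation_model(cohort, scores, values[, j], subjects,
                              name = an, covariates = covariates,
                              adjust = adjust)
    sig_b <- mf$b$pvalue < alpha_class
    sig_c <- mf$c$pvalue < alpha_class
    cls <- if (sig_b && sig_c) "mediator"
      else if (sig_b) "apoe_independent_delta_biomarker"
      else "unrelated"
    rows[[j]] <- data.frame(
      analyte = an, class = cls,
      a_est = mf$a$est, a_se = mf$a$se, a_p = mf$a$pvalue,
      b_est = mf$b$est, b_se = mf$b$se, b_p = mf$b$pvalue,
      c_est = mf$c$est, c_se = mf$c$se, c_p = mf$c$pvalue,
      indirect = mf$effect$indirect, sobel_z = mf$effect$sobel_z,
      sobel_p = mf$effect$pvalue, proportion = mf$effect$proportion,
      survives_bonferroni = mf$b$pvalue < gate & mf$c$pvalue < gate,
      chi2 = mf$fit$fit$chi2, df = mf$fit$fit$df,
      cfi = mf$fit$fit$cfi, rmsea = mf$fit$fit$rmsea,
      rep_chi2_diff = NA_real_, rep_df_diff = NA_integer_,
      rep_p = NA_real_, replicates = NA,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)

  do_rep <- switch(replicate,
    none = rep(FALSE, nrow(res)),
    all = rep(TRUE, nrow(res)),
    mediators = res$class == "mediator")
  for (j in which(do_rep)) {
    rr <- split_half_replicate(cohort, scores, values[, res$analyte[j]],
                               subjects, name = res$analyte[j],
                               covariates = covariates, seed = seed)
    res$rep_chi2_diff[j] <- rr$chi2_diff
    res$rep_df_diff[j] <- rr$df_diff
    res$rep_p[j] <- rr$pvalue
    res$replicates[j] <- rr$replicates
  }

  res <- res[order(res$analyte), ]
  rownames(res) <- NULL
  tables <- split(res$analyte, factor(res$class,
    levels = c("mediator", "apoe_independent_delta_biomarker",
               "unrelated")))
  structure(list(results = res, tables = tables, gate = gate,
                 screen_alpha = screen_alpha, alpha_class = alpha_class,
                 n_analytes = ncol(values), seed = seed,
                 adjust = adjust), class = "mediation_screen")
}

#' @export
print.mediation_screen <- function(x, ...) {
  cat("mediation_screen:", x$n_analytes, "analytes | gate =", x$gate,
      "| class alpha =", x$alpha_class, "\n")
  tb <- x$tables
  cat("  mediators:", length(tb$mediator),
      if (length(tb$mediator))
        paste0("(", paste(tb$mediator, collapse = ", "), ")"), "\n")
  med <- x$results[x$results$class == "mediator", ]
  if (nrow(med)) {
    for (i in seq_len(nrow(med)))
      cat(sprintf(
        "    %s: indirect = %.4f, z = %.2f, mediates %s%s\n",
        med$analyte[i], med$indirect[i], med$sobel_z[i],
        if (is.na(med$proportion[i])) "NA" else
          sprintf("%.1f%%", med$proportion[i]),
        if (!med$survives_bonferroni[i])
          " [does not survive Bonferroni]" else ""))
  }
  cat("  APOE-independent delta biomarkers:",
      length(tb$apoe_independent_delta_biomarker), "\n")
  cat("  unrelated:", length(tb$unrelated), "\n")
  invisible(x)
}
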