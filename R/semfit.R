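#' Fit a covariance-structure model by ML or FIML
#'
#' Estimates the free parameters of a \code{\link{sem_spec}} model by
#' minimizing the maximum-likelihood discrepancy
#' \deqn{F_{ML} = \log|\Sigma(\theta)| - \log|S| +
#'   \mathrm{tr}(S\Sigma(\theta)^{-1}) - p}
#' on complete data, or by maximizing the casewise (full-information)
#' normal likelihood over each subject's observed sub-vector when cells
#' are missing. The model chi-square is \eqn{(N-1)F_{ML}} for complete-data
#' ML and the likelihood ratio against the saturated model (fit by EM)
#' for FIML. Fit indices (CMIN/DF, CFI, RMSEA) are computed against the
#' independence model with free variances (and means under FIML).
#'
#' Variance parameters are optimized on the log scale for positivity;
#' unique variances shrinking to the boundary (Heywood tendency) are
#' flagged in the fit object. Standard errors come from the inverse of
#' the numerically differentiated observed information at the solution.
#'
#' @param spec a \code{"sem_spec"} model description.
#' @param data data.frame containing the observed variables (and the
#'   grouping variable, if any).
#' @param missing one of \code{"auto"} (FIML when any cell is missing,
#'   else ML), \code{"ml"} (complete data required), \code{"fiml"}, or
#'   \code{"listwise"} (drop incomplete rows, then ML).
#' @param meanstructure logical; model means/intercepts. Defaults to
#'   \code{TRUE} under FIML (required) and \code{FALSE} under ML.
#' @param group optional name of a grouping column for multi-group fits.
#' @param constrain character vector of parameter names
#'   (\code{"lhs op rhs"}, as in the parameter table) to constrain equal
#'   across groups. Syntax labels are always shared across groups.
#' @param se logical; compute standard errors (skip for speed in
#'   large screens where only point estimates are needed).
#' @param start optional named numeric vector of starting values
#'   overriding the data-driven defaults.
#' @return An object of class \code{"semfit"}; see
#'   \code{\link{summary.semfit}}, \code{\link{coef.semfit}},
#'   \code{\link{fit_indices}}, \code{\link{factor_scores}}.
#' @examples
#' set.seed(1)
#' lat <- rnorm(300)
#' d <- data.frame(x1 = 0.8 * lat + rnorm(300, sd = 0.6),
#'                 x2 = 0.7 * lat + rnorm(300, sd = 0.7),
#'                 x3 = 0.6 * lat + rnorm(300, sd = 0.8))
#' fit <- sem_fit(sem_spec("f =~ x1 + x2 + x3", std_lv = TRUE), d)
#' coef(fit)
#' @export
sem_fit <- function(spec, data, missing = c("auto", "ml", "fiml", "listwise"),
                    meanstructure = NULL, group = NULL, constrain = NULL,
                    se = TRUE, start = NULL) {
  stopifnot(inherits(spec, "sem_spec"))
  missing <- match.arg(missing)
  miss_cols <- setdiff(spec$observed, names(data))
  if (length(miss_cols))
    stop("data lacks modeled variable(s): ", paste(miss_cols, collapse = ", "))

  if (!is.null(group)) {
    if (!group %in% names(data)) stop("grouping column not found: ", group)
    gf <- factor(data[[group]])
    datal <- split(data[spec$observed], gf)
  } else datal <- list(data[spec$observed])
  Yl <- lapply(datal, function(d) as.matrix(as.data.frame(lapply(d, as.numeric))))
  # cases observed on no modeled variable carry no information
  Yl <- lapply(Yl, function(Y) {
    all_na <- rowSums(!is.na(Y)) == 0L
    if (any(all_na))
      warning(sum(all_na), " case(s) with no observed values dropped")
    Y[!all_na, , drop = FALSE]
  })
  for (Y in Yl) if (nrow(Y) <= ncol(Y))
    stop("more observed variables than cases in a group")

  has_na <- any(vapply(Yl, anyNA, TRUE))
  estimator <- switch(missing,
    auto = if (has_na) "fiml" else "ml",
    ml = "ml", fiml = "fiml", listwise = "ml")
  if (missing == "ml" && has_na)
    stop("missing cells present; use missing = 'fiml' or 'listwise'")
  if (missing == "listwise")
    Yl <- lapply(Yl, function(Y) Y[stats::complete.cases(Y), , drop = FALSE])
  if (is.null(meanstructure)) meanstructure <- estimator == "fiml"
  if (estimator == "fiml" && !meanstructure)
    stop("FIML requires meanstructure = TRUE")
  if (meanstructure) spec <- add_meanstructure(spec)

  G <- length(Yl)
  model <- build_model(spec, G, constrain)
  stats_g <- if (estimator == "fiml") lapply(Yl, fiml_stats)
             else lapply(Yl, ml_stats)

  theta0 <- start_values(model, Yl, meanstructure)
  if (!is.null(start)) {
    i <- match(names(start), model$keys)
    theta0[i[!is.na(i)]] <- start[!is.na(i)]
  }

  objfun <- if (estimator == "fiml")
    function(th, grad) fiml_objective(model, th, stats_g, grad)
  else
    function(th, grad) ml_objective(model, th, stats_g, meanstructure, grad)

  vp <- model$var_par
  to_nat <- function(phi) { th <- phi; th[vp] <- exp(phi[vp]); th }
  to_opt <- function(th) { ph <- th; ph[vp] <- log(pmax(th[vp], 1e-10)); ph }
  fn <- function(phi) objfun(to_nat(phi), FALSE)
  gr <- function(phi) {
    th <- to_nat(phi)
    g <- objfun(th, TRUE)$gr
    g[vp] <- g[vp] * th[vp]
    g
  }

  if (model$npar > 0L) {
    opt <- stats::optim(to_opt(theta0), fn, gr, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-12))
    theta <- to_nat(opt$par)
    fmin <- opt$value
    iterations <- opt$counts[["function"]]
    og <- objfun(theta, TRUE)$gr
    N <- sum(vapply(stats_g, `[[`, 0, "n"))
    gnorm <- max(abs(og)) / max(1, N - G)
    converged <- opt$convergence == 0 && is.finite(fmin) && gnorm < 1e-5
    if (!converged && opt$convergence == 0 && gnorm < 1e-3)
      converged <- TRUE  # flat likelihood near machine precision
  } else {
    theta <- numeric(0); fmin <- objfun(theta, FALSE)
    iterations <- 0L; gnorm <- 0; converged <- TRUE
  }

  N <- sum(vapply(stats_g, `[[`, 0, "n"))
  p <- model$p
  nmom <- G * (p * (p + 1) / 2 + if (meanstructure) p else 0)
  df <- nmom - model$npar
  if (df < 0) stop("model has negative degrees of freedom (", df, ")")

  if (estimator == "ml") {
    Fg <- ml_group_F(model, theta, stats_g, meanstructure)
    ns <- vapply(stats_g, `[[`, 0, "n")
    chi2 <- max(0, sum((ns - 1) * Fg))
    chi2_null <- sum(vapply(seq_len(G), function(g) {
      st <- stats_g[[g]]
      (st$n - 1) * (sum(log(diag(st$S))) - st$logdetS)
    }, 0))
    df_null <- nmom - G * (p + if (meanstructure) p else 0)
    ll_sat <- sum(vapply(Yl, sat_loglik_complete, 0))
    logLik <- ll_sat - sum(ns * Fg) / 2
  } else {
    sats <- lapply(Yl, em_saturated)
    ll_sat <- sum(vapply(sats, `[[`, 0, "logLik"))
    logLik <- -fmin / 2
    chi2 <- max(0, fmin - sum(vapply(sats, function(s) -2 * s$logLik, 0)))
    ll_null <- sum(vapply(Yl, fiml_independence_loglik, 0))
    chi2_null <- 2 * (ll_sat - ll_null)
    df_null <- nmom - G * 2 * p
  }

  idx <- fit_indices(chi2, df, chi2_null, df_null, N)

  # Heywood screen: unique variances at the positivity boundary
  heywood <- character(0)
  if (model$npar) {
    vidx <- which(model$var_par & theta < 1e-4)
    heywood <- model$keys[vidx]
  }

  vc <- NULL; ses <- rep(NA_real_, model$npar); se_method <- "none"
  if (se && model$npar > 0L) {
    if (estimator == "ml") {
      fse <- fast_ml_se(model, Yl[[1]], theta, meanstructure)
      if (!is.null(fse)) { ses <- fse; se_method <- "analytic" }
    }
    if (se_method == "none") {
      H <- grad_jacobian(function(th) objfun(th, TRUE)$gr, theta)
      info <- H / 2
      vc <- tryCatch(solve(info), error = function(e) NULL)
      if (!is.null(vc)) {
        dg <- diag(vc)
        ses <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
        dimnames(vc) <- list(model$keys, model$keys)
        se_method <- "observed_information"
      }
    }
  }

  pt <- spec$ptable
  est_tab <- lapply(seq_len(G), function(g) {
    cl <- model$cells[[g]]
    est <- ifelse(is.na(cl$free), cl$fixed, theta[c(cl$free)])
    se_g <- ifelse(is.na(cl$free), NA_real_, ses[c(cl$free)])
    cbind(pt[cl$row, c("lhs", "op", "rhs", "fixed", "label", "pname")],
          data.frame(group = g, est = est, se = se_g))
  })
  est_tab <- do.call(rbind, est_tab)
  rownames(est_tab) <- NULL
  est_tab$z <- est_tab$est / est_tab$se
  est_tab$pvalue <- 2 * stats::pnorm(-abs(est_tab$z))

  moments <- lapply(seq_len(G), function(g)
    implied_moments(model, fill_ram(model, g, theta)))
  for (g in seq_len(G)) {
    dimnames(moments[[g]]$Sigma) <- list(spec$observed, spec$observed)
    names(moments[[g]]$mu) <- spec$observed
  }

  structure(list(
    spec = spec, model = model, estimator = estimator,
    meanstructure = meanstructure, group = group,
    group_levels = if (G > 1) names(Yl) else NULL,
    theta = stats::setNames(theta, model$keys), vcov = vc,
    ptable = est_tab, moments = moments, data = Yl, stats = stats_g,
    fit = c(list(chi2 = chi2, df = df,
                 pvalue = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
                          else NA_real_,
                 chi2_null = chi2_null, df_null = df_null,
                 npar = model$npar, N = N, ngroups = G, logLik = logLik),
            as.list(idx)),
    converged = converged, iterations = iterations, gnorm = gnorm,
    se_method = se_method, heywood = heywood), class = "semfit")
}

# Data-driven deterministic starting values: sample moments for variances,
# covariances and means; OLS for regressions among observed variables;
# 0.7 loadings and half-variance uniquenesses elsewhere.
start_values <- function(model, Yl, meanstructure) {
  spec <- model$spec
  pt <- spec$ptable
  th <- numeric(model$npar)
  filled <- logical(model$npar)
  for (g in seq_along(Yl)) {
    Y <- Yl[[g]]
    cc <- Y[stats::complete.cases(Y), , drop = FALSE]
    if (nrow(cc) < ncol(Y) + 2L) {
      cc <- Y
      Sv <- diag(apply(Y, 2L, stats::var, na.rm = TRUE))
      dimnames(Sv) <- list(colnames(Y), colnames(Y))
      xb <- colMeans(Y, na.rm = TRUE)
      use_ols <- FALSE
    } else {
      # ML (divisor n) moments: for saturated blocks and recursive path
      # models these starts already sit at the optimum
      Sv <- stats::cov(cc) * (nrow(cc) - 1) / nrow(cc)
      xb <- colMeans(cc); use_ols <- TRUE
    }
    ols_cache <- list()
    cl <- model$cells[[g]]
    for (k in seq_len(nrow(cl))) {
      f <- cl$free[k]
      if (is.na(f) || filled[f]) next
      r <- cl$row[k]
      lhs <- pt$lhs[r]; rhs <- pt$rhs[r]; op <- pt$op[r]
      val <- NA_real_
      obs <- spec$observed
      if (op == "~1") {
        val <- if (lhs %in% obs) xb[lhs] else 0
      } else if (op == "~~") {
        if (lhs %in% obs && rhs %in% obs) {
          base <- if (lhs == rhs) Sv[lhs, lhs] else Sv[lhs, rhs]
          endog <- lhs %in% spec$endo
          val <- if (lhs == rhs && endog) 0.5 * base else base
        } else val <- if (lhs == rhs) 0.5 else 0
      } else if (op == "=~") {
        val <- 0.7 * if (rhs %in% obs) sqrt(Sv[rhs, rhs]) else 1
      } else {  # regression
        if (use_ols && lhs %in% obs) {
          if (is.null(ols_cache[[lhs]])) {
            preds <- pt$rhs[pt$op == "~" & pt$lhs == lhs]
            preds <- intersect(preds, obs)
            if (length(preds)) {
              b <- tryCatch(solve(Sv[preds, preds, drop = FALSE],
                                  Sv[preds, lhs]),
                            error = function(e) NULL)
              ols_cache[[lhs]] <- if (is.null(b)) NA else
                stats::setNames(as.numeric(b), preds)
            } else ols_cache[[lhs]] <- NA
          }
          bh <- ols_cache[[lhs]]
          val <- if (length(bh) > 1 || !is.na(bh[1])) {
            if (rhs %in% names(bh)) bh[[rhs]] else 0
          } else 0
        } else val <- 0
      }
      if (!is.na(val)) { th[f] <- val; filled[f] <- TRUE }
    }
    # refine unique variances of regression outcomes: residual variance
    for (k in seq_len(nrow(cl))) {
      f <- cl$free[k]
      if (is.na(f)) next
      r <- cl$row[k]
      if (pt$op[r] == "~~" && pt$lhs[r] == pt$rhs[r] &&
          pt$lhs[r] %in% names(ols_cache)) {
        bh <- ols_cache[[pt$lhs[r]]]
        if (length(bh) > 1 || !is.na(bh[1])) {
          preds <- names(bh)
          rv <- Sv[pt$lhs[r], pt$lhs[r]] -
            sum(bh * Sv[preds, pt$lhs[r]])
          if (is.finite(rv) && rv > 1e-8) th[f] <- rv
        }
      }
    }
  }
  th[model$var_par & th <= 1e-8] <- 0.1
  th
}

# Central-difference Jacobian of an analytic gradient (observed information).
grad_jacobian <- function(gfun, theta) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    h <- 1e-5 * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    H[, i] <- (gfun(tp) - gfun(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}
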