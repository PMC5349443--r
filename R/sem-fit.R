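# Internal covariance-structure machinery.
#
# Models are held in RAM form: for the stacked vector of observed and
# latent variables, A collects directed paths (loadings, regressions),
# S symmetric (co)variances, M means. With B = (I - A)^-1 the implied
# moments are Sigma = [B S B']_obs and mu = [B M]_obs. Gradients of the
# ML and FIML discrepancies are assembled analytically through the RAM
# chain rule, so fits stay fast at panel-screening scale.

build_model <- function(spec, ngroups, constrain = NULL) {
  pt <- spec$ptable
  vars <- c(spec$observed, spec$latents)
  v <- length(vars)
  obs_idx <- seq_along(spec$observed)

  cells <- vector("list", ngroups)
  keys <- character(0)
  key_isvar <- logical(0)
  for (g in seq_len(ngroups)) {
    mat <- character(nrow(pt)); ii <- jj <- integer(nrow(pt))
    for (r in seq_len(nrow(pt))) {
      l <- match(pt$lhs[r], vars); rr <- match(pt$rhs[r], vars)
      if (pt$op[r] == "=~") { mat[r] <- "A"; ii[r] <- rr; jj[r] <- l }
      else if (pt$op[r] == "~") { mat[r] <- "A"; ii[r] <- l; jj[r] <- rr }
      else if (pt$op[r] == "~~") { mat[r] <- "S"; ii[r] <- l; jj[r] <- rr }
      else { mat[r] <- "M"; ii[r] <- l; jj[r] <- 1L }
    }
    key <- ifelse(nzchar(pt$label), pt$label,
                  ifelse(pt$pname %in% constrain, pt$pname,
                         paste0(pt$pname, ".g", g)))
    key[pt$fixed] <- NA_character_
    isvar <- pt$op == "~~" & pt$lhs == pt$rhs
    new <- !is.na(key) & !(key %in% keys)
    keys <- c(keys, key[new])
    key_isvar <- c(key_isvar, isvar[new])
    cl <- data.frame(mat = mat, i = ii, j = jj,
                     free = match(key, keys), fixed = pt$value,
                     row = seq_len(nrow(pt)),
                     stringsAsFactors = FALSE)
    # precomputed linear indices for fast RAM filling in the hot loop
    selA <- which(cl$mat == "A"); selS <- which(cl$mat == "S")
    selM <- which(cl$mat == "M")
    attr(cl, "fast") <- list(
      selA = selA, liA = (cl$j[selA] - 1L) * v + cl$i[selA],
      selS = selS, liS1 = (cl$j[selS] - 1L) * v + cl$i[selS],
      liS2 = (cl$i[selS] - 1L) * v + cl$j[selS],
      selM = selM, liM = cl$i[selM])
    cells[[g]] <- cl
  }
  list(vars = vars, v = v, obs_idx = obs_idx, p = length(obs_idx),
       cells = cells, npar = length(keys), keys = keys,
       var_par = key_isvar, spec = spec)
}

fill_ram <- function(model, g, theta) {
  v <- model$v
  A <- matrix(0, v, v); S <- matrix(0, v, v); M <- numeric(v)
  cl <- model$cells[[g]]
  fs <- attr(cl, "fast")
  free <- cl$free
  val <- cl$fixed
  ok <- !is.na(free)
  val[ok] <- theta[free[ok]]
  A[fs$liA] <- val[fs$selA]
  S[fs$liS1] <- val[fs$selS]; S[fs$liS2] <- val[fs$selS]
  if (length(fs$selM)) M[fs$liM] <- val[fs$selM]
  list(A = A, S = S, M = M)
}

implied_moments <- function(model, ram) {
  B <- solve(diag(model$v) - ram$A)
  V <- B %*% ram$S %*% t(B)
  oi <- model$obs_idx
  list(B = B, V = V, Sigma = V[oi, oi, drop = FALSE],
       mu = as.numeric(B %*% ram$M)[oi])
}

# Map a gradient w.r.t. Sigma (W, p x p symmetric) and mu (w, length p)
# back to the free parameters of group g.
ram_grad <- function(model, g, ram, mom, W, w = NULL) {
  v <- model$v; oi <- model$obs_idx
  Gv <- matrix(0, v, v); Gv[oi, oi] <- W
  B <- mom$B; V <- mom$V
  P <- t(B) %*% Gv %*% B
  gradA <- 2 * (P %*% ram$S %*% t(B))
  gradS <- P * (2 - diag(v))  # off-diagonals move in pairs
  gradM <- NULL
  if (!is.null(w)) {
    wv <- numeric(v); wv[oi] <- w
    btw <- as.numeric(t(B) %*% wv)
    gradA <- gradA + outer(btw, as.numeric(B %*% ram$M))
    gradM <- btw
  }
  cl <- model$cells[[g]]
  fs <- attr(cl, "fast")
  contrib <- numeric(nrow(cl))
  contrib[fs$selA] <- gradA[fs$liA]
  contrib[fs$selS] <- gradS[fs$liS1]
  if (length(fs$selM) && !is.null(gradM))
    contrib[fs$selM] <- gradM[fs$liM]
  out <- numeric(model$npar)
  ok <- !is.na(cl$free)
  if (any(ok)) {
    acc <- rowsum(contrib[ok], cl$free[ok])
    out[as.integer(rownames(acc))] <- acc[, 1]
  }
  out
}

# Per-group sufficient statistics -------------------------------------------

# Complete-data sufficient statistics. S uses the ML (divisor N)
# covariance so that minimizing F_ML maximizes the exact normal
# likelihood and FIML with zero missingness reproduces ML estimates
# to optimizer precision. The reported chi-square is still the classic
# (N-1) * F_ML.
ml_stats <- function(Y) {
  n <- nrow(Y)
  S <- stats::cov(Y) * (n - 1) / n
  list(n = n, S = S, xbar = colMeans(Y),
       logdetS = determinant(S)$modulus[1])
}

fiml_stats <- function(Y) {
  obs <- !is.na(Y)
  if (any(colSums(obs) == 0L))
    stop("variable missing for all cases: ",
         paste(colnames(Y)[colSums(obs) == 0L], collapse = ", "))
  key <- apply(obs, 1L, function(z) paste(which(z), collapse = ","))
  pats <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    ji <- which(obs[rows[1], ])
    X <- Y[rows, ji, drop = FALSE]
    list(idx = ji, n = length(rows), m = colMeans(X),
         Sxx = crossprod(X) / length(rows))
  })
  list(n = nrow(Y), patterns = pats)
}

# Objective + gradient (chi-square scale) ------------------------------------

ml_objective <- function(model, theta, stats_g, meanstructure, grad = FALSE) {
  total <- 0; gr <- numeric(model$npar)
  for (g in seq_along(stats_g)) {
    st <- stats_g[[g]]
    ram <- fill_ram(model, g, theta)
    mom <- implied_moments(model, ram)
    Sig <- mom$Sigma
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(if (grad) list(f = 1e10, gr = gr) else 1e10)
    Sinv <- chol2inv(ch)
    ldet <- 2 * sum(log(diag(ch)))
    f <- ldet - st$logdetS + sum(Sinv * st$S) - model$p
    W <- Sinv - Sinv %*% st$S %*% Sinv
    w <- NULL
    if (meanstructure) {
      d <- st$xbar - mom$mu
      f <- f + sum(d * (Sinv %*% d))
      sd_ <- Sinv %*% d
      W <- W - sd_ %*% t(sd_)
      w <- as.numeric(-2 * sd_)
    }
    total <- total + st$n * f
    if (grad)
      gr <- gr + st$n * ram_grad(model, g, ram, mom, W, w)
  }
  if (grad) list(f = total, gr = gr) else total
}

# Per-group F_ML values at a solution (for the (N-1)-scaled chi-square).
ml_group_F <- function(model, theta, stats_g, meanstructure) {
  vapply(seq_along(stats_g), function(g) {
    st <- stats_g[[g]]
    ram <- fill_ram(model, g, theta)
    mom <- implied_moments(model, ram)
    Sinv <- solve(mom$Sigma)
    f <- determinant(mom$Sigma)$modulus[1] - st$logdetS +
      sum(Sinv * st$S) - model$p
    if (meanstructure) {
      d <- st$xbar - mom$mu
      f <- f + sum(d * (Sinv %*% d))
    }
    f
  }, 0)
}

fiml_objective <- function(model, theta, stats_g, grad = FALSE) {
  total <- 0; gr <- numeric(model$npar)
  l2pi <- log(2 * pi)
  for (g in seq_along(stats_g)) {
    st <- stats_g[[g]]
    ram <- fill_ram(model, g, theta)
    mom <- implied_moments(model, ram)
    W <- matrix(0, model$p, model$p); w <- numeric(model$p)
    for (pt in st$patterns) {
      ji <- pt$idx
      Sig <- mom$Sigma[ji, ji, drop = FALSE]
      mu <- mom$mu[ji]
      ch <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(ch)) return(if (grad) list(f = 1e10, gr = gr) else 1e10)
      Sinv <- chol2inv(ch)
      ldet <- 2 * sum(log(diag(ch)))
      C <- pt$Sxx - outer(pt$m, mu) - outer(mu, pt$m) + outer(mu, mu)
      total <- total + pt$n * (length(ji) * l2pi + ldet + sum(Sinv * C))
      if (grad) {
        W[ji, ji] <- W[ji, ji] + pt$n * (Sinv - Sinv %*% C %*% Sinv)
        w[ji] <- w[ji] + 2 * pt$n * as.numeric(Sinv %*% (mu - pt$m))
      }
    }
    if (grad) gr <- gr + ram_grad(model, g, ram, mom, W, w)
  }
  if (grad) list(f = total, gr = gr) else total
}

# Saturated and independence baselines ---------------------------------------

# EM for the saturated multivariate-normal model under missingness.
em_saturated <- function(Y, tol = 1e-8, maxit = 1000L) {
  p <- ncol(Y); n <- nrow(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  Sig <- stats::cov(Y, use = "pairwise.complete.obs")
  Sig[is.na(Sig)] <- 0
  diag(Sig)[is.na(diag(Sig)) | diag(Sig) <= 0] <- 1
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) Sig <- Sig + diag(1e-6 - min(ev, 0), p)
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(z) paste(which(z), collapse = ","))
  rows_by <- split(seq_len(n), key)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    sum_x <- numeric(p); sum_xx <- matrix(0, p, p); ll <- 0
    for (rows in rows_by) {
      ji <- which(obs[rows[1], ]); mi <- setdiff(seq_len(p), ji)
      X <- Y[rows, ji, drop = FALSE]; m <- length(rows)
      Soo <- Sig[ji, ji, drop = FALSE]
      ch <- chol(Soo); Sooi <- chol2inv(ch)
      dev <- sweep(X, 2L, mu[ji])
      ll <- ll - 0.5 * (m * (length(ji) * log(2 * pi) +
            2 * sum(log(diag(ch)))) + sum((dev %*% Sooi) * dev))
      Ex <- matrix(rep(mu, each = m), m, p)
      Ex[, ji] <- X
      if (length(mi)) {
        Beta <- Sig[mi, ji, drop = FALSE] %*% Sooi
        Ex[, mi] <- matrix(rep(mu[mi], each = m), m, length(mi)) +
          dev %*% t(Beta)
        Cmm <- Sig[mi, mi, drop = FALSE] -
          Beta %*% Sig[ji, mi, drop = FALSE]
        sum_xx[mi, mi] <- sum_xx[mi, mi] + m * Cmm
      }
      sum_x <- sum_x + colSums(Ex)
      sum_xx <- sum_xx + crossprod(Ex)
    }
    mu_new <- sum_x / n
    Sig_new <- sum_xx / n - outer(mu_new, mu_new)
    Sig_new <- (Sig_new + t(Sig_new)) / 2
    mu <- mu_new; Sig <- Sig_new
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sig, logLik = ll, iterations = it)
}

# Independence-model (free variances + means) log-likelihood, closed form.
fiml_independence_loglik <- function(Y) {
  sum(apply(Y, 2L, function(x) {
    x <- x[!is.na(x)]
    v <- mean((x - mean(x))^2)
    -0.5 * length(x) * (log(2 * pi) + log(v) + 1)
  }))
}

# Exact observed-information standard errors for complete-data ML fits of
# recursive path models (no latents, residuals uncorrelated, saturated
# exogenous block, single group, no equality constraints). The likelihood
# factorizes into per-equation conditional regressions plus the exogenous
# moment block, so the information matrix is block-diagonal and each
# block has a closed form: Var(beta) = sigma2_ml (Xc'Xc)^-1,
# Var(sigma2) = 2 sigma2^2 / n, Var(s_ij) = (s_ii s_jj + s_ij^2) / n.
fast_ml_se <- function(model, Y, theta, meanstructure) {
  spec <- model$spec
  pt <- spec$ptable
  if (length(spec$latents) || any(nzchar(pt$label))) return(NULL)
  if (length(model$cells) != 1L) return(NULL)
  if (any(pt$op == "~" & pt$fixed)) return(NULL)
  endo <- spec$endo
  free <- !pt$fixed
  # residual structure: endogenous variances only; exo-exo (co)variances
  for (r in which(free & pt$op == "~~")) {
    l <- pt$lhs[r]; rr <- pt$rhs[r]
    if (l %in% endo || rr %in% endo) {
      if (!(l == rr && l %in% endo)) return(NULL)
    }
  }
  n <- nrow(Y)
  ses <- stats::setNames(rep(NA_real_, model$npar), model$keys)
  cl <- model$cells[[1]]
  S <- stats::cov(Y) * (n - 1) / n
  eq <- split(which(pt$op == "~"), pt$lhs[pt$op == "~"])
  beta_se <- list()
  sig2 <- stats::setNames(rep(NA_real_, length(eq)), names(eq))
  for (o in names(eq)) {
    preds <- pt$rhs[eq[[o]]]
    Xc <- sweep(Y[, preds, drop = FALSE], 2L, colMeans(Y[, preds,
                                                         drop = FALSE]))
    yc <- Y[, o] - mean(Y[, o])
    XtX <- crossprod(Xc)
    b <- solve(XtX, crossprod(Xc, yc))
    s2 <- sum((yc - Xc %*% b)^2) / n
    sig2[o] <- s2
    beta_se[[o]] <- stats::setNames(sqrt(diag(s2 * solve(XtX))), preds)
  }
  for (k in seq_len(nrow(cl))) {
    f <- cl$free[k]
    if (is.na(f)) next
    r <- cl$row[k]
    l <- pt$lhs[r]; rr <- pt$rhs[r]; op <- pt$op[r]
    ses[f] <- if (op == "~") beta_se[[l]][[rr]]
      else if (op == "~~" && l == rr && l %in% endo)
        sig2[l] * sqrt(2 / n)
      else if (op == "~~" && l == rr) S[l, l] * sqrt(2 / n)
      else if (op == "~~") sqrt((S[l, l] * S[rr, rr] + S[l, rr]^2) / n)
      else if (op == "~1" && l %in% endo) {
        # intercept SE from the full OLS with intercept
        preds <- pt$rhs[eq[[l]]]
        X1 <- cbind(1, Y[, preds, drop = FALSE])
        sqrt(sig2[l] * solve(crossprod(X1))[1, 1])
      } else sqrt(S[l, l] / n)
  }
  ses
}

sat_loglik_complete <- function(Y) {
  n <- nrow(Y); p <- ncol(Y)
  Sml <- stats::cov(Y) * (n - 1) / n
  -0.5 * n * (p * log(2 * pi) + determinant(Sml)$modulus[1] + p)
}
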