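# Covariance-structure engine: specification, ML, FIML, indices,
# difference tests, scores, determinacy.

test_that("model syntax builds the expected parameter table", {
  sp <- sem_spec("f =~ x1 + x2 + x3\n y ~ f + z", std_lv = TRUE)
  pt <- sp$ptable
  expect_setequal(sp$latents, "f")
  expect_setequal(sp$observed, c("x1", "x2", "x3", "y", "z"))
  # std_lv fixes the factor variance, frees all loadings
  expect_true(all(!pt$fixed[pt$op == "=~"]))
  expect_true(any(pt$op == "~~" & pt$lhs == "f" & pt$fixed & pt$value == 1))
  # default identification fixes the first loading instead
  sp2 <- sem_spec("f =~ x1 + x2 + x3")
  expect_equal(sp2$ptable$value[sp2$ptable$op == "=~"][1], 1)
  # fixed values and labels parse
  sp3 <- sem_spec("f =~ 1*x1 + lam*x2 + x3\n f ~~ 0.5*f")
  expect_equal(sp3$ptable$label[sp3$ptable$rhs == "x2" &
                                  sp3$ptable$op == "=~"], "lam")
  expect_error(sem_spec("f =~"), "parse|empty")
  expect_error(sem_spec("g =~ 0*x1 + 0*x2"), "identified")
})

test_that("saturated model gives zero discrepancy and df", {
  d <- one_factor_data(200, c(0.8, 0.7, 0.6), seed = 2)
  fit <- sem_fit(sem_spec("x1 ~~ x2\n x1 ~~ x3\n x2 ~~ x3"), d)
  expect_equal(fit$fit$chi2, 0, tolerance = 1e-8)
  expect_identical(fit$fit$df, 0)
  expect_equal(unname(fitted(fit)$Sigma["x1", "x2"]),
               cov(d)[1, 2] * 199 / 200, tolerance = 1e-6)
})

test_that("one-factor ML recovers generating loadings at large n", {
  ld <- c(0.8, 0.7, 0.6)
  d <- one_factor_data(100000, ld, seed = 3)
  fit <- sem_fit(sem_spec("f =~ x1 + x2 + x3", std_lv = TRUE), d)
  est <- coef(fit)[paste0("f =~ x", 1:3, ".g1")]
  expect_true(fit$converged)
  expect_equal(unname(est), ld, tolerance = 0.01)
})

test_that("ML estimates match the established factor-analysis backend", {
  # factanal (base R) fits the same ML objective on the correlation
  # matrix; standardized loadings and uniquenesses must agree
  for (ld in list(c(0.8, 0.7, 0.6), c(0.7, 0.65, 0.55, 0.75, 0.6))) {
    d <- one_factor_data(4000, ld, seed = length(ld))
    fit <- sem_fit(sem_spec(paste("f =~",
      paste(names(d), collapse = " + ")), std_lv = TRUE), d)
    fa <- factanal(d, factors = 1, rotation = "none",
                   control = list(nstart = 3))
    std <- standardized(fit)
    lam <- abs(std$std[std$op == "=~"])
    expect_equal(lam, as.numeric(abs(fa$loadings)), tolerance = 1e-3)
    uni <- std$est[std$op == "~~" & std$lhs == std$rhs &
                     std$lhs != "f"] /
      diag(fitted(fit)$Sigma)
    expect_equal(unname(uni), unname(fa$uniquenesses), tolerance = 1e-3)
  }
})

test_that("ML path model equals equation-wise OLS (oracle) exactly", {
  set.seed(9)
  n <- 600
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$m <- 0.3 * d$x + rnorm(n)
  d$y <- 0.4 * d$m - 0.2 * d$x + 0.1 * d$z + rnorm(n)
  fit <- sem_fit(sem_spec("m ~ x + z\n y ~ x + m + z"), d)
  ols_m <- lm(m ~ x + z, d)
  ols_y <- lm(y ~ x + m + z, d)
  expect_equal(parameter(fit, "m ~ x")$est, unname(coef(ols_m)["x"]),
               tolerance = 1e-6)
  expect_equal(parameter(fit, "y ~ m")$est, unname(coef(ols_y)["m"]),
               tolerance = 1e-6)
  expect_equal(parameter(fit, "y ~ z")$est, unname(coef(ols_y)["z"]),
               tolerance = 1e-6)
  # analytic SEs agree with the OLS large-sample form
  expect_equal(parameter(fit, "y ~ m")$se,
               unname(sqrt(diag(vcov(ols_y)))["m"] * sqrt((n - 5) / n)),
               tolerance = 1e-3)
})

test_that("chi-square for a fixed zero covariance matches closed form", {
  set.seed(11)
  n <- 1000
  X <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, .5, .5, 1), 2))
  colnames(X) <- c("a", "b")
  fit <- sem_fit(sem_spec("a ~~ 0*b"), as.data.frame(X))
  r <- cor(X)[1, 2] * (n - 1) / n * n / (n - 1)  # sample correlation
  expect_equal(fit$fit$chi2, -(n - 1) * log(1 - cor(X)[1, 2]^2),
               tolerance = 1e-6)
})

test_that("FIML reduces to ML with complete data and handles MCAR", {
  d <- one_factor_data(2000, c(0.8, 0.7, 0.6), seed = 5)
  sp <- sem_spec("f =~ x1 + x2 + x3", std_lv = TRUE)
  f_ml <- sem_fit(sp, d, meanstructure = TRUE)
  f_fiml <- sem_fit(sp, d, missing = "fiml")
  expect_lt(max(abs(coef(f_ml) - coef(f_fiml)[names(coef(f_ml))])), 1e-6)

  d_big <- one_factor_data(100000, c(0.8, 0.7, 0.6), seed = 6)
  set.seed(7)
  for (j in 1:3) d_big[[j]][runif(nrow(d_big)) < 0.2] <- NA
  f_m <- suppressWarnings(sem_fit(sp, d_big, missing = "fiml"))
  expect_true(f_m$converged)
  est <- coef(f_m)[paste0("f =~ x", 1:3, ".g1")]
  expect_equal(unname(est), c(0.8, 0.7, 0.6), tolerance = 0.02)
})

test_that("FIML is unbiased under MAR where complete-case ML is not", {
  # deletion of x1 depends on x2 (modeled), so listwise deletion biases
  # the x1 loading; FIML does not. Paired replicates, moderate scale.
  reps <- 60
  err <- matrix(NA_real_, reps, 2,
                dimnames = list(NULL, c("fiml", "listwise")))
  sp <- sem_spec("f =~ x1 + x2 + x3", std_lv = TRUE)
  for (r in seq_len(reps)) {
    d <- one_factor_data(600, c(0.8, 0.7, 0.6), seed = 100 + r)
    set.seed(200 + r)
    p_del <- plogis(-2.2 + 2 * d$x2)   # ~25% deleted, MAR via x2
    d$x1[runif(600) < p_del] <- NA
    f1 <- sem_fit(sp, d, missing = "fiml", se = FALSE)
    f2 <- sem_fit(sp, d, missing = "listwise", se = FALSE)
    err[r, ] <- c(coef(f1)[["f =~ x1.g1"]], coef(f2)[["f =~ x1.g1"]]) - 0.8
  }
  bias <- colMeans(err)
  # designed bias in complete-case ML is comfortably detectable
  expect_lt(abs(bias["fiml"]), 0.03)
  expect_gt(abs(bias["listwise"]), abs(bias["fiml"]) + 0.02)
})

test_that("scale invariance: rescaling an indicator leaves chi-square", {
  d <- one_factor_data(500, c(0.8, 0.7, 0.6, 0.5), seed = 8)
  sp <- sem_spec("f =~ x1 + x2 + x3 + x4", std_lv = TRUE)
  f1 <- sem_fit(sp, d, se = FALSE)
  d2 <- d; d2$x2 <- d2$x2 * 7
  f2 <- sem_fit(sp, d2, se = FALSE)
  expect_equal(f1$fit$chi2, f2$fit$chi2, tolerance = 1e-6)
  expect_equal(coef(f2)[["f =~ x2.g1"]], 7 * coef(f1)[["f =~ x2.g1"]],
               tolerance = 1e-4)
})

test_that("fit indices reproduce printed-value arithmetic", {
  idx <- fit_indices(84.80, 11, n = 3381)
  expect_equal(unname(idx["cmin_df"]), 84.80 / 11, tolerance = 1e-10)
  expect_equal(unname(round(idx["rmsea"], 3)), 0.045)
  # perfect-fit limit
  idx2 <- fit_indices(11, 11, 300, 10, 500)
  expect_equal(unname(idx2["cfi"]), 1)
  expect_equal(unname(idx2["rmsea"]), 0)
  # saturated: explicit sentinel
  expect_true(all(is.na(fit_indices(0, 0, 10, 3, 100))))
})

test_that("chi-square difference test matches the chi-square law", {
  expect_equal(pchisq(1.9, 3, lower.tail = FALSE), 0.5934, tolerance = 1e-4)
  d <- one_factor_data(400, c(0.8, 0.7, 0.6, 0.5), seed = 12)
  d$g <- rep(c("A", "B"), 200)
  sp <- sem_spec("f =~ x1 + x2 + x3 + x4", std_lv = TRUE)
  free <- sem_fit(sp, d, group = "g", se = FALSE)
  con <- sem_fit(sp, d, group = "g", se = FALSE,
                 constrain = paste("f =~", c("x1", "x2", "x3", "x4")))
  res <- chi2_diff_test(con, free)
  expect_equal(res$df_diff, 4)
  expect_equal(res$pvalue,
               pchisq(res$chi2_diff, 4, lower.tail = FALSE))
  # identical fits: zero difference, p = 1
  same <- chi2_diff_test(free, free)
  expect_equal(same$chi2_diff, 0)
  expect_equal(same$pvalue, 1)
  # multi-group with no constraints equals separate fits
  fa_ <- sem_fit(sp, d[d$g == "A", ], se = FALSE)
  fb <- sem_fit(sp, d[d$g == "B", ], se = FALSE)
  expect_equal(free$fit$chi2, fa_$fit$chi2 + fb$fit$chi2,
               tolerance = 1e-6)
})

test_that("factor-score weights and determinacy match matrix oracles", {
  # symmetric 3-indicator fixture: equal weights by symmetry, and the
  # determinacy formula evaluated with plain solve() as the oracle
  d <- one_factor_data(5000, c(0.8, 0.8, 0.8), seed = 13)
  fit <- sem_fit(sem_spec("f =~ x1 + x2 + x3", std_lv = TRUE), d)
  W <- factor_score_weights(fit)
  expect_equal(max(W) / min(W), 1, tolerance = 0.1)
  Sig <- fitted(fit)$Sigma
  lam <- fit$ptable$est[fit$ptable$op == "=~"]
  W_oracle <- solve(Sig, lam)
  expect_equal(unname(W[, 1]), unname(W_oracle), tolerance = 1e-8)
  rho_oracle <- sqrt(sum(lam * W_oracle))
  expect_equal(unname(factor_determinacy(fit)["f"]), rho_oracle,
               tolerance = 1e-8)
  # population value for loadings .8 / uniques .36 via the same formula
  Sig0 <- matrix(0.64, 3, 3); diag(Sig0) <- 1
  rho_pop <- sqrt(drop(t(rep(.8, 3)) %*% solve(Sig0) %*% rep(.8, 3)))
  expect_equal(rho_pop, 0.91766, tolerance = 1e-4)
  expect_equal(unname(factor_determinacy(fit)["f"]), rho_pop,
               tolerance = 0.02)
})

test_that("degenerate-fixture scores behave as theory says", {
  # single indicator, loading 1, zero uniqueness: score == indicator
  set.seed(14)
  d <- data.frame(x = rnorm(50))
  fit <- sem_fit(sem_spec("f =~ 1*x\n x ~~ 0*x\n f ~~ f"), d)
  expect_equal(unname(factor_score_weights(fit)[1, 1]), 1,
               tolerance = 1e-6)
  expect_equal(unname(factor_determinacy(fit)["f"]), 1, tolerance = 1e-6)
  sc <- factor_scores(fit)
  expect_equal(unname(sc[, "f"]), d$x - mean(d$x), tolerance = 1e-6)
})

test_that("rows with missing indicators are scored from their observed
          sub-vector", {
  d <- one_factor_data(300, c(0.8, 0.7, 0.6), seed = 15)
  fit <- sem_fit(sem_spec("f =~ x1 + x2 + x3", std_lv = TRUE), d)
  d2 <- d; d2$x3[1:20] <- NA
  sc <- factor_scores(fit, d2)
  expect_equal(attr(sc, "n_partial"), 20L)
  expect_false(anyNA(sc))
  # oracle: re-solve the weight system on the observed 2x2 block
  Sig <- fitted(fit)$Sigma
  lam <- fit$ptable$est[fit$ptable$op == "=~"]
  W2 <- solve(Sig[1:2, 1:2], lam[1:2])
  mu <- colMeans(d)
  expect_equal(unname(sc[1, "f"]),
               sum(W2 * (unlist(d2[1, 1:2]) - mu[1:2])), tolerance = 1e-8)
})

test_that("missing-cell errors and flags are explicit", {
  d <- one_factor_data(100, c(0.8, 0.7, 0.6), seed = 16)
  d$x1[5] <- NA
  sp <- sem_spec("f =~ x1 + x2 + x3", std_lv = TRUE)
  expect_error(sem_fit(sp, d, missing = "ml"), "missing")
  d$x1 <- NA_real_
  expect_error(sem_fit(sp, d, missing = "fiml"), "x1")
})
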