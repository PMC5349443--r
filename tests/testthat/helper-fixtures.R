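# Shared fixtures, generated in code (no stored data).

# One-factor indicator data with known standardized loadings.
one_factor_data <- function(n, loadings, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  X <- sapply(seq_along(loadings), function(j)
    loadings[j] * f + rnorm(n, sd = sqrt(1 - loadings[j]^2)))
  colnames(X) <- paste0("x", seq_along(loadings))
  as.data.frame(X)
}

# Small clean biomarker panel object built by hand.
toy_panel <- function(read1, read2 = read1, low = NULL, ldd = NULL,
                      batch = NULL) {
  read1 <- as.matrix(read1); read2 <- as.matrix(read2)
  if (is.null(colnames(read1)))
    colnames(read1) <- colnames(read2) <- paste0("A", seq_len(ncol(read1)))
  if (is.null(low))
    low <- matrix(FALSE, nrow(read1), ncol(read1),
                  dimnames = dimnames(read1))
  if (is.null(ldd))
    ldd <- setNames(rep(1, ncol(read1)), colnames(read1))
  if (is.null(batch))
    batch <- factor(rep(1:2, length.out = nrow(read1)))
  structure(list(read1 = read1, read2 = read2, low = low, ldd = ldd,
                 batch = batch, subject = seq_len(nrow(read1))),
            class = "biomarker_panel")
}

# Small fast generator configuration for end-to-end tests; overrides win.
quick_config <- function(..., seed = 1) {
  defaults <- list(
    n_subjects = 1200,
    n_delta_only_analytes = 3, n_null_analytes = 3,
    delta_b = 0.12,
    low_censor_quantile = 0.02, duplicate_cv = 0.01,
    outlier_rate = 0.002, missing_rate = 0.01,
    seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}
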