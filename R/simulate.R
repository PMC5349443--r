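#' Configuration for the synthetic cohort generator
#'
#' Describes the data-generating world: a bifactor cognition structure
#' (a dementia factor \code{delta} loading on four cognitive tests and a
#' functional scale, an orthogonal residual-intelligence factor
#' \code{gprime} on the cognitive tests only), a dichotomous APOE e4
#' exposure with a standardized direct path to \code{delta}, a serum
#' analyte panel in which a small subset of analytes carries true
#' APOE -> analyte -> delta indirect paths, plus assay artifacts (batch
#' shifts, below-detection censoring, duplicate read noise, outliers,
#' missingness). All structural paths are on the standardized
#' (correlation) scale.
#'
#' @param n_subjects cohort size.
#' @param p_e4 carrier probability of the APOE e4 allele.
#' @param a_direct standardized direct APOE -> delta path (negative:
#'   carriers have worse function/cognition).
#' @param mediator_specs named list; each element
#'   \code{list(c = , b = )} gives one true mediator's standardized
#'   APOE -> analyte path (\code{c}) and analyte -> delta path
#'   (\code{b}).
#' @param n_delta_only_analytes count of analytes with \code{c = 0} but
#'   a real delta association \code{b = delta_b}.
#' @param n_null_analytes count of analytes with \code{b = c = 0}.
#' @param delta_b standardized b-path of the delta-only analytes
#'   (recycled).
#' @param loadings_delta named loadings of the five indicators on delta
#'   (LMII, VRI, COWA, DST, IADL).
#' @param loadings_gprime named loadings of the four cognitive
#'   indicators on gprime (no IADL entry).
#' @param covariate_effects list with named vectors \code{on_delta} and
#'   \code{on_indicators}: standardized covariate paths.
#' @param n_batches,batch_effect_sd assay batches and the SD of the
#'   additive per-batch shift (on the standardized analyte scale).
#' @param low_censor_quantile fraction of each analyte's distribution
#'   flagged below detection (LOW).
#' @param duplicate_cv coefficient of variation between duplicate reads.
#' @param outlier_rate fraction of cells replaced by >3-SD extremes.
#' @param missing_rate per-cell missingness probability (cohort
#'   indicators/covariates and panel cells).
#' @param missing_mechanism \code{"mcar"}, or \code{"mar"} where
#'   missingness probability increases with dementia severity.
#' @param seed RNG seed; identical configs give identical cohorts.
#' @return object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(
    n_subjects = 3385,
    p_e4 = 0.39,
    a_direct = -0.25,
    mediator_specs = list(
      CRP  = list(c = -0.15, b = 0.15),
      APN  = list(c = -0.10, b = 0.145),
      AREG = list(c = -0.13, b = 0.15)),
    n_delta_only_analytes = 83,
    n_null_analytes = 30,
    delta_b = 0.08,
    loadings_delta = c(LMII = 0.80, VRI = 0.75, COWA = 0.70,
                       DST = 0.55, IADL = 0.80),
    loadings_gprime = c(LMII = 0.20, VRI = 0.25, COWA = 0.40, DST = 0.65),
    covariate_effects = list(
      on_delta = c(age = -0.10, education = 0.10, ethnicity = 0,
                   gender = 0, GDS = -0.10, HCY = 0, HgbA1c = 0),
      on_indicators = c(age = -0.05, education = 0.05, ethnicity = 0,
                        gender = 0, GDS = -0.05, HCY = 0, HgbA1c = 0)),
    n_batches = 4,
    batch_effect_sd = 0.3,
    low_censor_quantile = 0.05,
    duplicate_cv = 0.02,
    outlier_rate = 0.005,
    missing_rate = 0.02,
    missing_mechanism = c("mcar", "mar"),
    seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(n_subjects = as.integer(n_subjects), p_e4 = p_e4,
              a_direct = a_direct, mediator_specs = mediator_specs,
              n_delta_only_analytes = as.integer(n_delta_only_analytes),
              n_null_analytes = as.integer(n_null_analytes),
              delta_b = delta_b,
              loadings_delta = loadings_delta,
              loadings_gprime = loadings_gprime,
              covariate_effects = covariate_effects,
              n_batches = as.integer(n_batches),
              batch_effect_sd = batch_effect_sd,
              low_censor_quantile = low_censor_quantile,
              duplicate_cv = duplicate_cv,
              outlier_rate = outlier_rate,
              missing_rate = missing_rate,
              missing_mechanism = missing_mechanism,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  probs <- c(p_e4 = cfg$p_e4, low_censor_quantile = cfg$low_censor_quantile,
             duplicate_cv = cfg$duplicate_cv, outlier_rate = cfg$outlier_rate,
             missing_rate = cfg$missing_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("rates/probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "))
  if (cfg$n_subjects < 1 || cfg$n_batches < 1 ||
      cfg$n_delta_only_analytes < 0 || cfg$n_null_analytes < 0)
    stop("counts must be positive")
  if (length(cfg$loadings_gprime) != length(cfg$loadings_delta) - 1L)
    stop("loadings_gprime must have one entry fewer than loadings_delta ",
         "(the functional indicator has no gprime loading)")
  if (is.null(names(cfg$loadings_delta)) ||
      !all(names(cfg$loadings_gprime) %in% names(cfg$loadings_delta)))
    stop("loading vectors must be named consistently")
  for (m in cfg$mediator_specs)
    if (!all(c("c", "b") %in% names(m)))
      stop("each mediator spec needs components 'c' and 'b'")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config: n =", x$n_subjects,
      "| P(e4) =", x$p_e4, "| a_direct =", x$a_direct, "\n")
  cat("  analytes:", length(x$mediator_specs), "mediator(s),",
      x$n_delta_only_analytes, "delta-only,",
      x$n_null_analytes, "null\n")
  cat("  artifacts: batch sd", x$batch_effect_sd, "| LOW",
      x$low_censor_quantile, "| dup CV", x$duplicate_cv, "| outliers",
      x$outlier_rate, "| missing", x$missing_rate,
      paste0("(", x$missing_mechanism, ")"), "| seed", x$seed, "\n")
  invisible(x)
}

# Covariate population moments (location/scale used for realism only;
# structural paths act on the standardized scale).
covariate_moments <- function() {
  data.frame(
    name = c("age", "education", "ethnicity", "gender", "GDS",
             "HCY", "HgbA1c"),
    mean = c(70.88, 13.24, 0.36, 0.39, 5.60, 10.0, 6.0),
    sd = c(9.48, 4.25, NA, NA, 5.25, 3.0, 1.0),
    binary = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort, analyte panel and ground truth
#'
#' Draws a cohort under the structural model described in
#' \code{\link{cohort_config}}: latents \code{gprime ~ N(0,1)}; each
#' analyte latent \code{M_j = c_j * APOE_std + noise} (unit variance);
#' \code{delta = a * APOE_std + sum(b_j * M_j) + covariate terms +
#' residual}, with the residual variance chosen so \code{delta} has
#' exactly unit variance; wave-1 and wave-2 indicators load on
#' \code{delta}/\code{gprime} with fresh unique noise per wave; clinical
#' diagnosis (NC/MCI/AD) and CDR sum of boxes are generated monotonically
#' from \code{delta} (lower \code{delta}, worse severity). Raw analyte
#' reads are log-normal on the concentration scale; batch shifts enter
#' the measured reads (not the biologically active latent). Assay
#' artifacts are injected by \code{\link{inject_assay_artifacts}} unless
#' \code{artifacts = FALSE}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param artifacts logical; apply LOW censoring, duplicate noise,
#'   outliers and missingness to the panel, and item missingness to the
#'   cohort table.
#' @return list of class \code{"synth_cohort"} with elements
#'   \code{cohort} (data.frame, one row per subject-wave),
#'   \code{panel} (a \code{"biomarker_panel"}), and \code{truth}
#'   (latent values and true paths).
#' @export
generate_cohort <- function(config, artifacts = TRUE) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_subjects

  apoe <- stats::rbinom(n, 1, config$p_e4)
  z_apoe <- (apoe - config$p_e4) / sqrt(config$p_e4 * (1 - config$p_e4))

  cm <- covariate_moments()
  # correlated normal scores: age-GDS and HCY-HgbA1c at r = 0.1
  zc <- matrix(stats::rnorm(n * 7), n, 7,
               dimnames = list(NULL, cm$name))
  r <- 0.1
  zc[, "GDS"] <- r * zc[, "age"] + sqrt(1 - r^2) * zc[, "GDS"]
  zc[, "HgbA1c"] <- r * zc[, "HCY"] + sqrt(1 - r^2) * zc[, "HgbA1c"]
  covs <- zc
  for (k in seq_len(nrow(cm))) {
    if (cm$binary[k]) {
      covs[, k] <- as.numeric(zc[, k] < stats::qnorm(cm$mean[k]))
    } else if (cm$name[k] == "GDS") {
      covs[, k] <- round(pmax(0, cm$mean[k] + cm$sd[k] * zc[, k]))
    } else {
      covs[, k] <- cm$mean[k] + cm$sd[k] * zc[, k]
    }
  }
  # standardized covariates as they enter the structural model
  zstd <- scale(covs)
  Rcov <- stats::cov(zstd)

  # analyte paths
  med <- config$mediator_specs
  m_names <- c(names(med),
               if (config$n_delta_only_analytes)
                 paste0("DLT", seq_len(config$n_delta_only_analytes)),
               if (config$n_null_analytes)
                 paste0("NUL", seq_len(config$n_null_analytes)))
  c_j <- c(vapply(med, `[[`, 0, "c"),
           rep(0, config$n_delta_only_analytes),
           rep(0, config$n_null_analytes))
  b_j <- c(vapply(med, `[[`, 0, "b"),
           rep_len(config$delta_b, config$n_delta_only_analytes),
           rep(0, config$n_null_analytes))
  names(c_j) <- names(b_j) <- m_names
  m <- length(m_names)
  if (any(abs(c_j) >= 1)) stop("analyte c-paths must be in (-1, 1)")

  # analyte latents, unit variance
  M <- sweep(matrix(stats::rnorm(n * m), n, m), 2L, sqrt(1 - c_j^2), `*`) +
    outer(z_apoe, c_j)
  colnames(M) <- m_names

  # delta with exact unit variance
  gam <- config$covariate_effects$on_delta[cm$name]
  gam[is.na(gam)] <- 0
  expl <- config$a_direct^2 + 2 * config$a_direct * sum(b_j * c_j) +
    (sum(b_j * c_j)^2 - sum((b_j * c_j)^2)) + sum(b_j^2) +
    as.numeric(t(gam) %*% Rcov %*% gam)
  if (expl >= 0.95)
    stop("structural effects explain >= 95% of delta variance; ",
         "reduce paths")
  delta <- config$a_direct * z_apoe + as.numeric(M %*% b_j) +
    as.numeric(zstd %*% gam) + stats::rnorm(n, sd = sqrt(1 - expl))
  gprime <- stats::rnorm(n)

  # indicators per wave (unit-variance construction, then test-like scale)
  ind_names <- names(config$loadings_delta)
  ind_scale <- data.frame(
    name = c("LMII", "VRI", "COWA", "DST", "IADL"),
    mean = c(8.05, 7.88, 8.41, 8.89, 10.48),
    sd = c(4.30, 3.68, 3.49, 3.01, 4.52))
  kap <- config$covariate_effects$on_indicators[cm$name]
  kap[is.na(kap)] <- 0
  var_cov_part <- as.numeric(t(kap) %*% Rcov %*% kap)
  make_wave <- function() {
    X <- matrix(NA_real_, n, length(ind_names),
                dimnames = list(NULL, ind_names))
    for (v in ind_names) {
      ld <- config$loadings_delta[[v]]
      lg <- if (v %in% names(config$loadings_gprime))
        config$loadings_gprime[[v]] else 0
      uv <- 1 - ld^2 - lg^2 - var_cov_part
      if (uv <= 0) stop("loadings/covariate effects exceed unit variance ",
                        "for indicator ", v)
      xs <- ld * delta + lg * gprime + as.numeric(zstd %*% kap) +
        stats::rnorm(n, sd = sqrt(uv))
      sc <- ind_scale[match(v, ind_scale$name), ]
      X[, v] <- if (is.na(sc$mean)) xs else sc$mean + sc$sd * xs
    }
    X
  }
  X1 <- make_wave(); X2 <- make_wave()

  # diagnosis and CDR-SB, monotone in delta (lower delta = worse)
  sev <- delta + stats::rnorm(n, sd = 0.3)
  sd_sev <- sqrt(1 + 0.3^2)
  q_ad <- stats::qnorm(0.37, sd = sd_sev)
  q_mci <- stats::qnorm(0.57, sd = sd_sev)
  diagnosis <- ifelse(sev < q_ad, "AD", ifelse(sev < q_mci, "MCI", "NC"))
  cdr <- pmax(0, 2.42 + 3.35 * (-0.95 * delta + sqrt(1 - 0.95^2) *
                                  stats::rnorm(n)))

  cohort <- rbind(
    data.frame(subject = seq_len(n), wave = 1L, X1, covs,
               APOE = apoe, diagnosis = diagnosis, CDR_SB = cdr),
    data.frame(subject = seq_len(n), wave = 2L, X2, covs,
               APOE = apoe, diagnosis = diagnosis, CDR_SB = cdr))
  cohort <- cohort[order(cohort$subject, cohort$wave), ]
  rownames(cohort) <- NULL

  # raw panel: log-normal concentration scale, batch shifts in the reads
  batch <- factor(sample.int(config$n_batches, n, replace = TRUE))
  lmu <- stats::runif(m, 0.5, 3)
  lsig <- stats::runif(m, 0.4, 0.8)
  shift <- matrix(stats::rnorm(config$n_batches * m,
                               sd = config$batch_effect_sd),
                  config$n_batches, m)
  L <- M + shift[as.integer(batch), , drop = FALSE]
  conc <- exp(sweep(sweep(L, 2L, lsig, `*`), 2L, lmu, `+`))
  colnames(conc) <- m_names
  panel <- structure(list(
    read1 = conc, read2 = conc,
    low = matrix(FALSE, n, m, dimnames = list(NULL, m_names)),
    ldd = stats::setNames(rep(NA_real_, m), m_names),
    batch = batch, subject = seq_len(n)), class = "biomarker_panel")

  truth <- list(
    delta = delta, gprime = gprime, analyte_latents = M,
    paths = list(a_direct = config$a_direct, c = c_j, b = b_j,
                 total_apoe_delta = config$a_direct + sum(b_j * c_j)),
    loadings_delta = config$loadings_delta,
    loadings_gprime = config$loadings_gprime,
    apoe = apoe, config = config)

  out <- structure(list(cohort = cohort, panel = panel, truth = truth),
                   class = "synth_cohort")
  if (artifacts) out <- inject_assay_artifacts(out, config)
  out
}

#' Inject assay artifacts into a clean synthetic panel
#'
#' Applies, in order: below-detection censoring (values under each
#' analyte's \code{low_censor_quantile} quantile become LOW flags, with
#' the threshold recorded as that analyte's least detectable dose),
#' duplicate-read perturbation at the configured coefficient of
#' variation, outlier injection (cells replaced by values beyond 3 SD of
#' the analyte mean), and per-cell missingness (MCAR, or MAR with
#' probability increasing as \code{delta} worsens). Cohort indicator and
#' covariate cells receive the same missingness treatment.
#'
#' @param x a \code{"synth_cohort"} from
#'   \code{\link{generate_cohort}(artifacts = FALSE)}.
#' @param config the generating \code{\link{cohort_config}}.
#' @return the modified \code{"synth_cohort"}; the injected-artifact
#'   counts are recorded in \code{attr(panel, "injected")}.
#' @export
inject_assay_artifacts <- function(x, config) {
  stopifnot(inherits(x, "synth_cohort"))
  panel <- x$panel
  n <- nrow(panel$read1); m <- ncol(panel$read1)
  counts <- list()

  # LOW censoring: threshold at the configured quantile of the clean reads
  if (config$low_censor_quantile > 0) {
    for (j in seq_len(m)) {
      thr <- stats::quantile(panel$read1[, j], config$low_censor_quantile,
                             na.rm = TRUE, names = FALSE)
      low <- !is.na(panel$read1[, j]) & panel$read1[, j] <= thr
      panel$low[low, j] <- TRUE
      panel$ldd[j] <- thr
    }
  } else {
    panel$ldd[] <- vapply(seq_len(m), function(j)
      min(panel$read1[, j], na.rm = TRUE) / 2, 0)
  }
  counts$n_low <- colSums(panel$low)

  # duplicate noise (multiplicative, CV-scaled)
  if (config$duplicate_cv > 0) {
    panel$read1 <- panel$read1 *
      pmax(1 + config$duplicate_cv * stats::rnorm(n * m), 0.01)
    panel$read2 <- panel$read2 *
      pmax(1 + config$duplicate_cv * stats::rnorm(n * m), 0.01)
  }

  # outliers: replace cells by values 3.5-6 SD above/below the mean
  n_out <- matrix(FALSE, n, m)
  if (config$outlier_rate > 0) {
    for (j in seq_len(m)) {
      k <- stats::rbinom(1, n, config$outlier_rate)
      if (k == 0) next
      rows <- sample.int(n, k)
      mu <- mean(panel$read1[, j], na.rm = TRUE)
      sd_ <- stats::sd(panel$read1[, j], na.rm = TRUE)
      val <- mu + sample(c(-1, 1), k, TRUE) *
        stats::runif(k, 3.5, 6) * sd_
      val <- pmax(val, mu + 3.5 * sd_)  # keep reads positive & extreme high
      panel$read1[rows, j] <- val
      panel$read2[rows, j] <- val
      panel$low[rows, j] <- FALSE
      n_out[rows, j] <- TRUE
    }
  }
  counts$n_outliers <- colSums(n_out)
  counts$outlier_cells <- which(n_out, arr.ind = TRUE)

  # missingness
  pmiss <- cell_missing_prob(config, x$truth$delta, n)
  if (any(pmiss > 0)) {
    drop <- matrix(stats::runif(n * m) < pmiss, n, m)
    panel$read1[drop] <- NA; panel$read2[drop] <- NA
    panel$low[drop] <- FALSE
    counts$n_missing <- colSums(drop)

    item_cols <- c(names(config$loadings_delta), "GDS", "HCY", "HgbA1c")
    ch <- x$cohort
    pm <- pmiss[ch$subject]
    for (col in item_cols)
      ch[[col]][stats::runif(nrow(ch)) < pm] <- NA
    x$cohort <- ch
  }
  attr(panel, "injected") <- counts
  x$panel <- panel
  x
}

cell_missing_prob <- function(config, delta, n) {
  if (config$missing_rate == 0) return(rep(0, n))
  if (config$missing_mechanism == "mcar") return(rep(config$missing_rate, n))
  # MAR: logistic in -delta, calibrated to the marginal rate
  lin <- -delta
  f <- function(a) mean(stats::plogis(a + lin)) - config$missing_rate
  a <- stats::uniroot(f, c(-20, 5))$root
  stats::plogis(a + lin)
}

#' Serialize / restore a generator configuration as JSON
#'
#' Named vectors are written as JSON objects so names survive the
#' round-trip; \code{read_config_json(write_config_json(cfg, f))}
#' reproduces the configuration exactly.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param path JSON file path.
#' @return \code{write_config_json}: the path, invisibly;
#'   \code{read_config_json}: a validated \code{"cohort_config"}.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  for (f in c("loadings_delta", "loadings_gprime"))
    out[[f]] <- as.list(out[[f]])
  out$covariate_effects <- lapply(out$covariate_effects, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("loadings_delta", "loadings_gprime"))
    raw[[f]] <- unlist(raw[[f]])
  raw$covariate_effects <- lapply(raw$covariate_effects, unlist)
  raw$mediator_specs <- lapply(raw$mediator_specs, lapply, as.numeric)
  do.call(cohort_config, raw)
}

#' @export
print.synth_cohort <- function(x, ...) {
  n <- length(unique(x$cohort$subject))
  cat("synth_cohort:", n, "subjects x 2 waves,",
      ncol(x$panel$read1), "analytes\n")
  cat("  true total APOE->delta effect:",
      round(x$truth$paths$total_apoe_delta, 4), "\n")
  invisible(x)
}
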