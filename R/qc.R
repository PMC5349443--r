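#' Reconcile duplicate immunoassay reads
#'
#' Duplicate reads are averaged when they agree; a pair whose relative
#' difference \eqn{|r_1 - r_2| / \bar r} exceeds \code{tol} (default 5\%)
#' is discarded (set missing). The denominator is the pair mean, which is
#' symmetric in the two reads and scale-free.
#'
#' @param read1,read2 numeric vectors of positive reads (recycled).
#' @param tol maximum tolerated relative difference.
#' @return numeric vector: pair mean, or \code{NA} where the pair was
#'   discordant or either read missing.
#' @examples
#' reconcile_duplicates(10.0, 10.2)  # 10.1
#' reconcile_duplicates(10.0, 11.0)  # NA (9.52% > 5%)
#' @export
reconcile_duplicates <- function(read1, read2, tol = 0.05) {
  both <- !is.na(read1) & !is.na(read2)
  if (any(read1[both] <= 0 | read2[both] <= 0))
    stop("nonpositive assay read")
  m <- (read1 + read2) / 2
  rel <- abs(read1 - read2) / m
  out <- ifelse(rel > tol, NA_real_, m)
  out[!both] <- NA_real_
  out
}

#' Resolve below-detection (LOW) readings for one analyte
#'
#' If more than 50\% of the non-missing readings are LOW the analyte is
#' dropped (return value \code{NULL}); otherwise every LOW cell is
#' imputed as LDD/2 (half the least detectable dose). Exactly 50\% LOW
#' retains the analyte: the rule is strictly "more than 50\%".
#'
#' @param values numeric vector (NA where LOW or missing).
#' @param low logical vector flagging LOW cells.
#' @param ldd the analyte's least detectable dose (> 0).
#' @return the column with LOW cells set to \code{ldd / 2}, or
#'   \code{NULL} if the analyte is dropped. The LOW fraction is attached
#'   as \code{attr(, "low_fraction")}.
#' @export
resolve_low <- function(values, low, ldd) {
  stopifnot(length(values) == length(low))
  if (!is.finite(ldd) || ldd <= 0) stop("LDD must be positive")
  nonmiss <- low | !is.na(values)
  frac <- if (any(nonmiss)) sum(low) / sum(nonmiss) else 0
  if (frac > 0.5) return(NULL)
  out <- values
  out[low] <- ldd / 2
  attr(out, "low_fraction") <- frac
  out
}

#' Delete 3-SD outliers (single pass)
#'
#' Cells beyond 3 standard deviations about the mean — both computed
#' from the full pre-deletion column — are set missing. The pass is
#' single-shot, not iterative.
#'
#' @param values numeric vector.
#' @param n_sd deletion threshold in SD units.
#' @return the vector with outliers set \code{NA};
#'   \code{attr(, "n_deleted")} carries the count.
#' @export
remove_outliers <- function(values, n_sd = 3) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) {
    warning("fewer than 3 non-missing values; outlier pass skipped")
    attr(values, "n_deleted") <- 0L
    return(values)
  }
  mu <- mean(values[ok])
  sd_ <- stats::sd(values[ok])
  out <- values
  if (sd_ > 0) {
    bad <- ok & abs(values - mu) > n_sd * sd_
    out[bad] <- NA_real_
    attr(out, "n_deleted") <- sum(bad)
  } else attr(out, "n_deleted") <- 0L
  out
}

sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

#' Normalize an analyte column
#'
#' Applies a natural-log transform when the sample skewness exceeds 1 in
#' absolute value (the conventional reading of "highly skewed"), then
#' standardizes to mean 0, unit variance. Zeros are shifted by half the
#' smallest positive value before logging.
#'
#' @param values numeric vector.
#' @param skew_threshold absolute skewness above which the log is taken.
#' @param name analyte name used in error messages.
#' @return standardized vector; \code{attr(, "log_applied")} records the
#'   transform decision.
#' @export
normalize_analyte <- function(values, skew_threshold = 1, name = "analyte") {
  ok <- !is.na(values)
  if (stats::sd(values[ok]) == 0)
    stop("zero variance in ", name, "; cannot standardize")
  logged <- FALSE
  out <- values
  if (abs(sample_skewness(values)) > skew_threshold) {
    if (any(values[ok] < 0))
      stop("negative values in ", name, "; log transform impossible")
    if (any(values[ok] == 0)) {
      shift <- min(values[ok][values[ok] > 0]) / 2
      out[ok] <- out[ok] + shift
    }
    out[ok] <- log(out[ok])
    logged <- TRUE
  }
  out[ok] <- (out[ok] - mean(out[ok])) / stats::sd(out[ok])
  attr(out, "log_applied") <- logged
  out
}

#' Residualize an analyte on assay batch
#'
#' Least-squares regression on batch indicator columns (reference-cell
#' coding); the output is the residual vector re-standardized to mean 0,
#' unit variance, so within-batch means are zero.
#'
#' @param values numeric vector.
#' @param batch factor (or coercible) of batch labels.
#' @return residualized, re-standardized vector.
#' @export
adjust_batch <- function(values, batch) {
  batch <- droplevels(factor(batch))
  if (nlevels(batch) < 2L) {
    warning("fewer than 2 batches; values returned re-standardized only")
    ok <- !is.na(values)
    values[ok] <- (values[ok] - mean(values[ok])) / stats::sd(values[ok])
    return(values)
  }
  if (any(table(batch) < 2L))
    warning("batch with fewer than 2 subjects; its residuals are zero")
  ok <- !is.na(values)
  res <- values
  res[ok] <- stats::resid(stats::lm(values ~ batch,
                                    na.action = stats::na.exclude))[ok]
  s <- stats::sd(res[ok])
  if (s == 0) stop("zero residual variance after batch adjustment")
  res[ok] <- (res[ok] - mean(res[ok])) / s
  res
}

#' Run the full analyte QC pipeline
#'
#' Fixed order: duplicate reconciliation (>5\% discordance discarded),
#' LOW resolution (majority-LOW analytes dropped, remaining LOW cells
#' imputed LDD/2), single-pass 3-SD outlier deletion on the raw scale,
#' log-normalization of skewed analytes plus standardization, and batch
#' residualization. Every deletion and drop decision is logged per
#' analyte; nothing outside the panel is touched.
#'
#' @param panel a \code{"biomarker_panel"} (matrices \code{read1},
#'   \code{read2}, logical \code{low}, vector \code{ldd}, factor
#'   \code{batch}).
#' @param duplicate_tol duplicate relative-difference tolerance.
#' @param low_drop_fraction LOW fraction above which an analyte is
#'   dropped.
#' @param outlier_sd outlier threshold in SDs.
#' @param skew_threshold absolute skewness triggering the log transform.
#' @param batch_adjust logical; residualize on batch.
#' @return object of class \code{"panel_qc"}: \code{values} (subjects x
#'   retained analytes, standardized), \code{log} (per-analyte QC
#'   decisions), \code{dropped}, \code{batch}, \code{subject}.
#' @export
qc_panel <- function(panel, duplicate_tol = 0.05, low_drop_fraction = 0.5,
                     outlier_sd = 3, skew_threshold = 1,
                     batch_adjust = TRUE) {
  stopifnot(inherits(panel, "biomarker_panel"))
  analytes <- colnames(panel$read1)
  n <- nrow(panel$read1)
  vals <- matrix(NA_real_, n, 0)
  dropped <- character(0)
  logs <- list()
  for (j in analytes) {
    low <- panel$low[, j]
    r1 <- panel$read1[, j]; r2 <- panel$read2[, j]
    r1[low] <- NA; r2[low] <- NA
    v <- reconcile_duplicates(r1, r2, tol = duplicate_tol)
    n_dup <- sum(!is.na(r1) & !is.na(r2) & is.na(v))
    ldd <- panel$ldd[[j]]
    rl <- resolve_low_frac(v, low, ldd, low_drop_fraction)
    entry <- data.frame(analyte = j, n_in = sum(low | !is.na(r1) | !is.na(r2)),
                        n_dup_discarded = n_dup,
                        low_fraction = rl$frac,
                        dropped = is.null(rl$values), reason = "",
                        n_low_imputed = if (is.null(rl$values)) 0L
                                        else sum(low),
                        n_outliers = 0L, log_applied = NA,
                        stringsAsFactors = FALSE)
    if (is.null(rl$values)) {
      entry$reason <- "majority_low"
      dropped <- c(dropped, j)
      logs[[j]] <- entry
      next
    }
    if (sum(!is.na(rl$values)) < 3L ||
        stats::sd(rl$values, na.rm = TRUE) == 0) {
      entry$dropped <- TRUE
      entry$reason <- "too_few_values"
      dropped <- c(dropped, j)
      logs[[j]] <- entry
      next
    }
    v <- remove_outliers(rl$values, n_sd = outlier_sd)
    entry$n_outliers <- attr(v, "n_deleted")
    v <- normalize_analyte(v, skew_threshold = skew_threshold, name = j)
    entry$log_applied <- attr(v, "log_applied")
    if (batch_adjust) v <- adjust_batch(v, panel$batch)
    vals <- cbind(vals, as.numeric(v))
    colnames(vals)[ncol(vals)] <- j
    logs[[j]] <- entry
  }
  structure(list(values = vals,
                 log = do.call(rbind, c(logs, make.row.names = FALSE)),
                 dropped = dropped, batch = panel$batch,
                 subject = panel$subject), class = "panel_qc")
}

# resolve_low with configurable drop fraction (the exported helper keeps
# the published 50% rule as its fixed default)
resolve_low_frac <- function(values, low, ldd, drop_fraction) {
  nonmiss <- low | !is.na(values)
  frac <- if (any(nonmiss)) sum(low) / sum(nonmiss) else 0
  if (frac > drop_fraction) return(list(values = NULL, frac = frac))
  if (any(low)) {
    if (!is.finite(ldd) || ldd <= 0) stop("LDD must be positive")
    values[low] <- ldd / 2
  }
  list(values = values, frac = frac)
}

#' @export
print.panel_qc <- function(x, ...) {
  cat("panel_qc:", ncol(x$values), "analytes retained,",
      length(x$dropped), "dropped\n")
  if (length(x$dropped))
    cat("  dropped (majority LOW):", paste(x$dropped, collapse = ", "), "\n")
  cat("  duplicate discards:", sum(x$log$n_dup_discarded),
      "| outliers deleted:", sum(x$log$n_outliers),
      "| log-transformed:", sum(x$log$log_applied, na.rm = TRUE), "\n")
  invisible(x)
}
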