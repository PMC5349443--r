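#' Descriptive summary of a cohort table
#'
#' Per-variable N (non-missing), mean and SD at wave 1 (covariates,
#' APOE, CDR) and wave 2 (indicators), in the style of a demographics
#' table. Dichotomous 0/1 variables are summarized by the proportion
#' coded 1 — the mean of the indicator — with its n-1-denominator
#' sample SD. Also reports the complete-case count across indicators
#' and covariates.
#'
#' @param cohort cohort data.frame (one row per subject-wave).
#' @param indicators indicator columns (summarized at wave 2).
#' @param covariates covariate columns (summarized at wave 1).
#' @return data.frame: variable, n, mean, sd, dichotomous.
#' @export
summarize_cohort <- function(cohort,
                             indicators = c("LMII", "VRI", "COWA",
                                            "DST", "IADL"),
                             covariates = delta_covariates()) {
  w1 <- cohort[cohort$wave == 1L, , drop = FALSE]
  w2 <- cohort[cohort$wave == 2L, , drop = FALSE]
  vars <- c(covariates, "APOE", "CDR_SB", indicators)
  rows <- lapply(vars, function(v) {
    src <- if (v %in% indicators) w2 else w1
    if (!v %in% names(src)) return(NULL)
    x <- as.numeric(src[[v]])
    ok <- !is.na(x)
    dich <- all(x[ok] %in% c(0, 1)) && length(unique(x[ok])) <= 2
    data.frame(variable = v, n = sum(ok), mean = mean(x[ok]),
               sd = stats::sd(x[ok]), dichotomous = dich,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cc_cols <- intersect(c(indicators, covariates), names(w2))
  cc <- merge(w2[c("subject", indicators)],
              w1[c("subject", intersect(covariates, names(w1)))],
              by = "subject")
  out <- rbind(out, data.frame(
    variable = "complete_cases",
    n = sum(stats::complete.cases(cc[setdiff(names(cc), "subject")])),
    mean = NA_real_, sd = NA_real_, dichotomous = FALSE))
  rownames(out) <- NULL
  out
}

#' Write / read pipeline tables
#'
#' CSV dialect: comma-separated, UTF-8, header row, missing cells
#' empty. The panel is written long (subject, analyte, read1, read2,
#' low, batch) with a companion analyte-metadata table (analyte, ldd).
#'
#' @param cohort,panel,x objects to write.
#' @param path,cohort_path,panel_path,meta_path file paths.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
write_panel_csv <- function(panel, panel_path, meta_path) {
  stopifnot(inherits(panel, "biomarker_panel"))
  analytes <- colnames(panel$read1)
  long <- data.frame(
    subject = rep(panel$subject, length(analytes)),
    analyte = rep(analytes, each = nrow(panel$read1)),
    read1 = as.vector(panel$read1),
    read2 = as.vector(panel$read2),
    low = as.vector(panel$low),
    batch = rep(as.character(panel$batch), length(analytes)))
  utils::write.csv(long, panel_path, row.names = FALSE, na = "")
  utils::write.csv(data.frame(analyte = analytes,
                              ldd = unname(panel$ldd[analytes])),
                   meta_path, row.names = FALSE, na = "")
  invisible(panel_path)
}

#' @rdname pipeline_io
#' @export
read_panel_csv <- function(panel_path, meta_path) {
  long <- utils::read.csv(panel_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("subject", "analyte", "read1", "read2", "low", "batch")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("panel CSV lacks column(s): ", paste(miss, collapse = ", "))
  subjects <- unique(long$subject)
  analytes <- unique(long$analyte)
  shape <- function(col, default) {
    m <- matrix(default, length(subjects), length(analytes),
                dimnames = list(NULL, analytes))
    i <- cbind(match(long$subject, subjects),
               match(long$analyte, analytes))
    m[i] <- col
    m
  }
  low <- shape(as.logical(long$low), FALSE)
  low[is.na(low)] <- FALSE
  b <- long$batch[match(subjects, long$subject)]
  structure(list(
    read1 = shape(as.numeric(long$read1), NA_real_),
    read2 = shape(as.numeric(long$read2), NA_real_),
    low = low,
    ldd = stats::setNames(meta$ldd[match(analytes, meta$analyte)],
                          analytes),
    batch = factor(b), subject = subjects), class = "biomarker_panel")
}

#' Run the full analysis pipeline
#'
#' Executes generate (optional, when no input files are given) -> panel
#' QC -> phenotype construction -> mediation screen, writing versioned
#' CSV/JSON artifacts and a manifest recording configuration, seed, row
#' counts and the QC drop log.
#'
#' @param out_dir output directory (created if needed).
#' @param config a \code{\link{cohort_config}} for synthetic input;
#'   ignored when \code{cohort_csv} is given.
#' @param cohort_csv,panel_csv,meta_csv optional paths to existing
#'   input tables (see \code{\link{read_panel_csv}} for the schema).
#' @param gate mediation significance gate.
#' @param seed seed for the replication split (and recorded in the
#'   manifest).
#' @param covariates adjustment set.
#' @return (invisibly) list with \code{delta_model}, \code{screen},
#'   \code{qc}, \code{summary} and the manifest; artifacts on disk:
#'   \code{cohort.csv}, \code{panel.csv}, \code{panel_meta.csv},
#'   \code{clean_panel.csv}, \code{qc_report.json}, \code{scores.csv},
#'   \code{delta.json}, \code{results.csv}, \code{screen.json},
#'   \code{summary.csv}, \code{manifest.json}.
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         cohort_csv = NULL, panel_csv = NULL,
                         meta_csv = NULL, gate = 0.001, seed = 42L,
                         covariates = delta_covariates()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)

  if (is.null(cohort_csv)) {
    sim <- generate_cohort(config)
    cohort <- sim$cohort; panel <- sim$panel
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_panel_csv(panel, file.path(out_dir, "panel.csv"),
                    file.path(out_dir, "panel_meta.csv"))
    jsonlite::write_json(
      list(config = unclass(config),
           true_paths = sim$truth$paths[c("a_direct", "total_apoe_delta")]),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stages <- c(stages, "generate")
  } else {
    if (is.null(panel_csv) || is.null(meta_csv))
      stop("panel_csv and meta_csv are required with cohort_csv")
    cohort <- read_cohort_csv(cohort_csv)
    panel <- read_panel_csv(panel_csv, meta_csv)
  }
  need <- c("subject", "wave", "APOE", covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))

  qc <- qc_panel(panel)
  clean <- data.frame(subject = qc$subject, qc$values)
  utils::write.csv(clean, file.path(out_dir, "clean_panel.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(list(seed = seed, log = qc$log,
                            dropped = qc$dropped),
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages <- c(stages, "qc")

  dm <- build_deq(cohort)
  utils::write.csv(dm$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(
    list(seed = seed,
         weights = as.data.frame(dm$weights),
         determinacy = as.list(dm$determinacy),
         fit = dm$fit$fit[c("chi2", "df", "cmin_df", "cfi", "rmsea")],
         auc = if (!is.null(dm$validation$auc_deq))
           dm$validation$auc_deq[c("auc", "ci")],
         cdr_r = dm$validation$cdr$r),
    file.path(out_dir, "delta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages <- c(stages, "build-delta")

  scr <- screen_panel(cohort, dm$scores, qc, gate = gate, seed = seed,
                      covariates = covariates)
  utils::write.csv(scr$results, file.path(out_dir, "results.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(
    list(seed = seed, gate = gate, n_analytes = scr$n_analytes,
         tables = scr$tables),
    file.path(out_dir, "screen.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages <- c(stages, "screen")

  summ <- summarize_cohort(cohort, covariates = covariates)
  utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, na = "")
  stages <- c(stages, "report")

  manifest <- list(
    stages = stages, seed = seed, gate = gate,
    n_subjects = length(unique(cohort$subject)),
    n_analytes_in = ncol(panel$read1),
    n_analytes_retained = ncol(qc$values),
    qc_dropped = qc$dropped,
    generated = is.null(cohort_csv),
    config = if (is.null(cohort_csv)) unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(delta_model = dm, screen = scr, qc = qc,
                 summary = summ, manifest = manifest))
}
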