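#' Specify a covariance-structure (SEM) model
#'
#' Parses a compact model syntax into a parameter table describing latent
#' factors, loadings, structural regressions, variances and covariances.
#' The syntax follows the conventions common to latent-variable software:
#'
#' \itemize{
#'   \item \code{F =~ x1 + x2 + x3} defines factor \code{F} measured by the
#'     listed indicators (loadings).
#'   \item \code{y ~ x1 + x2} regresses \code{y} on predictors.
#'   \item \code{a ~~ b} frees the (residual) covariance of \code{a} and
#'     \code{b}; \code{a ~~ a} its variance.
#' }
#'
#' A term may carry a premultiplier: a numeric one fixes the parameter
#' (\code{F =~ 1*x1}, \code{F ~~ 0*G}), an alphanumeric one labels it
#' (\code{deq ~ a*apoe}). Parameters sharing a label are constrained equal
#' — including across groups in multi-group fits.
#'
#' Unless given explicitly, every variable receives a free (residual)
#' variance, covariances among exogenous observed variables are freed, and
#' each factor is identified either by fixing its first loading to 1
#' (default) or, with \code{std_lv = TRUE}, by fixing its variance to 1 and
#' freeing all loadings.
#'
#' @param model character; model syntax (lines separated by newlines or
#'   semicolons, \code{#} comments allowed).
#' @param std_lv logical; identify factors by unit variance rather than by
#'   a fixed first loading.
#' @return An object of class \code{"sem_spec"}: the parameter table plus
#'   variable bookkeeping. Methods: \code{print}.
#' @examples
#' sem_spec("f =~ x1 + x2 + x3", std_lv = TRUE)
#' @export
sem_spec <- function(model, std_lv = FALSE) {
  stopifnot(is.character(model))
  lines <- unlist(strsplit(paste(model, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty model syntax")

  rows <- list()
  add <- function(lhs, op, rhs, fixed, value, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      lhs = lhs, op = op, rhs = rhs, fixed = fixed,
      value = value, label = label, user = TRUE,
      stringsAsFactors = FALSE)
  }

  for (ln in lines) {
    op <- if (grepl("=~", ln, fixed = TRUE)) "=~"
      else if (grepl("~~", ln, fixed = TRUE)) "~~"
      else if (grepl("~", ln, fixed = TRUE)) "~"
      else stop("cannot parse model line: ", ln)
    parts <- strsplit(ln, op, fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("cannot parse model line: ", ln)
    lhs <- trimws(parts[1])
    if (!grepl("^[A-Za-z._][A-Za-z0-9._]*$", lhs))
      stop("invalid variable name in: ", ln)
    terms <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    for (tm in terms) {
      if (!nzchar(tm)) stop("empty term in: ", ln)
      fixed <- FALSE; value <- NA_real_; label <- ""
      if (grepl("*", tm, fixed = TRUE)) {
        pre <- trimws(sub("\\*.*$", "", tm))
        var <- trimws(sub("^.*\\*", "", tm))
        num <- suppressWarnings(as.numeric(pre))
        if (!is.na(num)) { fixed <- TRUE; value <- num } else label <- pre
      } else var <- tm
      if (!grepl("^[A-Za-z._][A-Za-z0-9._]*$", var))
        stop("invalid variable name in: ", ln)
      add(lhs, op, var, fixed, value, label)
    }
  }
  pt <- do.call(rbind, rows)

  latents <- unique(pt$lhs[pt$op == "=~"])
  all_vars <- unique(c(pt$lhs, pt$rhs))
  observed <- setdiff(all_vars, latents)

  # endogenous: indicators and regression outcomes
  endo <- unique(c(pt$rhs[pt$op == "=~"], pt$lhs[pt$op == "~"]))
  exo <- setdiff(all_vars, endo)

  has_var <- function(v)
    any(pt$op == "~~" & pt$lhs == v & pt$rhs == v)
  has_cov <- function(a, b)
    any(pt$op == "~~" & ((pt$lhs == a & pt$rhs == b) |
                         (pt$lhs == b & pt$rhs == a)))

  auto <- list()
  # factor identification
  for (f in latents) {
    load_idx <- which(pt$op == "=~" & pt$lhs == f)
    if (std_lv) {
      if (!has_var(f))
        auto[[length(auto) + 1L]] <- data.frame(
          lhs = f, op = "~~", rhs = f, fixed = TRUE, value = 1,
          label = "", user = FALSE, stringsAsFactors = FALSE)
    } else if (!any(pt$fixed[load_idx])) {
      pt$fixed[load_idx[1]] <- TRUE
      pt$value[load_idx[1]] <- 1
    }
  }
  # free variances everywhere else
  for (v in all_vars) {
    if (!has_var(v) && !(std_lv && v %in% latents))
      auto[[length(auto) + 1L]] <- data.frame(
        lhs = v, op = "~~", rhs = v, fixed = FALSE, value = NA_real_,
        label = "", user = FALSE, stringsAsFactors = FALSE)
  }
  # saturated covariances among exogenous observed variables
  exo_obs <- intersect(exo, observed)
  if (length(exo_obs) > 1L) {
    for (i in seq_len(length(exo_obs) - 1L))
      for (j in seq(i + 1L, length(exo_obs))) {
        a <- exo_obs[i]; b <- exo_obs[j]
        if (!has_cov(a, b))
          auto[[length(auto) + 1L]] <- data.frame(
            lhs = a, op = "~~", rhs = b, fixed = FALSE, value = NA_real_,
            label = "", user = FALSE, stringsAsFactors = FALSE)
      }
  }
  # free covariances among exogenous latents
  exo_lat <- intersect(exo, latents)
  if (length(exo_lat) > 1L) {
    for (i in seq_len(length(exo_lat) - 1L))
      for (j in seq(i + 1L, length(exo_lat))) {
        a <- exo_lat[i]; b <- exo_lat[j]
        if (!has_cov(a, b))
          auto[[length(auto) + 1L]] <- data.frame(
            lhs = a, op = "~~", rhs = b, fixed = FALSE, value = NA_real_,
            label = "", user = FALSE, stringsAsFactors = FALSE)
      }
  }
  if (length(auto)) pt <- rbind(pt, do.call(rbind, auto))

  pt$pname <- paste(pt$lhs, pt$op, pt$rhs)
  if (anyDuplicated(pt$pname[pt$user]))
    stop("duplicated parameter in model syntax: ",
         pt$pname[pt$user][duplicated(pt$pname[pt$user])][1])

  # identification sanity: every latent needs a fixed loading or variance
  for (f in latents) {
    ok <- any(pt$op == "=~" & pt$lhs == f & pt$fixed & pt$value != 0) ||
      any(pt$op == "~~" & pt$lhs == f & pt$rhs == f & pt$fixed & pt$value > 0)
    if (!ok) stop("latent '", f, "' is not identified: fix a loading or ",
                  "its variance")
  }

  structure(list(ptable = pt, observed = observed, latents = latents,
                 exo = exo, endo = endo, std_lv = std_lv),
            class = "sem_spec")
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("sem_spec:", length(x$observed), "observed,",
      length(x$latents), "latent variable(s)\n")
  cat("  free parameters:", sum(!x$ptable$fixed), "\n")
  if (length(x$latents))
    cat("  latents:", paste(x$latents, collapse = ", "), "\n")
  invisible(x)
}

# Add mean-structure rows (observed intercepts free, latent means fixed 0).
add_meanstructure <- function(spec) {
  pt <- spec$ptable
  if (any(pt$op == "~1")) return(spec)
  mrows <- data.frame(
    lhs = c(spec$observed, spec$latents), op = "~1", rhs = "",
    fixed = c(rep(FALSE, length(spec$observed)),
              rep(TRUE, length(spec$latents))),
    value = c(rep(NA_real_, length(spec$observed)),
              rep(0, length(spec$latents))),
    label = "", user = FALSE, stringsAsFactors = FALSE)
  mrows$pname <- paste(mrows$lhs, mrows$op)
  spec$ptable <- rbind(pt, mrows)
  spec
}
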