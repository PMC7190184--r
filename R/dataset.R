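#' Assemble a survival mediation dataset
#'
#' Bundles the observed survival time \eqn{T_i = \min(D_i, C_i)}, the event
#' indicator \eqn{\delta_i}, a binary exposure \eqn{X_i}, optional baseline
#' covariates \eqn{Z_i} and the candidate mediator matrix \eqn{M_i} into a
#' validated container used by all downstream steps. Missing mediator values
#' are rejected: imputation, if any, must happen before ingest.
#'
#' @param time nonnegative observed times, length `n`.
#' @param event event indicators in \{0, 1\} (1 = event observed).
#' @param exposure exposure per subject (binary in the intended use).
#' @param mediators numeric `n x p` matrix of candidate mediators.
#' @param covariates optional numeric `n x q` matrix (or vector) of baseline
#'   covariates; `NULL` for none.
#' @param subject_ids,mediator_ids optional labels; defaults are generated.
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `time`, `event`, `exposure`, `covariates`, `mediators`, `subject_ids`,
#'   `mediator_ids`, `n`, `p`, `q`.
#' @export
survival_dataset <- function(time, event, exposure, mediators,
                             covariates = NULL, subject_ids = NULL,
                             mediator_ids = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  exposure <- as.numeric(exposure)
  mediators <- as.matrix(mediators)
  storage.mode(mediators) <- "double"
  n <- length(time)
  if (n < 2L) stop("need at least 2 subjects")
  if (n < 10L) warning("fewer than 10 subjects; estimates will be unstable")
  if (length(event) != n || length(exposure) != n || nrow(mediators) != n)
    stop("time, event, exposure and mediator rows must have equal length")
  if (anyNA(time) || any(time < 0)) stop("time must be nonnegative and complete")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (anyNA(exposure)) stop("exposure contains missing values")
  if (anyNA(mediators)) stop("missing mediator values: reject or impute upstream")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n) stop("covariate rows must match n")
    if (anyNA(covariates)) stop("covariates contain missing values")
  } else {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  if (is.null(mediator_ids)) {
    mediator_ids <- colnames(mediators)
    if (is.null(mediator_ids)) mediator_ids <- paste0("M", seq_len(ncol(mediators)))
  }
  colnames(mediators) <- mediator_ids
  structure(
    list(time = time, event = event, exposure = exposure,
         covariates = covariates, mediators = mediators,
         subject_ids = subject_ids, mediator_ids = mediator_ids,
         n = n, p = ncol(mediators), q = ncol(covariates)),
    class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("survival_dataset:", x$n, "subjects,", x$p, "mediators,",
      x$q, "covariates;", sum(x$event), "events (",
      sprintf("%.1f%%", 100 * (1 - mean(x$event))), "censored )\n")
  invisible(x)
}

#' Read a phenotype table and mediator matrix from delimited files
#'
#' Phenotype and mediator files may be TSV or CSV (decided by extension).
#' The mediator file is subjects x mediators with the first column holding
#' subject ids matching the phenotype table. Subjects with missing survival
#' time, event, exposure or covariates are dropped (complete-case filtering)
#' with a message reporting the count; missing mediator values are an error.
#'
#' @param pheno_file,mediator_file paths to the delimited files.
#' @param time_col,event_col,exposure_col column names in the phenotype table.
#' @param covariate_cols character vector of covariate column names (may be
#'   empty).
#' @param id_col subject-id column name in the phenotype table.
#' @return A [survival_dataset()].
#' @export
read_survival_data <- function(pheno_file, mediator_file,
                               time_col = "time", event_col = "event",
                               exposure_col = "exposure",
                               covariate_cols = character(),
                               id_col = "subject_id") {
  read_any <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      read.csv(path, check.names = FALSE)
    } else {
      read.delim(path, check.names = FALSE)
    }
  }
  ph <- read_any(pheno_file)
  md <- read_any(mediator_file)
  need <- c(id_col, time_col, event_col, exposure_col, covariate_cols)
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  keep <- stats::complete.cases(ph[, c(time_col, event_col, exposure_col,
                                       covariate_cols), drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " subject(s) dropped for missing phenotype values; ",
            sum(keep), " retained")
    ph <- ph[keep, , drop = FALSE]
  }
  mid <- as.character(md[[1]])
  mm <- as.matrix(md[, -1, drop = FALSE])
  storage.mode(mm) <- "double"
  idx <- match(as.character(ph[[id_col]]), mid)
  if (anyNA(idx)) stop("phenotype subjects missing from mediator matrix")
  mm <- mm[idx, , drop = FALSE]
  covs <- if (length(covariate_cols)) {
    as.matrix(ph[, covariate_cols, drop = FALSE])
  } else NULL
  survival_dataset(time = ph[[time_col]], event = ph[[event_col]],
                   exposure = ph[[exposure_col]], mediators = mm,
                   covariates = covs,
                   subject_ids = as.character(ph[[id_col]]))
}

# design matrix over the selected columns: exposure first, then covariates,
# then the requested mediators (in the given order)
design_matrix <- function(data, mediators = integer(0),
                          include_exposure = TRUE, include_covariates = TRUE) {
  cols <- list()
  nm <- character()
  if (include_exposure) {
    cols <- c(cols, list(data$exposure))
    nm <- c(nm, "exposure")
  }
  if (include_covariates && data$q > 0) {
    cols <- c(cols, list(data$covariates))
    nm <- c(nm, colnames(data$covariates) %||%
              paste0("Z", seq_len(data$q)))
  }
  if (length(mediators)) {
    cols <- c(cols, list(data$mediators[, mediators, drop = FALSE]))
    nm <- c(nm, data$mediator_ids[mediators])
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow = data$n, ncol = 0)
  colnames(X) <- nm
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sort order and tie-group first indices (0-based) for the C++ routines
cox_prep <- function(time) {
  ord <- order(time)
  ts <- time[ord]
  newgrp <- !duplicated(ts)
  first <- which(newgrp)[cumsum(newgrp)] - 1L
  list(ord = ord, first = as.integer(first))
}
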