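#' ROI time-series container
#'
#' One subject's ROI-by-timepoint array of average BOLD signals (or any
#' stand-in signal).  Constant series are rejected because their Pearson
#' correlation is undefined.
#'
#' @param values numeric matrix, ROIs in rows, timepoints in columns.
#' @param subject_id subject identifier.
#' @param roi_ids ordered ROI identifiers; defaults to `rownames(values)` or
#'   `1..nrow`.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, subject_id = "subject",
                           roi_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(roi_ids))
    roi_ids <- rownames(values) %||% seq_len(nrow(values))
  if (ncol(values) < 2)
    stop_input("need >= 2 timepoints, got %d", ncol(values))
  if (anyNA(values)) stop_input("time series contain missing values")
  v <- apply(values, 1, var)
  if (any(v <= 0))
    stop_input("constant time series for ROI(s): %s",
               paste(roi_ids[v <= 0], collapse = ", "))
  structure(list(subject_id = as.character(subject_id),
                 values = unname(values), roi_ids = roi_ids),
            class = "roi_timeseries")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Functional connectivity matrix container
#'
#' A symmetric ROI-by-ROI Pearson correlation matrix with unit diagonal.
#' On construction the matrix is checked for squareness, symmetry (within
#' `sym_tol`, then symmetrized by averaging with its transpose), exact unit
#' diagonal (enforced), and off-diagonal range \eqn{[-1, 1]}.
#'
#' @param matrix numeric square matrix.
#' @param subject_id subject identifier.
#' @param roi_ids ordered ROI identifiers.
#' @param sym_tol maximum tolerated asymmetry; `1e-12` for in-memory
#'   matrices, relaxed to `1e-8` when reading text files.
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix <- function(matrix, subject_id = "subject", roi_ids = NULL,
                      sym_tol = 1e-12) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m))
    stop_input("FC matrix must be square, got %d x %d", nrow(m), ncol(m))
  if (is.null(roi_ids))
    roi_ids <- rownames(m) %||% seq_len(nrow(m))
  if (length(roi_ids) != nrow(m))
    stop_input("roi_ids length %d != matrix dimension %d",
               length(roi_ids), nrow(m))
  asym <- max(abs(m - t(m)))
  if (asym > sym_tol)
    stop_input("FC matrix asymmetric beyond tolerance (max |m - t(m)| = %g)",
               asym)
  m <- (m + t(m)) / 2
  bad <- which(abs(m) > 1 + 1e-12 & row(m) < col(m), arr.ind = TRUE)
  if (nrow(bad))
    stop_input("off-diagonal entry out of [-1, 1] at row %d, column %d (%g)",
               bad[1, 1], bad[1, 2], m[bad[1, 1], bad[1, 2]])
  m[m > 1] <- 1; m[m < -1] <- -1
  if (any(abs(diag(m) - 1) > 1e-6))
    stop_input("diagonal entry differs from 1 at row %d",
               which(abs(diag(m) - 1) > 1e-6)[1])
  diag(m) <- 1
  dimnames(m) <- NULL
  structure(list(subject_id = as.character(subject_id), matrix = m,
                 roi_ids = roi_ids),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> subject '%s', %d ROIs\n",
              x$subject_id, nrow(x$matrix)))
  invisible(x)
}

#' Pearson functional connectivity from ROI time series
#'
#' Entry (i, j) is the sample Pearson correlation between the series of ROI i
#' and ROI j; the diagonal is set to exactly 1.
#'
#' @param ts a [roi_timeseries()].
#' @return An [fc_matrix()].
#' @export
pearson_fc <- function(ts) {
  if (!inherits(ts, "roi_timeseries")) ts <- roi_timeseries(ts)
  m <- cor(t(ts$values))
  fc_matrix(m, subject_id = ts$subject_id, roi_ids = ts$roi_ids,
            sym_tol = 1e-12)
}

#' Read / write FC matrices as CSV
#'
#' The on-disk format is a CSV with an ROI-id header row and first column.
#' Values are written with 17 significant digits so that
#' `read_fc_matrix(write_fc_matrix(x))` round-trips exactly.  On reading,
#' symmetry is checked at `1e-8` (text-format rounding tolerance) and the
#' matrix symmetrized.
#'
#' @param fc an [fc_matrix()].
#' @param path file path.
#' @param subject_id subject id to attach on read; defaults to the file name.
#' @return `read_fc_matrix` returns an [fc_matrix()]; `write_fc_matrix`
#'   returns `path` invisibly.
#' @export
write_fc_matrix <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  m <- matrix(format(fc$matrix, digits = 17, trim = TRUE),
              nrow = nrow(fc$matrix))
  dimnames(m) <- list(fc$roi_ids, fc$roi_ids)
  write.csv(m, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop_input("FC matrix file not found: %s", path)
  d <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m)) stop_input("non-numeric entries in %s", path)
  if (!identical(rownames(m), colnames(m)))
    stop_input("row and column ROI ids disagree in %s", path)
  fc_matrix(m, subject_id = subject_id %||%
              sub("\\.csv$", "", basename(path)),
            roi_ids = rownames(m), sym_tol = 1e-8)
}
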