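#' Expression matrix container
#'
#' Probe x sample matrix of summarized, normalized sample-channel signals
#' on the linear scale, together with the per-probe expressed mask, the
#' per-array summarized empty-spot level used for the expression call, and
#' the pre-processing provenance.
#'
#' @param signal numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = array ids); all values > 0.
#' @param expressed logical vector, one per probe row (may be \code{NULL}
#'   before \code{\link{call_expressed}} has been applied).
#' @param empty_summary numeric vector, one per array: mean summarized
#'   empty-spot signal.
#' @param provenance named list of pre-processing parameters.
#' @return object of class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(signal, expressed = NULL, empty_summary = NULL,
                              provenance = list()) {
  signal <- as.matrix(signal)
  if (any(!is.finite(signal)))
    stop("content error: signal matrix must be finite", call. = FALSE)
  if (any(signal <= 0))
    stop("content error: signal matrix must be strictly positive",
         call. = FALSE)
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("signal matrix needs probe rownames and sample colnames",
         call. = FALSE)
  if (!is.null(expressed) && length(expressed) != nrow(signal))
    stop("expressed mask length must equal the number of probe rows",
         call. = FALSE)
  structure(list(signal = signal, expressed = expressed,
                 empty_summary = empty_summary, provenance = provenance),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$signal), "probes x", ncol(x$signal),
      "samples")
  if (!is.null(x$expressed)) cat(";", sum(x$expressed), "expressed")
  cat("\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$signal)

#' Log2 view of an expression matrix
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param expressed_only keep only probes flagged expressed.
#' @return numeric matrix of log2 signals.
#' @export
log2_signal <- function(em, expressed_only = FALSE) {
  m <- em$signal
  if (expressed_only) {
    if (is.null(em$expressed))
      stop("no expressed mask available; run call_expressed() first",
           call. = FALSE)
    m <- m[em$expressed, , drop = FALSE]
  }
  log2(m)
}

#' Read or write an expression matrix
#'
#' The matrix goes to a TSV (\code{probe_id} column then one column per
#' sample, full double precision so the round trip is lossless); the
#' expressed mask, per-array empty-spot summaries and provenance go to a
#' JSON side-car at \code{<path>.meta.json}.
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param path path of the matrix TSV.
#' @return \code{read_expression_matrix} returns the restored object.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  if (any(is.na(em$signal)))
    stop("serialization refused: matrix contains NaN/NA", call. = FALSE)
  rn <- rownames(em$signal)
  df <- data.frame(probe_id = if (is.null(rn)) character(0) else rn,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(em$signal)))
    df[[colnames(em$signal)[j]]] <- format_full(em$signal[, j])
  write_tsv(df, path)
  meta <- list(samples = colnames(em$signal),
               expressed = em$expressed,
               empty_summary = if (is.null(em$empty_summary)) NULL else
                 format_full(em$empty_summary),
               provenance = em$provenance)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_checked(path, "probe_id")
  samples <- setdiff(names(df), "probe_id")
  m <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(df$probe_id, samples))
  for (j in seq_along(samples))
    m[, j] <- parse_numeric(df[[samples[j]]], samples[j])
  meta_path <- paste0(path, ".meta.json")
  expressed <- NULL; empty_summary <- NULL; provenance <- list()
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$expressed)) expressed <- as.logical(meta$expressed)
    if (!is.null(meta$empty_summary))
      empty_summary <- as.numeric(meta$empty_summary)
    if (!is.null(meta$provenance)) provenance <- as.list(meta$provenance)
  }
  if (nrow(m) == 0)  # header-only file: valid degenerate matrix
    return(structure(list(signal = m, expressed = expressed,
                          empty_summary = empty_summary,
                          provenance = provenance),
                     class = "expression_matrix"))
  expression_matrix(m, expressed, empty_summary, provenance)
}
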