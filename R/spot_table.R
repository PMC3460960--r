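#' Construct a spot table
#'
#' Raw two-channel intensities for one hybridization: one row per physical
#' spot, with the probe id, the replicate index (target probes are printed
#' in quadruplicate by default; empty spots appear once each), the
#' sample-channel (Hy3-like) and reference-channel (Hy5-like) raw
#' intensities.
#'
#' @param array_id identifier of the hybridization.
#' @param probe_id,replicate,sample_signal,reference_signal parallel
#'   vectors, one element per spot.
#' @param panel optional \code{\link{probe_panel}} to validate probe ids
#'   and replicate counts against.
#' @param replicates expected replicate count for non-empty probes
#'   (default 4).
#' @return data.frame of class \code{"spot_table"} with attribute
#'   \code{array_id}.
#' @export
spot_table <- function(array_id, probe_id, replicate, sample_signal,
                       reference_signal, panel = NULL, replicates = 4L) {
  df <- data.frame(probe_id = as.character(probe_id),
                   replicate = as.integer(replicate),
                   sample_signal = as.numeric(sample_signal),
                   reference_signal = as.numeric(reference_signal),
                   stringsAsFactors = FALSE)
  for (col in c("sample_signal", "reference_signal"))
    if (any(!is.finite(df[[col]]) | df[[col]] < 0))
      stop("content error: column '", col,
           "' must be finite and non-negative", call. = FALSE)
  if (!is.null(panel)) {
    unknown <- setdiff(df$probe_id, panel$probe_id)
    if (length(unknown))
      stop("content error: probe(s) absent from panel: ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    counts <- table(df$probe_id)
    nonempty <- panel$probe_id[!panel$is_empty]
    bad <- nonempty[counts[nonempty] != replicates]
    bad <- bad[!is.na(bad)]
    if (length(bad) || anyNA(counts[nonempty]))
      stop("content error: non-empty probes must appear with replicate ",
           "count ", replicates, "; offending probe(s): ",
           paste(utils::head(c(bad, nonempty[is.na(counts[nonempty])]), 3),
                 collapse = ", "), call. = FALSE)
  }
  attr(df, "array_id") <- as.character(array_id)
  class(df) <- c("spot_table", "data.frame")
  df
}

#' @export
print.spot_table <- function(x, ...) {
  cat("Spot table '", attr(x, "array_id"), "': ", nrow(x), " spots, ",
      length(unique(x$probe_id)), " probes\n", sep = "")
  invisible(x)
}

#' Read spot-table TSV files
#'
#' One file per hybridization; columns \code{probe_id}, \code{replicate},
#' \code{sample_signal}, \code{reference_signal}. The array id is the file
#' name without its extension.
#'
#' @param paths character vector of file paths.
#' @param panel a \code{\link{probe_panel}}; unknown probe ids are
#'   rejected and replicate counts validated.
#' @param replicates expected replicate count for non-empty probes.
#' @return list of \code{\link{spot_table}} objects.
#' @export
read_spot_tables <- function(paths, panel, replicates = 4L) {
  lapply(paths, function(path) {
    df <- read_tsv_checked(path, c("probe_id", "replicate", "sample_signal",
                                   "reference_signal"))
    spot_table(sub("\\.[^.]*$", "", basename(path)),
               df$probe_id,
               parse_numeric(df$replicate, "replicate"),
               parse_numeric(df$sample_signal, "sample_signal"),
               parse_numeric(df$reference_signal, "reference_signal"),
               panel = panel, replicates = replicates)
  })
}

#' Write spot tables to a directory
#'
#' @param tables list of \code{\link{spot_table}} objects.
#' @param dir output directory (created if needed); each table is written
#'   to \code{<array_id>.tsv}.
#' @return invisibly, the written file paths.
#' @export
write_spot_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(tables, function(tab) {
    stopifnot(inherits(tab, "spot_table"))
    path <- file.path(dir, paste0(attr(tab, "array_id"), ".tsv"))
    df <- as.data.frame(tab)
    df$sample_signal <- format_full(df$sample_signal)
    df$reference_signal <- format_full(df$reference_signal)
    write_tsv(df, path)
    path
  }, "")
  invisible(paths)
}
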