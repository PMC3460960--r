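#' Construct a probe panel
#'
#' The probe panel describes the printed content of the array: every probe
#' id, the RNA species each probe targets (a probe may recognize more than
#' one mature RNA, e.g. closely related small nucleolar RNAs; such probes
#' are carried as a single analysis variable keyed by probe id, with the
#' target names kept as annotation only), whether the position is a
#' probe-less empty spot, and whether the targets are human.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param targets list of character vectors (one per probe) naming the RNAs
#'   the probe recognizes, or a character vector of semicolon-joined names.
#'   Empty spots must have zero targets.
#' @param is_empty logical; \code{TRUE} for probe-less empty spots.
#' @param is_human logical; \code{TRUE} if the probe targets human RNAs.
#' @return A \code{data.frame} of class \code{"probe_panel"} with columns
#'   \code{probe_id}, \code{targets} (list column), \code{is_empty},
#'   \code{is_human}.
#' @export
probe_panel <- function(probe_id, targets, is_empty, is_human) {
  probe_id <- as.character(probe_id)
  n <- length(probe_id)
  if (is.character(targets)) {
    targets <- lapply(targets, function(x) {
      x <- strsplit(x, ";", fixed = TRUE)[[1]]
      x[nzchar(x)]
    })
  }
  if (!is.list(targets) || length(targets) != n)
    stop("'targets' must be a list (or semicolon-joined character) of length ",
         n, call. = FALSE)
  is_empty <- rep_len(as.logical(is_empty), n)
  is_human <- rep_len(as.logical(is_human), n)
  if (anyDuplicated(probe_id))
    stop("probe_id values must be unique; duplicated: ",
         paste(unique(probe_id[duplicated(probe_id)])[1:3], collapse = ", "),
         call. = FALSE)
  n_targets <- lengths(targets)
  if (any(is_empty & n_targets > 0))
    stop("empty-spot probes must have zero target RNAs", call. = FALSE)
  if (any(!is_empty & n_targets == 0))
    stop("every non-empty probe needs at least one target RNA", call. = FALSE)
  out <- data.frame(probe_id = probe_id, is_empty = is_empty,
                    is_human = is_human, stringsAsFactors = FALSE)
  out$targets <- targets
  out <- out[, c("probe_id", "targets", "is_empty", "is_human")]
  class(out) <- c("probe_panel", "data.frame")
  out
}

#' @export
print.probe_panel <- function(x, ...) {
  cat("Probe panel:", nrow(x), "probes (",
      sum(!x$is_empty), "target probes,", sum(x$is_empty), "empty spots,",
      sum(x$is_human), "human )\n")
  invisible(x)
}

#' Read or write a probe panel TSV
#'
#' Tab-separated UTF-8 with a single header row and columns
#' \code{probe_id}, \code{targets} (semicolon-joined RNA names, blank for
#' empty spots), \code{is_empty}, \code{is_human}.
#'
#' @param path file path.
#' @return \code{read_probe_panel} returns a \code{\link{probe_panel}}.
#' @export
read_probe_panel <- function(path) {
  df <- read_tsv_checked(path, c("probe_id", "targets", "is_empty", "is_human"))
  df$targets[is.na(df$targets)] <- ""  # blank cell = empty spot, no targets
  probe_panel(df$probe_id, as.character(df$targets),
              parse_logical(df$is_empty, "is_empty"),
              parse_logical(df$is_human, "is_human"))
}

#' @param panel a \code{\link{probe_panel}}.
#' @rdname read_probe_panel
#' @export
write_probe_panel <- function(panel, path) {
  stopifnot(inherits(panel, "probe_panel"))
  df <- data.frame(probe_id = panel$probe_id,
                   targets = vapply(panel$targets, paste, "", collapse = ";"),
                   is_empty = panel$is_empty, is_human = panel$is_human,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

## internal: shared TSV helpers -------------------------------------------

read_tsv_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("format error in '", basename(path), "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
}

parse_logical <- function(x, field) {
  out <- as.logical(toupper(x))
  out[x %in% c("1", "yes")] <- TRUE
  out[x %in% c("0", "no")] <- FALSE
  if (anyNA(out))
    stop("content error: column '", field, "' has non-logical value(s): ",
         paste(utils::head(unique(x[is.na(out)]), 3), collapse = ", "),
         call. = FALSE)
  out
}

parse_numeric <- function(x, field, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    stop("content error: column '", field, "' has non-numeric value(s): ",
         paste(utils::head(unique(x[bad]), 3), collapse = ", "), call. = FALSE)
  if (!allow_na && anyNA(out))
    stop("content error: column '", field, "' has missing value(s)",
         call. = FALSE)
  out
}

## number formatting that survives a text round trip bit-for-bit
format_full <- function(x) sprintf("%.17g", x)
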