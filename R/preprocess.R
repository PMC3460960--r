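#' Pre-processing parameters
#'
#' @param normexp_offset offset added to normexp-corrected intensities
#'   (default 10).
#' @param loess_span span of the global within-array loess normalization
#'   of M on A (default 1/3).
#' @param expressed_fold a probe is counted on an array when its
#'   summarized signal exceeds \code{expressed_fold} times that array's
#'   summarized empty-spot level (default 3).
#' @param expressed_fraction fraction of arrays on which the count must be
#'   reached, "at least" semantics via \code{ceiling} (default 0.25).
#' @param summarize_ratio_threshold replicate spots are averaged when
#'   max < threshold * min, otherwise the median is taken (default 1.5).
#' @param pooled_empty use one pooled empty-spot level across arrays for
#'   the expression call instead of per-array levels (default FALSE).
#' @return list of class \code{"preprocess_config"}.
#' @export
preprocess_config <- function(normexp_offset = 10, loess_span = 1 / 3,
                              expressed_fold = 3, expressed_fraction = 0.25,
                              summarize_ratio_threshold = 1.5,
                              pooled_empty = FALSE) {
  if (normexp_offset < 0)
    stop("config error: normexp_offset must be >= 0", call. = FALSE)
  if (loess_span <= 0 || loess_span > 1)
    stop("config error: loess_span must be in (0, 1]", call. = FALSE)
  if (expressed_fold <= 1)
    stop("config error: expressed_fold must be > 1", call. = FALSE)
  if (expressed_fraction <= 0 || expressed_fraction > 1)
    stop("config error: expressed_fraction must be in (0, 1]", call. = FALSE)
  if (summarize_ratio_threshold <= 1)
    stop("config error: summarize_ratio_threshold must be > 1",
         call. = FALSE)
  structure(as.list(environment()), class = "preprocess_config")
}

#' Within-array global loess normalization
#'
#' Fits a locally weighted degree-1 regression (tricube weights, three
#' robustness iterations) of the log-ratio M on the average log-intensity
#' A over all spots of the array jointly, and subtracts the fitted trend
#' from M. A is unchanged.
#'
#' @param array data.frame with numeric columns \code{M} and \code{A}
#'   (one row per spot), as produced inside
#'   \code{\link{build_expression_matrix}}.
#' @param span loess span in (0, 1].
#' @return the array with normalized \code{M}.
#' @export
loess_normalize_within <- function(array, span = 1 / 3) {
  if (span <= 0 || span > 1)
    stop("config error: span must be in (0, 1]", call. = FALSE)
  if (nrow(array) < 10)
    stop("need at least 10 spots for loess normalization", call. = FALSE)
  if (any(!is.finite(array$A)))
    stop("content error: A values must be finite", call. = FALSE)
  array$M <- array$M - ma_loess_fit(array$M, array$A, span)
  array
}

ma_loess_fit <- function(M, A, span) {
  fit <- stats::lowess(A, M, f = span, iter = 3)
  stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
}

#' Between-array reference-channel quantile normalization
#'
#' Maps the reference-channel intensities of every array onto a common
#' distribution (the mean of the per-rank sorted values across arrays;
#' ties receive the mean of their tied ranks' values). Each spot's
#' log-ratio M is left unchanged and the sample channel is recomputed
#' from (M, new reference), so all arrays end with identical
#' reference-channel distributions.
#'
#' @param arrays list of per-array data.frames with columns \code{M} and
#'   \code{A} and equal spot counts.
#' @return list of arrays with renormalized \code{A}.
#' @export
rquantile_between <- function(arrays) {
  if (length(arrays) == 0) stop("need at least one array", call. = FALSE)
  ns <- vapply(arrays, nrow, 0L)
  if (length(unique(ns)) != 1)
    stop("content error: arrays have differing spot counts", call. = FALSE)
  if (length(arrays) == 1) return(arrays)
  ## reference intensity per spot: R = 2^(A - M/2)
  log2ref <- lapply(arrays, function(a) a$A - a$M / 2)
  target <- rowMeans(vapply(log2ref, function(v) sort(2^v),
                            numeric(ns[1])))
  lapply(seq_along(arrays), function(j) {
    a <- arrays[[j]]
    r <- rank(log2ref[[j]], ties.method = "average")
    new_ref <- (target[floor(r)] + target[ceiling(r)]) / 2
    a$A <- log2(new_ref) + a$M / 2
    a
  })
}

#' Summarize replicate spot values for one probe
#'
#' Mean of the replicate values when the maximum is below
#' \code{ratio_threshold} times the minimum, otherwise the median (a
#' robust fallback for corrupted spots).
#'
#' @param values positive replicate values (k >= 1).
#' @param ratio_threshold default 1.5.
#' @return scalar summary.
#' @export
summarize_probe <- function(values, ratio_threshold = 1.5) {
  if (length(values) == 0)
    stop("content error: no replicate values to summarize", call. = FALSE)
  if (max(values) < ratio_threshold * min(values)) mean(values)
  else stats::median(values)
}

#' Build the summarized, normalized expression matrix
#'
#' Runs the full pre-processing chain on raw spot tables, in fixed order:
#' normexp background correction per array and channel (with offset),
#' within-array global loess normalization of M on A, between-array
#' quantile normalization of the reference channel, then replicate-spot
#' summarization of the sample-channel intensities per probe and array
#' (empty spots summarized identically). The expression call against
#' empty spots is applied unless \code{call = FALSE}.
#'
#' @param spot_tables list of \code{\link{spot_table}} objects sharing
#'   one panel.
#' @param panel the \code{\link{probe_panel}}.
#' @param config a \code{\link{preprocess_config}}.
#' @param call apply \code{\link{call_expressed}} (default TRUE).
#' @return an \code{\link{expression_matrix}} over the non-empty probes,
#'   with per-array empty-spot summaries and provenance recorded.
#' @export
build_expression_matrix <- function(spot_tables, panel,
                                    config = preprocess_config(),
                                    call = TRUE) {
  stopifnot(inherits(panel, "probe_panel"),
            inherits(config, "preprocess_config"))
  array_ids <- vapply(spot_tables, attr, "", "array_id")
  is_empty <- stats::setNames(panel$is_empty, panel$probe_id)

  arrays <- lapply(spot_tables, function(tab) {
    unknown <- setdiff(tab$probe_id, panel$probe_id)
    if (length(unknown))
      stop("content error: probe(s) absent from panel: ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    smp <- normexp_correct(tab$sample_signal, config$normexp_offset)
    ref <- normexp_correct(tab$reference_signal, config$normexp_offset)
    a <- data.frame(probe_id = tab$probe_id,
                    M = log2(smp) - log2(ref),
                    A = (log2(smp) + log2(ref)) / 2,
                    stringsAsFactors = FALSE)
    loess_normalize_within(a, config$loess_span)
  })
  arrays <- rquantile_between(arrays)

  probes <- panel$probe_id[!panel$is_empty]
  signal <- matrix(NA_real_, length(probes), length(arrays),
                   dimnames = list(probes, array_ids))
  empty_summary <- numeric(length(arrays))
  for (j in seq_along(arrays)) {
    a <- arrays[[j]]
    hy3 <- 2^(a$A + a$M / 2)  # back-transformed sample-channel intensity
    per_probe <- vapply(split(hy3, a$probe_id), summarize_probe,
                        numeric(1),
                        ratio_threshold = config$summarize_ratio_threshold)
    signal[, j] <- per_probe[probes]
    empty_summary[j] <- mean(per_probe[names(per_probe) %in%
                                         panel$probe_id[panel$is_empty]])
  }
  em <- expression_matrix(signal, NULL, empty_summary,
                          provenance = list(
                            normexp_offset = config$normexp_offset,
                            loess_span = config$loess_span,
                            summarize_ratio_threshold =
                              config$summarize_ratio_threshold,
                            expressed_fold = config$expressed_fold,
                            expressed_fraction = config$expressed_fraction,
                            pooled_empty = config$pooled_empty,
                            order = "normexp > loess_within > rquantile > summarize"))
  if (call)
    em <- call_expressed(em, fold = config$expressed_fold,
                         fraction = config$expressed_fraction,
                         pooled = config$pooled_empty)
  em
}

#' Call expressed probes against empty-spot levels
#'
#' A probe is flagged expressed when its summarized signal exceeds
#' \code{fold} times the (per-array, or pooled) summarized empty-spot
#' level on at least \code{ceiling(fraction * n_arrays)} arrays.
#'
#' @param em an \code{\link{expression_matrix}} carrying per-array
#'   empty-spot summaries.
#' @param fold default 3.
#' @param fraction default 0.25.
#' @param pooled compare against the pooled mean empty-spot level instead
#'   of per-array levels.
#' @return the matrix with its \code{expressed} mask set.
#' @export
call_expressed <- function(em, fold = 3, fraction = 0.25, pooled = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$empty_summary))
    stop("content error: no empty-spot summaries available", call. = FALSE)
  n_arrays <- ncol(em$signal)
  required <- ceiling(fraction * n_arrays)
  if (required < 1)
    stop("config error: expression-call fraction requires at least one ",
         "array", call. = FALSE)
  thresh <- if (pooled) rep(fold * mean(em$empty_summary), n_arrays)
  else fold * em$empty_summary
  counts <- rowSums(sweep(em$signal, 2, thresh, ">"))
  em$expressed <- counts >= required
  em$provenance$expressed_fold <- fold
  em$provenance$expressed_fraction <- fraction
  em$provenance$pooled_empty <- pooled
  em
}
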