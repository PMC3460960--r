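#' Configuration of the synthetic spot-level generator
#'
#' The generator emulates the statistical structure of a 45-subject
#' whole-blood two-color microRNA array study: 22 cases and 23 controls,
#' ~1305 target probes printed in quadruplicate plus 548 probe-less empty
#' spots per array, additive Normal background plus Exponential signal
#' intensities per spot, an intensity-dependent dye bias on the sample
#' channel, planted case/control fold-changes spanning the 0.54--1.59
#' range, one planted probe pair whose within-sample ordering separates
#' the classes perfectly in the latent signals, and an age covariate that
#' differs between classes (70.6 +/- 7.7 vs 59.9 +/- 9.1 years) and drives
#' a subset of probes.
#'
#' Scale defaults are calibrated so that, after pre-processing with the
#' default parameters, summarized empty-spot signals land near 11 and the
#' probe-level signal inter-quartile range is about 2^5.5 to 2^7.5.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param case_age_mean,case_age_sd,control_age_mean,control_age_sd age
#'   distributions (years), truncated to \code{case_age_range} /
#'   \code{control_age_range}.
#' @param case_age_range,control_age_range plausible age bounds.
#' @param n_probes number of target probes; \code{n_empty_spots} probe-less
#'   spots; \code{replicates} spots per target probe.
#' @param background_mean,background_sd Normal background per spot.
#' @param signal_scale multiplier linking latent linear expression to the
#'   Exponential spot-signal mean.
#' @param off_fraction fraction of probes whose target RNA is absent from
#'   blood: their spots carry background only. Whole-blood profiling
#'   detects only a minority of known microRNAs, and this bimodality is
#'   what lets background correction identify the background cleanly.
#' @param baseline_log2_mean,baseline_log2_sd across-probe spread of mean
#'   log2 expression levels for the expressed fraction.
#' @param sample_log2_sd within-probe biological spread across samples
#'   (log2 units).
#' @param dye_bias_amplitude amplitude (log2 units) of the smooth
#'   intensity-dependent sample-channel dye bias.
#' @param n_de_probes number of differentially expressed probes;
#'   \code{fold_change_range} the case/control fold-change range they are
#'   drawn from (uniform on the log2 scale).
#' @param de_fold_changes optional explicit vector of planted
#'   fold-changes (length \code{n_de_probes}) overriding the random draw,
#'   for parameter-recovery experiments.
#' @param planted_pair plant a perfectly separating probe pair?
#' @param pair_margin_log2 latent log2 ratio between the pair probes
#'   (reversed between classes). The quadruplicate Exponential spot noise
#'   puts ~1.1 log2 units of sd on any two-probe comparison, so margins
#'   of 4-5 are needed for separation to survive measurement.
#' @param n_age_probes,age_effect probes whose log2 level includes
#'   \code{age_effect * (age - mean age)}.
#' @param outlier_spot_rate,outlier_factor probability that a replicate
#'   spot is corrupted, and the multiplicative corruption.
#' @param seed integer RNG seed.
#' @return list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_cases = 22, n_controls = 23,
                             case_age_mean = 70.6, case_age_sd = 7.7,
                             control_age_mean = 59.9, control_age_sd = 9.1,
                             case_age_range = c(50, 85),
                             control_age_range = c(36, 74),
                             n_probes = 1305, n_empty_spots = 548,
                             replicates = 4,
                             background_mean = 60, background_sd = 0.5,
                             signal_scale = 1,
                             off_fraction = 0.65,
                             baseline_log2_mean = 6.5,
                             baseline_log2_sd = 1.48,
                             sample_log2_sd = 0.3,
                             dye_bias_amplitude = 0.3,
                             n_de_probes = 30,
                             fold_change_range = c(0.54, 1.59),
                             de_fold_changes = NULL,
                             planted_pair = TRUE, pair_margin_log2 = 5,
                             n_age_probes = 25, age_effect = 0.06,
                             outlier_spot_rate = 0.05, outlier_factor = 3,
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_cases", "n_controls", "n_probes", "n_empty_spots",
              "replicates")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop("config error: ", nm, " must be positive",
                            call. = FALSE)
  if (any(fold_change_range <= 0))
    stop("config error: fold-change range must be positive", call. = FALSE)
  if (outlier_spot_rate < 0 || outlier_spot_rate > 1)
    stop("config error: outlier_spot_rate must be in [0,1]", call. = FALSE)
  if (planted_pair && n_probes < 2)
    stop("config error: planted_pair requires at least 2 probes",
         call. = FALSE)
  if (n_de_probes + n_age_probes + 2 * planted_pair > n_probes)
    stop("config error: more planted probes than probes", call. = FALSE)
  if (!is.null(de_fold_changes)) {
    if (length(de_fold_changes) != n_de_probes ||
        any(de_fold_changes <= 0))
      stop("config error: de_fold_changes must be ", n_de_probes,
           " positive values", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

rnorm_trunc <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2]))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic spot-level dataset
#'
#' Draws, per sample and probe, a latent linear expression level
#' (log-normal baseline plus per-sample biological noise); case samples
#' multiply the levels of the planted DE probes by their fold-change;
#' age-linked probes add \code{age_effect * (age - mean age)} on the log2
#' scale; the planted pair rides on a shared per-sample baseline with a
#' reversed latent offset between classes. Each replicate spot intensity
#' is Normal background plus an Exponential draw whose mean is
#' \code{signal_scale} times the latent level; the reference channel uses
#' a common pooled latent level per probe (a universal-reference
#' emulation, identical across arrays up to spot noise); a smooth function
#' of log2 intensity is added to the sample-channel log signal as dye
#' bias; outlier spots are multiplied by a large factor; empty spots are
#' background only.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{spot_tables} (list of
#'   \code{\link{spot_table}}), \code{sheet} (a
#'   \code{\link{sample_sheet}}), \code{panel} (a
#'   \code{\link{probe_panel}}) and \code{truth} (a \code{ground_truth}
#'   recording every planted parameter).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_cases + config$n_controls
  is_case <- rep(c(TRUE, FALSE), c(config$n_cases, config$n_controls))
  ages <- numeric(n)
  ages[is_case] <- rnorm_trunc(config$n_cases, config$case_age_mean,
                               config$case_age_sd, config$case_age_range)
  ages[!is_case] <- rnorm_trunc(config$n_controls, config$control_age_mean,
                                config$control_age_sd,
                                config$control_age_range)
  ## blood parameters: cohort-realistic means/SDs; a few controls lack values
  wbc <- ifelse(is_case, stats::rnorm(n, 6.7, 1.8), stats::rnorm(n, 7.7, 2.7))
  plt <- ifelse(is_case, stats::rnorm(n, 233.9, 81.1),
                stats::rnorm(n, 263.4, 68.8))
  hgb <- ifelse(is_case, stats::rnorm(n, 13.5, 1.4),
                stats::rnorm(n, 13.5, 1.3))
  wbc <- pmax(wbc, 1); plt <- pmax(plt, 20); hgb <- pmax(hgb, 5)
  miss <- sample(which(!is_case), min(6, config$n_controls))
  wbc[miss] <- NA; plt[miss] <- NA; hgb[miss] <- NA
  sheet <- sample_sheet(
    sample_id = sprintf("S%02d", seq_len(n)),
    class = ifelse(is_case, "case", "control"),
    control_subtype = ifelse(is_case, "none",
                             ifelse(stats::runif(n) < 10 / 23, "nodule",
                                    "high_risk")),
    age = ages,
    gender = ifelse(stats::runif(n) < 0.53, "M", "F"),
    smoking = stats::runif(n) < 0.87,
    wbc = wbc, platelets = plt, hemoglobin = hgb)

  p <- config$n_probes
  probe_ids <- sprintf("probe_%04d", seq_len(p))
  empty_ids <- sprintf("empty_%04d", seq_len(config$n_empty_spots))
  panel <- probe_panel(
    c(probe_ids, empty_ids),
    c(sprintf("miR-sim-%04d", seq_len(p)),
      rep("", config$n_empty_spots)),
    is_empty = rep(c(FALSE, TRUE), c(p, config$n_empty_spots)),
    is_human = rep(c(TRUE, FALSE), c(p, config$n_empty_spots)))

  ## baseline log2 level per probe: a fraction of targets is simply
  ## absent from blood (background-only spots); the rest are log-normal
  m_p <- stats::rnorm(p, config$baseline_log2_mean, config$baseline_log2_sd)
  off <- stats::runif(p) < config$off_fraction
  m_p[off] <- -Inf  # zero latent signal

  ## planted roles: DE, age-linked, separating pair (disjoint); effects
  ## are planted on clearly expressed probes, as in the printed top
  ## differential lists where every probe sits well above background
  pair_idx <- if (config$planted_pair) c(1L, 2L) else integer()
  eligible <- setdiff(which(!off & m_p >= config$baseline_log2_mean),
                      pair_idx)
  need <- config$n_de_probes + config$n_age_probes
  if (length(eligible) < need)  # tiny configs: fall back to any probe
    eligible <- setdiff(seq_len(p), pair_idx)
  de_idx <- sort(sample(eligible, config$n_de_probes))
  age_idx <- sort(sample(setdiff(eligible, de_idx), config$n_age_probes))
  lfc <- if (!is.null(config$de_fold_changes))
    log2(config$de_fold_changes)
  else stats::runif(config$n_de_probes,
                    log2(config$fold_change_range[1]),
                    log2(config$fold_change_range[2]))

  ## latent log2 expression, probes x samples
  L <- matrix(m_p, p, n) +
    matrix(stats::rnorm(p * n, 0, config$sample_log2_sd), p, n)
  if (length(de_idx))
    L[de_idx, is_case] <- L[de_idx, is_case] + lfc
  age_c <- ages - mean(ages)
  if (length(age_idx))
    L[age_idx, ] <- L[age_idx, ] +
      config$age_effect * matrix(age_c, length(age_idx), n, byrow = TRUE)
  if (config$planted_pair) {
    ## pair rides on a shared per-sample baseline high enough that both
    ## probes stay clearly expressed on either side of the margin
    base <- stats::rnorm(n, config$baseline_log2_mean + 1.5,
                         config$sample_log2_sd)
    sgn <- ifelse(is_case, 1, -1)
    L[pair_idx[1], ] <- base + sgn * config$pair_margin_log2 / 2
    L[pair_idx[2], ] <- base - sgn * config$pair_margin_log2 / 2
  }

  ## pooled-reference latent per probe, common to every hybridization
  R <- log2(rowMeans(2^L)) + stats::rnorm(p, 0, 0.1)

  bias <- function(l2) config$dye_bias_amplitude *
    sin((l2 - config$baseline_log2_mean) / 2)

  k <- config$replicates
  spot_probe <- c(rep(probe_ids, each = k), empty_ids)
  spot_rep <- c(rep(seq_len(k), times = p), rep(1L, config$n_empty_spots))
  n_spots <- length(spot_probe)
  latent_rows <- rep(seq_len(p), each = k)

  spot_tables <- vector("list", n)
  for (s in seq_len(n)) {
    l2 <- L[latent_rows, s]
    mu_smp <- numeric(length(l2))
    fin <- is.finite(l2)
    mu_smp[fin] <- config$signal_scale * 2^(l2[fin] + bias(l2[fin]))
    mu_ref <- numeric(length(l2))
    finr <- is.finite(R[latent_rows])
    mu_ref[finr] <- config$signal_scale * 2^R[latent_rows][finr]
    bg <- function(m) pmax(stats::rnorm(m, config$background_mean,
                                        config$background_sd), 0)
    smp <- c(bg(p * k) + stats::rexp(p * k, rate = 1 / mu_smp),
             bg(config$n_empty_spots))
    ref <- c(bg(p * k) + stats::rexp(p * k, rate = 1 / mu_ref),
             bg(config$n_empty_spots))
    ## corruption hits probe spots (exercising the median fallback of
    ## replicate summarization); empty spots have no replicates to rescue
    out <- c(stats::runif(p * k) < config$outlier_spot_rate,
             rep(FALSE, config$n_empty_spots))
    smp[out] <- smp[out] * config$outlier_factor
    spot_tables[[s]] <- spot_table(sheet$sample_id[s], spot_probe, spot_rep,
                                   smp, ref)
  }

  truth <- structure(list(
    de = data.frame(probe_id = probe_ids[de_idx],
                    log2_fold_change = lfc,
                    fold_change = 2^lfc, stringsAsFactors = FALSE),
    age = data.frame(probe_id = probe_ids[age_idx],
                     slope = rep(config$age_effect, length(age_idx)),
                     stringsAsFactors = FALSE),
    pair = if (config$planted_pair)
      list(high_in_case = probe_ids[pair_idx[1]],
           low_in_case = probe_ids[pair_idx[2]],
           margin_log2 = config$pair_margin_log2)
    else NULL,
    latent_log2 = structure(L, dimnames = list(probe_ids, sheet$sample_id)),
    config = config), class = "ground_truth")

  list(spot_tables = spot_tables, sheet = sheet, panel = panel,
       truth = truth)
}

#' Tabulate the planted ground truth
#'
#' @param truth the \code{ground_truth} component of
#'   \code{\link{simulate_dataset}} output.
#' @return data.frame with columns \code{probe_id}, \code{role}
#'   (\code{"de"}, \code{"age"}, \code{"pair_high_in_case"},
#'   \code{"pair_low_in_case"}) and \code{value} (fold-change for DE rows,
#'   log2/year slope for age rows, latent log2 margin for the pair).
#' @export
ground_truth_report <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  rows <- list(
    data.frame(probe_id = truth$de$probe_id, role = "de",
               value = truth$de$fold_change, stringsAsFactors = FALSE),
    data.frame(probe_id = truth$age$probe_id, role = "age",
               value = truth$age$slope, stringsAsFactors = FALSE))
  if (!is.null(truth$pair))
    rows <- c(rows, list(data.frame(
      probe_id = c(truth$pair$high_in_case, truth$pair$low_in_case),
      role = c("pair_high_in_case", "pair_low_in_case"),
      value = truth$pair$margin_log2, stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Read or write a ground-truth report TSV
#'
#' @param report output of \code{\link{ground_truth_report}}.
#' @param path file path.
#' @export
write_ground_truth <- function(report, path) {
  report$value <- format_full(report$value)
  write_tsv(report, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read_tsv_checked(path, c("probe_id", "role", "value"))
  df$value <- parse_numeric(df$value, "value")
  df
}
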