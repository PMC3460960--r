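#' Construct a sample sheet
#'
#' One row per hybridized specimen with the class label (case = lung
#' adenocarcinoma, control = clinically relevant non-cancer), the control
#' subtype (benign nodule vs high-risk smoker; \code{"none"} for cases),
#' age in years, and optional blood parameters. Blood counts may be
#' missing for some subjects and are excluded pairwise from covariate
#' analyses.
#'
#' @param sample_id character, unique.
#' @param class \code{"case"} or \code{"control"}.
#' @param control_subtype \code{"nodule"}, \code{"high_risk"} or
#'   \code{"none"}; must be \code{"none"} exactly for cases.
#' @param age years, positive.
#' @param gender e.g. \code{"M"}/\code{"F"}.
#' @param smoking logical.
#' @param wbc,platelets,hemoglobin optional blood parameters
#'   (1000/ul, 1000/ul, g/dl); \code{NA} allowed.
#' @return data.frame of class \code{"sample_sheet"}.
#' @export
sample_sheet <- function(sample_id, class, control_subtype = NULL, age,
                         gender = NA_character_, smoking = NA,
                         wbc = NA_real_, platelets = NA_real_,
                         hemoglobin = NA_real_) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  class <- as.character(class)
  if (!all(class %in% c("case", "control")))
    stop("content error: class label must be 'case' or 'control', got: ",
         paste(utils::head(setdiff(unique(class), c("case", "control")), 3),
               collapse = ", "), call. = FALSE)
  if (is.null(control_subtype))
    control_subtype <- ifelse(class == "case", "none", "high_risk")
  control_subtype <- as.character(control_subtype)
  if (!all(control_subtype %in% c("nodule", "high_risk", "none")))
    stop("content error: control_subtype must be nodule|high_risk|none",
         call. = FALSE)
  if (any((control_subtype == "none") != (class == "case")))
    stop("content error: control_subtype must be 'none' iff class is 'case'",
         call. = FALSE)
  age <- as.numeric(age)
  if (any(!is.finite(age) | age <= 0))
    stop("content error: ages must be positive and finite", call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("content error: duplicated sample_id", call. = FALSE)
  out <- data.frame(sample_id = sample_id, class = class,
                    control_subtype = control_subtype, age = age,
                    gender = rep_len(as.character(gender), n),
                    smoking = rep_len(as.logical(smoking), n),
                    wbc = rep_len(as.numeric(wbc), n),
                    platelets = rep_len(as.numeric(platelets), n),
                    hemoglobin = rep_len(as.numeric(hemoglobin), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Read or write a sample sheet TSV
#'
#' Columns: \code{sample_id}, \code{class}, \code{control_subtype},
#' \code{age}, \code{gender}, \code{smoking}, \code{wbc}, \code{platelets},
#' \code{hemoglobin}. Blank cells in the three blood-parameter columns
#' become explicit missing values.
#'
#' @param path file path.
#' @return \code{read_sample_sheet} returns a \code{\link{sample_sheet}}.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "class", "control_subtype",
                                 "age", "gender", "smoking", "wbc",
                                 "platelets", "hemoglobin"))
  smoking <- df$smoking
  smoking[!is.na(smoking)] <- as.character(
    parse_logical(smoking[!is.na(smoking)], "smoking"))
  sample_sheet(df$sample_id, df$class, df$control_subtype,
               parse_numeric(df$age, "age"),
               df$gender, as.logical(smoking),
               parse_numeric(df$wbc, "wbc", allow_na = TRUE),
               parse_numeric(df$platelets, "platelets", allow_na = TRUE),
               parse_numeric(df$hemoglobin, "hemoglobin", allow_na = TRUE))
}

#' @param sheet a \code{\link{sample_sheet}}.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "sample_sheet"))
  df <- as.data.frame(sheet)
  for (col in c("age", "wbc", "platelets", "hemoglobin"))
    df[[col]] <- ifelse(is.na(df[[col]]), NA, format_full(df[[col]]))
  write_tsv(df, path)
  invisible(path)
}

#' Binary class factor from a sample sheet
#'
#' @param sheet a \code{\link{sample_sheet}}.
#' @return factor with levels \code{c("control", "case")}.
#' @export
class_labels <- function(sheet) {
  factor(sheet$class, levels = c("control", "case"))
}
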