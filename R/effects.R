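#' FLASH effect for crypt regeneration
#'
#' The harmonized crypt-regeneration effect compares the percentage of
#' surviving (regenerating) crypts between the ultra-high-dose-rate and
#' conventional arms:
#' \deqn{Effect_{crypt} = \frac{P_{UHDR} - P_{CONV}}{100}}
#' Positive values mean UHDR spared more crypts than CONV (a FLASH
#' benefit), negative the opposite, 0 no effect.
#'
#' @param p_uhdr,p_conv Percentages of regenerating crypts in `[0, 100]`.
#' @return The continuous effect value in `[-1, 1]`.
#' @examples
#' effect_crypt(80, 30)  # 0.5
#' @export
effect_crypt <- function(p_uhdr, p_conv) {
  check_percent(p_uhdr, "p_uhdr")
  check_percent(p_conv, "p_conv")
  (p_uhdr - p_conv) / 100
}

#' FLASH effect for moist desquamation
#'
#' For skin toxicity, reaching moist desquamation is an adverse outcome,
#' so the sign is reversed relative to [effect_crypt()]:
#' \deqn{Effect_{M.d.} = \frac{P_{CONV} - P_{UHDR}}{100}}
#' Positive values mean fewer UHDR animals reached moist desquamation
#' than CONV animals (a FLASH benefit).
#'
#' @param p_uhdr,p_conv Percentages of animals reaching moist
#'   desquamation, in `[0, 100]`.
#' @return The continuous effect value in `[-1, 1]`.
#' @examples
#' effect_moist_desquamation(20, 70)  # 0.5
#' @export
effect_moist_desquamation <- function(p_uhdr, p_conv) {
  check_percent(p_uhdr, "p_uhdr")
  check_percent(p_conv, "p_conv")
  (p_conv - p_uhdr) / 100
}

check_percent <- function(p, name) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 100))
    stop(sprintf("%s must be a percentage in [0, 100]", name), call. = FALSE)
  invisible(p)
}

#' Convert an absolute crypt count to a percentage
#'
#' When studies report absolute numbers of regenerating crypts, the
#' percentage is taken against an assumed average of 140 crypts per
#' investigated area (the denominator is exposed because some assays use
#' a different baseline). Counts above the denominator yield percentages
#' above 100; they are allowed but flagged with a warning.
#'
#' @param count Non-negative integer crypt count.
#' @param denominator Baseline crypt count per area (default 140).
#' @return Percentage `100 * count / denominator`.
#' @examples
#' crypt_percent_from_count(70)  # 50
#' @export
crypt_percent_from_count <- function(count, denominator = 140) {
  if (!is.numeric(count) || any(count < 0))
    stop("count must be >= 0", call. = FALSE)
  if (!is.numeric(denominator) || length(denominator) != 1L || denominator <= 0)
    stop("denominator must be > 0", call. = FALSE)
  p <- 100 * count / denominator
  if (any(p > 100))
    warning(sprintf("%d count(s) exceed the denominator (%g); percentage > 100",
                    sum(p > 100), denominator), call. = FALSE)
  p
}

#' Survival percentage from per-animal status codes
#'
#' Status codes follow the database convention: 0 = alive, 1 = dead at
#' the given day. Note this is the reverse of the usual epidemiological
#' event coding; any other values are refused.
#'
#' @param status Vector of 0/1 codes, one per animal.
#' @param day Day of assessment; 11 and 20 are the canonical days.
#' @return Percentage of animals alive (status 0).
#' @examples
#' survival_percent(c(0, 1, 0, 1, 0))  # 60
#' @export
survival_percent <- function(status, day = 11) {
  if (!length(status)) stop("empty status vector", call. = FALSE)
  if (!is.numeric(status) || !all(status %in% c(0, 1)))
    stop("status codes must be 0 (alive) or 1 (dead)", call. = FALSE)
  100 * sum(status == 0) / length(status)
}

#' Discretize a continuous effect value
#'
#' Maps the continuous effect in `[-1, 1]` to the discrete coding
#' `{-1, 0, 1}`: 0 when `|effect| <= epsilon` (no effect), otherwise the
#' sign. The default `epsilon = 0` codes any non-zero difference as an
#' effect.
#'
#' @param continuous Continuous effect value(s), `|x| <= 1`.
#' @param epsilon Non-negative no-effect tolerance (default 0).
#' @return Integer vector in `{-1, 0, 1}`.
#' @export
discretize_effect <- function(continuous, epsilon = 0) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("epsilon must be >= 0", call. = FALSE)
  if (any(abs(continuous) > 1 + 1e-12))
    stop("continuous effect must lie in [-1, 1]", call. = FALSE)
  as.integer(ifelse(abs(continuous) <= epsilon, 0L, sign(continuous)))
}

#' Toxicity scale map
#'
#' Studies grade skin toxicity on heterogeneous scales. A scale map
#' assigns every grade label a study uses to one of three harmonized
#' bands: `"light"`, `"moist_desquamation"`, `"severe"`.
#'
#' @param study_id Study identifier.
#' @param grade_labels Character vector of the study's grade labels.
#' @param bands Character vector of target bands, same length, each one
#'   of `"light"`, `"moist_desquamation"`, `"severe"`.
#' @return An object of class `toxicity_scale_map`.
#' @examples
#' toxicity_scale_map("s1", c("G1", "G2", "G3"),
#'                    c("light", "moist_desquamation", "severe"))
#' @export
toxicity_scale_map <- function(study_id, grade_labels, bands) {
  if (length(grade_labels) != length(bands))
    stop("grade_labels and bands must have equal length", call. = FALSE)
  if (anyDuplicated(grade_labels))
    stop("duplicated grade labels in scale map", call. = FALSE)
  bad <- setdiff(unique(bands), toxicity_bands())
  if (length(bad))
    stop(sprintf("unknown band(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(toxicity_bands(), collapse = ", ")), call. = FALSE)
  structure(list(study_id = as.character(study_id),
                 mapping = stats::setNames(as.character(bands),
                                           as.character(grade_labels))),
            class = "toxicity_scale_map")
}

#' The three harmonized toxicity bands, in severity order
#' @return `c("light", "moist_desquamation", "severe")`.
#' @export
toxicity_bands <- function() c("light", "moist_desquamation", "severe")

#' Harmonize per-animal toxicity grades into the three bands
#'
#' @param grades Character vector of per-animal worst (maximum) grade
#'   labels over the observation period.
#' @param scale_map A [toxicity_scale_map()] covering every label.
#' @return Character vector of bands, same length and order as `grades`.
#' @export
harmonize_grades <- function(grades, scale_map) {
  stopifnot(inherits(scale_map, "toxicity_scale_map"))
  if (!length(grades)) return(character(0))
  grades <- as.character(grades)
  missing <- setdiff(unique(grades), names(scale_map$mapping))
  if (length(missing))
    stop(sprintf("unmapped grade label(s) %s for study %s",
                 paste(missing, collapse = ", "), scale_map$study_id),
         call. = FALSE)
  unname(scale_map$mapping[grades])
}

#' Read toxicity scale maps from CSV
#'
#' The file needs columns `study_id`, `grade_label`, `band` (bands from
#' [toxicity_bands()]); one [toxicity_scale_map()] is built per study.
#'
#' @param path CSV file path.
#' @return Named list of [toxicity_scale_map()] objects, keyed by study id.
#' @examples
#' path <- system.file("extdata", "example_scale_maps.csv",
#'                     package = "flashdose")
#' read_scale_maps(path)
#' @export
read_scale_maps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "grade_label", "band")
  if (!all(need %in% names(df)))
    stop("scale-map file needs columns study_id, grade_label, band",
         call. = FALSE)
  maps <- lapply(split(df, df$study_id), function(d)
    toxicity_scale_map(d$study_id[1], d$grade_label, d$band))
  maps[unique(df$study_id)]
}

#' Percentage of animals reaching moist desquamation
#'
#' An animal has reached moist desquamation if its harmonized band is
#' `"moist_desquamation"` or worse: the severity ordering
#' light < moist_desquamation < severe means animals that progressed to
#' severe toxicity necessarily passed through (reached) moist
#' desquamation. Set `include_severe = FALSE` to count the
#' moist-desquamation band alone.
#'
#' @param bands Character vector of per-animal bands from
#'   [harmonize_grades()].
#' @param include_severe Count the severe band as having reached moist
#'   desquamation (default `TRUE`).
#' @return Percentage in `[0, 100]`.
#' @examples
#' percent_reaching_moist_desquamation(
#'   c("moist_desquamation", "severe", "light", "light"))  # 50
#' @export
percent_reaching_moist_desquamation <- function(bands, include_severe = TRUE) {
  if (!length(bands)) stop("empty band vector", call. = FALSE)
  bad <- setdiff(unique(bands), toxicity_bands())
  if (length(bad))
    stop(sprintf("unknown band(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  reached <- bands == "moist_desquamation"
  if (include_severe) reached <- reached | bands == "severe"
  100 * sum(reached) / length(bands)
}
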