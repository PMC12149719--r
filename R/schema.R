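#' Study-record schema
#'
#' The schema of one database entry: every collected parameter with its
#' attribute group, value type (`text`, `number`, `select`,
#' `multi_select`), whether it is mandatory, and numeric bounds where a
#' physical or inclusion constraint applies (publication year within the
#' review window 1966--2024; doses, dose rates, field sizes, sample
#' sizes, beam and pulse parameters non-negative). Machine and
#' dosimetric numeric parameters may additionally appear as paired
#' arm-specific columns with a `_conv` / `_uhdr` suffix when the two
#' arms differ.
#'
#' @return A data frame with columns `field`, `group`, `type`,
#'   `required`, `min`, `max`, `arm_specific`.
#' @export
study_schema <- function() {
  f <- function(field, group, type, required = FALSE,
                min = NA_real_, max = NA_real_, arm_specific = FALSE)
    data.frame(field = field, group = group, type = type,
               required = required, min = min, max = max,
               arm_specific = arm_specific)
  rbind(
    f("title", "general", "text", required = TRUE),
    f("year", "general", "number", required = TRUE, min = 1966, max = 2024),
    f("doi", "general", "text", required = TRUE),
    f("citation", "general", "text"),
    f("abstract", "general", "text"),
    f("authors", "general", "text"),
    f("institute", "general", "multi_select"),
    f("sample_size", "biological_model", "number", min = 0),
    f("strain", "biological_model", "multi_select"),
    f("age_weeks", "biological_model", "number", min = 0),
    f("sex", "biological_model", "multi_select"),
    f("bio_notes", "biological_model", "text"),
    f("anaesthesia", "biological_model", "multi_select"),
    f("oxygen_level", "biological_model", "multi_select"),
    f("depilation", "biological_model", "multi_select"),
    f("tumor_type", "biological_model", "multi_select"),
    f("tissue", "endpoint", "multi_select"),
    f("endpoints", "endpoint", "multi_select"),
    f("assessment", "endpoint", "text"),
    f("flash_effect_definition", "endpoint", "text"),
    f("euthanasia", "endpoint", "text"),
    f("particle", "machine", "select", required = TRUE),
    f("beam_energy_MeV", "machine", "number", min = 0, arm_specific = TRUE),
    f("beam_current_nA", "machine", "number", min = 0, arm_specific = TRUE),
    f("micro_pulse_width_us", "machine", "number", min = 0, arm_specific = TRUE),
    f("micro_pulse_freq_Hz", "machine", "number", min = 0, arm_specific = TRUE),
    f("macro_pulse_width_us", "machine", "number", min = 0, arm_specific = TRUE),
    f("macro_pulse_freq_Hz", "machine", "number", min = 0, arm_specific = TRUE),
    f("dose_per_pulse_Gy", "machine", "number", min = 0, arm_specific = TRUE),
    f("machine", "machine", "multi_select"),
    f("dose_Gy", "dosimetric", "number", min = 0, arm_specific = TRUE),
    f("avg_dose_rate_Gy_s", "dosimetric", "number", min = 0, arm_specific = TRUE),
    f("pbs_or_instant_dose_rate_Gy_s", "dosimetric", "number", min = 0,
      arm_specific = TRUE),
    f("field_size_cm2", "dosimetric", "number", min = 0),
    f("irradiation_type", "dosimetric", "multi_select"),
    f("setup", "dosimetric", "text")
  )
}

#' Default controlled vocabularies for select / multi-select fields
#'
#' The particle vocabulary is fixed by the inclusion criteria; the other
#' vocabularies are open-ended in real use and can be extended (or
#' replaced from a YAML/CSV config) — unknown values are reported by the
#' validator, never silently accepted.
#'
#' @return Named list mapping field name to allowed character values.
#' @export
default_vocabularies <- function() {
  list(
    particle = c("proton", "electron", "x-ray", "heavy ion"),
    sex = c("female", "male", "mixed"),
    strain = c("C57BL/6", "BALB/c", "C3H", "CDF1", "nude", "Sprague-Dawley",
               "Wistar", "FVB", "other"),
    institute = c("PSI", "CHUV", "Stanford", "Dresden", "Lund", "Curie",
                  "MGH", "MDACC", "other"),
    anaesthesia = c("isoflurane", "ketamine/xylazine", "pentobarbital",
                    "none", "other"),
    oxygen_level = c("normoxic", "hypoxic", "hyperoxic", "carbogen",
                     "unreported"),
    depilation = c("shaving", "cream", "none", "unreported"),
    tumor_type = c("none", "glioblastoma", "lung carcinoma", "sarcoma",
                   "melanoma", "pancreatic", "other"),
    tissue = c("abdomen", "skin", "brain", "lung", "whole body", "leg",
               "foot", "flank", "other"),
    endpoints = c("survival", "crypt regeneration", "skin toxicity",
                  "cognition", "fibrosis", "tumor control", "other"),
    machine = c("Gantry 1", "eRT6 Oriatron", "linac", "synchrotron",
                "cyclotron", "other"),
    irradiation_type = c("pencil beam scanning", "passive scattering",
                         "broad beam", "narrow beam", "transmission")
  )
}

#' Construct a study record
#'
#' Builds one database entry. Fields not supplied are `NA` (empty).
#' Multi-select fields take character vectors. Arm-specific numeric
#' fields may be given with a `_conv` or `_uhdr` suffix
#' (e.g. `dose_Gy_uhdr = 15`). The constructor does not validate:
#' use [validate_record()], which reports violations as data.
#'
#' @param ... Named field values; names must be schema fields or
#'   arm-suffixed variants of arm-specific fields.
#' @return An object of class `study_record` (a named list).
#' @examples
#' rec <- study_record(title = "UHDR abdominal irradiation", year = 2021,
#'                     doi = "10.1000/demo", particle = "proton",
#'                     dose_Gy = 15, tissue = "abdomen")
#' validate_record(rec)
#' @export
study_record <- function(...) {
  vals <- list(...)
  sch <- study_schema()
  allowed <- schema_field_names(sch)
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop(sprintf("unknown field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  rec <- stats::setNames(vector("list", length(sch$field)), sch$field)
  rec[names(vals)] <- vals
  structure(rec, class = "study_record")
}

schema_field_names <- function(sch = study_schema()) {
  c(sch$field,
    paste0(rep(sch$field[sch$arm_specific], each = 2), c("_conv", "_uhdr")))
}

# schema row (as list) governing a possibly arm-suffixed field name
schema_rule_for <- function(name, sch = study_schema()) {
  base <- sub("_(conv|uhdr)$", "", name)
  i <- match(base, sch$field)
  if (is.na(i)) return(NULL)
  if (base != name && !sch$arm_specific[i]) return(NULL)
  as.list(sch[i, ])
}

#' @export
print.study_record <- function(x, ...) {
  filled <- names(x)[!vapply(x, function(v) is.null(v) || all(is.na(v)), TRUE)]
  cat(sprintf("<study_record> %d/%d fields populated\n",
              length(filled), length(x)))
  for (f in utils::head(filled, 10L))
    cat(sprintf("  %-28s %s\n", f, paste(x[[f]], collapse = "; ")))
  if (length(filled) > 10L)
    cat(sprintf("  ... %d more fields\n", length(filled) - 10L))
  invisible(x)
}

#' Validate a study record against the schema and vocabularies
#'
#' Violations are returned as data, not raised as errors: a record is
#' valid exactly when the returned data frame has zero rows. Checks:
#' mandatory fields present; numeric fields numeric and within bounds
#' (year inside the 1966--2024 inclusion window, physical quantities
#' non-negative); select fields single-valued; select/multi-select
#' values drawn from the vocabulary.
#'
#' @param record A [study_record()] (or named list shaped like one).
#' @param vocabularies Named list of allowed values; default
#'   [default_vocabularies()].
#' @return A data frame with columns `field` and `violation`.
#' @export
validate_record <- function(record, vocabularies = default_vocabularies()) {
  sch <- study_schema()
  viol <- list()
  add <- function(field, msg)
    viol[[length(viol) + 1L]] <<- data.frame(field = field, violation = msg)

  present <- function(v) !is.null(v) && length(v) > 0 && !all(is.na(v))
  for (i in seq_len(nrow(sch)))
    if (sch$required[i] && !present(record[[sch$field[i]]]))
      add(sch$field[i], "mandatory field missing")

  for (name in names(record)) {
    v <- record[[name]]
    if (!present(v)) next
    rule <- schema_rule_for(name, sch)
    if (is.null(rule)) { add(name, "unknown field"); next }
    if (rule$type == "number") {
      if (!is.numeric(v) || length(v) != 1L) {
        add(name, "expected a single number"); next
      }
      if (!is.na(rule$min) && v < rule$min)
        add(name, sprintf("value %g below minimum %g%s", v, rule$min,
                          if (rule$field == "year") " (inclusion window)" else ""))
      if (!is.na(rule$max) && v > rule$max)
        add(name, sprintf("value %g above maximum %g%s", v, rule$max,
                          if (rule$field == "year") " (inclusion window)" else ""))
    } else if (rule$type %in% c("select", "multi_select")) {
      if (rule$type == "select" && length(v) != 1L)
        add(name, "select field must hold exactly one value")
      vocab <- vocabularies[[rule$field]]
      if (!is.null(vocab)) {
        bad <- setdiff(as.character(v), vocab)
        if (length(bad))
          add(name, sprintf("value(s) not in vocabulary: %s",
                            paste(bad, collapse = ", ")))
      }
    } else {
      if (!is.character(v) && !is.numeric(v))
        add(name, "expected text")
    }
  }
  if (!length(viol))
    return(data.frame(field = character(0), violation = character(0)))
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}

# multi-select serialization: values joined by "; " in one CSV cell
MS_SEP <- "; "

#' Read and write study tables
#'
#' Study tables are UTF-8 CSV files with one row per record and one
#' column per schema field (arm-suffixed columns allowed). Multi-select
#' cells hold `"; "`-separated values; missing values are empty cells
#' (never 0 or -1). `read_study_table()` refuses malformed headers and
#' duplicated DOIs. Writing then reading a table reproduces the records
#' exactly.
#'
#' @param path CSV file path.
#' @param records A list of [study_record()] objects (for writing).
#' @return `read_study_table()`: a list of `study_record` objects, in
#'   file order. `write_study_table()`: `path`, invisibly.
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  sch <- study_schema()
  allowed <- schema_field_names(sch)
  bad <- setdiff(names(df), allowed)
  if (length(bad))
    stop(sprintf("malformed header: unknown column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!all(c("title", "year", "doi") %in% names(df)))
    stop("malformed header: title, year and doi columns are required",
         call. = FALSE)
  if (nrow(df) > 0 && anyDuplicated(df$doi[df$doi != ""]))
    stop("duplicated DOI in study table", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    vals <- list()
    for (name in names(df)) {
      cell <- df[[name]][i]
      if (is.na(cell) || cell == "") next
      rule <- schema_rule_for(name, sch)
      vals[[name]] <-
        if (rule$type == "number") as.numeric(cell)
        else if (rule$type == "multi_select") strsplit(cell, MS_SEP, fixed = TRUE)[[1]]
        else cell
    }
    do.call(study_record, vals)
  })
}

#' @rdname read_study_table
#' @export
write_study_table <- function(records, path) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, TRUE, "study_record")))
  cols <- unique(unlist(lapply(records, function(r)
    names(r)[!vapply(r, function(v) is.null(v) || all(is.na(v)), TRUE)])))
  cols <- union(c("title", "year", "doi"), cols)
  cols <- cols[order(match(sub("_(conv|uhdr)$", "", cols),
                           study_schema()$field))]
  cells <- vapply(records, function(r) vapply(cols, function(cn) {
    v <- r[[cn]]
    if (is.null(v) || all(is.na(v))) "" else if (is.numeric(v))
      paste(vapply(v, format, "", trim = TRUE, scientific = FALSE,
                   digits = 15), collapse = MS_SEP)
    else paste(as.character(v), collapse = MS_SEP)
  }, ""), character(length(cols)))
  df <- as.data.frame(t(matrix(cells, nrow = length(cols))),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
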