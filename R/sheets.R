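#' Build the spreadsheet-style effect sheets from arm-level observations
#'
#' Converts a table of per-arm endpoint observations into the named
#' effect sheets used for cross-study statistical analysis. Observations
#' are paired per study (and, for survival, per day) across the UHDR and
#' CONV arms; pairs missing one arm, survival rows at non-canonical days
#' (only days 11 and 20 are kept), and rows whose percentage cannot be
#' resolved are emitted to an exclusion log rather than failing.
#'
#' The observation table needs columns `study_id`, `arm`
#' (`"UHDR"`/`"CONV"`), `endpoint` (`"crypt"`, `"survival"`,
#' `"moist_desquamation"`), `day` (for survival), and one of:
#' `percent`; `count` (crypt, converted via
#' [crypt_percent_from_count()]); a `status` list-column of per-animal
#' 0/1 codes (survival, via [survival_percent()]); or a `grades`
#' list-column of per-animal grade labels (moist desquamation, via
#' [harmonize_grades()] and the study's scale map).
#'
#' @param observations Data frame of arm-level observations (above).
#' @param scale_maps Named list of [toxicity_scale_map()] objects keyed
#'   by `study_id`, needed only for `grades` input.
#' @param epsilon No-effect tolerance for the discrete `01` sheets.
#' @param crypt_denominator Baseline crypt count for count conversion.
#' @return An object of class `effect_sheet_set`: a list with `sheets`
#'   (named data frames: `gut_crypt`, `gut_crypt_effect`,
#'   `gut_survival_percent`, `gut_survival_01`, `gut_effect_percent`,
#'   `gut_effect01`, `Max_Moist_desquamation_percent`,
#'   `Max_Moist_desquamation_effect_percent`,
#'   `Max_Moist_desquamation_effect01`) and `exclusions` (data frame
#'   `study_id`, `endpoint`, `day`, `reason`).
#' @export
build_effect_sheets <- function(observations, scale_maps = list(),
                                epsilon = 0, crypt_denominator = 140) {
  need <- c("study_id", "arm", "endpoint")
  if (!all(need %in% names(observations)))
    stop("observations must have columns study_id, arm, endpoint",
         call. = FALSE)
  obs <- as.data.frame(observations)
  if (!"day" %in% names(obs)) obs$day <- NA_real_
  if (!"percent" %in% names(obs)) obs$percent <- NA_real_
  excl <- list()
  note <- function(study, endpoint, day, reason)
    excl[[length(excl) + 1L]] <<- data.frame(
      study_id = study, endpoint = endpoint, day = day, reason = reason)

  # resolve a percentage for every row
  obs$p <- NA_real_
  for (i in seq_len(nrow(obs))) {
    p <- obs$percent[i]
    if (is.na(p)) p <- resolve_percent(obs, i, scale_maps, crypt_denominator)
    if (is.na(p))
      note(obs$study_id[i], obs$endpoint[i], obs$day[i],
           sprintf("no percentage resolvable for arm %s", obs$arm[i]))
    obs$p[i] <- p
  }

  pair <- function(sub) {
    key <- interaction(sub$study_id, ifelse(is.na(sub$day), -1, sub$day),
                       drop = TRUE)
    out <- list()
    for (k in levels(key)) {
      rows <- sub[key == k, ]
      u <- rows$p[rows$arm == "UHDR"]
      c_ <- rows$p[rows$arm == "CONV"]
      if (length(u) != 1L || length(c_) != 1L || is.na(u) || is.na(c_)) {
        note(rows$study_id[1], rows$endpoint[1], rows$day[1],
             "arm pairing incomplete (need one UHDR and one CONV arm)")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        study_id = rows$study_id[1], day = rows$day[1],
        p_uhdr = u, p_conv = c_)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(study_id = character(0), day = numeric(0),
                 p_uhdr = numeric(0), p_conv = numeric(0))
  }

  crypt <- obs[obs$endpoint == "crypt", ]
  surv <- obs[obs$endpoint == "survival", ]
  bad_day <- !is.na(surv$day) & !surv$day %in% c(11, 20)
  for (i in which(bad_day))
    note(surv$study_id[i], "survival", surv$day[i],
         "survival day restricted to 11 and 20")
  surv <- surv[!bad_day & !is.na(surv$day), ]
  skin <- obs[obs$endpoint == "moist_desquamation", ]

  crypt_pairs <- pair(crypt)
  surv_pairs <- pair(surv)
  skin_pairs <- pair(skin)

  crypt_eff <- effect_crypt_pairs(crypt_pairs)
  surv_eff <- effect_crypt_pairs(surv_pairs)  # survival uses the Eq.-1 sign
  skin_eff <- within(skin_pairs, effect <- (p_conv - p_uhdr) / 100)

  sheets <- list(
    gut_crypt = crypt_pairs[c("study_id", "p_uhdr", "p_conv")],
    gut_crypt_effect = data.frame(study_id = crypt_eff$study_id,
                                  effect = crypt_eff$effect),
    gut_survival_percent = surv_pairs[c("study_id", "day", "p_uhdr", "p_conv")],
    gut_survival_01 = survival_01_sheet(surv),
    gut_effect_percent = data.frame(study_id = surv_eff$study_id,
                                    day = surv_eff$day,
                                    effect = surv_eff$effect),
    gut_effect01 = data.frame(study_id = surv_eff$study_id,
                              day = surv_eff$day,
                              effect = discretize_effect(surv_eff$effect,
                                                         epsilon)),
    Max_Moist_desquamation_percent =
      skin_pairs[c("study_id", "p_uhdr", "p_conv")],
    Max_Moist_desquamation_effect_percent =
      data.frame(study_id = skin_eff$study_id, effect = skin_eff$effect),
    Max_Moist_desquamation_effect01 =
      data.frame(study_id = skin_eff$study_id,
                 effect = discretize_effect(skin_eff$effect, epsilon))
  )
  exclusions <- if (length(excl)) {
    e <- do.call(rbind, excl); rownames(e) <- NULL; e
  } else data.frame(study_id = character(0), endpoint = character(0),
                    day = numeric(0), reason = character(0))
  structure(list(sheets = sheets, exclusions = exclusions),
            class = "effect_sheet_set")
}

resolve_percent <- function(obs, i, scale_maps, crypt_denominator) {
  ep <- obs$endpoint[i]
  if (ep == "crypt" && "count" %in% names(obs) && !is.na(obs$count[i]))
    return(suppressWarnings(
      crypt_percent_from_count(obs$count[i], crypt_denominator)))
  if (ep == "survival" && "status" %in% names(obs) &&
      !is.null(obs$status[[i]]) && length(obs$status[[i]]))
    return(survival_percent(obs$status[[i]], obs$day[i]))
  if (ep == "moist_desquamation" && "grades" %in% names(obs) &&
      !is.null(obs$grades[[i]]) && length(obs$grades[[i]])) {
    sm <- scale_maps[[as.character(obs$study_id[i])]]
    if (is.null(sm)) return(NA_real_)
    return(percent_reaching_moist_desquamation(
      harmonize_grades(obs$grades[[i]], sm)))
  }
  NA_real_
}

effect_crypt_pairs <- function(pairs) {
  pairs$effect <- if (nrow(pairs)) (pairs$p_uhdr - pairs$p_conv) / 100
                  else numeric(0)
  pairs
}

# per-animal alive(0)/dead(1) rows; empty unless status columns were given
survival_01_sheet <- function(surv) {
  if (!"status" %in% names(surv))
    return(data.frame(study_id = character(0), arm = character(0),
                      day = numeric(0), animal = integer(0),
                      status = integer(0)))
  rows <- list()
  for (i in seq_len(nrow(surv))) {
    st <- surv$status[[i]]
    if (is.null(st) || !length(st)) next
    rows[[length(rows) + 1L]] <- data.frame(
      study_id = surv$study_id[i], arm = surv$arm[i], day = surv$day[i],
      animal = seq_along(st), status = as.integer(st))
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(study_id = character(0), arm = character(0),
               day = numeric(0), animal = integer(0), status = integer(0))
}

#' @export
print.effect_sheet_set <- function(x, ...) {
  cat("<effect_sheet_set>\n")
  for (nm in names(x$sheets))
    cat(sprintf("  %-38s %d row(s)\n", nm, nrow(x$sheets[[nm]])))
  cat(sprintf("  exclusion log: %d entr%s\n", nrow(x$exclusions),
              if (nrow(x$exclusions) == 1) "y" else "ies"))
  invisible(x)
}

#' Write an effect sheet set as per-sheet CSV files
#'
#' One CSV per sheet, named after the sheet, plus `exclusions.log`
#' (plain text) when any pair was excluded.
#'
#' @param set An [build_effect_sheets()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_effect_sheets <- function(set, dir) {
  stopifnot(inherits(set, "effect_sheet_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(set$sheets))
    utils::write.csv(set$sheets[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  if (nrow(set$exclusions))
    writeLines(sprintf("%s | %s | day %s | %s",
                       set$exclusions$study_id, set$exclusions$endpoint,
                       set$exclusions$day, set$exclusions$reason),
               file.path(dir, "exclusions.log"))
  invisible(dir)
}
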