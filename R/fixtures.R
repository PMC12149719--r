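#' Generate a synthetic study-outcome table with known ground truth
#'
#' Emulates the arm-level outcome tables the effect sheets are built
#' from, with a known true effect size so pipeline recovery can be
#' tested. Per study and endpoint the CONV-arm percentage is drawn
#' uniformly from a range chosen to keep both arms away from the 0/100
#' truncation bounds at moderate effect sizes (crypt and survival:
#' U\[20, 55\]; moist desquamation: U\[45, 80\]); the UHDR arm is then
#' shifted by the effect size in the beneficial direction for that
#' endpoint (higher crypt regeneration and survival, lower moist
#' desquamation) plus Gaussian noise, and truncated to \[0, 100\].
#'
#' @param seed Integer RNG seed; the output is a deterministic function
#'   of it.
#' @param n_studies Number of studies (`>= 1`).
#' @param effect_size True effect on the continuous effect scale
#'   (fraction, e.g. 0.3 = 30 percentage points between arms).
#' @param noise Standard deviation of the arm-difference noise, on the
#'   same scale (0.05 = 5 percentage points).
#' @param endpoints Endpoints to generate, subset of
#'   `c("crypt", "survival", "moist_desquamation")`. Survival rows are
#'   generated for both canonical days (11 and 20).
#' @return A list with `observations` (arm-level table as accepted by
#'   [build_effect_sheets()]) and `truth` (data frame with one row per
#'   study/endpoint/day holding the realized true continuous effect).
#' @examples
#' fx <- generate_fixture_studies(seed = 1, n_studies = 5)
#' head(fx$observations)
#' @export
generate_fixture_studies <- function(seed, n_studies,
                                     effect_size = 0.3, noise = 0.05,
                                     endpoints = c("crypt", "survival",
                                                   "moist_desquamation")) {
  stopifnot(n_studies >= 1)
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  obs <- list(); truth <- list()
  ids <- sprintf("study_%03d", seq_len(n_studies))
  for (ep in endpoints) {
    days <- if (ep == "survival") c(11, 20) else NA_real_
    for (day in days) {
      p_conv <- if (ep == "moist_desquamation") stats::runif(n_studies, 45, 80)
                else stats::runif(n_studies, 20, 55)
      shift <- 100 * effect_size * (if (ep == "moist_desquamation") -1 else 1)
      p_uhdr <- p_conv + shift + stats::rnorm(n_studies, 0, 100 * noise)
      p_uhdr <- pmin(pmax(p_uhdr, 0), 100)
      obs[[length(obs) + 1L]] <- data.frame(
        study_id = rep(ids, 2L),
        arm = rep(c("UHDR", "CONV"), each = n_studies),
        endpoint = ep, day = day,
        percent = c(p_uhdr, p_conv))
      eff <- if (ep == "moist_desquamation") (p_conv - p_uhdr) / 100
             else (p_uhdr - p_conv) / 100
      truth[[length(truth) + 1L]] <- data.frame(
        study_id = ids, endpoint = ep, day = day, true_effect = eff)
    }
  }
  list(observations = do.call(rbind, obs), truth = do.call(rbind, truth),
       effect_size = effect_size, noise = noise, seed = seed)
}

#' Generate synthetic PBS spot maps and a timing model
#'
#' Produces random rectangular spot plans (grid maps with weights drawn
#' uniformly from `w_range`) and a fixed timing model, optionally
#' written to `dir` as spot-table CSVs plus a one-row `timing.csv`.
#' Deterministic for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param n_maps Number of spot maps.
#' @param n_x,n_y Grid dimensions.
#' @param pitch Spot pitch in both directions (mm).
#' @param w_range Range of per-spot weights (Gy).
#' @param timing A [timing_model()] to pair with the maps.
#' @param dir Optional output directory for the files.
#' @return A list with `maps` (list of [spot_map()]), `timing`, and
#'   `paths` (written file paths, if `dir` was given).
#' @export
generate_fixture_spotmaps <- function(seed, n_maps = 20, n_x = 5, n_y = 5,
                                      pitch = 5, w_range = c(0.5, 2),
                                      timing = timing_model(
                                        t_spot_fixed = 1, t_spot_per_gy = 10,
                                        tau_x = 2, tau_y = 10),
                                      dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  maps <- lapply(seq_len(n_maps), function(i) {
    m <- generate_spot_map(n_x, n_y, pitch, pitch, w_center = 1)
    m$weight <- stats::runif(nrow(m), w_range[1], w_range[2])
    m
  })
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(seq_along(maps), function(i) {
      p <- file.path(dir, sprintf("spotmap_%03d.csv", i))
      write_spot_table(maps[[i]], p)
      p
    }, "")
    tp <- file.path(dir, "timing.csv")
    utils::write.csv(as.data.frame(unclass(timing)), tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  list(maps = maps, timing = timing, paths = paths)
}

#' Generate fully populated, schema-valid study records
#'
#' Synthetic records exercising every schema group, built to satisfy
#' [validate_record()] with the default vocabularies.
#'
#' @param seed Integer RNG seed.
#' @param n Number of records.
#' @return A list of [study_record()] objects.
#' @export
generate_fixture_records <- function(seed, n = 10) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  voc <- default_vocabularies()
  pick <- function(field, k = 1) sample(voc[[field]], k)
  lapply(seq_len(n), function(i) {
    study_record(
      title = sprintf("Synthetic UHDR study %03d", i),
      year = sample(1966:2024, 1),
      doi = sprintf("10.9999/synthetic.%04d", i),
      authors = sprintf("Author %d A; Author %d B", i, i),
      institute = pick("institute"),
      sample_size = sample(6:40, 1),
      strain = pick("strain"),
      age_weeks = round(stats::runif(1, 6, 12), 1),
      sex = pick("sex"),
      anaesthesia = pick("anaesthesia"),
      oxygen_level = pick("oxygen_level"),
      depilation = pick("depilation"),
      tumor_type = pick("tumor_type"),
      tissue = pick("tissue"),
      endpoints = pick("endpoints", 2),
      assessment = "synthetic endpoint assessment",
      flash_effect_definition = "normal-tissue sparing at iso-effect",
      euthanasia = "humane endpoint per institutional guideline",
      particle = pick("particle"),
      beam_energy_MeV = round(stats::runif(1, 4, 250), 1),
      beam_current_nA = round(stats::runif(1, 1, 500), 1),
      dose_per_pulse_Gy = round(stats::runif(1, 0.1, 10), 2),
      machine = pick("machine"),
      dose_Gy = round(stats::runif(1, 5, 40), 1),
      avg_dose_rate_Gy_s_uhdr = round(stats::runif(1, 40, 300), 1),
      avg_dose_rate_Gy_s_conv = round(stats::runif(1, 0.01, 0.3), 3),
      field_size_cm2 = round(stats::runif(1, 0.5, 4), 2),
      irradiation_type = pick("irradiation_type"),
      setup = "synthetic setup description")
  })
}

# save/restore the global RNG state so fixture generators are pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
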