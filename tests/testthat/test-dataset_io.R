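test_that("the schema covers every collected parameter group exactly once", {
  sch <- study_schema()
  expect_false(anyDuplicated(sch$field) > 0)
  expect_setequal(unique(sch$group),
                  c("general", "biological_model", "endpoint", "machine",
                    "dosimetric"))
  # the attribute groups hold their parameters
  expect_true(all(c("title", "year", "doi", "authors", "institute") %in%
                    sch$field[sch$group == "general"]))
  expect_true(all(c("sample_size", "strain", "age_weeks", "sex",
                    "anaesthesia", "oxygen_level", "depilation",
                    "tumor_type") %in%
                    sch$field[sch$group == "biological_model"]))
  expect_true(all(c("tissue", "endpoints", "assessment",
                    "flash_effect_definition", "euthanasia") %in%
                    sch$field[sch$group == "endpoint"]))
  expect_true(all(c("particle", "beam_energy_MeV", "beam_current_nA",
                    "micro_pulse_width_us", "micro_pulse_freq_Hz",
                    "macro_pulse_width_us", "macro_pulse_freq_Hz",
                    "dose_per_pulse_Gy", "machine") %in%
                    sch$field[sch$group == "machine"]))
  expect_true(all(c("dose_Gy", "avg_dose_rate_Gy_s",
                    "pbs_or_instant_dose_rate_Gy_s", "field_size_cm2",
                    "irradiation_type", "setup") %in%
                    sch$field[sch$group == "dosimetric"]))
  expect_setequal(default_vocabularies()$particle,
                  c("proton", "electron", "x-ray", "heavy ion"))
})

test_that("validation reports inclusion-window, range, vocabulary and type violations", {
  base <- list(title = "t", year = 2020, doi = "10.1/x", particle = "proton")
  ok <- do.call(study_record, base)
  expect_equal(nrow(validate_record(ok)), 0L)

  late <- do.call(study_record, modifyList(base, list(year = 2025)))
  v <- validate_record(late)
  expect_true(any(grepl("inclusion window", v$violation)))

  neg <- do.call(study_record, modifyList(base, list(dose_Gy = -1)))
  expect_true(any(grepl("below minimum", validate_record(neg)$violation)))

  oov <- do.call(study_record, modifyList(base, list(particle = "neutron")))
  expect_true(any(grepl("not in vocabulary", validate_record(oov)$violation)))

  multi <- do.call(study_record,
                   modifyList(base, list(particle = c("proton", "electron"))))
  expect_true(any(grepl("exactly one value", validate_record(multi)$violation)))

  incomplete <- study_record(title = "t")
  v2 <- validate_record(incomplete)
  expect_setequal(v2$field[v2$violation == "mandatory field missing"],
                  c("year", "doi", "particle"))

  txt <- do.call(study_record,
                 modifyList(base, list(sample_size = "twenty")))
  expect_true(any(grepl("single number", validate_record(txt)$violation)))

  # arm-specific suffixed fields validate against the base rule
  arm <- do.call(study_record,
                 modifyList(base, list(dose_Gy_uhdr = -5)))
  v3 <- validate_record(arm)
  expect_true(any(v3$field == "dose_Gy_uhdr" &
                    grepl("below minimum", v3$violation)))
  expect_error(study_record(bogus_field = 1), "unknown field")
})

test_that("fixture records are schema-valid and study tables round-trip", {
  recs <- generate_fixture_records(seed = 4, n = 10)
  expect_length(recs, 10L)
  for (r in recs) expect_equal(nrow(validate_record(r)), 0L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(recs, path)
  back <- read_study_table(path)
  expect_length(back, 10L)
  # order-preserving, field-for-field identity on populated fields
  for (i in seq_along(recs)) {
    filled <- names(recs[[i]])[!vapply(recs[[i]], function(v)
      is.null(v) || all(is.na(v)), TRUE)]
    for (f in filled) expect_equal(back[[i]][[f]], recs[[i]][[f]])
  }
  # write(read(x)) is byte-identical to the first write
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_study_table(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("malformed headers, duplicate DOIs and empty tables are handled", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("title,year,doi", p)
  expect_length(read_study_table(p), 0L)
  writeLines(c("title,year,doi,flux_capacitor", "a,2000,10.1/x,1"), p)
  expect_error(read_study_table(p), "malformed header")
  writeLines(c("title,year", "a,2000"), p)
  expect_error(read_study_table(p), "doi")
  writeLines(c("title,year,doi", "a,2000,10.1/x", "b,2001,10.1/x"), p)
  expect_error(read_study_table(p), "duplicated DOI")
})

test_that("effect sheets apply the endpoint formulas and log exclusions", {
  obs <- data.frame(
    study_id = c("s1", "s1", "s2", "s2", "s3"),
    arm = c("UHDR", "CONV", "UHDR", "CONV", "CONV"),
    endpoint = c("crypt", "crypt", "moist_desquamation",
                 "moist_desquamation", "crypt"),
    day = NA_real_,
    percent = c(80, 30, 20, 70, 40))
  set <- build_effect_sheets(obs)
  expect_equal(nrow(set$sheets$gut_crypt), 1L)
  expect_equal(set$sheets$gut_crypt_effect$effect, 0.5)
  expect_equal(set$sheets$Max_Moist_desquamation_effect_percent$effect, 0.5)
  expect_identical(set$sheets$Max_Moist_desquamation_effect01$effect, 1L)
  # the CONV-only study is excluded, not fatal
  expect_equal(nrow(set$exclusions), 1L)
  expect_match(set$exclusions$reason, "pairing incomplete")
  expect_equal(set$exclusions$study_id, "s3")
})

test_that("survival sheets restrict days to 11 and 20 and code per-animal rows", {
  obs <- data.frame(
    study_id = rep("s1", 6),
    arm = rep(c("UHDR", "CONV"), 3),
    endpoint = "survival",
    day = c(11, 11, 20, 20, 15, 15),
    percent = c(80, 60, 70, 40, 50, 50))
  set <- build_effect_sheets(obs)
  expect_setequal(set$sheets$gut_survival_percent$day, c(11, 20))
  expect_equal(sort(set$sheets$gut_effect_percent$effect), c(0.2, 0.3))
  expect_identical(set$sheets$gut_effect01$effect, c(1L, 1L))
  expect_true(all(set$exclusions$day == 15))
  # per-animal status input populates both the percent and the 01 sheet
  obs2 <- data.frame(study_id = "s9", arm = c("UHDR", "CONV"),
                     endpoint = "survival", day = 11)
  obs2$status <- list(c(0, 0, 1, 0), c(1, 1, 0, 1))
  set2 <- build_effect_sheets(obs2)
  expect_equal(set2$sheets$gut_survival_percent$p_uhdr, 75)
  expect_equal(set2$sheets$gut_survival_percent$p_conv, 25)
  expect_equal(set2$sheets$gut_effect_percent$effect, 0.5)
  expect_equal(nrow(set2$sheets$gut_survival_01), 8L)
  expect_setequal(unique(set2$sheets$gut_survival_01$status), c(0L, 1L))
})

test_that("grades plus a scale map resolve skin percentages inside the pipeline", {
  obs <- data.frame(study_id = "s1", arm = c("UHDR", "CONV"),
                    endpoint = "moist_desquamation", day = NA_real_)
  obs$grades <- list(c("G1", "G1", "G2", "G1"), c("G2", "G3", "G2", "G1"))
  maps <- list(s1 = toxicity_scale_map(
    "s1", c("G1", "G2", "G3"), c("light", "moist_desquamation", "severe")))
  set <- build_effect_sheets(obs, scale_maps = maps)
  expect_equal(set$sheets$Max_Moist_desquamation_percent$p_uhdr, 25)
  expect_equal(set$sheets$Max_Moist_desquamation_percent$p_conv, 75)
  expect_equal(set$sheets$Max_Moist_desquamation_effect_percent$effect, 0.5)
})

test_that("sheet values match a direct recomputation from generator ground truth", {
  fx <- generate_fixture_studies(seed = 12, n_studies = 20)
  set <- build_effect_sheets(fx$observations)
  expect_equal(nrow(set$exclusions), 0L)
  # continuous effects reproduce the generator's realized truth per study
  truth_crypt <- fx$truth[fx$truth$endpoint == "crypt", ]
  got <- set$sheets$gut_crypt_effect
  expect_equal(got$effect[match(truth_crypt$study_id, got$study_id)],
               truth_crypt$true_effect, tolerance = 1e-12)
  truth_md <- fx$truth[fx$truth$endpoint == "moist_desquamation", ]
  gotm <- set$sheets$Max_Moist_desquamation_effect_percent
  expect_equal(gotm$effect[match(truth_md$study_id, gotm$study_id)],
               truth_md$true_effect, tolerance = 1e-12)
  # all sheet ranges hold
  for (nm in c("gut_crypt_effect", "gut_effect_percent",
               "Max_Moist_desquamation_effect_percent"))
    expect_true(all(abs(set$sheets[[nm]]$effect) <= 1))
  expect_true(all(set$sheets$gut_effect01$effect %in% c(-1L, 0L, 1L)))
})

test_that("fixture generators are deterministic and recover the true effect", {
  a <- generate_fixture_studies(seed = 99, n_studies = 8)
  b <- generate_fixture_studies(seed = 99, n_studies = 8)
  expect_identical(a$observations, b$observations)
  # zero effect, zero noise: every continuous effect is exactly 0
  z <- generate_fixture_studies(seed = 5, n_studies = 10, effect_size = 0,
                                noise = 0)
  set <- build_effect_sheets(z$observations)
  expect_true(all(set$sheets$gut_crypt_effect$effect == 0))
  expect_true(all(set$sheets$Max_Moist_desquamation_effect_percent$effect == 0))
  # spot-map fixtures: deterministic and file round-trip
  f1 <- generate_fixture_spotmaps(3, n_maps = 2)
  f2 <- generate_fixture_spotmaps(3, n_maps = 2)
  expect_identical(f1$maps[[1]]$weight, f2$maps[[1]]$weight)
  dir <- withr::local_tempdir()
  f3 <- generate_fixture_spotmaps(3, n_maps = 2, dir = dir)
  expect_true(all(file.exists(f3$paths)))
  back <- read_spot_table(f3$paths[1])
  expect_equal(back$weight, f3$maps[[1]]$weight, tolerance = 1e-6)
})

test_that("effect sheets write one CSV per sheet plus an exclusion log", {
  fx <- generate_fixture_studies(seed = 2, n_studies = 3)
  obs <- rbind(fx$observations,
               data.frame(study_id = "orphan", arm = "CONV",
                          endpoint = "crypt", day = NA_real_, percent = 50))
  set <- build_effect_sheets(obs)
  dir <- withr::local_tempdir()
  write_effect_sheets(set, dir)
  files <- list.files(dir)
  expect_true(all(paste0(names(set$sheets), ".csv") %in% files))
  expect_true("exclusions.log" %in% files)
  back <- read.csv(file.path(dir, "gut_crypt_effect.csv"))
  expect_equal(back$effect, set$sheets$gut_crypt_effect$effect)
})
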