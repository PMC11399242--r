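small_cfg <- function(n_subjects = 3, ...) {
  study_config(n_subjects = n_subjects, n_timepoints = 200, ...)
}

test_that("studies are bit-reproducible and hierarchically seeded", {
  cfg <- small_cfg()
  s1 <- make_study(cfg, seed = 5)
  s2 <- make_study(cfg, seed = 5)
  expect_identical(get_session(s1, 2, "drug_a")$data,
                   get_session(s2, 2, "drug_a")$data)
  expect_identical(s1$side_effects$ratings, s2$side_effects$ratings)

  # subsetting subjects never changes the others' data
  cfg_big <- small_cfg(n_subjects = 4)
  s3 <- make_study(cfg_big, seed = 5)
  expect_identical(get_session(s1, 2, "placebo")$data,
                   get_session(s3, 2, "placebo")$data)

  s4 <- make_study(cfg, seed = 6)
  expect_false(identical(get_session(s1, 1, "placebo")$data,
                         get_session(s4, 1, "placebo")$data))
})

test_that("generated sessions are valid signal input", {
  study <- make_study(small_cfg(), seed = 8)
  vs <- get_session(study, 1, "baseline")
  expect_s3_class(vs, "vertex_series")
  expect_false(anyNA(vs$data))
  expect_true(all(apply(vs$data, 1, stats::sd) > 0))
  expect_equal(vs$n_vertices, study$mesh$n_vertices)
  expect_equal(vs$n_timepoints, 200)
  expect_error(get_session(study, 99, "placebo"), "out of range")
  expect_error(get_session(study, 1, "nope"), "unknown condition")
})

test_that("configuration inconsistencies are rejected", {
  expect_error(study_config(vertices_per_roi = 24), "perfect square")
  expect_error(study_config(n_networks = 7), "divide")
  expect_error(study_config(sensory_rois = 0:3), "out of range")
  expect_error(condition_profile(coupling_scale = -1), "> 0")
  expect_error(condition_profile(side_effect_p = rep(2, 17)), "\\[0, 1\\]")
  cfg <- study_config()
  expect_equal(cfg$n_rois * cfg$vertices_per_roi, 600)
})

test_that("halving the coupling lowers FC edge density for almost all subjects", {
  n <- 30
  conds <- list(full = condition_profile(coupling_scale = 1),
                half = condition_profile(coupling_scale = 0.5))
  cfg <- study_config(n_subjects = n, conditions = conds)
  study <- make_study(cfg, seed = 3)
  band <- band_spec(0.01, 0.1)
  lower <- vapply(seq_len(n), function(s) {
    dens <- vapply(c("full", "half"), function(cn) {
      fc <- compute_fc(bandpass(roi_average(get_session(study, s, cn),
                                            study$parcellation), band))
      edge_density(binarize(fc, 0.5))
    }, numeric(1))
    dens["half"] < dens["full"]
  }, logical(1))
  expect_gte(sum(lower), 28)
})

test_that("doubled local coherence lifts sensory-patch ReHo above the rest", {
  conds <- list(placebo = condition_profile(),
                boosted = condition_profile(local_coherence_boost = 2))
  cfg <- study_config(n_subjects = 4, n_timepoints = 300, conditions = conds)
  study <- make_study(cfg, seed = 9)
  sens <- study$parcellation$labels %in% cfg$sensory_rois
  mean_sens <- function(cn, s) {
    m <- reho_map(get_session(study, s, cn), study$mesh, hops = 2)
    c(sens = mean(m$values[sens]), other = mean(m$values[!sens]))
  }
  vals <- rowMeans(vapply(1:4, function(s) mean_sens("boosted", s), numeric(2)))
  expect_gt(vals["sens"], vals["other"])
  base <- rowMeans(vapply(1:4, function(s) mean_sens("placebo", s), numeric(2)))
  expect_gt(vals["sens"] - base["sens"], 0.02)
})

test_that("side-effect tables reflect the per-condition probabilities", {
  cfg <- small_cfg(n_subjects = 20)
  study <- make_study(cfg, seed = 12)
  r <- study$side_effects$ratings
  fatigue <- match("fatigue", study$side_effects$symptoms)
  drug <- match("drug_a", study$side_effects$conditions)
  placebo <- match("placebo", study$side_effects$conditions)
  expect_gt(mean(r[, fatigue, drug, ]), mean(r[, fatigue, placebo, ]) + 0.5)
  skin <- match("skin_reactions", study$side_effects$symptoms)
  expect_lt(abs(mean(r[, skin, drug, ]) - mean(r[, skin, placebo, ])), 0.3)
  expect_true(all(r %in% 0:3))
})

test_that("a study round-trips through its on-disk representation", {
  cfg <- study_config(n_subjects = 2, n_timepoints = 60)
  study <- make_study(cfg, seed = 4)
  dir <- withr::local_tempdir()
  write_study(study, dir, format = "rds")
  back <- load_study(dir)
  expect_identical(get_session(back, 2, "drug_a")$data,
                   get_session(study, 2, "drug_a")$data)
  expect_equal(back$parcellation$labels, study$parcellation$labels)
  expect_identical(back$side_effects$ratings, study$side_effects$ratings)
  expect_equal(back$references$maps, study$references$maps, tolerance = 1e-6)
  expect_equal(back$roi_networks, study$roi_networks)
})
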