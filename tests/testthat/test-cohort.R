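small_spec <- function(...) {
  cohort_spec(n_subjects = 3, n_regions = 8, n_frames = 200,
              n_communities = 2, seed = 99, ...)
}

test_that("identical spec and seed give bitwise-identical cohorts", {
  c1 <- generate_cohort(small_spec())
  c2 <- generate_cohort(small_spec())
  expect_identical(c1, c2)
})

test_that("adding subjects does not perturb earlier subjects", {
  c3 <- generate_cohort(small_spec())
  c5 <- generate_cohort(cohort_spec(n_subjects = 5, n_regions = 8,
                                    n_frames = 200, n_communities = 2,
                                    seed = 99))
  expect_identical(c3$series[[2]][[1]], c5$series[[2]][[1]])
  expect_identical(c3$motion[[3]][[2]], c5$motion[[3]][[2]])
})

test_that("degenerate no-motion spec yields all-zero FD", {
  co <- generate_cohort(small_spec(motion_prevalence_alpha = 1e-8,
                                   motion_prevalence_beta = 1e8,
                                   baseline_fd_sd = 0))
  for (s in 1:3) for (ses in 1:2) {
    expect_equal(co$motion[[s]][[ses]]$fd_mm, rep(0, 200))
    expect_equal(empirical_motion_fraction(co, s, ses), 0)
  }
})

test_that("community loading induces within-block correlation", {
  co <- generate_cohort(cohort_spec(n_subjects = 2, n_regions = 16,
                                    n_frames = 400, n_communities = 4,
                                    community_loading = 0.9,
                                    artifact_gain = 0, seed = 7))
  rc <- cor(as.matrix(co$series[[1]][[1]]))
  same <- outer(co$communities$community, co$communities$community, "==")
  diag(same) <- NA
  within <- mean(rc[same & upper.tri(rc)], na.rm = TRUE)
  between <- mean(rc[!same & upper.tri(rc)], na.rm = TRUE)
  expect_gt(within, between)
  expect_gt(within, 0.5)
})

test_that("no-motion, no-community spec gives independent AR(1) regions", {
  co <- generate_cohort(cohort_spec(n_subjects = 1, n_regions = 12,
                                    n_frames = 800, n_communities = 1,
                                    community_loading = 0,
                                    artifact_gain = 0, seed = 13))
  rc <- cor(as.matrix(co$series[[1]][[1]]))
  off <- rc[upper.tri(rc)]
  expect_lt(abs(mean(off)), 0.05)
})

test_that("empirical motion fraction tracks the latent probability", {
  co <- generate_cohort(cohort_spec(n_subjects = 200, n_regions = 2,
                                    n_frames = 300, n_communities = 1,
                                    seed = 17))
  emp <- vapply(1:200, function(s) empirical_motion_fraction(co, s, 1),
                numeric(1))
  expect_gt(cor(emp, co$truth$motion_probability), 0.9)

  # default Beta prior spans the sweep range across 200 subjects
  expect_true(any(emp < 0.10))
  expect_true(any(emp > 0.40))
})

test_that("subject AR coefficient is stable across sessions", {
  co <- generate_cohort(cohort_spec(n_subjects = 50, n_regions = 2,
                                    n_frames = 300, n_communities = 1,
                                    subject_sd = 0.3, session_noise_sd = 0.05,
                                    artifact_gain = 0, seed = 23))
  ac1 <- vapply(1:50, function(s)
    cor(co$series[[s]][[1]]$R001[-1], co$series[[s]][[1]]$R001[-300]),
    numeric(1))
  ac2 <- vapply(1:50, function(s)
    cor(co$series[[s]][[2]]$R001[-1], co$series[[s]][[2]]$R001[-300]),
    numeric(1))
  within <- mean(abs(ac1 - ac2))
  between <- mean(abs(outer(ac1, ac2, "-"))[lower.tri(matrix(0, 50, 50))])
  expect_lt(within, between)
  expect_gt(cor(ac1, ac2), 0.5)
})

test_that("invalid specs name the offending field", {
  expect_error(cohort_spec(n_subjects = 0), "n_subjects",
               class = "vgfc_error_validation")
  expect_error(cohort_spec(n_subjects = 2, community_loading = 1),
               "community_loading", class = "vgfc_error_validation")
  expect_error(cohort_spec(n_subjects = 2, motion_fd_scale = 0),
               "motion_fd_scale", class = "vgfc_error_validation")
  expect_error(cohort_spec(n_subjects = 2, ar_coefficient_mean = 1.2),
               "ar_coefficient_mean", class = "vgfc_error_validation")
  expect_error(empirical_motion_fraction(generate_cohort(small_spec()), 9, 1),
               class = "vgfc_error_lookup")
})

test_that("cohorts write to disk and read back through the manifest", {
  co <- generate_cohort(small_spec())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), 6)
  ts <- read_timeseries(man$series_path[1])
  expect_equal(as.data.frame(ts), as.data.frame(co$series[[1]][[1]]))
  fd <- read_fd(man$motion_path[6])
  expect_equal(fd$fd_mm, co$motion[[3]][[2]]$fd_mm)
})
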