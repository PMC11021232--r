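test_that("ICC(A,1) is exact in degenerate and analytic cases", {
  set.seed(103)
  s1 <- rnorm(50)

  # perfect agreement
  fit <- icc_absolute_agreement(cbind(s1, s1))
  expect_equal(fit$icc, 1)
  expect_equal(fit$ms_error, 0)

  # a constant offset in one session is penalised, and more so as it grows
  iccs <- vapply(c(0.5, 1, 2), function(cc)
    icc_absolute_agreement(cbind(s1, s1 + cc))$icc, numeric(1))
  expect_true(all(iccs < 1))
  expect_true(all(diff(iccs) < 0))

  # invariant under a common affine transform of all cells
  x <- cbind(s1, s1 + rnorm(50, sd = 0.5))
  expect_equal(icc_absolute_agreement(2 * x + 7)$icc,
               icc_absolute_agreement(x)$icc, tolerance = 1e-12)

  expect_error(icc_absolute_agreement(cbind(c(1, NA, 3), c(1, 2, 3))),
               class = "vgfc_error_validation")
})

test_that("ICC mean squares match the two-way ANOVA decomposition", {
  set.seed(107)
  x <- matrix(rnorm(20), 10, 2)
  fit <- icc_absolute_agreement(x)
  df <- data.frame(y = as.vector(x),
                   subject = factor(rep(1:10, 2)),
                   session = factor(rep(1:2, each = 10)))
  ms <- summary(aov(y ~ subject + session, data = df))[[1]][["Mean Sq"]]
  expect_equal(fit$ms_rows, ms[1], tolerance = 1e-10)
  expect_equal(fit$ms_cols, ms[2], tolerance = 1e-10)
  expect_equal(fit$ms_error, ms[3], tolerance = 1e-10)
})

test_that("ICC recovers known variance ratios", {
  # mean estimate over 20 simulated n = 500 cohorts per target, so the
  # +/-0.05 band checks estimator bias rather than one draw's noise
  targets <- list(c(3, 1, 0.75), c(1, 1, 0.50), c(1, 3, 0.25))
  for (i in seq_along(targets)) {
    set.seed(109 + i)
    vb <- targets[[i]][1]; ve <- targets[[i]][2]; truth <- targets[[i]][3]
    iccs <- replicate(20, {
      u <- rnorm(500, sd = sqrt(vb))
      x <- cbind(u + rnorm(500, sd = sqrt(ve)), u + rnorm(500, sd = sqrt(ve)))
      icc_absolute_agreement(x)$icc
    })
    expect_lt(abs(mean(iccs) - truth), 0.05)
  }
  # the F-based CI brackets the point estimate
  set.seed(120)
  u <- rnorm(500)
  fit <- icc_absolute_agreement(cbind(u + rnorm(500), u + rnorm(500)))
  expect_true(fit$ci95[1] <= fit$icc && fit$icc <= fit$ci95[2])
})

test_that("motion-feature correlation handles identity and null cases", {
  ft <- random_feature_table(60, 4, seed = 113)
  mp <- tibble::tibble(subject = 1:60, pct_corrupted = runif(60, 0, 50))

  # plant the motion percentage as one feature in one region
  ft2 <- ft
  idx <- ft2$region == "R01"
  ft2$modularity[idx] <- mp$pct_corrupted[ft2$subject[idx]]
  res <- motion_feature_correlation(ft2, mp)
  expect_equal(res$pearson_r[res$region == "R01" & res$feature == "modularity"], 1)

  # independent features: mean r across regions near zero
  ftn <- random_feature_table(200, 5, seed = 127)
  mpn <- tibble::tibble(subject = 1:200, pct_corrupted = runif(200, 0, 50))
  resn <- motion_feature_correlation(ftn, mpn)
  expect_lt(abs(mean(resn$pearson_r)), 0.05)

  # cap at 100% equals the uncapped analysis
  expect_equal(motion_feature_correlation(ftn, mpn, cap_percent = 100), resn)
})

test_that("the motion sweep tracks nested subsets over the 61-point grid", {
  ft <- random_feature_table(80, 3, seed = 131)
  mp <- tibble::tibble(subject = 1:80, pct_corrupted = runif(80, 0, 60))
  sw <- motion_sweep(ft, mp)
  expect_equal(sort(unique(sw$cap_percent)), seq(10, 40, by = 0.5))
  expect_equal(nrow(sw), 61 * 5)
  ns <- sw |> dplyr::distinct(cap_percent, n_subjects) |>
    dplyr::arrange(cap_percent)
  expect_true(all(diff(ns$n_subjects) >= 0))

  # null features: flat curves around zero
  expect_lt(max(abs(sw$mean_r_across_regions), na.rm = TRUE), 0.5)
  expect_lt(abs(mean(sw$mean_r_across_regions, na.rm = TRUE)), 0.1)

  # an empty lowest cap reports NA, not an error
  mp_hi <- tibble::tibble(subject = 1:80, pct_corrupted = runif(80, 45, 60))
  sw_hi <- motion_sweep(ft, mp_hi, caps = c(10, 50))
  expect_true(all(is.na(sw_hi$mean_r_across_regions[sw_hi$cap_percent == 10])))
})

test_that("reliability report screens subjects and computes per-cell ICC", {
  ft1 <- random_feature_table(40, 3, seed = 137)
  mp <- dplyr::bind_rows(
    tibble::tibble(subject = 1:40, session = 1, pct_corrupted = runif(40, 0, 15)),
    tibble::tibble(subject = 1:40, session = 2, pct_corrupted = runif(40, 0, 15)))

  # identical tables -> ICC 1 everywhere
  rep1 <- reliability_report(ft1, ft1, mp, cap_percent = 20)
  expect_true(all(rep1$icc == 1))
  expect_equal(nrow(rep1), 3 * 5)

  # independent sessions -> mean ICC near zero
  fta <- random_feature_table(200, 4, seed = 139)
  ftb <- random_feature_table(200, 4, seed = 141)
  mp2 <- dplyr::bind_rows(
    tibble::tibble(subject = 1:200, session = 1, pct_corrupted = 0),
    tibble::tibble(subject = 1:200, session = 2, pct_corrupted = 0))
  rep0 <- reliability_report(fta, ftb, mp2, cap_percent = 20)
  expect_lt(abs(mean(rep0$icc)), 0.1)

  # a subject present in one session only is excluded with a warning
  ft_missing <- dplyr::filter(ft1, subject != 7)
  expect_warning(rep_m <- reliability_report(ft_missing, ft1, mp, 20),
                 "one session")
  expect_true(all(rep_m$n_subjects <= 39))

  # the cap must hold in BOTH sessions
  mp3 <- mp
  mp3$pct_corrupted[mp3$subject == 1 & mp3$session == 2] <- 30
  rep_c <- reliability_report(ft1, ft1, mp3, cap_percent = 20)
  expect_true(all(rep_c$n_subjects == 39))
})

test_that("icc tidiers expose estimates and mean squares", {
  set.seed(149)
  u <- rnorm(100)
  fit <- icc_absolute_agreement(cbind(u + rnorm(100), u + rnorm(100)))
  td <- generics::tidy(fit)
  expect_equal(td$estimate, fit$icc)
  gl <- generics::glance(fit)
  expect_equal(gl$k_sessions, 2)
  expect_equal(gl$ms_rows, fit$ms_rows)
})
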