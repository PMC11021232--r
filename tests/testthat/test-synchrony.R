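test_that("degree synchrony is the Pearson correlation of degree series", {
  expect_equal(degree_synchrony(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(degree_synchrony(c(1, 2, 3), c(3, 2, 1)), -1)
  d <- c(2, 5, 3, 4)
  expect_equal(degree_synchrony(d, d), 1)
  expect_error(degree_synchrony(c(1, 2, 3), c(1, 1, 1)),
               class = "vgfc_error_degenerate")
  expect_error(degree_synchrony(1:3, 1:4), class = "vgfc_error_validation")
})

test_that("independent layers have near-zero synchrony at T = 2400", {
  set.seed(61)
  d1 <- degree_sequence(visibility_graph(r_ar1(2400)))
  d2 <- degree_sequence(visibility_graph(r_ar1(2400)))
  expect_lt(abs(degree_synchrony(d1, d2)), 0.08)
})

test_that("identical layers give a matrix of ones", {
  set.seed(67)
  x <- r_ar1(150)
  ts <- tibble::tibble(A = x, B = x, C = x)
  sm <- synchrony_matrix(ts)
  expect_equal(sm$r, matrix(1, 3, 3, dimnames = list(names(ts), names(ts))))
  # full off-diagonal mask under any thresholding rule
  for (method in c("fdr", "r", "density")) {
    th <- threshold_synchrony(sm, method = method,
                              level = if (method == "density") 1 else 0.05)
    expect_true(all(th$mask[upper.tri(th$mask)]))
    expect_false(any(diag(th$mask)))
  }
})

test_that("binary synchrony is invariant to positive affine rescaling", {
  set.seed(71)
  ts <- tibble::as_tibble(matrix(rnorm(200 * 4), 200, 4,
                                 dimnames = list(NULL, paste0("R", 1:4))))
  sm1 <- synchrony_matrix(ts)
  ts2 <- dplyr::mutate(ts, R2 = 3.7 * R2 + 11)
  sm2 <- synchrony_matrix(ts2)
  expect_equal(sm1$r, sm2$r)
})

test_that("community structure shows up as within > between synchrony", {
  co <- generate_cohort(cohort_spec(n_subjects = 1, n_regions = 12,
                                    n_frames = 400, n_communities = 4,
                                    community_loading = 0.9,
                                    artifact_gain = 0, seed = 73))
  sm <- synchrony_matrix(co$series[[1]][[1]])
  same <- outer(co$communities$community, co$communities$community, "==")
  ut <- upper.tri(sm$r)
  expect_gt(mean(sm$r[same & ut]), mean(sm$r[!same & ut]))
})

test_that("independent regions give off-diagonal synchrony centred at zero", {
  co <- generate_cohort(cohort_spec(n_subjects = 1, n_regions = 20,
                                    n_frames = 2400, n_communities = 1,
                                    community_loading = 0,
                                    artifact_gain = 0, seed = 79))
  sm <- synchrony_matrix(co$series[[1]][[1]])
  expect_lt(abs(mean(sm$r[upper.tri(sm$r)])), 0.02)
})

test_that("a constant-degree region propagates as NA with a warning", {
  # a strictly convex region maps to the complete graph, whose degree
  # sequence is constant (T - 1 everywhere): synchrony is undefined
  set.seed(82)
  ts <- tibble::tibble(A = rnorm(40), B = (1:40)^2, C = rnorm(40))
  expect_warning(sm <- synchrony_matrix(ts), "B")
  expect_true(all(is.na(sm$r[, "B"])))
  expect_true(all(is.na(sm$r["B", ])))
  expect_equal(sm$r["A", "A"], 1)
  th <- threshold_synchrony(sm, "r", 0.0)
  expect_false(any(th$mask[, 2]))  # NA entries are never retained
})

test_that("all-null p-values give an empty FDR mask", {
  set.seed(81)
  ts <- tibble::as_tibble(matrix(rnorm(60 * 4), 60, 4,
                                 dimnames = list(NULL, paste0("R", 1:4))))
  sm <- synchrony_matrix(ts)
  sm$p[] <- 0.5
  th <- threshold_synchrony(sm, "fdr", 0.05)
  expect_false(any(th$mask))
})

test_that("FDR thresholding recovers planted correlated pairs", {
  # 20 layers, pairs (1,2),(3,4),...,(19,20) share signal; 10 true pairs
  # among 190. Drive the thresholding rule with degree-series r/p computed
  # by the same t-statistic contract.
  set.seed(83)
  n <- 300
  tp <- 0; fp <- 0
  reps <- 50
  template <- synchrony_matrix(tibble::as_tibble(
    matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, sprintf("R%02d", 1:20)))))
  for (rep in seq_len(reps)) {
    base <- matrix(rnorm(n * 10), n, 10)
    degs <- matrix(rnorm(n * 20, sd = sqrt(0.5)), n, 20)
    for (k in 1:10) {
      degs[, 2 * k - 1] <- degs[, 2 * k - 1] + sqrt(0.5) * base[, k]
      degs[, 2 * k] <- degs[, 2 * k] + sqrt(0.5) * base[, k]
    }
    sm <- template
    sm$r <- cor(degs)
    tt <- sm$r * sqrt((n - 2) / (1 - sm$r^2))
    sm$p <- 2 * pt(-abs(tt), df = n - 2)
    diag(sm$p) <- NA
    th <- threshold_synchrony(sm, "fdr", 0.05)
    truth <- matrix(FALSE, 20, 20)
    for (k in 1:10) truth[2 * k - 1, 2 * k] <- TRUE
    ut <- upper.tri(truth)
    tp <- tp + sum(th$mask[ut] & truth[ut])
    fp <- fp + sum(th$mask[ut] & !truth[ut])
  }
  expect_gte(tp / reps, 8)
  expect_lte(fp / reps, 1)
})

test_that("group means average r and drop p", {
  set.seed(89)
  ts <- tibble::as_tibble(matrix(rnorm(100 * 3), 100, 3,
                                 dimnames = list(NULL, c("A", "B", "C"))))
  sm <- synchrony_matrix(ts)
  gm <- group_mean_synchrony(list(sm, sm))
  expect_equal(gm$r, sm$r)
  expect_null(gm$p)

  neg <- sm; neg$r <- -sm$r; diag(neg$r) <- 1
  gm0 <- group_mean_synchrony(list(sm, neg))
  expect_equal(gm0$r[upper.tri(gm0$r)], rep(0, 3))

  # Fisher-z mean fixed point
  half <- sm; half$r[] <- 0.5; diag(half$r) <- 1
  gmf <- group_mean_synchrony(list(half, half), fisher = TRUE)
  expect_equal(gmf$r[1, 2], 0.5, tolerance = 1e-12)

  bad <- sm; bad$region_labels <- c("X", "Y", "Z")
  expect_error(group_mean_synchrony(list(sm, bad)),
               class = "vgfc_error_validation")
})

test_that("tidy() emits the upper triangle in long form", {
  set.seed(97)
  ts <- tibble::as_tibble(matrix(rnorm(80 * 4), 80, 4,
                                 dimnames = list(NULL, paste0("R", 1:4))))
  sm <- threshold_synchrony(synchrony_matrix(ts), "density", 0.5)
  td <- generics::tidy(sm)
  expect_equal(nrow(td), 6)
  expect_true(all(td$region_i < td$region_j))
  expect_equal(sum(td$retained), 3)  # top half of 6 edges
})

test_that("clean-signal group synchrony is low to moderate", {
  co <- generate_cohort(cohort_spec(n_subjects = 8, n_regions = 12,
                                    n_frames = 400, artifact_gain = 0,
                                    seed = 101))
  gm <- group_mean_synchrony(lapply(1:8, function(s)
    synchrony_matrix(co$series[[s]][[1]])))
  expect_lt(mean(abs(gm$r[upper.tri(gm$r)])), 0.4)
})
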