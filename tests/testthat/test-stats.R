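# group_stats module: bootstrap SEM, rank tests, clustering, FDR,
# regression, case-control matching, R2 subsampling, group comparison.

test_that("bootstrap SEM of the median behaves", {
  expect_equal(bootstrap_median_sem(rep(3.2, 10), seed = 1)$sem, 0)
  r1 <- bootstrap_median_sem(c(1, 4, 2, 8, 5, 7), n_iter = 2000, seed = 7)
  r2 <- bootstrap_median_sem(c(1, 4, 2, 8, 5, 7), n_iter = 2000, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$median, 4.5)
  expect_true(is.na(bootstrap_median_sem(c(NA, NA, 2))$sem))
  # doubling n shrinks the SEM roughly by 1/sqrt(2)
  x <- withr::with_seed(11, rnorm(60))
  s1 <- bootstrap_median_sem(x[1:30], n_iter = 4000, seed = 3)$sem
  s2 <- bootstrap_median_sem(x, n_iter = 4000, seed = 3)$sem
  expect_equal(s2 / s1, 1 / sqrt(2), tolerance = 0.2)
})

test_that("rank-sum exact p equals the permutation-enumeration oracle", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(1, 3), c(2, 4)), 2 / 3)  # interleaved, exact
  # oracle: enumerate all assignments of pooled ranks to group a
  oracle <- function(a, b) {
    pooled <- c(a, b); rk <- rank(pooled)
    w_obs <- sum(rk[seq_along(a)])
    ws <- combn(length(pooled), length(a),
                function(ix) sum(rk[ix]))
    min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  }
  withr::with_seed(5, {
    for (na in 1:5) for (nb in na:(10 - na)) {
      a <- sample(1000, na); b <- sample(2000, nb) + 0.5
      expect_equal(rank_sum_test(a, b), oracle(a, b),
                   info = paste(na, nb))
    }
  })
})

test_that("rank-sum normal approximation matches the reference", {
  withr::with_seed(6, {
    a <- rnorm(40); b <- rnorm(45, 0.4)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    expect_equal(rank_sum_test(a, b), ref, tolerance = 1e-6)
    # tied data take the approximate path with tie correction
    at <- round(rnorm(30), 1); bt <- round(rnorm(30, 0.3), 1)
    reft <- stats::wilcox.test(at, bt, exact = FALSE,
                               correct = FALSE)$p.value
    expect_equal(rank_sum_test(at, bt), reft, tolerance = 1e-6)
  })
  expect_equal(rank_sum_test(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1)
})

test_that("signed-rank test matches the reference implementation", {
  withr::with_seed(8, {
    x <- rnorm(12); y <- rnorm(12, 0.5)
    ref <- stats::wilcox.test(x, y, paired = TRUE)$p.value  # exact, n<=15
    expect_equal(signed_rank_test(x, y), ref, tolerance = 1e-12)
    x2 <- rnorm(40); y2 <- rnorm(40, 0.3)
    ref2 <- stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                               correct = FALSE)$p.value
    expect_equal(signed_rank_test(x2, y2), ref2, tolerance = 1e-6)
  })
  expect_equal(signed_rank_test(1:4, 1:4), 1)
})

test_that("Kruskal-Wallis matches the reference and degenerates sanely", {
  withr::with_seed(9, {
    g <- list(rnorm(12), rnorm(15, 0.5), rnorm(9, 1))
    ref <- stats::kruskal.test(g)
    kw <- kruskal_wallis_test(g)
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-12)
    # two groups: asymptotically equivalent to the rank-sum z test
    a <- rnorm(30); b <- rnorm(30, 0.4)
    expect_equal(kruskal_wallis_test(list(a, b))$p_value,
                 rank_sum_test(a, b), tolerance = 0.01)
  })
  eq <- kruskal_wallis_test(list(rep(2, 5), rep(2, 6)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
})

test_that("cluster correction marks only runs of >= 3", {
  expect_equal(cluster_significant(c(0.04, 0.04, 0.04, 0.2, 0.04), 0.05),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(cluster_significant(c(0.2, 0.01, 0.01, 0.2), 0.05),
               rep(FALSE, 4))
  # run at the sequence edge counts; NA breaks runs
  expect_equal(cluster_significant(c(0.2, 0.2, 0.01, 0.01, 0.01), 0.05),
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(cluster_significant(c(0.01, 0.01, NA, 0.01, 0.01), 0.05),
               rep(FALSE, 5))
  # never more marks than plain thresholding
  withr::with_seed(10, {
    p <- runif(50)
    expect_true(all(!cluster_significant(p, 0.3) | (p < 0.3)))
  })
})

test_that("BH-FDR equals the brute-force step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_fdr(c(0.9, 0.8)), rep(FALSE, 2))
  expect_equal(bh_fdr(0.05, 0.05), TRUE)
  brute <- function(p, alpha) {
    m <- length(p); o <- order(p)
    ks <- which(p[o] <= seq_len(m) * alpha / m)
    if (!length(ks)) return(rep(FALSE, m))
    p <= p[o][max(ks)]
  }
  withr::with_seed(12, {
    for (i in 1:200) {
      p <- sample(seq(0, 1, 0.01), sample(1:6, 1), replace = TRUE)
      expect_equal(bh_fdr(p, 0.05), brute(p, 0.05))
    }
  })
  # agreement with p.adjust as an independent reference
  withr::with_seed(13, {
    p <- runif(25)
    expect_equal(bh_fdr(p, 0.05), p.adjust(p, "BH") <= 0.05)
  })
})

test_that("slope-age regression is exact on a line and calibrated on null", {
  r <- regress_slope_vs_age(c(50, 60, 70), c(1.0, 0.8, 0.6))
  expect_equal(r$beta2, -0.02, tolerance = 1e-12)
  expect_equal(r$beta1, 2.0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  # null calibration: ~5% rejections at alpha = 0.05
  rej <- withr::with_seed(14, mean(replicate(400, {
    regress_slope_vs_age(runif(40, 50, 88), rnorm(40))$p_value < 0.05
  })))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.12)
  expect_error(regress_slope_vs_age(rep(60, 5), rnorm(5)), "zero variance")
  # matches lm's t-test p-value
  withr::with_seed(15, {
    x <- runif(30, 50, 88); y <- 1 - 0.01 * x + rnorm(30, 0, 0.1)
    ref <- summary(lm(y ~ x))
    mine <- regress_slope_vs_age(x, y)
    expect_equal(mine$p_value, ref$coefficients[2, 4], tolerance = 1e-12)
    expect_equal(mine$r_squared, ref$r.squared, tolerance = 1e-12)
  })
})

test_that("case-control matching follows the +/-1 year, same-gender rule", {
  cases <- data.frame(id = c("c1", "c2"), age = c(70, 55),
                      gender = c("M", "F"), stringsAsFactors = FALSE)
  controls <- data.frame(id = paste0("h", 1:4),
                         age = c(69, 71, 70, 54),
                         gender = c("M", "M", "F", "M"),
                         stringsAsFactors = FALSE)
  metric <- c(c1 = 2, c2 = 3, h1 = 1, h2 = 5, h3 = 9, h4 = 7)
  expect_message(mp <- pair_case_controls(cases, controls, metric),
                 "c2 dropped")
  expect_equal(nrow(mp), 1)
  expect_equal(mp$control_value, 3)   # median of h1, h2 (h3 wrong gender)
  expect_equal(mp$n_controls, 2)
  # identical control values propagate unchanged, order never matters
  metric2 <- metric; metric2[c("h1", "h2")] <- 4
  mp2 <- pair_case_controls(cases[1, ], controls, metric2)
  expect_equal(mp2$control_value, 4)
  perm <- sample(nrow(controls))
  mp3 <- pair_case_controls(cases[1, ], controls[perm, ], metric2)
  expect_equal(mp3$control_value, mp2$control_value)
})

test_that("R2 subsampling matches per-bin counts", {
  withr::with_seed(16, {
    r2a <- runif(80, 0.3, 0.9); r2b <- runif(50, 0.4, 1.0)
    out <- subsample_match_r2(rnorm(80), r2a, rnorm(50), r2b, seed = 2)
    bins <- seq(0, 1.05, 0.05)
    ca <- table(cut(r2a[out$a], bins))
    cb <- table(cut(r2b[out$b], bins))
    expect_equal(as.vector(ca), as.vector(cb))
    # identical distributions are fully retained
    out2 <- subsample_match_r2(rnorm(30), r2a[1:30], rnorm(30), r2a[1:30],
                               seed = 3)
    expect_length(out2$a, 30)
    expect_error(subsample_match_r2(rnorm(5), rep(0.1, 5),
                                    rnorm(5), rep(0.9, 5)),
                 "no overlap")
  })
})

test_that("compare_groups assembles medians, p-values and clusters", {
  withr::with_seed(17, {
    profiles <- rbind(matrix(rnorm(10 * 8, 1.0, 0.05), 10),
                      matrix(rnorm(10 * 8, 1.6, 0.05), 10))
    grp <- rep(c("mid", "old"), each = 10)
    gc <- compare_groups(profiles, grp, centres = seq(40, 180, 20),
                         n_boot = 500, seed = 5)
    expect_s3_class(gc, "group_comparison")
    expect_equal(nrow(gc$table), 8)
    expect_true(all(gc$table$p_value < 0.01))
    expect_true(all(gc$clusters[, "alpha_0.05"]))
    expect_equal(gc$table$median_old - gc$table$median_mid,
                 rep(0.6, 8), tolerance = 0.1)
    expect_true(all(gc$table$sem_mid > 0))
    # same data in both groups: exact ties, p = 1 everywhere
    same <- rbind(profiles[1:10, ], profiles[1:10, ])
    gc2 <- compare_groups(same, grp, centres = seq(40, 180, 20), n_boot = 0)
    expect_true(all(gc2$table$p_value == 1))
    # missing values are dropped pairwise; < 2 per group -> NA p
    profiles[1:9, 1] <- NA
    gc3 <- compare_groups(profiles, grp, centres = seq(40, 180, 20),
                          n_boot = 0)
    expect_true(is.na(gc3$table$p_value[1]))
    expect_equal(gc3$table$n_mid[1], 1)
  })
})
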