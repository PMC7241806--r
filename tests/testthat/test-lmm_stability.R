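test_that("perfect between-gene agreement gives ICC 1", {
  set.seed(301)
  b <- rnorm(24, 0, 2)
  m <- cbind(A = 2^b, B = 2^(b + 1.5))
  rownames(m) <- paste0("s", 1:24)
  suppressWarnings(
    res <- fit_combination(m, groups = rep(c("g1", "g2", "g3"), each = 8),
                           combo = c("A", "B")))
  expect_equal(res$icc, 1, tolerance = 1e-9)
  expect_equal(res$sigma2_error, 0, tolerance = 1e-9)
  expect_equal(res$upper, 1)
})

test_that("balanced closed-form variance components equal the numerical REML fit", {
  set.seed(302)
  rq <- sim_two_gene(40, groups = rep(c("x", "y"), each = 20))
  df <- refstab:::combo_frame(rq, NULL, c("A", "B"), "log2_rq")
  ba <- refstab:::balanced_anova_fit(df, 2)
  fit <- refstab:::lmer_quiet(y ~ gene + group + gene:group + (1 | sample),
                              df, REML = TRUE)
  v <- refstab:::icc_from_lmer(fit)
  expect_equal(ba$sigma2_sample, unname(v["sample"]), tolerance = 1e-6)
  expect_equal(ba$sigma2_error, unname(v["error"]), tolerance = 1e-6)
})

test_that("F-band and bootstrap intervals agree on balanced data", {
  set.seed(303)
  rq <- sim_two_gene(50)
  fb <- fit_combination(rq, combo = c("A", "B"),
                        spec = lmm_spec(ci = "fband"))
  bs <- fit_combination(rq, combo = c("A", "B"),
                        spec = lmm_spec(ci = "bootstrap", n_boot = 400L),
                        seed = 99)
  expect_equal(fb$icc, bs$icc, tolerance = 1e-6)
  expect_lt(abs(fb$lower - bs$lower), 0.03)
  expect_lt(abs(fb$upper - bs$upper), 0.03)
})

test_that("missing data route to the bootstrap interval and stay in [0,1]", {
  set.seed(304)
  rq <- sim_two_gene(30)
  rq$rq[3, "A"] <- NA
  expect_warning(
    res <- fit_combination(rq, combo = c("A", "B"),
                           spec = lmm_spec(ci = "fband", n_boot = 100L),
                           seed = 7),
    "bootstrap")
  expect_equal(res$ci_method, "bootstrap")
  expect_true(res$lower >= 0 && res$upper <= 1)
  expect_true(res$lower <= res$icc && res$icc <= res$upper)
})

test_that("group shifts on one gene are detected by the systematic-effect LRT", {
  set.seed(305)
  n <- 56
  groups <- rep(paste0("g", 1:7), each = 8)
  b <- rnorm(n, 0, 1.2)
  shift <- ifelse(groups %in% c("g5", "g6", "g7"), 1, 0)
  m <- cbind(A = 2^(b + rnorm(n, 0, 0.4)),
             B = 2^(b + shift + rnorm(n, 0, 0.4)))
  rownames(m) <- paste0("s", 1:n)
  res <- fit_combination(m, groups = groups, combo = c("A", "B"))
  expect_lt(res$lrt_p, 0.05)
  expect_equal(res$lrt_df, 12L)        # (g-1)k with 7 groups, 2 genes
})

test_that("combination search selects the duplicate pair and stops", {
  set.seed(306)
  n <- 40
  b <- rnorm(n, 0, 1.5)
  m <- cbind(A = 2^(b + rnorm(n, 0, 0.2)), B = 2^(b + rnorm(n, 0, 0.2)),
             C = 2^rnorm(n, 0, 1.5))
  rownames(m) <- paste0("s", 1:n)
  sc <- search_combinations(m, groups = rep(c("u", "v"), each = 20),
                            max_k = 3)
  expect_setequal(sc$selected$combination, c("A", "B"))
  expect_equal(sc$stop_reason, "lower_bound_no_increase")
  expect_equal(sc$results$lower, sort(sc$results$lower, decreasing = TRUE))
  # selected has the maximal lower bound
  expect_equal(sc$selected$lower, max(sc$results$lower))
})

test_that("search returns an arg-max even for pure-noise candidates", {
  set.seed(307)
  m <- matrix(2^rnorm(90), 30, 3,
              dimnames = list(paste0("s", 1:30), c("A", "B", "C")))
  sc <- search_combinations(m, groups = rep("all", 30), max_k = 3)
  expect_true(all(sc$results$icc < 0.5))
  expect_equal(sc$selected$lower, max(sc$results$lower))
})

test_that("reliability classification combines lower-limit and point bands", {
  expect_equal(classify_reliability(0.86, lower = 0.65), "moderate to good")
  expect_equal(classify_reliability(0.95, lower = 0.92), "excellent")
  expect_equal(classify_reliability(0.4, lower = 0.1), "poor")
  expect_equal(classify_reliability(0.5, lower = 0.5), "moderate")
})

test_that("Bonett sample size matches direct formula evaluation", {
  expect_identical(bonett_sample_size(0.86, k = 2, width = 0.1), 106L)
  expect_identical(bonett_sample_size(0.8, k = 3, width = 0.2), 36L)
  expect_identical(bonett_sample_size(1, k = 2, width = 0.5), 1L)
  expect_error(bonett_sample_size(0.8, k = 1, width = 0.1),
               class = "refstab_error")
  # independent evaluation with z pinned at 1.959964
  z <- 1.959964
  n_direct <- ceiling(8 * z^2 * (1 - 0.7)^2 * (1 + 0.7)^2 /
                        (2 * 1 * 0.1^2) + 1)
  expect_identical(bonett_sample_size(0.7, k = 2, width = 0.1),
                   as.integer(n_direct))
})

test_that("sample-size table covers the grid with the expected monotonicities", {
  tab <- sample_size_table()
  cell <- tab$n[abs(tab$rho - 0.86) < 1e-9 & tab$k == 2 & tab$width == 0.1]
  expect_identical(cell, 106L)
  # non-increasing in rho at fixed k, width
  sub <- tab[tab$k == 2 & tab$width == 0.1, ]
  expect_true(all(diff(sub$n[order(sub$rho)]) <= 0))
  # w^-2 scaling up to ceiling and the +1
  n01 <- tab$n[abs(tab$rho - 0.8) < 1e-9 & tab$k == 2 & tab$width == 0.1]
  n02 <- tab$n[abs(tab$rho - 0.8) < 1e-9 & tab$k == 2 & tab$width == 0.2]
  expect_lt(abs(n01 / n02 - 4), 0.25)
  expect_error(sample_size_table(rhos = numeric(0)),
               class = "refstab_error")
})

test_that("variance of a product matches formulas and Monte Carlo", {
  expect_equal(variance_of_product(0, 0, 1, 2, independent = TRUE), 0)
  expect_equal(variance_of_product(0.04, 0.09, 1, 2, independent = TRUE),
               0.2536)
  expect_error(variance_of_product(0.1, 0.1, 0, 0),
               class = "refstab_error")
  # Monte-Carlo oracle, independent lognormals
  set.seed(308)
  x <- rlnorm(4e5, 0, 0.2)
  y <- rlnorm(4e5, 0.1, 0.3)
  v_ind <- variance_of_product(var(x), var(y), mean(x), mean(y),
                               independent = TRUE)
  v_dep <- variance_of_product(var(x), var(y), mean(x), mean(y),
                               cov_xy = cov(x, y),
                               cov_x2y2 = cov(x^2, y^2))
  expect_equal(v_ind, var(x * y), tolerance = 0.02)
  expect_equal(v_dep, var(x * y), tolerance = 0.02)
})

test_that("simulated-truth ICC is recovered without bias at moderate n", {
  set.seed(309)
  est <- replicate(40, {
    rq <- sim_two_gene(120, sigma_b2 = 3, sigma_e2 = 1)
    fit_combination(rq, combo = c("A", "B"))$icc
  })
  expect_lt(abs(mean(est) - 0.75), 0.03)
})
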