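test_that("geNorm M matches the pairwise log-ratio SD oracle", {
  m <- cbind(A = c(1, 2, 4, 8), B = c(2, 4, 8, 16), C = c(1, 1, 1, 1))
  rownames(m) <- paste0("s", 1:4)
  g <- genorm(m)
  # A and B keep a constant ratio: their mutual term is 0
  sd_ac <- sd(log2(m[, "A"] / m[, "C"]))        # SD of (0,1,2,3) = 1.2910
  expect_equal(unname(g$m["C"]), 1.2910, tolerance = 1e-4)
  expect_equal(unname(g$m["A"]), mean(c(0, sd_ac)), tolerance = 1e-12)
  expect_equal(unname(g$m["B"]), unname(g$m["A"]))
  expect_equal(g$stable_pair, c("A", "B"))
  expect_equal(g$ranking[3], "C")               # C eliminated first

  # independent oracle: M as mean over partners of pairwise SDs
  set.seed(101)
  r <- matrix(rlnorm(40), 8, 5, dimnames = list(paste0("s", 1:8),
                                                paste0("g", 1:5)))
  gr <- genorm(r)
  oracle <- sapply(colnames(r), function(j)
    mean(sapply(setdiff(colnames(r), j), function(k)
      sd(log2(r[, j] / r[, k])))))
  expect_equal(gr$m, oracle)
})

test_that("geNorm is invariant to multiplicative rescaling of one gene", {
  set.seed(102)
  m <- matrix(rlnorm(30), 10, 3, dimnames = list(paste0("s", 1:10),
                                                 c("A", "B", "C")))
  m2 <- m
  m2[, "B"] <- m2[, "B"] * 100
  expect_equal(genorm(m)$m, genorm(m2)$m)
})

test_that("geNorm pairwise variation flags a sufficient gene count", {
  set.seed(103)
  b <- rnorm(20, 0, 1)
  m <- 2^cbind(A = b + rnorm(20, 0, 0.05), B = b + rnorm(20, 0, 0.05),
               C = b + rnorm(20, 0, 0.05), D = b + rnorm(20, 0, 3))
  rownames(m) <- paste0("s", 1:20)
  g <- genorm(m)
  expect_true(g$v[1] < 0.15)          # two near-identical genes suffice
  expect_equal(g$n_sufficient, 2L)
  expect_true(all(g$v >= 0))
})

test_that("NormFinder reproduces a step-by-step hand oracle", {
  set.seed(104)
  groups <- rep(c("g1", "g2"), each = 3)
  y <- matrix(rnorm(18, 5, 0.3), 6, 3,
              dimnames = list(paste0("s", 1:6), c("A", "B", "C")))
  y[4:6, "C"] <- y[4:6, "C"] + 1      # group shift on C
  res <- normfinder(2^y, groups = groups)

  # hand oracle, steps (1)-(5)
  G <- 3
  z <- y - rowMeans(y)
  zbar <- colMeans(z)
  d <- rbind(colMeans(z[1:3, ]) - zbar, colMeans(z[4:6, ]) - zbar)
  s2 <- rbind(apply(z[1:3, ], 2, var), apply(z[4:6, ], 2, var))
  sig2 <- t(apply(s2, 1, function(r) pmax(r - mean(r) / G, 1e-12)))
  vard <- sig2 / 3
  gam2 <- max(0, mean(d^2) * G / (G - 1) - mean(vard))
  dt <- d * gam2 / (gam2 + vard)
  stab <- colMeans(abs(dt) + sqrt(vard))
  expect_equal(unname(res$stability), unname(stab))
  expect_equal(unname(res$gamma2), gam2)
  expect_equal(unname(res$d_hat), unname(d))
  # the shifted gene has the largest |d| and the worst stability
  expect_equal(names(which.max(abs(res$d_hat[2, ]))), "C")
  expect_equal(res$ranking[3], "C")
})

test_that("NormFinder degenerates to zero on identical data and handles one group", {
  m <- matrix(4, 6, 3, dimnames = list(paste0("s", 1:6), c("A", "B", "C")))
  res <- normfinder(m, groups = rep(c("g1", "g2"), each = 3))
  expect_true(all(res$stability < 1e-5))

  # single group: ranking by bias-corrected within-sample-centred variance
  set.seed(105)
  y <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("s", 1:20), c("A", "B", "C")))
  y[, "C"] <- y[, "C"] * 4
  res1 <- normfinder(2^y, groups = rep("all", 20))
  z <- y - rowMeans(y)
  s2 <- apply(z, 2, var)
  oracle <- sqrt(pmax(s2 - mean(s2) / 3, 1e-12))
  expect_equal(res1$stability, oracle)
  expect_equal(res1$ranking, names(sort(oracle)))

  # a 1-sample group is excluded with a warning
  expect_warning(
    normfinder(2^y, groups = c(rep("a", 10), rep("b", 9), "c")),
    "one sample")
})

test_that("BestKeeper uses MAD dispersion and index correlation", {
  cq <- cbind(A = c(20, 21, 22), B = c(20.5, 21.5, 22.5),
              C = c(25, 22, 19))
  rownames(cq) <- paste0("s", 1:3)
  bk <- bestkeeper(cq)
  a <- bk$stats[bk$stats$gene == "A", ]
  expect_equal(a$mean_cq, 21)
  expect_equal(a$sd_cq, 2 / 3)                  # (1+0+1)/3
  expect_equal(a$cv, 100 * (2 / 3) / 21)
  expect_equal(bk$index, apply(cq, 1, function(x) exp(mean(log(x)))),
               tolerance = 1e-12)
  # genes that track the index up to an additive constant correlate ~1
  cq2 <- cbind(A = c(20, 21, 22), B = c(21, 22, 23), C = c(22, 23, 24))
  bk2 <- bestkeeper(cq2)
  expect_true(all(bk2$stats$r > 0.9999))
  # dispersion reliability cutoff at 1 cycle (MAD, not RMS)
  expect_true(a$reliable)
  cstat <- bk$stats[bk$stats$gene == "C", ]
  expect_equal(cstat$sd_cq, 2)
  expect_false(cstat$reliable)
  expect_error(bestkeeper(cq[1:2, ]), class = "refstab_error")
})

test_that("comparative delta-Cq matches the pairwise SD oracle", {
  cq <- cbind(A = c(20, 21, 22), B = c(20, 22, 24), C = c(20, 20, 20))
  rownames(cq) <- paste0("s", 1:3)
  sc <- comparative_delta_cq(cq)
  expect_equal(unname(sc$score), c(1.0, 1.5, 1.5))
  expect_equal(sc$ranking[1], "A")
  # two genes at constant offset: their pair SD is 0
  ps <- attr(sc, "pair_sd")
  cq2 <- cbind(A = c(20, 21, 22), B = c(22, 23, 24), C = c(20, 25, 21))
  rownames(cq2) <- paste0("s", 1:3)
  ps2 <- attr(comparative_delta_cq(cq2), "pair_sd")
  expect_equal(ps2["A", "B"], 0)
})

test_that("geNorm M and delta-Cq agree when computed on the same log scale", {
  # both are mean pairwise SDs: delta-Cq on log2 RQ equals M exactly
  set.seed(106)
  m <- matrix(rlnorm(50), 10, 5, dimnames = list(paste0("s", 1:10),
                                                 paste0("g", 1:5)))
  g <- genorm(m)
  d <- comparative_delta_cq(log2(m))
  expect_equal(unname(g$m), unname(d$score))
})

test_that("all four rankings are permutations with finite scores", {
  set.seed(107)
  for (trial in 1:3) {
    n <- sample(6:12, 1)
    G <- sample(4:7, 1)
    b <- rnorm(n)
    m <- 2^(outer(b, rep(1, G)) + matrix(rnorm(n * G, 0, runif(1, 0.2, 2)),
                                         n, G))
    dimnames(m) <- list(paste0("s", 1:n), paste0("g", 1:G))
    groups <- rep(c("x", "y"), length.out = n)
    suite <- stability_suite(demo_rq(m, groups = groups))
    for (s in list(suite$genorm$scores, suite$normfinder$scores,
                   suite$bestkeeper$scores, suite$delta_cq)) {
      expect_setequal(s$ranking, colnames(m))
      expect_true(all(is.finite(s$score)))
    }
  }
})

test_that("score ties break deterministically by input gene order", {
  s <- stability_scores("delta_cq", c(B = 1, A = 1, C = 0.5),
                        "lower_better", gene_order = c("B", "A", "C"))
  expect_equal(s$ranking, c("C", "B", "A"))
})
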