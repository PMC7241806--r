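test_that("identical seed and config give bit-identical datasets", {
  cfg <- sim_config(n_groups = 2L, samples_per_group = 3L,
                    genes = default_gene_panel()[1:4, ],
                    missing_rate = 0.05)
  a <- simulate_dataset(cfg, seed = 77)
  b <- simulate_dataset(cfg, seed = 77)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$truth$b, b$truth$b)
  c <- simulate_dataset(cfg, seed = 78)
  expect_false(identical(a$replicates$cq, c$replicates$cq))
})

test_that("noiseless limit reproduces gene baselines exactly", {
  panel <- default_gene_panel()[1:3, ]
  panel$sigma_e <- 0
  cfg <- sim_config(n_groups = 1L, samples_per_group = 4L, genes = panel,
                    sigma_b = 0, plate_offsets = c(0, 0),
                    replicate_sd = 0)
  sim <- simulate_dataset(cfg, seed = 1)
  for (g in panel$gene) {
    cqs <- sim$replicates$cq[sim$replicates$gene == g]
    expect_equal(cqs, rep(panel$baseline_cq[panel$gene == g], length(cqs)))
  }
})

test_that("default configuration emulates the intended study layout", {
  cfg <- sim_config()
  sim <- simulate_dataset(cfg, seed = 3)
  expect_equal(length(unique(sim$replicates$sample_id)), 56L)
  expect_equal(length(unique(sim$replicates$group)), 7L)
  expect_equal(length(unique(sim$replicates$gene)), 10L)
  expect_equal(length(unique(sim$replicates$plate_id)), 2L)
  expect_equal(max(sim$replicates$replicate), 3L)
  expect_true(all(sim$efficiencies$efficiency > 1.8 &
                    sim$efficiencies$efficiency <= 2))
})

test_that("truth ICC follows the closed form", {
  panel <- default_gene_panel()[1:3, ]
  panel$sigma_e <- c(1, 1, 2)
  cfg <- sim_config(genes = panel, sigma_b = sqrt(3))
  expect_equal(truth_icc(cfg, panel$gene[1:2]), 0.75)
  cfg0 <- sim_config(genes = panel, sigma_b = 0)
  expect_equal(truth_icc(cfg0, panel$gene[1:2]), 0)
  panel0 <- panel
  panel0$sigma_e <- 0
  expect_equal(truth_icc(sim_config(genes = panel0, sigma_b = 1),
                         panel0$gene), 1)
  expect_error(truth_icc(cfg, "NOPE"), class = "refstab_error")
})

test_that("a gene given small residual SD outranks one given large SD everywhere", {
  panel <- default_gene_panel()[c(1, 9), ]   # sigma_e 0.45 vs 1.9
  panel <- rbind(panel, data.frame(gene = "MID", baseline_cq = 24,
                                   efficiency = 1.95, sigma_e = 1.0))
  cfg <- sim_config(n_groups = 2L, samples_per_group = 12L, genes = panel)
  sim <- simulate_dataset(cfg, seed = 21)
  cq <- aggregate_replicates(sim$replicates)
  rq <- relative_quantity(cq, sim$efficiencies, mode = "calibrator")
  suite <- stability_suite(rq)
  stable <- panel$gene[1]; unstable <- panel$gene[2]
  for (s in list(suite$genorm$scores, suite$normfinder$scores,
                 suite$delta_cq))
    expect_lt(match(stable, s$ranking), match(unstable, s$ranking))
})

test_that("simulated plate offsets are recovered by factor correction", {
  cfg <- sim_config(n_groups = 2L, samples_per_group = 10L,
                    genes = default_gene_panel()[1:4, ],
                    plate_offsets = c(0.5, -0.5), replicate_sd = 0)
  sim <- simulate_dataset(cfg, seed = 13)
  cq <- aggregate_replicates(sim$replicates)
  rq <- relative_quantity(cq, sim$efficiencies, mode = "calibrator")
  pc <- plate_factor_correction(rq)
  # a +0.5-cycle offset on plate 1 depresses quantities there; the fitted
  # factor must exceed 1 on plate 1 and fall below 1 on plate 2
  f <- pc$factors
  expect_true(all(f$factor[f$plate_id == "P1"] > 1))
  expect_true(all(f$factor[f$plate_id == "P2"] < 1))
  gm <- tapply(f$factor, f$gene, function(x) exp(mean(log(x))))
  expect_equal(as.vector(gm), rep(1, 4), tolerance = 1e-6)
})
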