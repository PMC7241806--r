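make_reps <- function(cq_by_key) {
  rows <- lapply(names(cq_by_key), function(key) {
    parts <- strsplit(key, ":")[[1]]
    cq <- cq_by_key[[key]]
    data.frame(sample_id = parts[1], group = "g", plate_id = parts[3],
               run_id = "R1", gene = parts[2],
               replicate = seq_along(cq), cq = cq, stringsAsFactors = FALSE)
  })
  validate_replicate_table(do.call(rbind, rows))
}

test_that("replicate aggregation means and QC flags follow the policy", {
  reps <- make_reps(list("S1:A:P1" = c(20.1, 20.2, 20.3),
                         "S2:A:P1" = c(20.0, 21.5, 20.2),
                         "S3:A:P1" = c(34.5, 34.6, 34.4),
                         "S4:A:P1" = c(25.0, NA, NA)))
  cq <- aggregate_replicates(reps)
  expect_s3_class(cq, "cq_table")
  get <- function(s) cq[cq$sample_id == s, ]
  expect_equal(get("S1")$mean_cq, 20.2)
  expect_equal(get("S1")$qc_flag, "pass")
  expect_equal(get("S2")$qc_flag, "spread_exceeded")   # spread 1.5 > 1
  expect_equal(get("S3")$mean_cq, 34.5)
  expect_equal(get("S3")$qc_flag, "above_max_cq")
  expect_equal(get("S4")$qc_flag, "missing_replicate")
  expect_equal(get("S4")$n_replicates, 1L)
})

test_that("relative quantification is efficiency-corrected in both modes", {
  reps <- make_reps(list("S1:A:P1" = c(20, 20, 20),
                         "S2:A:P1" = c(21, 21, 21),
                         "S1:B:P1" = c(15, 15, 15),
                         "S2:B:P1" = c(15, 15, 15)))
  eff <- validate_efficiency_table(data.frame(
    gene = c("A", "B"), plate_id = "P1", efficiency = c(2, 1.88),
    nq = c(100, 41)))
  cal <- relative_quantity(aggregate_replicates(reps), eff,
                           mode = "calibrator")
  expect_equal(cal$rq["S1", "A"], 1)            # the calibrator itself
  expect_equal(cal$rq["S2", "A"], 0.5)          # one doubling above
  nqm <- relative_quantity(aggregate_replicates(reps), eff, mode = "nq")
  expect_equal(nqm$rq["S1", "B"], 41 * 1.88^-15)  # direct arithmetic
  expect_equal(nqm$rq["S1", "A"], 100 * 2^-20)

  # monotonicity: RQ strictly decreasing in Cq for fixed E > 1
  cqs <- seq(18, 30, by = 0.5)
  rqs <- 1.9^(-cqs) * 50
  expect_true(all(diff(rqs) < 0))

  # missing efficiency record is a hard, named error
  eff_a <- validate_efficiency_table(data.frame(
    gene = "A", plate_id = "P1", efficiency = 2))
  err <- expect_error(
    relative_quantity(aggregate_replicates(reps), eff_a, mode = "calibrator"),
    class = "refstab_missing_record")
  expect_match(conditionMessage(err), "B")
})

test_that("plate factors centre to GM 1 and preserve per-gene GM", {
  set.seed(31)
  n <- 12
  m <- matrix(rlnorm(n * 3), n, 3,
              dimnames = list(sprintf("s%02d", 1:n), c("A", "B", "C")))
  plates <- rep(c("P1", "P2"), each = n / 2)
  # plate 2's per-gene GM is exactly 4x plate 1's
  m[plates == "P2", ] <- m[plates == "P1", ] * 4
  pc <- plate_factor_correction(demo_rq(m), plates = plates)
  # factor GM = 1 per gene
  gm_f <- tapply(pc$factors$factor, pc$factors$gene,
                 function(f) exp(mean(log(f))))
  expect_equal(as.vector(gm_f), rep(1, 3), tolerance = 1e-6)
  # the 4x plate-2 inflation maps to factors 2 and 0.5
  fA <- pc$factors[pc$factors$gene == "A", ]
  expect_equal(fA$factor[fA$plate_id == "P1"], 2, tolerance = 1e-9)
  expect_equal(fA$factor[fA$plate_id == "P2"], 0.5, tolerance = 1e-9)
  # per-gene overall GM conserved (balanced plates)
  gm <- function(x) exp(mean(log(x)))
  expect_equal(apply(pc$rq$rq, 2, gm), apply(m, 2, gm), tolerance = 1e-9)
  # corrected per-plate GMs agree
  for (g in colnames(m)) {
    gms <- tapply(pc$rq$rq[, g], plates, gm)
    expect_equal(unname(diff(gms)), 0, tolerance = 1e-9)
  }
})

test_that("plate correction is idempotent and identity on identical plates", {
  set.seed(32)
  m <- matrix(rlnorm(20), 10, 2,
              dimnames = list(sprintf("s%02d", 1:10), c("A", "B")))
  m[6:10, ] <- m[1:5, ]                      # plate 2 duplicates plate 1
  plates <- rep(c("P1", "P2"), each = 5)
  pc <- plate_factor_correction(demo_rq(m), plates = plates)
  expect_equal(pc$factors$factor, rep(1, 4), tolerance = 1e-12)
  expect_equal(pc$rq$rq, m, tolerance = 1e-12)

  set.seed(33)
  m2 <- matrix(rlnorm(20), 10, 2,
               dimnames = list(sprintf("s%02d", 1:10), c("A", "B")))
  once <- plate_factor_correction(demo_rq(m2), plates = plates)
  twice <- plate_factor_correction(once$rq)
  expect_equal(twice$factors$factor, rep(1, 4), tolerance = 1e-9)
})

test_that("single-plate input warns and returns identity factors", {
  m <- matrix(rlnorm(6), 3, 2,
              dimnames = list(paste0("s", 1:3), c("A", "B")))
  expect_warning(pc <- plate_factor_correction(demo_rq(m),
                                               plates = rep("P1", 3)),
                 "single plate")
  expect_equal(pc$factors$factor, rep(1, 2))
})
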