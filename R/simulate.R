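#' Simulation configuration for replicate-level qPCR data
#'
#' Describes a study of `n_groups` treatment groups with
#' `samples_per_group` biological samples each, a panel of candidate
#' reference genes measured in triplicate wells split across plates. The
#' latent log2 expression of gene g in sample s (group i) is
#' `x = mu_g + shift_ig + b_s + e_gs` with a shared per-sample random
#' effect `b_s ~ N(0, sigma_b^2)` and gene-specific residual
#' `e ~ N(0, sigma_e_g^2)`; it maps to the Cq scale through the gene's
#' amplification efficiency, `Cq = baseline_g - x * log(2)/log(E_g) +
#' plate offset + replicate noise`, so pipelines that ignore gene-specific
#' efficiencies are detectably wrong on simulated data.
#'
#' Defaults emulate a renal-injury style design: 7 groups of 8 samples
#' (56 total), the standard 10-gene candidate panel with efficiencies in
#' (1.84, 2.0], two plates with opposite 0.25-cycle offsets, triplicates
#' with 0.1-cycle well noise, and a stability gradient in the per-gene
#' residual SDs.
#'
#' @param n_groups number of treatment groups.
#' @param samples_per_group biological samples per group.
#' @param genes data.frame with columns `gene`, `baseline_cq`,
#'   `efficiency`, `sigma_e`; default panel described above.
#' @param sigma_b per-sample random-effect SD (log2 units).
#' @param group_shift matrix (groups x genes) of per-group per-gene shifts
#'   in log2 units, or `NULL` for none.
#' @param plate_offsets per-plate additive Cq offsets (cycles); their
#'   length sets the number of plates; samples alternate over plates.
#' @param replicate_sd technical well noise SD (cycles).
#' @param n_replicates wells per (sample, gene).
#' @param missing_rate probability a well is missing.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_groups = 7L, samples_per_group = 8L,
                       genes = default_gene_panel(), sigma_b = 1.2,
                       group_shift = NULL, plate_offsets = c(0.25, -0.25),
                       replicate_sd = 0.1, n_replicates = 3L,
                       missing_rate = 0) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "baseline_cq", "efficiency", "sigma_e") %in%
                  names(genes)))
  if (any(genes$efficiency <= 1 | genes$efficiency > 2))
    stop_refstab("gene efficiencies must lie in (1, 2]",
                 "refstab_validation_error")
  if (any(genes$sigma_e < 0) || sigma_b < 0 || replicate_sd < 0)
    stop_refstab("standard deviations must be non-negative",
                 "refstab_validation_error")
  assert_scalar_num(missing_rate, "missing_rate", lower = 0, upper = 1)
  if (!is.null(group_shift)) {
    group_shift <- as.matrix(group_shift)
    stopifnot(nrow(group_shift) == n_groups,
              ncol(group_shift) == nrow(genes))
  }
  structure(list(n_groups = as.integer(n_groups),
                 samples_per_group = as.integer(samples_per_group),
                 genes = genes, sigma_b = sigma_b,
                 group_shift = group_shift,
                 plate_offsets = plate_offsets,
                 replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 missing_rate = missing_rate),
            class = "sim_config")
}

#' Default 10-gene candidate panel for simulation
#'
#' The usual rat reference-gene panel, with baseline Cq values in the
#' range such panels show on kidney cDNA, plate-1-style amplification
#' efficiencies, and residual SDs graded from very stable (0.45 log2
#' units) to unstable (2.2) so the classic algorithms have a true ranking
#' to recover.
#'
#' @return data.frame with `gene`, `baseline_cq`, `efficiency`, `sigma_e`.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("HMBS", "PABPN1", "ACTB", "YWHAG", "YWHAZ",
             "TBP", "HPRT", "SDHA", "GAPDH", "18S"),
    baseline_cq = c(26.5, 25.0, 19.5, 24.0, 23.0,
                    27.5, 24.5, 25.5, 21.0, 10.5),
    efficiency = c(1.97, 1.84, 1.94, 2.00, 1.85,
                   2.00, 1.97, 1.98, 2.00, 1.88),
    sigma_e = c(0.45, 0.55, 0.65, 0.75, 0.9,
                1.1, 1.3, 1.6, 1.9, 2.2),
    stringsAsFactors = FALSE)
}

#' Simulate a replicate-level qPCR dataset with known ground truth
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return list with `replicates` (a `replicate_table`), `efficiencies`
#'   (an `efficiency_table`, one record per gene per plate), and `truth`
#'   (sample effects `b`, the latent log2 expression matrix `x`, group
#'   assignment, plate assignment, the config).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (missing(seed)) stop_refstab("seed is required",
                                  "refstab_invalid_argument")
  set.seed(as.integer(seed))
  n <- cfg$n_groups * cfg$samples_per_group
  G <- nrow(cfg$genes)
  sample_id <- sprintf("S%02d", seq_len(n))
  group <- rep(sprintf("G%d", seq_len(cfg$n_groups)),
               each = cfg$samples_per_group)
  n_plates <- length(cfg$plate_offsets)
  plate <- sprintf("P%d", (seq_len(n) - 1L) %% n_plates + 1L)
  b <- stats::rnorm(n, 0, cfg$sigma_b)
  x <- matrix(NA_real_, n, G, dimnames = list(sample_id, cfg$genes$gene))
  for (gi in seq_len(G)) {
    shift <- if (is.null(cfg$group_shift)) 0
             else cfg$group_shift[match(group, unique(group)), gi]
    x[, gi] <- shift + b + stats::rnorm(n, 0, cfg$genes$sigma_e[gi])
  }
  slope <- log(2) / log(cfg$genes$efficiency)   # cycles per log2 unit
  rows <- vector("list", n * G)
  idx <- 0L
  for (si in seq_len(n)) {
    po <- cfg$plate_offsets[match(plate[si], sprintf("P%d", seq_len(n_plates)))]
    for (gi in seq_len(G)) {
      cq_center <- cfg$genes$baseline_cq[gi] - x[si, gi] * slope[gi] + po
      cq <- cq_center + stats::rnorm(cfg$n_replicates, 0, cfg$replicate_sd)
      if (cfg$missing_rate > 0)
        cq[stats::runif(cfg$n_replicates) < cfg$missing_rate] <- NA_real_
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        sample_id = sample_id[si], group = group[si], plate_id = plate[si],
        run_id = "R1", gene = cfg$genes$gene[gi],
        replicate = seq_len(cfg$n_replicates), cq = cq,
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  reps$cq[!is.na(reps$cq) & reps$cq <= 0] <- NA_real_  # guard, ~impossible
  reps <- validate_replicate_table(reps)
  eff <- expand.grid(gene = cfg$genes$gene,
                     plate_id = sprintf("P%d", seq_len(n_plates)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff$efficiency <- cfg$genes$efficiency[match(eff$gene, cfg$genes$gene)]
  eff$nq <- NA_real_
  eff$factor <- NA_real_
  eff <- validate_efficiency_table(eff)
  list(replicates = reps, efficiencies = eff,
       truth = list(b = setNames(b, sample_id), x = x, group = group,
                    plate = setNames(plate, sample_id), config = cfg))
}

#' Ground-truth ICC of a gene combination under a simulation config
#'
#' Closed form under the generating model: the genes of the combination
#' share the sample effect (variance sigma_b^2) and differ by their own
#' residuals, so the intraclass correlation is
#' `sigma_b^2 / (sigma_b^2 + mean(sigma_e_g^2))` over the combination.
#'
#' @param cfg a [sim_config()].
#' @param combo gene names present in `cfg$genes`.
#' @return the true ICC in [0, 1].
#' @export
truth_icc <- function(cfg, combo) {
  stopifnot(inherits(cfg, "sim_config"))
  i <- match(combo, cfg$genes$gene)
  if (anyNA(i))
    stop_refstab("combo gene(s) not in the simulation config",
                 "refstab_invalid_argument")
  s2b <- cfg$sigma_b^2
  s2e <- mean(cfg$genes$sigma_e[i]^2)
  if (s2b + s2e == 0) return(1)
  s2b / (s2b + s2e)
}
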