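#' Replicate quality-control policy
#'
#' Wet-lab convention for technical replicates: a triplicate is suspect when
#' its Cq spread exceeds `max_spread` cycles (the bench rule is to re-assay;
#' software can only flag), and reference-gene quantification is unreliable
#' above `max_cq` cycles.
#'
#' @param max_spread maximum within-replicate Cq range (cycles), default 1.
#' @param max_cq maximum acceptable mean Cq (cycles), default 34.
#' @param min_replicates minimum replicates required for a pass, default 2.
#' @return a `qc_policy` list.
#' @export
qc_policy <- function(max_spread = 1.0, max_cq = 34.0, min_replicates = 2L) {
  assert_scalar_num(max_spread, "max_spread", lower = 0, open_lower = TRUE)
  assert_scalar_num(max_cq, "max_cq", lower = 0, open_lower = TRUE)
  assert_scalar_num(min_replicates, "min_replicates", lower = 1)
  structure(list(max_spread = max_spread, max_cq = max_cq,
                 min_replicates = as.integer(min_replicates)),
            class = "qc_policy")
}

#' Aggregate technical replicates into per-(sample, gene) Cq values
#'
#' Averages replicate wells (arithmetic mean of Cq, i.e. geometric mean of
#' quantities) and attaches a QC flag per record: `pass`, `spread_exceeded`
#' (replicate range above the policy maximum), `above_max_cq` (mean Cq beyond
#' the reliable quantification range), or `missing_replicate` (fewer
#' non-missing replicates than required). Flag precedence is
#' missing_replicate > spread_exceeded > above_max_cq.
#'
#' @param reps a `replicate_table`.
#' @param policy a [qc_policy()].
#' @return a `cq_table` data.frame: `sample_id`, `group`, `plate_id`,
#'   `run_id`, `gene`, `mean_cq`, `sd_cq`, `spread`, `n_replicates`,
#'   `qc_flag`.
#' @export
aggregate_replicates <- function(reps, policy = qc_policy()) {
  stopifnot(inherits(reps, "replicate_table"))
  key <- paste(reps$run_id, reps$sample_id, reps$gene, sep = "\r")
  idx <- split(seq_len(nrow(reps)), key)
  rows <- lapply(idx, function(i) {
    cq <- reps$cq[i]
    ok <- !is.na(cq)
    n <- sum(ok)
    mean_cq <- if (n > 0) mean(cq[ok]) else NA_real_
    spread <- if (n > 0) diff(range(cq[ok])) else NA_real_
    flag <- "pass"
    if (n < policy$min_replicates) flag <- "missing_replicate"
    else if (spread > policy$max_spread) flag <- "spread_exceeded"
    else if (mean_cq > policy$max_cq) flag <- "above_max_cq"
    data.frame(sample_id = reps$sample_id[i[1]], group = reps$group[i[1]],
               plate_id = reps$plate_id[i[1]], run_id = reps$run_id[i[1]],
               gene = reps$gene[i[1]], mean_cq = mean_cq,
               sd_cq = if (n >= 2) stats::sd(cq[ok]) else NA_real_,
               spread = spread, n_replicates = n, qc_flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$run_id, out$sample_id, out$gene), ]
  class(out) <- c("cq_table", "data.frame")
  out
}

#' Efficiency-corrected relative quantification
#'
#' Converts mean Cq values into relative quantities (RQ) using the
#' gene- and plate-specific amplification efficiency E:
#' \describe{
#'   \item{calibrator}{per gene, `RQ_s = E^(Cq_min - Cq_s)` against the
#'     lowest observed mean Cq for that gene, so the maximum RQ is 1;}
#'   \item{nq}{`RQ_s = N_q / E^Cq_s` with the plate-matched quantification
#'     threshold, an absolute per-plate scale that composes with inter-plate
#'     factor correction.}
#' }
#' In calibrator mode with plate-specific efficiencies, the per-sample E is
#' the plate-matched one and the calibrator is the minimum-Cq sample.
#'
#' @param cq a `cq_table` from [aggregate_replicates()].
#' @param eff an `efficiency_table`.
#' @param mode `"calibrator"` or `"nq"`.
#' @param include_flags QC flags to retain besides `"pass"`; default keeps
#'   flagged records out of the stability input, per bench practice of
#'   re-assaying failed triplicates.
#' @return an `rq_matrix`; entries for excluded/missing records are `NA`. A
#'   `rel_se` attribute carries per-entry relative standard errors derived
#'   from the replicate Cq spread (`ln(E) * sd_cq`).
#' @export
relative_quantity <- function(cq, eff, mode = c("calibrator", "nq"),
                              include_flags = character()) {
  mode <- match.arg(mode)
  stopifnot(inherits(cq, "cq_table"), inherits(eff, "efficiency_table"))
  keep <- cq$qc_flag %in% c("pass", include_flags) & !is.na(cq$mean_cq)
  cq <- cq[keep, , drop = FALSE]
  ekey <- paste(eff$gene, eff$plate_id, sep = "\r")
  ckey <- paste(cq$gene, cq$plate_id, sep = "\r")
  mi <- match(ckey, ekey)
  if (anyNA(mi)) {
    miss <- cq[which(is.na(mi))[1L], ]
    stop_refstab(sprintf("no efficiency record for gene %s on plate %s",
                         miss$gene, miss$plate_id), "refstab_missing_record")
  }
  E <- eff$efficiency[mi]
  nq <- eff$nq[mi]
  rq_long <- switch(mode,
    nq = {
      if (anyNA(nq))
        stop_refstab("nq mode requires a quantification threshold per record",
                     "refstab_missing_record")
      nq * E^(-cq$mean_cq)
    },
    calibrator = {
      # per gene: RQ = E^(Cq_min - Cq) with the sample's plate-matched E
      rq <- numeric(nrow(cq))
      for (g in unique(cq$gene)) {
        i <- which(cq$gene == g)
        cal <- min(cq$mean_cq[i])
        rq[i] <- E[i]^(cal - cq$mean_cq[i])
      }
      rq
    })
  samples <- sort(unique(cq$sample_id))
  genes <- unique(cq$gene)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  se <- m
  si <- match(cq$sample_id, samples)
  gi <- match(cq$gene, genes)
  m[cbind(si, gi)] <- rq_long
  se[cbind(si, gi)] <- ifelse(is.na(cq$sd_cq), NA_real_, log(E) * cq$sd_cq)
  group <- cq$group[match(samples, cq$sample_id)]
  plate <- cq$plate_id[match(samples, cq$sample_id)]
  out <- rq_matrix(m, group = group, plate = plate, rq_mode = mode)
  out$rel_se <- se
  out
}

#' Inter-plate factor correction
#'
#' Removes multiplicative between-plate (session) variation per gene. On the
#' log-RQ scale the plate factor is the deviation of the plate's per-gene
#' geometric mean from the overall per-gene geometric mean, re-centred so
#' the geometric mean of the factors across plates is exactly 1 — the
#' least-squares solution for a multiplicative session effect when plate
#' composition is balanced. Corrected RQ = RQ x F(plate of sample).
#'
#' @param rq an `rq_matrix` with per-sample plate assignment, or a plain
#'   positive matrix plus `plates`.
#' @param plates optional plate label per sample (overrides `rq$plate`).
#' @return list with `rq` (corrected `rq_matrix`) and `factors` (data.frame
#'   of gene, plate_id, factor; class `plate_factor_set`).
#' @export
plate_factor_correction <- function(rq, plates = NULL) {
  if (is.matrix(rq)) rq <- rq_matrix(rq, group = rep("all", nrow(rq)),
                                     plate = plates)
  plates <- plates %||% rq$plate
  if (is.null(plates))
    stop_refstab("plate assignment per sample is required",
                 "refstab_invalid_argument")
  if (length(plates) != nrow(rq$rq))
    stop_refstab("one plate label per sample required",
                 "refstab_invalid_argument")
  m <- rq$rq
  plate_levels <- sort(unique(plates))
  if (length(plate_levels) < 2L) {
    warning("single plate: identity correction factors")
    factors <- data.frame(gene = colnames(m), plate_id = plate_levels[1],
                          factor = 1, stringsAsFactors = FALSE)
    class(factors) <- c("plate_factor_set", "data.frame")
    return(list(rq = rq, factors = factors))
  }
  factors <- expand.grid(gene = colnames(m), plate_id = plate_levels,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  factors$factor <- NA_real_
  corrected <- m
  for (g in colnames(m)) {
    x <- m[, g]
    logf <- vapply(plate_levels, function(p) {
      xp <- x[plates == p & !is.na(x)]
      if (length(xp) == 0L) return(NA_real_)
      mean(log(x[!is.na(x)])) - mean(log(xp))
    }, numeric(1))
    if (anyNA(logf))
      warning(sprintf("gene %s has plate(s) with no observations; factor undefined", g))
    # GM-centre the defined factors so their geometric mean is exactly 1
    logf <- logf - mean(logf, na.rm = TRUE)
    f <- exp(logf)
    factors$factor[factors$gene == g] <- f[match(factors$plate_id[factors$gene == g],
                                                 plate_levels)]
    corrected[, g] <- x * f[match(plates, plate_levels)]
  }
  class(factors) <- c("plate_factor_set", "data.frame")
  out <- rq
  out$rq <- corrected
  out$plate <- as.character(plates)
  out$plate_corrected <- TRUE
  list(rq = out, factors = factors)
}
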