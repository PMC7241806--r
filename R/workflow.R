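#' Per-gene descriptive statistics of aggregated Cq values
#'
#' The familiar descriptive block of a reference-gene report: number of
#' values, min, max, arithmetic mean, SD (n-1), geometric mean of Cq, and
#' the D'Agostino-Pearson omnibus K2 normality p-value as a convenience
#' (no downstream decision depends on it).
#'
#' @param cq a `cq_table` or samples-by-genes Cq matrix.
#' @return data.frame, one row per statistic, one column per gene.
#' @export
descriptive_stats <- function(cq) {
  m <- cq_as_matrix(cq)
  stats_rows <- c("n", "min", "max", "mean", "sd", "geo_mean",
                  "dagostino_p")
  out <- as.data.frame(matrix(NA_real_, length(stats_rows), ncol(m),
                              dimnames = list(stats_rows, colnames(m))))
  for (g in colnames(m)) {
    x <- m[, g][!is.na(m[, g])]
    out["n", g] <- length(x)
    out["min", g] <- min(x)
    out["max", g] <- max(x)
    out["mean", g] <- mean(x)
    out["sd", g] <- if (length(x) >= 2) stats::sd(x) else NA_real_
    out["geo_mean", g] <- gm_mean(x)
    out["dagostino_p", g] <- tryCatch(dagostino_k2(x)$p.value,
                                      error = function(e) NA_real_)
  }
  out
}

#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Combines the standardised sample skewness and kurtosis into
#' K2 = Z1(sqrt(b1))^2 + Z2(b2)^2, referred to a chi-square with 2 df.
#' Uses the standard published transformations of the skewness
#' (D'Agostino 1970) and kurtosis (Anscombe & Glynn 1983) statistics.
#'
#' @param x numeric vector, n >= 20 recommended (hard minimum 8 for the
#'   kurtosis transformation).
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L)
    stop_refstab("K2 test needs at least 8 observations",
                 "refstab_invalid_argument")
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness: D'Agostino's Z1
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe-Glynn Z2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  b2 <- g2 + 3
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Run the full reference-gene stability pipeline
#'
#' Replicate QC and aggregation, efficiency-corrected relative
#' quantification, inter-plate factor correction, the four classic
#' stability algorithms, consensus rank aggregation, and the mixed-model
#' ICC combination search — one call, with every intermediate result
#' retained so each reported number is recomputable.
#'
#' @param replicates a `replicate_table` (or path readable by
#'   [read_replicate_table()]).
#' @param efficiencies an `efficiency_table` (or path).
#' @param policy a [qc_policy()].
#' @param rq_mode `"calibrator"` or `"nq"` (nq wins when thresholds are
#'   present and `rq_mode` is not given).
#' @param correct_plates apply inter-plate factor correction.
#' @param max_k largest ICC combination size searched.
#' @param spec an [lmm_spec()].
#' @param seed seed for stochastic stages (consensus CE is not run here;
#'   the assignment solution is exact).
#' @param weighted_consensus use the score-weighted footrule.
#' @return an `analysis_report` list: `qc` (the `cq_table`),
#'   `descriptives`, `rq`, `plate_factors`, `stability` (four results +
#'   ensemble), `consensus`, `icc_search`, `provenance`.
#' @export
run_full_analysis <- function(replicates, efficiencies,
                              policy = qc_policy(), rq_mode = NULL,
                              correct_plates = TRUE, max_k = 3L,
                              spec = lmm_spec(), seed = 1L,
                              weighted_consensus = FALSE) {
  if (is.character(replicates))
    replicates <- read_replicate_table(replicates)
  if (is.character(efficiencies))
    efficiencies <- read_efficiency_table(efficiencies)
  stage <- "replicate QC"
  report <- tryCatch({
    cq <- aggregate_replicates(replicates, policy)
    desc <- descriptive_stats(cq)
    stage <- "relative quantification"
    if (is.null(rq_mode))
      rq_mode <- if (all(!is.na(efficiencies$nq))) "nq" else "calibrator"
    rq <- relative_quantity(cq, efficiencies, mode = rq_mode)
    plate_factors <- NULL
    if (correct_plates && length(unique(rq$plate)) > 1L) {
      stage <- "plate factor correction"
      pc <- plate_factor_correction(rq)
      rq <- pc$rq
      plate_factors <- pc$factors
    }
    stage <- "classic stability algorithms"
    keep <- !apply(rq$rq, 1, anyNA)   # complete samples for the suite
    rqc <- rq
    rqc$rq <- rq$rq[keep, , drop = FALSE]
    rqc$group <- rq$group[keep]
    stab <- stability_suite(rqc, groups = rqc$group)
    stage <- "consensus aggregation"
    consensus <- brute_force_aggregate(stab$ensemble,
                                       weighted = weighted_consensus)
    stage <- "mixed-model ICC search"
    icc_search <- search_combinations(rqc, groups = rqc$group,
                                      max_k = max_k, spec = spec,
                                      seed = seed)
    list(qc = cq, descriptives = desc, rq = rq,
         plate_factors = plate_factors, stability = stab,
         consensus = consensus, icc_search = icc_search,
         provenance = list(
           rq_mode = rq_mode, plate_corrected = correct_plates,
           max_k = max_k, seed = seed,
           n_samples = nrow(rq$rq), n_genes = ncol(rq$rq),
           package_version = as.character(utils::packageVersion("refstab"))))
  }, error = function(e) {
    stop_refstab(sprintf("pipeline failed at stage '%s': %s", stage,
                         conditionMessage(e)), "refstab_pipeline_error")
  })
  class(report) <- "analysis_report"
  report
}

#' @exportS3Method base::print
print.analysis_report <- function(x, ...) {
  cat("reference-gene stability report\n")
  cat(sprintf("  samples: %d  genes: %d  rq mode: %s\n",
              x$provenance$n_samples, x$provenance$n_genes,
              x$provenance$rq_mode))
  cat("  consensus ranking:",
      paste(x$consensus$ordering, collapse = " > "), "\n")
  sel <- x$icc_search$selected
  cat(sprintf("  best combination: {%s}  ICC %.3f (%.3f, %.3f), %s\n",
              paste(sel$combination, collapse = ", "), sel$icc, sel$lower,
              sel$upper, classify_reliability(sel)))
  invisible(x)
}

#' Serialize an analysis report to JSON plus delimited tables
#'
#' Writes `report.json` (full structured document) and delimited twins of
#' the main tables (descriptives, stability scores, consensus, ICC search)
#' into a directory.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doc <- list(
    provenance = report$provenance,
    descriptives = cbind(statistic = rownames(report$descriptives),
                         report$descriptives),
    qc_flags = table(report$qc$qc_flag),
    stability = lapply(
      report$stability[c("genorm", "normfinder", "bestkeeper")],
      function(r) list(ranking = r$scores %||% NULL)),
    consensus = list(ordering = report$consensus$ordering,
                     objective = report$consensus$objective,
                     method = report$consensus$method),
    icc = report$icc_search$results,
    stop_reason = report$icc_search$stop_reason)
  write_result_json(doc, file.path(dir, "report.json"))
  utils::write.csv(cbind(statistic = rownames(report$descriptives),
                         report$descriptives),
                   file.path(dir, "descriptives.csv"), row.names = FALSE)
  scores <- do.call(rbind, lapply(
    list(report$stability$genorm$scores,
         report$stability$normfinder$scores,
         report$stability$bestkeeper$scores,
         report$stability$delta_cq),
    function(s) data.frame(algorithm = s$algorithm, gene = names(s$score),
                           score = unname(s$score),
                           rank = match(names(s$score), s$ranking),
                           stringsAsFactors = FALSE)))
  utils::write.csv(scores, file.path(dir, "stability_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(rank = seq_along(report$consensus$ordering),
                              gene = report$consensus$ordering),
                   file.path(dir, "consensus.csv"), row.names = FALSE)
  utils::write.csv(report$icc_search$results,
                   file.path(dir, "icc_combinations.csv"), row.names = FALSE)
  if (!is.null(report$plate_factors))
    utils::write.csv(report$plate_factors,
                     file.path(dir, "plate_factors.csv"), row.names = FALSE)
  invisible(dir)
}
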