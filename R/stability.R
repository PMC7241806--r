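#' geNorm expression-stability measure M with stepwise elimination
#'
#' For each candidate gene j, M_j is the mean over all other genes k of the
#' sample standard deviation (n-1 denominator) of the log2 expression ratio
#' log2(RQ_j / RQ_k): a gene that keeps a constant ratio to every other
#' candidate has M = 0. The stepwise procedure removes the gene with the
#' highest M, recomputes, and repeats until two genes remain; those two form
#' the most-stable pair. Pairwise variations V_n = SD over samples of
#' log2(NF_n / NF_{n+1}), where NF_n is the per-sample geometric mean RQ of
#' the n top-ranked genes, drive the "how many genes are enough" heuristic:
#' V_n < 0.15 suggests no benefit from adding gene n+1.
#'
#' @param rq an `rq_matrix` or positive samples-by-genes matrix.
#' @param v_cutoff pairwise-variation cutoff for the stopping heuristic.
#' @return a `genorm_result` list: `m` (first-pass M per gene), `ranking`,
#'   `elimination` (per-step M tables), `stable_pair`, `v` (named vector
#'   V2/3, V3/4, ...), `v_cutoff`, `n_sufficient` (smallest n with
#'   V_n < cutoff, NA if none), `scores` (a `stability_scores` view).
#' @export
genorm <- function(rq, v_cutoff = 0.15) {
  m <- rq_as_matrix(rq)
  if (ncol(m) < 3L)
    stop_refstab("geNorm stepwise elimination needs at least 3 genes",
                 "refstab_invalid_argument")
  if (nrow(m) < 3L)
    stop_refstab("geNorm needs at least 3 samples", "refstab_invalid_argument")
  lg <- log2(m)
  first_pass <- genorm_m(lg)

  # stepwise elimination on a shrinking gene set
  remaining <- colnames(lg)
  elimination <- list()
  elim_order <- character(0)
  while (length(remaining) > 2L) {
    mv <- genorm_m(lg[, remaining, drop = FALSE])
    elimination[[length(elimination) + 1L]] <- mv
    worst <- names(mv)[order(-mv, match(names(mv), colnames(lg)))][1L]
    elim_order <- c(elim_order, worst)
    remaining <- setdiff(remaining, worst)
  }
  # rank 1-2: the surviving pair (input order); then reverse elimination order
  ranking <- c(remaining, rev(elim_order))

  # pairwise variation V_n between normalisation factors of n and n+1 genes
  G <- ncol(lg)
  v <- numeric(0)
  if (G >= 3L) {
    v <- vapply(2:(G - 1L), function(n) {
      nf_n <- rowMeans(lg[, ranking[1:n], drop = FALSE], na.rm = FALSE)
      nf_n1 <- rowMeans(lg[, ranking[1:(n + 1L)], drop = FALSE], na.rm = FALSE)
      sd_n1(nf_n - nf_n1)
    }, numeric(1))
    names(v) <- paste0("V", 2:(G - 1L), "/", 3:G)
  }
  below <- which(v < v_cutoff)
  scores <- stability_scores("genorm", first_pass, "lower_better",
                             gene_order = colnames(m))
  structure(list(m = first_pass, ranking = ranking,
                 elimination = elimination, stable_pair = remaining,
                 v = v, v_cutoff = v_cutoff,
                 n_sufficient = if (length(below))
                   unname(below[1L]) + 1L else NA_integer_,
                 scores = scores),
            class = "genorm_result")
}

# mean over partner genes of SD of pairwise log-ratios; pairwise-complete
genorm_m <- function(lg) {
  genes <- colnames(lg)
  vapply(genes, function(j) {
    sds <- vapply(setdiff(genes, j), function(k) {
      r <- lg[, j] - lg[, k]
      sd_n1(r)
    }, numeric(1))
    mean(sds, na.rm = TRUE)
  }, numeric(1))
}

#' NormFinder model-based stability
#'
#' Variance-decomposition stability on y = log2 RQ. Each sample is centred
#' across genes; per treatment group the inter-group difference d of a gene
#' and its intra-group variance are estimated, the variance estimate is
#' bias-corrected for the centring, the inter-group differences are shrunk
#' toward zero by an empirical-Bayes factor, and the stability of gene g is
#' the mean over groups of |shrunken d| + sqrt(Var(d)). Lower is more
#' stable. With a single group the measure reduces to the square root of the
#' bias-corrected within-sample-centred variance. The best two-gene
#' normalisation factor minimises the combination stability.
#'
#' @param rq an `rq_matrix` or positive samples-by-genes matrix.
#' @param groups group label per sample; defaults to the `rq_matrix` groups.
#' @return a `normfinder_result` list exposing all intermediate quantities:
#'   `d_hat`, `d_tilde` (groups x genes), `sigma2` (intra-group variances),
#'   `var_d`, `gamma2`, `stability` (per gene), `ranking`, `best_pair`,
#'   `best_pair_stability`, `scores`.
#' @export
normfinder <- function(rq, groups = NULL) {
  m <- rq_as_matrix(rq)
  groups <- groups %||% (if (inherits(rq, "rq_matrix")) rq$group)
  if (is.null(groups)) groups <- rep("all", nrow(m))
  if (ncol(m) < 3L)
    stop_refstab("NormFinder needs at least 3 genes",
                 "refstab_invalid_argument")
  y <- log2(m)
  G <- ncol(y)
  # drop groups with a single sample (their variance is undefined)
  tab <- table(groups)
  if (any(tab < 2L) && length(tab) > 1L) {
    drop <- names(tab)[tab < 2L]
    warning(sprintf("excluding group(s) with one sample: %s",
                    paste(drop, collapse = ", ")))
    keep <- !groups %in% drop
    y <- y[keep, , drop = FALSE]
    groups <- groups[keep]
  }
  glev <- unique(groups)
  ng <- length(glev)
  eps <- 1e-12

  # (1) centre each sample across genes
  z <- y - rowMeans(y, na.rm = TRUE)

  if (ng == 1L) {
    s2 <- apply(z, 2, function(col) stats::var(col, na.rm = TRUE))
    sigma2 <- pmax(s2 - mean(s2) / G, eps)
    stability <- sqrt(sigma2)
    ranking <- names(stability)[order(stability, seq_along(stability))]
    pair <- best_normfinder_pair_single(sigma2, tab = sum(!is.na(z[, 1])))
    res <- list(d_hat = NULL, d_tilde = NULL, sigma2 = sigma2,
                var_d = NULL, gamma2 = NA_real_,
                stability = stability, ranking = ranking,
                best_pair = pair$pair, best_pair_stability = pair$value,
                scores = stability_scores("normfinder", stability,
                                          "lower_better",
                                          gene_order = colnames(m)))
    class(res) <- "normfinder_result"
    return(res)
  }

  zbar_all <- colMeans(z, na.rm = TRUE)
  d_hat <- matrix(NA_real_, ng, G, dimnames = list(glev, colnames(z)))
  s2 <- d_hat
  n_i <- setNames(integer(ng), glev)
  for (i in glev) {
    zi <- z[groups == i, , drop = FALSE]
    n_i[i] <- nrow(zi)
    d_hat[i, ] <- colMeans(zi, na.rm = TRUE) - zbar_all
    s2[i, ] <- apply(zi, 2, function(col) stats::var(col, na.rm = TRUE))
  }
  # (3) bias-correct the within-group variances for the sample centring
  sigma2 <- t(apply(s2, 1, function(row) pmax(row - mean(row) / G, eps)))
  dimnames(sigma2) <- dimnames(s2)
  # (4) sampling variance of d_hat; shrinkage variance gamma2
  var_d <- sweep(sigma2, 1, n_i, "/")
  gamma2 <- max(0, mean(d_hat^2) * G / (G - 1) - mean(var_d))
  d_tilde <- d_hat * gamma2 / (gamma2 + var_d)
  # (5) per-gene stability
  stability <- colMeans(abs(d_tilde) + sqrt(var_d))
  ranking <- names(stability)[order(stability, seq_along(stability))]
  # (6) best pair by combination stability
  pairs <- utils::combn(colnames(z), 2, simplify = FALSE)
  pair_stab <- vapply(pairs, function(p) {
    mean(abs(rowMeans(d_tilde[, p, drop = FALSE])) +
           sqrt(rowSums(var_d[, p, drop = FALSE])) / length(p))
  }, numeric(1))
  best <- which.min(pair_stab)
  res <- list(d_hat = d_hat, d_tilde = d_tilde, sigma2 = sigma2,
              var_d = var_d, gamma2 = gamma2, stability = stability,
              ranking = ranking, best_pair = pairs[[best]],
              best_pair_stability = pair_stab[best],
              scores = stability_scores("normfinder", stability,
                                        "lower_better",
                                        gene_order = colnames(m)))
  class(res) <- "normfinder_result"
  res
}

best_normfinder_pair_single <- function(sigma2, tab) {
  genes <- names(sigma2)
  pairs <- utils::combn(genes, 2, simplify = FALSE)
  vals <- vapply(pairs, function(p) sqrt(mean(sigma2[p]) / 2), numeric(1))
  best <- which.min(vals)
  list(pair = pairs[[best]], value = vals[best])
}

#' BestKeeper descriptive stability and index correlation
#'
#' Works on raw (or plate-corrected) Cq values. Per gene it reports the
#' arithmetic and geometric mean Cq, min, max, the BestKeeper "SD (+/- Cq)"
#' — the mean absolute deviation around the arithmetic mean, not the RMS
#' deviation — and CV = 100 * SD / mean. The BestKeeper index is the
#' per-sample geometric mean of all candidate Cq values (samples with any
#' missing gene are excluded from the index); each gene's association with
#' the index is summarised by the Pearson correlation and its two-sided
#' p-value. Genes with SD > 1 cycle are flagged unreliable.
#'
#' @param cq a `cq_table` or a samples-by-genes matrix of Cq values.
#' @param drop_outliers if `TRUE`, samples whose index residual exceeds
#'   3 x MAD are removed before correlation (off by default; the original
#'   tool's outlier handling is not rule-specified).
#' @return a `bestkeeper_result` list: `stats` (per-gene descriptives with
#'   `sd_cq`, `cv`, `r`, `p_value`, `reliable`), `index` (per sample),
#'   `scores` (r as `higher_better`).
#' @export
bestkeeper <- function(cq, drop_outliers = FALSE) {
  m <- cq_as_matrix(cq)
  if (ncol(m) < 2L)
    stop_refstab("BestKeeper needs at least 2 genes",
                 "refstab_invalid_argument")
  complete <- stats::complete.cases(m)
  if (sum(complete) < 3L)
    stop_refstab("BestKeeper correlations need at least 3 complete samples",
                 "refstab_invalid_argument")
  mi <- m[complete, , drop = FALSE]
  index <- apply(mi, 1, gm_mean)
  if (drop_outliers) {
    resid <- index - stats::median(index)
    keep <- abs(resid) <= 3 * stats::mad(index)
    mi <- mi[keep, , drop = FALSE]
    index <- index[keep]
  }
  stats_df <- do.call(rbind, lapply(colnames(m), function(g) {
    x <- m[, g][!is.na(m[, g])]
    amean <- mean(x)
    mad_cq <- mean(abs(x - amean))
    ct <- stats::cor.test(mi[, g], index)
    data.frame(gene = g, n = length(x), min_cq = min(x), max_cq = max(x),
               mean_cq = amean, geo_mean_cq = gm_mean(x),
               sd_cq = mad_cq, cv = 100 * mad_cq / amean,
               r = unname(ct$estimate), p_value = ct$p.value,
               reliable = mad_cq <= 1, stringsAsFactors = FALSE)
  }))
  rownames(stats_df) <- NULL
  structure(list(stats = stats_df, index = index,
                 scores = stability_scores(
                   "bestkeeper", setNames(stats_df$r, stats_df$gene),
                   "higher_better", gene_order = colnames(m))),
            class = "bestkeeper_result")
}

#' Comparative delta-Cq stability
#'
#' For every unordered gene pair the per-sample Cq difference is formed and
#' its standard deviation (n-1 denominator) computed; a gene's score is the
#' mean SD over all pairs that contain it. A gene whose offset to every
#' other candidate is constant across samples scores 0.
#'
#' @param cq a `cq_table` or samples-by-genes Cq matrix.
#' @return a `stability_scores` object (`lower_better`), with the per-pair
#'   SD matrix attached as attribute `pair_sd`.
#' @export
comparative_delta_cq <- function(cq) {
  m <- cq_as_matrix(cq)
  if (ncol(m) < 3L)
    stop_refstab("comparative delta-Cq needs at least 3 genes",
                 "refstab_invalid_argument")
  genes <- colnames(m)
  pair_sd <- matrix(NA_real_, length(genes), length(genes),
                    dimnames = list(genes, genes))
  for (a in seq_along(genes)[-length(genes)]) {
    for (b in (a + 1L):length(genes)) {
      d <- m[, a] - m[, b]
      s <- sd_n1(d)
      if (is.na(s))
        warning(sprintf("pair (%s, %s): fewer than 2 complete samples; skipped",
                        genes[a], genes[b]))
      pair_sd[a, b] <- pair_sd[b, a] <- s
    }
  }
  score <- vapply(genes, function(g)
    mean(pair_sd[g, setdiff(genes, g)], na.rm = TRUE), numeric(1))
  out <- stability_scores("delta_cq", score, "lower_better",
                          gene_order = genes)
  attr(out, "pair_sd") <- pair_sd
  out
}

#' Per-algorithm stability scores with a deterministic ranking
#'
#' @param algorithm one of `genorm`, `normfinder`, `bestkeeper`, `delta_cq`.
#' @param score named numeric vector of per-gene scores.
#' @param orientation `"lower_better"` or `"higher_better"`.
#' @param gene_order input gene order used to break ties (stable sort).
#' @return a `stability_scores` list with `algorithm`, `score`,
#'   `orientation`, `ranking` (gene names, rank 1 = most stable).
#' @export
stability_scores <- function(algorithm, score,
                             orientation = c("lower_better", "higher_better"),
                             gene_order = names(score)) {
  orientation <- match.arg(orientation)
  stopifnot(!is.null(names(score)))
  key <- if (orientation == "lower_better") score else -score
  ord <- order(key, match(names(score), gene_order))
  structure(list(algorithm = algorithm, score = score,
                 orientation = orientation, ranking = names(score)[ord]),
            class = "stability_scores")
}

#' @exportS3Method base::print
print.stability_scores <- function(x, ...) {
  cat(sprintf("%s stability (%s):\n", x$algorithm, x$orientation))
  print(data.frame(rank = seq_along(x$ranking), gene = x$ranking,
                   score = round(unname(x$score[x$ranking]), 4)))
  invisible(x)
}

rq_as_matrix <- function(rq) {
  if (inherits(rq, "rq_matrix")) return(rq$rq)
  m <- as.matrix(rq)
  if (any(!is.na(m) & m <= 0))
    stop_refstab("relative quantities must be positive",
                 "refstab_validation_error")
  m
}

cq_as_matrix <- function(cq) {
  if (inherits(cq, "cq_table")) {
    samples <- sort(unique(cq$sample_id))
    genes <- unique(cq$gene)
    keep <- cq$qc_flag == "pass"
    m <- matrix(NA_real_, length(samples), length(genes),
                dimnames = list(samples, genes))
    m[cbind(match(cq$sample_id[keep], samples),
            match(cq$gene[keep], genes))] <- cq$mean_cq[keep]
    return(m)
  }
  as.matrix(cq)
}

#' Run all four classic stability algorithms
#'
#' Convenience wrapper producing a ranking ensemble ready for consensus
#' aggregation. geNorm and NormFinder run on relative quantities;
#' BestKeeper and comparative delta-Cq run on Cq values. When only an RQ
#' matrix is given, Cq-scale input for the latter two is reconstructed as
#' -log2(RQ), which preserves all distances under perfect doubling.
#'
#' @param rq an `rq_matrix`.
#' @param cq optional samples-by-genes Cq matrix matching `rq`'s layout.
#' @param groups group labels for NormFinder (defaults to `rq$group`).
#' @return list of the four result objects plus `ensemble`, a
#'   [ranking_ensemble()] of the four rankings and score vectors.
#' @export
stability_suite <- function(rq, cq = NULL, groups = NULL) {
  m <- rq_as_matrix(rq)
  # pseudo-Cq reconstruction: a 30-cycle baseline keeps values positive;
  # BestKeeper's MAD and r and the delta-Cq SDs are shift-invariant
  if (is.null(cq)) cq <- 30 - log2(m)
  gn <- genorm(rq)
  nf <- normfinder(rq, groups = groups)
  bk <- bestkeeper(cq)
  dc <- comparative_delta_cq(cq)
  ens <- ranking_ensemble(list(gn$scores, nf$scores, bk$scores, dc))
  list(genorm = gn, normfinder = nf, bestkeeper = bk, delta_cq = dc,
       ensemble = ens)
}
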