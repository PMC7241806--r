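#' Normalised relative quantities for genes of interest
#'
#' Divides a gene of interest's relative quantity by the per-sample
#' geometric mean of the chosen reference genes' relative quantities (the
#' normalisation factor), and propagates uncertainty by first-order
#' (delta-method) quadrature on the log scale:
#' `rSE(NRQ) = sqrt( rSE(goi)^2 + (1/k^2) * sum_g rSE(ref_g)^2 )`
#' for k reference genes.
#'
#' @param goi_rq named numeric vector of positive GOI relative quantities
#'   per sample.
#' @param refs an `rq_matrix` (its `rel_se` is used when present) or a
#'   positive samples-by-genes matrix of reference RQs.
#' @param ref_genes reference combination; default all columns of `refs`.
#' @param goi_se per-sample relative standard errors of the GOI RQ
#'   (optional; default 0).
#' @param ref_se samples-by-genes matrix of reference relative standard
#'   errors (optional; taken from `refs$rel_se` when available).
#' @return an `nrq_result` data.frame: `sample_id`, `nrq`, `rel_se`,
#'   `norm_factor`; reference combination in attribute `ref_genes`. Samples
#'   lacking a reference value get `NA` with a warning.
#' @export
nrq <- function(goi_rq, refs, ref_genes = NULL, goi_se = NULL,
                ref_se = NULL) {
  rm <- rq_as_matrix(refs)
  if (inherits(refs, "rq_matrix") && is.null(ref_se)) ref_se <- refs$rel_se
  ref_genes <- ref_genes %||% colnames(rm)
  miss <- setdiff(ref_genes, colnames(rm))
  if (length(miss))
    stop_refstab(sprintf("reference gene(s) not found: %s",
                         paste(miss, collapse = ", ")),
                 "refstab_invalid_argument")
  if (is.null(names(goi_rq)))
    stop_refstab("goi_rq must be named by sample", "refstab_invalid_argument")
  if (any(!is.na(goi_rq) & goi_rq <= 0))
    stop_refstab("relative quantities must be > 0", "refstab_validation_error")
  samples <- names(goi_rq)
  common <- intersect(samples, rownames(rm))
  if (!length(common))
    stop_refstab("no samples in common between GOI and references",
                 "refstab_invalid_argument")
  k <- length(ref_genes)
  rsub <- rm[common, ref_genes, drop = FALSE]
  nf <- apply(rsub, 1, function(x) if (anyNA(x)) NA_real_ else gm_mean(x))
  if (anyNA(nf))
    warning(sprintf("%d sample(s) missing a reference value; NRQ set missing",
                    sum(is.na(nf))))
  goi_se <- goi_se %||% setNames(rep(0, length(samples)), samples)
  se_ref <- if (is.null(ref_se)) matrix(0, length(common), k)
            else { s <- ref_se[common, ref_genes, drop = FALSE]
                   s[is.na(s)] <- 0; s }
  out <- data.frame(
    sample_id = common,
    nrq = unname(goi_rq[common] / nf),
    rel_se = sqrt(unname(goi_se[common])^2 + rowSums(se_ref^2) / k^2),
    norm_factor = unname(nf),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ref_genes") <- ref_genes
  class(out) <- c("nrq_result", "data.frame")
  out
}
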