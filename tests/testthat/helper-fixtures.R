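# in-code fixtures shared across test files

write_demo_replicates <- function(path,
                                  rows = c("S1,control,P1,R1,ACTB,1,19.8",
                                           "S1,control,P1,R1,ACTB,2,19.9",
                                           "S1,control,P1,R1,ACTB,3,20.0")) {
  writeLines(c("sample,group,plate,run,gene,replicate,cq", rows), path)
  path
}

# minimal positive RQ matrix with sample rownames
demo_rq <- function(m, groups = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  rq_matrix(m, group = groups %||% rep("all", nrow(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-gene lognormal sample with shared random effect; used by several
# mixed-model tests
sim_two_gene <- function(n, sigma_b2 = 3, sigma_e2 = 1, groups = NULL) {
  b <- stats::rnorm(n, 0, sqrt(sigma_b2))
  m <- cbind(A = 2^(b + stats::rnorm(n, 0, sqrt(sigma_e2))),
             B = 2^(b + stats::rnorm(n, 0, sqrt(sigma_e2))))
  rownames(m) <- sprintf("s%03d", seq_len(n))
  rq_matrix(m, group = groups %||% rep("all", n))
}

table4_rankings <- function() {
  list(
    normfinder = c("HMBS", "PABPN1", "YWHAG", "ACTB", "YWHAZ",
                   "TBP", "HPRT", "SDHA", "18S", "GAPDH"),
    genorm = c("ACTB", "HMBS", "PABPN1", "YWHAZ", "YWHAG",
               "TBP", "HPRT", "SDHA", "GAPDH", "18S"),
    bestkeeper = c("HMBS", "YWHAG", "PABPN1", "YWHAZ", "ACTB",
                   "HPRT", "TBP", "GAPDH", "SDHA", "18S"),
    delta_cq = c("HMBS", "PABPN1", "ACTB", "YWHAG", "YWHAZ",
                 "TBP", "HPRT", "SDHA", "GAPDH", "18S"))
}

random_ensemble <- function(n_items, n_lists) {
  items <- LETTERS[seq_len(n_items)]
  ranking_ensemble(lapply(seq_len(n_lists), function(i) sample(items)))
}
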