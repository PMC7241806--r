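#' Model specification for ICC-based stability
#'
#' The stability of a reference-gene combination is measured as the
#' intraclass correlation of its genes' expression values within samples
#' after removing gene, treatment-group and gene-by-group fixed effects:
#' the genes act as repeated "raters" of each sample, samples are nested in
#' treatment groups, and ICC = sigma2_sample / (sigma2_sample +
#' sigma2_error) from a REML fit. Systematic (group and interaction)
#' effects are tested by a likelihood-ratio test on ML refits.
#'
#' @param response `"log2_rq"` (default; log2 of relative quantities) or
#'   `"neg_cq"` (negative Cq, for efficiency-1-assumed workflows).
#' @param ci `"fband"` (F-based consistency interval; exact for balanced
#'   complete data) or `"bootstrap"` (parametric bootstrap; the fallback
#'   for unbalanced or missing data).
#' @param conf_level two-sided confidence level, default 0.95.
#' @param n_boot parametric-bootstrap resamples, default 1000.
#' @return an `lmm_spec` list.
#' @export
lmm_spec <- function(response = c("log2_rq", "neg_cq"),
                     ci = c("auto", "fband", "bootstrap"),
                     conf_level = 0.95, n_boot = 1000L) {
  response <- match.arg(response)
  ci <- match.arg(ci)
  assert_scalar_num(conf_level, "conf_level", lower = 0, upper = 1,
                    open_lower = TRUE, open_upper = TRUE)
  assert_scalar_num(n_boot, "n_boot", lower = 1)
  structure(list(response = response, ci = ci, conf_level = conf_level,
                 n_boot = as.integer(n_boot)), class = "lmm_spec")
}

# long-format modelling frame for a gene combination
combo_frame <- function(expr, groups, combo, response) {
  m <- rq_as_matrix(expr)
  groups <- groups %||% (if (inherits(expr, "rq_matrix")) expr$group)
  if (is.null(groups)) groups <- rep("all", nrow(m))
  miss <- setdiff(combo, colnames(m))
  if (length(miss))
    stop_refstab(sprintf("gene(s) not in expression matrix: %s",
                         paste(miss, collapse = ", ")),
                 "refstab_invalid_argument")
  sub <- m[, combo, drop = FALSE]
  y <- if (response == "neg_cq") -sub else log2(sub)
  df <- data.frame(
    y = as.vector(y),
    sample = factor(rep(rownames(m), times = length(combo))),
    gene = factor(rep(combo, each = nrow(m)), levels = combo),
    group = factor(rep(as.character(groups), times = length(combo))))
  df <- df[is.finite(df$y), , drop = FALSE]
  droplevels(df)
}

# closed-form REML variance components for a balanced complete two-way
# layout (samples x genes, samples nested in groups): equals the lme4 REML
# solution, with the boundary truncated at zero
balanced_anova_fit <- function(df, k) {
  has_groups <- nlevels(df$group) > 1L
  form <- if (has_groups) y ~ group + sample + gene + gene:group
          else y ~ sample + gene
  an <- stats::anova(stats::lm(form, data = df))
  ms_s <- an["sample", "Mean Sq"]
  df_s <- an["sample", "Df"]
  ms_e <- an["Residuals", "Mean Sq"]
  df_e <- an["Residuals", "Df"]
  sigma2_e <- ms_e
  sigma2_s <- max(0, (ms_s - ms_e) / k)
  list(sigma2_sample = sigma2_s, sigma2_error = sigma2_e,
       ms_sample = ms_s, ms_error = ms_e, df_sample = df_s, df_error = df_e)
}

# F-based consistency CI on the ICC: each bound is
# (F/F_crit - 1)/(F/F_crit + k - 1), truncated to [0, 1]
fband_ci <- function(ms_s, ms_e, df_s, df_e, k, conf_level) {
  alpha <- 1 - conf_level
  F_obs <- ms_s / ms_e
  fl <- F_obs / stats::qf(1 - alpha / 2, df_s, df_e)
  fu <- F_obs * stats::qf(1 - alpha / 2, df_e, df_s)
  lower <- (fl - 1) / (fl + k - 1)
  upper <- (fu - 1) / (fu + k - 1)
  c(lower = min(max(lower, 0), 1), upper = min(max(upper, 0), 1))
}

icc_from_lmer <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_s <- vc$vcov[vc$grp == "sample"]
  s2_e <- vc$vcov[vc$grp == "Residual"]
  c(sample = s2_s, error = s2_e,
    icc = if (s2_s + s2_e > 0) s2_s / (s2_s + s2_e) else 0)
}

#' Fit the mixed-effects ICC stability model for one gene combination
#'
#' Fits `response ~ gene + group + gene:group + (1 | sample)` by REML and
#' reports the combination's ICC with a two-sided confidence interval, plus
#' a likelihood-ratio test (ML full vs ML without group and interaction,
#' chi-square with (g-1)k degrees of freedom) for systematic treatment
#' effects. Balanced complete data use the closed-form REML solution and
#' the F-based consistency interval; unbalanced or missing data fall back
#' to a numerical REML fit with a seeded parametric-bootstrap interval.
#'
#' @param expr an `rq_matrix` (or samples-by-genes matrix of positive RQs).
#' @param groups treatment-group label per sample (defaults to the
#'   `rq_matrix` groups; a single group disables the LRT).
#' @param combo character vector of at least 2 gene names.
#' @param spec an [lmm_spec()].
#' @param seed seed for the bootstrap interval (required when used).
#' @return an `icc_result`: `combination`, `sigma2_sample`, `sigma2_error`,
#'   `icc`, `lower`, `upper`, `width`, `conf_level`, `lrt_chisq`, `lrt_df`,
#'   `lrt_p`, `ci_method`, `degenerate` (zero sample-variance flag),
#'   `truncated` (CI truncation flag).
#' @export
fit_combination <- function(expr, groups = NULL, combo, spec = lmm_spec(),
                            seed = NULL) {
  if (length(combo) < 2L)
    stop_refstab("a combination needs at least 2 genes",
                 "refstab_invalid_argument")
  df <- combo_frame(expr, groups, combo, spec$response)
  k <- nlevels(df$gene)
  g <- nlevels(df$group)
  n <- nlevels(df$sample)
  counts <- table(df$sample, df$gene)
  balanced <- all(counts == 1L) &&
    (g == 1L || length(unique(table(unique(df[c("sample", "group")])$group))) == 1L)
  ci_method <- spec$ci
  if (ci_method == "auto") ci_method <- if (balanced) "fband" else "bootstrap"
  if (ci_method == "fband" && !balanced) {
    warning("data unbalanced/incomplete: switching to bootstrap CI")
    ci_method <- "bootstrap"
  }

  if (balanced) {
    ba <- balanced_anova_fit(df, k)
    s2_s <- ba$sigma2_sample; s2_e <- ba$sigma2_error
  } else {
    fit <- lmer_quiet(lmm_formula(g), df, REML = TRUE)
    v <- icc_from_lmer(fit)
    s2_s <- v["sample"]; s2_e <- v["error"]
  }
  icc <- if (s2_s + s2_e > 0) unname(s2_s / (s2_s + s2_e)) else 0
  degenerate <- s2_s <= 0

  truncated <- FALSE
  if (ci_method == "fband") {
    ci <- fband_ci(ba$ms_sample, ba$ms_error, ba$df_sample, ba$df_error, k,
                   spec$conf_level)
    raw_l <- (ba$ms_sample / ba$ms_error /
                stats::qf(1 - (1 - spec$conf_level) / 2, ba$df_sample,
                          ba$df_error) - 1)
    truncated <- ci["lower"] <= 0 && raw_l < -1e-12 || ci["upper"] >= 1
  } else {
    if (is.null(seed))
      stop_refstab("bootstrap CI requires a seed", "refstab_invalid_argument")
    ci <- bootstrap_icc_ci(df, g, spec, seed)
  }
  lower <- min(unname(ci["lower"]), icc)
  upper <- max(unname(ci["upper"]), icc)

  lrt <- list(chisq = NA_real_, df = NA_integer_, p = NA_real_,
              method = NA_character_)
  if (g > 1L)
    lrt <- lrt_systematic(df, g, k,
                          method = if (balanced) "exact" else "chisq")

  structure(list(combination = combo, sigma2_sample = unname(s2_s),
                 sigma2_error = unname(s2_e), icc = icc,
                 lower = lower, upper = upper, width = upper - lower,
                 conf_level = spec$conf_level,
                 lrt_chisq = lrt$chisq, lrt_df = lrt$df, lrt_p = lrt$p,
                 lrt_method = lrt$method,
                 ci_method = ci_method, degenerate = degenerate,
                 truncated = truncated),
            class = "icc_result")
}

lmm_formula <- function(g) {
  if (g > 1L) y ~ gene + group + gene:group + (1 | sample)
  else y ~ gene + (1 | sample)
}

lmer_quiet <- function(formula, data, REML) {
  withCallingHandlers(
    suppressMessages(lme4::lmer(formula, data = data, REML = REML,
                                control = lme4::lmerControl(
                                  check.conv.singular = "ignore"))),
    warning = function(w) {
      if (grepl("singular|converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# Systematic-effect test: group + gene:group jointly.
# The ML likelihood-ratio statistic (full vs gene-only model, df (g-1)k)
# is always computed and reported. Its p-value comes from one of two
# references:
#  * exact (balanced complete data): the design is orthogonal, so the
#    group main effect has an exact F-test against the between-sample
#    stratum (df g-1, n-g) and the gene:group interaction an exact F-test
#    against the residual stratum (df (g-1)(k-1), (n-g)(k-1)); the two are
#    independent under the null and are Fisher-combined
#    (-2 sum log p ~ chi-square_4). Finite-sample calibrated at any n.
#  * chisq: the asymptotic chi-square reference on the ML statistic; used
#    for unbalanced/incomplete data, anti-conservative at small n.
lrt_systematic <- function(df, g, k, method = c("exact", "chisq")) {
  method <- match.arg(method)
  full <- lmer_quiet(y ~ gene + group + gene:group + (1 | sample), df,
                     REML = FALSE)
  reduced <- lmer_quiet(y ~ gene + (1 | sample), df, REML = FALSE)
  chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                         as.numeric(stats::logLik(reduced))))
  dof <- (g - 1L) * k
  p <- if (method == "exact") exact_systematic_p(df, g, k)
       else stats::pchisq(chisq, dof, lower.tail = FALSE)
  list(chisq = chisq, df = dof, p = p, method = method)
}

exact_systematic_p <- function(df, g, k) {
  # group main effect on the per-sample gene averages (one-way ANOVA)
  avg <- stats::aggregate(y ~ sample + group, df, mean)
  a1 <- stats::anova(stats::lm(y ~ group, data = avg))
  p_group <- a1["group", "Pr(>F)"]
  # interaction against the residual stratum of the full two-way layout
  a2 <- stats::anova(stats::lm(y ~ group + sample + gene + gene:group,
                               data = df))
  p_int <- a2["group:gene", "Pr(>F)"]
  if (is.na(p_int)) p_int <- a2["gene:group", "Pr(>F)"]
  if (is.na(p_int)) return(p_group)     # k = 1 safeguard
  stats::pchisq(-2 * (log(p_group) + log(p_int)), df = 4,
                lower.tail = FALSE)
}

# parametric bootstrap percentile CI for the ICC
bootstrap_icc_ci <- function(df, g, spec, seed) {
  set.seed(as.integer(seed))
  fit <- lmer_quiet(lmm_formula(g), df, REML = TRUE)
  sims <- stats::simulate(fit, nsim = spec$n_boot)
  boot <- vapply(seq_len(spec$n_boot), function(b) {
    d2 <- df
    d2$y <- sims[[b]]
    icc_from_lmer(lmer_quiet(lmm_formula(g), d2, REML = TRUE))["icc"]
  }, numeric(1))
  alpha <- 1 - spec$conf_level
  q <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  c(lower = min(max(q[1], 0), 1), upper = min(max(q[2], 0), 1))
}

#' Reliability label from an ICC interval
#'
#' Bands: below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, 0.9 and above
#' excellent. The label combines the band of the lower confidence limit
#' with the band of the point estimate ("moderate to good" when they
#' differ).
#'
#' @param res an `icc_result`, or a numeric ICC (then supply `lower`).
#' @param lower lower confidence limit when `res` is numeric.
#' @return a character label.
#' @export
classify_reliability <- function(res, lower = NULL) {
  if (inherits(res, "icc_result")) {
    point <- res$icc; lo <- res$lower
  } else {
    point <- res; lo <- lower
    if (is.null(lo)) stop_refstab("lower limit required",
                                  "refstab_invalid_argument")
  }
  band <- function(x) {
    if (x < 0.5) "poor" else if (x < 0.75) "moderate"
    else if (x < 0.9) "good" else "excellent"
  }
  b_lo <- band(lo); b_pt <- band(point)
  if (identical(b_lo, b_pt)) b_lo else paste(b_lo, "to", b_pt)
}

#' Search reference-gene combinations by ICC lower confidence bound
#'
#' Evaluates every combination of a given size, smallest first, ranking by
#' the lower 95% confidence limit of the ICC (ties by narrower interval,
#' then input order). After finishing a size, the search stops if the best
#' lower bound did not exceed the best at the previous size — adding genes
#' is then not buying reliability. Combinations whose systematic-effect LRT
#' is significant (p <= 0.05) are flagged as unsuitable but not removed.
#'
#' @param expr an `rq_matrix` or positive samples-by-genes matrix.
#' @param groups group label per sample.
#' @param candidates candidate gene names (default: all columns).
#' @param max_k largest combination size to consider, default 5.
#' @param spec an [lmm_spec()].
#' @param seed seed passed to bootstrap CIs when needed.
#' @param lrt_alpha flag threshold for the systematic-effect LRT.
#' @return a `combination_search` list: `results` (data.frame over all
#'   evaluated combinations), `fits` (list of `icc_result`), `selected`,
#'   `stop_reason` (`"lower_bound_no_increase"` or `"max_size_reached"`).
#' @export
search_combinations <- function(expr, groups = NULL, candidates = NULL,
                                max_k = 5L, spec = lmm_spec(), seed = NULL,
                                lrt_alpha = 0.05) {
  m <- rq_as_matrix(expr)
  candidates <- candidates %||% colnames(m)
  if (length(candidates) < 3L)
    stop_refstab("need at least 3 candidate genes",
                 "refstab_invalid_argument")
  max_k <- min(max_k, length(candidates))
  fits <- list(); rows <- list()
  best_by_size <- numeric(0)
  stop_reason <- "max_size_reached"
  for (k in 2:max_k) {
    combos <- utils::combn(candidates, k, simplify = FALSE)
    for (cmb in combos) {
      res <- tryCatch(fit_combination(expr, groups, cmb, spec, seed = seed),
                      error = function(e) {
                        warning(sprintf("fit failed for {%s}: %s",
                                        paste(cmb, collapse = ", "),
                                        conditionMessage(e)))
                        NULL
                      })
      if (is.null(res)) next
      fits[[length(fits) + 1L]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        combination = paste(cmb, collapse = " x "), k = k,
        icc = res$icc, lower = res$lower, upper = res$upper,
        width = res$width, lrt_p = res$lrt_p,
        systematic_flag = !is.na(res$lrt_p) && res$lrt_p <= lrt_alpha,
        reliability = classify_reliability(res), stringsAsFactors = FALSE)
    }
    size_rows <- do.call(rbind, rows)
    best_k <- max(size_rows$lower[size_rows$k == k], -Inf)
    best_by_size <- c(best_by_size, best_k)
    if (k > 2L && best_k <= best_by_size[length(best_by_size) - 1L]) {
      stop_reason <- "lower_bound_no_increase"
      break
    }
  }
  results <- do.call(rbind, rows)
  ord <- order(-results$lower, results$width, seq_len(nrow(results)))
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, fits = fits[ord],
                 selected = fits[ord][[1L]], stop_reason = stop_reason),
            class = "combination_search")
}

#' @exportS3Method base::print
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC stability of {%s}\n",
              paste(x$combination, collapse = ", ")))
  cat(sprintf("  ICC = %.3f  %d%% CI (%.3f, %.3f)  width %.3f  [%s]\n",
              x$icc, round(100 * x$conf_level), x$lower, x$upper, x$width,
              classify_reliability(x)))
  if (!is.na(x$lrt_p))
    cat(sprintf("  systematic-effects LRT: chisq = %.3f, df = %d, p = %.4f\n",
                x$lrt_chisq, x$lrt_df, x$lrt_p))
  invisible(x)
}

#' @exportS3Method base::print
print.combination_search <- function(x, ...) {
  cat(sprintf("combination search (%d fits, stop: %s)\n",
              nrow(x$results), x$stop_reason))
  print(utils::head(x$results, 10))
  invisible(x)
}

#' Bonett minimum sample size for ICC precision
#'
#' Smallest number of samples (subjects) needed so that the two-sided
#' confidence interval of an intraclass correlation rho, measured with k
#' raters (reference genes), has expected width w:
#' `n = ceil( 8 z^2 (1-rho)^2 (1+(k-1)rho)^2 / (k (k-1) w^2) + 1 )`.
#'
#' @param rho anticipated ICC, in [0, 1].
#' @param k number of raters (genes), at least 2.
#' @param width desired total CI width, in (0, 1].
#' @param conf_level two-sided confidence level, default 0.95
#'   (z = 1.959964).
#' @param digits rho is rounded to this many decimals before evaluation
#'   (default 2, the calculator entry convention); `NULL` disables.
#' @return integer minimum sample size.
#' @examples
#' bonett_sample_size(0.86, k = 2, width = 0.1)  # 106
#' @export
bonett_sample_size <- function(rho, k, width, conf_level = 0.95,
                               digits = 2) {
  assert_scalar_num(rho, "rho", lower = 0, upper = 1)
  assert_scalar_num(width, "width", lower = 0, upper = 1, open_lower = TRUE)
  assert_scalar_num(conf_level, "conf_level", lower = 0, upper = 1,
                    open_lower = TRUE, open_upper = TRUE)
  if (!is.numeric(k) || length(k) != 1L || k < 2)
    stop_refstab("k must be an integer >= 2 (formula undefined below 2)",
                 "refstab_invalid_argument")
  if (!is.null(digits)) rho <- round(rho, digits)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n <- 8 * z^2 * (1 - rho)^2 * (1 + (k - 1) * rho)^2 /
    (k * (k - 1) * width^2) + 1
  as.integer(ceiling(n - 1e-9))
}

#' Sample-size planning table over a grid of ICCs, panel sizes and widths
#'
#' Cross-product of [bonett_sample_size()] over anticipated reliability
#' values, numbers of reference genes and CI widths; the default grid spans
#' 2-5 genes, ICC 0.7-0.9 and widths 0.1 and 0.2.
#'
#' @param rhos anticipated ICC values.
#' @param ks numbers of reference genes.
#' @param widths CI widths.
#' @param conf_level confidence level.
#' @return data.frame with columns `rho`, `k`, `width`, `n`.
#' @export
sample_size_table <- function(rhos = seq(0.7, 0.9, by = 0.02),
                              ks = 2:5, widths = c(0.1, 0.2),
                              conf_level = 0.95) {
  if (!length(rhos) || !length(ks) || !length(widths))
    stop_refstab("empty grid", "refstab_invalid_argument")
  grid <- expand.grid(rho = rhos, k = ks, width = widths,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n <- mapply(bonett_sample_size, rho = grid$rho, k = grid$k,
                   width = grid$width,
                   MoreArgs = list(conf_level = conf_level))
  grid
}

#' Variance of a product of two random variables
#'
#' Exact second-moment identities for Var(XY), used to reason about the
#' variance of a normalised quantity (gene of interest times the inverse
#' normalisation factor). In dependent mode:
#' `Var(XY) = Cov(X^2, Y^2) + (Var(X)+mu_x^2)(Var(Y)+mu_y^2)
#'            - (Cov(X,Y) - mu_x mu_y)^2`;
#' for independent X, Y (all covariances zero) this reduces to
#' `Var(X)Var(Y) + Var(X) mu_y^2 + Var(Y) mu_x^2`.
#'
#' @param var_x,var_y variances of X and Y.
#' @param mu_x,mu_y means of X and Y.
#' @param cov_xy Cov(X, Y) (dependent mode only).
#' @param cov_x2y2 Cov(X^2, Y^2) (dependent mode only).
#' @param independent use the independence simplification.
#' @return the variance of the product XY.
#' @export
variance_of_product <- function(var_x, var_y, mu_x, mu_y,
                                cov_xy = NULL, cov_x2y2 = NULL,
                                independent = FALSE) {
  assert_scalar_num(var_x, "var_x", lower = 0)
  assert_scalar_num(var_y, "var_y", lower = 0)
  assert_scalar_num(mu_x, "mu_x")
  assert_scalar_num(mu_y, "mu_y")
  if (independent)
    return(var_x * var_y + var_x * mu_y^2 + var_y * mu_x^2)
  if (is.null(cov_xy) || is.null(cov_x2y2))
    stop_refstab("dependent mode requires cov_xy and cov_x2y2",
                 "refstab_invalid_argument")
  cov_x2y2 + (var_x + mu_x^2) * (var_y + mu_y^2) - (cov_xy - mu_x * mu_y)^2
}
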