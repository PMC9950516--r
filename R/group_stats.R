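#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @return A one-row tibble: `statistic` (W), `p_value`, `n`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) abort("Shapiro-Wilk requires at least 3 values")
  if (length(unique(values)) == 1) {
    abort("normality undefined for a constant vector")
  }
  sw <- shapiro.test(values)
  tibble(statistic = unname(sw$statistic), p_value = sw$p.value,
         n = length(values))
}

#' Two-sample t comparison
#'
#' Student (pooled-variance) two-sample t-test by default, with the Welch
#' variant switchable; two-sided p-value.
#'
#' @param a,b Numeric vectors (each `n >= 2`).
#' @param variant `"student"` (pooled) or `"welch"`.
#' @param variable Optional variable name carried into the result.
#' @return A one-row tibble of class `fc_comparison`: group means/SDs/n,
#'   `t`, `df`, `p_value`.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch"),
                         variable = NA_character_) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(comparison_row(variable, a, b, t = 0, df = length(a) +
                              length(b) - 2, p = 1))
    }
    abort("zero variance in both groups with unequal means")
  }
  tt <- t.test(a, b, var.equal = (variant == "student"))
  comparison_row(variable, a, b, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
}

comparison_row <- function(variable, a, b, t, df, p) {
  out <- tibble(
    variable = variable,
    mean_a = mean(a), sd_a = sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = sd(b), n_b = length(b),
    t = t, df = df, p_value = p)
  class(out) <- c("fc_comparison", class(out))
  out
}

#' Student t from summary statistics
#'
#' Pooled-variance two-sample t computed directly from group means,
#' standard deviations and sizes -- e.g. to recompute a published t-value
#' from a printed `mean +/- SD` table.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return A one-row tibble: `t`, `df`, `p_value`.
#' @export
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) abort("each group needs n >= 2")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- (mean_a - mean_b) / se
  tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values and the rejection set at level `q`.
#' Benjamini-Yekutieli is available for dependence-robust control.
#'
#' @param pvalues Raw p-values in `[0, 1]` (`NA` allowed; never rejected).
#' @param q FDR level.
#' @param method `"BH"` (default) or `"BY"`.
#' @return A tibble: `p`, `p_adj`, `reject`.
#' @export
bh_fdr <- function(pvalues, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(pvalues, method = method)
  tibble(p = pvalues, p_adj = adj,
         reject = !is.na(adj) & adj <= q)
}

#' Edgewise two-group comparison with FDR correction
#'
#' Mass-univariate two-sample t-tests on the Fisher-z value of every
#' unordered node pair, Benjamini-Hochberg corrected across all pairs;
#' returns each edge with its effect direction and significance at the
#' corrected level. Edges with degenerate variance in both groups are
#' excluded (counted in attribute `n_degenerate`).
#'
#' @param z_a,z_b Lists of z matrices (or `fc_conn` objects) per group.
#' @param alpha Significance level applied to adjusted p-values.
#' @param variant t-test variant, see [two_sample_t()].
#' @return A tibble with one row per node pair: `node_i`, `node_j`,
#'   `mean_a`, `mean_b`, `t`, `p`, `p_adj`, `significant`, `direction`
#'   (`"a>b"`/`"a<b"`).
#' @export
edgewise_comparison <- function(z_a, z_b, alpha = 0.01,
                                variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(z_a) < 2 || length(z_b) < 2) {
    abort("each group needs at least 2 subjects")
  }
  get_z <- function(m) if (inherits(m, "fc_conn")) m$z else m
  nodes <- if (inherits(z_a[[1]], "fc_conn")) z_a[[1]]$nodes else
    seq_len(nrow(get_z(z_a[[1]])))
  ut <- which(upper.tri(get_z(z_a[[1]])), arr.ind = TRUE)
  stack <- function(zl) {
    vapply(zl, function(m) get_z(m)[ut], numeric(nrow(ut)))
  }
  A <- stack(z_a)  # n_edges x n_subj_a
  B <- stack(z_b)
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  if (variant == "student") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tstat <- (ma - mb) / se
    dfv <- rep(df, length(tstat))
  } else {
    se <- sqrt(va / na + vb / nb)
    tstat <- (ma - mb) / se
    dfv <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- 2 * pt(-abs(tstat), dfv)
  degen <- !is.finite(tstat)
  if (any(degen)) {
    inform(sprintf("%d edge(s) with degenerate variance excluded",
                   sum(degen)))
    p[degen] <- NA_real_
  }
  fdr <- bh_fdr(p, q = alpha)
  out <- tibble(
    node_i = nodes[ut[, 1]], node_j = nodes[ut[, 2]],
    mean_a = ma, mean_b = mb, t = tstat, p = p, p_adj = fdr$p_adj,
    significant = fdr$reject,
    direction = ifelse(ma > mb, "a>b", "a<b"))
  attr(out, "n_degenerate") <- sum(degen)
  out
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' @param counts 2 x 2 matrix of non-negative integer counts.
#' @param correct Apply Yates continuity correction.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) abort("counts must be 2 x 2")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero marginal in the 2 x 2 table")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Correlation between a network metric and a CRS-R scale
#'
#' Pearson correlation (with two-sided p) between per-subject metric values
#' and the chosen Coma Recovery Scale-Revised scale.
#'
#' @param metric_values Per-subject metric values (e.g. region-averaged
#'   nodal AUCs).
#' @param scores Matching CRS-R scores (total or one subscale).
#' @param metric,scale Optional labels carried into the result.
#' @return A one-row tibble: `metric`, `scale`, `r`, `p_value`, `n`.
#' @export
crsr_correlation <- function(metric_values, scores,
                             metric = NA_character_,
                             scale = NA_character_) {
  ok <- is.finite(metric_values) & is.finite(scores)
  x <- metric_values[ok]; y <- scores[ok]
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0) abort("constant input; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble(metric = metric, scale = scale, r = unname(ct$estimate),
         p_value = ct$p.value, n = length(x))
}
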