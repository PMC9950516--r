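# realize a vector with exactly the requested mean and SD
vec_with_summary <- function(m, s, n, seed = 1) {
  withr::with_seed(seed, z <- rnorm(n))
  m + s * (z - mean(z)) / sd(z)
}

test_that("Shapiro-Wilk discriminates normal from exponential samples", {
  res <- withr::with_seed(20, {
    norm_p <- replicate(100, normality_check(rnorm(500))$p_value)
    exp_p <- replicate(100, normality_check(rexp(500))$p_value)
    list(norm_p = norm_p, exp_p = exp_p)
  })
  expect_gte(mean(res$norm_p > 0.05), 0.90)
  expect_gte(mean(res$exp_p < 0.05), 0.90)
  expect_error(normality_check(rep(3, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "at least 3")
})

test_that("two-sample t: identity, symmetry, and summary equivalence", {
  a <- c(1, 2, 3, 4)
  cmp <- two_sample_t(a, a)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p_value, 1)

  b <- c(2, 3, 5, 7)
  c1 <- two_sample_t(a, b)
  c2 <- two_sample_t(b, a)
  expect_equal(c1$t, -c2$t)
  expect_equal(c1$p_value, c2$p_value)

  # Student t from summaries equals t from vectors realizing those summaries
  x <- vec_with_summary(0.322, 0.080, 16, seed = 21)
  y <- vec_with_summary(0.225, 0.080, 15, seed = 22)
  ts <- t_from_summary(0.322, 0.080, 16, 0.225, 0.080, 15)
  tv <- two_sample_t(x, y)
  expect_equal(ts$t, tv$t, tolerance = 1e-10)
  expect_equal(ts$df, 29)

  # Welch variant differs when variances do
  w <- two_sample_t(c(1, 2, 3), c(10, 20, 30, 40), variant = "welch")
  s <- two_sample_t(c(1, 2, 3), c(10, 20, 30, 40), variant = "student")
  expect_false(isTRUE(all.equal(w$df, s$df)))
})

test_that("Benjamini-Hochberg step-up: hand-computed case and invariances", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(res$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$p_adj, p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"))

  single <- bh_fdr(0.031)
  expect_equal(single$p_adj, 0.031)

  withr::with_seed(23, p <- runif(50))
  r1 <- bh_fdr(p)
  ord <- order(p)
  r2 <- bh_fdr(p[ord])
  expect_equal(r2$p_adj, r1$p_adj[ord])          # order invariance
  expect_true(all(diff(r2$p_adj[order(r2$p)]) >= -1e-15))  # monotone
  expect_true(all(r1$p_adj >= r1$p))
  expect_error(bh_fdr(c(0.5, 1.3)), "\\[0, 1\\]")
})

test_that("edgewise comparison recovers a planted group difference", {
  atlas <- packaged_atlas()
  cfg <- synth_config(seed = 30)
  truth <- build_truth(cfg, atlas)
  hit <- abs(truth$hc - truth$mcs) > 1e-6 & upper.tri(truth$hc)

  gen_z <- function(truth50, n_subj, seed) {
    U <- chol(truth50 + diag(1e-6, 50))
    withr::with_seed(seed, {
      lapply(seq_len(n_subj), function(s) {
        X <- t(U) %*% matrix(rnorm(50 * 200), 50, 200)
        fisher_z_rectify(cor(t(X)))
      })
    })
  }
  za <- gen_z(truth$hc, 16, 31)
  zb <- gen_z(truth$mcs, 15, 32)
  res <- edgewise_comparison(za, zb, alpha = 0.01)
  expect_equal(nrow(res), choose(50, 2))

  found <- res$significant
  planted <- hit[which(upper.tri(truth$hc))]
  sens <- sum(found & planted) / sum(planted)
  fdrp <- if (sum(found)) sum(found & !planted) / sum(found) else 0
  expect_gt(sens, 0.5)
  expect_lt(fdrp, 0.2)
  expect_true(all(res$direction[found & planted] == "a>b"))

  # permuted labels: shuffling subjects across groups kills the signal
  pool <- c(za[1:8], zb[1:8])
  perm <- withr::with_seed(33, sample(16))
  null_res <- edgewise_comparison(pool[perm[1:8]], pool[perm[9:16]],
                                  alpha = 0.01)
  expect_lte(sum(null_res$significant), 2)

  expect_error(edgewise_comparison(za[1], zb[1]), "2 subjects")
})

test_that("chi-square on 2x2 tables matches the closed form", {
  # published gender split: no group difference
  genders <- matrix(c(9, 7, 8, 7), 2, 2, byrow = TRUE)
  expect_gt(chi_square_2x2(genders)$p_value, 0.05)

  balanced <- matrix(c(5, 5, 5, 5), 2, 2)
  expect_equal(chi_square_2x2(balanced)$statistic, 0)

  tab <- matrix(c(12, 5, 6, 14), 2, 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_2x2(tab)$statistic, sum((tab - e)^2 / e))
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "marginal")
})

test_that("metric-score correlations: exact, null, and guarded cases", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(crsr_correlation(x, 2 * x + 1)$r, 1)

  pv <- withr::with_seed(24, {
    replicate(50, {
      a <- rnorm(15)
      crsr_correlation(a, sample(0:4, 15, replace = TRUE))$p_value
    })
  })
  expect_gt(mean(pv > 0.05), 0.8)

  expect_error(crsr_correlation(rep(1, 5), 1:5), "constant")
  expect_error(crsr_correlation(1:2, 1:2), "at least 3")
})
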