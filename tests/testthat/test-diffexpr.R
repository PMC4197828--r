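# builds a probe table for one hybridisation directly from (M, A) pairs
hyb_table <- function(M, A) {
  data.frame(probe_id = sprintf("p%d", seq_along(M)),
             gene_id = sprintf("g%d", seq_along(M)),
             comparison = "c1", bio_rep = 1, dye_swap = FALSE,
             R = 2^(A + M / 2), G = 2^(A - M / 2))
}

test_that("loess normalisation leaves unbiased data nearly untouched", {
  set.seed(1)
  n <- 5000
  tab <- hyb_table(rnorm(n, 0, 0.3), runif(n, 6, 16))
  m_raw <- log2(tab$R / tab$G)
  out <- loess_normalize(tab)
  expect_lt(mean(abs(out$M - m_raw)), 0.05)
})

test_that("a constant log-ratio offset is removed entirely", {
  set.seed(2)
  tab <- hyb_table(rep(0.7, 500), runif(500, 6, 16))
  out <- loess_normalize(tab)
  expect_lt(max(abs(out$M)), 0.02)
})

test_that("constant intensity falls back to mean-centring", {
  tab <- hyb_table(rnorm(100, 1, 0.1), rep(10, 100))
  out <- loess_normalize(tab)
  expect_equal(mean(out$M), 0, tolerance = 1e-12)
})

test_that("a planted bias curve is removed down to the noise floor", {
  design <- array_design()
  bias <- function(a) 0.1 * (a - 10)^2 * 0.05
  s0 <- 0.02
  sim <- gen_two_colour_arrays(design, 400, de_fraction = 0.3,
                               effect_size = 2, bias_curve = bias,
                               seed = 3, d0 = Inf, s0_sq = s0)
  out <- loess_normalize(sim$probes)
  truth <- sim$truth$true_logratio[cbind(out$gene_id, out$comparison)]
  truth <- ifelse(out$dye_swap, -truth, truth)
  noise_floor <- sqrt(s0 * 4)   # per-measurement noise sd in this design
  expect_lt(sqrt(mean((out$M - truth)^2)), noise_floor * 1.2)
})

test_that("averaging honours duplicates, dye orientation and the replicate count", {
  design <- array_design(comparisons = "c1", replicates = 2)
  tab <- data.frame(
    probe_id = rep(c("p1", "p2"), 4),
    gene_id = "g1",
    comparison = "c1",
    bio_rep = rep(1:2, each = 4),
    dye_swap = rep(c(FALSE, FALSE, TRUE, TRUE), 2),
    M = c(1.5, 1.5, -1.5, -1.5,    # rep 1: swap pair stored (+m, -m) -> m
          2.0, 1.0, -1.0, -2.0))   # rep 2: same, with probe scatter
  lrm <- average_replicates(tab, design)
  expect_equal(dim(lrm$replicates), c(1, 1, 2))
  expect_equal(unname(lrm$replicates[1, 1, ]), c(1.5, 1.5))
  expect_equal(unname(lrm$mean[1, 1]), 1.5)
})

test_that("averaging equals a brute-force grouped mean on a random table", {
  set.seed(4)
  design <- array_design(comparisons = c("c1", "c2"), replicates = 3)
  sim <- gen_two_colour_arrays(design, 30, 0.5, 1, seed = 5)
  pr <- sim$probes
  pr$M <- log2(pr$R / pr$G)
  lrm <- average_replicates(pr, design)
  m_bio <- ifelse(pr$dye_swap, -pr$M, pr$M)
  for (i in sample(30, 5)) {
    g <- sprintf("g%05d", i)
    for (cc in design$comparisons) for (r in 1:3) {
      sel <- pr$gene_id == g & pr$comparison == cc & pr$bio_rep == r
      expect_equal(unname(lrm$replicates[g, cc, r]), mean(m_bio[sel]))
    }
  }
})

test_that("the dye-swap sign flip is an involution on the final matrix", {
  design <- array_design(comparisons = "c1", replicates = 2)
  set.seed(6)
  base <- expand.grid(probe_id = c("p1", "p2"), gene_id = "g1",
                      comparison = "c1", bio_rep = 1:2,
                      dye_swap = c(FALSE, TRUE), stringsAsFactors = FALSE)
  base$M <- rnorm(nrow(base))
  # storing -M under the opposite dye flag describes the same biology
  flipped <- base
  flipped$M <- -base$M
  flipped$dye_swap <- !base$dye_swap
  expect_equal(average_replicates(base, design)$mean,
               average_replicates(flipped, design)$mean)
})

test_that("a gene absent from one replicate is flagged but kept", {
  design <- array_design(comparisons = "c1", replicates = 2)
  tab <- data.frame(probe_id = "p1", gene_id = c("g1", "g2", "g1"),
                    comparison = "c1", bio_rep = c(1, 1, 2),
                    dye_swap = FALSE, M = c(1, 2, 3))
  expect_warning(lrm <- average_replicates(tab, design), "without probes")
  expect_equal(unname(lrm$mean["g1", "c1"]), 2)  # mean of the present reps
  expect_equal(unname(lrm$mean["g2", "c1"]), 2)
})

test_that("the variance prior is recovered from simulated variances", {
  set.seed(7)
  n <- 10000; d0 <- 4; s0 <- 0.05; df <- 2
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, df) / df
  prior <- estimate_prior(s2, df)
  expect_lt(abs(prior$d0 - d0), 1.5)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.2)
})

test_that("identical variances give an infinite prior df", {
  prior <- estimate_prior(rep(0.05, 100), 2)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0_sq, 0.05)
})

test_that("the prior is scale-equivariant in s0 and invariant in d0", {
  set.seed(8)
  s2 <- 0.05 * rchisq(2000, 2) / 2 * (4 * 0.05 / rchisq(2000, 4) / 0.05)
  p1 <- estimate_prior(s2, 2)
  p2 <- estimate_prior(2 * s2, 2)
  expect_equal(p2$s0_sq, 2 * p1$s0_sq, tolerance = 1e-8)
  expect_equal(p2$d0, p1$d0, tolerance = 1e-6)
})

rep_array <- function(values, gene = "g1") {
  array(values, dim = c(1, 1, length(values)),
        dimnames = list(gene, "c1", paste0("rep", seq_along(values))))
}

test_that("the moderated statistic matches the hand-computed worked example", {
  # replicates (1.0, 1.2, 0.8): s_g^2 = 0.04; with d0 = 3, s0^2 = 0.04 the
  # posterior variance stays 0.04 and the statistic is 1 / (0.2 sqrt(1/3))
  arr <- rep_array(c(1.0, 1.2, 0.8))
  res <- moderated_test(arr, prior = list(d0 = 3, s0_sq = 0.04))
  expect_equal(res$s2, 0.04, tolerance = 1e-12)
  expect_equal(res$s2_post, 0.04, tolerance = 1e-12)
  expect_equal(res$stat, 1 / (0.2 * sqrt(1 / 3)), tolerance = 1e-10)
  expect_equal(res$stat, 8.660, tolerance = 1e-3)
  expect_lt(res$p, 1e-15)
})

test_that("all-zero replicates give statistic 0 and p 1", {
  res <- moderated_test(rep_array(c(0, 0, 0)),
                        prior = list(d0 = 3, s0_sq = 0.04))
  expect_equal(res$stat, 0)
  expect_equal(res$p, 1)
})

test_that("an infinite prior df pins every posterior variance at s0^2", {
  set.seed(9)
  arr <- array(rnorm(60), dim = c(10, 2, 3),
               dimnames = list(sprintf("g%d", 1:10), c("c1", "c2"), NULL))
  res <- moderated_test(arr, prior = list(d0 = Inf, s0_sq = 0.07))
  expect_true(all(res$s2_post == 0.07))
})

test_that("posterior variances are a convex combination of s0^2 and s_g^2", {
  set.seed(10)
  arr <- array(rnorm(300, sd = 0.5), dim = c(50, 2, 3),
               dimnames = list(sprintf("g%d", 1:50), c("c1", "c2"), NULL))
  res <- moderated_test(arr, prior = list(d0 = 4, s0_sq = 0.1))
  expect_true(all(res$s2_post >= pmin(0.1, res$s2) - 1e-12))
  expect_true(all(res$s2_post <= pmax(0.1, res$s2) + 1e-12))
})

test_that("p-value adjustments match their definitions and oracles", {
  expect_equal(adjust_pvalues(rep(0.01, 7), "bonferroni")[1], 0.07)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  set.seed(11)
  p <- runif(200)
  expect_equal(adjust_pvalues(p, "bh"), oracle_bh(p))
  expect_true(all(adjust_pvalues(p, "bonferroni") >=
                    adjust_pvalues(p, "bh") - 1e-12))
  expect_true(all(adjust_pvalues(p, "bh") >= p - 1e-12))
  for (m in c("bonferroni", "bh", "local_fdr"))
    expect_equal(adjust_pvalues(0.37, m), 0.37)
  expect_length(adjust_pvalues(numeric(0), "bh"), 0)
})

test_that("the local fdr separates planted signal from null", {
  set.seed(12)
  z <- c(rnorm(1800), rnorm(200, -4))           # 10% strong signal
  p <- pnorm(z)
  lf <- adjust_pvalues(p, "local_fdr")
  expect_true(all(lf >= 0 & lf <= 1))
  expect_lt(mean(lf[1801:2000]), 0.35)          # signal: low posterior null prob
  expect_gt(mean(lf[1:1800]), 0.6)              # null: high posterior null prob
})

test_that("type-I error is nominal under the t null and inflated under the normal null", {
  set.seed(13)
  n <- 4000; d0 <- 4; s0 <- 0.05
  sigma2 <- d0 * s0 / rchisq(n, d0)
  arr <- array(rnorm(n * 3, sd = sqrt(rep(sigma2, 3))), dim = c(n, 1, 3),
               dimnames = list(sprintf("g%d", 1:n), "c1", NULL))
  res_t <- moderated_test(arr, null = "t")
  res_n <- moderated_test(arr, null = "normal")
  frac_t <- mean(res_t$p < 0.05)
  frac_n <- mean(res_n$p < 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac_t - 0.05), 3 * se)
  expect_gte(frac_n, 0.05 - se)   # normal null is anticonservative here
  expect_gt(frac_n, frac_t)
})

test_that("the MAPK-dependence rule is a sign-agnostic 1-log2 difference", {
  col <- c(gA = 2.0, gB = 2.0, gC = -1.6, gD = 1.0)
  mut <- list(mpk3 = c(gA = 0.8, gB = 1.5, gC = -0.4))  # gD missing
  dep <- mapk_dependence(col, mut)
  expect_equal(dep$status, c("affected", "unaffected", "affected",
                             "unclassifiable"))
})
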