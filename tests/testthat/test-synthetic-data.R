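design_small <- array_design(replicates = 3)

test_that("generators are pure functions of their seed", {
  a <- gen_two_colour_arrays(design_small, 50, 0.2, 1.5, seed = 7)
  b <- gen_two_colour_arrays(design_small, 50, 0.2, 1.5, seed = 7)
  expect_identical(a, b)

  sc <- mixture_scenario("overlapping", d = 4)
  m1 <- gen_mixture_profiles(100, 4, 3, sc$proportions, sc$means[, 1:4],
                             sc$volumes, sc$shape_matrix[1:4, 1:4] /
                               det(sc$shape_matrix[1:4, 1:4])^(1 / 4), seed = 3)
  m2 <- gen_mixture_profiles(100, 4, 3, sc$proportions, sc$means[, 1:4],
                             sc$volumes, sc$shape_matrix[1:4, 1:4] /
                               det(sc$shape_matrix[1:4, 1:4])^(1 / 4), seed = 3)
  expect_identical(m1, m2)

  p1 <- gen_promoters(20, 200, seed = 5)
  p2 <- gen_promoters(20, 200, seed = 5)
  expect_identical(as.character(p1$promoters), as.character(p2$promoters))

  e1 <- gen_annotations_and_edges(100, seed = 9)
  e2 <- gen_annotations_and_edges(100, seed = 9)
  expect_identical(e1, e2)
})

test_that("with no effect, no bias and vanishing noise all M are near zero", {
  sim <- gen_two_colour_arrays(design_small, 50, de_fraction = 0,
                               effect_size = 0, seed = 1,
                               d0 = Inf, s0_sq = 1e-12)
  m <- log2(sim$probes$R / sim$probes$G)
  expect_lt(max(abs(m)), 1e-4)
  expect_true(all(sim$probes$R > 0 & sim$probes$G > 0))
  expect_true(all(sim$truth$true_logratio == 0))
})

test_that("a planted intensity-dependent bias shows up in raw M as b(A)", {
  bias <- function(a) 0.1 * (a - 10)^2 * 0.05
  sim <- gen_two_colour_arrays(design_small, 200, de_fraction = 0.3,
                               effect_size = 2, bias_curve = bias, seed = 2,
                               d0 = Inf, s0_sq = 1e-10)
  pr <- sim$probes
  m <- log2(pr$R / pr$G)
  a <- (log2(pr$R) + log2(pr$G)) / 2
  truth <- sim$truth$true_logratio[cbind(pr$gene_id, pr$comparison)]
  truth <- ifelse(pr$dye_swap, -truth, truth)
  # with the noise switched off, raw M minus signed truth IS the bias curve
  expect_lt(max(abs((m - truth) - bias(a))), 1e-4)
})

test_that("de_flags mark exactly the non-zero planted effects", {
  sim <- gen_two_colour_arrays(design_small, 100, 0.4, 1.5, seed = 4)
  expect_identical(sim$truth$de_flags, sim$truth$true_logratio != 0)
  de_genes <- rownames(sim$truth$de_flags)[rowSums(sim$truth$de_flags) > 0]
  expect_equal(length(de_genes), round(0.4 * 100))
})

test_that("replicate-level gene variances follow the scaled-F law implied by the prior", {
  n <- 5000
  d0 <- 4; s0 <- 0.05
  sim <- gen_two_colour_arrays(array_design(comparisons = "c1"), n,
                               de_fraction = 0, effect_size = 0, seed = 11,
                               d0 = d0, s0_sq = s0)
  pr <- sim$probes        # no bias planted: average raw log-ratios directly
  pr$M <- log2(pr$R / pr$G)
  lrm <- average_replicates(pr, array_design(comparisons = "c1"))
  s2 <- apply(lrm$replicates[, 1, ], 1, var)
  # s_g^2 / s0^2 ~ F(n_rep - 1, d0) marginally
  ks <- suppressWarnings(ks.test(s2 / s0, "pf", 2, d0))
  expect_gt(ks$p.value, 0.001)
})

test_that("single-component mixture draws obey the law of large numbers", {
  n <- 20000
  sim <- gen_mixture_profiles(n, 3, 1, 1, matrix(c(1, -2, 0.5), 1),
                              volumes = 1, shape_matrix = diag(3), seed = 6)
  se <- 1 / sqrt(n)
  expect_true(all(abs(colMeans(sim$X) - c(1, -2, 0.5)) < 3 * se))
  expect_lt(max(abs(cov(sim$X) - diag(3))), 3 * sqrt(2 / n) * 3)
})

test_that("well-separated components are recovered by nearest-mean labelling", {
  mu <- rbind(rep(0, 3), rep(10, 3))
  sim <- gen_mixture_profiles(500, 3, 2, c(0.4, 0.6), mu, c(1, 1),
                              diag(3), seed = 8)
  d2 <- sapply(1:2, function(k) rowSums(sweep(sim$X, 2, mu[k, ])^2))
  expect_identical(max.col(-d2), sim$labels)
})

test_that("mixture label frequencies match the proportions", {
  sim <- gen_mixture_profiles(10000, 2, 2, c(0.3, 0.7),
                              rbind(c(0, 0), c(5, 5)), c(1, 1), diag(2),
                              seed = 9)
  freq <- tabulate(sim$labels, 2) / 10000
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(freq[1] - 0.3), 3 * se)
})

test_that("a shape matrix without unit determinant is rejected", {
  expect_error(gen_mixture_profiles(10, 2, 1, 1, matrix(0, 1, 2), 1,
                                    2 * diag(2), seed = 1),
               "determinant 1")
  expect_error(gen_mixture_profiles(10, 2, 1, 1, matrix(0, 1, 2), 1,
                                    matrix(c(1, 0.5, 0.1, 1), 2), seed = 1),
               "symmetric")
})

test_that("forced planting puts a verifiable match inside the window in every target", {
  res <- gen_promoters(100, 1000,
                       planted = list(list(motif = "TTGACC", genes = 1:50,
                                           window = c(-300, -200), prob = 1)),
                       seed = 10)
  seqs <- as.character(res$promoters)
  for (g in 1:50) {
    hits <- oracle_scan(seqs[g], "TTGACC", both = FALSE)
    expect_true(any(hits >= -300 & hits <= -200))
  }
  expect_equal(nrow(res$truth), 50)
  expect_true(all(res$truth$position >= -300 & res$truth$position <= -200))
})

test_that("background motif counts match the i.i.d. closed form", {
  n <- 400; L <- 1000; gc <- 0.4
  res <- gen_promoters(n, L, planted = list(), gc = gc, seed = 12)
  # forward-strand matches of a fixed 6-mer with one degenerate letter
  motif <- "TTGACY"
  p_base <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  p_match <- prod(vapply(iupac_table[strsplit(motif, "")[[1]]],
                         function(s) sum(p_base[s]), 1))
  expected <- n * (L - nchar(motif) + 1) * p_match
  observed <- sum(lengths(lapply(as.character(res$promoters), oracle_scan,
                                 motif = motif, both = FALSE)))
  expect_lt(abs(observed - expected), 4 * sqrt(expected))
})

test_that("non-IUPAC motifs are rejected by the promoter generator", {
  expect_error(gen_promoters(10, 100,
                             planted = list(list(motif = "TTQAC", genes = 1,
                                                 window = c(-50, -20), prob = 1))),
               "IUPAC")
})

test_that("planted hubs reach their degree and edge lists are clean", {
  res <- gen_annotations_and_edges(200, ppi_density = 0.01,
                                   tf_target_count = 50,
                                   planted_hubs = list(list(gene = 5L, degree = 30L)),
                                   seed = 13)
  deg <- oracle_degrees(res$ppi, res$tf_target, sprintf("g%05d", 1:200))
  expect_gte(deg[["g00005"]], 30)
  expect_true(all(res$ppi$a != res$ppi$b))
  expect_false(any(duplicated(res$ppi[c("a", "b")])))
  expect_false(any(duplicated(res$tf_target[c("a", "b")])))
})

test_that("zero density and zero TF count give empty edge lists", {
  res <- gen_annotations_and_edges(50, ppi_density = 0, tf_target_count = 0,
                                   seed = 14)
  expect_equal(nrow(res$ppi), 0)
  expect_equal(nrow(res$tf_target), 0)
  expect_error(gen_annotations_and_edges(50, ppi_density = 1.5), "n\\(n-1\\)/2")
})
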