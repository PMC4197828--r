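#' Intensity-dependent (loess) normalisation of one or more hybridisations
#'
#' For each hybridisation the raw log-ratio M = log2(R/G) is regressed on the
#' mean log-intensity A = (log2 R + log2 G)/2 by local linear regression with
#' tricube weights, and the fit is subtracted, removing the intensity-
#' dependent dye bias. Hybridisations with (numerically) constant A fall back
#' to subtracting the plain mean of M.
#'
#' @param probes Probe-level data frame with columns `R`, `G` and the
#'   hybridisation keys `comparison`, `bio_rep`, `dye_swap` (any other
#'   columns are carried through).
#' @param span Loess span (default 0.3, with 2 robustness iterations).
#' @return The input with columns `A` and `M` added, `M` dye-bias corrected,
#'   still in raw (dye) orientation.
#' @export
loess_normalize <- function(probes, span = 0.3) {
  stopifnot(all(c("R", "G") %in% names(probes)), all(probes$R > 0),
            all(probes$G > 0))
  keys <- intersect(c("comparison", "bio_rep", "dye_swap"), names(probes))
  probes$A <- (log2(probes$R) + log2(probes$G)) / 2
  probes$M <- log2(probes$R) - log2(probes$G)
  hyb <- if (length(keys)) interaction(probes[keys], drop = TRUE)
         else factor(rep(1, nrow(probes)))
  for (h in levels(hyb)) {
    i <- which(hyb == h)
    if (length(i) < 50)
      stop("hybridisation '", h, "' has fewer than 50 probes")
    a <- probes$A[i]
    m <- probes$M[i]
    if (stats::sd(a) < 1e-12) {
      probes$M[i] <- m - mean(m)
    } else {
      fit <- stats::loess(m ~ a, span = span, degree = 1,
                          family = "symmetric",
                          control = stats::loess.control(iterations = 2))
      probes$M[i] <- m - stats::predict(fit, a)
    }
  }
  probes
}

#' Average duplicate probes and dye-swapped technical replicates
#'
#' Dye-swapped hybridisations are first sign-flipped to biological
#' orientation; then, within each biological replicate, the gene value is the
#' mean over duplicate probes and over the dye pair, so each gene retains
#' exactly one value per biological replicate per comparison. The
#' replicate-level array is kept for variance estimation alongside the
#' replicate-averaged log-ratio matrix.
#'
#' @param normalized Data frame from [loess_normalize()] (needs `gene_id`,
#'   `comparison`, `bio_rep`, `dye_swap`, `M`).
#' @param design The [array_design()] (fixes comparison order).
#' @return Object of class `logratio_matrix`: list with `mean` (genes x
#'   comparisons matrix), `replicates` (genes x comparisons x bio_rep array)
#'   and `n_rep`.
#' @export
average_replicates <- function(normalized, design) {
  stopifnot(all(c("gene_id", "comparison", "bio_rep", "dye_swap", "M") %in%
                  names(normalized)))
  m <- ifelse(normalized$dye_swap, -normalized$M, normalized$M)
  genes <- sort(unique(normalized$gene_id))
  comps <- design$comparisons
  reps <- sort(unique(normalized$bio_rep))
  gi <- match(normalized$gene_id, genes)
  ci <- match(normalized$comparison, comps)
  ri <- match(normalized$bio_rep, reps)
  if (anyNA(ci)) stop("comparison labels not in design")

  idx <- gi + (ci - 1L) * length(genes) + (ri - 1L) * length(genes) * length(comps)
  sums <- tapply(m, idx, sum)
  counts <- tapply(m, idx, length)
  arr <- array(NA_real_, dim = c(length(genes), length(comps), length(reps)),
               dimnames = list(genes, comps, paste0("rep", reps)))
  arr[as.integer(names(sums))] <- sums / counts

  miss <- is.na(arr)
  if (any(miss)) {
    gone <- apply(miss, 1:2, all)
    if (any(gone))
      stop("gene(s) with no probe data in any replicate of a comparison: ",
           paste(utils::head(rownames(gone)[rowSums(gone) > 0], 5), collapse = ", "))
    warning(sum(miss), " gene x comparison x replicate cell(s) without probes; ",
            "excluded from those replicates")
  }
  structure(list(mean = apply(arr, 1:2, mean, na.rm = TRUE),
                 replicates = arr, n_rep = length(reps)),
            class = "logratio_matrix")
}

#' @export
print.logratio_matrix <- function(x, ...) {
  cat("Log-ratio matrix:", nrow(x$mean), "genes x", ncol(x$mean),
      "comparisons,", x$n_rep, "biological replicates\n")
  invisible(x)
}

#' Estimate the empirical-Bayes variance prior (d0, s0^2)
#'
#' Fits the scaled-F hierarchical model for gene-wise residual variances by
#' matching moments of log s_g^2, delegating to the standard limma machinery.
#' Returns d0 = Inf when the spread of log s_g^2 does not exceed what the
#' residual degrees of freedom alone explain.
#'
#' @param s2 Vector of residual variances s_g^2.
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List with `d0` (prior df, possibly Inf) and `s0_sq` (prior value).
#' @export
estimate_prior <- function(s2, df) {
  keep <- is.finite(s2) & s2 >= 0 & (if (length(df) > 1) df >= 1 else TRUE)
  s2 <- s2[keep]
  df2 <- if (length(df) > 1) df[keep] else df
  if (length(s2) < 20) stop("need >= 20 genes with df >= 1")
  if (stats::sd(log(pmax(s2, 1e-300))) < 1e-12)
    return(list(d0 = Inf, s0_sq = s2[1]))
  fit <- limma::fitFDist(s2, df1 = df2)
  list(d0 = fit$df2, s0_sq = fit$scale)
}

#' Moderated t-tests on the replicate-level log-ratio array
#'
#' For each gene and comparison: the statistic is the replicate mean divided
#' by s_tilde * sqrt(1/n_rep), where s_tilde^2 = (d0 s0^2 + d_g s_g^2) /
#' (d0 + d_g) is the posterior (shrunken) variance. Under `null = "normal"`
#' the statistic is referred to the standard normal (the convention for
#' CATMA-style designs where variances show no evidence of heterogeneity);
#' under `null = "t"` to a t distribution on d0 + d_g degrees of freedom.
#'
#' @param lrm A `logratio_matrix` from [average_replicates()], or a genes x
#'   comparisons x replicates array.
#' @param prior A prior from [estimate_prior()]; `NULL` estimates it from the
#'   pooled gene x comparison variances.
#' @param null `"normal"` (default) or `"t"`.
#' @param de_alpha Adjusted-p cutoff for the DE flag.
#' @param adjust Adjustment method for the DE call: `"bh"` (default),
#'   `"bonferroni"` or `"local_fdr"`; Bonferroni and BH columns are always
#'   emitted.
#' @return Data frame of class `de_result`: gene, comparison, logratio, s2,
#'   df, s2_post, stat, p, p_bonf, p_bh, p_adj, de_flag.
#' @export
moderated_test <- function(lrm, prior = NULL, null = c("normal", "t"),
                           de_alpha = 0.05, adjust = c("bh", "bonferroni", "local_fdr")) {
  null <- match.arg(null)
  adjust <- match.arg(adjust)
  arr <- if (inherits(lrm, "logratio_matrix")) lrm$replicates else lrm
  stopifnot(length(dim(arr)) == 3)
  n_rep <- apply(!is.na(arr), 1:2, sum)
  if (any(n_rep < 2)) stop("need >= 2 biological replicates per gene per comparison")
  mean_lr <- apply(arr, 1:2, mean, na.rm = TRUE)
  s2 <- apply(arr, 1:2, stats::var, na.rm = TRUE)
  dfres <- n_rep - 1

  if (is.null(prior)) prior <- estimate_prior(as.vector(s2), as.vector(dfres))
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) matrix(prior$s0_sq, nrow(s2), ncol(s2),
                                         dimnames = dimnames(s2))
             else (d0 * prior$s0_sq + dfres * s2) / (d0 + dfres)

  stat <- mean_lr / sqrt(s2_post / n_rep)
  zero <- s2_post == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero posterior variance; p set to 0")
    stat[zero] <- ifelse(mean_lr[zero] == 0, 0, sign(mean_lr[zero]) * Inf)
  }
  p <- if (null == "normal") 2 * stats::pnorm(-abs(stat))
       else 2 * stats::pt(-abs(stat), df = d0 + dfres)
  p[zero & mean_lr == 0] <- 1   # 0/0: no effect, no evidence

  res <- data.frame(
    gene = rep(rownames(mean_lr), ncol(mean_lr)),
    comparison = rep(colnames(mean_lr), each = nrow(mean_lr)),
    logratio = as.vector(mean_lr), s2 = as.vector(s2),
    df = as.vector(dfres), s2_post = as.vector(s2_post),
    stat = as.vector(stat), p = as.vector(p), stringsAsFactors = FALSE)
  # adjust within each comparison (each contrast is its own family of tests)
  res$p_bonf <- stats::ave(res$p, res$comparison,
                           FUN = function(p) adjust_pvalues(p, "bonferroni"))
  res$p_bh <- stats::ave(res$p, res$comparison,
                         FUN = function(p) adjust_pvalues(p, "bh"))
  res$p_adj <- switch(adjust,
                      bh = res$p_bh,
                      bonferroni = res$p_bonf,
                      local_fdr = stats::ave(res$p, res$comparison,
                                             FUN = function(p) adjust_pvalues(p, "local_fdr")))
  res$de_flag <- res$p_adj <= de_alpha
  attr(res, "prior") <- prior
  attr(res, "null") <- null
  class(res) <- c("de_result", class(res))
  res
}

#' Multiple-testing adjustment
#'
#' `bonferroni` and `bh` are the classical adjustments. `local_fdr` is a
#' semi-parametric two-component local false discovery rate: raw p-values are
#' probit-transformed, the marginal density is estimated by a Gaussian kernel,
#' the null proportion pi0 by the conservative density-ratio at the null mode,
#' and each test receives its posterior null probability
#' pi0 * f0(z) / f(z), clipped to [0, 1].
#'
#' @param p Vector of p-values in [0, 1].
#' @param method `"bonferroni"`, `"bh"` or `"local_fdr"`.
#' @return Adjusted values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "local_fdr")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  switch(method,
    bonferroni = stats::p.adjust(p, "bonferroni"),
    bh = stats::p.adjust(p, "BH"),
    local_fdr = local_fdr(p))
}

# Two-component kernel local fdr on probit scale. One-sided probit keeps the
# alternative mass on the left; the null component is standard normal.
local_fdr <- function(p) {
  n <- length(p)
  if (n < 2) return(p)
  z <- stats::qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16))
  f <- stats::density(z, bw = "nrd0", n = 1024,
                      from = min(z) - 1, to = max(z) + 1)
  fz <- stats::approx(f$x, f$y, xout = z, rule = 2)$y
  f0z <- stats::dnorm(z)
  # pi0: the marginal cannot fall below pi0 * f0 anywhere; take the min ratio
  # over the right (null-dominated) half, capped at 1
  right <- z >= stats::median(z)
  pi0 <- min(1, stats::quantile(fz[right] / f0z[right], 0.1, names = FALSE))
  pmin(1, pi0 * f0z / pmax(fz, 1e-300))
}

#' MAPK-dependence calls
#'
#' A gene that is flg22-regulated in the wild type is called *affected* in a
#' mutant when its flg22-induced log-ratio differs from the wild-type one by
#' at least `threshold` log2 units (sign-agnostic), i.e. it loses (or gains)
#' at least a two-fold part of its flg22 response in that mutant.
#'
#' @param col_lr Named vector of wild-type flg22 log-ratios for the genes
#'   flg22-regulated in the wild type.
#' @param mutant_lr Named list (one element per mutant) of vectors of the
#'   mutant flg22 log-ratios, names matching genes.
#' @param threshold Log2 difference required (default 1).
#' @return Data frame gene, mutant, status in
#'   `{"affected", "unaffected", "unclassifiable"}`.
#' @export
mapk_dependence <- function(col_lr, mutant_lr, threshold = 1) {
  stopifnot(!is.null(names(col_lr)), is.list(mutant_lr))
  out <- lapply(names(mutant_lr), function(mut) {
    mv <- mutant_lr[[mut]][names(col_lr)]
    status <- unname(ifelse(is.na(mv), "unclassifiable",
                            ifelse(abs(mv - col_lr) >= threshold,
                                   "affected", "unaffected")))
    data.frame(gene = names(col_lr), mutant = mut, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
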