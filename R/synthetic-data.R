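#' Two-colour array experimental design
#'
#' Describes the hybridisation layout the simulator and the averaging step
#' share: the labelled contrasts, the number of biological replicates per
#' contrast, whether each biological replicate carries a dye-reversed
#' technical replicate, and the number of duplicate probes per gene (one per
#' strand on CATMA-style arrays).
#'
#' @param comparisons Character vector of contrast labels. The default is the
#'   seven-contrast layout of a flg22 / MAPK-mutant study: wild type plus
#'   elicitor versus wild type, each mutant versus wild type, and each mutant
#'   plus elicitor versus the untreated mutant.
#' @param replicates Number of biological replicates per contrast.
#' @param dye_swap If `TRUE` every biological replicate is hybridised twice,
#'   once with the fluorophores exchanged.
#' @param duplicate_probes Probes per gene within one hybridisation.
#' @return An object of class `array_design`.
#' @export
array_design <- function(comparisons = c("col_flg22_vs_col",
                                         "mpk3_vs_col",
                                         "mpk4_vs_col",
                                         "mpk6_vs_col",
                                         "mpk3_flg22_vs_mpk3",
                                         "mpk4_flg22_vs_mpk4",
                                         "mpk6_flg22_vs_mpk6"),
                         replicates = 3, dye_swap = TRUE,
                         duplicate_probes = 2) {
  stopifnot(length(comparisons) >= 1, !anyDuplicated(comparisons),
            replicates >= 1, duplicate_probes >= 1)
  structure(list(comparisons = as.character(comparisons),
                 replicates = as.integer(replicates),
                 dye_swap = isTRUE(dye_swap),
                 duplicate_probes = as.integer(duplicate_probes)),
            class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat("Two-colour array design:", length(x$comparisons), "comparisons,",
      x$replicates, "biological replicates,",
      if (x$dye_swap) "with" else "without", "dye swap,",
      x$duplicate_probes, "duplicate probes per gene\n")
  invisible(x)
}

# Draw per-gene residual variances from the scaled inverse chi-square prior
# sigma_g^2 ~ d0 * s0^2 / chisq(d0); d0 = Inf collapses to the constant s0^2.
draw_gene_variances <- function(n_genes, d0 = 4, s0_sq = 0.05) {
  stopifnot(d0 > 0, s0_sq > 0)
  if (is.infinite(d0)) return(rep(s0_sq, n_genes))
  d0 * s0_sq / stats::rchisq(n_genes, df = d0)
}

#' Simulate probe-level two-colour hybridisations with known truth
#'
#' Generates red/green intensity pairs for every probe in every hybridisation
#' of `design`, such that the raw log-ratio M = log2(R/G) decomposes as
#' (signed) true log-ratio + dye-bias curve evaluated at the mean
#' log-intensity A + Gaussian noise. Dye-reversed hybridisations store the
#' biological effect with flipped sign, so downstream orientation handling is
#' exercised. Gene-wise residual variances follow a scaled inverse chi-square
#' prior with parameters `(d0, s0_sq)`, the hierarchical model the moderated
#' t-statistic assumes; measurement noise is scaled so that the
#' replicate-level averaged log-ratio has variance sigma_g^2.
#'
#' @param design An [array_design()].
#' @param n_genes Number of genes (>= 10).
#' @param de_fraction Fraction of genes given a non-zero effect somewhere.
#' @param effect_size Absolute effect, in log2 units, of planted effects.
#' @param bias_curve Function of A giving the intensity-dependent dye bias
#'   added to raw M; default no bias.
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param d0,s0_sq Variance-prior parameters.
#' @param a_range Range of the mean log2 intensity A (uniform draw).
#' @return List with `probes` (data frame: probe_id, gene_id, comparison,
#'   bio_rep, dye_swap, R, G) and `truth` (list with `true_logratio`,
#'   `de_flags`, `sigma_sq`, and the prior parameters).
#' @export
gen_two_colour_arrays <- function(design, n_genes, de_fraction, effect_size,
                                  bias_curve = function(a) rep(0, length(a)),
                                  seed = 1L, d0 = 4, s0_sq = 0.05,
                                  a_range = c(6, 16)) {
  stopifnot(inherits(design, "array_design"), n_genes >= 10,
            de_fraction >= 0, de_fraction <= 1, length(a_range) == 2)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  d <- length(design$comparisons)

  true_lr <- matrix(0, n_genes, d, dimnames = list(genes, design$comparisons))
  n_de <- round(de_fraction * n_genes)
  if (n_de > 0) {
    de_genes <- sample.int(n_genes, n_de)
    for (g in de_genes) {
      hit <- stats::runif(d) < 0.5
      if (!any(hit)) hit[sample.int(d, 1)] <- TRUE
      true_lr[g, hit] <- effect_size * sample(c(-1, 1), sum(hit), replace = TRUE)
    }
  }
  sigma_sq <- draw_gene_variances(n_genes, d0, s0_sq)

  dyes <- if (design$dye_swap) c(FALSE, TRUE) else FALSE
  n_meas <- design$duplicate_probes * length(dyes)  # measurements per bio rep
  meas_sd <- sqrt(sigma_sq * n_meas)                # so replicate mean has var sigma_g^2

  grid <- expand.grid(probe = seq_len(design$duplicate_probes),
                      gene = seq_len(n_genes),
                      dye_swap = dyes,
                      bio_rep = seq_len(design$replicates),
                      comparison = seq_len(d),
                      KEEP.OUT.ATTRS = FALSE)
  n_rows <- nrow(grid)
  a <- stats::runif(n_rows, a_range[1], a_range[2])
  sign <- ifelse(grid$dye_swap, -1, 1)
  m <- sign * true_lr[cbind(grid$gene, grid$comparison)] +
    bias_curve(a) + stats::rnorm(n_rows, 0, meas_sd[grid$gene])
  r <- pmax(2^(a + m / 2), 1e-8)
  g <- pmax(2^(a - m / 2), 1e-8)

  probes <- data.frame(
    probe_id = sprintf("%s_p%d", genes[grid$gene], grid$probe),
    gene_id = genes[grid$gene],
    comparison = design$comparisons[grid$comparison],
    bio_rep = grid$bio_rep,
    dye_swap = grid$dye_swap,
    R = r, G = g,
    stringsAsFactors = FALSE)

  list(probes = probes,
       truth = list(true_logratio = true_lr,
                    de_flags = true_lr != 0,
                    sigma_sq = stats::setNames(sigma_sq, genes),
                    d0 = d0, s0_sq = s0_sq))
}

#' Simulate profiles from a volume-varying shared-shape Gaussian mixture
#'
#' Draws `n` d-dimensional rows from sum_k pi_k N(mu_k, lambda_k * C) where C
#' is a shared symmetric positive-definite shape/orientation matrix with unit
#' determinant and the lambda_k are component-specific volumes — exactly the
#' covariance family the clustering module fits.
#'
#' @param n Number of observations.
#' @param d Dimension (number of expression contrasts).
#' @param K Number of components.
#' @param proportions Mixing proportions, summing to 1.
#' @param means K x d matrix of component means.
#' @param volumes Positive volumes lambda_k, length K.
#' @param shape_matrix d x d symmetric positive-definite matrix with
#'   determinant 1 (tolerance 1e-8).
#' @param seed Integer seed.
#' @return List with `X` (n x d matrix) and `labels` (integer vector).
#' @export
gen_mixture_profiles <- function(n, d, K, proportions, means, volumes,
                                 shape_matrix = diag(d), seed = 1L) {
  stopifnot(n >= 1, K >= 1, length(proportions) == K,
            abs(sum(proportions) - 1) < 1e-8, all(proportions > 0),
            nrow(means) == K, ncol(means) == d,
            length(volumes) == K, all(volumes > 0))
  check_shape_matrix(shape_matrix, d)
  set.seed(seed)
  labels <- sample.int(K, n, replace = TRUE, prob = proportions)
  L <- chol(shape_matrix)              # C = L'L
  Z <- matrix(stats::rnorm(n * d), n, d) %*% L
  X <- means[labels, , drop = FALSE] + Z * sqrt(volumes[labels])
  colnames(X) <- sprintf("dim%d", seq_len(d))
  list(X = X, labels = labels)
}

check_shape_matrix <- function(C, d, det_tol = 1e-8) {
  if (!is.matrix(C) || nrow(C) != d || ncol(C) != d)
    stop("shape_matrix must be ", d, " x ", d)
  if (max(abs(C - t(C))) > 1e-10) stop("shape_matrix must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("shape_matrix must be positive definite")
  if (abs(prod(ev) - 1) > det_tol)
    stop("shape_matrix must have determinant 1 (got ", format(prod(ev)), ")")
  invisible(TRUE)
}

#' Reference mixture scenarios used in simulation studies
#'
#' Fixed parameterisations of the volume-varying shared-shape mixture used by
#' the validation suite: an `overlapping` three-component scenario with means
#' roughly two component standard deviations apart (so the threshold-MAP rule
#' has work to do) and a `separated` scenario with essentially disjoint
#' components.
#'
#' @param kind `"overlapping"` or `"separated"`.
#' @param d Dimension (default 7, the study's contrast count).
#' @return List with `K`, `proportions`, `means`, `volumes`, `shape_matrix`.
#' @export
mixture_scenario <- function(kind = c("overlapping", "separated"), d = 7) {
  kind <- match.arg(kind)
  K <- 3
  # AR(1)-style shape, rescaled to unit determinant
  C <- 0.3^abs(outer(seq_len(d), seq_len(d), "-"))
  C <- C / det(C)^(1 / d)
  sep <- if (kind == "separated") 10 else 2
  stopifnot(d >= 3)
  mu2 <- rep(0, d); mu2[1] <- sep; mu2[2] <- sep / 2
  mu3 <- rep(0, d); mu3[1] <- -sep / 2; mu3[d - 1] <- sep * 0.75; mu3[d] <- sep / 2
  mu <- rbind(rep(0, d), mu2, mu3)
  list(K = K,
       proportions = c(0.25, 0.40, 0.35),
       means = mu,
       volumes = c(0.5, 1, 2),
       shape_matrix = C)
}

## ---- promoters -------------------------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

check_iupac <- function(motif) {
  letters <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC letter(s) in motif '", motif, "': ",
         paste(unique(bad), collapse = ", "))
  letters
}

# One concrete realisation of an IUPAC pattern (uniform over each letter set).
realise_iupac <- function(motif) {
  letters <- check_iupac(motif)
  paste(vapply(letters, function(l) {
    s <- IUPAC_SETS[[l]]
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}

#' Simulate TSS-anchored promoter sequences with planted motifs
#'
#' Background sequences are i.i.d. with the given GC content over positions
#' -length .. -1 relative to the transcription start site. Each planting
#' instruction places one concrete realisation of an IUPAC motif uniformly
#' inside its window, in each target gene independently with the stated
#' probability, overwriting the background.
#'
#' @param n_genes Number of promoters.
#' @param length Promoter length in bases (default 1000).
#' @param planted List of plantings, each a list with elements `motif`
#'   (IUPAC string), `genes` (indices or gene ids), `window` (integer c(a, b),
#'   both negative, closed, within -length .. -1) and `prob` (per-gene
#'   planting probability).
#' @param gc GC content of the background.
#' @param seed Integer seed.
#' @return List with `promoters` (a [Biostrings::DNAStringSet], names = gene
#'   ids) and `truth` (data frame gene_id, motif, position of each planting;
#'   position is the match base closest to the TSS).
#' @export
gen_promoters <- function(n_genes, length = 1000, planted = list(),
                          gc = 0.36, seed = 1L) {
  stopifnot(n_genes >= 1, length >= 10, gc > 0, gc < 1)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  mat <- matrix(sample(names(base_p), n_genes * length, replace = TRUE,
                       prob = base_p), nrow = n_genes)

  truth <- list()
  for (pl in planted) {
    letters <- check_iupac(pl$motif)
    m <- length(letters)
    w <- as.integer(pl$window)
    if (w[1] > w[2] || w[1] < -length || w[2] > -1)
      stop("window must lie inside [-", length, ", -1]")
    if (m > w[2] - w[1] + 1) stop("motif longer than its window")
    target <- pl$genes
    if (is.character(target)) target <- match(target, genes)
    stopifnot(!anyNA(target), all(target >= 1), all(target <= n_genes))
    for (g in target) {
      if (stats::runif(1) > pl$prob) next
      # start position (TSS-relative) of the match, uniform so it fits in window
      start_pos <- sample(seq(w[1], w[2] - m + 1), 1)
      idx <- (start_pos + length + 1):(start_pos + length + m)
      mat[g, idx] <- strsplit(realise_iupac(pl$motif), "")[[1]]
      truth[[length(truth) + 1]] <- data.frame(
        gene_id = genes[g], motif = pl$motif,
        position = start_pos + m - 1L, stringsAsFactors = FALSE)
    }
  }
  seqs <- Biostrings::DNAStringSet(apply(mat, 1, paste, collapse = ""))
  names(seqs) <- genes
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), motif = character(),
               position = integer(), stringsAsFactors = FALSE)
  list(promoters = seqs, truth = truth)
}

## ---- annotations and edges -------------------------------------------------

#' Simulate GO annotations and interaction edge lists with planted hubs
#'
#' GO terms get sizes from `term_size_law` and draw member genes uniformly.
#' Undirected PPI edges form an Erdos-Renyi graph at the requested density;
#' directed TF-target edges are sampled uniformly. Planted hub genes receive
#' additional PPI partners until their requested degree is met. No self-loops;
#' edge lists are deduplicated.
#'
#' @param n_genes Number of genes (ids g00001...).
#' @param n_terms Number of GO-like terms.
#' @param term_size_law Function(n_terms) returning integer term sizes.
#' @param ppi_density Fraction of the n(n-1)/2 possible undirected pairs.
#' @param tf_target_count Number of directed TF-target edges.
#' @param planted_hubs List of `list(gene = id-or-index, degree = k)`.
#' @param seed Integer seed.
#' @return List with `go` (gene_id, term_id), `ppi` (a, b, type) and
#'   `tf_target` (a, b, type) data frames, plus `hub_genes`.
#' @export
gen_annotations_and_edges <- function(n_genes, n_terms = 50,
                                      term_size_law = function(k) pmax(3L, stats::rpois(k, 20)),
                                      ppi_density = 0.001,
                                      tf_target_count = 100,
                                      planted_hubs = list(), seed = 1L) {
  stopifnot(n_genes >= 2, ppi_density >= 0, tf_target_count >= 0)
  if (ppi_density > 1) stop("ppi_density implies more than n(n-1)/2 edges")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))

  sizes <- pmin(term_size_law(n_terms), n_genes)
  go <- do.call(rbind, lapply(seq_len(n_terms), function(t) {
    data.frame(gene_id = genes[sample.int(n_genes, sizes[t])],
               term_id = sprintf("GO:%07d", t), stringsAsFactors = FALSE)
  }))
  if (is.null(go)) go <- data.frame(gene_id = character(), term_id = character())

  n_pairs <- n_genes * (n_genes - 1) / 2
  n_edges <- round(ppi_density * n_pairs)
  pick_pairs <- function(k) {
    if (k == 0) return(matrix(integer(), 0, 2))
    # rejection-free sampling of distinct unordered pairs via linear index
    idx <- sample(n_pairs, k)
    i <- floor((1 + sqrt(8 * (idx - 1) + 1)) / 2) + 1
    j <- idx - (i - 1) * (i - 2) / 2
    cbind(as.integer(i), as.integer(j))
  }
  ppi_idx <- pick_pairs(n_edges)

  hub_genes <- character(0)
  extra <- list()
  for (h in planted_hubs) {
    g <- h$gene
    if (is.character(g)) g <- match(g, genes)
    stopifnot(!is.na(g), h$degree < n_genes)
    hub_genes <- c(hub_genes, genes[g])
    have <- unique(c(ppi_idx[ppi_idx[, 1] == g, 2], ppi_idx[ppi_idx[, 2] == g, 1]))
    need <- h$degree - length(have)
    if (need > 0) {
      partners <- sample(setdiff(seq_len(n_genes)[-g], have), need)
      extra[[length(extra) + 1]] <- cbind(g, partners)
    }
  }
  if (length(extra)) ppi_idx <- rbind(ppi_idx, do.call(rbind, extra))
  # canonical order + dedup
  if (nrow(ppi_idx)) {
    ppi_idx <- t(apply(ppi_idx, 1, sort))
    ppi_idx <- unique(ppi_idx[ppi_idx[, 1] != ppi_idx[, 2], , drop = FALSE])
  }
  ppi <- data.frame(a = genes[ppi_idx[, 1]], b = genes[ppi_idx[, 2]],
                    type = rep("ppi", nrow(ppi_idx)), stringsAsFactors = FALSE)

  if (tf_target_count > 0) {
    tf <- data.frame(a = genes[sample.int(n_genes, tf_target_count, replace = TRUE)],
                     b = genes[sample.int(n_genes, tf_target_count, replace = TRUE)],
                     type = "tf_target", stringsAsFactors = FALSE)
    tf <- unique(tf[tf$a != tf$b, , drop = FALSE])
  } else {
    tf <- data.frame(a = character(), b = character(), type = character(),
                     stringsAsFactors = FALSE)
  }
  list(go = go, ppi = ppi, tf_target = tf, hub_genes = hub_genes)
}
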