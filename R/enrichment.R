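#' Hypergeometric over-representation of annotation terms in a gene set
#'
#' For every term with at least one cluster member, compares the relative
#' occurrence of the term in the cluster with its relative occurrence in the
#' annotated universe by a one-sided hypergeometric test:
#' p = P(X >= k) with X ~ Hypergeometric(N, K_term, n). No multiple-testing
#' correction is applied to the significance flag (raw p < `alpha`); a BH
#' column is emitted for reference.
#'
#' @param cluster_genes Character vector of cluster gene ids (subset of the
#'   universe).
#' @param annotation Data frame with columns `gene_id`, `term_id`.
#' @param universe Character vector of all genes considered; defaults to the
#'   genes present in `annotation`.
#' @param alpha Raw-p significance cutoff (default 0.05).
#' @return Data frame: term_id, k, n, K_term, N, ratio, p_value, p_bh,
#'   significant; one row per term with k >= 1, ordered by p.
#' @export
hypergeom_enrichment <- function(cluster_genes, annotation,
                                 universe = unique(annotation$gene_id),
                                 alpha = 0.05) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  if (length(universe) == 0) stop("empty universe")
  if (!all(cluster_genes %in% universe))
    stop("cluster genes outside the universe")
  ann <- unique(annotation[annotation$gene_id %in% universe, c("gene_id", "term_id")])
  N <- length(unique(ann$gene_id))
  n <- length(intersect(cluster_genes, unique(ann$gene_id)))
  in_cluster <- ann$gene_id %in% cluster_genes
  K_term <- table(ann$term_id)
  k <- table(ann$term_id[in_cluster])
  terms <- names(k)
  if (length(terms) == 0)
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K_term = integer(), N = integer(), ratio = numeric(),
                      p_value = numeric(), p_bh = numeric(),
                      significant = logical()))
  kk <- as.integer(k)
  KK <- as.integer(K_term[terms])
  p <- stats::phyper(kk - 1, KK, N - KK, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms, k = kk, n = n, K_term = KK, N = N,
                    ratio = (kk / n) / (KK / N),
                    p_value = p, p_bh = stats::p.adjust(p, "BH"),
                    significant = p < alpha, stringsAsFactors = FALSE)
  out[order(out$p_value), , drop = FALSE]
}

#' Kinetic class of a gene from its 1 h and 3 h fold changes
#'
#' Classifies flg22-response trajectories into ten classes from linear-scale
#' fold changes at 1 h and 3 h after treatment. Upregulated branch (a gene
#' induced at either time, i.e. fold change >= `induced_threshold`):
#' F = induced at 1 h, back to basal at 3 h; G = induced at both, at least
#' two-fold weaker at 3 h; H = induced at both, 1 h and 3 h within two-fold
#' of each other; I = induced at both, at least two-fold stronger at 3 h;
#' J = not induced at 1 h, induced at 3 h. Classes A-E mirror F-J for
#' repression, using reciprocal fold changes. So a gene induced 10x at 1 h
#' and 15x at 3 h is class H, while 10x then 50x is class I.
#'
#' @param fc_1h,fc_3h Positive linear-scale fold changes (vectorised).
#' @param induced_threshold Fold change declaring induction (default 2);
#'   repression is declared below its reciprocal.
#' @return Character vector of class labels in A..J or "unclassified".
#' @export
classify_kinetics <- function(fc_1h, fc_3h, induced_threshold = 2) {
  stopifnot(length(fc_1h) == length(fc_3h))
  if (any(fc_1h <= 0 | fc_3h <= 0, na.rm = TRUE))
    stop("fold changes must be positive (linear scale)")
  thr <- induced_threshold
  up_branch <- function(f1, f3) {
    i1 <- f1 >= thr; i3 <- f3 >= thr
    if (i1 && !i3) "F"
    else if (i1 && i3 && f1 / f3 >= 2) "G"
    else if (i1 && i3 && f3 / f1 >= 2) "I"
    else if (i1 && i3) "H"
    else if (!i1 && i3) "J"
    else NA_character_
  }
  down_letters <- c(F = "A", G = "B", H = "C", I = "D", J = "E")
  vapply(seq_along(fc_1h), function(i) {
    f1 <- fc_1h[i]; f3 <- fc_3h[i]
    if (is.na(f1) || is.na(f3)) return("unclassified")
    if (f1 >= thr || f3 >= thr) {
      cl <- up_branch(f1, f3)
    } else if (1 / f1 >= thr || 1 / f3 >= thr) {
      cl <- down_letters[up_branch(1 / f1, 1 / f3)]
    } else cl <- NA_character_
    if (is.na(cl)) "unclassified" else unname(cl)
  }, character(1))
}

#' Kinetic-class enrichment of a gene set
#'
#' Applies the hypergeometric over-representation machinery with the kinetic
#' classes as terms: is the cluster enriched in, e.g., late-induced (class J)
#' genes relative to the universe?
#'
#' @param cluster_genes Character vector of cluster gene ids.
#' @param class_table Data frame `gene_id`, `class` covering the universe
#'   (classes from [classify_kinetics()]; "unclassified" rows allowed and
#'   kept as their own category).
#' @param alpha Raw-p cutoff (default 0.05).
#' @return Data frame as [hypergeom_enrichment()], one row per class present
#'   in the cluster; classes absent from the cluster get p = 1 rows.
#' @export
class_enrichment <- function(cluster_genes, class_table, alpha = 0.05) {
  stopifnot(all(c("gene_id", "class") %in% names(class_table)))
  ann <- data.frame(gene_id = class_table$gene_id,
                    term_id = class_table$class, stringsAsFactors = FALSE)
  res <- hypergeom_enrichment(cluster_genes, ann,
                              universe = unique(ann$gene_id), alpha = alpha)
  absent <- setdiff(unique(ann$term_id), res$term_id)
  if (length(absent)) {
    N <- length(unique(ann$gene_id))
    n <- length(intersect(cluster_genes, unique(ann$gene_id)))
    K_abs <- as.integer(table(unique(ann)$term_id)[absent])
    res <- rbind(res, data.frame(term_id = absent, k = 0L, n = n,
                                 K_term = K_abs, N = N, ratio = 0,
                                 p_value = 1, p_bh = 1, significant = FALSE,
                                 stringsAsFactors = FALSE))
  }
  names(res)[names(res) == "term_id"] <- "class"
  res
}
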