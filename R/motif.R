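#' Scan TSS-anchored promoters for an IUPAC motif
#'
#' Promoter sequences cover positions -L .. -1 relative to the transcription
#' start site (last base adjacent to the TSS). Every exact IUPAC match is
#' reported at the position of its match base closest to the TSS. With
#' `strands = "both"`, matches of the reverse complement are reported at the
#' forward-strand window they occupy, under the same anchor convention.
#'
#' @param promoters A [Biostrings::DNAStringSet], all sequences the same
#'   length, names = gene ids.
#' @param motif IUPAC pattern (ACGT plus degeneracy codes).
#' @param strands `"both"` (default) or `"given"` (forward strand only).
#' @return Named list (one element per gene) of integer vectors of
#'   TSS-relative occurrence positions (may be empty); multiple occurrences
#'   are all reported.
#' @export
scan_motif <- function(promoters, motif, strands = c("both", "given")) {
  strands <- match.arg(strands)
  check_iupac(motif)
  L <- unique(Biostrings::width(promoters))
  if (length(L) != 1) stop("promoters must all have the same length")
  if (nchar(motif) > L) stop("motif longer than the promoters")

  hit_ends <- function(pattern) {
    m <- Biostrings::vmatchPattern(pattern, promoters, fixed = "subject")
    lapply(Biostrings::endIndex(m), function(e) if (is.null(e)) integer(0) else e)
  }
  ends <- hit_ends(Biostrings::DNAString(motif))
  if (strands == "both") {
    rc <- Biostrings::reverseComplement(Biostrings::DNAString(motif))
    if (as.character(rc) != toupper(motif)) {       # palindromes count once
      ends_rc <- hit_ends(rc)
      ends <- Map(function(a, b) sort(unique(c(a, b))), ends, ends_rc)
    }
  }
  out <- lapply(ends, function(e) as.integer(e) - L - 1L)
  names(out) <- names(promoters)
  out
}

#' Detect a preferentially located motif (PLM)
#'
#' Tests whether a motif's occurrences concentrate in a particular region of
#' the promoter. Gene-level occurrences are binned at `bin_width` over
#' -L .. -1; each bin's gene count is compared with the uniform expectation
#' (total gene-bin incidences / number of bins) by a one-sided binomial test,
#' Bonferroni-corrected over bins. The functional window is the maximal run
#' of contiguous individually-significant bins (the run holding the smallest
#' bin p-value on ties); the motif is a PLM iff such a run exists.
#'
#' @param occurrences Output of [scan_motif()] on the genome-wide promoter
#'   set: per-gene positions.
#' @param promoter_length Promoter length L (default 1000).
#' @param bin_width Bin width in bases (default 50; must divide L).
#' @param alpha_detect Per-family significance level (default 0.01,
#'   Bonferroni over the bins).
#' @return `NULL` when the motif is not preferentially located, otherwise a
#'   list of class `plm_record`: `window` (c(a, b), TSS-relative, closed),
#'   `p_value` (smallest bin p), `genes_with_hit_in_window`, `genome_total`,
#'   `bin_counts`.
#' @export
detect_plm <- function(occurrences, promoter_length = 1000, bin_width = 50,
                       alpha_detect = 0.01) {
  stopifnot(promoter_length %% bin_width == 0)
  n_bins <- promoter_length / bin_width
  has_hit <- lengths(occurrences) > 0
  if (!any(has_hit)) stop("no occurrence genome-wide")

  # gene-level presence per bin: a gene counts once per bin it hits
  bin_of <- function(pos) unique(ceiling((pos + promoter_length + 1) / bin_width))
  gene_bins <- lapply(occurrences[has_hit], bin_of)
  counts <- tabulate(unlist(gene_bins), nbins = n_bins)
  total <- sum(counts)

  p_bin <- stats::pbinom(counts - 1, total, 1 / n_bins, lower.tail = FALSE)
  sig <- p_bin < alpha_detect / n_bins
  if (!any(sig)) return(NULL)

  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values)
  # longest run; ties broken by the run containing the smallest bin p-value
  best <- cand[order(-runs$lengths[cand],
                     vapply(cand, function(r) min(p_bin[starts[r]:ends[r]]), 1))][1]
  b1 <- starts[best]; b2 <- ends[best]
  window <- c((b1 - 1) * bin_width - promoter_length,
              b2 * bin_width - promoter_length - 1)

  in_window <- vapply(occurrences, function(pos)
    any(pos >= window[1] & pos <= window[2]), logical(1))
  structure(list(window = as.integer(window),
                 p_value = min(p_bin[b1:b2]),
                 genes_with_hit_in_window = sum(in_window),
                 genome_total = length(occurrences),
                 bin_counts = counts),
            class = "plm_record")
}

#' @export
print.plm_record <- function(x, ...) {
  cat("PLM: functional window [", x$window[1], ", ", x$window[2],
      "] (p = ", format(x$p_value, digits = 3), "), ",
      x$genes_with_hit_in_window, "/", x$genome_total,
      " genes with a hit in the window\n", sep = "")
  invisible(x)
}

#' Binomial over-representation of a PLM in a cluster
#'
#' Compares the number of cluster genes carrying the motif inside its
#' functional window with the genome-wide proportion, by an exact one-sided
#' binomial test: p = P(X >= k), X ~ Binomial(n, p0), p0 the genome
#' proportion of genes with a windowed hit. Each gene counts at most once.
#'
#' @param plm A `plm_record` from [detect_plm()].
#' @param cluster_genes Character vector of cluster gene ids.
#' @param occurrences Genome-wide per-gene occurrence positions (the scan the
#'   PLM was derived from); names are the gene universe.
#' @param alpha Significance cutoff (default 0.01).
#' @return One-row data frame: k, n, p0, p_value, significant.
#' @export
test_cluster_enrichment <- function(plm, cluster_genes, occurrences,
                                    alpha = 0.01) {
  stopifnot(inherits(plm, "plm_record"), length(cluster_genes) > 0)
  universe <- names(occurrences)
  if (!all(cluster_genes %in% universe))
    stop("cluster genes outside the promoter universe")
  w <- plm$window
  hit <- vapply(occurrences, function(pos)
    any(pos >= w[1] & pos <= w[2]), logical(1))
  k <- sum(hit[cluster_genes])
  n <- length(cluster_genes)
  p0 <- sum(hit) / length(hit)
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  data.frame(k = k, n = n, p0 = p0, p_value = p,
             significant = p < alpha)
}
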