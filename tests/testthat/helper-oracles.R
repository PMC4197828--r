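# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain string search, direct combinatorial sums,
# direct adjacency tallies.

iupac_table <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

# all concrete ACGT words an IUPAC pattern denotes
iupac_expand <- function(motif) {
  sets <- iupac_table[strsplit(toupper(motif), "")[[1]]]
  words <- Reduce(function(acc, s) as.vector(outer(acc, s, paste0)), sets, "")
  words
}

revcomp_str <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# oracle scan: expand the motif (and its reverse complement) to concrete
# words and string-search each; returns sorted TSS-relative end positions
oracle_scan <- function(seq_str, motif, both = TRUE) {
  L <- nchar(seq_str)
  m <- nchar(motif)
  words <- iupac_expand(motif)
  if (both) words <- unique(c(words, vapply(words, revcomp_str, "")))
  hits <- integer(0)
  for (w in words) {
    start <- 1
    repeat {
      i <- regexpr(w, substr(seq_str, start, L), fixed = TRUE)
      if (i == -1) break
      s <- start + as.integer(i) - 1
      hits <- c(hits, s + m - 1)
      start <- s + 1
    }
  }
  as.integer(sort(unique(hits)) - L - 1)
}

# exact binomial upper tail by direct summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# exact hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force distinct-neighbour degree tally over typed edge tables
oracle_degrees <- function(ppi, tf, universe) {
  e <- rbind(ppi[c("a", "b")], tf[c("a", "b")])
  e <- e[e$a %in% universe & e$b %in% universe & e$a != e$b, ]
  nb <- list()
  for (i in seq_len(nrow(e))) {
    nb[[e$a[i]]] <- union(nb[[e$a[i]]], e$b[i])
    nb[[e$b[i]]] <- union(nb[[e$b[i]]], e$a[i])
  }
  lengths(nb)
}

# match cluster labels to truth by majority vote, then misclassification
true_misclassification <- function(map, labels, classified, K) {
  tab <- table(factor(labels, 1:K), factor(map, 1:K))
  perm <- apply(tab, 2, which.max)
  mean(perm[map[classified]] != labels[classified])
}

# step-up BH by direct enumeration of the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, n / i * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}
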