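# Small builders and independent brute-force oracles shared across tests.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

make_gene_bed <- function(rows) {
  write_lines_tmp(rows, ext = ".bed")
}

make_track <- function(chrom, position, effect, pvalue) {
  df <- data.frame(chrom = chrom, position = position, effect = effect,
                   pvalue = pvalue)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A flat correlation profile: every distance maps to the same correlation.
const_profile <- function(r, d_max = 1e7) {
  corr_profile(c(0, d_max), r)
}

# O(n * m) all-pairs overlap scan (the oracle associate_loci must match).
bf_overlap <- function(loci, intervals) {
  hits <- matrix(FALSE, nrow(loci), nrow(intervals))
  for (i in seq_len(nrow(loci))) {
    for (j in seq_len(nrow(intervals))) {
      hits[i, j] <- loci$chrom[i] == intervals$chrom[j] &&
        loci$position[i] >= intervals$start[j] &&
        loci$position[i] < intervals$end[j]
    }
  }
  hits
}

# O(n^2) neighbor-pair count oracle: for each significant locus, one pair
# per existing closest-upstream locus and one per closest-downstream.
bf_pair_count <- function(positions, p, threshold) {
  count <- 0
  for (i in seq_along(positions)) {
    if (p[i] > threshold) next
    has_up <- any(positions < positions[i])
    has_dn <- any(positions > positions[i])
    count <- count + has_up + has_dn
  }
  count
}

# Connectivity by breadth-first search on an adjacency matrix (independent
# of igraph).
bf_connected <- function(A, nodes) {
  if (length(nodes) <= 1) return(TRUE)
  seen <- nodes[1]
  frontier <- nodes[1]
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, function(u) {
      nodes[A[u, nodes] > 0]
    })))
    frontier <- setdiff(nb, seen)
    seen <- union(seen, frontier)
  }
  length(seen) == length(nodes)
}

# Exhaustive maximum-weight connected subgraph on small graphs.
bf_mwcs <- function(A, w) {
  n <- length(w)
  best <- max(w)
  for (mask in seq_len(2^n - 1)) {
    nodes <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!bf_connected(A, nodes)) next
    best <- max(best, sum(w[nodes]))
  }
  best
}

# Scored network helper: an igraph with named vertices and score attrs.
scored_graph <- function(A, fisher, combined_p = exp(-fisher / 2)) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("N%02d", seq_len(nrow(A)))
  igraph::V(g)$fisher_score <- fisher
  igraph::V(g)$combined_p <- pmin(combined_p, 1)
  igraph::V(g)$no_data <- FALSE
  g
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
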