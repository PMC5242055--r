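#' Overlay gene scores on an interaction network
#'
#' Builds an undirected igraph from an edge list, removes self-loops and
#' duplicate edges, keeps the largest connected component (dropped
#' components are reported), and attaches `fisher_score` / `combined_p`
#' vertex attributes. Network nodes without a score are kept with score 0
#' and p 1 and flagged `no_data`; scored genes absent from the network are
#' listed in the `unplaced` graph attribute, dropped component members in
#' `dropped_nodes`.
#'
#' @param edges two-column `data.frame` (or matrix) of gene id pairs.
#' @param gene_scores `data.frame` with columns `gene_id`, `combined_p`,
#'   `fisher_score`.
#' @return an igraph with vertex attributes `fisher_score`, `combined_p`,
#'   `no_data`; graph attributes record dropped components.
#' @export
build_scored_network <- function(edges, gene_scores) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) stop("empty edge list")
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    keep <- which.max(comp$csize)
    dropped <- igraph::V(g)$name[comp$membership != keep]
    message("dropping ", comp$no - 1, " minor component(s) with ",
            length(dropped), " node(s)")
    g <- igraph::induced_subgraph(g, comp$membership == keep)
    g <- igraph::set_graph_attr(g, "dropped_nodes", dropped)
  } else {
    g <- igraph::set_graph_attr(g, "dropped_nodes", character())
  }
  idx <- match(igraph::V(g)$name, gene_scores$gene_id)
  fs <- ifelse(is.na(idx), 0, gene_scores$fisher_score[idx])
  cp <- ifelse(is.na(idx), 1, gene_scores$combined_p[idx])
  g <- igraph::set_vertex_attr(g, "fisher_score", value = fs)
  g <- igraph::set_vertex_attr(g, "combined_p", value = cp)
  g <- igraph::set_vertex_attr(g, "no_data", value = is.na(idx))
  igraph::set_graph_attr(g, "unplaced",
                         setdiff(gene_scores$gene_id, igraph::V(g)$name))
}

# Edge weights coupling node scores into the community objective: each edge
# gets 1 + the mean of its endpoints' max-normalized Fisher scores, keeping
# all weights positive in [1, 2].
score_edge_weights <- function(g) {
  ns <- igraph::V(g)$fisher_score
  mx <- max(ns)
  ns <- if (is.finite(mx) && mx > 0) ns / mx else rep(0, length(ns))
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  1 + (ns[ends[, 1]] + ns[ends[, 2]]) / 2
}

#' Find score-enriched modules by spin-glass community detection
#'
#' Runs spin-glass community detection (resolution parameter
#' `gamma = 0.5`) on the scored network with edge weights uplifted by the
#' endpoint scores, then filters communities to the size window
#' `[min_size, max_size]`. Oversized communities are re-split by one
#' recursive spin-glass pass and discarded if still oversized. Each
#' retained module is reported with its chi-squared significance
#' ([module_significance()]); unscored nodes participate in the topology
#' and contribute `log(1) = 0` to the significance.
#'
#' Simulated annealing is stochastic and can settle in local optima, so
#' the partition is re-run `restarts` times and the solution maximizing
#' the Reichardt-Bornholdt objective at the same `gamma` is kept.
#'
#' @param network scored igraph from [build_scored_network()]; must be
#'   connected.
#' @param gamma spin-glass resolution parameter.
#' @param min_size,max_size module size window (genes).
#' @param spins maximum number of communities attempted.
#' @param restarts independent annealing runs; the best partition under
#'   the generalized-modularity objective wins.
#' @param seed optional integer seed; fixed seeds reproduce module lists
#'   exactly.
#' @return list of `gene_module` objects (unranked; see [rank_modules()]).
#' @export
spinglass_modules <- function(network, gamma = 0.5, min_size = 8,
                              max_size = 100, spins = 25, restarts = 3,
                              seed = NULL) {
  stopifnot(igraph::is_connected(network), restarts >= 1)
  if (igraph::vcount(network) < min_size) {
    warning("network smaller than min_size; no modules")
    return(list())
  }
  groups <- with_seed(seed, spinglass_partition(network, gamma, spins,
                                                min_size, max_size,
                                                restarts = restarts))
  if (!length(groups)) {
    warning("no community within the size window [", min_size, ", ",
            max_size, "]")
    return(list())
  }
  ew <- score_edge_weights(network)
  modules <- lapply(seq_along(groups), function(i) {
    make_module(sprintf("M%02d", i), groups[[i]], network, ew,
                algorithm = "spinglass")
  })
  modules
}

# Generalized (Reichardt-Bornholdt) modularity of a weighted partition:
# sum over communities of W_c / W - gamma * (S_c / 2W)^2.
rb_modularity <- function(g, memb, w, gamma) {
  en <- igraph::ends(g, igraph::E(g), names = FALSE)
  W <- sum(w)
  s_v <- igraph::strength(g, weights = w)
  q <- 0
  for (k in unique(memb)) {
    internal <- memb[en[, 1]] == k & memb[en[, 2]] == k
    q <- q + sum(w[internal]) / W - gamma * (sum(s_v[memb == k]) / (2 * W))^2
  }
  q
}

# One (optionally recursive) spin-glass pass returning gene-name groups
# within the size window; best of `restarts` annealing runs.
spinglass_partition <- function(g, gamma, spins, min_size, max_size,
                                restarts = 1, resplit = TRUE) {
  w <- score_edge_weights(g)
  memb <- NULL
  best_q <- -Inf
  for (r in seq_len(restarts)) {
    comm <- igraph::cluster_spinglass(g, weights = w, spins = spins,
                                      gamma = gamma)
    m <- igraph::membership(comm)
    q <- rb_modularity(g, m, w, gamma)
    if (q > best_q) {
      best_q <- q
      memb <- m
    }
  }
  out <- list()
  for (k in sort(unique(memb))) {
    nodes <- igraph::V(g)$name[memb == k]
    if (length(nodes) > max_size && resplit) {
      sub <- igraph::induced_subgraph(g, memb == k)
      sc <- igraph::components(sub)
      if (sc$no > 1) {
        sub <- igraph::induced_subgraph(sub, sc$membership == which.max(sc$csize))
      }
      if (igraph::vcount(sub) > min_size) {
        out <- c(out, spinglass_partition(sub, gamma, spins, min_size,
                                          max_size, restarts = restarts,
                                          resplit = FALSE))
      }
    } else if (length(nodes) >= min_size && length(nodes) <= max_size) {
      out <- c(out, list(nodes))
    }
  }
  out
}

make_module <- function(id, genes, network, ew, algorithm,
                        total_weight = NA_real_) {
  vidx <- match(genes, igraph::V(network)$name)
  p <- igraph::V(network)$combined_p[vidx]
  fs <- igraph::V(network)$fisher_score[vidx]
  sig <- module_significance(p)
  # weighted modularity contribution of this node set
  m <- sum(ew)
  ends <- igraph::ends(network, igraph::E(network), names = FALSE)
  is_in <- ends[, 1] %in% vidx & ends[, 2] %in% vidx
  touches <- ends[, 1] %in% vidx | ends[, 2] %in% vidx
  w_in <- sum(ew[is_in])
  strength <- sum(ew[touches]) + w_in  # degree-sum counts internal edges twice
  contribution <- w_in / m - (strength / (2 * m))^2
  structure(list(module_id = id, genes = genes, k = length(genes),
                 chi2_stat = sig$chi2_stat, df = sig$df,
                 p_value = sig$p_value, mean_score = mean(fs),
                 modularity_contribution = contribution,
                 algorithm = algorithm, total_weight = total_weight),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat("module ", x$module_id, " [", x$algorithm, "]: ", x$k, " genes, ",
      "chi2 = ", signif(x$chi2_stat, 4), " (df ", x$df, "), p = ",
      signif(x$p_value, 3), ", mean score ", signif(x$mean_score, 3),
      "\n", sep = "")
  invisible(x)
}

#' Chi-squared module significance
#'
#' Fisher's method over the module's combined gene p-values:
#' `chi2 = -2 * sum(log(p_g))`, compared to a chi-squared distribution
#' with `2k` degrees of freedom (`k` genes). Genes without data carry
#' `p = 1` and contribute 0, so modules may legitimately implicate
#' members that have no significant evidence of their own.
#'
#' @param combined_p combined p-values of the module's genes.
#' @return list with `chi2_stat`, `df`, `p_value`.
#' @export
module_significance <- function(combined_p) {
  stopifnot(all(combined_p > 0), all(combined_p <= 1))
  chi2 <- -2 * sum(log(combined_p))
  df <- 2L * length(combined_p)
  list(chi2_stat = chi2, df = df,
       p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Rank modules by significance
#'
#' Ascending by p-value; ties broken by descending mean score, then by
#' module id.
#'
#' @param modules list of `gene_module` objects.
#' @return the reordered list.
#' @export
rank_modules <- function(modules) {
  if (!length(modules)) return(modules)
  p <- vapply(modules, `[[`, numeric(1), "p_value")
  ms <- vapply(modules, `[[`, numeric(1), "mean_score")
  id <- vapply(modules, `[[`, character(1), "module_id")
  modules[order(p, -ms, id)]
}

#' Greedy maximum-weight connected subgraph module
#'
#' A greedy heuristic for the maximum-weight connected subgraph problem
#' (the exact branch-and-cut formulation requires an integer-programming
#' solver and is out of scope). Node weights are
#' `fisher_score - score_offset`, where the offset is typically the
#' background quantile from [select_high_scoring()]. Expansion starts from
#' the maximum-weight node and repeatedly attaches the positive-weight
#' node with the best weight-minus-path-penalty over a node-weighted
#' shortest path (negative nodes on the path cost their weight), as long
#' as the total weight increases. The result is a single connected
#' subnetwork, typically larger than individual spin-glass modules. If
#' every weight is negative the single best node is returned.
#'
#' @param network scored igraph from [build_scored_network()].
#' @param score_offset subtracted from every node's Fisher score.
#' @return a `gene_module` (algorithm `"mwcs"`) whose `total_weight` is
#'   the summed node weight of the subgraph.
#' @export
greedy_mwcs <- function(network, score_offset) {
  n <- igraph::vcount(network)
  stopifnot(n >= 1)
  w <- igraph::V(network)$fisher_score - score_offset
  adj <- lapply(igraph::as_adj_list(network), as.integer)
  S <- which.max(w)
  repeat {
    cost <- pmax(0, -w)
    dist <- rep(Inf, n)
    pred <- rep(NA_integer_, n)
    done <- rep(FALSE, n)
    dist[S] <- 0
    done[S] <- TRUE
    for (u in S) {
      for (v in adj[[u]]) {
        if (!done[v] && cost[v] < dist[v]) {
          dist[v] <- cost[v]
          pred[v] <- u
        }
      }
    }
    repeat {
      open <- which(!done & is.finite(dist))
      if (!length(open)) break
      u <- open[which.min(dist[open])]
      done[u] <- TRUE
      for (v in adj[[u]]) {
        if (!done[v] && dist[u] + cost[v] < dist[v]) {
          dist[v] <- dist[u] + cost[v]
          pred[v] <- u
        }
      }
    }
    cand <- setdiff(which(w > 0), S)
    if (!length(cand)) break
    gain <- w[cand] - dist[cand]
    if (max(gain) <= 0) break
    v <- cand[which.max(gain)]
    path <- integer()
    u <- v
    while (!(u %in% S)) {
      path <- c(path, u)
      u <- pred[u]
    }
    S <- c(S, path)
  }
  S <- sort(S)
  make_module("MWCS", igraph::V(network)$name[S], network,
              score_edge_weights(network), algorithm = "mwcs",
              total_weight = sum(w[S]))
}

#' Module tables
#'
#' Flattens a module list into the two standard output tables: a per-gene
#' table (`module_id`, `gene`, `combined_p`, `fisher_score`) and a summary
#' table (`module_id`, `k`, `chi2`, `df`, `p_value`, `mean_score`).
#'
#' @param modules list of `gene_module` objects.
#' @param network the scored igraph the modules came from.
#' @return list with `genes` and `summary` data frames.
#' @export
module_tables <- function(modules, network) {
  if (!length(modules)) {
    return(list(
      genes = data.frame(module_id = character(), gene = character(),
                         combined_p = numeric(), fisher_score = numeric()),
      summary = data.frame(module_id = character(), k = integer(),
                           chi2 = numeric(), df = integer(),
                           p_value = numeric(), mean_score = numeric())))
  }
  genes <- do.call(rbind, lapply(modules, function(m) {
    vidx <- match(m$genes, igraph::V(network)$name)
    data.frame(module_id = m$module_id, gene = m$genes,
               combined_p = igraph::V(network)$combined_p[vidx],
               fisher_score = igraph::V(network)$fisher_score[vidx],
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(modules, function(m) {
    data.frame(module_id = m$module_id, k = m$k, chi2 = m$chi2_stat,
               df = m$df, p_value = m$p_value, mean_score = m$mean_score,
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- rownames(summary) <- NULL
  list(genes = genes, summary = summary)
}
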