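test_that("network building keeps the main component and flags gaps", {
  edges <- data.frame(from = c("A", "B", "C", "X", "B"),
                      to = c("B", "C", "D", "Y", "A"))
  gs <- data.frame(gene_id = c("A", "B", "C", "Z"),
                   combined_p = c(0.1, 0.2, 0.3, 0.4),
                   fisher_score = fisher_score(c(0.1, 0.2, 0.3, 0.4)),
                   stringsAsFactors = FALSE)
  expect_message(g <- build_scored_network(edges, gs), "dropping")
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C", "D"))
  # duplicate A-B / B-A collapses to a single undirected edge
  expect_equal(igraph::ecount(g), 3)
  # unscored node D kept with p = 1 and flagged
  expect_equal(igraph::V(g)$combined_p[igraph::V(g)$name == "D"], 1)
  expect_true(igraph::V(g)$no_data[igraph::V(g)$name == "D"])
  expect_equal(igraph::graph_attr(g, "unplaced"), "Z")
  expect_error(build_scored_network(edges[0, ], gs), "empty")
})

test_that("spin-glass separates two cliques joined by a bridge", {
  A <- matrix(0, 20, 20)
  A[1:10, 1:10] <- 1
  A[11:20, 11:20] <- 1
  diag(A) <- 0
  A[10, 11] <- A[11, 10] <- 1
  g <- scored_graph(A, fisher = rep(1, 20))
  mods <- spinglass_modules(g, min_size = 8, max_size = 100, seed = 1)
  expect_equal(length(mods), 2)
  sets <- lapply(mods, `[[`, "genes")
  expect_true(any(vapply(sets, setequal, logical(1), sprintf("N%02d", 1:10))))
  expect_true(any(vapply(sets, setequal, logical(1), sprintf("N%02d", 11:20))))
})

test_that("returned modules are connected and within the size window", {
  set.seed(61)
  # ring of 30 nodes
  A <- matrix(0, 30, 30)
  for (i in 1:30) {
    j <- i %% 30 + 1
    A[i, j] <- A[j, i] <- 1
  }
  g <- scored_graph(A, fisher = runif(30))
  mods <- suppressWarnings(spinglass_modules(g, seed = 2))
  expect_true(is.list(mods))
  for (m in mods) {
    expect_gte(m$k, 8)
    expect_lte(m$k, 100)
    idx <- match(m$genes, igraph::V(g)$name)
    expect_true(bf_connected(A, idx))
  }
})

test_that("spin-glass recovers a planted community with shifted scores", {
  set.seed(62)
  cfg <- sim_config(n_genes = 300, n_planted = 20, effect_shift = 3,
                    seed = 62)
  ids <- sprintf("G%04d", 1:300)
  planted <- ids[1:20]
  net <- simulate_network(cfg, ids, planted, tempfile())
  z <- abs(rnorm(300) + 3 * (ids %in% planted))
  gs <- data.frame(gene_id = ids,
                   combined_p = pmin(2 * stats::pnorm(-z), 1),
                   fisher_score = fisher_score(pmin(2 * stats::pnorm(-z), 1)),
                   stringsAsFactors = FALSE)
  g <- suppressMessages(build_scored_network(net$edges, gs))
  mods <- spinglass_modules(g, seed = 63)
  best <- max(vapply(mods, function(m) jaccard(m$genes, planted),
                     numeric(1)))
  expect_gte(best, 0.8)
  # enrichment: the top-ranked module's scores dominate the full
  # distribution (every block of the benchmark graph is a topological
  # community, so ranking by significance is what singles out signal)
  top <- rank_modules(mods)[[1]]
  ks <- suppressWarnings(
    stats::ks.test(gs$fisher_score[gs$gene_id %in% top$genes],
                   gs$fisher_score, alternative = "less"))
  expect_lt(ks$p.value, 0.01)
})

test_that("module significance follows the chi-squared combination", {
  s <- module_significance(rep(1, 3))
  expect_equal(s$chi2_stat, 0)
  expect_equal(s$df, 6L)
  expect_equal(s$p_value, 1)
  s1 <- module_significance(exp(-1))
  expect_equal(s1$chi2_stat, 2)
  expect_equal(s1$p_value, exp(-1), tolerance = 1e-12)
})

test_that("module significance is calibrated under the null", {
  set.seed(64)
  n_mod <- 4000
  p_mat <- matrix(runif(n_mod * 5), ncol = 5)
  rej <- mean(apply(p_mat, 1, function(p) {
    module_significance(p)$p_value
  }) < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("module ranking orders by p, then mean score, then id", {
  mk <- function(id, p, ms) {
    structure(list(module_id = id, genes = "x", k = 1, chi2_stat = 1,
                   df = 2, p_value = p, mean_score = ms,
                   modularity_contribution = 0, algorithm = "spinglass",
                   total_weight = NA_real_), class = "gene_module")
  }
  mods <- list(mk("M1", 0.5, 1), mk("M2", 0.01, 2), mk("M3", 0.01, 3))
  ranked <- rank_modules(mods)
  expect_equal(vapply(ranked, `[[`, character(1), "module_id"),
               c("M3", "M2", "M1"))
  expect_equal(rank_modules(list()), list())
  # output is a permutation of the input
  expect_setequal(vapply(rank_modules(mods), `[[`, character(1),
                         "module_id"),
                  c("M1", "M2", "M3"))
})

test_that("greedy subnetwork stays put when expansion only loses weight", {
  A <- matrix(0, 6, 6)
  A[1, 2:6] <- A[2:6, 1] <- 1  # star
  g <- scored_graph(A, fisher = c(5, rep(-1, 5)) + 10)
  m <- greedy_mwcs(g, score_offset = 10)
  expect_equal(m$genes, "N01")
  expect_equal(m$total_weight, 5)
})

test_that("greedy subnetwork crosses a worthwhile negative bridge", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  g <- scored_graph(A, fisher = c(2, -1, 3) + 10)
  m <- greedy_mwcs(g, score_offset = 10)
  expect_setequal(m$genes, c("N01", "N02", "N03"))
  expect_equal(m$total_weight, 4)
  # exhaustive oracle agrees this is optimal
  expect_equal(bf_mwcs(A, c(2, -1, 3)), 4)
})

test_that("greedy subnetwork weight approaches the exhaustive optimum", {
  set.seed(65)
  wins <- 0
  n_inst <- 30
  for (i in seq_len(n_inst)) {
    n <- 8
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.35)
    A <- A + t(A)
    w <- round(rnorm(n, 0, 2), 3)
    g <- scored_graph(A, fisher = w + 50)
    m <- greedy_mwcs(g, score_offset = 50)
    # oracle restricted to the component the greedy works in
    keep <- match(igraph::V(g)$name, sprintf("N%02d", 1:n))
    opt <- bf_mwcs(A[keep, keep, drop = FALSE], w[keep])
    ok <- if (opt > 0) m$total_weight >= 0.8 * opt else
      m$total_weight >= opt - 1e-9
    wins <- wins + ok
  }
  expect_gte(wins / n_inst, 0.85)
})

test_that("module tables flatten gene and summary views", {
  A <- matrix(0, 12, 12)
  A[1:6, 1:6] <- 1
  A[7:12, 7:12] <- 1
  diag(A) <- 0
  A[6, 7] <- A[7, 6] <- 1
  g <- scored_graph(A, fisher = rep(2, 12))
  mods <- suppressWarnings(spinglass_modules(g, min_size = 3, seed = 3))
  tabs <- module_tables(mods, g)
  expect_equal(nrow(tabs$genes), sum(vapply(mods, `[[`, numeric(1), "k")))
  expect_equal(nrow(tabs$summary), length(mods))
  expect_true(all(tabs$summary$df == 2 * tabs$summary$k))
})
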