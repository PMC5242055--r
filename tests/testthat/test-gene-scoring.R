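two_ctx <- function(w_expr = 1, w_prom = 1) {
  list(context_def("expr", "expression", expression_rule(),
                   weight = w_expr, direction = 1),
       context_def("prom", "meth", promoter_rule(),
                   weight = w_prom, direction = -1))
}

test_that("gene combination applies weights and directionality", {
  ctx <- list(context_def("expr", "expression", expression_rule(),
                          weight = 1, direction = 1))
  cs <- data.frame(gene_id = "G1", context = "expr", adjusted_p = 0.0455,
                   direction = 1, stringsAsFactors = FALSE)
  gs <- combine_gene_scores(cs, ctx)
  expect_equal(gs$statistic, 2.0, tolerance = 1e-3)

  # expression up plus promoter methylation up cancel exactly
  cs2 <- data.frame(gene_id = "G1", context = c("expr", "prom"),
                    adjusted_p = rep(2 * stats::pnorm(-2), 2),
                    direction = c(1, 1), stringsAsFactors = FALSE)
  gs2 <- combine_gene_scores(cs2, two_ctx())
  expect_equal(gs2$statistic, 0, tolerance = 1e-9)

  # promoter methylation down is concordant and adds
  cs3 <- cs2
  cs3$direction <- c(1, -1)
  gs3 <- combine_gene_scores(cs3, two_ctx())
  expect_equal(gs3$statistic, 4 / sqrt(2), tolerance = 1e-8)
})

test_that("agnostic contexts always contribute positively", {
  ctx <- list(context_def("expr", "expression", expression_rule(),
                          weight = 1, direction = 1),
              context_def("hydroxy", "meth", body_rule(),
                          weight = 1, direction = 0))
  p2 <- 2 * stats::pnorm(-2)
  cs <- data.frame(gene_id = "G1", context = c("expr", "hydroxy"),
                   adjusted_p = c(p2, p2), direction = c(1, -1),
                   stringsAsFactors = FALSE)
  gs <- combine_gene_scores(cs, ctx)
  expect_equal(gs$statistic, 4 / sqrt(2), tolerance = 1e-8)
})

test_that("genes with partial data are scored from available contexts", {
  p2 <- 2 * stats::pnorm(-2)
  cs <- data.frame(gene_id = c("G1", "G1", "G2"),
                   context = c("expr", "prom", "expr"),
                   adjusted_p = p2, direction = c(1, -1, 1),
                   stringsAsFactors = FALSE)
  gs <- combine_gene_scores(cs, two_ctx())
  expect_equal(nrow(gs), 2)
  expect_equal(gs$statistic[gs$gene_id == "G2"], 2, tolerance = 1e-8)
  expect_equal(gs$pattern, c("expr+prom", "expr"))
})

test_that("bootstrap p-values are exchangeable across identical genes", {
  cs <- data.frame(gene_id = sprintf("G%03d", 1:60), context = "expr",
                   adjusted_p = 0.2, direction = 1, stringsAsFactors = FALSE)
  ctx <- list(context_def("expr", "expression", expression_rule(),
                          weight = 1, direction = 1))
  gs <- combine_gene_scores(cs, ctx)
  gs <- bootstrap_gene_p(gs, cs, ctx, n_boot = 500, seed = 1)
  expect_equal(length(unique(gs$combined_p)), 1)
})

test_that("bootstrap nulls are calibrated on fully null data", {
  set.seed(51)
  n <- 500
  cs <- data.frame(gene_id = sprintf("G%03d", 1:n), context = "expr",
                   adjusted_p = runif(n),
                   direction = sample(c(-1, 1), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  ctx <- list(context_def("expr", "expression", expression_rule(),
                          weight = 1, direction = 1))
  gs <- bootstrap_gene_p(combine_gene_scores(cs, ctx), cs, ctx,
                         n_boot = 5000, seed = 2)
  ks <- suppressWarnings(stats::ks.test(gs$combined_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted signal separates from background in bootstrap p", {
  # the bootstrap pool contains the planted genes, so the planted
  # fraction must stay small for their p-values to clear 0.05
  set.seed(52)
  n <- 500
  planted <- 1:20
  z <- abs(rnorm(n) + 3 * (seq_len(n) %in% planted))
  cs <- data.frame(gene_id = sprintf("G%03d", 1:n), context = "expr",
                   adjusted_p = 2 * stats::pnorm(-z), direction = 1,
                   stringsAsFactors = FALSE)
  ctx <- list(context_def("expr", "expression", expression_rule(),
                          weight = 1, direction = 1))
  gs <- bootstrap_gene_p(combine_gene_scores(cs, ctx), cs, ctx,
                         n_boot = 1000, seed = 3)
  expect_lt(median(gs$combined_p[planted]), 0.05)
  expect_gt(median(gs$combined_p[-planted]), 0.3)
  expect_lt(median(gs$combined_p[-planted]), 0.7)
})

test_that("Fisher scores follow -2 log p", {
  expect_equal(fisher_score(1), 0)
  expect_equal(fisher_score(exp(-1)), 2)
  expect_equal(fisher_score(0.01), 9.2103404, tolerance = 1e-7)
  expect_error(fisher_score(0))
})

test_that("high-scoring selection honors the alpha boundaries", {
  set.seed(53)
  scores <- stats::setNames(rexp(100), sprintf("G%03d", 1:100))
  all_g <- suppressWarnings(select_high_scoring(scores, alpha = 1, seed = 4))
  expect_setequal(as.vector(all_g), names(scores))
  top <- suppressWarnings(select_high_scoring(scores, alpha = 0, seed = 5))
  expect_true(all(top %in% names(scores)[scores == max(scores)]))
  expect_gte(length(top), 1)
})

test_that("high-scoring selection recalls planted genes", {
  set.seed(54)
  n <- 1000
  planted <- 1:50
  z <- abs(rnorm(n) + 3 * (seq_len(n) %in% planted))
  cs <- data.frame(gene_id = sprintf("G%04d", 1:n), context = "expr",
                   adjusted_p = 2 * stats::pnorm(-z), direction = 1,
                   stringsAsFactors = FALSE)
  ctx <- list(context_def("expr", "expression", expression_rule(),
                          weight = 1, direction = 1))
  gs <- bootstrap_gene_p(combine_gene_scores(cs, ctx), cs, ctx,
                         n_boot = 1000, seed = 6)
  gs$fisher_score <- fisher_score(gs$combined_p)
  sel <- select_high_scoring(stats::setNames(gs$fisher_score, gs$gene_id),
                             alpha = 0.05, seed = 7)
  recall <- mean(sprintf("G%04d", planted) %in% sel)
  expect_gte(recall, 0.6)
})

test_that("raising a context weight raises its genes' relative rank", {
  # X is strong in prom only, Y in expr only; equal weights tie them
  p_str <- 0.001
  p_wk <- 0.5
  cs <- data.frame(gene_id = c("X", "X", "Y", "Y"),
                   context = c("expr", "prom", "expr", "prom"),
                   adjusted_p = c(p_wk, p_str, p_str, p_wk),
                   direction = c(1, -1, 1, -1), stringsAsFactors = FALSE)
  even <- combine_gene_scores(cs, two_ctx(1, 1))
  expect_equal(abs(even$statistic[even$gene_id == "X"]),
               abs(even$statistic[even$gene_id == "Y"]), tolerance = 1e-9)
  tilted <- combine_gene_scores(cs, two_ctx(1, 3))
  expect_gt(abs(tilted$statistic[tilted$gene_id == "X"]),
            abs(tilted$statistic[tilted$gene_id == "Y"]))
})

test_that("genes without any context data are reported, not dropped silently", {
  cs <- data.frame(gene_id = "G1", context = "expr", adjusted_p = 0.5,
                   direction = 1, stringsAsFactors = FALSE)
  ctx <- list(context_def("expr", "expression", expression_rule(),
                          weight = 1, direction = 1),
              context_def("prom", "meth", promoter_rule(),
                          weight = 0, direction = -1))
  cs2 <- rbind(cs, data.frame(gene_id = "G2", context = "prom",
                              adjusted_p = 0.5, direction = 1))
  gs <- combine_gene_scores(cs2, ctx)
  expect_equal(gs$gene_id, "G1")
  expect_equal(attr(gs, "no_data"), "G2")
})
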