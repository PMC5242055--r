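#' Simulation configuration
#'
#' Describes a complete synthetic study: gene models tiled along synthetic
#' chromosomes, one epigenomic score track with spatially correlated
#' p-values, a gene-level expression table, and an interaction network
#' with a planted community. Planted genes receive a mean shift on the
#' Z-scale in every context (epigenomic loci and expression) with a
#' coherent repression signature — expression down, promoter methylation
#' up, gene-body methylation down (mirrored when `effect_shift` is
#' negative) — so that the directionality algebra of the reduced model
#' adds the planted evidence constructively. Effect signs match the
#' signature with probability `sign_consistency`. The planted community
#' is written alongside the network for recovery scoring.
#'
#' Defaults emulate a desk-scale differential methylation study: 500
#' genes of 5 kb spaced 10 kb apart, 5-15 promoter and 10-40 gene-body
#' loci per gene, exponential distance-decay correlation with a 1 kb
#' length scale (local methylation correlation decays over roughly this
#' scale), 25 planted genes at a Z shift of +3, effect signs concordant
#' with the shift 90% of the time, and a planted-partition network
#' (within-community edge probability 0.3, background 0.01).
#'
#' @param n_genes number of genes.
#' @param gene_length,gene_spacing gene body length and intergenic gap
#'   (bp).
#' @param promoter_loci,body_loci integer ranges (length-2) for the number
#'   of loci per promoter / gene body.
#' @param corr_model list: `list(type = "independent")`,
#'   `list(type = "exp_decay", lambda = <bp>)` or
#'   `list(type = "block", rho = <r>)`.
#' @param n_planted number of planted high-scoring genes.
#' @param effect_shift Z-scale mean shift added to planted genes' signals.
#' @param sign_consistency probability a planted locus effect sign matches
#'   the shift sign.
#' @param network list: `list(type = "planted_partition", p_in =, p_out =,
#'   bg_block_size =)` or `list(type = "erdos_renyi", p =)`. Under the
#'   planted partition the planted genes form one block and the remaining
#'   genes are partitioned into background blocks of `bg_block_size`, so
#'   every node has a home community; edges appear with probability `p_in`
#'   within a block and `p_out` between blocks. The defaults (0.3 within,
#'   0.005 between, background blocks of 40) put the graph in the regime
#'   where the planted partition is itself the generalized-modularity
#'   optimum at resolution 0.5: the between-block penalty exceeds the
#'   Poisson fluctuation of cross-block edge counts, which is what makes
#'   community recovery a well-posed benchmark.
#' @param n_chromosomes genes are dealt round-robin across this many
#'   synthetic chromosomes.
#' @param enhancers also emit a BED of enhancer-like peaks upstream of a
#'   subset of genes?
#' @param seed integer master seed; all stage seeds derive from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, gene_length = 5000, gene_spacing = 10000,
                       promoter_loci = c(5, 15), body_loci = c(10, 40),
                       corr_model = list(type = "exp_decay", lambda = 1000),
                       n_planted = 25, effect_shift = 3,
                       sign_consistency = 0.9,
                       network = list(type = "planted_partition",
                                      p_in = 0.3, p_out = 0.005,
                                      bg_block_size = 40),
                       n_chromosomes = 1, enhancers = FALSE, seed = 1) {
  stopifnot(n_genes >= 1, gene_length > 0, gene_spacing >= 0,
            length(promoter_loci) == 2, length(body_loci) == 2,
            promoter_loci[1] >= 1, body_loci[1] >= 1,
            n_planted >= 0, n_planted <= n_genes,
            sign_consistency >= 0, sign_consistency <= 1,
            corr_model$type %in% c("independent", "exp_decay", "block"),
            network$type %in% c("planted_partition", "erdos_renyi"))
  if (corr_model$type == "exp_decay") stopifnot(corr_model$lambda > 0)
  if (corr_model$type == "block") {
    stopifnot(corr_model$rho >= 0, corr_model$rho < 1)
  }
  structure(as.list(environment()), class = "sim_config")
}

# Correlated folded-normal machinery: draw Z ~ N(shift, Sigma(positions)).
sim_z <- function(positions, corr_model, shift = 0) {
  n <- length(positions)
  eps <- rnorm(n)
  z <- switch(corr_model$type,
    independent = eps,
    exp_decay = {
      Sg <- exp(-abs(outer(positions, positions, "-")) / corr_model$lambda)
      as.vector(t(chol(Sg)) %*% eps)
    },
    block = {
      rho <- corr_model$rho
      sqrt(rho) * rnorm(1) + sqrt(1 - rho) * eps
    })
  z + shift
}

# Signed effect with configurable sign concordance for planted loci.
# `target` is the planted effect direction (+1/-1, possibly per locus);
# null loci take the sign of their own Z.
sim_effect <- function(z, planted, target, sign_consistency) {
  s <- sign(z)
  s[s == 0] <- 1
  if (planted) {
    target <- rep_len(target, length(z))
    flip <- runif(length(z)) > sign_consistency
    s <- ifelse(flip, -target, target)
  }
  abs(z) * s
}

#' Simulate a synthetic genome-scale input set
#'
#' Writes, under `dir`: `genes.bed` (BED6), `methylation.tsv` (score
#' track: `chrom position effect pvalue`), `expression.tsv`
#' (`gene effect pvalue`), `planted_genes.txt`, and optionally
#' `enhancers.bed`. Loci are placed at unique positions across each
#' gene's promoter window and body; Z-scores are drawn from the
#' configured spatial correlation model, shifted for planted genes, and
#' converted to two-sided p-values `2 * (1 - Phi(|Z|))`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisible manifest list: file paths, the gene table, planted
#'   gene ids.
#' @export
simulate_genome <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(stage_seed(config$seed, "genome"), {
    n <- config$n_genes
    pitch <- config$gene_length + config$gene_spacing
    chrom_i <- rep_len(seq_len(config$n_chromosomes), n)
    within <- stats::ave(seq_len(n), chrom_i, FUN = seq_along)
    start <- 2000 + (within - 1) * pitch
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(n)),
      chrom = paste0("chrS", chrom_i),
      start = start, end = start + config$gene_length,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    planted <- if (config$n_planted > 0) {
      sort(sample(genes$gene_id, config$n_planted))
    } else character()

    loci <- vector("list", n)
    for (i in seq_len(n)) {
      tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i]
      prom <- if (genes$strand[i] == "+") {
        c(max(tss - 1000, 0), tss + 500)
      } else {
        c(tss - 500, tss + 1000)
      }
      n_p <- sample(config$promoter_loci[1]:config$promoter_loci[2], 1)
      n_b <- sample(config$body_loci[1]:config$body_loci[2], 1)
      pos <- sort(c(sample(prom[1]:(prom[2] - 1), n_p),
                    sample(genes$start[i]:(genes$end[i] - 1), n_b)))
      pos <- unique(pos)
      is_planted <- genes$gene_id[i] %in% planted
      shift <- if (is_planted) config$effect_shift else 0
      z <- sim_z(pos, config$corr_model, shift)
      # planted repression signature: promoter methylation up, gene-body
      # methylation down (flipped with the sign of effect_shift)
      in_prom <- pos >= prom[1] & pos < prom[2]
      target <- ifelse(in_prom, 1, -1) * sign(config$effect_shift + (config$effect_shift == 0))
      loci[[i]] <- data.frame(
        chrom = genes$chrom[i], position = pos,
        effect = round(sim_effect(z, is_planted, target,
                                  config$sign_consistency), 6),
        pvalue = signif(clamp_p(2 * stats::pnorm(-abs(z))), 8),
        stringsAsFactors = FALSE)
    }
    track <- do.call(rbind, loci)
    track <- track[order(track$chrom, track$position), , drop = FALSE]

    is_pl <- genes$gene_id %in% planted
    ze <- rnorm(n) + config$effect_shift * is_pl
    # planted expression goes down (repression), completing the signature
    expr_target <- -sign(config$effect_shift + (config$effect_shift == 0))
    expr <- data.frame(
      gene = genes$gene_id,
      effect = round(vapply(seq_len(n), function(i) {
        sim_effect(ze[i], is_pl[i], expr_target, config$sign_consistency)
      }, numeric(1)), 6),
      pvalue = signif(clamp_p(2 * stats::pnorm(-abs(ze))), 8),
      stringsAsFactors = FALSE)

    paths <- list(
      genes = file.path(dir, "genes.bed"),
      methylation = file.path(dir, "methylation.tsv"),
      expression = file.path(dir, "expression.tsv"),
      planted = file.path(dir, "planted_genes.txt"))
    bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                      0, genes$strand)
    utils::write.table(bed, paths$genes, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_tsv(track, paths$methylation)
    write_tsv(expr, paths$expression)
    writeLines(planted, paths$planted)
    if (isTRUE(config$enhancers)) {
      idx <- seq(1, n, by = 5)
      tss <- ifelse(genes$strand == "+", genes$start, genes$end)[idx]
      enh <- data.frame(genes$chrom[idx], pmax(tss - 3000, 0),
                        pmax(tss - 3000, 0) + 500)
      paths$enhancers <- file.path(dir, "enhancers.bed")
      utils::write.table(enh, paths$enhancers, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    invisible(list(paths = paths, genes = genes, planted = planted))
  })
}

#' Simulate a gene interaction network with a planted community
#'
#' Under the planted-partition model the planted genes form a block with
#' internal edge probability `p_in`; every other pair (background and
#' cross) has probability `p_out`. If the planted block comes out
#' disconnected, it is redrawn with a fresh substream (logged). The edge
#' list is written as a 2-column TSV (no header) and the planted
#' membership to a truth file.
#'
#' @param config a [sim_config()].
#' @param gene_ids character vector of node names.
#' @param planted gene ids forming the planted community (ignored under
#'   `erdos_renyi`).
#' @param dir output directory.
#' @return invisible list: `paths` (edges, truth), `edges` data frame.
#' @export
simulate_network <- function(config, gene_ids, planted = character(), dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(gene_ids)
  model <- config$network
  edges <- NULL
  for (try in 1:20) {
    edges <- with_seed(stage_seed(config$seed, paste0("network", try)), {
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      p_edge <- if (model$type == "erdos_renyi") {
        rep(model$p, nrow(pairs))
      } else {
        # planted genes form block 1; everyone else is dealt into
        # background blocks so the whole graph has community structure
        bs <- model$bg_block_size %||% 40
        block <- integer(n)
        block[gene_ids %in% planted] <- 1L
        bg <- which(!gene_ids %in% planted)
        block[bg] <- 1L + ceiling(seq_along(bg) / bs)
        same <- block[pairs[, 1]] == block[pairs[, 2]]
        ifelse(same, model$p_in, model$p_out)
      }
      keep <- runif(nrow(pairs)) < p_edge
      data.frame(from = gene_ids[pairs[keep, 1]],
                 to = gene_ids[pairs[keep, 2]], stringsAsFactors = FALSE)
    })
    if (model$type == "erdos_renyi" || length(planted) < 2) break
    sub <- edges[edges$from %in% planted & edges$to %in% planted, ]
    if (nrow(sub) && planted_connected(sub, planted)) break
    message("planted community disconnected; regenerating network (try ",
            try, ")")
  }
  paths <- list(edges = file.path(dir, "edges.tsv"),
                truth = file.path(dir, "planted_community.txt"))
  utils::write.table(edges, paths$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(planted, paths$truth)
  invisible(list(paths = paths, edges = edges))
}

planted_connected <- function(edges, planted) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = planted)
  igraph::is_connected(g)
}

#' Simulate a complete study (genome inputs + network)
#'
#' Convenience wrapper running [simulate_genome()] and
#' [simulate_network()] into one directory.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return invisible manifest combining both stages.
#' @export
simulate_study <- function(config, dir) {
  gen <- simulate_genome(config, dir)
  net <- simulate_network(config, gen$genes$gene_id, gen$planted, dir)
  invisible(list(paths = c(gen$paths, net$paths), genes = gen$genes,
                 planted = gen$planted, edges = net$edges))
}
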