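#' Combine a gene's context scores into a single statistic
#'
#' Applies the weighted Stouffer method across the contexts present for
#' each gene: `statistic = sum_j w_j * s_j * z_j / sqrt(sum_j w_j^2)` where
#' `z_j = qnorm(1 - adjusted_p_j / 2)` and the sign `s_j` is
#' `direction_j * B_j` for contexts with a directionality coefficient
#' `B_j != 0`, and `+1` for agnostic contexts (`B_j = 0`), which therefore
#' always contribute their evidence positively. Contexts missing for a
#' gene are simply absent from both sums, so partial data never excludes a
#' gene. Genes with no context data at all are excluded and reported via
#' the `"no_data"` attribute.
#'
#' Under the directionality convention, discordant strong evidence cancels:
#' e.g. expression up (`B = +1`) together with promoter methylation up
#' under `B = -1` yields a statistic of 0, while promoter methylation
#' *down* under `B = -1` adds constructively.
#'
#' @param context_scores `data.frame` with columns `gene_id`, `context`,
#'   `adjusted_p`, `direction` (rows = gene-context scores).
#' @param contexts list of [context_def()] covering every context name in
#'   `context_scores`.
#' @return `data.frame` with columns `gene_id`, `statistic`, `n_contexts`,
#'   `pattern` (the sorted context combination, used for bootstrap
#'   caching).
#' @export
combine_gene_scores <- function(context_scores, contexts) {
  defs <- context_lookup(contexts)
  cs <- context_scores
  if (!all(cs$context %in% names(defs))) {
    stop("context scores reference undefined context(s): ",
         paste(setdiff(unique(cs$context), names(defs)), collapse = ", "))
  }
  w <- vapply(defs, `[[`, numeric(1), "weight")[cs$context]
  B <- vapply(defs, `[[`, numeric(1), "direction")[cs$context]
  z <- z_transform(clamp_p(cs$adjusted_p))
  s <- ifelse(B == 0, 1, cs$direction * B)
  term <- w * s * z
  by_gene <- split(seq_len(nrow(cs)), cs$gene_id)
  stat <- vapply(by_gene, function(i) {
    ww <- w[i]
    if (all(ww == 0)) return(NA_real_)
    sum(term[i]) / sqrt(sum(ww^2))
  }, numeric(1))
  pattern <- vapply(by_gene, function(i) {
    paste(sort(cs$context[i]), collapse = "+")
  }, character(1))
  out <- data.frame(gene_id = names(by_gene), statistic = unname(stat),
                    n_contexts = lengths(by_gene),
                    pattern = unname(pattern), stringsAsFactors = FALSE)
  drop <- out$gene_id[is.na(out$statistic)]
  out <- out[!is.na(out$statistic), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "no_data") <- drop
  out
}

context_lookup <- function(contexts) {
  if (inherits(contexts, "context_def")) contexts <- list(contexts)
  stopifnot(all(vapply(contexts, inherits, logical(1), "context_def")))
  nm <- vapply(contexts, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate context names")
  stats::setNames(contexts, nm)
}

#' Bootstrap null p-values for combined gene statistics
#'
#' The null model resamples each context's signed contributions
#' (`s_j * z_j`) across genes — preserving every context's marginal
#' distribution, which is the only structure the exchangeability null
#' assumes — recombines them with the same weights, and compares the
#' observed statistic against the null by magnitude (two-sided folding).
#' Genes sharing a context pattern share a cached null sample. The
#' combined p-value uses the add-one estimator
#' `(count(|null| >= |obs|) + 1) / (n_boot + 1)` and is therefore never 0.
#'
#' @param gene_stats output of [combine_gene_scores()].
#' @param context_scores the `data.frame` the statistics were built from.
#' @param contexts list of [context_def()].
#' @param n_boot bootstrap resamples (values below 100 warn: unstable
#'   tail).
#' @param seed optional integer seed.
#' @return `gene_stats` with an added `combined_p` column.
#' @export
bootstrap_gene_p <- function(gene_stats, context_scores, contexts,
                             n_boot = 1000, seed = NULL) {
  if (n_boot < 100) warning("n_boot < 100 gives unstable tail probabilities")
  if (nrow(gene_stats) < 50) {
    warning("fewer than 50 genes; bootstrap null may be coarse")
  }
  defs <- context_lookup(contexts)
  cs <- context_scores
  B <- vapply(defs, `[[`, numeric(1), "direction")[cs$context]
  z <- z_transform(clamp_p(cs$adjusted_p))
  s <- ifelse(B == 0, 1, cs$direction * B)
  pools <- split(s * z, cs$context)
  w_all <- vapply(defs, `[[`, numeric(1), "weight")
  with_seed(seed, {
    combined_p <- numeric(nrow(gene_stats))
    for (pat in unique(gene_stats$pattern)) {
      ctx_names <- strsplit(pat, "+", fixed = TRUE)[[1]]
      ww <- w_all[ctx_names]
      null_stat <- numeric(n_boot)
      for (cn in ctx_names) {
        null_stat <- null_stat +
          w_all[[cn]] * sample(pools[[cn]], n_boot, replace = TRUE)
      }
      null_stat <- abs(null_stat / sqrt(sum(ww^2)))
      null_sorted <- sort.int(null_stat)
      rows <- which(gene_stats$pattern == pat)
      n_lt <- findInterval(abs(gene_stats$statistic[rows]), null_sorted,
                           left.open = TRUE)
      combined_p[rows] <- (n_boot - n_lt + 1) / (n_boot + 1)
    }
    gene_stats$combined_p <- combined_p
  })
  gene_stats
}

#' Fisher score of a combined p-value
#'
#' `G = -2 * log(p)`, chi-squared with 2 degrees of freedom under the
#' null. This is the gene score carried onto the network.
#'
#' @param combined_p p-values in (0, 1].
#' @return nonnegative scores.
#' @export
fisher_score <- function(combined_p) {
  stopifnot(all(combined_p > 0), all(combined_p <= 1))
  -2 * log(combined_p)
}

#' Select high-scoring genes against a resampled background
#'
#' The background distribution is built by pooling `n_resamples` bootstrap
#' draws of the score vector; genes at or above the `(1 - alpha)` quantile
#' of the pooled background are returned. `alpha = 1` returns every gene;
#' `alpha = 0` returns at most the maximum-score gene(s).
#'
#' @param scores named numeric vector of gene scores (names = gene ids).
#' @param n_resamples bootstrap draws.
#' @param alpha upper-tail mass retained.
#' @param seed optional integer seed.
#' @return character vector of selected gene ids (attribute `"threshold"`
#'   carries the score cutoff).
#' @export
select_high_scoring <- function(scores, n_resamples = 1000, alpha = 0.05,
                                seed = NULL) {
  stopifnot(!is.null(names(scores)), alpha >= 0, alpha <= 1)
  if (length(scores) < 50) warning("fewer than 50 scored genes")
  with_seed(seed, {
    bg <- sample(scores, length(scores) * n_resamples, replace = TRUE)
    thr <- unname(stats::quantile(bg, 1 - alpha, type = 1))
    sel <- names(scores)[scores >= thr]
    if (!length(sel)) message("no gene above the background threshold")
    attr(sel, "threshold") <- thr
    sel
  })
}
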