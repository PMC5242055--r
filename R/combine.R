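#' Decorrelate folded Z-scores with the interval's Cholesky factor
#'
#' Whitens a vector of (correlated) Z-scores against the interval
#' correlation matrix `Sigma = L L^T` by forward substitution on the lower
#' Cholesky factor, `z* = L^{-1} z`. A triangular solve is used throughout;
#' the matrix is never inverted explicitly. If `Sigma` is the identity,
#' `z*` equals `z`.
#'
#' @param z numeric vector of Z-scores.
#' @param interval_corr an `interval_corr` from [interval_matrix()].
#' @return the decorrelated vector `z*`.
#' @export
decorrelate <- function(z, interval_corr) {
  stopifnot(inherits(interval_corr, "interval_corr"))
  U <- interval_corr$chol
  if (length(z) != nrow(U)) {
    stop("z has length ", length(z), " but correlation matrix is ",
         nrow(U), " x ", nrow(U))
  }
  as.vector(forwardsolve(t(U), z))
}

#' Weighted Stouffer aggregation
#'
#' Combines Z-scores as `sum(w * z) / sqrt(sum(w^2))`, which is N(0, 1)
#' under independence of the inputs. Weights must be nonnegative with at
#' least one positive entry; a single value is returned unchanged whatever
#' its weight.
#'
#' @param z numeric vector of Z-scores.
#' @param w nonnegative weights, recycled to `length(z)`.
#' @return the aggregate Z-score.
#' @export
stouffer_aggregate <- function(z, w = rep(1, length(z))) {
  w <- rep_len(w, length(z))
  if (any(w < 0)) stop("negative weights are not allowed")
  if (all(w == 0)) stop("all-zero weights")
  sum(w * z) / sqrt(sum(w^2))
}

#' Simple locus-level p-value combiners
#'
#' Drop-in alternatives to the Stouffer route for combining the p-values of
#' one interval: Sidak's adjustment of the minimum p-value, Fisher's
#' chi-squared method, and a binomial exceedance test counting p-values at
#' or below `binom_alpha`. These operate on raw p-values and bypass the
#' decorrelation step; the Stouffer route is the default and the only one
#' covered by the decorrelation guarantees.
#'
#' @param p numeric vector of p-values.
#' @param method one of `"sidak"`, `"fisher"`, `"binomial"`.
#' @param binom_alpha per-locus significance cutoff for the binomial count.
#' @return a single combined p-value.
#' @export
combine_pvalues <- function(p, method = c("sidak", "fisher", "binomial"),
                            binom_alpha = 0.05) {
  method <- match.arg(method)
  p <- clamp_p(p)
  n <- length(p)
  switch(method,
    sidak = 1 - (1 - min(p))^n,
    fisher = stats::pchisq(-2 * sum(log(p)), df = 2 * n, lower.tail = FALSE),
    binomial = stats::pbinom(sum(p <= binom_alpha) - 1, size = n,
                             prob = binom_alpha, lower.tail = FALSE))
}

# Quantile strata over the number of combined values; strata smaller than
# min_stratum are merged into their nearest neighbor.
make_strata <- function(n_combined, n_strata, min_stratum) {
  qs <- unique(stats::quantile(n_combined,
                               probs = seq(0, 1, length.out = n_strata + 1),
                               type = 1, names = FALSE))
  if (length(qs) == 1) return(rep(1L, length(n_combined)))
  s <- cut(n_combined, breaks = qs, include.lowest = TRUE, labels = FALSE)
  repeat {
    tab <- table(s)
    if (length(tab) <= 1) break
    small <- as.integer(names(tab)[tab < min_stratum])
    if (!length(small)) break
    i <- small[1]
    others <- setdiff(as.integer(names(tab)), i)
    j <- others[which.min(abs(others - i))]
    message("merging sparse N-stratum ", i, " into stratum ", j)
    s[s == i] <- j
  }
  match(s, sort(unique(s)))
}

#' Quantile-permutation adjustment for the number of combined values
#'
#' Stouffer aggregates of folded Z-scores drift upward with the number of
#' values combined, so a raw aggregate is only comparable to aggregates
#' built from similarly many loci. Scores are stratified into quantile
#' strata of `n_combined`; each observed score is compared against
#' `n_null_distributions` random same-size samples (with replacement) of
#' scores from its own stratum. Per sample the proportion of scores at or
#' above the observation is recorded (ties contribute half, plus an
#' add-one floor so the proportion is never 0), and the mean proportion
#' over samples is returned as the adjusted p-value.
#'
#' With fewer than 20 scores the adjustment is skipped with a warning and
#' the upper-tail normal probability of the raw score is returned.
#'
#' @param raw numeric vector of raw Stouffer aggregates.
#' @param n_combined integer vector, the number of values behind each score.
#' @param n_strata requested number of quantile strata.
#' @param n_null_distributions random samples drawn per stratum.
#' @param min_stratum smallest allowed stratum before merging.
#' @param seed optional integer seed.
#' @return numeric vector of adjusted p-values in (0, 1].
#' @export
quantile_permutation_adjust <- function(raw, n_combined, n_strata = 10,
                                        n_null_distributions = 100,
                                        min_stratum = 5, seed = NULL) {
  stopifnot(length(raw) == length(n_combined), n_strata >= 1,
            n_null_distributions >= 1)
  if (length(raw) < 20) {
    warning("fewer than 20 scores; quantile-permutation adjustment skipped")
    return(stats::pnorm(raw, lower.tail = FALSE))
  }
  with_seed(seed, {
    s <- make_strata(n_combined, n_strata, min_stratum)
    out <- numeric(length(raw))
    for (k in unique(s)) {
      idx <- which(s == k)
      r <- raw[idx]
      m <- length(r)
      acc <- numeric(m)
      for (d in seq_len(n_null_distributions)) {
        smp <- sort.int(sample(r, m, replace = TRUE))
        n_le <- findInterval(r, smp)
        n_lt <- findInterval(r, smp, left.open = TRUE)
        n_gt <- m - n_le
        n_eq <- n_le - n_lt
        acc <- acc + (n_gt + 0.5 * n_eq + 1) / (m + 1)
      }
      out[idx] <- acc / n_null_distributions
    }
    out
  })
}

#' Assign an effect direction to an interval
#'
#' The direction is the sign of the weighted Z-majority
#' `sum(w * sign(effect) * z)`: loci with stronger evidence pull harder.
#' An exact zero (reported as a tie) defaults to `+1`.
#'
#' @param effects signed per-locus effect sizes.
#' @param z folded Z-scores of the same loci.
#' @param w nonnegative locus weights.
#' @return `+1` or `-1`.
#' @export
assign_direction <- function(effects, z, w = rep(1, length(effects))) {
  stopifnot(length(effects) >= 1, length(effects) == length(z))
  w <- rep_len(w, length(effects))
  s <- sum(w * sign(effects) * z)
  if (s == 0) {
    message("tied effect direction; defaulting to +1")
    return(1)
  }
  sign(s)
}

#' Score one context across all genes
#'
#' For each interval with data: fold the locus p-values to Z-scores,
#' decorrelate against the interval correlation matrix derived from
#' `profile`, aggregate with the weighted Stouffer method, and assign an
#' effect direction. The raw aggregates are then corrected for the number
#' of combined values by [quantile_permutation_adjust()]. Intervals with no
#' data are skipped and reported via the `"missing_data"` attribute.
#'
#' @param assoc a `context_assoc` from [associate_loci()].
#' @param profile a [corr_profile()] for this (track, context) pair.
#' @param adjust run the quantile-permutation adjustment? When `FALSE` the
#'   adjusted p-value is the upper-tail normal probability of the raw
#'   aggregate.
#' @param n_strata,n_null_distributions,min_stratum passed to
#'   [quantile_permutation_adjust()].
#' @param seed optional integer seed for the adjustment.
#' @return `data.frame` with columns `gene_id`, `context`, `n`, `raw`,
#'   `adjusted_p`, `direction`; attribute `"missing_data"` lists gene ids
#'   without loci.
#' @export
score_context <- function(assoc, profile, adjust = TRUE, n_strata = 10,
                          n_null_distributions = 100, min_stratum = 5,
                          seed = NULL) {
  stopifnot(inherits(assoc, "context_assoc"), inherits(profile, "corr_profile"))
  keep <- which(assoc$intervals$n > 0)
  # a gene may own several intervals in a custom-BED context; its loci are
  # pooled so each gene gets exactly one aggregate per context
  by_gene <- split(keep, assoc$intervals$gene_id[keep])
  genes <- names(by_gene)
  raw <- numeric(length(by_gene))
  dir <- numeric(length(by_gene))
  n <- integer(length(by_gene))
  for (i in seq_along(by_gene)) {
    df <- do.call(rbind, assoc$loci[by_gene[[i]]])
    df <- df[order(df$position), , drop = FALSE]
    z <- z_transform(df$p)
    ic <- interval_matrix(df$position, profile)
    zs <- decorrelate(z, ic)
    raw[i] <- stouffer_aggregate(zs, df$weight)
    dir[i] <- assign_direction(df$effect, z, df$weight)
    n[i] <- nrow(df)
  }
  adjusted <- if (adjust) {
    quantile_permutation_adjust(raw, n, n_strata = n_strata,
                                n_null_distributions = n_null_distributions,
                                min_stratum = min_stratum, seed = seed)
  } else {
    stats::pnorm(raw, lower.tail = FALSE)
  }
  out <- data.frame(gene_id = genes,
                    context = assoc$context$name,
                    n = n, raw = raw, adjusted_p = clamp_p(adjusted),
                    direction = dir, stringsAsFactors = FALSE)
  attr(out, "missing_data") <- attr(assoc, "missing_data")
  out
}
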