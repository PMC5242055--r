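#' Fold a p-value onto the standard normal scale
#'
#' `z_transform(p)` returns `qnorm(1 - p/2)`, the folded (nonnegative)
#' normal quantile of a two-sided p-value. It is monotone decreasing in `p`
#' with `z_transform(1) == 0`. Inputs are clamped into `[p_floor, 1]`; a
#' p-value of exactly 0 is clamped with a warning, values outside `[0, 1]`
#' are an error.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param p_floor smallest admissible p-value before transformation.
#' @return numeric vector of nonnegative Z-scores.
#' @export
z_transform <- function(p, p_floor = 1e-16) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (any(p == 0)) warning("p-value(s) of 0 clamped to ", p_floor)
  # upper-tail form keeps full precision for very small p
  stats::qnorm(clamp_p(p, p_floor) / 2, lower.tail = FALSE)
}

#' Collect neighbor pairs of transformed p-values
#'
#' For every locus with `p <= significance_threshold`, emits the distance to
#' its closest upstream neighbor and to its closest downstream neighbor
#' within the same interval, together with both folded Z values. These
#' pairs are the raw material for the distance-decay correlation profile.
#' Intervals with fewer than two loci contribute nothing.
#'
#' @param assoc a `context_assoc` from [associate_loci()].
#' @param significance_threshold p-value cutoff selecting anchor loci.
#' @return `data.frame` with columns `distance`, `z_a` (anchor), `z_b`
#'   (neighbor).
#' @export
neighbor_pairs <- function(assoc, significance_threshold = 0.05) {
  stopifnot(inherits(assoc, "context_assoc"),
            significance_threshold > 0, significance_threshold <= 1)
  res <- lapply(assoc$loci, function(df) {
    n <- nrow(df)
    if (n < 2) return(NULL)
    sig <- which(df$p <= significance_threshold)
    if (!length(sig)) return(NULL)
    z <- z_transform(df$p)
    up <- sig[sig > 1]
    dn <- sig[sig < n]
    data.frame(
      distance = c(df$position[up] - df$position[up - 1],
                   df$position[dn + 1] - df$position[dn]),
      z_a = c(z[up], z[dn]),
      z_b = c(z[up - 1], z[dn + 1]))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(distance = numeric(), z_a = numeric(), z_b = numeric()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Construct a distance-binned correlation profile
#'
#' Builds a `corr_profile` directly from bin edges and per-bin mean
#' correlations. Useful for supplying a known or externally estimated
#' correlation model; [estimate_profile()] produces the same structure from
#' data.
#'
#' @param bin_edges strictly increasing numeric vector of bin boundaries
#'   (bp), length `B + 1`.
#' @param mean_corr per-bin mean Pearson correlations in \[-1, 1\],
#'   length `B`.
#' @param n_pairs optional per-bin pair counts.
#' @param n_resamples number of resamples used (NA when constructed).
#' @return an object of class `corr_profile`.
#' @export
corr_profile <- function(bin_edges, mean_corr, n_pairs = NA_integer_,
                         n_resamples = NA_integer_) {
  stopifnot(length(bin_edges) == length(mean_corr) + 1,
            all(diff(bin_edges) > 0),
            all(mean_corr >= -1 & mean_corr <= 1))
  df <- data.frame(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    bin_mid = (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2,
    mean_corr = mean_corr,
    n_pairs = as.integer(n_pairs),
    populated = !is.na(mean_corr) & (is.na(n_pairs) | n_pairs > 0))
  structure(df, class = c("corr_profile", "data.frame"),
            n_resamples = n_resamples)
}

#' @export
print.corr_profile <- function(x, ...) {
  cat("correlation profile: ", nrow(x), " bins over [",
      min(x$bin_lo), ", ", max(x$bin_hi), "] bp; ",
      sum(x$populated), " populated\n", sep = "")
  invisible(x)
}

#' Estimate the distance-decay correlation profile by Monte Carlo
#'
#' Distances between neighboring loci are partitioned into (up to)
#' `n_bins` quantile bins, so the densely observed short distances get the
#' narrowest bins (down to single-basepair width); duplicate quantile edges
#' are collapsed. Within each bin the pairs are resampled with replacement
#' (same size as the bin) `n_resamples` times, the Pearson correlation of
#' the two Z vectors is computed for each resample, and the mean is stored
#' as the bin's correlation. Bins with fewer than `min_pairs` pairs carry
#' correlation 0 and are flagged unpopulated.
#'
#' @param pairs output of [neighbor_pairs()].
#' @param n_bins requested number of distance bins.
#' @param n_resamples bootstrap resamples per bin.
#' @param min_pairs minimum pairs for a Pearson estimate.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a [corr_profile()].
#' @export
estimate_profile <- function(pairs, n_bins = 500, n_resamples = 500,
                             min_pairs = 3, seed = NULL) {
  stopifnot(nrow(pairs) >= 1, n_bins >= 1, n_resamples >= 1)
  d <- pairs$distance
  edges <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1),
                                  type = 1, names = FALSE))
  if (length(edges) == 1) edges <- c(edges, edges + 1)
  # widen the outer edges so cut() captures the extremes
  bin <- cut(d, breaks = edges, include.lowest = TRUE, labels = FALSE)
  B <- length(edges) - 1
  mean_corr <- numeric(B)
  n_pairs <- integer(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- which(bin == b)
      m <- length(idx)
      n_pairs[b] <- m
      if (m < min_pairs) next
      za <- pairs$z_a[idx]
      zb <- pairs$z_b[idx]
      smp <- matrix(sample.int(m, m * n_resamples, replace = TRUE), nrow = m)
      xa <- matrix(za[smp], nrow = m)
      xb <- matrix(zb[smp], nrow = m)
      sa <- colSums(xa); sb <- colSums(xb)
      num <- m * colSums(xa * xb) - sa * sb
      den <- sqrt(pmax(m * colSums(xa^2) - sa^2, 0) *
                    pmax(m * colSums(xb^2) - sb^2, 0))
      r <- ifelse(den > 0, num / den, NA_real_)
      r <- r[is.finite(r)]
      mean_corr[b] <- if (length(r)) max(-1, min(1, mean(r))) else 0
    }
  })
  prof <- corr_profile(edges, mean_corr, n_resamples = n_resamples)
  prof$n_pairs <- n_pairs
  prof$populated <- n_pairs >= min_pairs
  prof
}

#' Look up profile correlations at given distances
#'
#' Nearest-bin-center lookup; distances beyond the profile range take the
#' outermost bin's value.
#'
#' @param profile a [corr_profile()].
#' @param d numeric vector (or matrix) of distances in bp.
#' @return correlations with the shape of `d`.
#' @export
profile_lookup <- function(profile, d) {
  stopifnot(inherits(profile, "corr_profile"))
  centers <- profile$bin_mid
  if (length(centers) == 1) {
    out <- rep(profile$mean_corr, length(d))
  } else {
    cuts <- (centers[-length(centers)] + centers[-1]) / 2
    out <- profile$mean_corr[findInterval(as.vector(d), cuts) + 1]
  }
  if (is.matrix(d)) out <- matrix(out, nrow(d), ncol(d))
  out
}

#' Build the correlation matrix of an interval's loci
#'
#' Entry (a, b) is the profile correlation at distance `|pos_a - pos_b|`;
#' the diagonal is 1. Because bin lookups do not guarantee positive
#' definiteness, a non-PD matrix is repaired by clipping eigenvalues at
#' `eig_floor`, reconstructing, and renormalizing the diagonal to 1 (the
#' clip/renormalize pass is iterated until the smallest eigenvalue clears
#' the floor). The upper Cholesky factor (`sigma == t(chol) %*% chol`) is
#' computed and cached.
#'
#' @param positions locus positions (bp) of one interval.
#' @param profile a [corr_profile()].
#' @param eig_floor smallest admissible eigenvalue after repair.
#' @return an object of class `interval_corr`: list with `positions`,
#'   `sigma`, `chol` (upper triangular), `repaired` (logical), or `NULL`
#'   for an empty interval.
#' @export
interval_matrix <- function(positions, profile, eig_floor = 1e-6) {
  n <- length(positions)
  if (n == 0) return(NULL)
  if (n == 1) {
    return(structure(list(positions = positions,
                          sigma = matrix(1, 1, 1),
                          chol = matrix(1, 1, 1), repaired = FALSE),
                     class = "interval_corr"))
  }
  D <- abs(outer(positions, positions, "-"))
  M <- profile_lookup(profile, D)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  U <- tryCatch(chol(M), error = function(e) NULL)
  repaired <- FALSE
  if (is.null(U)) {
    repaired <- TRUE
    for (i in 1:10) {
      e <- eigen(M, symmetric = TRUE)
      if (min(e$values) >= eig_floor) break
      M <- e$vectors %*% (pmax(e$values, eig_floor) * t(e$vectors))
      dg <- sqrt(diag(M))
      M <- M / outer(dg, dg)
      M <- (M + t(M)) / 2
      diag(M) <- 1
    }
    U <- chol(M)
  }
  structure(list(positions = positions, sigma = M, chol = U,
                 repaired = repaired),
            class = "interval_corr")
}

#' Write / read a correlation profile as TSV
#'
#' Serialized columns: `bin_lo`, `bin_hi`, `mean_corr`, `n_pairs`.
#'
#' @param profile a [corr_profile()].
#' @param path file path.
#' @return `write_profile` the path, invisibly; `read_profile` a
#'   [corr_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "corr_profile"))
  write_tsv(data.frame(bin_lo = profile$bin_lo, bin_hi = profile$bin_hi,
                       mean_corr = profile$mean_corr,
                       n_pairs = profile$n_pairs), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read_tsv(path)
  prof <- corr_profile(c(df$bin_lo, df$bin_hi[nrow(df)]), df$mean_corr)
  prof$n_pairs <- as.integer(df$n_pairs)
  prof$populated <- prof$n_pairs > 0
  prof
}
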