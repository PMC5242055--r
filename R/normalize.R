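#' Normalize adjusted p-values across contexts
#'
#' Even after size adjustment, the adjusted-p distributions of different
#' contexts can differ slightly in location and spread, and the context
#' with the heavier tail would dominate the final gene score. Both methods
#' here are monotone within each context (gene ranks are preserved
#' exactly) and move every context onto a common scale defined by the
#' moments of the pooled data.
#'
#' * `"logit"`: logit-transform the p-values, rescale each context's
#'   logits to the pooled mean and standard deviation, and back-transform.
#' * `"boxcox"`: on `-log(p)` (positive support), pick the power
#'   transformation maximizing the Box-Cox log-likelihood over a grid
#'   `lambda` in \[-2, 2\] (step 0.01) per context, standardize the
#'   transformed values to the pooled moments, and back-transform.
#' * `"none"`: pass through.
#'
#' A context with zero variance (or too few values) is returned unchanged
#' with a warning.
#'
#' @param p_by_context named list of numeric vectors of p-values in (0, 1),
#'   one per context.
#' @param method `"logit"`, `"boxcox"` or `"none"`.
#' @return list with elements `p` (the normalized list, same shape) and
#'   `report` (a `normalization_report` data frame with pre/post moments of
#'   `-log(p)` and a per-context rank check).
#' @export
normalize_scores <- function(p_by_context,
                             method = c("logit", "boxcox", "none")) {
  method <- match.arg(method)
  stopifnot(is.list(p_by_context), length(p_by_context) >= 1,
            !is.null(names(p_by_context)))
  eps <- 1e-12
  p_in <- lapply(p_by_context, function(p) pmin(pmax(p, eps), 1 - eps))
  out <- switch(method,
                none = p_in,
                logit = logit_rescale(p_in),
                boxcox = boxcox_normalize(p_in))
  report <- do.call(rbind, lapply(names(p_in), function(nm) {
    pre <- -log(p_in[[nm]]); post <- -log(out[[nm]])
    data.frame(context = nm, method = method,
               pre_mean = mean(pre), pre_sd = stats::sd(pre),
               pre_q25 = unname(stats::quantile(pre, 0.25)),
               pre_q75 = unname(stats::quantile(pre, 0.75)),
               post_mean = mean(post), post_sd = stats::sd(post),
               post_q25 = unname(stats::quantile(post, 0.25)),
               post_q75 = unname(stats::quantile(post, 0.75)),
               rank_check = isTRUE(all.equal(rank(pre), rank(post))),
               stringsAsFactors = FALSE)
  }))
  class(report) <- c("normalization_report", "data.frame")
  list(p = out, report = report)
}

# Population standard deviation: with the n-1 denominator a context and
# the pool of identical contexts would disagree slightly, breaking exact
# identity/idempotence of the rescale.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Logit rescale to pooled moments. Pooled mean/sd are computed on the
# concatenated logits so the operation is symmetric in the contexts; when
# every context already matches the pooled scale it is (numerically) the
# identity, which also makes the transformation idempotent.
logit_rescale <- function(p_in) {
  x <- lapply(p_in, stats::qlogis)
  all_x <- unlist(x, use.names = FALSE)
  m_t <- mean(all_x)
  s_t <- pop_sd(all_x)
  lapply(x, function(xc) {
    s_c <- pop_sd(xc)
    if (!is.finite(s_c) || s_c == 0) {
      warning("context with zero logit variance left unchanged")
      return(stats::plogis(xc))
    }
    stats::plogis((xc - mean(xc)) / s_c * s_t + m_t)
  })
}

# Box-Cox transform of y > 0 at power lambda (log at lambda = 0).
bc_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

bc_inverse <- function(t, lambda) {
  if (abs(lambda) < 1e-12) return(exp(t))
  base <- pmax(lambda * t + 1, 1e-12)
  base^(1 / lambda)
}

#' Grid-search Box-Cox maximum-likelihood exponent
#'
#' Profile log-likelihood of the Box-Cox model for positive data `y`:
#' `-n/2 * log(sigma2_hat(lambda)) + (lambda - 1) * sum(log(y))`,
#' maximized over an equally spaced grid.
#'
#' @param y positive numeric vector.
#' @param grid candidate exponents.
#' @return the maximizing `lambda`.
#' @export
boxcox_lambda <- function(y, grid = seq(-2, 2, by = 0.01)) {
  stopifnot(all(y > 0))
  n <- length(y)
  slog <- sum(log(y))
  ll <- vapply(grid, function(l) {
    t <- bc_transform(y, l)
    v <- mean((t - mean(t))^2)
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (l - 1) * slog
  }, numeric(1))
  grid[which.max(ll)]
}

boxcox_normalize <- function(p_in) {
  y <- lapply(p_in, function(p) pmax(-log(p), 1e-12))
  lam <- vapply(y, function(yc) {
    if (stats::sd(yc) == 0) NA_real_ else boxcox_lambda(yc)
  }, numeric(1))
  t_list <- Map(function(yc, l) if (is.na(l)) yc else bc_transform(yc, l),
                y, lam)
  all_t <- unlist(t_list, use.names = FALSE)
  m_t <- mean(all_t)
  s_t <- pop_sd(all_t)
  Map(function(tc, yc, l) {
    if (is.na(l)) {
      warning("degenerate (constant) context left unchanged")
      return(exp(-yc))
    }
    s_c <- pop_sd(tc)
    if (s_c == 0) return(exp(-yc))
    tt <- (tc - mean(tc)) / s_c * s_t + m_t
    yy <- pmax(bc_inverse(tt, l), 1e-12)
    pmin(pmax(exp(-yy), 1e-300), 1)
  }, t_list, y, lam)
}
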