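`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp p-values into (0, 1]
#'
#' Raw p-values of exactly zero (common after permutation tests or numeric
#' underflow) break the normal-quantile transform, so every entry point of
#' the package floors p-values at `floor` before transforming.
#'
#' @param p numeric vector of p-values.
#' @param floor smallest admissible p-value.
#' @return clamped numeric vector.
#' @keywords internal
clamp_p <- function(p, floor = 1e-16) {
  pmin(pmax(p, floor), 1)
}

# Small deterministic string hash (31-adic, mod 2^31 - 1). Used only to
# derive per-stage RNG seeds from a single global seed, so that inserting a
# pipeline stage never perturbs the random streams of earlier stages.
str_hash <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Derive a per-stage seed from a global seed
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed in \[0, 2^31).
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  as.integer((abs(as.numeric(seed)) * 48271 + str_hash(stage)) %% 2147483647)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream; seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# write.table with the fixed conventions used for every output table, so
# that identical inputs + seed give byte-identical files.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "", ...)
}
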