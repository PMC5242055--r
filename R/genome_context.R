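#' Read a gene annotation BED file
#'
#' Reads a BED4/BED6 file (tab-delimited, no header, `#` comments skipped)
#' describing gene models. Coordinates follow the BED convention: 0-based,
#' half-open `[start, end)`. Column 4 is taken as the gene identifier;
#' column 6, when present, as the strand. Rows with a missing strand default
#' to `"+"` with a warning.
#'
#' @param path path to the BED file.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("gene BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 4) {
    stop("gene BED needs at least 4 columns (chrom, start, end, name): ", path)
  }
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop("non-integer coordinates in gene BED at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("start >= end in gene BED at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (ncol(df) >= 6) {
    strand <- as.character(df[[6]])
    if (!all(strand %in% c("+", "-"))) {
      stop("invalid strand value(s) in gene BED; expected '+' or '-'")
    }
  } else {
    warning("no strand column in ", basename(path), "; defaulting to '+'")
    strand <- rep("+", nrow(df))
  }
  gene_id <- as.character(df[[4]])
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup)) {
    stop("duplicate gene ids in gene BED: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  data.frame(gene_id = gene_id, chrom = as.character(df[[1]]),
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a per-locus score track
#'
#' Score tracks are tab-delimited files with a header line
#' `chrom position effect pvalue`, one row per assayed locus (e.g. a CpG
#' from a differential methylation analysis). `effect` is a signed effect
#' size whose sign encodes the direction of change; `pvalue` the associated
#' significance. Positions are stored internally 0-based; files whose
#' positions are 1-based must say so via `one_based = TRUE` and are shifted
#' by -1 on load.
#'
#' @param path path to the track file.
#' @param one_based logical; are file positions 1-based?
#' @param track_id optional identifier attached to the result.
#' @return a `data.frame` with columns `chrom`, `position`, `effect`, `p`,
#'   sorted by (`chrom`, `position`).
#' @export
read_score_track <- function(path, one_based = FALSE, track_id = basename(path)) {
  if (!file.exists(path)) stop("score track not found: ", path)
  df <- read_tsv(path)
  need <- c("chrom", "position", "effect", "pvalue")
  if (!all(need %in% names(df))) {
    stop("score track ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  pos <- as.numeric(df$position)
  if (any(!is.finite(pos)) || any(pos != floor(pos))) {
    stop("non-integer positions in score track ", path)
  }
  if (one_based) pos <- pos - 1
  if (any(pos < 0)) stop("negative positions in score track ", path)
  p <- as.numeric(df$pvalue)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values outside [0, 1] in score track ", path)
  }
  out <- data.frame(chrom = as.character(df$chrom), position = as.integer(pos),
                    effect = as.numeric(df$effect), p = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "track_id") <- track_id
  out
}

#' Read a gene-level expression table
#'
#' Tab-delimited with header `gene effect pvalue`: one differential
#' expression result per gene.
#'
#' @param path path to the table.
#' @return `data.frame` with columns `gene_id`, `effect`, `p`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- read_tsv(path)
  need <- c("gene", "effect", "pvalue")
  if (!all(need %in% names(df))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  p <- as.numeric(df$pvalue)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values outside [0, 1] in expression table ", path)
  }
  data.frame(gene_id = as.character(df$gene), effect = as.numeric(df$effect),
             p = p, stringsAsFactors = FALSE)
}

#' Read a gene interaction network edge list
#'
#' Two-column tab-delimited file, no header, one undirected edge per row.
#'
#' @param path path to the edge list.
#' @return a two-column character `data.frame` (`from`, `to`).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs 2 columns: ", path)
  data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

# ---- context definitions ----------------------------------------------------

#' Interval rules for genomic contexts
#'
#' A context definition anchors a class of genomic intervals to genes:
#' `promoter_rule()` takes a window around the transcription start site
#' (strand-aware), `body_rule()` the annotated gene body, `bed_rule()` an
#' external BED file of intervals (e.g. ChIP-seq enhancer peaks) linked to
#' the gene with the nearest TSS, and `expression_rule()` marks a context
#' fed by a gene-level table rather than a locus track.
#'
#' @param upstream,downstream promoter window half-widths in bp (both >= 0).
#' @param path path to a BED file of intervals.
#' @param flank bp added to each side of every BED interval.
#' @param max_distance maximum TSS distance (bp) for linking a BED interval
#'   to a gene; intervals farther from every TSS are dropped.
#' @return a rule list consumed by [context_def()].
#' @export
promoter_rule <- function(upstream = 1000, downstream = 500) {
  stopifnot(upstream >= 0, downstream >= 0)
  list(type = "promoter", upstream = upstream, downstream = downstream)
}

#' @rdname promoter_rule
#' @export
body_rule <- function() list(type = "gene_body")

#' @rdname promoter_rule
#' @export
bed_rule <- function(path, flank = 0, max_distance = 50000) {
  stopifnot(flank >= 0, max_distance >= 0)
  list(type = "custom_bed", path = path, flank = flank,
       max_distance = max_distance)
}

#' @rdname promoter_rule
#' @export
expression_rule <- function() list(type = "expression")

#' Define a genomic context
#'
#' A context couples an interval rule with the score track it draws loci
#' from, a context weight used when contexts are combined per gene, a
#' directionality coefficient encoding the assumed relationship with gene
#' expression, and a locus weighting scheme.
#'
#' @param name unique context name.
#' @param track name of the score track this context reads
#'   (or `"expression"`).
#' @param rule one of [promoter_rule()], [body_rule()], [bed_rule()],
#'   [expression_rule()].
#' @param weight nonnegative context weight.
#' @param direction directionality coefficient in `{-1, 0, +1}`. `+1`:
#'   increases in this signal support gene prioritization in the same
#'   direction as expression; `-1`: opposite direction (the classic
#'   promoter-methylation/expression anticorrelation); `0`: agnostic, the
#'   context always contributes with positive sign.
#' @param locus_weighting `"uniform"` or `"tss_decay"`
#'   (weight `2^(-d / halflife)` for a locus `d` bp from the TSS).
#' @param halflife decay half-life in bp for `"tss_decay"`. The default of
#'   5000 bp (a typical gene length) makes the weighting a mild tilt
#'   toward the TSS; much shorter half-lives effectively truncate gene
#'   bodies to their first kilobase.
#' @return an object of class `context_def`.
#' @export
context_def <- function(name, track, rule = promoter_rule(), weight = 1,
                        direction = 0,
                        locus_weighting = c("uniform", "tss_decay"),
                        halflife = 5000) {
  locus_weighting <- match.arg(locus_weighting)
  stopifnot(is.character(name), nchar(name) > 0, !grepl("+", name, fixed = TRUE),
            weight >= 0, direction %in% c(-1, 0, 1), halflife > 0)
  structure(list(name = name, track = track, rule = rule, weight = weight,
                 direction = direction, locus_weighting = locus_weighting,
                 halflife = halflife),
            class = "context_def")
}

#' @export
print.context_def <- function(x, ...) {
  cat("context '", x$name, "' [", x$rule$type, "] track=", x$track,
      " w=", x$weight, " B=", x$direction, " locus weights=",
      x$locus_weighting, "\n", sep = "")
  invisible(x)
}

# ---- interval derivation ----------------------------------------------------

#' Derive per-gene context intervals
#'
#' Builds the genomic interval of a context for every gene. Promoters are
#' `[TSS - upstream, TSS + downstream)` oriented by strand (on `-` genes the
#' upstream side extends to larger coordinates); gene bodies are
#' `[start, end)`; custom BED intervals (optionally flanked) are assigned to
#' the gene with the nearest TSS within `max_distance`, ties broken by the
#' lexicographically smaller gene id. Promoters extending below coordinate 0
#' are truncated at 0.
#'
#' @param genes gene table from [read_gene_bed()].
#' @param ctx a [context_def()].
#' @return a `data.frame` with columns `gene_id`, `context`, `chrom`,
#'   `start`, `end`, `tss` (0-based half-open intervals).
#' @export
derive_intervals <- function(genes, ctx) {
  stopifnot(inherits(ctx, "context_def"))
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  rule <- ctx$rule
  if (rule$type == "promoter") {
    up <- rule$upstream; dn <- rule$downstream
    lo <- ifelse(genes$strand == "+", tss - up, tss - dn)
    hi <- ifelse(genes$strand == "+", tss + dn, tss + up)
    if (any(lo < 0)) {
      message(sum(lo < 0), " promoter interval(s) truncated at coordinate 0")
      lo <- pmax(lo, 0)
    }
    out <- data.frame(gene_id = genes$gene_id, context = ctx$name,
                      chrom = genes$chrom, start = lo, end = hi, tss = tss,
                      stringsAsFactors = FALSE)
  } else if (rule$type == "gene_body") {
    out <- data.frame(gene_id = genes$gene_id, context = ctx$name,
                      chrom = genes$chrom, start = genes$start,
                      end = genes$end, tss = tss, stringsAsFactors = FALSE)
  } else if (rule$type == "custom_bed") {
    out <- link_bed_intervals(genes, tss, ctx)
  } else if (rule$type == "expression") {
    stop("expression contexts carry no genomic intervals")
  } else {
    stop("unknown interval rule type: ", rule$type)
  }
  rownames(out) <- NULL
  out
}

# Nearest-TSS assignment of external BED intervals to genes.
link_bed_intervals <- function(genes, tss, ctx) {
  rule <- ctx$rule
  bed <- utils::read.table(rule$path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("interval BED needs >= 3 columns: ", rule$path)
  lo <- pmax(as.integer(bed[[2]]) - rule$flank, 0)
  hi <- as.integer(bed[[3]]) + rule$flank
  if (any(lo >= hi)) stop("empty interval(s) in BED ", rule$path)
  peaks <- GenomicRanges::GRanges(as.character(bed[[1]]),
                                  IRanges::IRanges(lo + 1, hi))
  tss_gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(tss + 1, tss + 1))
  hits <- GenomicRanges::distanceToNearest(peaks, tss_gr, select = "all")
  hd <- S4Vectors::mcols(hits)$distance
  keep <- hd <= rule$max_distance
  qh <- S4Vectors::queryHits(hits)[keep]
  sh <- S4Vectors::subjectHits(hits)[keep]
  if (!length(qh)) {
    message("no BED interval within ", rule$max_distance, " bp of any TSS")
    return(data.frame(gene_id = character(), context = character(),
                      chrom = character(), start = integer(), end = integer(),
                      tss = integer(), stringsAsFactors = FALSE))
  }
  dropped <- length(peaks) - length(unique(qh))
  if (dropped > 0) {
    message(dropped, " BED interval(s) beyond ", rule$max_distance,
            " bp of every TSS dropped")
  }
  # ties in distance: lexicographically smaller gene id wins
  gid <- genes$gene_id[sh]
  ord <- order(qh, gid)
  qh <- qh[ord]; sh <- sh[ord]
  first <- !duplicated(qh)
  qh <- qh[first]; sh <- sh[first]
  data.frame(gene_id = genes$gene_id[sh], context = ctx$name,
             chrom = as.character(bed[[1]])[qh], start = lo[qh], end = hi[qh],
             tss = tss[sh], stringsAsFactors = FALSE)
}

#' Associate score-track loci with context intervals
#'
#' Attaches to each interval every track locus with
#' `start <= position < end` (half-open semantics: a locus at `position ==
#' end` is excluded) and computes per-locus weights under the context's
#' weighting scheme. Intervals with no overlapping loci are retained with
#' `n = 0` and reported via the `"missing_data"` attribute.
#'
#' @param intervals interval table from [derive_intervals()].
#' @param loci score track from [read_score_track()].
#' @param ctx the [context_def()].
#' @return an object of class `context_assoc`: a list with elements
#'   `context`, `intervals` (the input plus an `n` column) and `loci` (a
#'   list, parallel to interval rows, of data frames with columns
#'   `position`, `effect`, `p`, `weight`, sorted by position).
#' @export
associate_loci <- function(intervals, loci, ctx) {
  stopifnot(inherits(ctx, "context_def"))
  n_iv <- nrow(intervals)
  assoc <- vector("list", n_iv)
  nonempty <- which(intervals$end > intervals$start)
  if (length(nonempty) && nrow(loci)) {
    iv_gr <- GenomicRanges::GRanges(
      intervals$chrom[nonempty],
      IRanges::IRanges(intervals$start[nonempty] + 1, intervals$end[nonempty]))
    lo_gr <- GenomicRanges::GRanges(
      loci$chrom, IRanges::IRanges(loci$position + 1, loci$position + 1))
    ov <- GenomicRanges::findOverlaps(lo_gr, iv_gr)
    qh <- S4Vectors::queryHits(ov)
    sh <- nonempty[S4Vectors::subjectHits(ov)]
    if (length(qh)) {
      ord <- order(sh, loci$position[qh])
      qh <- qh[ord]; sh <- sh[ord]
      d <- abs(loci$position[qh] - intervals$tss[sh])
      w <- if (ctx$locus_weighting == "tss_decay") 2^(-d / ctx$halflife) else rep(1, length(qh))
      big <- data.frame(position = loci$position[qh], effect = loci$effect[qh],
                        p = loci$p[qh], weight = w, stringsAsFactors = FALSE)
      assoc[unique(sh)] <- split(big, factor(sh, levels = unique(sh)))
    }
  }
  empty <- data.frame(position = integer(), effect = numeric(),
                      p = numeric(), weight = numeric())
  assoc[vapply(assoc, is.null, logical(1))] <- list(empty)
  intervals$n <- vapply(assoc, nrow, integer(1))
  out <- structure(list(context = ctx, intervals = intervals, loci = assoc),
                   class = "context_assoc")
  attr(out, "missing_data") <- intervals$gene_id[intervals$n == 0]
  out
}

#' @export
print.context_assoc <- function(x, ...) {
  cat("context association '", x$context$name, "': ", nrow(x$intervals),
      " intervals, ", sum(x$intervals$n), " loci (",
      sum(x$intervals$n == 0), " intervals without data)\n", sep = "")
  invisible(x)
}
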