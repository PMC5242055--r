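RUN_CONFIG_KEYS <- c("genes", "tracks", "expression", "contexts", "network",
                     "correlation", "adjustment", "normalization", "scoring",
                     "modules", "seed", "output_dir")

#' Build a run configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Unknown keys are rejected before any computation; the total context
#' weight must be positive.
#'
#' @param genes path to the gene BED.
#' @param tracks named list of score tracks, each
#'   `list(path =, one_based = FALSE)`.
#' @param contexts list of [context_def()].
#' @param expression optional path to a gene-level expression table (for
#'   contexts with [expression_rule()]).
#' @param network optional path to an edge-list TSV.
#' @param correlation list: `n_bins`, `n_resamples`,
#'   `significance_threshold` for the correlation profile.
#' @param adjustment list: `n_strata`, `n_null_distributions` for the
#'   quantile-permutation step.
#' @param normalization `"logit"`, `"boxcox"` or `"none"`.
#' @param scoring list: `n_boot` for the gene-level bootstrap.
#' @param modules list: `algorithm` (`"spinglass"`, `"mwcs"`, `"both"`),
#'   `gamma`, `min_size`, `max_size`, `spins`, `alpha` (background
#'   quantile used as the MWCS offset).
#' @param seed integer global seed; every stage derives its own stream
#'   from it.
#' @param output_dir where all result tables are written.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(genes, tracks = list(), contexts, expression = NULL,
                       network = NULL, correlation = list(),
                       adjustment = list(), normalization = "logit",
                       scoring = list(), modules = list(), seed,
                       output_dir) {
  cfg <- list(genes = genes, tracks = tracks, expression = expression,
              contexts = contexts, network = network,
              correlation = correlation, adjustment = adjustment,
              normalization = normalization, scoring = scoring,
              modules = modules, seed = seed, output_dir = output_dir)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("genes", "contexts", "seed", "output_dir")) {
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  }
  cfg$contexts <- lapply(cfg$contexts, function(ct) {
    if (inherits(ct, "context_def")) ct else do.call(context_def, ct)
  })
  defs <- context_lookup(cfg$contexts)
  w <- vapply(defs, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) stop("total context weight must be positive")
  for (ct in defs) {
    if (ct$rule$type == "expression") {
      if (is.null(cfg$expression)) {
        stop("context '", ct$name, "' needs an expression table")
      }
    } else if (!ct$track %in% names(cfg$tracks)) {
      stop("context '", ct$name, "' references unknown track '", ct$track, "'")
    }
  }
  defaults <- list(
    correlation = list(n_bins = 500, n_resamples = 500,
                       significance_threshold = 0.05),
    adjustment = list(n_strata = 10, n_null_distributions = 100),
    scoring = list(n_boot = 1000),
    modules = list(algorithm = "spinglass", gamma = 0.5, min_size = 8,
                   max_size = 100, spins = 25, restarts = 3, alpha = 0.05))
  for (blk in names(defaults)) {
    given <- cfg[[blk]] %||% list()
    unknown <- setdiff(names(given), names(defaults[[blk]]))
    if (length(unknown)) {
      stop("unknown key(s) in config block '", blk, "': ",
           paste(unknown, collapse = ", "))
    }
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], given)
  }
  cfg$normalization <- cfg$normalization %||% "logit"
  if (!cfg$normalization %in% c("logit", "boxcox", "none")) {
    stop("normalization must be 'logit', 'boxcox' or 'none'")
  }
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]: top-level keys plus a `contexts`
#' sequence of mappings (fields of [context_def()], with `rule` given as a
#' mapping with a `type` field).
#'
#' @param path YAML file path.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$contexts)) {
    raw$contexts <- lapply(raw$contexts, function(ct) {
      if (!is.null(ct$rule)) {
        rl <- ct$rule
        ct$rule <- switch(rl$type,
          promoter = promoter_rule(rl$upstream %||% 1000,
                                   rl$downstream %||% 500),
          gene_body = body_rule(),
          custom_bed = bed_rule(rl$path, rl$flank %||% 0,
                                rl$max_distance %||% 50000),
          expression = expression_rule(),
          stop("unknown rule type: ", rl$type))
      }
      ct
    })
  }
  validate_run_config(raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full scoring and module-discovery pipeline
#'
#' Executes, in order: input parsing, per-context interval derivation and
#' locus association, correlation-profile estimation, decorrelated
#' Stouffer aggregation with quantile-permutation adjustment,
#' cross-context normalization, gene-level combination with a bootstrap
#' null, and (when a network is configured) module discovery with
#' chi-squared module significance. All intermediate tables are written
#' under `output_dir` along with a JSON manifest; re-running with the same
#' config and seed reproduces every output byte for byte.
#'
#' @param config a `run_config` (or plain list; validated on entry).
#' @return invisible list: `gene_scores`, `context_scores`, `modules`
#'   (ranked list), `module_tables`, `reports`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(unclass(config))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  defs <- context_lookup(config$contexts)

  genes <- run_stage("read_genes", read_gene_bed(config$genes))
  tracks <- run_stage("read_tracks", lapply(config$tracks, function(tk) {
    read_score_track(tk$path, one_based = isTRUE(tk$one_based))
  }))
  expr <- if (!is.null(config$expression)) {
    run_stage("read_expression", read_expression_table(config$expression))
  }

  cs_list <- list()
  reports <- list(missing_data = list())
  for (ct in defs) {
    if (ct$rule$type == "expression") {
      cs <- run_stage(paste0("expression_context:", ct$name), {
        keep <- expr$gene_id %in% genes$gene_id
        ex <- expr[keep, , drop = FALSE]
        dir <- sign(ex$effect)
        dir[dir == 0] <- 1
        data.frame(gene_id = ex$gene_id, context = ct$name, n = 1L,
                   raw = z_transform(ex$p), adjusted_p = clamp_p(ex$p),
                   direction = dir, stringsAsFactors = FALSE)
      })
    } else {
      cs <- run_stage(paste0("score_context:", ct$name), {
        iv <- derive_intervals(genes, ct)
        assoc <- associate_loci(iv, tracks[[ct$track]], ct)
        pairs <- neighbor_pairs(
          assoc, significance_threshold = config$correlation$significance_threshold)
        profile <- if (nrow(pairs) >= 1) {
          estimate_profile(pairs,
                           n_bins = config$correlation$n_bins,
                           n_resamples = config$correlation$n_resamples,
                           seed = stage_seed(seed, paste0("profile:", ct$name)))
        } else {
          message("no neighbor pairs in context '", ct$name,
                  "'; assuming independence")
          corr_profile(c(0, 1), 0)
        }
        write_profile(profile,
                      file.path(out_dir, paste0("profile_", ct$name, ".tsv")))
        score_context(assoc, profile,
                      n_strata = config$adjustment$n_strata,
                      n_null_distributions = config$adjustment$n_null_distributions,
                      seed = stage_seed(seed, paste0("adjust:", ct$name)))
      })
      reports$missing_data[[ct$name]] <- attr(cs, "missing_data")
    }
    cs_list[[ct$name]] <- cs
  }

  norm <- run_stage("normalize", {
    p_by_ctx <- lapply(cs_list, `[[`, "adjusted_p")
    normalize_scores(p_by_ctx, method = config$normalization)
  })
  for (nm in names(cs_list)) cs_list[[nm]]$adjusted_p <- norm$p[[nm]]
  context_scores <- do.call(rbind, cs_list)
  rownames(context_scores) <- NULL

  gene_scores <- run_stage("gene_scoring", {
    gs <- combine_gene_scores(context_scores, config$contexts)
    gs <- bootstrap_gene_p(gs, context_scores, config$contexts,
                           n_boot = config$scoring$n_boot,
                           seed = stage_seed(seed, "bootstrap"))
    gs$fisher_score <- fisher_score(gs$combined_p)
    reports$no_data <- attr(gs, "no_data")
    gs
  })

  # wide per-context columns for the primary machine-readable output
  gs_out <- gene_scores
  for (nm in names(cs_list)) {
    i <- match(gs_out$gene_id, cs_list[[nm]]$gene_id)
    gs_out[[paste0("p_", nm)]] <- cs_list[[nm]]$adjusted_p[i]
    gs_out[[paste0("dir_", nm)]] <- cs_list[[nm]]$direction[i]
  }
  write_tsv(context_scores, file.path(out_dir, "context_scores.tsv"))
  write_tsv(norm$report, file.path(out_dir, "normalization_report.tsv"))
  write_tsv(gs_out, file.path(out_dir, "gene_scores.tsv"))

  modules <- list()
  mod_tabs <- NULL
  if (!is.null(config$network)) {
    modules <- run_stage("modules", {
      edges <- read_edge_list(config$network)
      net <- build_scored_network(edges, gene_scores)
      mcfg <- config$modules
      mods <- list()
      if (mcfg$algorithm %in% c("spinglass", "both")) {
        mods <- spinglass_modules(net, gamma = mcfg$gamma,
                                  min_size = mcfg$min_size,
                                  max_size = mcfg$max_size,
                                  spins = mcfg$spins,
                                  restarts = mcfg$restarts,
                                  seed = stage_seed(seed, "spinglass"))
      }
      if (mcfg$algorithm %in% c("mwcs", "both")) {
        sel <- select_high_scoring(
          stats::setNames(gene_scores$fisher_score, gene_scores$gene_id),
          alpha = mcfg$alpha, seed = stage_seed(seed, "background"))
        mods <- c(mods, list(greedy_mwcs(net, attr(sel, "threshold"))))
      }
      mods <- rank_modules(mods)
      mod_tabs <- module_tables(mods, net)
      write_tsv(mod_tabs$genes, file.path(out_dir, "modules.tsv"))
      write_tsv(mod_tabs$summary, file.path(out_dir, "module_summary.tsv"))
      mods
    })
  }

  manifest <- list(
    package = "sigmodules",
    version = as.character(utils::packageVersion("sigmodules")),
    seed = seed,
    config_hash = str_hash(paste(deparse(config), collapse = "")),
    normalization = config$normalization,
    n_genes_scored = nrow(gene_scores),
    n_modules = length(modules),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(gene_scores = gene_scores, context_scores = context_scores,
                 modules = modules, module_tables = mod_tabs,
                 reports = reports, output_dir = out_dir))
}

#' Compare two contexts' component scores
#'
#' Pairs per-gene scores (`-log(adjusted_p)`, signed by direction) of two
#' contexts and reports the rate at which their effect directions agree —
#' e.g. to ask whether promoter losses co-occur with gene-body losses.
#'
#' @param context_scores table with columns `gene_id`, `context`,
#'   `adjusted_p`, `direction`.
#' @param context_a,context_b the two context names.
#' @return list: `table` (paired per-gene scores) and `concordance`
#'   (fraction of genes with matching directions).
#' @export
compare_context_scores <- function(context_scores, context_a, context_b) {
  a <- context_scores[context_scores$context == context_a, , drop = FALSE]
  b <- context_scores[context_scores$context == context_b, , drop = FALSE]
  if (!nrow(a)) stop("context '", context_a, "' has no scores")
  if (!nrow(b)) stop("context '", context_b, "' has no scores")
  common <- intersect(a$gene_id, b$gene_id)
  if (!length(common)) stop("no genes scored in both contexts")
  ia <- match(common, a$gene_id)
  ib <- match(common, b$gene_id)
  tab <- data.frame(
    gene_id = common,
    score_a = -log(a$adjusted_p[ia]) * a$direction[ia],
    score_b = -log(b$adjusted_p[ib]) * b$direction[ib],
    direction_a = a$direction[ia], direction_b = b$direction[ib],
    stringsAsFactors = FALSE)
  list(table = tab,
       concordance = mean(tab$direction_a == tab$direction_b))
}

#' Default run configuration for a simulated study
#'
#' Maps the files written by [simulate_study()] onto a reduced-model run
#' configuration: expression (weight 1, direction +1), promoter
#' methylation (weight 1, direction -1: methylation gains at promoters
#' oppose expression) and gene-body methylation (weight 1, direction +1).
#'
#' @param manifest return value of [simulate_study()] (or
#'   [simulate_genome()]).
#' @param output_dir pipeline output directory.
#' @param seed global pipeline seed.
#' @param locus_weighting `"uniform"` or `"tss_decay"` for the epigenomic
#'   contexts.
#' @param ... overrides merged into the config (e.g. `scoring`,
#'   `modules`).
#' @return a validated `run_config`.
#' @export
sim_run_config <- function(manifest, output_dir, seed = 1,
                           locus_weighting = "uniform", ...) {
  cfg <- list(
    genes = manifest$paths$genes,
    tracks = list(methylation = list(path = manifest$paths$methylation)),
    expression = manifest$paths$expression,
    network = manifest$paths$edges,
    contexts = list(
      context_def("expression", "expression", expression_rule(),
                  weight = 1, direction = 1),
      context_def("promoter_meth", "methylation", promoter_rule(),
                  weight = 1, direction = -1,
                  locus_weighting = locus_weighting),
      context_def("body_meth", "methylation", body_rule(),
                  weight = 1, direction = 1,
                  locus_weighting = locus_weighting)),
    seed = seed, output_dir = output_dir)
  over <- list(...)
  cfg[names(over)] <- over
  validate_run_config(cfg)
}
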