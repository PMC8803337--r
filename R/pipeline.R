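#' Build a validated pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis in one validated object.
#' Two input modes exist: `"synthetic"` generates a paired study from a
#' [generative_config()]; `"files"` reads DE tables, an ortholog map and
#' gene sets from disk. Every run writes its resolved configuration
#' verbatim into the output directory.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param out_dir output directory for all result tables.
#' @param seed integer seed governing all randomness of the run.
#' @param gen a [generative_config()] (synthetic mode; its seed is
#'   overridden by `seed`).
#' @param shared_programs program names shared across species (synthetic
#'   mode); defaults to all.
#' @param paths named list for files mode: `de_a`, `de_b`, `map` required;
#'   `sets`, `tf_targets`, `markers` optional.
#' @param species_a,species_b species of the two tables (files mode).
#' @param label_a,label_b labels of the two tables (files mode).
#' @param fdr_max,lfc_min signature thresholds (defaults 0.1 and 1).
#' @param top_k query size for the cumulative-overlap analyses (default
#'   100).
#' @param significance_alpha adjusted-p cutoff for enrichment calls
#'   (default 0.05).
#' @param ortholog_policy `"strict_one_to_one"` or `"expand_all"` for
#'   signature mapping.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), out_dir, seed = 1L,
                       gen = generative_config(), shared_programs = NULL,
                       paths = list(), species_a = "mouse",
                       species_b = "human", label_a = "study_a",
                       label_b = "study_b", fdr_max = 0.1, lfc_min = 1.0,
                       top_k = 100L, significance_alpha = 0.05,
                       ortholog_policy = c("strict_one_to_one",
                                           "expand_all")) {
  mode <- match.arg(mode)
  ortholog_policy <- match.arg(ortholog_policy)
  if (!is.numeric(fdr_max) || fdr_max < 0 || fdr_max > 1) {
    stop("fdr_max must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(lfc_min) || lfc_min <= 0) {
    stop("lfc_min must be positive", call. = FALSE)
  }
  if (!is.numeric(significance_alpha) || significance_alpha <= 0 ||
      significance_alpha >= 1) {
    stop("significance_alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(top_k) || top_k < 1L) {
    stop("top_k must be a positive integer", call. = FALSE)
  }
  if (mode == "files") {
    for (need in c("de_a", "de_b", "map")) {
      if (is.null(paths[[need]])) {
        stop("files mode needs paths$", need, call. = FALSE)
      }
    }
  }
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 gen = gen, shared_programs = shared_programs,
                 paths = paths, species_a = species_a,
                 species_b = species_b, label_a = label_a,
                 label_b = label_b, fdr_max = fdr_max, lfc_min = lfc_min,
                 top_k = as.integer(top_k),
                 significance_alpha = significance_alpha,
                 ortholog_policy = ortholog_policy),
            class = "run_config")
}

# Serialize a run_config to a plain list for the JSON provenance record.
config_as_list <- function(config) {
  gen <- config$gen
  list(mode = config$mode, out_dir = config$out_dir, seed = config$seed,
       shared_programs = config$shared_programs,
       paths = config$paths, species_a = config$species_a,
       species_b = config$species_b, label_a = config$label_a,
       label_b = config$label_b, fdr_max = config$fdr_max,
       lfc_min = config$lfc_min, top_k = config$top_k,
       significance_alpha = config$significance_alpha,
       ortholog_policy = config$ortholog_policy,
       gen = if (config$mode == "synthetic") {
         list(n_genes = gen$n_genes,
              programs = lapply(gen$programs, unclass),
              program_membership_overlap = gen$program_membership_overlap,
              n_replicates_per_group = gen$n_replicates_per_group,
              residual_sd = gen$residual_sd,
              ortholog_coverage = gen$ortholog_coverage,
              one_to_many_fraction = gen$one_to_many_fraction,
              refset_sensitivity = gen$refset_sensitivity,
              refset_precision = gen$refset_precision)
       })
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full cross-species comparison pipeline
#'
#' Chains the modules end to end: acquire inputs (simulate or read), adjust
#' FDR where missing, extract up/down signatures, pair fold changes over
#' strict one-to-one orthologs, compute the Spearman correlation, build
#' cumulative-overlap curves for the top-k increased and decreased query
#' genes, summarize signature overlaps, and (when gene sets are available)
#' run observed/expected enrichment. All result tables are written to the
#' output directory with JSON sidecars; the resolved configuration is
#' written verbatim as `config.json`; the run is deterministic given config
#' and seed.
#'
#' @param config a [run_config()].
#' @return A list of class `run_report`: per-stage record counts, dropped
#'   gene accounting, the result objects, the output paths, and a config
#'   hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  resolved <- config_as_list(config)
  jsonlite::write_json(resolved, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  counts <- list()
  outputs <- character(0)
  params <- list(fdr_max = config$fdr_max, lfc_min = config$lfc_min,
                 top_k = config$top_k,
                 significance_alpha = config$significance_alpha,
                 ortholog_policy = config$ortholog_policy)

  inputs <- run_stage("inputs", {
    if (config$mode == "synthetic") {
      gen <- config$gen
      gen$seed <- config$seed
      pair <- if (is.null(config$shared_programs)) simulate_pair(gen)
              else simulate_pair(gen, config$shared_programs)
      list(table_a = pair$table_a, table_b = pair$table_b, map = pair$map,
           sets = pair$reference_sets, tf_targets = NULL, markers = NULL)
    } else {
      list(table_a = read_de_table(config$paths$de_a, config$label_a,
                                   config$species_a),
           table_b = read_de_table(config$paths$de_b, config$label_b,
                                   config$species_b),
           map = read_ortholog_map(config$paths$map, config$species_a,
                                   config$species_b),
           sets = if (!is.null(config$paths$sets))
             read_gmt(config$paths$sets),
           tf_targets = if (!is.null(config$paths$tf_targets))
             read_tf_targets(config$paths$tf_targets),
           markers = if (!is.null(config$paths$markers))
             read_gmt(config$paths$markers))
    }
  })
  table_a <- inputs$table_a
  table_b <- inputs$table_b
  if (anyNA(table_a$fdr)) table_a <- adjust_de_table(table_a)
  if (anyNA(table_b$fdr)) table_b <- adjust_de_table(table_b)
  counts$genes_a <- nrow(table_a)
  counts$genes_b <- nrow(table_b)

  sig_a <- run_stage("extract", extract_signature(table_a, config$fdr_max,
                                                  config$lfc_min))
  sig_b <- run_stage("extract", extract_signature(table_b, config$fdr_max,
                                                  config$lfc_min))
  counts$signature_a <- c(up = length(sig_a$up), down = length(sig_a$down))
  counts$signature_b <- c(up = length(sig_b$up), down = length(sig_b$down))
  for (side in c("a", "b")) {
    sig <- if (side == "a") sig_a else sig_b
    df <- data.frame(gene = c(sig$up, sig$down),
                     direction = rep(c("up", "down"),
                                     c(length(sig$up), length(sig$down))),
                     stringsAsFactors = FALSE)
    if (nrow(df) > 0L) {
      path <- file.path(config$out_dir, paste0("signature_", side, ".tsv"))
      write_results(df, path, params = params, seed = config$seed)
      outputs <- c(outputs, path)
    }
  }

  paired <- run_stage("pair", pair_fold_changes(table_a, table_b,
                                                inputs$map))
  counts$paired <- attr(paired, "n_pairs")
  counts$dropped <- as.list(attr(paired, "dropped"))
  path <- file.path(config$out_dir, "paired_fc.tsv")
  write_results(as.data.frame(paired), path, params = params,
                seed = config$seed)
  outputs <- c(outputs, path)
  write_drop_report(paired, file.path(config$out_dir, "drop_report.tsv"))
  outputs <- c(outputs, file.path(config$out_dir, "drop_report.tsv"))

  rs <- run_stage("correlate", spearman_rho(paired))
  corr <- data.frame(comparison_id = paste(attr(table_a, "label"),
                                           attr(table_b, "label"),
                                           sep = "_vs_"),
                     rs = rs, n_genes = attr(paired, "n_pairs"),
                     stringsAsFactors = FALSE)
  path <- file.path(config$out_dir, "correlation.tsv")
  write_results(corr, path, params = params, seed = config$seed)
  outputs <- c(outputs, path)

  inv_map <- ortholog_map(inputs$map$gene_b, inputs$map$gene_a,
                          attr(inputs$map, "b_species"),
                          attr(inputs$map, "a_species"))
  curves <- list()
  for (dir_mode in c("increased", "decreased")) {
    curves[[dir_mode]] <- run_stage(paste0("overlap_", dir_mode), {
      ranking <- rank_by_fc(table_a, if (dir_mode == "increased")
        "descending" else "ascending")
      k_eff <- min(config$top_k, nrow(table_b))
      top_b <- top_k(table_b, k_eff, dir_mode)
      mapped <- map_gene_set(top_b, inv_map, config$ortholog_policy)
      if (length(intersect(mapped$mapped, ranking$gene)) == 0L) NULL
      else cumulative_overlap(ranking, mapped$mapped)
    })
    if (!is.null(curves[[dir_mode]])) {
      path <- file.path(config$out_dir,
                        paste0("overlap_curve_", dir_mode, ".tsv"))
      write_overlap_curve(curves[[dir_mode]], path)
      outputs <- c(outputs, path)
    }
  }

  overlaps <- run_stage("overlap_summary", {
    sig_b_up_in_a <- map_gene_set(sig_b$up, inv_map,
                                  config$ortholog_policy)$mapped
    sig_b_down_in_a <- map_gene_set(sig_b$down, inv_map,
                                    config$ortholog_policy)$mapped
    up <- if (length(sig_a$up) > 0L)
      overlap_summary(sig_a$up, sig_b_up_in_a)
    down <- if (length(sig_a$down) > 0L)
      overlap_summary(sig_a$down, sig_b_down_in_a)
    rows <- list()
    if (!is.null(up)) rows$up <- data.frame(direction = "up",
                                            as.data.frame(up))
    if (!is.null(down)) rows$down <- data.frame(direction = "down",
                                                as.data.frame(down))
    if (length(rows) > 0L) do.call(rbind, rows)
  })
  if (!is.null(overlaps)) {
    path <- file.path(config$out_dir, "overlap_summary.tsv")
    write_results(overlaps, path, params = params, seed = config$seed)
    outputs <- c(outputs, path)
  }

  enrichment <- NULL
  if (!is.null(inputs$sets) && length(sig_a$up) > 0L) {
    enrichment <- run_stage("enrich", {
      enrich_collection(sig_a$up, inputs$sets, table_a$gene,
                        alpha = config$significance_alpha)
    })
    path <- file.path(config$out_dir, "enrichment.tsv")
    write_results(enrichment, path, params = params, seed = config$seed)
    outputs <- c(outputs, path)
  }

  tf <- NULL
  if (!is.null(inputs$tf_targets)) {
    tf <- run_stage("tf_enrich", {
      tf_enrichment(sig_a$up, sig_a$down, inputs$tf_targets, table_a$gene,
                    alpha = config$significance_alpha)
    })
    path <- file.path(config$out_dir, "tf_enrichment.tsv")
    write_results(tf, path, params = params, seed = config$seed)
    outputs <- c(outputs, path)
  }

  cell_states <- NULL
  if (!is.null(inputs$markers)) {
    cell_states <- run_stage("project", {
      project_cell_states(table_a, inputs$markers)
    })
    path <- file.path(config$out_dir, "cell_states.tsv")
    write_results(cell_states, path, params = params, seed = config$seed)
    outputs <- c(outputs, path)
  }

  report <- structure(list(counts = counts, correlation = corr,
                           curves = curves, overlaps = overlaps,
                           enrichment = enrichment, tf_enrichment = tf,
                           cell_states = cell_states, outputs = outputs,
                           config_hash = fnv1a_hash(
                             jsonlite::toJSON(resolved, auto_unbox = TRUE,
                                              digits = NA, null = "null")),
                           version = as.character(
                             utils::packageVersion("orthosig"))),
                      class = "run_report")
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(
    list(counts = counts, outputs = basename(outputs),
         config_hash = report$config_hash, version = report$version),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (config", x$config_hash, ")\n")
  cat("  genes:", x$counts$genes_a, "(A),", x$counts$genes_b, "(B);",
      "pairs:", x$counts$paired, "\n")
  cat("  rs =", format(x$correlation$rs, digits = 4), "over",
      x$correlation$n_genes, "pairs\n")
  cat("  outputs:", length(x$outputs), "tables\n")
  invisible(x)
}
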