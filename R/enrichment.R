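#' Observed/expected hypergeometric enrichment of a query in one gene set
#'
#' Core overlap statistic for gene-set similarity readouts: the observed
#' overlap between a query signature and a reference set, divided by the
#' overlap expected under uniform sampling from the universe
#' (`expected = n * K / N`), with a one-sided hypergeometric upper-tail
#' p-value `P(X >= observed)`.
#'
#' The reference set is intersected with the universe before computing `K`;
#' a set with no member in the universe is untestable and returned with
#' `NA` statistics rather than an arbitrary value.
#'
#' @param query character vector, a subset of `universe`.
#' @param ref_set character vector, the reference gene set.
#' @param universe character vector of all genes eligible for sampling
#'   (typically the query's source DE table's gene universe, optionally
#'   intersected with the reference experiment's measurable genes).
#' @param set_name label carried into the result.
#' @return A one-row data frame of class `enrichment_result` with columns
#'   `set_name`, `n_universe`, `k_set`, `n_query`, `observed`, `expected`,
#'   `ratio`, `p_value`, `testable`.
#' @export
hypergeom_enrichment <- function(query, ref_set, universe,
                                 set_name = "set") {
  query <- unique(as.character(query))
  ref_set <- unique(as.character(ref_set))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe)) {
    stop("query is not a subset of the universe (",
         sum(!(query %in% universe)), " genes outside)", call. = FALSE)
  }
  k <- length(intersect(ref_set, universe))
  n <- length(query)
  big_n <- length(universe)
  if (k == 0L) {
    return(structure(data.frame(set_name = set_name, n_universe = big_n,
                                k_set = 0L, n_query = n, observed = 0L,
                                expected = NA_real_, ratio = NA_real_,
                                p_value = NA_real_, testable = FALSE,
                                stringsAsFactors = FALSE),
                     class = c("enrichment_result", "data.frame")))
  }
  obs <- length(intersect(intersect(query, ref_set), universe))
  expected <- n * k / big_n
  p <- phyper(obs - 1L, k, big_n - k, n, lower.tail = FALSE)
  structure(data.frame(set_name = set_name, n_universe = big_n, k_set = k,
                       n_query = n, observed = obs, expected = expected,
                       ratio = obs / expected, p_value = p, testable = TRUE,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Enrichment of a query signature across a gene-set collection
#'
#' Runs [hypergeom_enrichment()] for every set in a collection and adjusts
#' the p-values with Benjamini-Hochberg across the sets actually tested in
#' the call (sets with no member in the universe are reported untestable
#' and excluded from the adjustment's m). Significance is called at
#' `adj_p < alpha`.
#'
#' @param query character vector, a subset of `universe`.
#' @param collection a [gene_set_collection()].
#' @param universe character vector of eligible genes.
#' @param alpha significance cutoff on the adjusted p-value (default 0.05).
#' @return Data frame with one row per set: all [hypergeom_enrichment()]
#'   columns plus `adj_p` and logical `significant`.
#' @export
enrich_collection <- function(query, collection, universe, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- lapply(names(collection), function(nm) {
    hypergeom_enrichment(query, collection[[nm]], universe, set_name = nm)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$adj_p <- NA_real_
  out$adj_p[out$testable] <- bh_adjust(out$p_value[out$testable])
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha
  rownames(out) <- NULL
  out
}

#' Read transcription-factor target sets in three-column (TRRUST-style) form
#'
#' Parses `TF<TAB>target<TAB>mode` lines into a gene-set collection keyed by
#' TF. The regulation mode is carried through in the `modes` attribute but
#' not used by the enrichment test, which asks only whether targets overlap.
#'
#' @param path path to a three-column tab-separated file (no header).
#' @return A [gene_set_collection()] of TF target sets.
#' @export
read_tf_targets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0L) stop("empty TF-target file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("TF-target line(s) with fewer than 3 fields: line ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  tf <- vapply(fields, `[[`, character(1), 1L)
  target <- vapply(fields, `[[`, character(1), 2L)
  mode <- vapply(fields, `[[`, character(1), 3L)
  sets <- split(target, tf)
  coll <- gene_set_collection(sets, source_label = basename(path))
  attr(coll, "modes") <- split(mode, tf)
  coll
}

#' Directional transcription-factor target enrichment
#'
#' For each TF, tests its target set for enrichment separately in the
#' upregulated and the downregulated signature, adjusting p-values with
#' Benjamini-Hochberg within each direction across all testable TFs. The
#' display score summarizes both sides in one signed number: positive when
#' the up-side enrichment dominates (smaller adjusted p), negative when the
#' down side dominates, magnitude `-log10` of the dominant adjusted p. A
#' dead heat (equal adjusted p on both sides, including both at 1) scores 0.
#'
#' @param up,down disjoint character vectors (an extracted signature's up
#'   and down sets), subsets of `universe`.
#' @param tf_targets a [gene_set_collection()] keyed by TF (see
#'   [read_tf_targets()]).
#' @param universe character vector of eligible genes.
#' @param alpha significance cutoff on adjusted p-values.
#' @return Data frame with one row per TF: `tf_name`, up/down observed,
#'   expected, ratio, p and adjusted p columns (`*_up`, `*_down`),
#'   `display_score`, `testable`.
#' @export
tf_enrichment <- function(up, down, tf_targets, universe, alpha = 0.05) {
  stopifnot(inherits(tf_targets, "gene_set_collection"))
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0L) {
    stop("up and down sets must be disjoint", call. = FALSE)
  }
  res_up <- enrich_collection(up, tf_targets, universe, alpha = alpha)
  res_down <- enrich_collection(down, tf_targets, universe, alpha = alpha)
  score <- numeric(nrow(res_up))
  for (i in seq_len(nrow(res_up))) {
    pu <- res_up$adj_p[i]
    pd <- res_down$adj_p[i]
    score[i] <- if (is.na(pu) || is.na(pd) || pu == pd) 0 else
      if (pu < pd) -log10(max(pu, .Machine$double.xmin)) else
      log10(max(pd, .Machine$double.xmin))
  }
  data.frame(tf_name = res_up$set_name,
             k_targets = res_up$k_set,
             observed_up = res_up$observed, expected_up = res_up$expected,
             ratio_up = res_up$ratio, p_up = res_up$p_value,
             adj_p_up = res_up$adj_p,
             observed_down = res_down$observed,
             expected_down = res_down$expected,
             ratio_down = res_down$ratio, p_down = res_down$p_value,
             adj_p_down = res_down$adj_p,
             display_score = score,
             testable = res_up$testable,
             stringsAsFactors = FALSE)
}

#' Project a bulk DE table onto single-cell marker sets
#'
#' For each cell state, collects the log2 fold changes of its marker genes
#' found in the bulk table, summarizes them (median and interquartile
#' range), and tests whether markers shift relative to all non-marker genes
#' with a rank-based (Mann-Whitney) test on the table's deterministic
#' fold-change ranking. States with fewer than `min_members` markers in the
#' table are reported untestable.
#'
#' @param table a [de_table()].
#' @param markers a [gene_set_collection()] of cell-state marker sets.
#' @param min_members minimum markers found to summarize/test (default 3).
#' @param alternative sidedness of the rank test (default two-sided).
#' @return Data frame with one row per state: `state_name`, `n_markers`,
#'   `n_found`, `median_fc`, `iqr_fc`, `p_value`, `testable`.
#' @export
project_cell_states <- function(table, markers, min_members = 3L,
                                alternative = c("two_sided", "top_enriched",
                                                "bottom_enriched")) {
  stopifnot(inherits(table, "de_table"), inherits(markers, "gene_set_collection"))
  alternative <- match.arg(alternative)
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  ranking <- rank_by_fc(table, "descending")
  rows <- lapply(names(markers), function(nm) {
    found <- intersect(markers[[nm]], table$gene)
    n_found <- length(found)
    if (n_found < min_members || n_found == nrow(table)) {
      return(data.frame(state_name = nm, n_markers = length(markers[[nm]]),
                        n_found = n_found, median_fc = NA_real_,
                        iqr_fc = NA_real_, p_value = NA_real_,
                        testable = FALSE, stringsAsFactors = FALSE))
    }
    fc <- table$log2fc[match(found, table$gene)]
    data.frame(state_name = nm, n_markers = length(markers[[nm]]),
               n_found = n_found, median_fc = median(fc),
               iqr_fc = unname(diff(quantile(fc, c(0.25, 0.75)))),
               p_value = rank_sum_test(ranking, found, alternative),
               testable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
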