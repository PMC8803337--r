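#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts raw p-values for multiple testing with the Benjamini-Hochberg
#' step-up procedure: sort ascending, multiply `p_(i)` by `m/i`, enforce
#' monotonicity from the largest rank down, cap at 1, and return values in
#' the original order. Delegates to [stats::p.adjust()] after validation.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, elementwise >= the input and <= 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.002)) # 0.02 0.04 0.04 0.008
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Fill in the FDR column of a DE table
#'
#' Applies [bh_adjust()] to the table's raw p-values and clears the
#' `needs_bh` flag. A no-op (with a warning) if FDR values are already
#' present.
#'
#' @param table a [de_table()].
#' @return The table with `fdr` populated.
#' @export
adjust_de_table <- function(table) {
  stopifnot(inherits(table, "de_table"))
  if (!isTRUE(attr(table, "needs_bh")) && !anyNA(table$fdr)) {
    warning("table already carries FDR values; leaving them untouched")
    return(table)
  }
  table$fdr <- bh_adjust(table$pvalue)
  attr(table, "needs_bh") <- FALSE
  table
}

#' Extract an up/down significance signature from a DE table
#'
#' Applies the inclusive significance rule used throughout the package:
#' a gene is *up* when `fdr <= fdr_max` and `log2fc >= lfc_min`, *down* when
#' `fdr <= fdr_max` and `log2fc <= -lfc_min`. Defaults implement the
#' FDR <= 0.1, |log2FC| >= 1 rule.
#'
#' @param table a [de_table()] whose `fdr` column is populated (run
#'   [adjust_de_table()] first otherwise).
#' @param fdr_max inclusive FDR ceiling (default 0.1).
#' @param lfc_min inclusive absolute log2 fold-change floor (default 1);
#'   must be positive.
#' @return An object of class `de_signature`: a list with character vectors
#'   `up` and `down` (disjoint), the thresholds, and the source label.
#' @export
extract_signature <- function(table, fdr_max = 0.1, lfc_min = 1.0) {
  stopifnot(inherits(table, "de_table"))
  if (anyNA(table$fdr)) {
    stop("fdr missing on some records; run adjust_de_table() first",
         call. = FALSE)
  }
  if (!is.numeric(lfc_min) || lfc_min <= 0) {
    stop("lfc_min must be positive", call. = FALSE)
  }
  sig <- table$fdr <= fdr_max
  structure(list(up = table$gene[sig & table$log2fc >= lfc_min],
                 down = table$gene[sig & table$log2fc <= -lfc_min],
                 fdr_max = fdr_max, lfc_min = lfc_min,
                 source_label = attr(table, "label")),
            class = "de_signature")
}

#' @export
print.de_signature <- function(x, ...) {
  cat(sprintf("de_signature '%s' (FDR <= %g, |log2FC| >= %g): %d up, %d down\n",
              x$source_label, x$fdr_max, x$lfc_min,
              length(x$up), length(x$down)))
  invisible(x)
}

#' Combine signatures from two data sets of the same condition
#'
#' When a condition was profiled in independent data sets, their
#' signatures can be combined by union (default: a gene significant in
#' either set counts) or intersection (significant in both). The chosen
#' mode is recorded in the result's label so downstream outputs carry it.
#' A gene up in one set and down in the other is contradictory and is
#' excluded from both sides of the combination.
#'
#' @param a,b `de_signature` objects from [extract_signature()].
#' @param mode `"union"` or `"intersection"`.
#' @return A `de_signature` labelled `<label_a>+<label_b>(<mode>)`.
#' @export
combine_signatures <- function(a, b, mode = c("union", "intersection")) {
  stopifnot(inherits(a, "de_signature"), inherits(b, "de_signature"))
  mode <- match.arg(mode)
  comb <- if (mode == "union") base::union else base::intersect
  up <- comb(a$up, b$up)
  down <- comb(a$down, b$down)
  contradictory <- union(intersect(a$up, b$down), intersect(a$down, b$up))
  structure(list(up = setdiff(up, contradictory),
                 down = setdiff(down, contradictory),
                 fdr_max = max(a$fdr_max, b$fdr_max),
                 lfc_min = min(a$lfc_min, b$lfc_min),
                 source_label = sprintf("%s+%s(%s)", a$source_label,
                                        b$source_label, mode)),
            class = "de_signature")
}

#' Top-k genes by fold change
#'
#' The `k` genes with the largest (`"increased"`) or smallest
#' (`"decreased"`) log2 fold changes; ties are broken by gene identifier so
#' the selection is deterministic. By default the ranking is over all genes,
#' matching a pure fold-change top-100 selection; set `fdr_max` to add a
#' significance gate first.
#'
#' @param table a [de_table()].
#' @param k number of genes, at most the table size.
#' @param direction `"increased"` or `"decreased"`.
#' @param fdr_max optional inclusive FDR gate applied before ranking.
#' @return Character vector of `k` gene identifiers.
#' @export
top_k <- function(table, k, direction = c("increased", "decreased"),
                  fdr_max = NULL) {
  stopifnot(inherits(table, "de_table"))
  direction <- match.arg(direction)
  if (!is.null(fdr_max)) {
    if (anyNA(table$fdr)) stop("fdr gate requested but fdr missing",
                               call. = FALSE)
    table <- table[table$fdr <= fdr_max, , drop = FALSE]
  }
  if (k < 1L || k > nrow(table)) {
    stop("k must be between 1 and the (gated) table size (", nrow(table), ")",
         call. = FALSE)
  }
  ord <- if (direction == "increased") {
    order(-table$log2fc, table$gene)
  } else {
    order(table$log2fc, table$gene)
  }
  table$gene[ord][seq_len(k)]
}

#' Rank a DE table by fold change
#'
#' Full deterministic ordering of a table by log2 fold change, ties broken
#' by gene identifier. Descending order puts the most increased genes first
#' and is the reference ranking for "increased" cumulative-overlap analyses;
#' ascending is the "decreased" counterpart.
#'
#' @param table a non-empty [de_table()].
#' @param order `"descending"` or `"ascending"`.
#' @return A data frame of class `ranked_genes` with columns `gene`,
#'   `log2fc` and attribute `order`.
#' @export
rank_by_fc <- function(table, order = c("descending", "ascending")) {
  stopifnot(inherits(table, "de_table"))
  order <- match.arg(order)
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  idx <- if (order == "descending") {
    base::order(-table$log2fc, table$gene)
  } else {
    base::order(table$log2fc, table$gene)
  }
  structure(data.frame(gene = table$gene[idx], log2fc = table$log2fc[idx],
                       stringsAsFactors = FALSE),
            order = order, source_label = attr(table, "label"),
            class = c("ranked_genes", "data.frame"))
}

#' Mean-centered principal component analysis with a fixed sign convention
#'
#' Thin wrapper over [stats::prcomp()] (no scaling) for sample QC plots.
#' Each component's sign is fixed by forcing its largest-magnitude loading
#' positive, so coordinates are reproducible across platforms.
#'
#' @param x numeric matrix, samples in rows, genes (features) in columns.
#' @param n_components number of components to return; at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return List with `coordinates` (samples x n_components),
#'   `variance_fraction` (per returned component, fractions of total
#'   variance; sums to <= 1) and `loadings`.
#' @export
pca_projection <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  max_nc <- min(nrow(x) - 1L, ncol(x))
  if (n_components < 1L || n_components > max_nc) {
    stop("n_components must be in [1, ", max_nc, "]", call. = FALSE)
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(fit$sdev^2)
  keep <- seq_len(n_components)
  rot <- fit$rotation[, keep, drop = FALSE]
  coords <- fit$x[, keep, drop = FALSE]
  for (j in keep) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  list(coordinates = coords,
       variance_fraction = fit$sdev[keep]^2 / total_var,
       loadings = rot, center = fit$center)
}
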