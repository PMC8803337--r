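#' Map a gene set across species through an ortholog map
#'
#' Two policies are offered. `strict_one_to_one` keeps only genes whose
#' pairing is unique in both directions of the whole map — the conservative
#' choice that avoids double counting in enrichment universes (one-to-many
#' families such as the three mouse Dsg1 genes versus one human DSG1 are
#' dropped). `expand_all` includes every mapped partner. Dropped genes are
#' reported by reason, never silently discarded.
#'
#' @param genes character vector of identifiers in the map's A species.
#' @param map an [ortholog_map()].
#' @param policy `"strict_one_to_one"` (default) or `"expand_all"`.
#' @return List with `mapped` (character vector of B-species identifiers)
#'   and `dropped` (data frame `gene`, `reason` with reasons `unmapped` or
#'   `ambiguous`).
#' @export
map_gene_set <- function(genes, map,
                         policy = c("strict_one_to_one", "expand_all")) {
  stopifnot(inherits(map, "ortholog_map"))
  policy <- match.arg(policy)
  genes <- unique(as.character(genes))
  count_a <- table(map$gene_a)
  count_b <- table(map$gene_b)
  in_map <- genes %in% map$gene_a
  dropped <- data.frame(gene = genes[!in_map],
                        reason = rep("unmapped", sum(!in_map)),
                        stringsAsFactors = FALSE)
  if (policy == "expand_all") {
    mapped <- unique(map$gene_b[map$gene_a %in% genes])
  } else {
    unique_pair <- count_a[map$gene_a] == 1L & count_b[map$gene_b] == 1L
    strict <- map[unique_pair, , drop = FALSE]
    ambiguous <- genes[in_map & !(genes %in% strict$gene_a)]
    if (length(ambiguous) > 0L) {
      dropped <- rbind(dropped,
                       data.frame(gene = ambiguous, reason = "ambiguous",
                                  stringsAsFactors = FALSE))
    }
    mapped <- strict$gene_b[match(intersect(genes, strict$gene_a),
                                  strict$gene_a)]
  }
  list(mapped = mapped, dropped = dropped)
}

#' Pair fold changes across two species over strict one-to-one orthologs
#'
#' Builds the paired fold-change vector behind every cross-species
#' correlation and overlap analysis: one entry per strict one-to-one
#' ortholog pair present in both tables, ordered by the A-species
#' identifier. Every A-species gene is accounted for: it is either paired or
#' counted as dropped with a reason (`unmapped`, `ambiguous`,
#' `missing_in_b`).
#'
#' @param table_a,table_b [de_table()]s for the map's A and B species.
#' @param map an [ortholog_map()] whose species match the tables.
#' @return A data frame of class `paired_fc` with columns `gene_a`,
#'   `gene_b`, `fc_a`, `fc_b`, and attributes `n_pairs` and `dropped`
#'   (named counts by reason).
#' @export
pair_fold_changes <- function(table_a, table_b, map) {
  stopifnot(inherits(table_a, "de_table"), inherits(table_b, "de_table"),
            inherits(map, "ortholog_map"))
  sp_a <- attr(table_a, "species")
  sp_b <- attr(table_b, "species")
  if (!identical(sp_a, attr(map, "a_species")) ||
      !identical(sp_b, attr(map, "b_species"))) {
    stop("species mismatch between tables (", sp_a, ", ", sp_b,
         ") and map (", attr(map, "a_species"), ", ", attr(map, "b_species"),
         ")", call. = FALSE)
  }
  count_a <- table(map$gene_a)
  count_b <- table(map$gene_b)
  unique_pair <- count_a[map$gene_a] == 1L & count_b[map$gene_b] == 1L
  strict <- map[unique_pair, , drop = FALSE]

  genes_a <- table_a$gene
  idx <- match(genes_a, strict$gene_a)
  unmapped <- !(genes_a %in% map$gene_a)
  ambiguous <- (genes_a %in% map$gene_a) & is.na(idx)
  partner <- strict$gene_b[idx]
  missing_in_b <- !is.na(idx) & !(partner %in% table_b$gene)
  keep <- !is.na(idx) & !missing_in_b

  gene_a <- genes_a[keep]
  gene_b <- partner[keep]
  ord <- base::order(gene_a)
  gene_a <- gene_a[ord]
  gene_b <- gene_b[ord]
  if (length(gene_a) == 0L) {
    stop("no ortholog pairs shared by both tables", call. = FALSE)
  }
  out <- data.frame(gene_a = gene_a, gene_b = gene_b,
                    fc_a = table_a$log2fc[match(gene_a, table_a$gene)],
                    fc_b = table_b$log2fc[match(gene_b, table_b$gene)],
                    stringsAsFactors = FALSE)
  structure(out, n_pairs = nrow(out),
            dropped = c(unmapped = sum(unmapped),
                        ambiguous = sum(ambiguous),
                        missing_in_b = sum(missing_in_b)),
            labels = c(a = attr(table_a, "label"),
                       b = attr(table_b, "label")),
            class = c("paired_fc", "data.frame"))
}

#' @export
print.paired_fc <- function(x, ...) {
  d <- attr(x, "dropped")
  cat(sprintf(
    "paired_fc: %d pairs (dropped: %d unmapped, %d ambiguous, %d missing_in_b)\n",
    attr(x, "n_pairs"), d[["unmapped"]], d[["ambiguous"]],
    d[["missing_in_b"]]))
  invisible(x)
}

#' Build an uppercase-identity ortholog map
#'
#' Convenience constructor for the common mouse-to-human symbol convention
#' (`Dsg1` -> `DSG1`). Mapping always requires an explicit
#' [ortholog_map()]; this helper simply builds one, it is never applied as a
#' silent fallback.
#'
#' @param genes character vector of A-species identifiers.
#' @param a_species,b_species species labels for the two sides.
#' @return An [ortholog_map()] pairing each gene with its uppercased symbol.
#' @export
build_uppercase_map <- function(genes, a_species = "mouse",
                                b_species = "human") {
  genes <- unique(as.character(genes))
  ortholog_map(genes, toupper(genes), a_species, b_species)
}

#' Write a drop report alongside results
#'
#' @param paired a `paired_fc` object from [pair_fold_changes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_drop_report <- function(paired, path) {
  stopifnot(inherits(paired, "paired_fc"))
  d <- attr(paired, "dropped")
  df <- data.frame(reason = c("paired", names(d)),
                   n = c(attr(paired, "n_pairs"), unname(d)),
                   stringsAsFactors = FALSE)
  write_results(df, path, params = list(labels = as.list(attr(paired, "labels"))))
}
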