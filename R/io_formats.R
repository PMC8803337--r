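#' Construct a differential-expression table
#'
#' A `de_table` is the package's in-memory form of a per-gene
#' differential-expression result: one row per gene with its log2 fold
#' change, raw p-value and (optionally) FDR. All downstream operations —
#' signature extraction, ranking, ortholog pairing, enrichment — consume
#' this type rather than files.
#'
#' @param gene character vector of unique, non-empty gene identifiers.
#'   Identifiers are case-sensitive; no cross-species case munging happens
#'   here (see [build_uppercase_map()] for the explicit helper).
#' @param log2fc finite numeric vector of log2 fold changes.
#' @param pvalue numeric vector of raw p-values in \[0, 1\].
#' @param fdr optional numeric vector of adjusted p-values in \[0, 1\];
#'   `NULL` leaves the column `NA` and flags the table as needing
#'   [bh_adjust()] before thresholding.
#' @param label character scalar naming the contrast
#'   (e.g. `"Dsg1-KO_E18.5_ds1"`).
#' @param species one of `"mouse"`, `"human"`, `"synthetic"`.
#'
#' @return A data frame of class `de_table` with columns `gene`, `log2fc`,
#'   `pvalue`, `fdr` and attributes `label`, `species` and `needs_bh`.
#' @export
#' @examples
#' de_table(c("G1", "G2"), c(1.5, -2), c(0.01, 0.002), label = "toy",
#'          species = "synthetic")
de_table <- function(gene, log2fc, pvalue, fdr = NULL, label, species) {
  stopifnot(is.character(gene), is.numeric(log2fc), is.numeric(pvalue))
  species <- match_species(species)
  if (length(gene) < 1L) {
    stop("a de_table needs at least one record", call. = FALSE)
  }
  if (any(gene == "" | is.na(gene))) {
    stop("empty or missing gene identifiers are not allowed", call. = FALSE)
  }
  dup <- unique(gene[duplicated(gene)])
  if (length(dup) > 0L) {
    stop("duplicate gene id(s): ", paste(head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(log2fc))) {
    stop("log2fc must be finite for every gene", call. = FALSE)
  }
  if (any(is.na(pvalue)) || any(pvalue < 0 | pvalue > 1)) {
    stop("pvalue outside [0, 1]", call. = FALSE)
  }
  needs_bh <- is.null(fdr)
  if (needs_bh) {
    fdr <- rep(NA_real_, length(gene))
  } else if (any(!is.na(fdr) & (fdr < 0 | fdr > 1))) {
    stop("fdr outside [0, 1]", call. = FALSE)
  }
  out <- data.frame(gene = gene, log2fc = as.numeric(log2fc),
                    pvalue = as.numeric(pvalue), fdr = as.numeric(fdr),
                    stringsAsFactors = FALSE)
  structure(out, label = as.character(label)[1L], species = species,
            needs_bh = needs_bh, class = c("de_table", "data.frame"))
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("de_table '%s' (%s): %d genes%s\n",
              attr(x, "label"), attr(x, "species"), nrow(x),
              if (isTRUE(attr(x, "needs_bh"))) " [needs BH adjustment]" else ""))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read a differential-expression table from tab-separated text
#'
#' Reads a header-bearing TSV with (at least) gene, log2 fold-change and
#' p-value columns. Rows with an empty gene identifier or a non-numeric
#' log2fc/p-value are rejected — never silently dropped — and reported in the
#' `rejected` attribute of the result; accepted + rejected row counts always
#' add up to the input row count. Duplicate gene identifiers are an error.
#'
#' @param path path to a tab-separated file with a header row.
#' @param label,species passed to [de_table()].
#' @param columns named character vector mapping the canonical names
#'   `gene`, `log2fc`, `pvalue`, `fdr` to the column names used in the file.
#'   The `fdr` column is optional in the file; when absent the table is
#'   flagged as needing [bh_adjust()].
#' @return A [de_table()] with attribute `rejected`: a data frame
#'   (`row`, `gene`, `reason`) of rejected input rows.
#' @export
read_de_table <- function(path, label, species,
                          columns = c(gene = "gene", log2fc = "log2fc",
                                      pvalue = "pvalue", fdr = "fdr")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  defaults <- c(gene = "gene", log2fc = "log2fc", pvalue = "pvalue",
                fdr = "fdr")
  columns <- c(columns, defaults[setdiff(names(defaults), names(columns))])
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE)
  for (need in c("gene", "log2fc", "pvalue")) {
    if (!columns[[need]] %in% names(raw)) {
      stop("missing mandatory column '", columns[[need]], "' in ", path,
           call. = FALSE)
    }
  }
  gene <- raw[[columns[["gene"]]]]
  lfc <- suppressWarnings(as.numeric(raw[[columns[["log2fc"]]]]))
  p <- suppressWarnings(as.numeric(raw[[columns[["pvalue"]]]]))
  has_fdr <- columns[["fdr"]] %in% names(raw)
  fdr <- if (has_fdr) {
    suppressWarnings(as.numeric(raw[[columns[["fdr"]]]]))
  } else {
    rep(NA_real_, nrow(raw))
  }

  bad_gene <- is.na(gene) | gene == ""
  bad_lfc <- !is.finite(lfc)
  bad_p <- is.na(p)
  reject <- bad_gene | bad_lfc | bad_p
  reason <- character(nrow(raw))
  reason[bad_p] <- "non-numeric pvalue"
  reason[bad_lfc] <- "non-numeric log2fc"
  reason[bad_gene] <- "empty gene"
  rejected <- data.frame(row = which(reject),
                         gene = ifelse(bad_gene[reject], NA, gene[reject]),
                         reason = reason[reject], stringsAsFactors = FALSE)
  keep <- !reject
  if (!any(keep)) stop("no valid rows in ", path, call. = FALSE)

  tab <- de_table(gene[keep], lfc[keep], p[keep],
                  fdr = if (has_fdr) fdr[keep] else NULL,
                  label = label, species = species)
  attr(tab, "rejected") <- rejected
  tab
}

#' Construct a gene-set collection
#'
#' A named list of deduplicated gene-identifier vectors, the in-memory
#' equivalent of a GMT file. Used for cytokine-response reference
#' signatures, transcription-factor target sets and cell-state marker sets.
#'
#' @param sets named list of character vectors (set name -> members).
#' @param descriptions optional character vector parallel to `sets`.
#' @param source_label character scalar recording where the sets came from.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                source_label = "unspecified") {
  stopifnot(is.list(sets))
  if (length(sets) == 0L) stop("empty gene-set collection", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm) || any(nm == "")) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(sets, function(m) unique(as.character(m[m != ""])))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s): ",
         paste(nm[lengths(sets) == 0L], collapse = ", "), call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = setNames(as.character(descriptions), nm),
            source_label = source_label, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets (sizes %s)\n",
              attr(x, "source_label"), length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' deduplicated and empty member fields dropped.
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(head(short, 5L), collapse = ", "), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  gene_set_collection(setNames(members, nm), descriptions = desc,
                      source_label = basename(path))
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an ortholog map
#'
#' Cross-species gene pairings with multiplicity: a one-to-many ortholog is
#' recorded as multiple `(gene_a, gene_b)` pairs. Exact duplicate pairs are
#' an error.
#'
#' @param gene_a,gene_b character vectors of paired identifiers.
#' @param a_species,b_species species of each column.
#' @return A data frame of class `ortholog_map` with columns `gene_a`,
#'   `gene_b` and attributes `a_species`, `b_species`.
#' @export
ortholog_map <- function(gene_a, gene_b, a_species, b_species) {
  stopifnot(is.character(gene_a), is.character(gene_b),
            length(gene_a) == length(gene_b))
  a_species <- match_species(a_species)
  b_species <- match_species(b_species)
  if (length(gene_a) == 0L) stop("empty ortholog map", call. = FALSE)
  if (any(gene_a == "" | gene_b == "")) {
    stop("empty identifier in ortholog map", call. = FALSE)
  }
  key <- paste(gene_a, gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate ortholog pair: ", gene_a[d], " -> ", gene_b[d],
         call. = FALSE)
  }
  out <- data.frame(gene_a = gene_a, gene_b = gene_b,
                    stringsAsFactors = FALSE)
  structure(out, a_species = a_species, b_species = b_species,
            class = c("ortholog_map", "data.frame"))
}

#' Multiplicity summary of an ortholog map
#'
#' @param map an [ortholog_map()].
#' @return A list with counts `one_to_one`, `one_to_many`, `many_to_one`,
#'   `many_to_many` (pair counts by the multiplicity of their endpoints) and
#'   `n_pairs`.
#' @export
ortholog_multiplicity <- function(map) {
  stopifnot(inherits(map, "ortholog_map"))
  na <- table(map$gene_a)[map$gene_a]
  nb <- table(map$gene_b)[map$gene_b]
  list(n_pairs = nrow(map),
       one_to_one = sum(na == 1L & nb == 1L),
       one_to_many = sum(na > 1L & nb == 1L),
       many_to_one = sum(na == 1L & nb > 1L),
       many_to_many = sum(na > 1L & nb > 1L))
}

#' Read a two-column tab-separated ortholog map
#'
#' @param path path to a two-column TSV (`gene_a<TAB>gene_b`), optionally
#'   with a header row.
#' @param a_species,b_species species of the two columns.
#' @param header does the file carry a header row?
#' @return An [ortholog_map()]; its multiplicity summary is attached as
#'   attribute `multiplicity`.
#' @export
read_ortholog_map <- function(path, a_species, b_species, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  if (header && length(lines) > 0L) lines <- lines[-1L]
  if (length(lines) == 0L) stop("empty ortholog map file: ", path,
                                call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    stop("malformed ortholog-map line(s): line ",
         paste(head(bad + header, 5L), collapse = ", "), call. = FALSE)
  }
  map <- ortholog_map(vapply(fields, `[[`, character(1), 1L),
                      vapply(fields, `[[`, character(1), 2L),
                      a_species, b_species)
  attr(map, "multiplicity") <- ortholog_multiplicity(map)
  map
}

#' Write a result table with a machine-readable run summary
#'
#' Writes any result collection coercible to a data frame as tab-separated
#' text with a header, plus a JSON sidecar (`<path>.summary.json`) recording
#' the parameters, seed and row count of the run. Output is byte-identical
#' for identical inputs and parameters.
#'
#' @param results a non-empty data frame (or object coercible to one).
#' @param path output path for the TSV.
#' @param params named list of run parameters recorded in the sidecar.
#' @param seed the seed used for the run, if any.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, params = list(), seed = NULL) {
  df <- as.data.frame(results, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("refusing to write an empty result table",
                           call. = FALSE)
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con), add = TRUE)
  # fixed eol + fixed 15-digit numeric formatting => deterministic bytes
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  sidecar <- paste0(path, ".summary.json")
  summary <- list(file = basename(path), n_rows = nrow(df),
                  columns = names(df), params = params, seed = seed)
  jsonlite::write_json(summary, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a table written by [write_results()]
#'
#' @param path path to the TSV.
#' @return A data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", quote = "", check.names = FALSE,
             stringsAsFactors = FALSE)
}
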