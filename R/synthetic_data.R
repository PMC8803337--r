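#' Specify a planted transcriptional program
#'
#' A program is a block of genes sharing one latent effect: the synthetic
#' stand-in for a coordinated transcriptional response (an IL-17-like
#' signaling module, say). The program's effect size is drawn once per
#' program — not per gene — so two studies that share a program share the
#' identical true signal; per-gene heterogeneity enters only through
#' `effect_sd`.
#'
#' @param name unique program name.
#' @param size number of member genes (>= 1).
#' @param effect mean true log2 fold change of the program.
#' @param effect_sd standard deviation of the program-level effect draw
#'   (>= 0).
#' @param direction `"up"` (positive effect; requires `effect > 0`),
#'   `"down"` (negative), or `"mixed"` (per-gene random sign).
#' @return An object of class `program_spec`.
#' @export
program_spec <- function(name, size, effect, effect_sd = 0,
                         direction = c("up", "down", "mixed")) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, size >= 1L,
            is.numeric(effect), effect_sd >= 0)
  if (direction == "up" && effect <= 0) {
    stop("an up program needs a positive effect", call. = FALSE)
  }
  structure(list(name = name, size = as.integer(size), effect = effect,
                 effect_sd = effect_sd, direction = direction),
            class = "program_spec")
}

#' Configuration of the two-species synthetic generator
#'
#' Defaults encode the package's canonical study conditions: 2000 genes, a
#' single shared upregulated program of 100 genes with effect 2 (log2
#' units) and no program-level spread, per-replicate log2 expression noise
#' of 1 with 4 replicates per group (so the fold-change standard error is
#' `residual_sd * sqrt(2 / n_replicates) ~ 0.707`), an ortholog map
#' covering 90% of genes with 5% one-to-many contamination, and reference
#' sets that tag the planted program with 80% sensitivity and 80%
#' precision.
#'
#' @param n_genes total genes per study.
#' @param programs list of [program_spec()]s; sizes must sum to at most
#'   `n_genes`.
#' @param program_membership_overlap fraction of each program's members
#'   (after the first program) recruited from earlier programs, in \[0, 1).
#' @param n_replicates_per_group replicates per group (>= 2); sets the
#'   fold-change sampling error together with `residual_sd`.
#' @param residual_sd per-replicate log2 expression noise (> 0).
#' @param ortholog_coverage fraction of genes covered by the ortholog map,
#'   in (0, 1\].
#' @param one_to_many_fraction fraction of mapped genes given a second,
#'   ambiguous map entry, in \[0, 1).
#' @param refset_sensitivity,refset_precision reference-set tagging quality
#'   in (0, 1\] (see [simulate_reference_sets()]).
#' @param seed integer seed; the generator draws everything from one stream
#'   in documented order, so identical configs give identical output.
#' @return An object of class `generative_config`.
#' @export
generative_config <- function(n_genes = 2000L,
                              programs = list(
                                program_spec("program1", 100L, 2, 0, "up")),
                              program_membership_overlap = 0,
                              n_replicates_per_group = 4L,
                              residual_sd = 1,
                              ortholog_coverage = 0.9,
                              one_to_many_fraction = 0.05,
                              refset_sensitivity = 0.8,
                              refset_precision = 0.8,
                              seed = 1L) {
  stopifnot(n_genes >= 1L, is.list(programs),
            n_replicates_per_group >= 2L, residual_sd > 0)
  if (length(programs) > 0L) {
    stopifnot(all(vapply(programs, inherits, logical(1), "program_spec")))
    nm <- vapply(programs, `[[`, character(1), "name")
    if (anyDuplicated(nm)) stop("duplicate program names", call. = FALSE)
    if (sum(vapply(programs, `[[`, integer(1), "size")) > n_genes) {
      stop("program sizes exceed n_genes", call. = FALSE)
    }
  }
  stopifnot(program_membership_overlap >= 0, program_membership_overlap < 1,
            ortholog_coverage > 0, ortholog_coverage <= 1,
            one_to_many_fraction >= 0, one_to_many_fraction < 1,
            refset_sensitivity > 0, refset_sensitivity <= 1,
            refset_precision > 0, refset_precision <= 1)
  structure(list(n_genes = as.integer(n_genes), programs = programs,
                 program_membership_overlap = program_membership_overlap,
                 n_replicates_per_group = as.integer(n_replicates_per_group),
                 residual_sd = residual_sd,
                 ortholog_coverage = ortholog_coverage,
                 one_to_many_fraction = one_to_many_fraction,
                 refset_sensitivity = refset_sensitivity,
                 refset_precision = refset_precision,
                 seed = as.integer(seed)),
            class = "generative_config")
}

#' Fold-change sampling standard error implied by a config
#'
#' `tau = residual_sd * sqrt(2 / n_replicates_per_group)`: the standard
#' error of a two-group log2 fold change when each group averages
#' `n_replicates_per_group` replicates of per-replicate noise
#' `residual_sd`.
#'
#' @param config a [generative_config()].
#' @return Numeric scalar.
#' @export
fc_standard_error <- function(config) {
  config$residual_sd * sqrt(2 / config$n_replicates_per_group)
}

# Draw program memberships (gene indices) and per-program effects.
# RNG order: for each program in list order, membership indices, then its
# effect draw, then (mixed only) per-gene signs.
plant_programs <- function(config) {
  n <- config$n_genes
  assigned <- integer(0)
  membership <- list()
  delta <- numeric(0)
  signs <- list()
  for (pr in config$programs) {
    n_ov <- if (length(assigned) > 0L) {
      min(floor(config$program_membership_overlap * pr$size),
          length(assigned))
    } else 0L
    ov <- if (n_ov > 0L) sample(assigned, n_ov) else integer(0)
    fresh <- sample(setdiff(seq_len(n), assigned), pr$size - n_ov)
    members <- sort(c(ov, fresh))
    assigned <- union(assigned, members)
    d <- rnorm(1L, pr$effect, pr$effect_sd)
    d <- switch(pr$direction, up = abs(d), down = -abs(d), mixed = d)
    s <- if (pr$direction == "mixed") {
      sample(c(-1, 1), pr$size, replace = TRUE)
    } else {
      rep(1, pr$size)
    }
    membership[[pr$name]] <- members
    delta[pr$name] <- d
    signs[[pr$name]] <- s
  }
  list(membership = membership, delta = delta, signs = signs)
}

# True per-gene effect vector from a planting.
true_beta <- function(n_genes, planting) {
  beta <- numeric(n_genes)
  for (nm in names(planting$membership)) {
    beta[planting$membership[[nm]]] <-
      beta[planting$membership[[nm]]] +
      planting$delta[[nm]] * planting$signs[[nm]]
  }
  beta
}

# Program label per gene (";"-joined for overlapping memberships).
program_labels <- function(n_genes, planting) {
  lab <- rep(NA_character_, n_genes)
  for (nm in names(planting$membership)) {
    idx <- planting$membership[[nm]]
    lab[idx] <- ifelse(is.na(lab[idx]), nm, paste(lab[idx], nm, sep = ";"))
  }
  lab
}

# Observe one study: draw fold changes around beta, z-test p-values, BH FDR.
observe_study <- function(genes, beta, tau, label, species) {
  lfc <- rnorm(length(beta), beta, tau)
  p <- 2 * pnorm(abs(lfc) / tau, lower.tail = FALSE)
  de_table(genes, lfc, p, fdr = bh_adjust(p), label = label,
           species = species)
}

#' Simulate one differential-expression study with planted programs
#'
#' Generates per-gene true effects `beta_g` as the sum of program effects
#' over the gene's memberships, observed log2 fold changes
#' `~ Normal(beta_g, tau^2)` with `tau` from [fc_standard_error()],
#' two-sided z-test p-values, and Benjamini-Hochberg FDR. Deterministic
#' given the config's seed.
#'
#' @param config a [generative_config()].
#' @param label,species passed to [de_table()].
#' @return List with `table` (a [de_table()]) and `truth` (data frame
#'   `gene`, `program`, `beta`; non-members have `beta = 0` and `NA`
#'   program).
#' @export
simulate_de_study <- function(config, label = "synthetic_study",
                              species = "synthetic") {
  stopifnot(inherits(config, "generative_config"))
  with_seed(config$seed, {
    genes <- sprintf("gene%05d", seq_len(config$n_genes))
    planting <- plant_programs(config)
    beta <- true_beta(config$n_genes, planting)
    table <- observe_study(genes, beta, fc_standard_error(config), label,
                           species)
    list(table = table,
         truth = data.frame(gene = genes,
                            program = program_labels(config$n_genes, planting),
                            beta = beta, stringsAsFactors = FALSE))
  })
}

#' Simulate reference gene sets that imperfectly tag planted programs
#'
#' One set per program: each true member is included with probability
#' `sensitivity`, and the set is padded with non-members so that the
#' expected fraction of true members equals `precision`. A decoy set of
#' matched size, drawn uniformly from genes belonging to no program, is
#' added per program (named `decoy_<program>`) as a built-in null.
#'
#' @param truth a truth data frame (`gene`, `program`, `beta`) from the
#'   simulate functions.
#' @param sensitivity,precision in (0, 1\].
#' @param seed integer seed, or `NULL` to draw from the current RNG state
#'   (used internally to keep one stream per config).
#' @return A [gene_set_collection()].
#' @export
simulate_reference_sets <- function(truth, sensitivity, precision,
                                    seed = NULL) {
  stopifnot(is.data.frame(truth), nrow(truth) > 0L)
  if (sensitivity <= 0 || sensitivity > 1 || precision <= 0 || precision > 1) {
    stop("sensitivity and precision must lie in (0, 1]", call. = FALSE)
  }
  programs <- unique(unlist(strsplit(truth$program[!is.na(truth$program)],
                                     ";", fixed = TRUE)))
  if (length(programs) == 0L) {
    stop("truth contains no program members", call. = FALSE)
  }
  free_genes <- truth$gene[is.na(truth$program)]
  with_seed(seed, {
    sets <- list()
    desc <- character(0)
    for (nm in programs) {
      members <- truth$gene[!is.na(truth$program) &
                              vapply(strsplit(truth$program, ";", fixed = TRUE),
                                     function(x) nm %in% x, logical(1))]
      keep <- members[runif(length(members)) <= sensitivity]
      if (length(keep) == 0L) keep <- sample(members, 1L)
      n_pad <- round(length(keep) * (1 - precision) / precision)
      non_members <- setdiff(truth$gene, members)
      pad <- if (n_pad > 0L) sample(non_members, min(n_pad,
                                                     length(non_members)))
             else character(0)
      sets[[nm]] <- c(keep, pad)
      desc <- c(desc, sprintf("reference set tagging %s", nm))
      decoy_size <- length(sets[[nm]])
      sets[[paste0("decoy_", nm)]] <-
        sample(free_genes, min(decoy_size, length(free_genes)))
      desc <- c(desc, sprintf("size-matched decoy for %s", nm))
    }
    gene_set_collection(sets, descriptions = desc,
                        source_label = "synthetic_reference_sets")
  })
}

# Build the cross-species scaffolding shared by simulate_pair and
# simulate_comparison_bank: B symbols, coverage-limited map with optional
# one-to-many contamination. RNG order: mapped-gene choice, ambiguous-gene
# choice, extra-partner choice.
build_species_b <- function(config, a_genes) {
  n <- config$n_genes
  n_mapped <- floor(config$ortholog_coverage * n)
  mapped_idx <- sort(sample(seq_len(n), n_mapped))
  b_genes <- character(n)
  b_genes[mapped_idx] <- toupper(a_genes[mapped_idx])
  unmapped_idx <- setdiff(seq_len(n), mapped_idx)
  b_genes[unmapped_idx] <- paste0(toupper(a_genes[unmapped_idx]), "U1")
  pair_a <- a_genes[mapped_idx]
  pair_b <- b_genes[mapped_idx]
  m <- floor(config$one_to_many_fraction * n_mapped)
  if (m > 0L) {
    if (m > length(unmapped_idx)) {
      stop("one_to_many_fraction too large for the unmapped gene pool",
           call. = FALSE)
    }
    ambig <- sample(mapped_idx, m)
    extra_partner_idx <- sample(unmapped_idx, m)
    pair_a <- c(pair_a, a_genes[ambig])
    pair_b <- c(pair_b, b_genes[extra_partner_idx])
  }
  map <- ortholog_map(pair_a, pair_b, "synthetic", "synthetic")
  list(b_genes = b_genes, map = map, n_mapped = n_mapped,
       n_ambiguous = m)
}

#' Simulate a paired two-species study with shared programs
#'
#' Generates two studies over orthologous gene universes. Programs named in
#' `shared_programs` are planted identically in both species (same member
#' genes through the ortholog correspondence, same program effect,
#' independent measurement noise); the remaining programs are planted
#' independently in each species (independent members and effects), so they
#' contribute signal but no cross-species correlation. Species-B symbols
#' are the uppercased species-A symbols; genes missing from the ortholog
#' map get a distinguishing suffix so no implicit case-mapping can recover
#' them.
#'
#' RNG order (one stream from the config seed): species-A planting,
#' species-B scaffolding (map), species-B independent planting, species-A
#' noise, species-B noise, reference sets.
#'
#' @param config a [generative_config()].
#' @param shared_programs character vector of program names shared by both
#'   species; defaults to all configured programs. May be empty.
#' @return List of class `synthetic_study_pair`: `table_a`, `table_b`
#'   ([de_table()]s), `map` (an [ortholog_map()]), `reference_sets` (a
#'   [gene_set_collection()] over species-A symbols, with decoys), `truth`
#'   (list with `table_a`, `table_b` truth frames and `shared_programs`).
#' @export
simulate_pair <- function(config,
                          shared_programs = vapply(config$programs, `[[`,
                                                   character(1), "name")) {
  stopifnot(inherits(config, "generative_config"))
  all_names <- vapply(config$programs, `[[`, character(1), "name")
  if (!all(shared_programs %in% all_names)) {
    stop("unknown shared program(s): ",
         paste(setdiff(shared_programs, all_names), collapse = ", "),
         call. = FALSE)
  }
  with_seed(config$seed, {
    a_genes <- sprintf("gene%05d", seq_len(config$n_genes))
    planting_a <- plant_programs(config)
    scaffold <- build_species_b(config, a_genes)

    shared <- list(membership = planting_a$membership[shared_programs],
                   delta = planting_a$delta[shared_programs],
                   signs = planting_a$signs[shared_programs])
    indep_specs <- config$programs[!(all_names %in% shared_programs)]
    config_b <- config
    config_b$programs <- indep_specs
    planting_b_new <- plant_programs(config_b)
    planting_b <- list(
      membership = c(shared$membership, planting_b_new$membership),
      delta = c(shared$delta, planting_b_new$delta),
      signs = c(shared$signs, planting_b_new$signs))

    tau <- fc_standard_error(config)
    table_a <- observe_study(a_genes, true_beta(config$n_genes, planting_a),
                             tau, "synthetic_species_a", "synthetic")
    table_b <- observe_study(scaffold$b_genes,
                             true_beta(config$n_genes, planting_b),
                             tau, "synthetic_species_b", "synthetic")
    truth_a <- data.frame(gene = a_genes,
                          program = program_labels(config$n_genes, planting_a),
                          beta = true_beta(config$n_genes, planting_a),
                          stringsAsFactors = FALSE)
    truth_b <- data.frame(gene = scaffold$b_genes,
                          program = program_labels(config$n_genes, planting_b),
                          beta = true_beta(config$n_genes, planting_b),
                          stringsAsFactors = FALSE)
    reference_sets <- simulate_reference_sets(truth_a,
                                              config$refset_sensitivity,
                                              config$refset_precision,
                                              seed = NULL)
    structure(list(table_a = table_a, table_b = table_b,
                   map = scaffold$map, reference_sets = reference_sets,
                   truth = list(table_a = truth_a, table_b = truth_b,
                                shared_programs = shared_programs)),
              class = "synthetic_study_pair")
  })
}

#' Simulate a bank of comparisons against one reference study
#'
#' The synthetic analogue of ranking many per-patient disease fold-change
#' signatures against one knockout signature: one species-A reference study
#' plus `n_sharing` species-B comparisons that share the planted programs
#' (same members and effects, independent measurement noise) and `n_null`
#' comparisons whose programs are planted independently — signal-bearing
#' but uncorrelated with the reference.
#'
#' @param config a [generative_config()].
#' @param n_sharing,n_null numbers of program-sharing and independent
#'   comparisons.
#' @return List with `reference` (the species-A [de_table()]), `map`,
#'   `comparisons` (named list of species-B [de_table()]s), `sharing`
#'   (named logical), `truth` (species-A truth frame).
#' @export
simulate_comparison_bank <- function(config, n_sharing = 21L, n_null = 15L) {
  stopifnot(inherits(config, "generative_config"),
            n_sharing >= 0L, n_null >= 0L, n_sharing + n_null >= 1L)
  with_seed(config$seed, {
    a_genes <- sprintf("gene%05d", seq_len(config$n_genes))
    planting_a <- plant_programs(config)
    scaffold <- build_species_b(config, a_genes)
    tau <- fc_standard_error(config)
    reference <- observe_study(a_genes,
                               true_beta(config$n_genes, planting_a), tau,
                               "synthetic_reference", "synthetic")
    ids <- c(sprintf("share%02d", seq_len(n_sharing)),
             sprintf("indep%02d", seq_len(n_null)))
    sharing <- setNames(rep(c(TRUE, FALSE), c(n_sharing, n_null)), ids)
    comparisons <- setNames(vector("list", length(ids)), ids)
    for (id in ids) {
      planting <- if (sharing[[id]]) planting_a else plant_programs(config)
      comparisons[[id]] <- observe_study(
        scaffold$b_genes, true_beta(config$n_genes, planting), tau,
        paste0("synthetic_", id), "synthetic")
    }
    list(reference = reference, map = scaffold$map,
         comparisons = comparisons, sharing = sharing,
         truth = data.frame(gene = a_genes,
                            program = program_labels(config$n_genes,
                                                     planting_a),
                            beta = true_beta(config$n_genes, planting_a),
                            stringsAsFactors = FALSE))
  })
}

#' Write a synthetic study pair to disk through the standard formats
#'
#' Emits the two DE tables (TSV), the ortholog map (two-column TSV), the
#' reference sets (GMT) and the truth tables, so the file-based pipeline
#' can run end to end on generated data.
#'
#' @param pair a `synthetic_study_pair` from [simulate_pair()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_study_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "synthetic_study_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    de_a = file.path(dir, "de_table_a.tsv"),
    de_b = file.path(dir, "de_table_b.tsv"),
    map = file.path(dir, "ortholog_map.tsv"),
    sets = file.path(dir, "reference_sets.gmt"),
    truth_a = file.path(dir, "truth_a.tsv"),
    truth_b = file.path(dir, "truth_b.tsv"))
  write_results(as.data.frame(pair$table_a), paths[["de_a"]])
  write_results(as.data.frame(pair$table_b), paths[["de_b"]])
  writeLines(paste(pair$map$gene_a, pair$map$gene_b, sep = "\t"),
             paths[["map"]])
  write_gmt(pair$reference_sets, paths[["sets"]])
  write_results(pair$truth$table_a, paths[["truth_a"]])
  write_results(pair$truth$table_b, paths[["truth_b"]])
  invisible(paths)
}
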