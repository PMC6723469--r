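#' End-to-end concordance analysis of two annotation sources
#'
#' In-memory orchestration of the full method: per-species normalization of
#' both sources, homolog identification against the enzyme seed queries,
#' per-(enzyme, species) reciprocal-best-hit classification, the
#' redundant-unpaired exclusion, optional tree-based rescue of unpaired
#' genes, and the final summaries.
#'
#' @param records_a,records_b raw annotation sets for sources A and B (may
#'   span several species).
#' @param seeds named character vector of seed query CDS, one or more per
#'   enzyme; names must be enzyme labels from [FBP_ENZYMES] (optionally
#'   suffixed, e.g. `"CHS.1"`).
#' @param params [search_params()] used for mining and pairwise alignment.
#' @param trim [trim_params()] for alignment trimming before trees.
#' @param min_len minimum CDS length in nt.
#' @param rescue run the phylogenetic rescue stage.
#' @param keep_trees always build and return per-enzyme gene trees, even
#'   when no rescue is possible.
#' @param bootstraps,min_support,gamma_shape tree building and rescue
#'   options (see [build_tree()], [rescue_unpaired()]).
#' @param seed RNG seed for bootstrap resampling.
#' @return list with normalized sets (`norm_a`, `norm_b`), homolog
#'   assignments (`homologs_a`, `homologs_b`), `pair_records`, `report`
#'   (a [concordance_report()]), `copy_matrix` (a [copy_number_matrix()]),
#'   `lengths` (a [length_stats()] table), `final` (merged gene set) and
#'   `trees` (per-enzyme `ape::phylo`, when built).
#' @export
concordance_analysis <- function(records_a, records_b, seeds,
                                 params = search_params(),
                                 trim = trim_params(), min_len = 300L,
                                 rescue = TRUE, keep_trees = FALSE,
                                 bootstraps = 1000L, min_support = 0,
                                 gamma_shape = 1, seed = 1L) {
  norm_a <- normalize_by_species(records_a, min_len)
  norm_b <- normalize_by_species(records_b, min_len)
  specs <- seeds_to_specs(seeds)
  hom_a <- identify_homologs(specs, norm_a, params)
  hom_b <- identify_homologs(specs, norm_b, params)
  genes_a <- merge(hom_a$assignments,
                   norm_a[, c("gene_id", "species")], by = "gene_id")
  genes_b <- merge(hom_b$assignments,
                   norm_b[, c("gene_id", "species")], by = "gene_id")

  species <- sort(unique(c(genes_a$species, genes_b$species)))
  rec_list <- list()
  for (e in FBP_ENZYMES) {
    for (sp in species) {
      sub_a <- norm_a[norm_a$gene_id %in%
                        genes_a$gene_id[genes_a$enzyme == e &
                                          genes_a$species == sp], ,
                      drop = FALSE]
      sub_b <- norm_b[norm_b$gene_id %in%
                        genes_b$gene_id[genes_b$enzyme == e &
                                          genes_b$species == sp], ,
                      drop = FALSE]
      if (nrow(sub_a) == 0 && nrow(sub_b) == 0) next
      rbh <- reciprocal_best_hits(sub_a, sub_b, params)
      rec_list[[length(rec_list) + 1]] <-
        classify_pairs(rbh, sub_a, sub_b, enzyme = e, species = sp)
    }
  }
  records <- if (length(rec_list) == 0)
    classify_pairs(data.frame(a = character(), b = character(),
                              identity = numeric(), score = numeric()),
                   norm_a[0, ], norm_b[0, ])
  else do.call(rbind, rec_list)
  records <- exclude_redundant_unpaired(records, norm_a, norm_b)

  trees <- list()
  if (rescue || keep_trees) {
    for (e in unique(records$enzyme)) {
      re <- records[records$enzyme == e, , drop = FALSE]
      want_rescue <- rescue && any(re$category == "UNPAIRED_A") &&
        any(re$category == "UNPAIRED_B")
      if (!want_rescue && !keep_trees) next
      leaf <- enzyme_leaves(re, norm_a, norm_b)
      if (nrow(leaf) < 3) next
      aln <- align_family(setNames(leaf$sequence, leaf$label), params)
      aln <- tryCatch(trim_codon_blocks(aln, trim), error = function(err) {
        warning(sprintf("enzyme %s: %s; using the untrimmed alignment",
                        e, conditionMessage(err)), call. = FALSE)
        aln
      })
      kept <- drop_all_gap_rows(aln, e)
      aln <- kept$aln
      leaf <- leaf[leaf$label %in% names(aln$rows), , drop = FALSE]
      if (length(aln$rows) < 3) next
      tree <- build_tree(aln, bootstraps = bootstraps, seed = seed,
                         gamma_shape = gamma_shape, leaf_meta = leaf)
      trees[[e]] <- tree
      if (want_rescue)
        records <- rescue_unpaired(tree, records, leaf_meta = leaf,
                                   set_a = norm_a, set_b = norm_b,
                                   min_support = min_support,
                                   params = params)
    }
  }

  final <- merge_final(records)
  list(norm_a = norm_a, norm_b = norm_b,
       homologs_a = genes_a, homologs_b = genes_b,
       pair_records = records,
       report = concordance_report(records),
       copy_matrix = copy_number_matrix(genes_a, genes_b, species = species),
       lengths = length_stats(records, norm_a, norm_b),
       final = final, trees = trees)
}

normalize_by_species <- function(records, min_len = 300L) {
  validate_annotation_set(records)
  if (nrow(records) == 0) return(records)
  parts <- split(records, records$species)
  out <- do.call(rbind, lapply(parts, normalize_annotations,
                               min_len = min_len))
  rownames(out) <- NULL
  out
}

seeds_to_specs <- function(seeds) {
  enz <- sub("\\..*$", "", names(seeds))
  bad <- setdiff(unique(enz), FBP_ENZYMES)
  if (length(bad) > 0)
    stop("seed names must be enzyme labels; unknown: ",
         paste(bad, collapse = ", "), call. = FALSE)
  lapply(intersect(FBP_ENZYMES, enz), function(e)
    enzyme_spec(e, seeds[enz == e]))
}

# Rows that end up fully gapped after trimming carry no signal for the
# tree; they are set aside with a warning (their pair records are left
# untouched).
drop_all_gap_rows <- function(aln, enzyme) {
  gapped <- grepl("^-+$", aln$rows)
  if (any(gapped)) {
    warning(sprintf("enzyme %s: %d sequence(s) fully gapped after trimming; excluded from the tree",
                    enzyme, sum(gapped)), call. = FALSE)
    aln$rows <- aln$rows[!gapped]
  }
  list(aln = aln, dropped = names(gapped)[gapped])
}

# Leaves for one enzyme's gene tree: every non-excluded member from both
# sources, labelled "<source>|<gene_id>".
enzyme_leaves <- function(records, norm_a, norm_b) {
  keep <- records$category != "EXCLUDED_REDUNDANT"
  ga <- records$member_a[keep & !is.na(records$member_a)]
  gb <- records$member_b[keep & !is.na(records$member_b)]
  rows <- rbind(
    data.frame(label = paste0("A|", ga), gene_id = ga, source = "A",
               species = norm_a$species[match(ga, norm_a$gene_id)],
               sequence = norm_a$sequence[match(ga, norm_a$gene_id)],
               stringsAsFactors = FALSE),
    data.frame(label = paste0("B|", gb), gene_id = gb, source = "B",
               species = norm_b$species[match(gb, norm_b$gene_id)],
               sequence = norm_b$sequence[match(gb, norm_b$gene_id)],
               stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}

#' Compare pipeline categories with the simulator's truth table
#'
#' For every true gene present in at least one source, checks that the pair
#' records reproduce the implied category (with the correct partner for
#' paired categories); injected duplicates are checked to be
#' EXCLUDED_REDUNDANT.
#'
#' @param result output of [concordance_analysis()].
#' @param sim output of [simulate_annotation_pair()].
#' @return list with `n`, `recovered`, `fraction`, a per-implied-category
#'   `table`, and `duplicates_excluded` (fraction of injected duplicates
#'   recovered as EXCLUDED_REDUNDANT).
#' @export
compare_to_truth <- function(result, sim) {
  truth <- sim$truth
  rec <- result$pair_records
  truth <- truth[truth$implied_category != "MISSING", , drop = FALSE]
  ok <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    expect <- truth$implied_category[i]
    ida <- truth$gene_id_a[i]; idb <- truth$gene_id_b[i]
    ok[i] <- switch(
      expect,
      PERFECT = ,
      IMPERFECT = any(!is.na(rec$member_a) & rec$member_a == ida &
                        !is.na(rec$member_b) & rec$member_b == idb &
                        rec$category == expect),
      UNPAIRED_A = any(!is.na(rec$member_a) & rec$member_a == ida &
                         rec$category == "UNPAIRED_A"),
      UNPAIRED_B = any(!is.na(rec$member_b) & rec$member_b == idb &
                         rec$category == "UNPAIRED_B"),
      EXCLUDED_REDUNDANT = {
        id <- if (!is.na(ida)) ida else idb
        col <- if (!is.na(ida)) rec$member_a else rec$member_b
        any(!is.na(col) & col == id & rec$category == "EXCLUDED_REDUNDANT")
      },
      FALSE)
  }
  dup_ok <- NA_real_
  if (nrow(sim$duplicates) > 0) {
    d_ok <- vapply(seq_len(nrow(sim$duplicates)), function(i) {
      id <- sim$duplicates$gene_id[i]
      col <- if (sim$duplicates$source[i] == "A") rec$member_a else rec$member_b
      any(!is.na(col) & col == id & rec$category == "EXCLUDED_REDUNDANT")
    }, logical(1))
    dup_ok <- mean(d_ok)
  }
  list(n = nrow(truth), recovered = sum(ok), fraction = mean(ok),
       table = table(truth$implied_category, ok),
       duplicates_excluded = dup_ok)
}
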