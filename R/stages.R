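#' Pipeline configuration
#'
#' One structured configuration driving the staged, on-disk pipeline run by
#' [run_stage()].  Real annotation inputs may be supplied through `inputs`
#' (per-source FASTA/feature-table paths and a seed-query FASTA); when they
#' are absent the `simulate` stage provides them.
#'
#' @param outdir output directory; each stage writes into a subdirectory
#'   and records a manifest (inputs, parameters, seed, checksums).
#' @param seed integer seed recorded in all outputs and used for every
#'   source of randomness.
#' @param simulation a [simulation_config()]; its seed is derived from
#'   `seed` unless supplied explicitly.
#' @param params a [search_params()].
#' @param trim a [trim_params()].
#' @param bootstraps bootstrap replicates for gene trees.
#' @param min_support minimum cherry support for rescue (0 disables).
#' @param min_len minimum CDS length (nt).
#' @param inputs optional list with elements `source_a`, `source_b` (each a
#'   list with `fasta`, optional `feature_table`, `species`) and `seeds`
#'   (FASTA of enzyme seed queries named by enzyme label).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            simulation = NULL,
                            params = search_params(),
                            trim = trim_params(),
                            bootstraps = 1000L, min_support = 0,
                            min_len = 300L, inputs = NULL) {
  if (is.null(simulation)) simulation <- simulation_config(seed = seed)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulation = simulation, params = params, trim = trim,
                 bootstraps = as.integer(bootstraps),
                 min_support = min_support, min_len = as.integer(min_len),
                 inputs = inputs),
            class = "pipeline_config")
}

stage_dir <- function(config, stage) {
  d <- file.path(config$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_manifest <- function(config, stage, files, extra = character()) {
  d <- file.path(config$outdir, stage)
  sums <- tools::md5sum(files)
  lines <- c(sprintf("stage\t%s", stage),
             sprintf("seed\t%d", config$seed),
             extra,
             sprintf("file\t%s\t%s", basename(files), unname(sums)))
  writeLines(lines, file.path(d, "manifest.tsv"))
}

require_artifact <- function(config, path, producing_stage) {
  if (!file.exists(path))
    stop(sprintf("missing artifact '%s'; run stage '%s' first",
                 path, producing_stage), call. = FALSE)
  path
}

read_annotation_tsv <- function(fasta, records_tsv, source) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- read.table(records_tsv, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  m <- match(ids, meta$gene_id)
  annotation_set(gene_id = ids, locus_id = meta$locus_id[m],
                 transcript_id = meta$transcript_id[m],
                 species = meta$species[m], source = source,
                 sequence = as.character(seqs),
                 is_cds = if ("is_cds" %in% names(meta)) meta$is_cds[m] else TRUE)
}

load_sources <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    rec <- function(x, src) {
      parse_annotation_set(x$fasta, species = x$species, source = src,
                           feature_path = x$feature_table,
                           is_cds = isTRUE(x$is_cds))
    }
    seeds <- Biostrings::readDNAStringSet(inp$seeds)
    list(source_a = rec(inp$source_a, "A"), source_b = rec(inp$source_b, "B"),
         seeds = setNames(as.character(seeds), sub("\\s.*$", "", names(seeds))))
  } else {
    d <- file.path(config$outdir, "simulate")
    require_artifact(config, file.path(d, "source_a.fasta"), "simulate")
    list(source_a = read_annotation_tsv(file.path(d, "source_a.fasta"),
                                        file.path(d, "source_a.records.tsv"), "A"),
         source_b = read_annotation_tsv(file.path(d, "source_b.fasta"),
                                        file.path(d, "source_b.records.tsv"), "B"),
         seeds = {
           s <- Biostrings::readDNAStringSet(file.path(d, "seed_queries.fasta"))
           setNames(as.character(s), sub("\\s.*$", "", names(s)))
         })
  }
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Subcommand-style orchestration.  Stages: `simulate` (write a simulated
#' annotation pair), `normalize` (CDS inference, length filter, variant
#' dedup), `mine` (homolog identification), `classify` (RBH classification
#' and redundancy exclusion), `tree` (per-enzyme alignments and bootstrap
#' trees), `rescue` (reclassify cross-source unpaired cherries), `report`
#' (concordance, copy-number, length summaries), and `all` (chain in that
#' order; `simulate` is included only when no external inputs are
#' configured).  Every stage writes its artifacts plus a `manifest.tsv`
#' with parameters, seed and file checksums; a stage whose upstream
#' artifacts are missing fails with an error naming the stage to run
#' first.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return invisibly, the stage's primary in-memory product.
#' @export
run_stage <- function(name = c("all", "simulate", "normalize", "mine",
                               "classify", "tree", "rescue", "report"),
                      config) {
  name <- match.arg(name)
  switch(name,
         simulate = stage_simulate(config),
         normalize = stage_normalize(config),
         mine = stage_mine(config),
         classify = stage_classify(config),
         tree = stage_tree(config),
         rescue = stage_rescue(config),
         report = stage_report(config),
         all = {
           if (is.null(config$inputs)) stage_simulate(config)
           stage_normalize(config)
           stage_mine(config)
           stage_classify(config)
           stage_tree(config)
           stage_rescue(config)
           stage_report(config)
         })
}

stage_simulate <- function(config) {
  d <- stage_dir(config, "simulate")
  sim <- simulate_annotation_pair(config$simulation)
  write_simulation(sim, d)
  write_manifest(config, "simulate",
                 list.files(d, full.names = TRUE, pattern = "\\.(fasta|tsv|txt)$"),
                 sprintf("sim_seed\t%d", config$simulation$seed))
  invisible(sim)
}

stage_normalize <- function(config) {
  d <- stage_dir(config, "normalize")
  src <- load_sources(config)
  out <- list()
  for (s in c("a", "b")) {
    norm <- normalize_by_species(src[[paste0("source_", s)]], config$min_len)
    write_annotation_fasta(norm, file.path(d, sprintf("normalized_%s.fasta", s)))
    man <- record_manifest(norm)
    man$locus_id <- norm$locus_id
    man$transcript_id <- norm$transcript_id
    write.table(man, file.path(d, sprintf("normalized_%s.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out[[s]] <- norm
  }
  write_manifest(config, "normalize",
                 list.files(d, full.names = TRUE, pattern = "\\.(fasta|tsv)$"),
                 sprintf("min_len\t%d", config$min_len))
  invisible(out)
}

load_normalized <- function(config, s) {
  d <- file.path(config$outdir, "normalize")
  fasta <- require_artifact(config, file.path(d, sprintf("normalized_%s.fasta", s)),
                            "normalize")
  meta <- read.table(file.path(d, sprintf("normalized_%s.tsv", s)),
                     header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  m <- match(ids, meta$gene_id)
  annotation_set(gene_id = ids, locus_id = meta$locus_id[m],
                 transcript_id = meta$transcript_id[m],
                 species = meta$species[m], source = toupper(s),
                 sequence = as.character(seqs), is_cds = TRUE)
}

stage_mine <- function(config) {
  d <- stage_dir(config, "mine")
  src <- load_sources(config)
  specs <- seeds_to_specs(src$seeds)
  out <- list()
  for (s in c("a", "b")) {
    norm <- load_normalized(config, s)
    hom <- identify_homologs(specs, norm, config$params)
    asg <- merge(hom$assignments, norm[, c("gene_id", "species")],
                 by = "gene_id")
    write.table(asg, file.path(d, sprintf("assignments_%s.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(hom$cyp75, file.path(d, sprintf("cyp75_%s.txt", s)))
    out[[s]] <- asg
  }
  write_manifest(config, "mine",
                 list.files(d, full.names = TRUE, pattern = "\\.(tsv|txt)$"),
                 sprintf("evalue_max\t%g", config$params$evalue_max))
  invisible(out)
}

load_assignments <- function(config, s) {
  p <- require_artifact(config,
                        file.path(config$outdir, "mine",
                                  sprintf("assignments_%s.tsv", s)), "mine")
  read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

stage_classify <- function(config) {
  d <- stage_dir(config, "classify")
  norm_a <- load_normalized(config, "a")
  norm_b <- load_normalized(config, "b")
  asg_a <- load_assignments(config, "a")
  asg_b <- load_assignments(config, "b")
  species <- sort(unique(c(asg_a$species, asg_b$species)))
  rec_list <- list()
  for (e in FBP_ENZYMES) {
    for (sp in species) {
      sub_a <- norm_a[norm_a$gene_id %in%
                        asg_a$gene_id[asg_a$enzyme == e & asg_a$species == sp], ,
                      drop = FALSE]
      sub_b <- norm_b[norm_b$gene_id %in%
                        asg_b$gene_id[asg_b$enzyme == e & asg_b$species == sp], ,
                      drop = FALSE]
      if (nrow(sub_a) == 0 && nrow(sub_b) == 0) next
      rbh <- reciprocal_best_hits(sub_a, sub_b, config$params)
      rec_list[[length(rec_list) + 1]] <-
        classify_pairs(rbh, sub_a, sub_b, enzyme = e, species = sp)
    }
  }
  records <- do.call(rbind, rec_list)
  records <- exclude_redundant_unpaired(records, norm_a, norm_b)
  write_pair_table(records, file.path(d, "pairs.tsv"))
  write_manifest(config, "classify", file.path(d, "pairs.tsv"))
  invisible(records)
}

load_pairs <- function(config, rescued = FALSE) {
  p <- if (rescued) file.path(config$outdir, "rescue", "pairs_rescued.tsv")
  else file.path(config$outdir, "classify", "pairs.tsv")
  require_artifact(config, p, if (rescued) "rescue" else "classify")
  rec <- read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "")
  rec$rescued_by_tree <- as.logical(rec$rescued_by_tree)
  rec
}

stage_tree <- function(config) {
  d <- stage_dir(config, "tree")
  records <- load_pairs(config)
  norm_a <- load_normalized(config, "a")
  norm_b <- load_normalized(config, "b")
  trees <- list()
  for (e in unique(records$enzyme)) {
    re <- records[records$enzyme == e, , drop = FALSE]
    leaf <- enzyme_leaves(re, norm_a, norm_b)
    if (nrow(leaf) < 3) next
    aln <- align_family(setNames(leaf$sequence, leaf$label), config$params)
    trimmed <- tryCatch(trim_codon_blocks(aln, config$trim),
                        error = function(err) {
                          warning(sprintf("enzyme %s: %s; using untrimmed alignment",
                                          e, conditionMessage(err)),
                                  call. = FALSE)
                          aln
                        })
    trimmed <- drop_all_gap_rows(trimmed, e)$aln
    leaf <- leaf[leaf$label %in% names(trimmed$rows), , drop = FALSE]
    if (length(trimmed$rows) < 3) next
    write_msa_fasta(trimmed, file.path(d, sprintf("aln_%s.fasta", e)))
    tree <- build_tree(trimmed, bootstraps = config$bootstraps,
                       seed = config$seed, leaf_meta = leaf)
    ape::write.tree(tree, file.path(d, sprintf("tree_%s.nwk", e)))
    write.table(leaf[, c("label", "gene_id", "source", "species")],
                file.path(d, sprintf("leafmeta_%s.tsv", e)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    trees[[e]] <- tree
  }
  write_manifest(config, "tree",
                 list.files(d, full.names = TRUE, pattern = "\\.(nwk|tsv|fasta)$"),
                 sprintf("bootstraps\t%d", config$bootstraps))
  invisible(trees)
}

stage_rescue <- function(config) {
  d <- stage_dir(config, "rescue")
  records <- load_pairs(config)
  norm_a <- load_normalized(config, "a")
  norm_b <- load_normalized(config, "b")
  tdir <- file.path(config$outdir, "tree")
  require_artifact(config, file.path(tdir, "manifest.tsv"), "tree")
  for (e in unique(records$enzyme)) {
    tf <- file.path(tdir, sprintf("tree_%s.nwk", e))
    mf <- file.path(tdir, sprintf("leafmeta_%s.tsv", e))
    if (!file.exists(tf)) next
    tree <- ape::read.tree(tf)
    leaf <- read.table(mf, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    records <- rescue_unpaired(tree, records, leaf_meta = leaf,
                               set_a = norm_a, set_b = norm_b,
                               min_support = config$min_support,
                               params = config$params)
  }
  write_pair_table(records, file.path(d, "pairs_rescued.tsv"))
  write_manifest(config, "rescue", file.path(d, "pairs_rescued.tsv"),
                 sprintf("min_support\t%g", config$min_support))
  invisible(records)
}

stage_report <- function(config) {
  d <- stage_dir(config, "report")
  records <- load_pairs(config, rescued = TRUE)
  norm_a <- load_normalized(config, "a")
  norm_b <- load_normalized(config, "b")
  asg_a <- load_assignments(config, "a")
  asg_b <- load_assignments(config, "b")
  report <- concordance_report(records)
  write_concordance_report(report, file.path(d, "concordance.tsv"))
  cnm <- copy_number_matrix(asg_a, asg_b,
                            species = sort(unique(c(asg_a$species,
                                                    asg_b$species))))
  write_copy_number_matrix(cnm, file.path(d, "copy_number.tsv"))
  ls_ <- length_stats(records, norm_a, norm_b)
  write.table(ls_, file.path(d, "length_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  final <- merge_final(records)
  write.table(final, file.path(d, "final_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(config, "report",
                 list.files(d, full.names = TRUE, pattern = "\\.tsv$"))
  invisible(list(report = report, copy_matrix = cnm, lengths = ls_,
                 final = final, records = records))
}
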