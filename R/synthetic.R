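#' Default species tree for simulations
#'
#' A synthetic 21-taxon eudicot-like topology: eight Solanaceae, one
#' Convolvulaceae, three Lamiales, one Gentianales, four campanulids and
#' four rosid outgroups, with branch lengths in expected substitutions per
#' site (root-to-tip depth about 0.3).
#'
#' @return an `ape::phylo`.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((((((Slyc:0.02,Stub:0.02):0.02,Smel:0.04):0.02,Cann:0.06):0.02,",
    "((Ntab:0.01,Nsyl:0.01):0.005,Ntom:0.015):0.065):0.02,Phyb:0.1):0.05,",
    "Inil:0.15):0.03,(((Mgut:0.1,Sind:0.1):0.03,Oeur:0.13):0.04,",
    "Ccan:0.17):0.01):0.04,((Dcar:0.12,(Hann:0.08,Lsat:0.08):0.04):0.04,",
    "Ccar:0.16):0.06):0.08,((Atha:0.18,Gmax:0.18):0.04,",
    "(Vvin:0.2,Ptri:0.2):0.02):0.08);"))
}

#' Configuration for the annotation-pair simulator
#'
#' Defaults define the study conditions: seven gene families (one per
#' enzyme), a birth-death gene family process along the species tree, K80
#' (HKY with equal base frequencies) sequence evolution, and two
#' independently corrupted annotation sources reproducing the discrepancy
#' modes the concordance analysis must detect: missed genes, coding-boundary
#' (UTR) discrepancies, redundant transcript variants, and identical
#' within-source duplicates.
#'
#' @param species_tree species tree (`ape::phylo`) with branch lengths in
#'   substitutions/site.
#' @param family_names family labels; also the enzyme labels used by the
#'   seed queries.
#' @param dup_rate,loss_rate birth-death rates per branch-length unit.
#' @param root_length root CDS length in nt (codon multiple, incl. start
#'   and stop codons).
#' @param model substitution model, `"JC"` or `"HKY"`.
#' @param kappa transition/transversion rate ratio for HKY.
#' @param miss_prob per-source probability that a true gene is absent.
#' @param utr_extend_prob probability that an emitted transcript carries
#'   UTR flanks.
#' @param boundary_shift_prob probability, given a UTR extension, that the
#'   5' flank carries an in-frame upstream start codon so the inferred CDS
#'   boundary genuinely shifts.
#' @param truncation_prob probability of an in-frame 3' truncation of the
#'   annotated CDS.
#' @param variant_count_probs distribution of transcript variants per locus
#'   (1..length(variant_count_probs) variants).
#' @param identical_duplicate_prob probability of injecting an identical
#'   within-source duplicate at a new locus.
#' @param max_expected_family_size guard against runaway birth rates.
#' @param seed integer RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(species_tree = default_species_tree(),
                              family_names = FBP_ENZYMES,
                              dup_rate = 2, loss_rate = 0.5,
                              root_length = 900L,
                              model = c("HKY", "JC"), kappa = 2,
                              miss_prob = 0.1,
                              utr_extend_prob = 0.3,
                              boundary_shift_prob = 0.3,
                              truncation_prob = 0.05,
                              variant_count_probs = c(0.6, 0.25, 0.1, 0.05),
                              identical_duplicate_prob = 0.05,
                              max_expected_family_size = 50,
                              seed = 1L) {
  model <- match.arg(model)
  stopifnot(dup_rate >= 0, loss_rate >= 0, root_length %% 3L == 0L,
            miss_prob >= 0, miss_prob <= 1,
            utr_extend_prob >= 0, utr_extend_prob + truncation_prob <= 1,
            identical_duplicate_prob >= 0, identical_duplicate_prob <= 1)
  structure(list(species_tree = species_tree, family_names = family_names,
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 root_length = as.integer(root_length), model = model,
                 kappa = if (model == "JC") 1 else kappa,
                 miss_prob = miss_prob, utr_extend_prob = utr_extend_prob,
                 boundary_shift_prob = boundary_shift_prob,
                 truncation_prob = truncation_prob,
                 variant_count_probs = variant_count_probs,
                 identical_duplicate_prob = identical_duplicate_prob,
                 max_expected_family_size = max_expected_family_size,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

NON_STOP_CODONS <- local({
  all_codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  c("T", "C", "A", "G")), 1, paste, collapse = "")
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
})

#' Draw a random coding sequence
#'
#' ATG start, uniform non-stop internal codons, one terminal stop codon.
#' Uses the current RNG state.
#'
#' @param n_codons total codon count (>= 3).
#' @return a CDS string.
#' @export
random_root_cds <- function(n_codons) {
  stopifnot(n_codons >= 3)
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Simulate one gene family along the species tree
#'
#' A single ancestral gene lineage enters the root; along every branch it
#' undergoes a linear birth-death process (duplications split the lineage,
#' losses terminate it) with the configured rates, and every lineage
#' surviving at a species-tree tip is one true gene.  Uses the current RNG
#' state; [simulate_annotation_pair()] seeds it once from the config.
#'
#' @param config a [simulation_config()].
#' @param family family label used in gene keys.
#' @return list with `genes` (data frame `gene_key`, `species`), `tree`
#'   (gene tree as `ape::phylo`, `NULL` if fewer than 2 surviving genes)
#'   and `tip_depth` (named root-to-tip path lengths, used to evolve
#'   sequences when no tree object exists).
#' @export
simulate_family <- function(config, family = "FAM") {
  sp <- config$species_tree
  lambda <- config$dup_rate; mu <- config$loss_rate
  depths <- ape::node.depth.edgelength(sp)
  tmax <- max(depths[seq_along(sp$tip.label)])
  if (exp((lambda - mu) * tmax) > config$max_expected_family_size)
    stop("expected family size exceeds the configured cap; lower dup_rate",
         call. = FALSE)
  ntip <- length(sp$tip.label)
  kids <- split(seq_len(nrow(sp$edge)), sp$edge[, 1])
  counter <- new.env()
  counter$i <- 0L
  tips <- list()

  at_node <- function(node) {
    # a lineage arriving exactly at a species-tree node
    if (node <= ntip) {
      counter$i <- counter$i + 1L
      key <- sprintf("%s_%s_t%03d", family, sp$tip.label[node], counter$i)
      tips[[length(tips) + 1L]] <<- data.frame(gene_key = key,
                                               species = sp$tip.label[node],
                                               stringsAsFactors = FALSE)
      return(list(str = key, len = 0))
    }
    parts <- list()
    for (e in kids[[as.character(node)]]) {
      r <- on_branch(sp$edge.length[e], sp$edge[e, 2])
      if (!is.null(r)) parts[[length(parts) + 1L]] <- r
    }
    if (length(parts) == 0) return(NULL)
    if (length(parts) == 1) return(parts[[1]])
    list(str = paste0("(", paste(vapply(parts, function(p)
      paste0(p$str, ":", format(p$len, digits = 12)), ""), collapse = ","),
      ")"), len = 0)
  }

  on_branch <- function(t, node) {
    # one lineage travelling down a branch of remaining length t
    tau <- rexp(1, lambda + mu)
    if (!is.finite(tau) || tau >= t) {
      r <- at_node(node)
      if (is.null(r)) return(NULL)
      r$len <- r$len + t
      return(r)
    }
    if (runif(1) < mu / (lambda + mu)) return(NULL)  # loss
    left <- on_branch(t - tau, node)
    right <- on_branch(t - tau, node)
    if (is.null(left) && is.null(right)) return(NULL)
    if (is.null(left)) { right$len <- right$len + tau; return(right) }
    if (is.null(right)) { left$len <- left$len + tau; return(left) }
    list(str = paste0("(", left$str, ":", format(left$len, digits = 12), ",",
                      right$str, ":", format(right$len, digits = 12), ")"),
         len = tau)
  }

  if (lambda + mu == 0) {
    # no events: one gene per species, gene tree equals the species tree
    genes <- data.frame(gene_key = sprintf("%s_%s_t%03d", family,
                                           sp$tip.label, seq_len(ntip)),
                        species = sp$tip.label, stringsAsFactors = FALSE)
    tree <- sp
    tree$tip.label <- genes$gene_key
    depth <- setNames(depths[seq_len(ntip)], genes$gene_key)
    return(list(genes = genes, tree = tree, tip_depth = depth))
  }

  root <- at_node(ntip + 1L)
  genes <- if (length(tips) == 0)
    data.frame(gene_key = character(), species = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, tips)
  tree <- NULL
  tip_depth <- NULL
  if (nrow(genes) >= 2) {
    tree <- ape::read.tree(text = paste0(root$str, ";"))
    # root pending length is ancestral stem; irrelevant for tip sequences
  } else if (nrow(genes) == 1) {
    tip_depth <- setNames(root$len, genes$gene_key)
  }
  list(genes = genes, tree = tree, tip_depth = tip_depth)
}

# K80 / JC transition probabilities for one branch
k80_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  e4 <- exp(-4 * beta * t)
  e2 <- exp(-2 * beta * (kappa + 1) * t)
  p_ts <- 0.25 + 0.25 * e4 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e4
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")
TV_PARTNER1 <- c(A = "C", C = "A", G = "C", T = "A")
TV_PARTNER2 <- c(A = "T", C = "G", G = "T", T = "G")

evolve_branch <- function(seq, t, kappa, preserve_cds = TRUE) {
  if (t <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  p <- k80_probs(t, kappa)
  mutate_sites <- function(b) {
    u <- runif(length(b))
    out <- b
    out[u >= p["same"] & u < p["same"] + p["ts"]] <-
      TS_PARTNER[b[u >= p["same"] & u < p["same"] + p["ts"]]]
    i1 <- u >= p["same"] + p["ts"] & u < p["same"] + p["ts"] + p["tv"]
    out[i1] <- TV_PARTNER1[b[i1]]
    i2 <- u >= p["same"] + p["ts"] + p["tv"]
    out[i2] <- TV_PARTNER2[b[i2]]
    out
  }
  new <- mutate_sites(bases)
  if (preserve_cds) {
    n <- length(bases)
    ncod <- n %/% 3L
    new[1:3] <- bases[1:3]                      # fixed start codon
    new[(n - 2):n] <- bases[(n - 2):n]          # fixed terminal stop
    # resample internal codons that mutated into stops
    for (iter in 1:50) {
      starts <- seq(4L, by = 3L, length.out = ncod - 2L)
      cod <- paste0(new[starts], new[starts + 1L], new[starts + 2L])
      bad <- which(cod %in% STOP_CODONS)
      if (length(bad) == 0) break
      for (bidx in bad) {
        sites <- starts[bidx] + 0:2
        new[sites] <- mutate_sites(bases[sites])
      }
      if (iter == 50) {
        for (bidx in bad) {
          sites <- starts[bidx] + 0:2
          new[sites] <- bases[sites]  # fall back to the parent codon
        }
      }
    }
  }
  paste(new, collapse = "")
}

#' Evolve sequences along a simulated gene tree
#'
#' Applies K80/JC substitutions along every branch, treating codon positions
#' independently.  With `preserve_cds = TRUE` (the default) the start codon
#' and terminal stop are held fixed and internal codons that mutate into
#' stops are resampled, so every emitted sequence remains a well-formed CDS
#' whose longest open reading frame is itself.
#'
#' @param family_sim result of [simulate_family()].
#' @param root_cds ancestral coding sequence (e.g. [random_root_cds()]).
#' @param config a [simulation_config()].
#' @param preserve_cds keep CDS structure intact (see above).
#' @return named character vector of tip sequences (one per gene).
#' @export
evolve_sequences <- function(family_sim, root_cds, config,
                             preserve_cds = TRUE) {
  genes <- family_sim$genes
  if (nrow(genes) == 0) return(setNames(character(), character()))
  kappa <- config$kappa
  if (nrow(genes) == 1) {
    return(setNames(evolve_branch(root_cds, unname(family_sim$tip_depth),
                                  kappa, preserve_cds), genes$gene_key))
  }
  tree <- family_sim$tree
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- character(ntip + nnode)
  seqs[ntip + 1L] <- root_cds
  # edges in preorder: parents before children
  ord <- order(tree$edge[, 1])
  for (e in ord) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    seqs[child] <- evolve_branch(seqs[par], tree$edge.length[e], kappa,
                                 preserve_cds)
  }
  setNames(seqs[seq_len(ntip)], tree$tip.label)
}

# Random UTR-like flank guaranteed to contain no ATG substring.
random_flank <- function(n) {
  if (n <= 0) return("")
  repeat {
    s <- paste(sample(DNA_LETTERS, n, replace = TRUE), collapse = "")
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

#' Corrupt true genes into two annotation sources with ground truth
#'
#' Per source and gene, independently: the gene is dropped with
#' `miss_prob`; its transcript is UTR-extended with `utr_extend_prob`
#' (flanks carry an in-frame upstream ATG - a genuine coding-boundary shift
#' that survives CDS re-inference - with `boundary_shift_prob`, and are
#' otherwise built ATG-free so the longest-ORF rule recovers the true CDS);
#' or the annotation is truncated in frame with `truncation_prob`.  Loci are
#' expanded into redundant transcript variants and identical within-source
#' duplicate loci are injected with `identical_duplicate_prob`.  The truth
#' table records every event and the concordance category it implies.
#'
#' @param genes data frame with `gene_key`, `species`, `family`,
#'   `true_cds`.
#' @param config a [simulation_config()].
#' @return list with annotation sets `source_a`, `source_b` (all records
#'   flagged `is_cds = FALSE`), `truth` (per-gene table with per-source
#'   presence, representative gene ids, expected post-inference CDS and
#'   `implied_category`), and `duplicates` (injected duplicate records,
#'   implied EXCLUDED_REDUNDANT).
#' @export
corrupt_annotations <- function(genes, config) {
  sources <- c("A", "B")
  rec_rows <- list(A = list(), B = list())
  truth <- genes
  truth$present_a <- FALSE; truth$present_b <- FALSE
  truth$gene_id_a <- NA_character_; truth$gene_id_b <- NA_character_
  truth$cds_a <- NA_character_; truth$cds_b <- NA_character_
  truth$modified_a <- FALSE; truth$modified_b <- FALSE
  dup_rows <- list()
  counters <- new.env()
  next_ids <- function(species, source) {
    key <- paste(species, source, sep = ".")
    cur <- counters[[key]] %||% c(gene = 0L, locus = 0L)
    cur
  }
  bump <- function(species, source, cur) {
    counters[[paste(species, source, sep = ".")]] <- cur
  }

  for (src in sources) {
    pcol <- paste0("present_", tolower(src))
    gcol <- paste0("gene_id_", tolower(src))
    ccol <- paste0("cds_", tolower(src))
    mcol <- paste0("modified_", tolower(src))
    for (i in seq_len(nrow(genes))) {
      if (runif(1) < config$miss_prob) next
      cds <- genes$true_cds[i]
      ncod <- nchar(cds) %/% 3L
      u <- runif(1)
      flank5 <- ""; flank3 <- ""; body <- cds
      emitted_cds <- cds; modified <- FALSE
      if (u < config$utr_extend_prob) {
        if (runif(1) < config$boundary_shift_prob) {
          # an ATG-free stretch, then an in-frame upstream ATG plus s
          # stop-free codons fused to the true CDS; ATG cannot form across
          # the junctions (the codon after the junk starts with A), so the
          # planted ATG is the first in-frame start and the inferred CDS
          # gains exactly s + 1 codons
          junk <- random_flank(sample(0:30, 1))
          s <- sample(1:20, 1)
          ext <- paste(sample(NON_STOP_CODONS[NON_STOP_CODONS != "ATG"],
                              s, replace = TRUE), collapse = "")
          flank5 <- paste0(junk, "ATG", ext)
          emitted_cds <- paste0("ATG", ext, cds)
          modified <- TRUE
        } else {
          flank5 <- random_flank(sample(5:60, 1))
        }
        flank3 <- random_flank(sample(5:60, 1))
      } else if (u < config$utr_extend_prob + config$truncation_prob) {
        min_keep <- max(100L, ceiling(0.6 * ncod))
        if (min_keep < ncod) {
          keep <- sample_one(min_keep:(ncod - 1L))
          emitted_cds <- substring(cds, 1, 3L * keep)
          body <- emitted_cds
          modified <- TRUE
        }
      }
      transcript <- paste0(flank5, body, flank3)
      # variants: extra transcripts cut strictly into the CDS
      nvar <- sample(seq_along(config$variant_count_probs), 1,
                     prob = config$variant_count_probs)
      cur <- next_ids(genes$species[i], src)
      cur["locus"] <- cur["locus"] + 1L
      locus <- sprintf("%s_%s_L%03d", genes$species[i], src, cur["locus"])
      cds_end <- nchar(flank5) + nchar(body)
      tx_seqs <- transcript
      for (v in seq_len(nvar - 1L)) {
        lo <- nchar(flank5) + 303L
        hi <- cds_end - 3L
        if (lo > hi) break
        tx_seqs <- c(tx_seqs, substring(transcript, 1, sample_one(lo:hi)))
      }
      rep_gene_id <- NA_character_
      for (v in seq_along(tx_seqs)) {
        cur["gene"] <- cur["gene"] + 1L
        gid <- sprintf("%s_%s_g%04d", genes$species[i], src, cur["gene"])
        if (v == 1L) rep_gene_id <- gid
        rec_rows[[src]][[length(rec_rows[[src]]) + 1L]] <- data.frame(
          gene_id = gid, locus_id = locus,
          transcript_id = sprintf("%s.%d", locus, v),
          species = genes$species[i], source = src, sequence = tx_seqs[v],
          is_cds = FALSE, stringsAsFactors = FALSE)
      }
      # identical within-source duplicate at a fresh locus
      if (runif(1) < config$identical_duplicate_prob) {
        cur["locus"] <- cur["locus"] + 1L
        cur["gene"] <- cur["gene"] + 1L
        dlocus <- sprintf("%s_%s_L%03d", genes$species[i], src, cur["locus"])
        dgid <- sprintf("%s_%s_g%04d", genes$species[i], src, cur["gene"])
        rec_rows[[src]][[length(rec_rows[[src]]) + 1L]] <- data.frame(
          gene_id = dgid, locus_id = dlocus,
          transcript_id = paste0(dlocus, ".1"),
          species = genes$species[i], source = src, sequence = transcript,
          is_cds = FALSE, stringsAsFactors = FALSE)
        dup_rows[[length(dup_rows) + 1L]] <- data.frame(
          gene_key = genes$gene_key[i], species = genes$species[i],
          family = genes$family[i], source = src, gene_id = dgid,
          implied_category = "EXCLUDED_REDUNDANT", stringsAsFactors = FALSE)
      }
      bump(genes$species[i], src, cur)
      truth[[pcol]][i] <- TRUE
      truth[[gcol]][i] <- rep_gene_id
      truth[[ccol]][i] <- emitted_cds
      truth[[mcol]][i] <- modified
    }
  }

  duplicates <- if (length(dup_rows) == 0)
    data.frame(gene_key = character(), species = character(),
               family = character(), source = character(),
               gene_id = character(), implied_category = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, dup_rows)

  # implied categories
  truth$implied_category <- NA_character_
  has_dup <- function(keys, src) keys %in%
    duplicates$gene_key[duplicates$source == src]
  for (i in seq_len(nrow(truth))) {
    pa <- truth$present_a[i]; pb <- truth$present_b[i]
    if (pa && pb) {
      truth$implied_category[i] <-
        if (identical(truth$cds_a[i], truth$cds_b[i])) "PERFECT" else "IMPERFECT"
    } else if (pa || pb) {
      src <- if (pa) "a" else "b"
      SRC <- toupper(src)
      cds <- truth[[paste0("cds_", src)]][i]
      same_src <- truth[[paste0("present_", src)]] &
        truth$species == truth$species[i] & seq_len(nrow(truth)) != i
      twin <- any(truth[[paste0("cds_", src)]][same_src] == cds) ||
        has_dup(truth$gene_key[i], SRC)
      truth$implied_category[i] <-
        if (twin) "EXCLUDED_REDUNDANT" else paste0("UNPAIRED_", SRC)
    } else {
      truth$implied_category[i] <- "MISSING"
    }
  }

  mk_set <- function(src) {
    if (length(rec_rows[[src]]) == 0)
      return(annotation_set(character(), character(), character(),
                            character(), character(), character(), logical()))
    df <- do.call(rbind, rec_rows[[src]])
    validate_annotation_set(df)
    df
  }
  list(source_a = mk_set("A"), source_b = mk_set("B"), truth = truth,
       duplicates = duplicates)
}

#' Simulate a pair of corrupted annotation sources with ground truth
#'
#' Top-level generator: per family, draws a root CDS (also returned as the
#' family's seed query), runs the birth-death process along the species
#' tree, evolves sequences, and corrupts the resulting true gene set into
#' the two annotation sources.
#'
#' @param config a [simulation_config()].
#' @return list with `source_a`, `source_b` (annotation sets), `truth`,
#'   `duplicates`, `seeds` (named root CDS per family), `family_sizes`
#'   (species x family matrix of true copy numbers) and `config`.
#' @export
simulate_annotation_pair <- function(config = simulation_config()) {
  set.seed(config$seed)
  all_genes <- list()
  seeds <- character()
  for (fam in config$family_names) {
    root_cds <- random_root_cds(config$root_length %/% 3L)
    seeds[[fam]] <- root_cds
    sim <- simulate_family(config, fam)
    seqs <- evolve_sequences(sim, root_cds, config)
    if (nrow(sim$genes) > 0) {
      g <- sim$genes
      g$family <- fam
      g$true_cds <- unname(seqs[g$gene_key])
      all_genes[[fam]] <- g
    }
  }
  genes <- if (length(all_genes) == 0)
    data.frame(gene_key = character(), species = character(),
               family = character(), true_cds = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, all_genes)
  rownames(genes) <- NULL
  corr <- corrupt_annotations(genes, config)
  species <- config$species_tree$tip.label
  fams <- config$family_names
  family_sizes <- table(factor(genes$species, levels = species),
                        factor(genes$family, levels = fams))
  c(corr, list(seeds = seeds, family_sizes = family_sizes,
               genes = genes, config = config))
}

#' Write simulated annotation sources to disk
#'
#' Emits per-source FASTA and transcript-to-locus tab files consumable by
#' [parse_annotation_set()], the seed queries, the truth table, and a plain
#' text dump of the configuration.
#'
#' @param sim result of [simulate_annotation_pair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (src in c("a", "b")) {
    set <- sim[[paste0("source_", src)]]
    seqs <- Biostrings::DNAStringSet(setNames(set$sequence, set$gene_id))
    Biostrings::writeXStringSet(seqs, file.path(dir, sprintf("source_%s.fasta", src)))
    # FASTA entries are keyed by gene_id, so the locus map is too
    write.table(set[, c("gene_id", "locus_id")],
                file.path(dir, sprintf("source_%s.map.tsv", src)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    # gene ids are needed to re-link records to the truth table
    write.table(set[, c("gene_id", "locus_id", "transcript_id", "species",
                        "is_cds")],
                file.path(dir, sprintf("source_%s.records.tsv", src)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$seeds),
                              file.path(dir, "seed_queries.fasta"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  write.table(sim$duplicates, file.path(dir, "duplicates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  cfg <- sim$config
  cfg_lines <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("species_tree: %s", ape::write.tree(cfg$species_tree)),
    sprintf("families: %s", paste(cfg$family_names, collapse = ",")),
    sprintf("dup_rate: %g", cfg$dup_rate),
    sprintf("loss_rate: %g", cfg$loss_rate),
    sprintf("root_length: %d", cfg$root_length),
    sprintf("model: %s", cfg$model), sprintf("kappa: %g", cfg$kappa),
    sprintf("miss_prob: %g", cfg$miss_prob),
    sprintf("utr_extend_prob: %g", cfg$utr_extend_prob),
    sprintf("boundary_shift_prob: %g", cfg$boundary_shift_prob),
    sprintf("truncation_prob: %g", cfg$truncation_prob),
    sprintf("identical_duplicate_prob: %g", cfg$identical_duplicate_prob))
  writeLines(cfg_lines, file.path(dir, "config.txt"))
  invisible(dir)
}
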