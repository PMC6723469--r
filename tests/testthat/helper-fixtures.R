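# Shared fixtures and independent oracles, built in code.

# Brute-force longest-ORF oracle: enumerate every (frame, ATG start) pair,
# extend to the first in-frame stop (or sequence end), keep the longest
# (ties: lowest frame, then leftmost start).  Independent of longest_orf().
brute_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    pos <- seq(1L + frame, n - 2L, by = 3L)
    if (length(pos) == 0) next
    for (p in pos) {
      if (substring(seq, p, p + 2L) != "ATG") next
      q <- p
      end <- NA
      while (q + 2L <= n) {
        if (substring(seq, q, q + 2L) %in% stops) { end <- q + 2L; break }
        q <- q + 3L
      }
      if (is.na(end)) end <- p + 3L * ((n - p + 1L) %/% 3L) - 1L
      len <- end - p + 1L
      if (is.null(best) || len > best$len)
        best <- list(len = len, cds = substring(seq, p, end))
    }
  }
  best
}

# A random transcript: UTR-free CDS embedded in flanks (flanks may contain
# ATGs, so the oracle comparison is the only ground truth).
random_transcript <- function(min_codons = 110, max_codons = 200) {
  nc <- sample(min_codons:max_codons, 1)
  cds <- random_root_cds(nc)
  paste0(paste(sample(c("A", "C", "G", "T"), sample(0:40, 1), TRUE),
               collapse = ""),
         cds,
         paste(sample(c("A", "C", "G", "T"), sample(0:40, 1), TRUE),
               collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute a fraction of positions (never to the same base)
mutate_seq <- function(seq, frac) {
  b <- strsplit(seq, "")[[1]]
  idx <- sample(length(b), ceiling(frac * length(b)))
  for (i in idx) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

# small clean two-source simulation used by several tests
clean_sim_config <- function(n_species = 4, families = FBP_ENZYMES[1:3],
                             seed = 7, root_length = 600) {
  tree <- ape::keep.tip(default_species_tree(),
                        default_species_tree()$tip.label[seq_len(n_species)])
  simulation_config(species_tree = tree, family_names = families,
                    dup_rate = 0, loss_rate = 0, miss_prob = 0,
                    utr_extend_prob = 0, truncation_prob = 0,
                    variant_count_probs = 1, identical_duplicate_prob = 0,
                    root_length = root_length, seed = seed)
}

corrupt_sim_config <- function(n_species = 10, seed = 1, ...) {
  tree <- ape::keep.tip(default_species_tree(),
                        default_species_tree()$tip.label[seq_len(n_species)])
  simulation_config(species_tree = tree, seed = seed, ...)
}

# one-row annotation set
one_record <- function(gene_id, seq, species = "S1", source = "A",
                       locus = gene_id, is_cds = TRUE) {
  annotation_set(gene_id = gene_id, locus_id = locus,
                 transcript_id = gene_id, species = species,
                 source = source, sequence = seq, is_cds = is_cds)
}

# planted cross-source unpaired pairs for rescue tests: returns records,
# leaf metadata and sequences; each pair diverged <= `divergence` with a
# shifted 5' coding boundary in source B
planted_rescue_fixture <- function(n_pairs = 20, divergence = 0.03,
                                   n_codons = 150) {
  seqs <- character(); recs <- list()
  unpaired_rec <- function(enzyme, ga, gb, la, lb) {
    rbind(data.frame(enzyme = enzyme, species = "S1", member_a = ga,
                     member_b = NA_character_, category = "UNPAIRED_A",
                     identity = NA_real_, length_a = la, length_b = NA_real_,
                     length_ratio = NA_real_, rescued_by_tree = FALSE,
                     stringsAsFactors = FALSE),
          data.frame(enzyme = enzyme, species = "S1",
                     member_a = NA_character_, member_b = gb,
                     category = "UNPAIRED_B", identity = NA_real_,
                     length_a = NA_real_, length_b = lb,
                     length_ratio = NA_real_, rescued_by_tree = FALSE,
                     stringsAsFactors = FALSE))
  }
  drift <- function(cds, t) {
    unname(evolve_sequences(
      list(genes = data.frame(gene_key = "g", species = "S1"),
           tree = NULL, tip_depth = c(g = t)),
      cds, simulation_config(dup_rate = 0, loss_rate = 0)))
  }
  for (i in seq_len(n_pairs)) {
    cds <- random_root_cds(n_codons)
    b <- drift(cds, divergence)
    bseq <- paste0("ATGGCTGCA", substring(b, 4))  # 2-codon 5' boundary shift
    ga <- sprintf("S1_A_g%03d", i); gb <- sprintf("S1_B_g%03d", i)
    seqs[[paste0("A|", ga)]] <- cds
    seqs[[paste0("B|", gb)]] <- bseq
    recs[[i]] <- unpaired_rec("CHS", ga, gb, nchar(cds), nchar(bseq))
  }
  records <- do.call(rbind, recs)
  leaf <- data.frame(label = names(seqs),
                     gene_id = sub("^[AB][|]", "", names(seqs)),
                     source = substring(names(seqs), 1, 1),
                     species = "S1", stringsAsFactors = FALSE)
  list(records = records, leaf = leaf, seqs = unlist(seqs))
}
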