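test_that("FASTA parsing resolves loci from feature tables and falls back gracefully", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "in.fasta")
  set.seed(1)
  seqs <- Biostrings::DNAStringSet(c(t1.1 = random_dna(90), t1.2 = random_dna(60),
                                     t2.1 = random_dna(75)))
  Biostrings::writeXStringSet(seqs, fa)
  tab <- file.path(d, "map.tsv")
  writeLines(c("t1.1\tL1", "t1.2\tL1", "t2.1\tL2"), tab)
  rec <- parse_annotation_set(fa, species = "Spc", source = "A",
                              feature_path = tab)
  expect_equal(nrow(rec), 3)
  expect_equal(sort(unique(rec$locus_id)), c("L1", "L2"))

  # identifier rule: strip trailing .<int>
  rec2 <- parse_annotation_set(fa, species = "Spc", source = "A")
  expect_equal(sort(unique(rec2$locus_id)), c("t1", "t2"))

  # entry absent from feature table: kept, locus = transcript, warning
  writeLines(c("t1.1\tL1", "t1.2\tL1"), tab)
  expect_warning(rec3 <- parse_annotation_set(fa, species = "Spc",
                                              source = "A",
                                              feature_path = tab),
                 "absent")
  expect_equal(rec3$locus_id[rec3$gene_id == "t2.1"], "t2.1")

  # empty FASTA -> empty collection
  fa0 <- file.path(d, "empty.fasta")
  file.create(fa0)
  expect_equal(nrow(parse_annotation_set(fa0, species = "Spc", source = "A")), 0)

  # unreadable file is fatal
  expect_error(parse_annotation_set(file.path(d, "nope.fa"), "Spc", "A"),
               "cannot read")
})

test_that("simulator FASTA output round-trips through the parser", {
  d <- withr::local_tempdir()
  sim <- simulate_annotation_pair(clean_sim_config(seed = 3))
  write_simulation(sim, d)
  rec <- parse_annotation_set(file.path(d, "source_a.fasta"),
                              species = "multi", source = "A",
                              feature_path = file.path(d, "source_a.map.tsv"),
                              is_cds = FALSE)
  expect_setequal(paste(rec$gene_id, rec$sequence),
                  paste(sim$source_a$gene_id, sim$source_a$sequence))
})

test_that("longest ORF obeys the 300 nt floor and matches brute-force enumeration", {
  # exactly 300 nt, ATG...TAA, no internal stop: returned unchanged
  set.seed(11)
  cds300 <- random_root_cds(100)
  expect_equal(nchar(cds300), 300)
  rec <- one_record("g1", cds300, is_cds = FALSE)
  out <- infer_cds(rec)
  expect_equal(out$sequence, cds300)
  expect_true(out$is_cds)

  # an ORF short of 300 nt inside a longer transcript is rejected at the
  # 300 bp floor: ATG-free flank + ATG + 97 codons + truncated stop = 297 nt
  flank <- gsub("ATG", "CCC", random_dna(150))
  tx299 <- paste0(flank, "ATG", paste(rep("GCA", 97), collapse = ""), "TA")
  rec2 <- one_record("g2", tx299, is_cds = FALSE)
  out2 <- infer_cds(rec2)
  expect_equal(nrow(out2), 0)
  expect_equal(nrow(attr(out2, "rejected")), 1)

  # two ORFs (330 and 600 nt): the longer one wins, against the oracle
  orf_a <- random_root_cds(110)   # 330 nt
  orf_b <- random_root_cds(200)   # 600 nt
  sep <- gsub("ATG", "CCC", random_dna(50))
  tx2 <- paste0(sep, orf_a, sep, orf_b, sep)
  got <- longest_orf(tx2)
  expect_equal(got$cds, orf_b)
  expect_equal(got$cds, brute_orf(tx2)$cds)

  # randomized agreement with the brute-force oracle
  for (i in 1:20) {
    tx <- random_transcript()
    expect_equal(longest_orf(tx)$cds, brute_orf(tx)$cds)
  }

  # alphabet validation is fatal; N inside an ORF is tolerated
  expect_error(longest_orf("ATGXXXTAA"), "outside")
  withN <- paste0("ATG", paste(rep("GCN", 100), collapse = ""), "TAA")
  expect_equal(longest_orf(withN)$cds, withN)
})

test_that("inferred CDS are codon-multiples of at least min_len", {
  set.seed(21)
  for (i in 1:10) {
    tx <- random_transcript()
    out <- infer_cds(one_record("g", tx, is_cds = FALSE), min_len = 300)
    if (nrow(out) == 1) {
      expect_gte(nchar(out$sequence), 300)
      expect_equal(nchar(out$sequence) %% 3, 0)
    }
  }
})

test_that("variant dedup keeps the longest transcript per locus, deterministically", {
  set.seed(31)
  dialect <- source_dialect("B", "longest_per_locus")
  rec <- annotation_set(gene_id = c("g1", "g2"), locus_id = "L1",
                        transcript_id = c("L1.1", "L1.2"),
                        species = "S", source = "B",
                        sequence = c(random_dna(900), random_dna(1200)))
  out <- dedup_variants(rec, dialect)
  expect_equal(out$gene_id, "g2")
  expect_equal(nchar(out$sequence), 1200)

  # idempotence and passthrough
  expect_equal(dedup_variants(out, dialect), out)
  one_per <- annotation_set(gene_id = c("a", "b"), locus_id = c("L1", "L2"),
                            species = "S", source = "B",
                            sequence = c(random_dna(30), random_dna(60)))
  expect_equal(dedup_variants(one_per, dialect), one_per)
  expect_equal(dedup_variants(rec, source_dialect("p", "prefiltered_primary")),
               rec)

  # 50 loci with 1-4 variants: sizes and per-locus maxima match a
  # group-by-max oracle
  rows <- list()
  for (l in 1:50) {
    nv <- sample(1:4, 1)
    for (v in 1:nv) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sprintf("g%02d_%d", l, v), locus_id = sprintf("L%02d", l),
        transcript_id = sprintf("L%02d.%d", l, v), species = "S",
        source = "B", sequence = random_dna(3 * sample(100:200, 1)),
        is_cds = TRUE, stringsAsFactors = FALSE)
    }
  }
  big <- do.call(rbind, rows)
  out2 <- dedup_variants(big, dialect)
  expect_equal(nrow(out2), 50)
  oracle <- tapply(nchar(big$sequence), big$locus_id, max)
  expect_equal(as.vector(oracle[out2$locus_id]), nchar(out2$sequence))

  # equal-length tie goes to the lexicographically smallest transcript id
  tie <- annotation_set(gene_id = c("gB", "gA"), locus_id = "L",
                        transcript_id = c("L.2", "L.1"), species = "S",
                        source = "B", sequence = rep(random_dna(300), 2))
  expect_equal(dedup_variants(tie, dialect)$transcript_id, "L.1")
})

test_that("normalization drops overly ambiguous sequences and preserves content", {
  seqn <- paste0("ATG", paste(rep("NNN", 120), collapse = ""), "TAA")
  rec <- rbind(one_record("gN", seqn), one_record("g1", random_root_cds(150)))
  expect_warning(out <- normalize_annotations(rec), "N bases")
  expect_equal(out$gene_id, "g1")
  # filtering never edits surviving already-CDS sequences
  expect_equal(out$sequence, rec$sequence[rec$gene_id == "g1"])
})
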