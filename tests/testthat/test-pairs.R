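test_that("reciprocal best hits handle singletons, empties and mutual bests", {
  set.seed(9)
  x <- random_root_cds(150)
  a <- one_record("a1", x)
  b <- one_record("b1", x, source = "B")
  rbh <- reciprocal_best_hits(a, b)
  expect_equal(rbh$a, "a1")
  expect_equal(rbh$b, "b1")
  expect_equal(rbh$identity, 100)

  expect_equal(nrow(reciprocal_best_hits(a, b[0, ])), 0)
  expect_equal(nrow(reciprocal_best_hits(a[0, ], b)), 0)
})

test_that("RBH pairs on diverged 4x4 families match an exhaustive best-hit oracle", {
  set.seed(10)
  p <- search_params()
  base <- lapply(1:4, function(i) random_root_cds(130))
  seq_a <- vapply(base, function(s) mutate_seq(s, 0.04), "")
  seq_b <- vapply(base, function(s) mutate_seq(s, 0.04), "")
  set_a <- annotation_set(gene_id = paste0("a", 1:4),
                          locus_id = paste0("a", 1:4), species = "S",
                          source = "A", sequence = seq_a)
  set_b <- annotation_set(gene_id = paste0("b", 1:4),
                          locus_id = paste0("b", 1:4), species = "S",
                          source = "B", sequence = seq_b)
  rbh <- reciprocal_best_hits(set_a, set_b, p)
  # truth pairing: a_i <-> b_i (same ancestral gene)
  expect_equal(nrow(rbh), 4)
  expect_equal(sub("a", "", rbh$a), sub("b", "", rbh$b))
  # exhaustive all-pairs tabulation with sw_align directly
  S <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    S[i, j] <- sw_align(seq_a[i], seq_b[j], p)$score
  best_a <- apply(S, 1, which.max)
  best_b <- apply(S, 2, which.max)
  mutual <- which(best_b[best_a] == 1:4)
  expect_equal(rbh$a, paste0("a", mutual))
  expect_equal(rbh$b, paste0("b", best_a[mutual]))
})

test_that("pair categories: string equality is PERFECT, all else IMPERFECT/UNPAIRED", {
  set.seed(12)
  x <- random_root_cds(400)  # 1200 nt
  a <- one_record("a1", x)
  b <- one_record("b1", x, source = "B")
  rec <- classify_pairs(reciprocal_best_hits(a, b), a, b, enzyme = "CHS")
  expect_equal(rec$category, "PERFECT")
  expect_equal(rec$identity, 100)
  expect_equal(rec$length_ratio, 1)

  # a 60 nt in-frame 5' extension: IMPERFECT with length ratio 1260/1200
  ext <- paste0("ATG", paste(sample(setdiff(fbpconcord:::NON_STOP_CODONS,
                                            "ATG"), 19, TRUE),
                             collapse = ""))
  b2 <- one_record("b1", paste0(ext, x), source = "B")
  rec2 <- classify_pairs(reciprocal_best_hits(a, b2), a, b2, enzyme = "CHS")
  expect_equal(rec2$category, "IMPERFECT")
  expect_equal(rec2$length_ratio, 1260 / 1200)
  # the local alignment of the shared region is perfect; the pair is
  # imperfect because the full coding sequences differ in length
  expect_equal(rec2$identity, 100)

  # no partner at all
  rec3 <- classify_pairs(reciprocal_best_hits(a, b[0, ]), a, b[0, ],
                         enzyme = "CHS")
  expect_equal(rec3$category, "UNPAIRED_A")
  expect_true(is.na(rec3$member_b))
})

test_that("unpaired in-source duplicates are excluded, others untouched", {
  set.seed(13)
  x <- random_root_cds(120); y <- random_root_cds(120)
  # a1/b1 pair perfectly; a2 duplicates a1 in-source and stays unpaired
  set_a <- annotation_set(gene_id = c("a1", "a2", "a3"),
                          locus_id = c("L1", "L2", "L3"), species = "S",
                          source = "A", sequence = c(x, x, y))
  set_b <- one_record("b1", x, source = "B")
  rec <- classify_pairs(reciprocal_best_hits(set_a, set_b), set_a, set_b,
                        enzyme = "CHS")
  out <- exclude_redundant_unpaired(rec, set_a, set_b)
  expect_equal(out$category[out$member_a %in% "a2"], "EXCLUDED_REDUNDANT")
  expect_equal(out$category[out$member_a %in% "a3"], "UNPAIRED_A")

  # no duplicates anywhere: a no-op
  set_a2 <- set_a[set_a$gene_id != "a2", ]
  rec2 <- classify_pairs(reciprocal_best_hits(set_a2, set_b), set_a2, set_b)
  expect_identical(exclude_redundant_unpaired(rec2, set_a2, set_b), rec2)

  # simulator-planted duplicates: exactly k records recategorised
  sim <- simulate_annotation_pair(
    corrupt_sim_config(seed = 5, identical_duplicate_prob = 0.3,
                       miss_prob = 0, utr_extend_prob = 0,
                       truncation_prob = 0, variant_count_probs = 1))
  res <- concordance_analysis(sim$source_a, sim$source_b, sim$seeds,
                              rescue = FALSE, bootstraps = 0)
  k <- nrow(sim$duplicates)
  expect_gt(k, 0)
  expect_equal(sum(res$pair_records$category == "EXCLUDED_REDUNDANT"), k)
})

test_that("final merge prefers source A for pairs and keeps residual unpaired", {
  rec <- data.frame(
    enzyme = "CHS", species = "S",
    member_a = c("a1", "a2", NA), member_b = c("b1", "b2", "b3"),
    category = c("PERFECT", "PERFECT", "UNPAIRED_B"),
    identity = c(100, 100, NA), length_a = c(300, 300, NA),
    length_b = c(300, 300, 300), length_ratio = c(1, 1, NA),
    rescued_by_tree = FALSE, stringsAsFactors = FALSE)
  fin <- merge_final(rec)
  expect_equal(nrow(fin), 3)
  expect_equal(sum(fin$source == "A"), 2)
  expect_equal(fin$gene_id[fin$source == "B"], "b3")

  rec$category[3] <- "EXCLUDED_REDUNDANT"
  expect_equal(nrow(merge_final(rec)), 2)
  expect_true(all(merge_final(rec)$source == "A"))
})

test_that("classification partitions every gene exactly once (conservation)", {
  for (seed in c(21, 22)) {
    sim <- simulate_annotation_pair(corrupt_sim_config(seed = seed))
    res <- concordance_analysis(sim$source_a, sim$source_b, sim$seeds,
                                rescue = FALSE, bootstraps = 0)
    rec <- res$pair_records
    # each normalized homolog occupies exactly one record slot
    hom_a <- res$homologs_a$gene_id
    hom_b <- res$homologs_b$gene_id
    slots_a <- rec$member_a[!is.na(rec$member_a)]
    slots_b <- rec$member_b[!is.na(rec$member_b)]
    expect_setequal(slots_a, hom_a)
    expect_setequal(slots_b, hom_b)
    expect_equal(anyDuplicated(slots_a), 0)
    expect_equal(anyDuplicated(slots_b), 0)
    rep_ <- res$report
    expect_equal(rep_$totals_a,
                 rep_$perfect + rep_$imperfect + rep_$unpaired_a + rep_$excluded_a)
    expect_equal(rep_$totals_b,
                 rep_$perfect + rep_$imperfect + rep_$unpaired_b + rep_$excluded_b)
  }
})
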