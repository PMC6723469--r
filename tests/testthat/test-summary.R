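test_that("concordance report satisfies the accounting identities", {
  sim <- simulate_annotation_pair(corrupt_sim_config(n_species = 6, seed = 14))
  res <- concordance_analysis(sim$source_a, sim$source_b, sim$seeds,
                              rescue = FALSE, bootstraps = 0)
  rep_ <- res$report
  rec <- res$pair_records
  # independent recount over the record table
  expect_equal(rep_$perfect, sum(rec$category == "PERFECT"))
  expect_equal(rep_$imperfect, sum(rec$category == "IMPERFECT"))
  expect_equal(rep_$unpaired_a, sum(rec$category == "UNPAIRED_A"))
  expect_equal(rep_$unpaired_b, sum(rec$category == "UNPAIRED_B"))
  expect_equal(rep_$shared_pairs, rep_$perfect + rep_$imperfect)
  expect_equal(rep_$totals_a, rep_$shared_pairs + rep_$unpaired_a +
                 rep_$excluded_a)

  empty <- concordance_report(rec[0, ])
  expect_true(all(unlist(empty) == 0))
})

test_that("length statistics use population SD with singleton strata at zero", {
  set_a <- one_record("a1", random_root_cds(400))   # 1200 nt
  set_b <- one_record("b1", random_root_cds(400), source = "B")
  rec <- data.frame(enzyme = "DFR", species = "S1", member_a = "a1",
                    member_b = "b1", category = "IMPERFECT", identity = 99,
                    length_a = 1200, length_b = 1200, length_ratio = 1,
                    rescued_by_tree = FALSE, stringsAsFactors = FALSE)
  ls_ <- length_stats(rec, set_a, set_b)
  expect_equal(ls_$n, c(1, 1))
  expect_equal(ls_$mean_nt, c(1200, 1200))
  expect_equal(ls_$sd_nt, c(0, 0))

  # two-point closed form: lengths {900, 1100} -> mean 1000, sd 100
  set_a2 <- annotation_set(gene_id = c("a1", "a2"),
                           locus_id = c("a1", "a2"), species = "S1",
                           source = "A",
                           sequence = c(random_dna(900), random_dna(1100)))
  rec2 <- data.frame(enzyme = "CHS", species = "S1",
                     member_a = c("a1", "a2"), member_b = NA_character_,
                     category = "UNPAIRED_A", identity = NA_real_,
                     length_a = c(900, 1100), length_b = NA_real_,
                     length_ratio = NA_real_, rescued_by_tree = FALSE,
                     stringsAsFactors = FALSE)
  ls2 <- length_stats(rec2, set_a2, set_b[0, ])
  expect_equal(ls2$n, 2)
  expect_equal(ls2$mean_nt, 1000)
  expect_equal(ls2$sd_nt, 100)
})

test_that("copy-number cells, marginals and flags recount correctly", {
  genes_a <- data.frame(
    enzyme = c("CHS", "CHS", "CHS", "DFR", "DFR"),
    species = c("S1", "S1", "S2", "S1", "S2"),
    gene_id = paste0("a", 1:5), stringsAsFactors = FALSE)
  genes_b <- data.frame(
    enzyme = c("CHS", "DFR", "DFR"),
    species = c("S1", "S1", "S2"),
    gene_id = paste0("b", 1:3), stringsAsFactors = FALSE)
  cnm <- copy_number_matrix(genes_a, genes_b)
  expect_equal(cnm$counts["CHS", "S1", "A"], 2L)
  expect_equal(cnm$counts["CHS", "S1", "B"], 1L)
  expect_true(cnm$discrepancy["CHS", "S1"])
  expect_false(cnm$discrepancy["DFR", "S1"])
  expect_true(cnm$zero["CHS", "S2"])  # B reports zero CHS in S2
  # marginals equal independent row/column sums
  expect_equal(cnm$enzyme_totals[, "A"],
               rowSums(cnm$counts[, , "A"]))
  expect_equal(cnm$species_totals[, "B"],
               colSums(cnm$counts[, , "B"]))
  expect_equal(sum(cnm$counts[, , "A"]), nrow(genes_a))
})

test_that("simulated copy numbers recount from serialized gene sets", {
  d <- withr::local_tempdir()
  sim <- simulate_annotation_pair(clean_sim_config(seed = 15))
  res <- concordance_analysis(sim$source_a, sim$source_b, sim$seeds,
                              rescue = FALSE, bootstraps = 0)
  cnm <- res$copy_matrix
  # reproducible from the homolog tables alone (no hidden state)
  for (e in FBP_ENZYMES) for (sp in colnames(cnm$discrepancy)) {
    expect_equal(unname(cnm$counts[e, sp, "A"]),
                 sum(res$homologs_a$enzyme == e & res$homologs_a$species == sp))
  }
})
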