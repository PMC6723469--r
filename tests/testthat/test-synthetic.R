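test_that("zero rates give exactly one gene per species", {
  cfg <- clean_sim_config(n_species = 6, families = "CHS")
  set.seed(1)
  fam <- simulate_family(cfg, "CHS")
  expect_equal(nrow(fam$genes), 6)
  expect_setequal(fam$genes$species, cfg$species_tree$tip.label)
  expect_equal(sort(fam$tree$tip.label), sort(fam$genes$gene_key))
})

test_that("runaway birth rates are refused", {
  cfg <- clean_sim_config(n_species = 4)
  cfg$dup_rate <- 100
  expect_error(simulate_family(cfg, "F"), "cap")
})

test_that("identical seeds give byte-identical simulated FASTA", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- corrupt_sim_config(n_species = 4, seed = 77)
  write_simulation(simulate_annotation_pair(cfg), d1)
  write_simulation(simulate_annotation_pair(cfg), d2)
  for (f in c("source_a.fasta", "source_b.fasta", "truth.tsv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("zero-length branches leave sequences unchanged", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  cfg <- simulation_config(species_tree = tr, dup_rate = 0, loss_rate = 0,
                           root_length = 300)
  set.seed(2)
  fam <- simulate_family(cfg, "F")
  root <- random_root_cds(100)
  seqs <- evolve_sequences(fam, root, cfg)
  expect_true(all(seqs == root))
})

test_that("HKY transitions outnumber transversions", {
  cfg <- simulation_config(species_tree = ape::read.tree(text = "(S1:0.2);"),
                           dup_rate = 0, loss_rate = 0, kappa = 4,
                           root_length = 6000)
  set.seed(3)
  fam <- simulate_family(cfg, "F")
  root <- random_root_cds(2000)
  child <- evolve_sequences(fam, root, cfg, preserve_cds = FALSE)[[1]]
  a <- strsplit(root, "")[[1]]; b <- strsplit(child, "")[[1]]
  changed <- a != b
  purine <- c("A", "G")
  ts <- sum(changed & ((a %in% purine) == (b %in% purine)))
  tv <- sum(changed) - ts
  expect_gt(ts / tv, 1)
})

test_that("per-source gene losses follow the configured miss probability", {
  cfg <- corrupt_sim_config(n_species = 10, seed = 9, dup_rate = 2,
                            loss_rate = 0.2, miss_prob = 0.1,
                            utr_extend_prob = 0, truncation_prob = 0,
                            variant_count_probs = 1,
                            identical_duplicate_prob = 0)
  sim <- simulate_annotation_pair(cfg)
  n <- nrow(sim$truth)
  expect_gt(n, 50)
  dropped <- sum(!sim$truth$present_a) + sum(!sim$truth$present_b)
  expected <- 2 * n * 0.1
  se <- sqrt(2 * n * 0.1 * 0.9)
  expect_lt(abs(dropped - expected), 3 * se)
})

test_that("a clean channel implies all-PERFECT truth and emitted sets equal truth", {
  sim <- simulate_annotation_pair(clean_sim_config(seed = 4))
  expect_true(all(sim$truth$implied_category == "PERFECT"))
  expect_equal(sort(sim$source_a$sequence), sort(sim$genes$true_cds))
  expect_equal(nrow(sim$duplicates), 0)
})

test_that("coding-boundary shifts imply IMPERFECT pairs with longer CDS", {
  cfg <- corrupt_sim_config(n_species = 4, seed = 6, miss_prob = 0,
                            utr_extend_prob = 1, boundary_shift_prob = 1,
                            truncation_prob = 0, variant_count_probs = 1,
                            identical_duplicate_prob = 0)
  sim <- simulate_annotation_pair(cfg)
  expect_true(all(sim$truth$implied_category == "IMPERFECT"))
  expect_true(all(nchar(sim$truth$cds_a) > nchar(sim$genes$true_cds)))
  # the emitted transcript still decodes to the shifted CDS via longest ORF
  i <- 1
  rec <- sim$source_a[sim$source_a$gene_id == sim$truth$gene_id_a[i], ]
  rec <- rec[1, ]
  expect_equal(longest_orf(rec$sequence)$cds, sim$truth$cds_a[i])
})

test_that("every emitted record traces to exactly one true gene or duplicate", {
  sim <- simulate_annotation_pair(corrupt_sim_config(n_species = 6, seed = 8))
  # representatives + variants share the locus of their true gene; count
  # loci per source = present true genes + injected duplicates
  for (src in c("a", "b")) {
    set <- sim[[paste0("source_", src)]]
    n_loci <- length(unique(set$locus_id))
    n_true <- sum(sim$truth[[paste0("present_", src)]])
    n_dup <- sum(sim$duplicates$source == toupper(src))
    expect_equal(n_loci, n_true + n_dup)
  }
})
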