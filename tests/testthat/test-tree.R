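test_that("identical rows are at distance zero in matrix and tree", {
  set.seed(40)
  s <- random_root_cds(100)
  other <- mutate_seq(s, 0.2)
  aln <- align_family(c(a = s, b = s, c = other))
  D <- gtr_distances(aln)
  expect_equal(D["a", "b"], 0)
  tree <- build_tree(aln, bootstraps = 0)
  td <- ape::cophenetic.phylo(tree)
  expect_lt(td["a", "b"], 1e-9)
})

test_that("three-taxon branch lengths follow the closed-form three-point solution", {
  set.seed(41)
  s <- random_root_cds(400)
  seqs <- c(a = mutate_seq(s, 0.02), b = mutate_seq(s, 0.04),
            c = mutate_seq(s, 0.10))
  aln <- align_family(seqs)
  D <- gtr_distances(aln, gamma_shape = 1)
  tree <- build_tree(aln, bootstraps = 0, gamma_shape = 1)
  bl <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                 tree$tip.label)
  expect_equal(bl[["a"]], (D["a", "b"] + D["a", "c"] - D["b", "c"]) / 2,
               tolerance = 1e-9)
  expect_equal(bl[["b"]], (D["a", "b"] + D["b", "c"] - D["a", "c"]) / 2,
               tolerance = 1e-9)
  expect_equal(bl[["c"]], (D["a", "c"] + D["b", "c"] - D["a", "b"]) / 2,
               tolerance = 1e-9)
})

test_that("neighbor joining recovers the generating 5-taxon topology", {
  tr <- ape::read.tree(
    text = "((S1:0.05,S2:0.05):0.04,(S3:0.05,S4:0.05):0.04,S5:0.09);")
  cfg <- simulation_config(species_tree = tr, dup_rate = 0, loss_rate = 0,
                           root_length = 3000, model = "JC", seed = 1)
  set.seed(202)
  for (r in 1:3) {
    fam <- simulate_family(cfg, "F")
    seqs <- evolve_sequences(fam, random_root_cds(1000), cfg)
    names(seqs) <- fam$genes$species
    tree <- build_tree(align_family(seqs), bootstraps = 0, gamma_shape = Inf)
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate alignments are rejected", {
  set.seed(42)
  s <- random_root_cds(50)
  aln <- align_family(c(a = s, b = s, c = s))
  aln$rows[["c"]] <- paste(rep("-", nchar(s)), collapse = "")
  expect_error(build_tree(aln, bootstraps = 0), "all-gap")
  expect_error(build_tree(align_family(c(a = s, b = s))), ">= 3")
})

test_that("rescue merges only same-species cross-source cherries", {
  set.seed(43)
  fx <- planted_rescue_fixture(n_pairs = 4)
  tree <- build_tree(align_family(fx$seqs), bootstraps = 0,
                     leaf_meta = fx$leaf)
  out <- rescue_unpaired(tree, fx$records, leaf_meta = fx$leaf)
  expect_equal(sum(out$category == "IMPERFECT" & out$rescued_by_tree), 4)
  expect_true(all(out$length_ratio[out$rescued_by_tree] > 1))

  # total gene count is conserved: members before == members after
  count_members <- function(r)
    sum(!is.na(r$member_a)) + sum(!is.na(r$member_b))
  expect_equal(count_members(out), count_members(fx$records))

  # records without unpaired leaves pass through untouched
  perfect <- fx$records[1, ]
  perfect$category <- "PERFECT"; perfect$member_b <- "S1_B_g999"
  expect_equal(rescue_unpaired(tree, perfect, leaf_meta = fx$leaf), perfect)

  # a cherry of two same-source leaves never merges
  x <- random_root_cds(150)
  seqs <- c(fx$seqs[1:4],
            `A|S1_A_twin1` = x, `A|S1_A_twin2` = mutate_seq(x, 0.01))
  leaf <- rbind(fx$leaf[1:4, ],
                data.frame(label = c("A|S1_A_twin1", "A|S1_A_twin2"),
                           gene_id = c("S1_A_twin1", "S1_A_twin2"),
                           source = "A", species = "S1",
                           stringsAsFactors = FALSE))
  recs <- rbind(fx$records[1:4, ],
                data.frame(enzyme = "CHS", species = "S1",
                           member_a = c("S1_A_twin1", "S1_A_twin2"),
                           member_b = NA_character_,
                           category = "UNPAIRED_A", identity = NA_real_,
                           length_a = nchar(x), length_b = NA_real_,
                           length_ratio = NA_real_,
                           rescued_by_tree = FALSE, stringsAsFactors = FALSE))
  tree2 <- build_tree(align_family(seqs), bootstraps = 0, leaf_meta = leaf)
  out2 <- rescue_unpaired(tree2, recs, leaf_meta = leaf)
  expect_equal(out2$category[out2$member_a %in%
                               c("S1_A_twin1", "S1_A_twin2")],
               rep("UNPAIRED_A", 2))
})

test_that("outgroup rooting handles single, monophyletic and conflicting outgroups", {
  set.seed(44)
  s <- random_root_cds(150)
  seqs <- setNames(c(mutate_seq(s, 0.02), mutate_seq(s, 0.02),
                     mutate_seq(s, 0.03), mutate_seq(s, 0.25)),
                   c("in1", "in2", "in3", "og1"))
  tree <- build_tree(align_family(seqs), bootstraps = 0)
  rooted <- root_with_outgroup(tree, "og1")
  expect_true(ape::is.rooted(rooted))
  og_tip <- which(rooted$tip.label == "og1")
  root_node <- length(rooted$tip.label) + 1L
  expect_true(rooted$edge[rooted$edge[, 2] == og_tip, 1] == root_node)

  expect_error(root_with_outgroup(tree, character(0)), "empty")
  expect_error(root_with_outgroup(tree, "nope"), "absent")

  # non-monophyletic outgroup: best-agreement edge with a warning
  expect_warning(r2 <- root_with_outgroup(tree, c("og1", "in2")),
                 "monophyletic")
  expect_true(ape::is.rooted(r2))
})

test_that("bootstrap supports are deterministic given a seed", {
  set.seed(45)
  base <- random_root_cds(120)
  seqs <- setNames(vapply(1:5, function(i) mutate_seq(base, 0.1), ""),
                   paste0("s", 1:5))
  aln <- align_family(seqs)
  t1 <- build_tree(aln, bootstraps = 50, seed = 99)
  t2 <- build_tree(aln, bootstraps = 50, seed = 99)
  expect_equal(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label[-1] >= 0 & t1$node.label[-1] <= 100))
})
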