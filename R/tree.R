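#' GTR pairwise distances from a codon alignment
#'
#' Maximum-likelihood-consistent pairwise distances under the general
#' time-reversible model, computed in closed form from the symmetrised
#' divergence matrix F of each sequence pair:
#' `d = -tr(Pi logm(Pi^-1 F))`, evaluated through the eigen-decomposition of
#' `Pi^-1 F`.  Gamma rate heterogeneity with shape `gamma_shape` is applied
#' as the standard eigenvalue transform `-log(e) -> alpha (e^(-1/alpha)-1)`
#' (exact for equal-frequency models, a documented approximation for GTR).
#' Saturated or degenerate pairs are capped at `max_dist`.
#'
#' @param msa a `codon_msa`.
#' @param gamma_shape gamma shape alpha; `Inf` disables rate heterogeneity.
#' @param max_dist cap for saturated distances (substitutions/site).
#' @return symmetric distance matrix with sequence names.
#' @export
gtr_distances <- function(msa, gamma_shape = 1, max_dist = 10) {
  m <- msa_int_matrix(msa)
  d <- .gtr_dist(m, gamma_shape, max_dist)
  dimnames(d) <- list(names(msa$rows), names(msa$rows))
  d
}

msa_int_matrix <- function(msa) {
  t(vapply(msa$rows, encode_dna, integer(msa_ncol(msa))))
}

#' Build a bootstrap gene tree from a codon alignment
#'
#' Internal reference backend for maximum-likelihood tree programs:
#' neighbor-joining on pairwise GTR(+Gamma) distances (see
#' [gtr_distances()]), with nonparametric bootstrap over codon columns for
#' internal-edge supports.  Deterministic for a fixed seed.
#'
#' @param msa a `codon_msa` with >= 3 rows.
#' @param bootstraps number of bootstrap replicates (default 1000); 0 skips
#'   support estimation.
#' @param seed RNG seed for the bootstrap resampling.
#' @param gamma_shape,max_dist passed to [gtr_distances()].
#' @param leaf_meta optional data frame of leaf metadata (column `label`
#'   plus e.g. `gene_id`, `source`, `species`, `category`), attached as
#'   `attr(, "leaf_meta")`.
#' @return an unrooted `ape::phylo` tree; `node.label` holds bootstrap
#'   support percentages (root entry `NA`).
#' @export
build_tree <- function(msa, bootstraps = 1000L, seed = 1L, gamma_shape = 1,
                       max_dist = 10, leaf_meta = NULL) {
  if (length(msa$rows) < 3) stop("build_tree requires >= 3 sequences",
                                 call. = FALSE)
  m <- msa_int_matrix(msa)
  if (any(rowSums(m < 4L) == 0))
    stop("alignment contains an all-gap row", call. = FALSE)
  D <- .gtr_dist(m, gamma_shape, max_dist)
  dimnames(D) <- list(names(msa$rows), names(msa$rows))
  tree <- ape::nj(as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (bootstraps > 0) {
    ncod <- ncol(m) %/% 3L
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    codon_idx <- matrix(sample.int(ncod, bootstraps * ncod, replace = TRUE),
                        nrow = bootstraps)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    nt_idx <- matrix(0L, bootstraps, 3L * ncod)
    nt_idx[, seq(1, by = 3, length.out = ncod)] <- 3L * (codon_idx - 1L) + 1L
    nt_idx[, seq(2, by = 3, length.out = ncod)] <- 3L * (codon_idx - 1L) + 2L
    nt_idx[, seq(3, by = 3, length.out = ncod)] <- 3L * codon_idx
    reps <- .gtr_boot_dist(m, nt_idx, gamma_shape, max_dist)
    boot_trees <- lapply(reps, function(Db) {
      dimnames(Db) <- dimnames(D)
      ape::nj(as.dist(Db))
    })
    counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    supports <- round(100 * counts / bootstraps)
    supports[1L] <- NA  # root of the unrooted representation
    tree$node.label <- supports
  }
  if (!is.null(leaf_meta)) attr(tree, "leaf_meta") <- leaf_meta
  tree
}

# Internal nodes whose two children are both tips (cherries), as a list of
# tip-label pairs with the cherry node id.
find_cherries <- function(tree) {
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- list()
  for (node in names(kids)) {
    k <- kids[[node]]
    if (length(k) == 2 && all(k <= nt)) {
      out[[length(out) + 1]] <- list(node = as.integer(node),
                                     tips = tree$tip.label[k])
    }
  }
  out
}

#' Rescue unpaired genes that form cross-source cherries
#'
#' For every cherry (two-leaf sister clade) consisting of exactly one
#' UNPAIRED_A and one UNPAIRED_B leaf from the same species, the two pair
#' records are merged into a single IMPERFECT record flagged
#' `rescued_by_tree`.  All other records pass through unchanged and no leaf
#' participates in more than one rescue.  Bootstrap support is not required
#' by default; set `min_support` to demand a minimum cherry support.
#'
#' @param tree a gene tree from [build_tree()] whose tip labels are
#'   `<source>|<gene_id>`.
#' @param records pair records (after exclusion).
#' @param leaf_meta data frame mapping tip labels to genes; defaults to
#'   `attr(tree, "leaf_meta")`.  Needs columns `label`, `gene_id`,
#'   `source`, `species`.
#' @param set_a,set_b optional annotation sets used to recompute identity
#'   and lengths for the merged records.
#' @param min_support minimum bootstrap support (0-100) for a rescuing
#'   cherry; 0 (default) disables the check.
#' @param params [search_params()] for the identity computation.
#' @return updated pair records.
#' @export
rescue_unpaired <- function(tree, records, leaf_meta = attr(tree, "leaf_meta"),
                            set_a = NULL, set_b = NULL, min_support = 0,
                            params = search_params()) {
  if (is.null(leaf_meta))
    stop("rescue_unpaired needs leaf metadata (label, gene_id, source, species)",
         call. = FALSE)
  cherries <- find_cherries(tree)
  drop_rows <- integer()
  for (ch in cherries) {
    meta <- leaf_meta[match(ch$tips, leaf_meta$label), , drop = FALSE]
    if (any(is.na(meta$gene_id))) next
    if (!setequal(meta$source, c("A", "B"))) next
    if (length(unique(meta$species)) != 1) next
    ga <- meta$gene_id[meta$source == "A"]
    gb <- meta$gene_id[meta$source == "B"]
    ia <- which(records$category == "UNPAIRED_A" & records$member_a == ga)
    ib <- which(records$category == "UNPAIRED_B" & records$member_b == gb)
    if (length(ia) != 1 || length(ib) != 1) next
    if (min_support > 0 && !is.null(tree$node.label)) {
      sup <- tree$node.label[ch$node - length(tree$tip.label)]
      if (is.na(sup) || sup < min_support) next
    }
    records$member_b[ia] <- gb
    records$category[ia] <- "IMPERFECT"
    records$rescued_by_tree[ia] <- TRUE
    records$length_b[ia] <- records$length_b[ib]
    if (!is.null(set_a) && !is.null(set_b)) {
      sa <- record_seqs(set_a)[[ga]]
      sb <- record_seqs(set_b)[[gb]]
      st <- sw_align(sa, sb, params)
      records$identity[ia] <-
        if (st$aln_length > 0) 100 * st$matches / st$aln_length else NA_real_
      records$length_a[ia] <- nchar(sa)
      records$length_b[ia] <- nchar(sb)
    }
    records$length_ratio[ia] <-
      with(records[ia, ], pmax(length_a, length_b) / pmin(length_a, length_b))
    drop_rows <- c(drop_rows, ib)
  }
  if (length(drop_rows) > 0) records <- records[-drop_rows, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Root a gene tree with an outgroup
#'
#' Roots on the edge subtending the smallest clade containing all outgroup
#' leaves.  When the outgroup is not monophyletic in the unrooted tree, the
#' edge whose induced bipartition best agrees with the outgroup/ingroup
#' split (most leaves on the correct side) is chosen and a warning is
#' emitted.
#'
#' @param tree an `ape::phylo`.
#' @param outgroup_labels non-empty character vector of tip labels.
#' @return rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  if (length(outgroup_labels) == 0)
    stop("outgroup set is empty", call. = FALSE)
  missing_labels <- setdiff(outgroup_labels, tree$tip.label)
  if (length(missing_labels) > 0)
    stop("outgroup labels absent from tree: ",
         paste(missing_labels, collapse = ", "), call. = FALSE)
  nt <- length(tree$tip.label)
  og <- tree$tip.label %in% outgroup_labels
  if (all(og)) stop("outgroup contains every leaf", call. = FALSE)
  if (length(outgroup_labels) == 1 ||
      ape::is.monophyletic(tree, outgroup_labels)) {
    return(ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE))
  }
  warning("outgroup not monophyletic; rooting on the best-agreement edge",
          call. = FALSE)
  desc <- phangorn::Descendants(tree, type = "tips")
  best_edge <- NULL; best_score <- -1
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    side <- rep(FALSE, nt)
    side[desc[[child]]] <- TRUE
    agree <- sum(side & og) + sum(!side & !og)
    score <- max(agree, nt - agree)
    if (score > best_score) { best_score <- score; best_edge <- e }
  }
  child <- tree$edge[best_edge, 2]
  if (child <= nt) {
    ape::root(tree, outgroup = tree$tip.label[child], resolve.root = TRUE)
  } else {
    ape::root(tree, node = child, resolve.root = TRUE)
  }
}
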