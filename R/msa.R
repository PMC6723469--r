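#' Multiple alignment of a coding-sequence family
#'
#' Deterministic codon-aware progressive alignment, the internal reference
#' backend standing in for a general-purpose aligner.  A guide tree is built
#' by neighbor-joining on k-mer distances (k = 6, fractional shared 6-mer
#' count) and rooted at its midpoint; profiles are then merged post-order
#' with a global profile-profile alignment whose unit is the codon, so gaps
#' are always inserted in frame-preserving multiples of three.  Profile
#' columns are scored by expected match/mismatch score over the three codon
#' positions under the `params` scoring scheme.
#'
#' Inputs must be in-frame coding sequences (length divisible by 3); the
#' result is invariant to input order up to row order.
#'
#' @param seqs named character vector of >= 2 CDS.
#' @param params a [search_params()] supplying match/mismatch and gap costs.
#' @return a `codon_msa` object: list with `rows` (named gapped sequences,
#'   equal length) and `codon_frame = TRUE`.
#' @export
align_family <- function(seqs, params = search_params()) {
  if (length(seqs) < 2) stop("align_family requires >= 2 sequences",
                             call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names", call. = FALSE)
  validate_dna(seqs, "family sequences")
  if (any(nchar(seqs) %% 3L != 0L))
    stop("align_family expects in-frame CDS (lengths divisible by 3)",
         call. = FALSE)
  orig_order <- names(seqs)
  seqs <- seqs[order(names(seqs))]  # canonical order for determinism
  mats <- lapply(seqs, function(s) matrix(codon_split(s), nrow = 1))
  names(mats) <- names(seqs)
  go <- params$gap_open
  ge <- 3 * params$gap_extend  # per-codon extension

  merge_two <- function(m1, m2) {
    path <- .nw_profile(codon_profile(m1), codon_profile(m2), go, ge)
    n1 <- nrow(m1); n2 <- nrow(m2)
    out <- matrix("---", n1 + n2, length(path))
    i <- 0L; j <- 0L
    for (k in seq_along(path)) {
      mv <- path[k]
      if (mv == 0L) {
        i <- i + 1L; j <- j + 1L
        out[seq_len(n1), k] <- m1[, i]
        out[n1 + seq_len(n2), k] <- m2[, j]
      } else if (mv == 1L) {
        i <- i + 1L
        out[seq_len(n1), k] <- m1[, i]
      } else {
        j <- j + 1L
        out[n1 + seq_len(n2), k] <- m2[, j]
      }
    }
    rownames(out) <- c(rownames(m1), rownames(m2))
    out
  }
  for (k in seq_along(mats)) rownames(mats[[k]]) <- names(mats)[k]

  if (length(seqs) == 2) {
    aln <- merge_two(mats[[1]], mats[[2]])
  } else {
    d <- kmer_distance(seqs, k = 6L)
    guide <- phangorn::midpoint(ape::nj(as.dist(d)))
    aln <- merge_postorder(guide, mats, merge_two)
  }
  rows <- apply(aln, 1, paste, collapse = "")
  rows <- rows[orig_order]
  structure(list(rows = rows, codon_frame = TRUE), class = "codon_msa")
}

# Position-specific nucleotide frequency profile of a codon matrix:
# (#codon columns) x 12, positions 1..3 x letters A,C,G,T; gap rows
# contribute no mass, N spreads 0.25 over the four letters.
codon_profile <- function(m) {
  ncol_ <- ncol(m); nr <- nrow(m)
  prof <- matrix(0, ncol_, 12)
  for (p in 1:3) {
    ch <- substring(m, p, p)  # column-major over the matrix
    dim(ch) <- dim(m)
    for (a in 1:4) {
      prof[, (p - 1) * 4 + a] <- colSums(ch == DNA_LETTERS[a]) / nr
    }
    isn <- colSums(ch == "N") / nr
    if (any(isn > 0))
      for (a in 1:4) prof[, (p - 1) * 4 + a] <-
          prof[, (p - 1) * 4 + a] + 0.25 * isn
  }
  prof
}

kmer_distance <- function(seqs, k = 6L) {
  dss <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::oligonucleotideFrequency(dss, width = k)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  tot <- nchar(seqs) - k + 1L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sum(pmin(freq[i, ], freq[j, ])) / min(tot[i], tot[j])
      d[i, j] <- d[j, i] <- 1 - shared
    }
  }
  d
}

merge_postorder <- function(guide, mats, merge_two) {
  nt <- length(guide$tip.label)
  children <- split(guide$edge[, 2], guide$edge[, 1])
  rec <- function(node) {
    if (node <= nt) return(mats[[guide$tip.label[node]]])
    kids <- children[[as.character(node)]]
    acc <- rec(kids[1])
    for (kk in kids[-1]) acc <- merge_two(acc, rec(kk))
    acc
  }
  rec(nt + 1L)
}

#' @export
print.codon_msa <- function(x, ...) {
  cat(sprintf("codon_msa: %d sequences x %d columns (%d codons)\n",
              length(x$rows), nchar(x$rows[1]), nchar(x$rows[1]) %/% 3L))
  invisible(x)
}

#' Number of alignment columns
#' @param msa a `codon_msa`.
#' @return integer column count (nucleotides).
#' @export
msa_ncol <- function(msa) if (length(msa$rows) == 0) 0L else nchar(msa$rows[[1]])

# Alignment as a matrix of codon strings (rows x codon columns).
msa_codon_matrix <- function(msa) {
  t(vapply(msa$rows, function(r) codon_split(r),
           character(msa_ncol(msa) %/% 3L)))
}

#' Trimming parameters for conserved codon blocks
#'
#' Simplified block rule over codon columns, mirroring codon-mode conserved
#' block selection: `b2` is the minimum fraction of non-gap rows that the
#' most frequent codon of a column must reach for the column to count as
#' conserved; `b4` is the minimum length (in codons) of a retained block;
#' `b5` is the maximum fraction of gap rows allowed in a column.
#'
#' @param b2 minimum majority-codon fraction (default 0.5).
#' @param b4 minimum block length in codons (default 5).
#' @param b5 maximum gap fraction (default 0.5).
#' @return a `trim_params` list.
#' @export
trim_params <- function(b2 = 0.5, b4 = 5L, b5 = 0.5) {
  stopifnot(b2 > 0, b2 <= 1, b4 >= 1, b5 > 0, b5 <= 1)
  structure(list(b2 = b2, b4 = as.integer(b4), b5 = b5),
            class = "trim_params")
}

#' Trim an alignment to conserved codon blocks
#'
#' A codon column is good when its gap fraction is at most `b5` and its most
#' frequent codon occurs in at least fraction `b2` of the non-gap rows.
#' Maximal runs of good columns shorter than `b4` codons are discarded; the
#' surviving runs are concatenated in order.
#'
#' @param msa a `codon_msa` (codon frame required).
#' @param params a [trim_params()].
#' @return trimmed `codon_msa`; kept codon-column ranges are attached as
#'   `attr(, "kept_blocks")` (data frame `from`, `to`, 1-based codons).
#' @export
trim_codon_blocks <- function(msa, params = trim_params()) {
  if (!inherits(msa, "codon_msa") || !isTRUE(msa$codon_frame))
    stop("trim_codon_blocks requires a codon-frame alignment", call. = FALSE)
  cm <- msa_codon_matrix(msa)
  good <- codon_column_good(cm, params)
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_run <- r$values & r$lengths >= params$b4
  if (!any(keep_run))
    stop("no codon blocks survive trimming; relax b2/b4/b5", call. = FALSE)
  blocks <- data.frame(from = starts[keep_run], to = ends[keep_run])
  keep_cols <- unlist(mapply(seq, blocks$from, blocks$to, SIMPLIFY = FALSE))
  rows <- apply(cm[, keep_cols, drop = FALSE], 1, paste, collapse = "")
  out <- structure(list(rows = setNames(rows, names(msa$rows)),
                        codon_frame = TRUE), class = "codon_msa")
  attr(out, "kept_blocks") <- blocks
  out
}

# The per-column rule, exposed for reuse: gap fraction <= b5 and majority
# codon >= b2 of non-gap rows.
codon_column_good <- function(codon_matrix, params) {
  apply(codon_matrix, 2, function(col) {
    isgap <- col == "---"
    if (mean(isgap) > params$b5) return(FALSE)
    ng <- col[!isgap]
    if (length(ng) == 0) return(FALSE)
    max(table(ng)) >= params$b2 * length(ng)
  })
}

#' Write an alignment as aligned FASTA
#' @param msa a `codon_msa`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(msa$rows), path)
  invisible(path)
}

#' Write kept-block ranges from a trimmed alignment
#' @param trimmed result of [trim_codon_blocks()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_trim_report <- function(trimmed, path) {
  blocks <- attr(trimmed, "kept_blocks")
  write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
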