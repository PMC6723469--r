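#' Reciprocal best hits between two gene sets
#'
#' Computes optimal local alignments for every cross-source pair inside one
#' (species, enzyme family) and returns the pairs `(a, b)` where `b` is
#' `a`'s best-scoring hit in `set_b` and `a` is `b`'s best in `set_a`.
#' Best means highest bit score; ties are broken by lower E-value, then
#' higher percent identity, then the lexicographically smallest partner id,
#' so the result is deterministic.  Each gene appears in at most one pair.
#'
#' @param set_a,set_b annotation sets from sources A and B (one species and
#'   enzyme family each).
#' @param params a [search_params()]; the default mirrors an unrestricted
#'   ("default blastn") comparison, i.e. no E-value filtering is applied
#'   beyond mutual-best ranking.
#' @return data frame with columns `a`, `b`, `identity`, `score`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, params = search_params()) {
  empty <- data.frame(a = character(), b = character(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)
  seqs_a <- record_seqs(set_a)
  seqs_b <- record_seqs(set_b)
  na <- length(seqs_a); nb <- length(seqs_b)
  enc_a <- lapply(seqs_a, encode_dna)
  enc_b <- lapply(seqs_b, encode_dna)
  score <- .sw_score_matrix(enc_a, enc_b, params$match, params$mismatch,
                            params$gap_open, params$gap_extend)
  dimnames(score) <- list(names(seqs_a), names(seqs_b))
  # identity computed lazily (traceback is costly): only for score ties and
  # for the reported mutual pairs
  ident <- matrix(NA_real_, na, nb, dimnames = dimnames(score))
  identity_at <- function(i, j) {
    if (is.na(ident[i, j])) {
      st <- .sw_traceback(enc_a[[i]], enc_b[[j]], params$match,
                          params$mismatch, params$gap_open,
                          params$gap_extend)
      ident[i, j] <<- if (st$aln_length > 0)
        100 * st$matches / st$aln_length else 0
    }
    ident[i, j]
  }
  # ordering: higher score (== higher bit score, lower evalue), then higher
  # identity, then lexicographically smaller partner id
  pick_best <- function(sc, ids, get_id) {
    top <- which(sc == max(sc))
    if (length(top) > 1) {
      idn <- vapply(top, get_id, 0)
      ord <- order(-idn, ids[top])
      top <- top[ord]
    }
    top[1L]
  }
  best_for_a <- vapply(seq_len(na), function(i)
    pick_best(score[i, ], colnames(score), function(j) identity_at(i, j)),
    0L)
  best_for_b <- vapply(seq_len(nb), function(j)
    pick_best(score[, j], rownames(score), function(i) identity_at(i, j)),
    0L)
  mutual_a <- which(best_for_b[best_for_a] == seq_len(na))
  if (length(mutual_a) == 0) return(empty)
  out <- data.frame(a = rownames(score)[mutual_a],
                    b = colnames(score)[best_for_a[mutual_a]],
                    stringsAsFactors = FALSE)
  out$identity <- vapply(seq_along(mutual_a), function(k)
    identity_at(mutual_a[k], best_for_a[mutual_a[k]]), 0)
  out$score <- score[cbind(mutual_a, best_for_a[mutual_a])]
  out <- out[order(out$a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_pair_records <- function(enzyme, species, member_a, member_b, category,
                             identity, length_a, length_b, rescued) {
  len_ratio <- ifelse(is.na(length_a) | is.na(length_b), NA_real_,
                      pmax(length_a, length_b) / pmin(length_a, length_b))
  data.frame(enzyme = enzyme, species = species,
             member_a = member_a, member_b = member_b, category = category,
             identity = identity, length_a = length_a, length_b = length_b,
             length_ratio = len_ratio, rescued_by_tree = rescued,
             stringsAsFactors = FALSE)
}

#' Classify reciprocal best hits as perfect or imperfect pairs
#'
#' A pair is PERFECT if and only if the two coding sequences are identical
#' strings (the bidirectional reading of "100% identity over 100% of the
#' length"); every other reciprocal best hit is IMPERFECT, with percent
#' identity and the length ratio (longer/shorter) recorded.  Genes without a
#' reciprocal partner become UNPAIRED_A / UNPAIRED_B.
#'
#' @param rbh result of [reciprocal_best_hits()] on the same sets.
#' @param set_a,set_b the annotation sets the RBH was computed from.
#' @param enzyme,species labels stored on the records (defaults taken from
#'   the sets when unambiguous).
#' @return a pair-record data frame with columns `enzyme`, `species`,
#'   `member_a`, `member_b`, `category`, `identity`, `length_a`, `length_b`,
#'   `length_ratio`, `rescued_by_tree`.
#' @export
classify_pairs <- function(rbh, set_a, set_b,
                           enzyme = NA_character_, species = NA_character_) {
  if (is.na(species)) {
    sp <- unique(c(set_a$species, set_b$species))
    species <- if (length(sp) == 1) sp else NA_character_
  }
  seqs_a <- record_seqs(set_a)
  seqs_b <- record_seqs(set_b)
  recs <- list()
  if (nrow(rbh) > 0) {
    la <- nchar(seqs_a[rbh$a]); lb <- nchar(seqs_b[rbh$b])
    perfect <- unname(seqs_a[rbh$a] == seqs_b[rbh$b])
    recs[[length(recs) + 1]] <- new_pair_records(
      enzyme, species, rbh$a, rbh$b,
      ifelse(perfect, "PERFECT", "IMPERFECT"),
      ifelse(perfect, 100, rbh$identity), unname(la), unname(lb), FALSE)
  }
  un_a <- setdiff(names(seqs_a), rbh$a)
  if (length(un_a) > 0)
    recs[[length(recs) + 1]] <- new_pair_records(
      enzyme, species, un_a, NA_character_, "UNPAIRED_A", NA_real_,
      unname(nchar(seqs_a[un_a])), NA_real_, FALSE)
  un_b <- setdiff(names(seqs_b), rbh$b)
  if (length(un_b) > 0)
    recs[[length(recs) + 1]] <- new_pair_records(
      enzyme, species, NA_character_, un_b, "UNPAIRED_B", NA_real_,
      NA_real_, unname(nchar(seqs_b[un_b])), FALSE)
  if (length(recs) == 0)
    return(new_pair_records(character(), character(), character(),
                            character(), character(), numeric(), numeric(),
                            numeric(), logical()))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Exclude unpaired annotations that duplicate another gene in-source
#'
#' Any UNPAIRED record whose coding sequence is string-identical to the
#' sequence of a different gene in the same (species, source) annotation set
#' is recategorised as EXCLUDED_REDUNDANT; all other records pass through
#' unchanged.
#'
#' @param records pair records from [classify_pairs()].
#' @param set_a,set_b the full per-source annotation sets used for the
#'   within-source identity check.
#' @return updated pair records.
#' @export
exclude_redundant_unpaired <- function(records, set_a, set_b) {
  has_twin <- function(gene_id, set) {
    i <- match(gene_id, set$gene_id)
    if (is.na(i)) return(FALSE)
    same <- set$species == set$species[i] & set$gene_id != gene_id
    any(set$sequence[same] == set$sequence[i])
  }
  ia <- which(records$category == "UNPAIRED_A")
  for (i in ia) {
    if (has_twin(records$member_a[i], set_a))
      records$category[i] <- "EXCLUDED_REDUNDANT"
  }
  ib <- which(records$category == "UNPAIRED_B")
  for (i in ib) {
    if (has_twin(records$member_b[i], set_b))
      records$category[i] <- "EXCLUDED_REDUNDANT"
  }
  records
}

#' Merge pair records into the final gene set
#'
#' Keeps one annotation per concordant pair, preferring the source-A (NCBI
#' pipeline) member of every PERFECT/IMPERFECT pair, plus all remaining
#' unpaired genes from either source.  EXCLUDED_REDUNDANT records contribute
#' nothing.
#'
#' @param records pair records after exclusion (and tree rescue, if run).
#' @return data frame with `enzyme`, `species`, `gene_id`, `source`.
#' @export
merge_final <- function(records) {
  paired <- records$category %in% c("PERFECT", "IMPERFECT")
  un_a <- records$category == "UNPAIRED_A"
  un_b <- records$category == "UNPAIRED_B"
  out <- rbind(
    data.frame(enzyme = records$enzyme[paired],
               species = records$species[paired],
               gene_id = records$member_a[paired],
               source = rep("A", sum(paired)), stringsAsFactors = FALSE),
    data.frame(enzyme = records$enzyme[un_a],
               species = records$species[un_a],
               gene_id = records$member_a[un_a],
               source = rep("A", sum(un_a)), stringsAsFactors = FALSE),
    data.frame(enzyme = records$enzyme[un_b],
               species = records$species[un_b],
               gene_id = records$member_b[un_b],
               source = rep("B", sum(un_b)), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Write a pair-record table
#'
#' @param records pair records.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
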