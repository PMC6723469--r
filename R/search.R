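#' Scoring parameters for the relaxed local similarity search
#'
#' Defaults mirror a relaxed nucleotide search: match +1, mismatch -1,
#' E-value cutoff 1e-50.  Gap costs are not pinned by that parameterisation;
#' the defaults (open 5, extend 2) are conventional for +/-1 nucleotide
#' scoring and configurable.  A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open,gap_extend affine gap costs (positive).
#' @param evalue_max E-value threshold for reported hits.
#' @return a `search_params` list, with the Karlin-Altschul `lambda` and `K`
#'   for the scoring scheme attached.
#' @export
search_params <- function(match = 1, mismatch = -1, gap_open = 5,
                          gap_extend = 2, evalue_max = 1e-50) {
  stopifnot(match > 0, mismatch < 0, evalue_max > 0,
            gap_open >= 0, gap_extend > 0)
  ka <- karlin_altschul(match, mismatch)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, evalue_max = evalue_max,
                 lambda = ka$lambda, K = ka$K),
            class = "search_params")
}

#' Karlin-Altschul parameters for a match/mismatch scoring scheme
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` under uniform base frequencies
#' (for +1/-1 scoring, `lambda = log 3` exactly).  `K` is fixed at 0.1, a
#' documented order-of-magnitude approximation: the ungapped statistics are
#' applied to gapped scores and downstream decisions depend only on
#' thresholding at very small E-values, which is insensitive to `K`.
#'
#' @param match,mismatch scoring scheme.
#' @return list with `lambda` and `K`.
#' @export
karlin_altschul <- function(match = 1, mismatch = -1) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lambda <- uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  list(lambda = lambda, K = 0.1)
}

# E-value of a local alignment score S for query length m against a subject
# database of total length n: E = K * m * n * exp(-lambda * S).
evalue_from_score <- function(score, m, n, params) {
  params$K * as.numeric(m) * as.numeric(n) * exp(-params$lambda * score)
}

bit_score <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman alignment with affine gaps under the scoring scheme in
#' `params`.  N scores zero against every base and counts as a mismatch in
#' the identity summary.
#'
#' @param a,b nucleotide strings.
#' @param params a [search_params()].
#' @return list with `score`, `matches`, `mismatches`, `gap_opens`,
#'   `gap_residues`, `aln_length`, and 1-based endpoints `q_start`, `q_end`,
#'   `s_start`, `s_end`.
#' @export
sw_align <- function(a, b, params = search_params()) {
  validate_dna(a, "query"); validate_dna(b, "subject")
  .sw_traceback(encode_dna(a), encode_dna(b), params$match, params$mismatch,
                params$gap_open, params$gap_extend)
}

#' Local similarity search of queries against subjects
#'
#' The internal reference backend computes optimal local alignments under
#' the scoring scheme for every query-subject pair (single best HSP per
#' pair) and converts scores to E-values with Karlin-Altschul statistics
#' over the pooled search space (query length x total subject length).
#' Hits with E-value above `params$evalue_max` are discarded.
#'
#' @param queries,subjects named character vectors of nucleotide sequences.
#' @param params a [search_params()].
#' @param stats compute per-hit alignment summaries (identity, endpoints)
#'   by traceback; disable when only scores/E-values are needed.
#' @return data frame in blast tabular layout: `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`, plus
#'   `score` and `query_coverage`.
#' @export
local_search <- function(queries, subjects, params = search_params(),
                         stats = TRUE) {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(),
                      alignment_length = integer(), mismatches = integer(),
                      gap_opens = integer(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), evalue = numeric(),
                      bit_score = numeric(), score = numeric(),
                      query_coverage = numeric(), stringsAsFactors = FALSE)
  if (length(queries) == 0 || length(subjects) == 0) return(empty)
  validate_dna(queries, "queries"); validate_dna(subjects, "subjects")
  short <- nchar(queries) < 50
  if (any(short))
    warning(sprintf("%d query sequence(s) shorter than 50 nt", sum(short)),
            call. = FALSE)
  qenc <- lapply(queries, encode_dna)
  senc <- lapply(subjects, encode_dna)
  scores <- .sw_score_matrix(qenc, senc, params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
  space_n <- sum(nchar(subjects))
  rows <- vector("list", 64)
  k <- 0
  for (i in seq_along(queries)) {
    ev <- evalue_from_score(scores[i, ], nchar(queries[i]), space_n, params)
    for (j in which(ev <= params$evalue_max)) {
      if (stats) {
        st <- .sw_traceback(qenc[[i]], senc[[j]], params$match,
                            params$mismatch, params$gap_open,
                            params$gap_extend)
      } else {
        st <- list(score = scores[i, j], matches = NA_integer_,
                   mismatches = NA_integer_, gap_opens = NA_integer_,
                   aln_length = NA_integer_, q_start = NA_integer_,
                   q_end = NA_integer_, s_start = NA_integer_,
                   s_end = NA_integer_)
      }
      k <- k + 1
      if (k > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[k]] <- data.frame(
        query_id = names(queries)[i], subject_id = names(subjects)[j],
        percent_identity = 100 * st$matches / st$aln_length,
        alignment_length = st$aln_length, mismatches = st$mismatches,
        gap_opens = st$gap_opens, q_start = st$q_start, q_end = st$q_end,
        s_start = st$s_start, s_end = st$s_end, evalue = ev[j],
        bit_score = bit_score(st$score, params), score = st$score,
        query_coverage = (st$q_end - st$q_start + 1) / nchar(queries[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0) return(empty)
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Write a hit table in 12-column blast tabular format
#'
#' @param hits result of [local_search()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bit_score")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Seed queries for one enzyme
#'
#' @param enzyme one of [FBP_ENZYMES].
#' @param seed_queries named character vector of seed CDS (>= 1).
#' @param kegg_code optional KEGG orthology label.
#' @return an `enzyme_spec` list.
#' @export
enzyme_spec <- function(enzyme, seed_queries,
                        kegg_code = FBP_KEGG_CODES[[enzyme]] %||% "") {
  enzyme <- match.arg(enzyme, FBP_ENZYMES)
  if (length(seed_queries) < 1)
    stop("enzyme_spec requires at least one seed query", call. = FALSE)
  if (is.null(names(seed_queries)))
    names(seed_queries) <- paste0(enzyme, "_seed", seq_along(seed_queries))
  structure(list(enzyme = enzyme, seed_queries = seed_queries,
                 kegg_code = kegg_code), class = "enzyme_spec")
}

#' Identify enzyme homologs in a normalized annotation set
#'
#' Runs the relaxed local search of every enzyme's seed queries against the
#' annotation and assigns each gene with at least one passing hit to the
#' single enzyme whose seeds give its best bit score (ties broken by enzyme
#' order in [FBP_ENZYMES]).  The CYP75 pair F3pH/F3p5pH is additionally
#' reported as a merged set for joint downstream analysis.
#'
#' @param specs list of [enzyme_spec()] objects.
#' @param records normalized annotation set (deduplicated, CDS inferred).
#' @param params a [search_params()].
#' @return list with `assignments` (data frame gene_id, enzyme, bit_score),
#'   `sets` (list of gene_id vectors per enzyme) and `cyp75` (merged
#'   F3pH + F3p5pH gene ids).
#' @export
identify_homologs <- function(specs, records, params = search_params()) {
  validate_annotation_set(records)
  subjects <- record_seqs(records)
  best <- data.frame(gene_id = character(), enzyme = character(),
                     bit_score = numeric(), stringsAsFactors = FALSE)
  for (spec in specs) {
    hits <- suppressWarnings(
      local_search(spec$seed_queries, subjects, params, stats = FALSE))
    if (nrow(hits) == 0) next
    top <- vapply(split(hits$bit_score, hits$subject_id), max, 0)
    best <- rbind(best, data.frame(gene_id = names(top),
                                   enzyme = spec$enzyme, bit_score = top,
                                   stringsAsFactors = FALSE))
  }
  if (nrow(best) > 0) {
    best$enzyme_rank <- match(best$enzyme, FBP_ENZYMES)
    best <- best[order(best$gene_id, -best$bit_score, best$enzyme_rank), ]
    best <- best[!duplicated(best$gene_id), ]
    best$enzyme_rank <- NULL
    best <- best[order(match(best$gene_id, records$gene_id)), ]
    rownames(best) <- NULL
  }
  sets <- lapply(setNames(FBP_ENZYMES, FBP_ENZYMES), function(e)
    best$gene_id[best$enzyme == e])
  list(assignments = best, sets = sets,
       cyp75 = c(sets$F3pH, sets$F3p5pH))
}
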