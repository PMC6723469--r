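#' Construct an annotation record set
#'
#' An annotation set is a plain `data.frame` with one row per annotated
#' transcript/CDS and columns `gene_id`, `locus_id`, `transcript_id`,
#' `species`, `source` (`"A"` for NCBI-style pipelines, `"B"` for
#' genome-specific pipelines), `sequence`, and `is_cds` (whether the
#' sequence is already a coding sequence or may still include UTRs).
#'
#' @param gene_id,locus_id,transcript_id,species,source,sequence,is_cds
#'   vectors recycled to a common length.
#' @return a validated annotation set `data.frame`.
#' @export
annotation_set <- function(gene_id, locus_id, transcript_id = gene_id,
                           species, source, sequence, is_cds = TRUE) {
  df <- data.frame(gene_id = as.character(gene_id),
                   locus_id = as.character(locus_id),
                   transcript_id = as.character(transcript_id),
                   species = as.character(species),
                   source = as.character(source),
                   sequence = toupper(as.character(sequence)),
                   is_cds = as.logical(is_cds),
                   stringsAsFactors = FALSE)
  validate_annotation_set(df)
  df
}

#' Validate an annotation set
#'
#' Checks the structural invariants: required columns, non-empty sequences
#' over the DNA alphabet, and gene ids unique within (species, source).
#'
#' @param records annotation set data frame.
#' @return the records, invisibly.
#' @export
validate_annotation_set <- function(records) {
  need <- c("gene_id", "locus_id", "transcript_id", "species", "source",
            "sequence", "is_cds")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("annotation set is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0) return(invisible(records))
  if (any(nchar(records$sequence) < 1))
    stop("annotation set contains empty sequences", call. = FALSE)
  validate_dna(setNames(records$sequence, records$gene_id), "annotation set")
  key <- paste(records$species, records$source, records$gene_id)
  if (anyDuplicated(key))
    stop("gene_id values are not unique within (species, source)",
         call. = FALSE)
  invisible(records)
}

#' Describe how a source encodes transcript variants
#'
#' @param name label for the source.
#' @param variant_policy one of `"prefiltered_primary"` (the source already
#'   holds one primary transcript per locus), `"longest_per_locus"` (keep
#'   the longest sequence per locus, locus parsed from identifiers), or
#'   `"longest_per_locus_feature_table"` (same rule, loci resolved from a
#'   feature table).
#' @return a `source_dialect` list.
#' @export
source_dialect <- function(name,
                           variant_policy = c("longest_per_locus",
                                              "prefiltered_primary",
                                              "longest_per_locus_feature_table")) {
  variant_policy <- match.arg(variant_policy)
  structure(list(name = name, variant_policy = variant_policy),
            class = "source_dialect")
}

# Resolve locus ids without a feature table: strip one trailing ".<int>"
# version/isoform suffix from the transcript id.
default_locus_rule <- function(transcript_id) {
  sub("\\.[0-9]+$", "", transcript_id)
}

read_feature_map <- function(feature_path) {
  if (grepl("\\.gff3?$", feature_path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 feature tables requires the rtracklayer package",
           call. = FALSE)
    gff <- rtracklayer::import(feature_path)
    mrna <- gff[gff$type %in% c("mRNA", "transcript")]
    parent <- vapply(mrna$Parent, function(p)
      if (length(p) > 0) as.character(p[[1]]) else NA_character_, "")
    data.frame(transcript_id = as.character(mrna$ID),
               locus_id = parent, stringsAsFactors = FALSE)
  } else {
    tab <- read.table(feature_path, header = FALSE, sep = "\t",
                      col.names = c("transcript_id", "locus_id"),
                      stringsAsFactors = FALSE, comment.char = "#")
    tab
  }
}

#' Parse one annotation source into an annotation set
#'
#' Reads a nucleotide FASTA of annotated transcripts or coding sequences and
#' resolves each entry to a locus, either through a feature table (GFF3 with
#' mRNA->gene `Parent` links, or a two-column tab file of
#' `transcript_id<TAB>locus_id`) or through the identifier rule of stripping
#' a trailing `.<integer>` isoform suffix.
#'
#' @param cds_path FASTA file of sequences; entry names become transcript and
#'   gene ids.
#' @param species species tag.
#' @param source `"A"` or `"B"`.
#' @param dialect a [source_dialect()].
#' @param feature_path optional GFF3 or tab feature table; required when the
#'   dialect policy is `"longest_per_locus_feature_table"`.
#' @param is_cds whether the sequences are already coding sequences
#'   (`FALSE` when they may still carry UTRs).
#' @return an annotation set data frame.
#' @export
parse_annotation_set <- function(cds_path, species, source,
                                 dialect = source_dialect(source),
                                 feature_path = NULL, is_cds = TRUE) {
  if (!file.exists(cds_path))
    stop("cannot read FASTA file: ", cds_path, call. = FALSE)
  if (dialect$variant_policy == "longest_per_locus_feature_table" &&
      is.null(feature_path))
    stop("dialect requires a feature table but feature_path is missing",
         call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(cds_path)
  if (length(seqs) == 0) {
    return(annotation_set(character(), character(), character(),
                          character(), character(), character(), logical()))
  }
  ids <- sub("\\s.*$", "", names(seqs))  # first whitespace-delimited token
  sequence <- as.character(seqs)
  if (is.null(feature_path)) {
    locus <- default_locus_rule(ids)
  } else {
    map <- read_feature_map(feature_path)
    locus <- map$locus_id[match(ids, map$transcript_id)]
    absent <- is.na(locus)
    if (any(absent)) {
      warning(sprintf("%d FASTA entries absent from feature table; using transcript_id as locus_id",
                      sum(absent)), call. = FALSE)
      locus[absent] <- ids[absent]
    }
  }
  annotation_set(gene_id = ids, locus_id = locus, transcript_id = ids,
                 species = species, source = source, sequence = sequence,
                 is_cds = is_cds)
}

#' Find the longest open reading frame of a transcript
#'
#' Scans the forward strand in all three frames for ATG-initiated open
#' reading frames under the standard genetic code.  An ORF runs from an ATG
#' to the first in-frame stop codon (stop included); an ORF with no stop
#' before the end of the sequence is kept as an open 3' ORF truncated to a
#' codon multiple.  Codons containing N are treated as non-stop.  Ties in
#' length are broken by frame (0, 1, 2) and then by leftmost start.
#'
#' @param seq a nucleotide string over A,C,G,T,N.
#' @return `NULL` if no ORF exists, otherwise a list with `cds`, `start`,
#'   `end` (1-based nucleotide coordinates) and `frame` (0..2).
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  validate_dna(seq, "transcript")
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1) next
    starts <- frame + seq(1L, by = 3L, length.out = ncod)
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    # segment index: which inter-stop segment each codon belongs to
    seg <- cumsum(c(0L, head(is_stop, -1L)))
    for (s in unique(seg[is_atg])) {
      in_seg <- seg == s
      first_atg <- which(is_atg & in_seg)[1L]
      stop_here <- which(is_stop & in_seg)
      last <- if (length(stop_here) > 0) stop_here[1L] else max(which(in_seg))
      len <- (last - first_atg + 1L) * 3L
      if (is.null(best) || len > best$len) {
        best <- list(len = len, frame = frame,
                     start = starts[first_atg], end = starts[last] + 2L)
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(cds = substring(seq, best$start, best$end),
       start = best$start, end = best$end, frame = best$frame)
}

#' Infer coding sequences from transcripts
#'
#' Replaces the sequence of every record with `is_cds = FALSE` by its longest
#' open reading frame (see [longest_orf()]), rejecting records whose longest
#' ORF is shorter than `min_len` nucleotides.  Records already flagged as
#' CDS pass through unchanged.
#'
#' @param records annotation set.
#' @param min_len minimum accepted coding-sequence length in nucleotides
#'   (default 300).
#' @return the accepted records with `is_cds = TRUE` and sequences replaced;
#'   rejected records are attached as `attr(, "rejected")`.
#' @export
infer_cds <- function(records, min_len = 300L) {
  validate_annotation_set(records)
  if (nrow(records) == 0) {
    attr(records, "rejected") <- records
    return(records)
  }
  keep <- rep(TRUE, nrow(records))
  for (i in which(!records$is_cds)) {
    orf <- longest_orf(records$sequence[i])
    if (is.null(orf) || nchar(orf$cds) < min_len) {
      keep[i] <- FALSE
    } else {
      records$sequence[i] <- orf$cds
      records$is_cds[i] <- TRUE
    }
  }
  rejected <- records[!keep, , drop = FALSE]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Collapse transcript variants to one representative per locus
#'
#' Under the `"prefiltered_primary"` policy the input passes through
#' unchanged.  Under the longest-per-locus policies, the longest sequence at
#' each locus is kept; equal lengths are broken by the lexicographically
#' smallest transcript id, so the operation is deterministic and idempotent.
#'
#' @param records annotation set sharing one (species, source).
#' @param dialect a [source_dialect()].
#' @return subset of `records` with at most one row per locus.
#' @export
dedup_variants <- function(records, dialect = source_dialect("default")) {
  validate_annotation_set(records)
  if (nrow(records) == 0) return(records)
  if (length(unique(records$species)) > 1 ||
      length(unique(records$source)) > 1)
    stop("dedup_variants expects records from a single (species, source)",
         call. = FALSE)
  if (dialect$variant_policy == "prefiltered_primary") return(records)
  len <- nchar(records$sequence)
  ord <- order(records$locus_id, -len, records$transcript_id)
  sorted <- records[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$locus_id), , drop = FALSE]
  out <- out[order(match(out$gene_id, records$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize one annotation source
#'
#' Applies the full per-source filter chain: CDS inference with the
#' `min_len` floor, the minimum-length filter for records already annotated
#' as CDS, variant deduplication per the source dialect, and removal of
#' records whose deduplicated CDS is more than `max_n_frac` ambiguous (N)
#' bases.
#'
#' @inheritParams dedup_variants
#' @inheritParams infer_cds
#' @param max_n_frac maximum tolerated fraction of N in a kept CDS.
#' @return normalized annotation set.
#' @export
normalize_annotations <- function(records, dialect = source_dialect("default"),
                                  min_len = 300L, max_n_frac = 0.1) {
  records <- infer_cds(records, min_len = min_len)
  records <- records[nchar(records$sequence) >= min_len, , drop = FALSE]
  records <- dedup_variants(records, dialect)
  if (nrow(records) > 0) {
    n_frac <- vapply(records$sequence, function(s) {
      mean(strsplit(s, "")[[1]] == "N")
    }, 0, USE.NAMES = FALSE)
    drop <- n_frac > max_n_frac
    if (any(drop)) {
      warning(sprintf("dropping %d record(s) with > %.0f%% N bases",
                      sum(drop), 100 * max_n_frac), call. = FALSE)
      records <- records[!drop, , drop = FALSE]
    }
  }
  rownames(records) <- NULL
  records
}

#' Write an annotation set as FASTA
#'
#' @param records annotation set.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_fasta <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(setNames(records$sequence,
                                            records$gene_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Record manifest for an annotation set
#'
#' @param records annotation set.
#' @return data frame with gene_id, locus_id, species, source, length.
#' @export
record_manifest <- function(records) {
  data.frame(gene_id = records$gene_id, locus_id = records$locus_id,
             species = records$species, source = records$source,
             length = nchar(records$sequence), stringsAsFactors = FALSE)
}
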