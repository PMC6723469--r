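# Internal helpers shared across modules.

# Encode a DNA string as integers A=0, C=1, G=2, T=3, other (N) = 4.
encode_dna <- function(seq) {
  v <- utf8ToInt(toupper(seq))
  out <- integer(length(v))
  out[] <- 4L
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

DNA_LETTERS <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

validate_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", toupper(seq))
  if (any(bad)) {
    offender <- names(seq)[bad][1L]
    where <- if (is.null(offender) || is.na(offender)) ""
    else sprintf(" (first offender: %s)", offender)
    stop(sprintf("%s contains characters outside {A,C,G,T,N}%s", what, where),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Split a CDS string into codon triplets.
codon_split <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Named character vector of sequences from an annotation set data frame.
record_seqs <- function(records) {
  setNames(records$sequence, records$gene_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric as 1:n; this does not
sample_one <- function(x) x[sample.int(length(x), 1L)]
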