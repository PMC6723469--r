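#' Concordance report over pair records
#'
#' Totals per annotation source and counts per category, with the
#' accounting identities `totals_a = perfect + imperfect + unpaired_a +
#' excluded_a` (and the source-B analog) and `shared_pairs = perfect +
#' imperfect` guaranteed by construction and re-checked before returning.
#'
#' @param records pair records (classification, exclusion and rescue done).
#' @return a `concordance_report` list with fields `totals_a`, `totals_b`,
#'   `shared_pairs`, `perfect`, `imperfect`, `unpaired_a`, `unpaired_b`,
#'   `excluded_a`, `excluded_b`.
#' @export
concordance_report <- function(records) {
  cat_ <- records$category
  perfect <- sum(cat_ == "PERFECT")
  imperfect <- sum(cat_ == "IMPERFECT")
  unpaired_a <- sum(cat_ == "UNPAIRED_A")
  unpaired_b <- sum(cat_ == "UNPAIRED_B")
  excluded_a <- sum(cat_ == "EXCLUDED_REDUNDANT" & !is.na(records$member_a))
  excluded_b <- sum(cat_ == "EXCLUDED_REDUNDANT" & !is.na(records$member_b))
  rep_ <- list(totals_a = perfect + imperfect + unpaired_a + excluded_a,
               totals_b = perfect + imperfect + unpaired_b + excluded_b,
               shared_pairs = perfect + imperfect,
               perfect = perfect, imperfect = imperfect,
               unpaired_a = unpaired_a, unpaired_b = unpaired_b,
               excluded_a = excluded_a, excluded_b = excluded_b)
  stopifnot(rep_$totals_a == rep_$perfect + rep_$imperfect +
              rep_$unpaired_a + rep_$excluded_a,
            rep_$totals_b == rep_$perfect + rep_$imperfect +
              rep_$unpaired_b + rep_$excluded_b,
            rep_$shared_pairs == rep_$perfect + rep_$imperfect)
  structure(rep_, class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Annotation concordance\n",
    "  source A total: %d   source B total: %d\n",
    "  shared pairs:   %d (perfect %d, imperfect %d)\n",
    "  unpaired:       A %d, B %d\n",
    "  excluded (redundant): A %d, B %d\n"),
    x$totals_a, x$totals_b, x$shared_pairs, x$perfect, x$imperfect,
    x$unpaired_a, x$unpaired_b, x$excluded_a, x$excluded_b))
  invisible(x)
}

#' Serialize a concordance report
#' @param report a `concordance_report`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_concordance_report <- function(report, path) {
  df <- data.frame(field = names(unclass(report)),
                   value = unlist(report, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-enzyme, per-species copy-number matrix
#'
#' Counts homologs per (enzyme, species, source), flags cells where the two
#' sources disagree and cells where a source reports zero copies, and adds
#' per-enzyme and per-species marginal sums.
#'
#' @param genes_a,genes_b data frames with columns `enzyme`, `species`,
#'   `gene_id` for sources A and B (e.g. expanded from
#'   [identify_homologs()] assignments).
#' @param species optional character vector fixing species order.
#' @return a `copy_number_matrix` list: `counts` (enzyme x species x
#'   source array), `discrepancy` and `zero` (enzyme x species logical
#'   matrices), `enzyme_totals`, `species_totals` (per source).
#' @export
copy_number_matrix <- function(genes_a, genes_b, species = NULL) {
  species <- species %||% sort(unique(c(genes_a$species, genes_b$species)))
  enz <- FBP_ENZYMES
  counts <- array(0L, dim = c(length(enz), length(species), 2),
                  dimnames = list(enzyme = enz, species = species,
                                  source = c("A", "B")))
  tab <- function(g) table(factor(g$enzyme, levels = enz),
                           factor(g$species, levels = species))
  counts[, , "A"] <- as.integer(tab(genes_a))
  counts[, , "B"] <- as.integer(tab(genes_b))
  discrepancy <- counts[, , "A"] != counts[, , "B"]
  zero <- counts[, , "A"] == 0L | counts[, , "B"] == 0L
  structure(list(counts = counts, discrepancy = discrepancy, zero = zero,
                 enzyme_totals = apply(counts, c(1, 3), sum),
                 species_totals = apply(counts, c(2, 3), sum)),
            class = "copy_number_matrix")
}

#' @export
print.copy_number_matrix <- function(x, ...) {
  cat("Copy-number matrix (source A / source B); * marks discrepant cells\n")
  m <- matrix("", nrow = dim(x$counts)[1], ncol = dim(x$counts)[2],
              dimnames = dimnames(x$counts)[1:2])
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      m[i, j] <- paste0(x$counts[i, j, 1], "/", x$counts[i, j, 2],
                        if (x$discrepancy[i, j]) "*" else "")
  print(m, quote = FALSE)
  invisible(x)
}

#' Serialize a copy-number matrix
#' @param cnm a `copy_number_matrix`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_copy_number_matrix <- function(cnm, path) {
  dn <- dimnames(cnm$counts)
  df <- expand.grid(enzyme = dn$enzyme, species = dn$species,
                    stringsAsFactors = FALSE)
  df$count_a <- as.integer(cnm$counts[cbind(df$enzyme, df$species, "A")])
  df$count_b <- as.integer(cnm$counts[cbind(df$enzyme, df$species, "B")])
  df$discrepant <- cnm$discrepancy[cbind(df$enzyme, df$species)]
  df$zero <- cnm$zero[cbind(df$enzyme, df$species)]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coding-sequence length statistics by category
#'
#' Mean and population (n-denominator) standard deviation of CDS length per
#' (enzyme, source, category) stratum; empty strata are omitted and a
#' singleton stratum reports sd 0.
#'
#' @param records pair records.
#' @param set_a,set_b annotation sets supplying sequence lengths.
#' @return data frame `enzyme`, `source`, `category`, `n`, `mean_nt`,
#'   `sd_nt`.
#' @export
length_stats <- function(records, set_a, set_b) {
  len_a <- setNames(nchar(set_a$sequence), set_a$gene_id)
  len_b <- setNames(nchar(set_b$sequence), set_b$gene_id)
  rows <- list()
  add <- function(enzyme, source, category, lens) {
    lens <- lens[!is.na(lens)]
    if (length(lens) == 0) return()
    rows[[length(rows) + 1]] <<- data.frame(
      enzyme = enzyme, source = source, category = category,
      n = length(lens), mean_nt = mean(lens),
      sd_nt = sqrt(mean((lens - mean(lens))^2)), stringsAsFactors = FALSE)
  }
  for (e in unique(records$enzyme)) {
    re <- records[records$enzyme == e, , drop = FALSE]
    for (cat_ in unique(re$category)) {
      rc <- re[re$category == cat_, , drop = FALSE]
      add(e, "A", cat_, len_a[rc$member_a[!is.na(rc$member_a)]])
      add(e, "B", cat_, len_b[rc$member_b[!is.na(rc$member_b)]])
    }
  }
  if (length(rows) == 0)
    return(data.frame(enzyme = character(), source = character(),
                      category = character(), n = integer(),
                      mean_nt = numeric(), sd_nt = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$enzyme, out$source, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
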