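#' MEM matching parameters
#'
#' Each maximal exact match must be at least `min_mem_len` bp long, and the
#' qualifying MEMs of a read against a reference must together cover at least
#' `min_coverage` bp of the read for the reference to be eligible.
#'
#' @param min_mem_len minimum MEM length in bp.
#' @param min_coverage minimum read coverage in bp.
#' @return a `match_params` list.
#' @export
match_params <- function(min_mem_len = 7L, min_coverage = 17L) {
  stopifnot(min_mem_len >= 1, min_coverage >= min_mem_len)
  structure(list(min_mem_len = as.integer(min_mem_len),
                 min_coverage = as.integer(min_coverage)),
            class = "match_params")
}

#' Find maximal exact matches of a read against one reference
#'
#' A MEM is a read interval `[p, p+L)` (0-based, half-open) whose substring
#' occurs in the reference while neither the left-extended nor the
#' right-extended substring does. Intervals are reported with `L >= min_len`.
#'
#' @param read,ref character scalars over a common canonical alphabet
#'   (use [rna_to_dna()] on catalog sequences before matching DNA reads).
#' @param min_len minimum MEM length.
#' @return integer matrix with columns `start` (0-based) and `length`.
#' @export
find_mems <- function(read, ref, min_len = 7L) {
  stopifnot(length(read) == 1L, length(ref) == 1L)
  cpp_find_mems(toupper(read), toupper(ref), as.integer(min_len))
}

#' Read coverage of a set of MEMs
#'
#' @param mems matrix as returned by [find_mems()].
#' @return size (bp) of the union of the intervals.
#' @export
read_coverage <- function(mems) {
  if (is.null(mems) || nrow(mems) == 0L) return(0L)
  pos <- unlist(lapply(seq_len(nrow(mems)),
                       function(i) seq.int(mems[i, 1], length.out = mems[i, 2])))
  length(unique(pos))
}

#' Assign candidate reads to catalog entries
#'
#' For each read, the MEM coverage (union of qualifying MEM intervals on the
#' read) against every reference is computed; references reaching
#' `min_coverage` are eligible and the one with the most matching basepairs
#' wins. Residual ties are broken by the lexicographically smallest reference
#' name and flagged. Reads with no eligible reference stay unassigned.
#'
#' @param reads character vector of trimmed candidate reads (DNA).
#' @param catalog a `memir_catalog`.
#' @param params a [match_params()] list.
#' @param read_ids optional read identifiers.
#' @return data frame `read_id`, `assigned_ref` (NA if unassigned),
#'   `covered_bp`, `tie_flag`.
#' @export
assign_reads <- function(reads, catalog, params = match_params(),
                         read_ids = NULL) {
  reads <- toupper(as.character(reads))
  refs_dna <- rna_to_dna(catalog$sequence)
  res <- cpp_assign_reads(reads, refs_dna, catalog$name,
                          params$min_mem_len, params$min_coverage)
  data.frame(read_id = read_ids %||% paste0("read", seq_along(reads)),
             assigned_ref = ifelse(is.na(res$ref_idx), NA_character_,
                                   catalog$name[res$ref_idx]),
             covered_bp = res$covered_bp,
             tie_flag = res$tie_flag,
             stringsAsFactors = FALSE)
}

#' Tally assigned reads per reference
#'
#' @param assignments data frame from [assign_reads()] (or a list of them,
#'   one per sample).
#' @param catalog a `memir_catalog`.
#' @param sample sample name(s), one per assignment set.
#' @return integer count matrix, rows = reference names, columns = samples;
#'   unassigned reads are excluded, spike-assigned reads are tallied under
#'   their spike entry.
#' @export
count_reads <- function(assignments, catalog, sample = "sample1") {
  if (is.data.frame(assignments)) assignments <- list(assignments)
  stopifnot(length(assignments) == length(sample))
  mat <- matrix(0L, nrow(catalog), length(sample),
                dimnames = list(catalog$name, sample))
  for (j in seq_along(assignments)) {
    ref <- assignments[[j]]$assigned_ref
    tab <- table(factor(ref[!is.na(ref)], levels = catalog$name))
    mat[, j] <- as.integer(tab)
  }
  mat
}

#' Write / read a count matrix as TSV
#' @param counts matrix with reference rownames.
#' @param path TSV path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(reference = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
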