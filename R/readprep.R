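#' Adapter trimming parameters
#'
#' Defaults follow the small-RNA library protocol: the 21-nt 3' adapter
#' TGGAATTCTCGGGTGCCAAGG, a minimum overlap of 4 bp for a 3'-flush adapter
#' prefix, an error budget of 20% of the aligned adapter length (floored),
#' and a 16-28 bp window for candidate mature-miRNA reads.
#'
#' @param adapter 3' adapter, DNA alphabet.
#' @param min_overlap minimum adapter-prefix length at the read's 3' end.
#' @param max_error_rate maximum fraction of edit errors per aligned adapter
#'   length; the budget for an aligned length L is `floor(rate * L)`.
#' @param min_len,max_len trimmed-length window for candidate reads.
#' @return a `trim_params` list.
#' @export
trim_params <- function(adapter = "TGGAATTCTCGGGTGCCAAGG", min_overlap = 4L,
                        max_error_rate = 0.20, min_len = 16L, max_len = 28L) {
  stopifnot(max_error_rate >= 0, max_error_rate < 1,
            min_overlap >= 1, min_overlap <= nchar(adapter),
            min_len <= max_len)
  structure(list(adapter = toupper(adapter), min_overlap = as.integer(min_overlap),
                 max_error_rate = max_error_rate, min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = "trim_params")
}

#' Classify a trimmed read by length
#'
#' Reads shorter than `min_len` are discarded as `too_short`; reads between
#' `min_len` and `max_len` (inclusive) are `candidate` mature-miRNA reads;
#' longer reads (including untrimmed full-length reads) are `too_long` and
#' excluded from mature-miRNA counting.
#'
#' @param len trimmed read length(s) (or a `trim_result` data frame, from
#'   which `trimmed_seq` lengths are taken).
#' @param params a [trim_params()] list.
#' @return character vector in `{too_short, candidate, too_long}`.
#' @export
classify_read <- function(len, params = trim_params()) {
  if (is.data.frame(len)) len <- nchar(len$trimmed_seq)
  ifelse(len < params$min_len, "too_short",
         ifelse(len <= params$max_len, "candidate", "too_long"))
}

#' Search for and remove the 3' adapter
#'
#' Considers every placement of (a) the full adapter starting at any read
#' position with the trailing read free, and (b) an adapter prefix of at least
#' `min_overlap` bases flush with the read's 3' end. A placement is admissible
#' when its unit-cost edit distance e (substitutions, insertions, deletions)
#' satisfies `e <= floor(max_error_rate * aligned_adapter_length)`. Among the
#' admissible placements the one with the most matched bases wins; ties go to
#' fewer errors, then to the smallest start. If no placement is admissible the
#' read is returned untrimmed.
#'
#' @param reads character vector of uppercase DNA reads (N allowed; N matches
#'   nothing).
#' @param params a [trim_params()] list.
#' @return a data frame with columns `trimmed_seq`, `adapter_found`,
#'   `adapter_start` (0-based, NA when not found), `n_errors`, `read_class`.
#' @export
trim_adapter <- function(reads, params = trim_params()) {
  reads <- toupper(as.character(reads))
  stopifnot(all(nzchar(reads)))
  res <- cpp_trim_reads(reads, params$adapter, params$min_overlap,
                        params$max_error_rate)
  trimmed <- ifelse(res$adapter_found, substr(reads, 1L, res$adapter_start), reads)
  out <- data.frame(trimmed_seq = trimmed,
                    adapter_found = res$adapter_found,
                    adapter_start = res$adapter_start,
                    n_errors = res$n_errors,
                    stringsAsFactors = FALSE)
  out$read_class <- classify_read(nchar(out$trimmed_seq), params)
  out
}

#' Trim a FASTQ file and write candidate reads
#'
#' Reads a 4-line-record FASTQ, trims the 3' adapter, carries qualities
#' through (truncated with the read), and writes the candidate-class reads to
#' `out_fastq`. Returns the per-class trimming report.
#'
#' @param fastq input FASTQ path.
#' @param out_fastq output path for trimmed candidate reads (NULL to skip
#'   writing).
#' @param params a [trim_params()] list.
#' @return a one-row data frame: `total`, `adapter_found`, `too_short`,
#'   `candidate`, `too_long`, with the trimmed reads in attribute `"trimmed"`.
#' @export
trim_fastq <- function(fastq, out_fastq = NULL, params = trim_params()) {
  set <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                      with.qualities = TRUE)
  reads <- as.character(set)
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  tr <- trim_adapter(reads, params)
  tr$read_id <- names(set)
  tr$quality <- substr(quals, 1L, nchar(tr$trimmed_seq))
  keep <- tr$read_class == "candidate"
  if (!is.null(out_fastq)) {
    out <- Biostrings::DNAStringSet(tr$trimmed_seq[keep])
    names(out) <- tr$read_id[keep]
    Biostrings::writeXStringSet(out, out_fastq, format = "fastq",
                                qualities = Biostrings::BStringSet(tr$quality[keep]))
  }
  report <- data.frame(total = nrow(tr),
                       adapter_found = sum(tr$adapter_found),
                       too_short = sum(tr$read_class == "too_short"),
                       candidate = sum(keep),
                       too_long = sum(tr$read_class == "too_long"))
  attr(report, "trimmed") <- tr
  report
}
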