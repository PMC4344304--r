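#' Mature miRNA reference catalogs
#'
#' A reference catalog is a data frame with one row per distinct mature
#' sequence and columns `name` (identifier), `sequence` (uppercase RNA
#' alphabet), `member_names` (comma-joined identifiers collapsed into the
#' entry) and `is_spike` (`TRUE` for siRNA / scrambled-control spike-in
#' entries, whose reads are tallied but excluded from miRNA totals).
#'
#' @param name,sequence,member_names,is_spike column vectors, recycled to a
#'   common length.
#' @return a `memir_catalog` data frame.
#' @export
reference_catalog <- function(name = character(), sequence = character(),
                              member_names = name, is_spike = FALSE) {
  sequence <- toupper(dna_to_rna(sequence))
  bad <- grepl("[^ACGU]", sequence) | !nzchar(sequence)
  if (any(bad))
    stop("invalid reference sequence(s): ", paste(name[bad], collapse = ", "))
  cat <- data.frame(name = as.character(name), sequence = sequence,
                    member_names = as.character(member_names),
                    is_spike = rep_len(as.logical(is_spike), length(name)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(cat$name)) stop("duplicate reference names")
  class(cat) <- c("memir_catalog", "data.frame")
  cat
}

#' Parse a mature-miRNA FASTA file
#'
#' Reads a miRBase-style mature FASTA (wrapped or unwrapped). Sequences are
#' uppercased and T is normalized to U; record order is preserved. The name of
#' each entry is the first whitespace-delimited token of its header.
#'
#' @param path path to a FASTA file.
#' @return a `memir_catalog` data frame, one entry per record.
#' @export
parse_mature_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  seqs <- as.character(set)
  if (length(seqs) == 0L) stop("no FASTA records in '", path, "'")
  nm <- sub("\\s.*$", "", names(set))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(nm[empty], collapse = ", "))
  reference_catalog(name = nm, sequence = seqs)
}

#' Collapse entries with identical sequences
#'
#' Entries sharing a sequence are merged into one whose `member_names` is the
#' union of the merged names and whose `name` is the lexicographically
#' smallest member name; the relative order of surviving entries is kept.
#' Idempotent.
#'
#' @param catalog a `memir_catalog`.
#' @return the collapsed catalog (all sequences distinct).
#' @export
collapse_identical <- function(catalog) {
  if (nrow(catalog) == 0L) return(catalog)
  members <- strsplit(catalog$member_names, ",", fixed = TRUE)
  grp <- match(catalog$sequence, unique(catalog$sequence))
  rows <- lapply(split(seq_len(nrow(catalog)), grp), function(i) {
    nm <- sort(unique(unlist(members[i], use.names = FALSE)), method = "radix")
    data.frame(name = nm[1], sequence = catalog$sequence[i[1]],
               member_names = paste(nm, collapse = ","),
               is_spike = any(catalog$is_spike[i]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[order(as.integer(names(rows)))])
  rownames(out) <- NULL
  class(out) <- c("memir_catalog", "data.frame")
  out
}

#' siRNA and scrambled-control spike-in sequences
#'
#' The three knockdown siRNAs, their reverse complements and the scrambled
#' control with its reverse complement, added to the reference so their reads
#' are identified and kept out of the miRNA totals.
#'
#' @return a named character vector of 8 RNA sequences.
#' @export
fto_sirna_spikes <- function() {
  toupper(c(
    SR312322A     = "gcagcugaaauauccuaaacuaatt",
    SR312322A_rc  = "uuaguuuaggauauuucagcugc",
    SR312322B     = "agacagaacuuagagacaucccagt",
    SR312322B_rc  = "acugggaugucucuaaguucugucu",
    SR312322C     = "agcgugugacaaagccuaaccuact",
    SR312322C_rc  = "aguagguuaggcuuugucacacgcu",
    Scrambled     = "cguuaaucgcguauaauacgcguat",
    Scrambled_rc  = "auacgcguauuauacgcgauuaacg"
  ))
}

#' Append spike-in entries to a catalog
#'
#' @param catalog a `memir_catalog`.
#' @param spikes named character vector of spike sequences (RNA or DNA
#'   spelling); defaults to [fto_sirna_spikes()].
#' @return the catalog with spikes appended (`is_spike = TRUE`) and identical
#'   sequences re-collapsed.
#' @export
add_spikes <- function(catalog, spikes = fto_sirna_spikes()) {
  if (length(spikes) == 0L) return(catalog)
  if (is.null(names(spikes)) || any(!nzchar(names(spikes))))
    stop("spikes must be named")
  clash <- intersect(names(spikes), catalog$name)
  if (length(clash))
    stop("spike name(s) already in catalog: ", paste(clash, collapse = ", "))
  sp <- reference_catalog(name = names(spikes), sequence = unname(spikes),
                          is_spike = TRUE)
  out <- rbind(catalog, sp)
  class(out) <- c("memir_catalog", "data.frame")
  collapse_identical(out)
}

#' Serialize / read a catalog as TSV
#'
#' @param catalog a `memir_catalog`.
#' @param path output (or input) TSV path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  reference_catalog(df$name, df$sequence, df$member_names, df$is_spike)
}

#' Write a catalog as FASTA
#' @param catalog a `memir_catalog`.
#' @param path output FASTA path.
#' @export
write_catalog_fasta <- function(catalog, path) {
  set <- Biostrings::BStringSet(setNames(catalog$sequence, catalog$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.memir_catalog <- function(x, ...) {
  cat(sprintf("miRNA reference catalog: %d entries (%d spike-in)\n",
              nrow(x), sum(x$is_spike)))
  if (nrow(x)) print.data.frame(head(x, 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more entries\n")
  invisible(x)
}
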