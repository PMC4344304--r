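#' Configuration of the synthetic small-RNA experiment
#'
#' Defines the ground-truthed experiment the simulator emulates: a catalog of
#' mature-length references, a methylated subset carrying a planted
#' methyltransferase-consensus motif instance, knockdown/scrambled and
#' m6A-IP/IgG-IP sample pairs (3 replicates each), and adapter-bearing 50-bp
#' reads with substitution errors.
#'
#' @param n_refs number of reference sequences.
#' @param ref_len_range mature-length range in nt (inclusive).
#' @param methylated_fraction fraction of references flagged methylated.
#' @param planted_motif concrete motif instance planted in methylated
#'   references (an RRACH instance by default).
#' @param motif_plant_rate_ip fraction of methylated references that receive a
#'   planted motif instance.
#' @param ip_enrichment_fold weight multiplier of methylated references in
#'   m6A-IP samples.
#' @param kd_down_fold weight multiplier of methylated references in
#'   knockdown samples.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters
#'   (natural-log scale).
#' @param reads_per_sample reads simulated per sample.
#' @param error_rate per-base substitution error rate in the insert.
#' @param no_adapter_rate fraction of reads emitted as 50-bp random sequence
#'   with no adapter.
#' @param read_len read length in bp.
#' @param seed mandatory integer seed; every stochastic call derives a
#'   deterministic substream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_refs = 300L, ref_len_range = c(19L, 27L),
                       methylated_fraction = 0.25, planted_motif = "GGACU",
                       motif_plant_rate_ip = 0.6, ip_enrichment_fold = 8,
                       kd_down_fold = 0.4, abundance_meanlog = log(100),
                       abundance_sdlog = 1.5, reads_per_sample = 50000L,
                       error_rate = 0.005, no_adapter_rate = 0.02,
                       read_len = 50L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(methylated_fraction >= 0, methylated_fraction <= 1,
            motif_plant_rate_ip >= 0, motif_plant_rate_ip <= 1,
            error_rate >= 0, error_rate <= 1,
            no_adapter_rate >= 0, no_adapter_rate <= 1,
            ip_enrichment_fold > 0, kd_down_fold > 0)
  structure(list(n_refs = as.integer(n_refs),
                 ref_len_range = as.integer(ref_len_range),
                 methylated_fraction = methylated_fraction,
                 planted_motif = toupper(planted_motif),
                 motif_plant_rate_ip = motif_plant_rate_ip,
                 ip_enrichment_fold = ip_enrichment_fold,
                 kd_down_fold = kd_down_fold,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate,
                 no_adapter_rate = no_adapter_rate,
                 read_len = as.integer(read_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic substream seeds, one per named stage/sample
substream_seed <- function(config, stream) {
  offsets <- c(catalog = 1L, counts = 2L)
  off <- if (stream %in% names(offsets)) offsets[[stream]]
  else 10L + sum(utf8ToInt(stream))
  (config$seed * 7919L + off) %% .Machine$integer.max
}

random_rna <- function(n, lens) {
  vapply(lens, function(L)
    paste(sample(RNA_BASES, L, replace = TRUE), collapse = ""), character(1))
}

#' Generate a ground-truthed reference catalog
#'
#' Random mature-length RNA sequences; a sampled methylated subset; a planted
#' motif instance written at a random valid offset into the designated
#' fraction of methylated references. All sequences are distinct.
#'
#' @param config a [sim_config()].
#' @return list with `catalog` (a `memir_catalog`) and `truth` (data frame
#'   `name`, `sequence`, `methylated`, `motif_planted`, `motif_offset`
#'   (0-based, NA if none), `abundance`).
#' @export
generate_catalog <- function(config) {
  set.seed(substream_seed(config, "catalog"))
  n <- config$n_refs
  lens <- sample(seq(config$ref_len_range[1], config$ref_len_range[2]),
                 n, replace = TRUE)
  seqs <- random_rna(n, lens)
  for (tries in 1:100) {
    dup <- duplicated(seqs)
    if (!any(dup)) break
    seqs[dup] <- random_rna(sum(dup), lens[dup])
  }
  if (anyDuplicated(seqs)) stop("could not generate distinct sequences")
  meth <- rep(FALSE, n)
  meth[sample(n, round(config$methylated_fraction * n))] <- TRUE
  plant <- meth & runif(n) < config$motif_plant_rate_ip
  motif <- config$planted_motif
  mk <- nchar(motif)
  offset <- rep(NA_integer_, n)
  for (i in which(plant)) {
    if (lens[i] < mk) { plant[i] <- FALSE; next }
    off <- sample.int(lens[i] - mk + 1L, 1L) - 1L
    substr(seqs[i], off + 1L, off + mk) <- motif
    offset[i] <- off
  }
  # motif insertion can recreate a duplicate; regenerate colliders' padding
  if (anyDuplicated(seqs)) stop("sequence collision after motif planting")
  abundance <- rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  names <- sprintf("syn-mir-%03d", seq_len(n))
  truth <- data.frame(name = names, sequence = seqs, methylated = meth,
                      motif_planted = plant, motif_offset = offset,
                      abundance = abundance, stringsAsFactors = FALSE)
  list(catalog = reference_catalog(names, seqs), truth = truth)
}

#' The simulated sample sheet
#'
#' Three knockdown/scrambled pairs and three m6A-IP/IgG-IP pairs.
#'
#' @return data frame `sample`, `condition` (scr/kd/m6A/IgG), `replicate`.
#' @export
sample_sheet <- function() {
  data.frame(sample = c(paste0("scr", 1:3), paste0("kd", 1:3),
                        paste0("m6A", 1:3), paste0("IgG", 1:3)),
             condition = rep(c("scr", "kd", "m6A", "IgG"), each = 3),
             replicate = rep(1:3, 4), stringsAsFactors = FALSE)
}

#' Expected per-sample sampling weights
#'
#' Weight = abundance, times `kd_down_fold` for methylated references in
#' knockdown samples, times `ip_enrichment_fold` for methylated references in
#' m6A-IP samples; scrambled and IgG samples carry the base abundance.
#'
#' @param truth truth table from [generate_catalog()].
#' @param design a sample sheet as from [sample_sheet()].
#' @param config a [sim_config()].
#' @return numeric matrix, rows = references, columns = samples.
#' @export
simulate_counts <- function(truth, design = sample_sheet(), config) {
  stopifnot(all(design$condition %in% c("scr", "kd", "m6A", "IgG")))
  w <- matrix(truth$abundance, nrow(truth), nrow(design),
              dimnames = list(truth$name, design$sample))
  for (j in seq_len(nrow(design))) {
    if (design$condition[j] == "kd")
      w[truth$methylated, j] <- w[truth$methylated, j] * config$kd_down_fold
    if (design$condition[j] == "m6A")
      w[truth$methylated, j] <- w[truth$methylated, j] * config$ip_enrichment_fold
  }
  w
}

#' Simulate adapter-bearing reads for one sample
#'
#' Draws `reads_per_sample` reads from the weight-proportional multinomial
#' over references. Each read is the reference sequence (U spelled as T) with
#' iid substitution errors, followed by the 3' adapter and random padding to
#' `read_len` bp; with probability `no_adapter_rate` a fully random 50-bp read
#' is emitted instead. Quality is a constant string.
#'
#' @param weights a column of [simulate_counts()] (named by reference).
#' @param catalog a `memir_catalog` (names must cover the weight names).
#' @param config a [sim_config()].
#' @param sample sample name (selects the deterministic substream).
#' @param adapter 3' adapter appended to each insert.
#' @return data frame `read_id`, `sequence`, `quality`, `true_ref` (NA for
#'   adapter-free random reads).
#' @export
simulate_reads <- function(weights, catalog, config, sample = "sample1",
                           adapter = trim_params()$adapter) {
  stopifnot(all(weights >= 0), any(weights > 0))
  set.seed(substream_seed(config, sample))
  n <- config$reads_per_sample
  rl <- config$read_len
  refs <- names(weights)
  seq_dna <- rna_to_dna(catalog$sequence[match(refs, catalog$name)])
  pick <- sample.int(length(refs), n, replace = TRUE, prob = weights)
  random_read <- runif(n) < config$no_adapter_rate
  out <- character(n)
  for (i in seq_len(n)) {
    if (random_read[i]) {
      out[i] <- paste(sample(DNA_BASES, rl, replace = TRUE), collapse = "")
      next
    }
    ins <- strsplit(seq_dna[pick[i]], "")[[1]]
    err <- runif(length(ins)) < config$error_rate
    if (any(err))
      ins[err] <- vapply(ins[err], function(b)
        sample(setdiff(DNA_BASES, b), 1L), character(1))
    read <- paste0(paste(ins, collapse = ""), adapter)
    pad <- rl - nchar(read)
    if (pad > 0)
      read <- paste0(read, paste(sample(DNA_BASES, pad, replace = TRUE),
                                 collapse = ""))
    out[i] <- substr(read, 1L, rl)
  }
  data.frame(read_id = sprintf("%s_read%06d", sample, seq_len(n)),
             sequence = out,
             quality = strrep("I", rl),
             true_ref = ifelse(random_read, NA_character_, refs[pick]),
             stringsAsFactors = FALSE)
}

#' Write simulated reads as FASTQ
#' @param reads data frame from [simulate_reads()].
#' @param path FASTQ path.
#' @export
write_reads_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Simulate the full experiment to disk
#'
#' Writes the catalog FASTA, one FASTQ per sample, the truth table and the
#' sample sheet into `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @return list of written paths plus the in-memory `catalog`, `truth`,
#'   `design` and `weights`.
#' @export
simulate_experiment <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_catalog(config)
  design <- sample_sheet()
  weights <- simulate_counts(gen$truth, design, config)
  fasta <- file.path(dir, "catalog.fasta")
  write_catalog_fasta(gen$catalog, fasta)
  fastqs <- setNames(file.path(dir, paste0(design$sample, ".fastq")),
                     design$sample)
  for (s in design$sample) {
    rd <- simulate_reads(weights[, s], gen$catalog, config, sample = s)
    write_reads_fastq(rd, fastqs[[s]])
  }
  truth_path <- file.path(dir, "truth.tsv")
  write.table(gen$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sheet_path <- file.path(dir, "samples.tsv")
  write.table(design, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(catalog_fasta = fasta, fastq = fastqs, truth_tsv = truth_path,
       sample_sheet = sheet_path, catalog = gen$catalog, truth = gen$truth,
       design = design, weights = weights)
}
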