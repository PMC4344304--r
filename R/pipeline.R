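#' Pipeline run configuration
#'
#' Collects paths and stage parameters for [run_pipeline()]. Any component can
#' be overridden; defaults reproduce the standard analysis on a simulated
#' experiment.
#'
#' @param out_dir output directory for all artifacts.
#' @param catalog_fasta mature reference FASTA (written by the simulate stage
#'   when simulating).
#' @param sample_sheet TSV with columns `sample`, `condition`, `replicate`.
#' @param fastq_dir directory holding `<sample>.fastq` files.
#' @param trim,match,diff,rip parameter lists ([trim_params()],
#'   [match_params()], [diff_params()], [rip_params()]).
#' @param motif_form the [motif_space_form()] scanned by the motifs stage.
#' @param sim a [sim_config()] for the simulate stage (NULL to require real
#'   inputs).
#' @param seed integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, catalog_fasta = NULL, sample_sheet = NULL,
                            fastq_dir = NULL, trim = trim_params(),
                            match = match_params(), diff = diff_params(),
                            rip = rip_params(),
                            motif_form = motif_space_form(3, 2, 2, 0),
                            sim = NULL, seed = 1L) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(out_dir = out_dir,
                 catalog_fasta = catalog_fasta %||% file.path(out_dir, "sim", "catalog.fasta"),
                 sample_sheet = sample_sheet %||% file.path(out_dir, "sim", "samples.tsv"),
                 fastq_dir = fastq_dir %||% file.path(out_dir, "sim"),
                 trim = trim, match = match, diff = diff, rip = rip,
                 motif_form = motif_form, sim = sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; parameter
#' blocks (`trim`, `match`, `diff`, `rip`, `sim`) hold the corresponding
#' constructor arguments, `motif_form` is a list `k`, `x`, `y`, `n`. Unknown
#' keys are an error.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file is read.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  known <- c("out_dir", "catalog_fasta", "sample_sheet", "fastq_dir", "trim",
             "match", "diff", "rip", "motif_form", "sim", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  over <- list(...)
  raw[names(over)] <- over
  if (is.list(raw$trim)) raw$trim <- do.call(trim_params, raw$trim)
  if (is.list(raw$match)) raw$match <- do.call(match_params, raw$match)
  if (is.list(raw$diff)) raw$diff <- do.call(diff_params, raw$diff)
  if (is.list(raw$rip)) raw$rip <- do.call(rip_params, raw$rip)
  if (is.list(raw$motif_form)) {
    # YAML 1.1 parses bare y/n keys as booleans; map them back
    nm <- names(raw$motif_form)
    nm[nm == "TRUE"] <- "y"; nm[nm == "FALSE"] <- "n"
    names(raw$motif_form) <- nm
    raw$motif_form <- do.call(motif_space_form, raw$motif_form)
  }
  if (is.list(raw$sim)) raw$sim <- do.call(sim_config, c(raw$sim, if (!"seed" %in% names(raw$sim)) list(seed = raw$seed %||% 1L)))
  do.call(pipeline_config, raw)
}

require_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input artifact(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
}

write_manifest <- function(config, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("memir")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = list(trim = unclass(config$trim), match = unclass(config$match),
                      diff = unclass(config$diff), rip = unclass(config$rip),
                      motif_form = unclass(config$motif_form),
                      sim = unclass(config$sim)),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(outputs))
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

read_sheet <- function(config) {
  require_inputs(config$sample_sheet)
  read.delim(config$sample_sheet, stringsAsFactors = FALSE)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages, in order: `simulate` (write a seeded synthetic experiment), `trim`
#' (adapter removal and read classification), `count` (MEM assignment and the
#' count matrix), `quantify` (RPM normalization and the expressed list),
#' `diff` (knockdown vs scrambled calls), `rip` (m6A-IP vs IgG-IP methylation
#' calls), `motifs` (discriminative IUPAC motif scan of methylated vs
#' remaining references), `correlate` (enrichment vs knockdown-response
#' scatter and statistics), or `all`. Each stage writes its artifacts plus a
#' JSON run manifest (parameters, input checksums, versions) under
#' `config$out_dir` and logs timestamped record counts.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(stage = "all", config) {
  stages <- c("simulate", "trim", "count", "quantify", "diff", "rip",
              "motifs", "correlate")
  stage <- match.arg(stage, c(stages, "all"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    out <- list()
    for (s in stages) out <- c(out, run_pipeline(s, config))
    return(invisible(out))
  }
  out <- switch(stage,
    simulate = stage_simulate(config),
    trim = stage_trim(config),
    count = stage_count(config),
    quantify = stage_quantify(config),
    diff = stage_diff(config),
    rip = stage_rip(config),
    motifs = stage_motifs(config),
    correlate = stage_correlate(config))
  invisible(out)
}

stage_simulate <- function(config) {
  log_msg("simulate: ", config$sim$n_refs, " references, ",
          config$sim$reads_per_sample, " reads/sample")
  sim <- simulate_experiment(config$sim, file.path(config$out_dir, "sim"))
  outs <- c(catalog = sim$catalog_fasta, truth = sim$truth_tsv,
            sheet = sim$sample_sheet, sim$fastq)
  write_manifest(config, "simulate", character(), outs)
  as.list(outs)
}

stage_trim <- function(config) {
  require_inputs(config$sample_sheet)
  design <- read_sheet(config)
  fq <- file.path(config$fastq_dir, paste0(design$sample, ".fastq"))
  require_inputs(fq)
  dir.create(file.path(config$out_dir, "trimmed"), showWarnings = FALSE)
  reports <- vector("list", nrow(design))
  outs <- file.path(config$out_dir, "trimmed", paste0(design$sample, ".fastq"))
  for (i in seq_len(nrow(design))) {
    rep <- trim_fastq(fq[i], outs[i], config$trim)
    reports[[i]] <- cbind(sample = design$sample[i], rep)
    log_msg("trim ", design$sample[i], ": ", rep$candidate, "/", rep$total,
            " candidate reads")
  }
  report <- do.call(rbind, reports)
  rp <- file.path(config$out_dir, "trimming_report.tsv")
  write.table(report, rp, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "trim", fq, c(outs, rp))
  list(trimming_report = rp, trimmed = outs)
}

load_catalog <- function(config) {
  require_inputs(config$catalog_fasta)
  add_spikes(collapse_identical(parse_mature_fasta(config$catalog_fasta)))
}

stage_count <- function(config) {
  design <- read_sheet(config)
  trimmed <- file.path(config$out_dir, "trimmed", paste0(design$sample, ".fastq"))
  require_inputs(trimmed)
  catalog <- load_catalog(config)
  cols <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    set <- Biostrings::readDNAStringSet(trimmed[i], format = "fastq")
    asn <- assign_reads(as.character(set), catalog, config$match,
                        read_ids = names(set))
    cols[[i]] <- asn
    log_msg("count ", design$sample[i], ": ", sum(!is.na(asn$assigned_ref)),
            "/", nrow(asn), " reads assigned")
  }
  counts <- count_reads(cols, catalog, design$sample)
  cp <- file.path(config$out_dir, "counts.tsv")
  write_counts_tsv(counts, cp)
  ctp <- file.path(config$out_dir, "catalog.tsv")
  write_catalog_tsv(catalog, ctp)
  write_manifest(config, "count", c(config$catalog_fasta, trimmed), c(cp, ctp))
  list(counts = cp, catalog_tsv = ctp)
}

stage_quantify <- function(config) {
  cp <- file.path(config$out_dir, "counts.tsv")
  ctp <- file.path(config$out_dir, "catalog.tsv")
  require_inputs(c(cp, ctp))
  counts <- read_counts_tsv(cp)
  catalog <- read_catalog_tsv(ctp)
  norm <- normalize_rpm(counts, catalog)
  np <- file.path(config$out_dir, "rpm.tsv")
  write_counts_tsv(norm, np)
  design <- read_sheet(config)
  scr <- design$sample[design$condition == "scr"]
  expressed <- filter_expressed(norm[!catalog$is_spike, , drop = FALSE],
                                scr, config$diff$min_rpm)
  ep <- file.path(config$out_dir, "expressed.tsv")
  write.table(data.frame(name = expressed), ep, sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_msg("quantify: ", length(expressed), " expressed references")
  write_manifest(config, "quantify", c(cp, ctp), c(np, ep))
  list(rpm = np, expressed = ep)
}

stage_diff <- function(config) {
  np <- file.path(config$out_dir, "rpm.tsv")
  ctp <- file.path(config$out_dir, "catalog.tsv")
  require_inputs(c(np, ctp))
  norm <- read_counts_tsv(np)
  catalog <- read_catalog_tsv(ctp)
  design <- read_sheet(config)
  kd <- design[design$condition == "kd", ]
  scr <- design[design$condition == "scr", ]
  pairs <- data.frame(treated = kd$sample[order(kd$replicate)],
                      control = scr$sample[order(scr$replicate)])
  calls <- call_differential(norm[!catalog$is_spike, , drop = FALSE], pairs,
                             config$diff)
  dp <- file.path(config$out_dir, "differential.tsv")
  write.table(calls, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("diff: ", sum(calls$status == "down"), " down, ",
          sum(calls$status == "up"), " up")
  write_manifest(config, "diff", np, dp)
  list(differential = dp)
}

stage_rip <- function(config) {
  np <- file.path(config$out_dir, "rpm.tsv")
  ctp <- file.path(config$out_dir, "catalog.tsv")
  require_inputs(c(np, ctp))
  norm <- read_counts_tsv(np)
  catalog <- read_catalog_tsv(ctp)
  design <- read_sheet(config)
  ip <- design[design$condition == "m6A", ]
  igg <- design[design$condition == "IgG", ]
  nonspike <- !catalog$is_spike
  calls <- call_methylated(
    norm[nonspike, ip$sample[order(ip$replicate)], drop = FALSE],
    norm[nonspike, igg$sample[order(igg$replicate)], drop = FALSE],
    config$rip)
  rp <- file.path(config$out_dir, "enrichment.tsv")
  write.table(calls, rp, sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("rip: ", sum(calls$methylated), " methylated references")
  write_manifest(config, "rip", np, rp)
  list(enrichment = rp)
}

stage_motifs <- function(config) {
  rp <- file.path(config$out_dir, "enrichment.tsv")
  ctp <- file.path(config$out_dir, "catalog.tsv")
  require_inputs(c(rp, ctp))
  enr <- read.delim(rp, stringsAsFactors = FALSE)
  catalog <- read_catalog_tsv(ctp)
  catalog <- catalog[!catalog$is_spike, ]
  ip_names <- enr$name[enr$methylated]
  ip <- catalog$sequence[catalog$name %in% ip_names]
  bg <- catalog$sequence[!catalog$name %in% ip_names]
  if (length(ip) == 0L) stop("no methylated references; cannot scan motifs")
  scan <- rank_motifs(config$motif_form, ip, bg, model_p = TRUE)
  mp <- file.path(config$out_dir, "motifs.tsv")
  write.table(as.data.frame(scan), mp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tp <- file.path(config$out_dir, "motifs_top50.tsv")
  write_motif_report(scan, tp)
  log_msg("motifs: top motif ", scan$motif[1], " (fisher p = ",
          signif(scan$fisher_p[1], 3), ")")
  write_manifest(config, "motifs", c(rp, ctp), c(mp, tp))
  list(motifs = mp, motifs_top50 = tp)
}

stage_correlate <- function(config) {
  rp <- file.path(config$out_dir, "enrichment.tsv")
  dp <- file.path(config$out_dir, "differential.tsv")
  require_inputs(c(rp, dp))
  enr <- read.delim(rp, stringsAsFactors = FALSE)
  class(enr) <- c("memir_enrichment", "data.frame")
  dif <- read.delim(dp, stringsAsFactors = FALSE)
  lfc <- log2_fold_changes(enr, dif)
  sp <- file.path(config$out_dir, "scatter.tsv")
  write_scatter_tsv(lfc, sp)
  fit <- pearson_r(lfc$log2_enrichment, lfc$log2_kd_fc)
  sw <- shapiro_wilk(lfc$log2_kd_fc)
  stats <- data.frame(n = fit$n, pearson_r = fit$r, slope = fit$slope,
                      intercept = fit$intercept, shapiro_W = sw$W,
                      shapiro_p = sw$p.value,
                      frac_down = mean(lfc$log2_kd_fc < 0))
  stp <- file.path(config$out_dir, "correlation.tsv")
  write.table(stats, stp, sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("correlate: r = ", signif(fit$r, 3), ", ",
          round(100 * stats$frac_down), "% of methylated references down")
  write_manifest(config, "correlate", c(rp, dp), c(sp, stp))
  list(scatter = sp, correlation = stp)
}
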