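#' Thresholds for differential (knockdown vs scrambled) calls
#'
#' A miRNA is called down when the scrambled controls show at least `min_rpm`
#' normalized reads in every pair and the mean fold change falls below
#' `down_fraction` ("fewer than 50% reads" in the knockdown); up when the
#' knockdowns show at least `min_rpm` everywhere and the mean fold change
#' exceeds `up_fold`. Status is also reported at the `alt_fold` setting.
#'
#' @param min_rpm expression floor in reads per million.
#' @param down_fraction strict upper bound on the mean fold change for a down
#'   call at the primary setting.
#' @param up_fold strict lower bound on the mean fold change for an up call.
#' @param alt_fold secondary fold threshold (up > alt_fold, down < 1/alt_fold).
#' @param pseudocount RPM added to numerator and denominator of a pair's
#'   ratio when the control is zero.
#' @return a `diff_params` list.
#' @export
diff_params <- function(min_rpm = 15, down_fraction = 0.5, up_fold = 2.0,
                        alt_fold = 1.5, pseudocount = 1.0) {
  structure(list(min_rpm = min_rpm, down_fraction = down_fraction,
                 up_fold = up_fold, alt_fold = alt_fold,
                 pseudocount = pseudocount), class = "diff_params")
}

#' Thresholds for methylation (m6A-IP vs IgG-IP) calls
#'
#' @param min_rpm read floor applied to every m6A replicate.
#' @param min_fold minimum mean IP/IgG enrichment ("at least 2 fold").
#' @param pseudocount RPM added to both sides of every enrichment ratio.
#' @return a `rip_params` list.
#' @export
rip_params <- function(min_rpm = 100, min_fold = 2.0, pseudocount = 1.0) {
  structure(list(min_rpm = min_rpm, min_fold = min_fold,
                 pseudocount = pseudocount), class = "rip_params")
}

#' Reads-per-million normalization
#'
#' Each sample's counts are scaled to reads per million mapped miRNA reads.
#' The denominator is the per-sample sum over non-spike references; spike rows
#' are normalized by the same denominator but never contribute to it. A sample
#' with no mapped non-spike reads yields an all-zero column and a warning.
#'
#' @param counts count matrix (rows = references, columns = samples).
#' @param is_spike logical vector per row, or a `memir_catalog` whose
#'   `is_spike` is matched to the rownames.
#' @return numeric matrix of the same shape, in RPM.
#' @export
normalize_rpm <- function(counts, is_spike = FALSE) {
  if (inherits(is_spike, "memir_catalog"))
    is_spike <- is_spike$is_spike[match(rownames(counts), is_spike$name)]
  is_spike <- rep_len(is_spike, nrow(counts))
  denom <- colSums(counts[!is_spike, , drop = FALSE])
  if (any(denom == 0)) {
    warning("sample(s) with zero mapped miRNA reads: ",
            paste(colnames(counts)[denom == 0], collapse = ", "))
  }
  scale <- ifelse(denom > 0, 1e6 / denom, 0)
  sweep(counts, 2, scale, `*`)
}

#' Expressed references: at least `min_rpm` in every listed sample
#'
#' @param norm RPM matrix.
#' @param samples column names to require.
#' @param min_rpm inclusive threshold.
#' @return character vector of reference names.
#' @export
filter_expressed <- function(norm, samples = colnames(norm), min_rpm = 15) {
  stopifnot(length(samples) >= 1, all(samples %in% colnames(norm)))
  sub <- norm[, samples, drop = FALSE]
  rownames(norm)[rowSums(sub >= min_rpm) == length(samples)]
}

pair_fold_changes <- function(norm, treated, control, pseudocount) {
  fc <- matrix(NA_real_, nrow(norm), length(treated),
               dimnames = list(rownames(norm), NULL))
  for (j in seq_along(treated)) {
    tr <- norm[, treated[j]]
    ct <- norm[, control[j]]
    fc[, j] <- ifelse(ct > 0, tr / ct, (tr + pseudocount) / (ct + pseudocount))
  }
  fc
}

#' Call up-/down-regulated references from knockdown/control pairs
#'
#' Per-pair fold changes treated/control are averaged over pairs; a reference
#' is down when the controls reach `min_rpm` in every pair and the mean fold
#' change is strictly below `down_fraction`, up when the treated samples reach
#' `min_rpm` everywhere and the mean exceeds `up_fold`. Status is evaluated at
#' both the primary (2-fold) and alternative (1.5-fold) settings.
#'
#' @param norm RPM matrix.
#' @param pairs data frame with columns `treated` and `control` naming sample
#'   columns (here treated = knockdown, control = scrambled).
#' @param params a [diff_params()] list.
#' @return a `memir_diff` data frame: `name`, per-pair `fc.*` columns,
#'   `mean_fc`, `sd_fc`, `status` (primary), `status_alt`.
#' @export
call_differential <- function(norm, pairs, params = diff_params()) {
  stopifnot(nrow(pairs) >= 1)
  missing <- setdiff(c(pairs$treated, pairs$control), colnames(norm))
  if (length(missing))
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  fc <- pair_fold_changes(norm, pairs$treated, pairs$control, params$pseudocount)
  mean_fc <- rowMeans(fc)
  sd_fc <- apply(fc, 1, sd)
  ctrl_ok <- rowSums(norm[, pairs$control, drop = FALSE] >= params$min_rpm) ==
    nrow(pairs)
  trt_ok <- rowSums(norm[, pairs$treated, drop = FALSE] >= params$min_rpm) ==
    nrow(pairs)
  status_at <- function(up, down) {
    ifelse(trt_ok & mean_fc > up, "up",
           ifelse(ctrl_ok & mean_fc < down, "down", "none"))
  }
  out <- data.frame(name = rownames(norm), fc, mean_fc = mean_fc, sd_fc = sd_fc,
                    status = status_at(params$up_fold, params$down_fraction),
                    status_alt = status_at(params$alt_fold, 1 / params$alt_fold),
                    stringsAsFactors = FALSE)
  names(out)[2:(1 + ncol(fc))] <- paste0("fc.", seq_len(ncol(fc)))
  rownames(out) <- NULL
  class(out) <- c("memir_diff", "data.frame")
  out
}

#' Call methylated references from paired m6A-IP / IgG-IP replicates
#'
#' Per-replicate enrichment is `(ip + pseudocount) / (igg + pseudocount)`.
#' A reference is methylated when every m6A replicate reaches `min_rpm`
#' normalized reads and the mean enrichment is at least `min_fold`. Output is
#' sorted by mean enrichment, descending.
#'
#' @param norm_ip RPM matrix of the m6A-IP samples.
#' @param norm_ctrl RPM matrix of the IgG-IP samples, same references, columns
#'   paired with `norm_ip` in order.
#' @param params a [rip_params()] list.
#' @return a `memir_enrichment` data frame: `name`, per-replicate
#'   `enrichment.*`, `mean_enrichment`, `sd_enrichment`, `methylated`.
#' @export
call_methylated <- function(norm_ip, norm_ctrl, params = rip_params()) {
  if (!identical(dim(norm_ip), dim(norm_ctrl)) ||
      !identical(rownames(norm_ip), rownames(norm_ctrl)))
    stop("m6A and IgG matrices must have identical references and paired columns")
  pc <- params$pseudocount
  enr <- (norm_ip + pc) / (norm_ctrl + pc)
  mean_enr <- rowMeans(enr)
  sd_enr <- apply(enr, 1, sd)
  ip_ok <- rowSums(norm_ip >= params$min_rpm) == ncol(norm_ip)
  out <- data.frame(name = rownames(norm_ip), enr,
                    mean_enrichment = mean_enr, sd_enrichment = sd_enr,
                    methylated = ip_ok & mean_enr >= params$min_fold,
                    stringsAsFactors = FALSE)
  names(out)[2:(1 + ncol(enr))] <- paste0("enrichment.", seq_len(ncol(enr)))
  out <- out[order(-out$mean_enrichment), ]
  rownames(out) <- NULL
  class(out) <- c("memir_enrichment", "data.frame")
  out
}

#' Pair log2 enrichment with log2 knockdown fold change
#'
#' @param enrichment a `memir_enrichment` table.
#' @param diff a `memir_diff` table.
#' @param methylated_only restrict to methylated references.
#' @return data frame `name`, `log2_enrichment`, `log2_kd_fc`; references
#'   whose mean enrichment or mean fold change is zero are dropped with a
#'   message.
#' @export
log2_fold_changes <- function(enrichment, diff, methylated_only = TRUE) {
  if (methylated_only) enrichment <- enrichment[enrichment$methylated, ]
  common <- intersect(enrichment$name, diff$name)
  e <- enrichment$mean_enrichment[match(common, enrichment$name)]
  f <- diff$mean_fc[match(common, diff$name)]
  zero <- e <= 0 | f <= 0
  if (any(zero))
    message("dropping ", sum(zero), " reference(s) with zero mean values")
  data.frame(name = common[!zero],
             log2_enrichment = log2(e[!zero]),
             log2_kd_fc = log2(f[!zero]),
             stringsAsFactors = FALSE)
}

#' @export
print.memir_diff <- function(x, ...) {
  cat(sprintf("differential calls: %d references (%d up, %d down at primary threshold)\n",
              nrow(x), sum(x$status == "up"), sum(x$status == "down")))
  print.data.frame(head(x, 10), digits = 4)
  invisible(x)
}

#' @export
print.memir_enrichment <- function(x, ...) {
  cat(sprintf("RIP enrichment calls: %d references, %d methylated\n",
              nrow(x), sum(x$methylated)))
  print.data.frame(head(x, 10), digits = 4)
  invisible(x)
}
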