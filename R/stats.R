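#' Pearson product-moment correlation with least-squares line
#'
#' The standard product-moment coefficient between two equal-length vectors,
#' together with the slope and intercept of the ordinary least-squares
#' regression of `ys` on `xs` (the line drawn through an enrichment versus
#' knockdown-response scatter).
#'
#' @param xs,ys numeric vectors of equal length >= 3 with non-zero variance.
#' @return a `memir_cor` list: `r`, `n`, `slope`, `intercept`.
#' @export
pearson_r <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  if (sd(xs) == 0 || sd(ys) == 0) stop("zero variance in input")
  n <- length(xs)
  sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  r <- sxy / sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  slope <- sxy / sum((xs - mean(xs))^2)
  structure(list(r = r, n = n, slope = slope,
                 intercept = mean(ys) - slope * mean(xs)),
            class = "memir_cor")
}

#' @export
print.memir_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d); OLS line y = %.3f x + %.3f\n",
              x$r, x$n, x$slope, x$intercept))
  invisible(x)
}

#' Shapiro-Wilk normality test (Royston version)
#'
#' Interface wrapper around the standard Royston algorithm as implemented in
#' [stats::shapiro.test()].
#'
#' @param xs numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p.value`.
#' @export
shapiro_wilk <- function(xs) {
  if (length(xs) < 3 || length(xs) > 5000)
    stop("sample size must be between 3 and 5000")
  if (sd(xs) == 0) stop("zero variance in input")
  fit <- shapiro.test(xs)
  list(W = unname(fit$statistic), p.value = fit$p.value)
}

#' Export an enrichment versus knockdown-response scatter as TSV
#'
#' @param log2fc data frame from [log2_fold_changes()].
#' @param path TSV path.
#' @export
write_scatter_tsv <- function(log2fc, path) {
  write.table(log2fc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of enrichment versus knockdown response
#'
#' Log2 fold enrichment (x) against log2 knockdown fold change (y) with the
#' least-squares regression line dotted in red.
#'
#' @param log2fc data frame from [log2_fold_changes()].
#' @param ... further arguments to [plot()].
#' @return the [pearson_r()] fit, invisibly.
#' @export
plot_enrichment_scatter <- function(log2fc, ...) {
  fit <- pearson_r(log2fc$log2_enrichment, log2fc$log2_kd_fc)
  plot(log2fc$log2_enrichment, log2fc$log2_kd_fc,
       xlab = "log2 fold enrichment (m6A-IP / IgG-IP)",
       ylab = "log2 fold change (knockdown / scrambled)", pch = 19,
       col = "grey30", ...)
  graphics::abline(fit$intercept, fit$slope, col = "red", lty = 3, lwd = 2)
  invisible(fit)
}
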