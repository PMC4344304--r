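mk_counts <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  m
}

test_that("RPM normalization uses the non-spike denominator", {
  m <- matrix(5, 1, 1, dimnames = list("A", "s1"))
  expect_equal(normalize_rpm(m)[1, 1], 1e6)

  m2 <- mk_counts(A = 3, B = 1)
  colnames(m2) <- "s1"
  expect_equal(unname(normalize_rpm(m2)[, 1]), c(750000, 250000))

  m3 <- mk_counts(A = 3, spike = 97)
  colnames(m3) <- "s1"
  n3 <- normalize_rpm(m3, is_spike = c(FALSE, TRUE))
  expect_equal(n3["A", 1], 1e6)          # denominator excludes the spike
  expect_equal(n3["spike", 1], 97 / 3 * 1e6)

  zero <- matrix(0L, 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_warning(nz <- normalize_rpm(zero), "zero mapped")
  expect_true(all(nz == 0))
})

test_that("per-sample non-spike RPM sums are one million", {
  set.seed(501)
  counts <- matrix(rpois(50 * 4, 20), 50, 4,
                   dimnames = list(paste0("m", 1:50), paste0("s", 1:4)))
  spike <- seq_len(50) <= 5
  norm <- normalize_rpm(counts, spike)
  expect_equal(unname(colSums(norm[!spike, ])), rep(1e6, 4),
               tolerance = 1e-6)
})

test_that("expressed filter requires the floor in every sample", {
  norm <- rbind(ok = c(15, 15, 15), low = c(14.9, 100, 100),
                high = c(40, 50, 60))
  colnames(norm) <- paste0("s", 1:3)
  expect_setequal(filter_expressed(norm, min_rpm = 15), c("ok", "high"))

  # brute-force row scan on a random matrix
  set.seed(502)
  m <- matrix(runif(300, 0, 40), 100, 3,
              dimnames = list(paste0("m", 1:100), paste0("s", 1:3)))
  exp_scan <- rownames(m)[apply(m >= 15, 1, all)]
  expect_setequal(filter_expressed(m, min_rpm = 15), exp_scan)
})

test_that("differential calls follow the mean-fold-change thresholds", {
  norm <- rbind(dn = c(20, 18, 30, 5, 6, 9),
                edge = c(15, 15, 15, 7.5, 7.5, 7.5),
                up = c(10, 10, 10, 40, 40, 40),
                quiet = c(1, 1, 1, 0.2, 0.2, 0.2))
  colnames(norm) <- c(paste0("scr", 1:3), paste0("kd", 1:3))
  pairs <- data.frame(treated = paste0("kd", 1:3), control = paste0("scr", 1:3))
  calls <- call_differential(norm, pairs)

  dn <- calls[calls$name == "dn", ]
  expect_equal(dn$mean_fc, mean(c(5 / 20, 6 / 18, 9 / 30)))  # 0.2944
  expect_equal(dn$status, "down")

  # mean fold change exactly 0.5: "fewer than 50%" is strict
  expect_equal(calls$mean_fc[calls$name == "edge"], 0.5)
  expect_equal(calls$status[calls$name == "edge"], "none")

  up <- calls[calls$name == "up", ]
  expect_equal(up$mean_fc, 4)
  expect_equal(up$status, "up")
  expect_equal(up$status_alt, "up")

  # below the expression floor: no call despite a strong ratio
  expect_equal(calls$status[calls$name == "quiet"], "none")

  expect_error(call_differential(norm,
                                 data.frame(treated = "kd9", control = "scr1")),
               "kd9")
})

test_that("methylation calls combine the RPM floor and mean enrichment", {
  ip <- rbind(yes = c(250, 300, 260), lowrep = c(99, 300, 300),
              rescued = c(500, 500, 500), weak = c(150, 150, 150))
  igg <- rbind(yes = c(50, 60, 70), lowrep = c(10, 10, 10),
               rescued = c(0, 0, 0), weak = c(140, 150, 160))
  colnames(ip) <- paste0("m6A", 1:3); colnames(igg) <- paste0("IgG", 1:3)
  calls <- call_methylated(ip, igg)

  yes <- calls[calls$name == "yes", ]
  expect_equal(yes$mean_enrichment, mean((c(250, 300, 260) + 1) / (c(50, 60, 70) + 1)))
  expect_true(yes$methylated)

  expect_false(calls$methylated[calls$name == "lowrep"])  # 99 < 100 once
  resc <- calls[calls$name == "rescued", ]
  expect_true(is.finite(resc$mean_enrichment))            # pseudocount rescue
  expect_true(resc$methylated)
  expect_false(calls$methylated[calls$name == "weak"])    # enrichment ~1

  expect_equal(calls$mean_enrichment, sort(calls$mean_enrichment,
                                           decreasing = TRUE))
  expect_error(call_methylated(ip, igg[1:3, ]), "identical")
})

test_that("raising thresholds never grows the called sets", {
  set.seed(503)
  norm <- matrix(rlnorm(200 * 6, log(50), 1), 200, 6,
                 dimnames = list(paste0("m", 1:200),
                                 c(paste0("m6A", 1:3), paste0("IgG", 1:3))))
  ip <- norm[, 1:3]; igg <- norm[, 4:6]
  base <- call_methylated(ip, igg, rip_params(min_rpm = 50, min_fold = 1.5))
  stricter_rpm <- call_methylated(ip, igg, rip_params(min_rpm = 100, min_fold = 1.5))
  stricter_fold <- call_methylated(ip, igg, rip_params(min_rpm = 50, min_fold = 2.5))
  in_set <- function(x) x$name[x$methylated]
  expect_true(all(in_set(stricter_rpm) %in% in_set(base)))
  expect_true(all(in_set(stricter_fold) %in% in_set(base)))
  expect_true(all(filter_expressed(norm, min_rpm = 30) %in%
                    filter_expressed(norm, min_rpm = 15)))
})

test_that("log2 tables take logs of mean values and drop zero rows", {
  enr <- data.frame(name = c("a", "b", "c"),
                    mean_enrichment = c(0.5, 485.21, 0),
                    methylated = TRUE)
  class(enr) <- c("memir_enrichment", "data.frame")
  dif <- data.frame(name = c("a", "b", "c"), mean_fc = c(0.5, 1, 2))
  expect_message(lfc <- log2_fold_changes(enr, dif), "zero")
  expect_equal(lfc$name, c("a", "b"))
  expect_equal(lfc$log2_enrichment[1], -1)
  expect_equal(lfc$log2_enrichment[2], log2(485.21), tolerance = 1e-12)
  expect_equal(round(lfc$log2_enrichment[2], 2), 8.92)
  expect_equal(lfc$log2_kd_fc, c(-1, 0))
})
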