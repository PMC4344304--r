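test_that("motif space enumeration matches the closed form for all forms k <= 5", {
  # degenerate-class composition counts from one full enumeration per k
  for (k in 1:5) {
    full <- enumerate_motif_space(motif_space_form(k, k, k, k))
    expect_equal(length(full), 15^k)
    expect_false(is.unsorted(full))          # lexicographic order
    expect_equal(anyDuplicated(full), 0L)
    cls <- cbind(nchar(gsub("[^RYKMWS]", "", full)),
                 nchar(gsub("[^BDHV]", "", full)),
                 nchar(gsub("[^N]", "", full)))
    for (x in 0:k) for (y in 0:k) for (n in 0:k) {
      n_enum <- sum(cls[, 1] <= x & cls[, 2] <= y & cls[, 3] <= n)
      expect_equal(n_enum, oracle_space_size(k, x, y, n),
                   label = sprintf("form %d-%d-%d-%d", k, x, y, n))
    }
    # direct enumeration spot-checks against the composition table
    for (f in list(c(x = 1, y = 1, n = 1), c(x = k, y = 0, n = 0))) {
      expect_equal(motif_space_size(motif_space_form(k, f["x"], f["y"], f["n"])),
                   oracle_space_size(k, f["x"], f["y"], f["n"]))
    }
  }
  expect_equal(enumerate_motif_space(motif_space_form(1, 0, 0, 0)),
               c("A", "C", "G", "U"))
})

test_that("motif spaces are monotone in their caps", {
  small <- enumerate_motif_space(motif_space_form(3, 1, 0, 0))
  large <- enumerate_motif_space(motif_space_form(3, 2, 1, 1))
  expect_true(all(small %in% large))
})

test_that("stated containment examples hold", {
  expect_true(motif_matches_sequence("RAC", "GGACU"))
  expect_true(motif_matches_sequence("RRACH", "GGACU"))
  expect_false(motif_matches_sequence("RAC", "CCCCC"))
  expect_false(motif_matches_sequence("RRACH", "GAC"))  # motif longer than seq
})

test_that("containment equals the naive window-scan oracle on random pairs", {
  set.seed(601)
  for (i in 1:10000) {
    k <- sample(1:5, 1)
    motif <- random_iupac_motif(k)
    seq <- random_dna(sample(k:12, 1))
    expect_equal(motif_matches_sequence(motif, seq),
                 oracle_motif_match(motif, seq),
                 label = paste(motif, seq))
  }
})

test_that("contingency tables count per-sequence containment with fixed margins", {
  ip <- c("GGACU", "AGACU", "GGGGG")
  bg <- c("CCCCC", "UUUUU", "GACAC", "AAAAA")
  tb <- build_contingency("RAC", ip, bg)
  expect_equal(unname(tb), c(2L, 1L, 1L, 3L))
  expect_equal(tb[["a"]] + tb[["b"]], length(ip))
  expect_equal(tb[["c"]] + tb[["d"]], length(bg))

  all_in <- build_contingency("N", ip, bg)
  expect_equal(unname(all_in), c(3L, 0L, 4L, 0L))
})

test_that("two-sided Fisher p agrees with brute force and the stats routine", {
  expect_equal(fisher_two_sided(10, 10, 10, 10), 1.0)
  set.seed(602)
  for (i in 1:200) {
    a <- sample(0:50, 1); b <- sample(0:50, 1)
    c <- sample(0:50, 1); d <- sample(0:50, 1)
    if (a + b == 0 || c + d == 0) next
    p <- fisher_two_sided(a, b, c, d)
    expect_equal(p, oracle_fisher(a, b, c, d), tolerance = 1e-10,
                 label = paste(a, b, c, d))
    expect_equal(p,
                 stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
  expect_error(fisher_two_sided(-1, 2, 3, 4), "negative")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(1e-10, 2464), 2.464e-7)
  expect_equal(bonferroni(0.5, 10), 1.0)
  expect_equal(bonferroni(0, 1000), 0)
})

test_that("background model matches hand-computed smoothed counts", {
  m <- estimate_background_model("AAAA", 2)
  expect_equal(m$trans["A", "A"], (3 + 1) / (3 + 4))
  expect_equal(unname(rowSums(m$trans)), rep(1, 4), tolerance = 1e-9)

  # symmetric background (every dinucleotide once): uniform conditionals
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  sym <- estimate_background_model(dinucs, 2)
  expect_true(all(abs(sym$trans - 0.25) < 1e-9))
})

test_that("model p-value has the stated closed forms and tail monotonicity", {
  uni <- estimate_background_model(c("ACGT"), 1, order = 0)
  expect_equal(model_pvalue("A", "G", uni, a = 1), 0.25)
  expect_equal(model_pvalue("RAC", c("GGGG", "CCCC"), uni, a = 0), 1.0)

  ip <- c("GGACUGGACU", "ACGUACGUAC", "GGGGGGGGGG")
  bgm <- estimate_background_model(ip, 3)
  ps <- vapply(1:3, function(a) model_pvalue("GAC", ip, bgm, a = a), numeric(1))
  expect_true(all(diff(ps) < 0))  # p falls strictly as a rises

  # for one sequence, P(X >= 1) is the exact occurrence probability; check it
  # against a Monte Carlo estimate under a uniform order-0 model
  set.seed(603)
  sims <- replicate(10000, paste(sample(c("A", "C", "G", "T"), 8,
                                        replace = TRUE), collapse = ""))
  emp <- mean(grepl("G[AG]C", sims))
  p1 <- model_pvalue("GRC", "AAAAAAAA",
                     estimate_background_model(c("ACGT"), 3, order = 0), a = 1)
  expect_equal(p1, emp, tolerance = 0.05)
})

test_that("a planted motif outranks the space and null scans stay flat", {
  set.seed(604)
  plant_in <- function(seqs, motif, rate) {
    hit <- runif(length(seqs)) < rate
    for (i in which(hit)) {
      off <- sample(nchar(seqs[i]) - nchar(motif) + 1, 1)
      substr(seqs[i], off, off + nchar(motif) - 1) <- motif
    }
    seqs
  }
  ip <- plant_in(vapply(1:80, function(i) random_dna(22), character(1)),
                 "GAC", 0.8)
  bg <- vapply(1:800, function(i) random_dna(22), character(1))
  scan <- rank_motifs(motif_space_form(3, 2, 2, 0), ip, bg, model_p = TRUE)
  expect_equal(attr(scan, "space_size"), 2464L)
  expect_true(motif_matches_sequence(scan$motif[1], "GAC"))
  expect_true(all(scan$bonferroni_p >= scan$fisher_p))
  expect_lt(scan$bonferroni_p[1], 0.05)
  # scan counts equal direct containment for the top motif
  tb <- build_contingency(scan$motif[1], ip, bg)
  expect_equal(unname(unlist(scan[1, c("a", "b", "c", "d")])), unname(tb))
  # model p-value for the top motif is also extreme
  expect_lt(scan$model_p[1], 1e-4)

  # identical composition: nothing significant
  null_ip <- vapply(1:60, function(i) random_dna(22), character(1))
  null_bg <- vapply(1:600, function(i) random_dna(22), character(1))
  null_scan <- rank_motifs(motif_space_form(3, 2, 2, 0), null_ip, null_bg)
  expect_gt(min(null_scan$bonferroni_p), 0.05)

  expect_error(rank_motifs(motif_space_form(3, 2, 2, 0), character(), bg),
               "empty")
})
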