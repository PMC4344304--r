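ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("stated trimming examples hold", {
  insert <- "ACGTACGTACGTACGTACGTAC"  # 22-mer
  tr <- trim_adapter(paste0(insert, ADAPTER, "AAAAAAA"))
  expect_true(tr$adapter_found)
  expect_equal(tr$adapter_start, 22L)
  expect_equal(tr$trimmed_seq, insert)
  expect_equal(tr$read_class, "candidate")

  tr <- trim_adapter(strrep("A", 30))
  expect_false(tr$adapter_found)
  expect_equal(tr$trimmed_seq, strrep("A", 30))
  expect_equal(tr$read_class, "too_long")

  i14 <- "ACGTACGTACGTAC"
  tr <- trim_adapter(paste0(i14, ADAPTER, "CCCCCCCCCCCCCCC"))
  expect_equal(nchar(tr$trimmed_seq), 14L)
  expect_equal(tr$read_class, "too_short")
})

test_that("flush 3' adapter prefixes and the error budget behave as scored", {
  # exact 4-base prefix flush at the 3' end
  insert24 <- "ACGTACGTACGTACGTACGTACGT"
  read <- paste0(insert24, "TGGA")
  orc <- oracle_trim(read)
  tr <- trim_adapter(read)
  expect_true(tr$adapter_found)
  expect_equal(tr$adapter_start, orc$start)
  expect_equal(nchar(tr$trimmed_seq), 24L)

  # 4 substitutions in the full adapter (19% <= 20%) found; 5 (23.8%) not
  insert <- "ACGTACGTACGTACGTACGTAC"
  ad4 <- ADAPTER
  for (pos in c(2, 6, 10, 14))
    substr(ad4, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(ad4, pos, pos))[1]
  tr4 <- trim_adapter(paste0(insert, ad4, "AAAAAAA"))
  expect_true(tr4$adapter_found)
  expect_equal(tr4$n_errors, 4L)
  ad5 <- ad4
  substr(ad5, 18, 18) <- setdiff(c("A", "C", "G", "T"), substr(ad5, 18, 18))[1]
  expect_false(trim_adapter(paste0(insert, ad5, "AAAAAAA"))$adapter_found)
})

test_that("read length classification follows the 16-28 bp window", {
  p <- trim_params()
  expect_equal(classify_read(15, p), "too_short")
  expect_equal(classify_read(16, p), "candidate")
  expect_equal(classify_read(28, p), "candidate")
  expect_equal(classify_read(29, p), "too_long")
})

test_that("trimming never lengthens a read and is idempotent when no placement", {
  set.seed(301)
  reads <- vapply(1:50, function(i) random_dna(sample(20:50, 1)), character(1))
  tr <- trim_adapter(reads)
  expect_true(all(nchar(tr$trimmed_seq) <= nchar(reads)))
  none <- !tr$adapter_found
  retr <- trim_adapter(tr$trimmed_seq[none])
  # reads whose first pass found nothing admissible still find nothing
  expect_equal(retr$trimmed_seq, tr$trimmed_seq[none])
})

test_that("planted inserts are recovered exactly under adapter-confined errors", {
  set.seed(302)
  for (i in 1:40) {
    ins_len <- sample(16:28, 1)
    # a CC suffix keeps the insert/adapter boundary unambiguous (the adapter
    # front carries no C), so the planted insert is recoverable bit-exactly
    insert <- paste0(random_dna(ins_len - 2), "CC")
    ad <- ADAPTER
    n_err <- sample(0:4, 1)  # floor(0.2 * 21) = 4
    # a substitution at the adapter's first base is indistinguishable from a
    # shifted boundary when the insert ends with that base; keep errors inside
    for (pos in sample(2:nchar(ad), n_err))
      substr(ad, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                      substr(ad, pos, pos))[1]
    read <- substr(paste0(insert, ad, random_dna(50)), 1, 50)
    # only keep fixtures whose insert carries no admissible placement itself
    if (oracle_trim(insert)$found) next
    tr <- trim_adapter(read)
    expect_true(tr$adapter_found)
    expect_equal(tr$trimmed_seq, insert)
  }
})

test_that("trimmer agrees with the brute-force placement enumerator", {
  set.seed(303)
  n_cases <- 1000
  reads <- character(n_cases)
  for (i in seq_len(n_cases)) {
    mode <- sample(3, 1)
    if (mode == 1) {              # pure random read
      reads[i] <- random_dna(sample(10:50, 1))
    } else if (mode == 2) {       # insert + adapter (+- errors) + pad
      insert <- random_dna(sample(5:30, 1))
      ad <- ADAPTER
      for (pos in sample(nchar(ad), sample(0:5, 1)))
        substr(ad, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      reads[i] <- substr(paste0(insert, ad, random_dna(50)), 1, 50)
    } else {                      # insert + truncated adapter at the 3' end
      insert <- random_dna(sample(10:40, 1))
      reads[i] <- paste0(insert, substr(ADAPTER, 1, sample(1:12, 1)))
    }
  }
  got <- trim_adapter(reads)
  for (i in seq_len(n_cases)) {
    orc <- oracle_trim(reads[i])
    expect_equal(got$adapter_found[i], orc$found, label = reads[i])
    if (orc$found) {
      expect_equal(got$adapter_start[i], orc$start, label = reads[i])
      expect_equal(got$n_errors[i], orc$errors, label = reads[i])
    }
  }
})

test_that("FASTQ round trip keeps qualities aligned with trimmed reads", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  out <- withr::local_tempfile(fileext = ".fastq")
  insert <- "ACGTACGTACGTACGTACGTAC"
  reads <- c(paste0(insert, ADAPTER, "AAAAAAA"), strrep("G", 50))
  writeLines(c("@r1", reads[1], "+", strrep("F", nchar(reads[1])),
               "@r2", reads[2], "+", strrep("D", 50)), fq)
  rep <- trim_fastq(fq, out)
  expect_equal(rep$total, 2L)
  expect_equal(rep$candidate, 1L)
  expect_equal(rep$too_long, 1L)
  lines <- readLines(out)
  expect_equal(lines[2], insert)
  expect_equal(lines[4], strrep("F", nchar(insert)))
})
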