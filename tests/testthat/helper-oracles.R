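# Independent brute-force oracles, written directly from the operation
# contracts in pure R. They share no code with the package internals.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# ---- MEM oracle: enumerate every read interval, test occurrence-in-ref and
# both one-character extensions --------------------------------------------
oracle_find_mems <- function(read, ref, min_len) {
  n <- nchar(read)
  occurs <- function(s) grepl(s, ref, fixed = TRUE)
  out <- list()
  for (p in 0:(n - 1)) {
    if (n - p < min_len) next
    for (L in min_len:(n - p)) {
      if (L < 1) next
      sub <- substr(read, p + 1, p + L)
      if (!occurs(sub)) next
      left_ok <- p == 0 || !occurs(substr(read, p, p + L))
      right_ok <- p + L == n || !occurs(substr(read, p + 1, p + L + 1))
      if (left_ok && right_ok) out[[length(out) + 1]] <- c(p, L)
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 2,
                                  dimnames = list(NULL, c("start", "length"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "length")
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

oracle_coverage <- function(mems) {
  if (nrow(mems) == 0) return(0L)
  length(unique(unlist(apply(mems, 1, function(r) seq(r[1], r[1] + r[2] - 1)))))
}

# per-read assignment straight from the contract
oracle_assign <- function(read, catalog, min_mem_len = 7, min_coverage = 17) {
  cov <- vapply(seq_len(nrow(catalog)), function(i) {
    oracle_coverage(oracle_find_mems(read, chartr("U", "T", catalog$sequence[i]),
                                     min_mem_len))
  }, numeric(1))
  elig <- which(cov >= min_coverage)
  if (!length(elig)) return(list(ref = NA_character_, covered = 0, tie = FALSE))
  best <- elig[cov[elig] == max(cov[elig])]
  nm <- sort(catalog$name[best], method = "radix")
  list(ref = nm[1], covered = max(cov[elig]), tie = length(best) > 1)
}

# ---- adapter placement oracle: score every placement with a plain
# edit-distance DP; same admissibility and selection rules -------------------
oracle_edit_dp <- function(pattern, text) {
  # D[i+1, j+1] = min edits pattern[1..i] vs text[1..j]; M tracks matches of a
  # minimal-cost alignment (ties resolved toward more matches)
  np <- nchar(pattern); nt <- nchar(text)
  D <- matrix(0L, np + 1, nt + 1); M <- matrix(0L, np + 1, nt + 1)
  D[, 1] <- 0:np
  D[1, ] <- 0:nt
  pc <- strsplit(pattern, "")[[1]]; tc <- strsplit(text, "")[[1]]
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    eq <- pc[i] == tc[j] && tc[j] != "N"
    cand_cost <- c(D[i, j] + !eq, D[i, j + 1] + 1L, D[i + 1, j] + 1L)
    cand_match <- c(M[i, j] + eq, M[i, j + 1], M[i + 1, j])
    best <- which(cand_cost == min(cand_cost))
    pick <- best[which.max(cand_match[best])]
    D[i + 1, j + 1] <- cand_cost[pick]
    M[i + 1, j + 1] <- cand_match[pick]
  }
  list(D = D, M = M)
}

# exact min-cost screen (row-vectorized; the left-neighbour chain is the
# classic j + cummin(row - j) identity) returning starts with any admissible
# placement
oracle_admissible_starts <- function(read, adapter, min_overlap, rate) {
  n <- nchar(read); m <- nchar(adapter)
  pc <- strsplit(adapter, "")[[1]]
  tcs <- strsplit(read, "")[[1]]
  full_budget <- floor(rate * m)
  ok <- logical(n)
  for (p in 0:(n - 1)) {
    tc <- tcs[(p + 1):n]
    len <- length(tc)
    seq0 <- 0:len
    prevD <- seq0
    for (i in seq_len(m)) {
      sub <- ifelse(tc == pc[i] & tc != "N", 0L, 1L)
      row <- c(i, pmin(prevD[1:len] + sub, prevD[2:(len + 1)] + 1L))
      row <- pmin(row, seq0 + cummin(row - seq0))
      if (i == m && any(row <= full_budget)) ok[p + 1] <- TRUE
      if (i >= min_overlap && row[len + 1] <= floor(rate * i)) ok[p + 1] <- TRUE
      prevD <- row
    }
  }
  which(ok) - 1L
}

oracle_trim <- function(read, adapter = "TGGAATTCTCGGGTGCCAAGG",
                        min_overlap = 4, rate = 0.2) {
  n <- nchar(read); m <- nchar(adapter)
  cands <- list()
  for (p in oracle_admissible_starts(read, adapter, min_overlap, rate)) {
    suffix <- substr(read, p + 1, n)
    dp <- oracle_edit_dp(adapter, suffix)
    len <- nchar(suffix)
    # (a) full adapter, any end within the suffix
    for (j in 0:len) {
      e <- dp$D[m + 1, j + 1]
      if (e <= floor(rate * m))
        cands[[length(cands) + 1]] <- c(p, e, dp$M[m + 1, j + 1])
    }
    # (b) adapter prefix flush with the 3' end
    for (l in min_overlap:m) {
      e <- dp$D[l + 1, len + 1]
      if (e <= floor(rate * l))
        cands[[length(cands) + 1]] <- c(p, e, dp$M[l + 1, len + 1])
    }
  }
  if (!length(cands))
    return(list(found = FALSE, start = NA_integer_, errors = NA_integer_))
  tab <- do.call(rbind, cands)
  ord <- order(-tab[, 3], tab[, 2], tab[, 1])
  list(found = TRUE, start = tab[ord[1], 1], errors = tab[ord[1], 2])
}

# ---- Fisher oracle: literal sum over all tables with the observed margins --
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  p_table <- function(a2) {
    b2 <- a + b - a2; c2 <- a + c - a2; d2 <- d - a + a2
    if (min(b2, c2, d2) < 0) return(NA_real_)
    exp(lchoose(a2 + b2, a2) + lchoose(c2 + d2, c2) - lchoose(n, a2 + c2))
  }
  probs <- vapply(0:(a + b), p_table, numeric(1))
  probs <- probs[!is.na(probs)]
  sum(probs[probs <= p_table(a) * (1 + 1e-7)])
}

# ---- naive IUPAC window-scan oracle ---------------------------------------
IUPAC_ORACLE <- list(A = "A", C = "C", G = "G", U = "T", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"),
                     M = c("A", "C"), W = c("A", "T"), S = c("C", "G"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracle_motif_match <- function(motif, seq) {
  seq <- chartr("U", "T", toupper(seq))
  mc <- strsplit(toupper(motif), "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  k <- length(mc); L <- length(sc)
  if (k > L) return(FALSE)
  for (s in 0:(L - k)) {
    ok <- TRUE
    for (i in seq_len(k)) {
      if (!(sc[s + i] %in% IUPAC_ORACLE[[mc[i]]])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# ---- inclusion-exclusion closed form for k-x-y-n space sizes ---------------
oracle_space_size <- function(k, x, y, n) {
  tot <- 0
  for (i in 0:x) for (j in 0:y) for (l in 0:n) {
    r <- k - i - j - l
    if (r < 0) next
    tot <- tot + factorial(k) / (factorial(i) * factorial(j) *
                                   factorial(l) * factorial(r)) *
      6^i * 4^j * 1^l * 4^r
  }
  tot
}

random_iupac_motif <- function(k) {
  paste(sample(names(IUPAC_ORACLE)[names(IUPAC_ORACLE) != "T"], k,
               replace = TRUE), collapse = "")
}
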