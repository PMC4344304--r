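#' IUPAC nucleotide codes
#'
#' The 15-letter degenerate alphabet: the four bases, the twofold codes
#' R,Y,K,M,W,S, the threefold codes B,D,H,V, and N. U and T are treated as the
#' same symbol throughout motif matching.
#'
#' @format named list mapping each code to its base set (DNA spelling).
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"),
  M = c("A", "C"), W = c("A", "T"), S = c("C", "G"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_TWOFOLD <- c("R", "Y", "K", "M", "W", "S")
IUPAC_THREEFOLD <- c("B", "D", "H", "V")
# lexicographic (ASCII) order of the full alphabet, U for the RNA base
IUPAC_ALPHABET <- sort(names(IUPAC_SETS), method = "radix")

iupac_class <- function(ch) {
  ifelse(ch %in% IUPAC_TWOFOLD, "two",
         ifelse(ch %in% IUPAC_THREEFOLD, "three",
                ifelse(ch == "N", "n", "base")))
}

#' A k-x-y-n motif space form
#'
#' Motifs of length `k` over the 15-letter IUPAC alphabet with at most `x`
#' twofold-degenerate characters (R,Y,K,M,W,S), at most `y` threefold
#' characters (B,D,H,V) and at most `n` Ns.
#'
#' @param k motif length.
#' @param x,y,n per-class caps.
#' @return a `motif_space_form` list.
#' @export
motif_space_form <- function(k, x, y, n) {
  stopifnot(k >= 1, x >= 0, y >= 0, n >= 0, x <= k, y <= k, n <= k)
  structure(list(k = as.integer(k), x = as.integer(x), y = as.integer(y),
                 n = as.integer(n)), class = "motif_space_form")
}

#' Enumerate a k-x-y-n IUPAC motif space
#'
#' Generates every length-`k` string over the 15-letter IUPAC alphabet
#' respecting the form's per-class caps, each exactly once, in lexicographic
#' order.
#'
#' @param form a [motif_space_form()], or `k` when `x`,`y`,`n` are given.
#' @param x,y,n per-class caps when `form` is a bare length.
#' @return character vector of motif patterns (RNA spelling, with U).
#' @export
enumerate_motif_space <- function(form, x = NULL, y = NULL, n = NULL) {
  if (!inherits(form, "motif_space_form"))
    form <- motif_space_form(form, x, y, n)
  k <- form$k
  cls <- iupac_class(IUPAC_ALPHABET)
  # expand.grid varies its first argument fastest; feed positions reversed so
  # that position 1 is most significant, giving lexicographic output order
  grid <- as.matrix(expand.grid(rev(rep(list(seq_along(IUPAC_ALPHABET)), k)),
                                KEEP.OUT.ATTRS = FALSE))[, k:1, drop = FALSE]
  cl <- matrix(cls[grid], ncol = k)
  keep <- rowSums(cl == "two") <= form$x &
    rowSums(cl == "three") <= form$y &
    rowSums(cl == "n") <= form$n
  letters_mat <- matrix(IUPAC_ALPHABET[grid[keep, , drop = FALSE]], ncol = k)
  do.call(paste0, as.data.frame(letters_mat, stringsAsFactors = FALSE))
}

#' @describeIn enumerate_motif_space number of motifs in the space (by direct
#'   enumeration).
#' @export
motif_space_size <- function(form, x = NULL, y = NULL, n = NULL) {
  length(enumerate_motif_space(form, x, y, n))
}

motif_to_regex <- function(motif) {
  chars <- strsplit(chartr("T", "U", toupper(motif)), "")[[1]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad)) stop("invalid IUPAC character(s): ",
                     paste(unique(chars[bad]), collapse = ", "))
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Does a sequence contain an IUPAC motif?
#'
#' Containment: some window of the sequence matches the motif, where each
#' motif character's IUPAC base set must contain the sequence base and N
#' matches any base. U and T are interchangeable on both sides. A motif longer
#' than the sequence never matches.
#'
#' @param motif IUPAC pattern (scalar).
#' @param seqs character vector of sequences.
#' @return logical vector, one per sequence.
#' @export
motif_matches_sequence <- function(motif, seqs) {
  grepl(motif_to_regex(motif), rna_to_dna(toupper(seqs)))
}

#' 2x2 contingency table of motif containment
#'
#' Counts how many immunoprecipitated and background sequences contain the
#' motif (per-sequence containment; occurrence multiplicity is ignored).
#'
#' @param motif IUPAC pattern.
#' @param ip_seqs,bg_seqs character vectors (disjoint sets).
#' @return named integer vector `c(a, b, c, d)`: IP with / IP without /
#'   background with / background without.
#' @export
build_contingency <- function(motif, ip_seqs, bg_seqs) {
  a <- sum(motif_matches_sequence(motif, ip_seqs))
  cc <- sum(motif_matches_sequence(motif, bg_seqs))
  c(a = a, b = length(ip_seqs) - a, c = cc, d = length(bg_seqs) - cc)
}

#' Two-sided Fisher exact test (point-probability method)
#'
#' The two-sided p-value is the sum, over all tables with the observed
#' margins, of hypergeometric probabilities not exceeding that of the observed
#' table (within relative tolerance 1e-7). Vectorized over tables.
#'
#' @param a,b,c,d cell counts (`a`,`b` = first group with/without; `c`,`d` =
#'   second group with/without), or `a` may be a length-4 vector / 2x2 matrix.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    tb <- as.vector(a)
    stopifnot(length(tb) == 4L)
    a <- tb[1]; b <- tb[2]; c <- tb[3]; d <- tb[4]
  }
  if (any(c(a, b, c, d) < 0)) stop("negative cell counts")
  if (any(a + b == 0L) || any(c + d == 0L)) stop("zero margin")
  mapply(function(a, b, c, d) {
    m <- a + c; n <- b + d; kk <- a + b
    supp <- max(0L, kk - n):min(kk, m)
    pr <- dhyper(supp, m, n, kk)
    sum(pr[pr <= dhyper(a, m, n, kk) * (1 + 1e-7)])
  }, a, b, c, d)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param m number of tests (size of the scanned motif space).
#' @return `min(1, p * m)`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

# ---- Markov background model ------------------------------------------------

count_kmers <- function(seqs, k) {
  seqs <- rna_to_dna(toupper(seqs))
  all <- enumerate_motif_space(motif_space_form(k, 0, 0, 0))
  all <- rna_to_dna(all)
  counts <- setNames(integer(length(all)), all)
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    km <- substring(s, 1:(L - k + 1), k:L)
    tb <- table(km)
    idx <- match(names(tb), all)
    ok <- !is.na(idx)
    counts[idx[ok]] <- counts[idx[ok]] + as.integer(tb)[ok]
  }
  counts
}

#' Estimate a Markov background text model from k-mer counts
#'
#' Transition probabilities of an order-`order` Markov chain are estimated
#' from the pooled (order+1)-mer counts of the background sequences with
#' add-one smoothing; the initial distribution over order-mers likewise.
#'
#' @param bg_seqs background sequences.
#' @param k the motif length the model will serve (default order is `k - 1`,
#'   i.e. a text model built from the k-mers).
#' @param order Markov order, `0 <= order <= k - 1`.
#' @return a `background_model` list with elements `order`, `trans`
#'   (4^order x 4 row-stochastic matrix) and `init` (length 4^order).
#' @export
estimate_background_model <- function(bg_seqs, k, order = k - 1) {
  stopifnot(length(bg_seqs) >= 1, order >= 0, order <= k - 1)
  cnt <- count_kmers(bg_seqs, order + 1)
  trans <- matrix(cnt + 1, nrow = 4^order, ncol = 4, byrow = TRUE)
  trans <- trans / rowSums(trans)
  rownames(trans) <- if (order > 0)
    rna_to_dna(enumerate_motif_space(motif_space_form(order, 0, 0, 0))) else ""
  colnames(trans) <- DNA_BASES
  if (order > 0) {
    icnt <- count_kmers(bg_seqs, order)
    init <- (icnt + 1) / (sum(icnt) + 4^order)
  } else init <- setNames(1, "")
  structure(list(order = order, trans = trans, init = init, k = k),
            class = "background_model")
}

# P(>= 1 occurrence of motif) in a random text of each length 1..Lmax under
# the model, by dynamic programming over (position, last k-1 bases), removing
# probability mass the moment a window completes the motif.
motif_occurrence_prob <- function(motif, model, lengths) {
  motif <- rna_to_dna(toupper(motif))
  k <- nchar(motif)
  sets <- IUPAC_SETS[strsplit(chartr("T", "U", motif), "")[[1]]]
  ord <- model$order
  ctx <- k - 1L
  Lmax <- max(lengths)
  q <- setNames(numeric(length(lengths)), lengths)
  if (Lmax < k) return(q)
  # per-position base masks of the motif
  inset <- vapply(sets, function(s) DNA_BASES %in% s, logical(4))  # 4 x k
  if (ctx == 0L) {
    # single-character motif: each emitted base is its own window
    u <- 1
    probs <- model$trans[1, ]
    surv <- sum(probs[!inset[, 1]])
    for (t in seq_len(Lmax)) {
      u <- u * surv
      hit <- match(t, lengths)
      if (!is.na(hit)) q[hit] <- 1 - u
    }
    return(q)
  }
  nstate <- 4^ctx
  states <- seq_len(nstate) - 1L
  base_at <- function(code, pos_from_left, width)  # 0-based digits
    (code %/% 4^(width - pos_from_left)) %% 4
  # does the ctx-mer prefix of a window match motif positions 1..ctx? and
  # transition context rows: last `ord` bases of each state
  row_of <- states %% 4^ord + 1L
  # alive-state mask never needed: windows only complete on a new base
  # kill[s, b]: appending base b (0..3) to context s completes the motif
  kill <- matrix(FALSE, nstate, 4)
  prefix_ok <- rep(TRUE, nstate)
  for (j in seq_len(ctx))
    prefix_ok <- prefix_ok & inset[base_at(states, j, ctx) + 1L, j]
  for (b in 0:3) kill[, b + 1L] <- prefix_ok & inset[b + 1L, k]
  # distribution over the first ctx bases (no window can exist yet)
  if (ord == ctx) {
    u <- as.numeric(model$init)
  } else {
    # grow a prefix from the order-mer initial distribution
    u <- as.numeric(model$init)           # over 4^ord prefixes
    width <- ord
    while (width < ctx) {
      nn <- 4^(width + 1)
      v <- numeric(nn)
      pre <- seq_len(4^width) - 1L
      rows <- pre %% 4^ord + 1L
      for (b in 0:3) v[pre * 4L + b + 1L] <- u * model$trans[rows, b + 1L]
      u <- v
      width <- width + 1L
    }
  }
  # state s encodes the last ctx bases, first base most significant:
  # s = f * 4^(ctx-1) + r; appending base b moves to state r * 4 + b
  M <- 4^(ctx - 1L)
  for (t in (ctx + 1):Lmax) {
    v <- numeric(nstate)
    for (b in 0:3) {
      w <- u * model$trans[row_of, b + 1L]
      w[kill[, b + 1L]] <- 0
      by_r <- rowSums(matrix(w, nrow = M))  # sum out the dropped first base
      idx <- (seq_len(M) - 1L) * 4L + b + 1L
      v[idx] <- v[idx] + by_r
    }
    u <- v
    hit <- match(t, lengths)
    if (!is.na(hit)) q[hit] <- 1 - sum(u)
  }
  q
}

#' Background-model p-value of a motif's IP occurrence count
#'
#' For each immunoprecipitated sequence the probability q_i of at least one
#' motif occurrence in a random text of the same length is computed exactly by
#' dynamic programming under the Markov background model; the p-value is the
#' upper tail P(X >= a) of the Poisson-binomial sum of the independent
#' per-sequence indicators (a = observed number of IP sequences containing
#' the motif), computed by convolution.
#'
#' @param motif IUPAC pattern.
#' @param ip_seqs immunoprecipitated sequences.
#' @param model a [estimate_background_model()] fit.
#' @param a optional observed containment count (recomputed if missing).
#' @return p-value in `[0, 1]`.
#' @export
model_pvalue <- function(motif, ip_seqs, model, a = NULL) {
  if (is.null(a)) a <- sum(motif_matches_sequence(motif, ip_seqs))
  if (a == 0L) return(1.0)
  lens <- nchar(ip_seqs)
  tab <- table(lens)
  q <- motif_occurrence_prob(motif, model, as.integer(names(tab)))
  # X = sum over length groups of Binomial(n_len, q_len); convolve pmfs
  pmf <- 1
  for (i in seq_along(tab)) {
    g <- dbinom(0:as.integer(tab[i]), as.integer(tab[i]), q[i])
    pmf <- convolve_pmf(pmf, g)
  }
  sum(pmf[(a + 1):length(pmf)])
}

convolve_pmf <- function(f, g) {
  out <- numeric(length(f) + length(g) - 1L)
  for (i in seq_along(f)) {
    idx <- i:(i + length(g) - 1L)
    out[idx] <- out[idx] + f[i] * g
  }
  out
}

# ---- full-space scan --------------------------------------------------------

# indices (1-based, into the 4^k concrete k-mer table in lexicographic DNA
# order) of a motif's concrete expansions
expand_motif_codes <- function(motif) {
  sets <- IUPAC_SETS[strsplit(chartr("T", "U", rna_to_dna(toupper(motif))),
                              "")[[1]]]
  v <- 0L
  for (s in sets) v <- as.vector(outer(v * 4L, match(s, DNA_BASES) - 1L, `+`))
  v + 1L
}

kmer_presence_matrix <- function(seqs, k) {
  seqs <- rna_to_dna(toupper(seqs))
  nk <- 4^k
  kmers <- rna_to_dna(enumerate_motif_space(motif_space_form(k, 0, 0, 0)))
  pres <- matrix(0, length(seqs), nk)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    if (L < k) next
    idx <- match(unique(substring(seqs[i], 1:(L - k + 1), k:L)), kmers)
    pres[i, idx[!is.na(idx)]] <- 1
  }
  pres
}

#' Scan a motif space for discrimination between IP and background sets
#'
#' Every motif in the k-x-y-n space is scored on its 2x2 per-sequence
#' containment table (IP vs background) with the two-sided Fisher exact test,
#' Bonferroni-corrected by the space size, and optionally with the Markov
#' background-model p-value. Containment is computed by uniting the per-
#' sequence k-mer presence sets of each motif's concrete expansions; Fisher
#' p-values are cached by table since margins are fixed across the scan.
#'
#' @param form a [motif_space_form()].
#' @param ip_seqs,bg_seqs the two sequence sets.
#' @param model_p compute the background-model p-value column (slower).
#' @param model optional pre-fitted [estimate_background_model()]; fitted from
#'   `bg_seqs` at order `k - 1` when omitted and `model_p` is TRUE.
#' @param chunk_size motifs scored per block (memory control for large spaces).
#' @return a `memir_motif_scan` data frame sorted by ascending `fisher_p`
#'   (ties by pattern): `motif`, `a`, `b`, `c`, `d`, `fisher_p`,
#'   `bonferroni_p`, and `model_p` when requested.
#' @export
rank_motifs <- function(form, ip_seqs, bg_seqs, model_p = FALSE, model = NULL,
                        chunk_size = 20000L) {
  if (length(ip_seqs) == 0L) stop("empty IP set")
  if (length(bg_seqs) == 0L) stop("empty background set")
  k <- form$k
  motifs <- enumerate_motif_space(form)
  m_space <- length(motifs)
  pres_ip <- kmer_presence_matrix(ip_seqs, k)
  pres_bg <- kmer_presence_matrix(bg_seqs, k)
  nk <- 4^k
  a_all <- integer(m_space); c_all <- integer(m_space)
  for (lo in seq(1L, m_space, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, m_space)
    block <- motifs[lo:hi]
    memb <- matrix(0, nk, length(block))
    for (j in seq_along(block)) memb[expand_motif_codes(block[j]), j] <- 1
    a_all[lo:hi] <- colSums(pres_ip %*% memb > 0)
    c_all[lo:hi] <- colSums(pres_bg %*% memb > 0)
  }
  nip <- length(ip_seqs); nbg <- length(bg_seqs)
  key <- paste(a_all, c_all)
  uk <- !duplicated(key)
  p_u <- fisher_two_sided(a_all[uk], nip - a_all[uk],
                          c_all[uk], nbg - c_all[uk])
  fisher_p <- p_u[match(key, key[uk])]
  out <- data.frame(motif = motifs, a = a_all, b = nip - a_all,
                    c = c_all, d = nbg - c_all,
                    fisher_p = fisher_p,
                    bonferroni_p = bonferroni(fisher_p, m_space),
                    stringsAsFactors = FALSE)
  if (model_p) {
    if (is.null(model)) model <- estimate_background_model(bg_seqs, k)
    lens <- table(nchar(ip_seqs))
    out$model_p <- vapply(seq_len(m_space), function(i) {
      if (out$a[i] == 0L) return(1.0)
      q <- motif_occurrence_prob(out$motif[i], model,
                                 as.integer(names(lens)))
      pmf <- 1
      for (j in seq_along(lens))
        pmf <- convolve_pmf(pmf, dbinom(0:as.integer(lens[j]),
                                        as.integer(lens[j]), q[j]))
      sum(pmf[(out$a[i] + 1):length(pmf)])
    }, numeric(1))
  }
  out <- out[order(out$fisher_p, out$motif, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "space_size") <- m_space
  attr(out, "form") <- form
  class(out) <- c("memir_motif_scan", "data.frame")
  out
}

#' @export
print.memir_motif_scan <- function(x, ...) {
  f <- attr(x, "form")
  cat(sprintf("motif scan: form %d-%d-%d-%d, %d motifs; top hits:\n",
              f$k, f$x, f$y, f$n, attr(x, "space_size")))
  print.data.frame(head(x, 10), digits = 3)
  invisible(x)
}

#' Write the top motifs of a scan as TSV
#' @param scan a `memir_motif_scan`.
#' @param path TSV path.
#' @param top number of motifs to keep (default 50, supplementary-table style).
#' @export
write_motif_report <- function(scan, path, top = 50L) {
  write.table(head(as.data.frame(scan), top), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
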