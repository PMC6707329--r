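# Independent oracles used to check the package's operations.
# Each takes a deliberately different route from the implementation it
# verifies (codon-table re-translation, exhaustive substring or subset
# enumeration, hand-rolled step-up, combinatorial sums).

# Frame translation via seqinr's codon table, split at '*' by hand.
oracle_translate_frame <- function(sequence, frame) {
  chars <- seqinr::s2c(tolower(sequence))
  n_codon <- (length(chars) - frame) %/% 3
  if (n_codon < 1) return(character(0))
  aa <- seqinr::translate(chars[(frame + 1):(frame + 3 * n_codon)])
  paste(aa, collapse = "")
}

oracle_orf_segments <- function(sequence, frame, min_len) {
  aa <- oracle_translate_frame(sequence, frame)
  if (!length(aa) || !nzchar(aa)) return(character(0))
  segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
  segs[nchar(segs) >= min_len]
}

# Tryptic digestion by filtering all O(n^2) substrings for validity.
oracle_digest <- function(sequence, max_missed, min_len) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_site <- function(k) k >= 1 && k < n && chars[k] %in% c("K", "R") &&
    chars[k + 1] != "P"
  rows <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_len) next
      ok_start <- i == 1 || is_site(i - 1)
      ok_end <- j == n || is_site(j)
      if (!ok_start || !ok_end) next
      internal <- sum(vapply(seq(i, j - 1, length.out = max(0, j - i)),
                             is_site, logical(1)))
      if (j == i) internal <- 0
      pep <- substr(sequence, i, j)
      if (internal <= max_missed && !grepl("X", pep, fixed = TRUE))
        rows[[length(rows) + 1]] <- data.frame(sequence = pep,
                                               start = i - 1L,
                                               missed = internal)
    }
  }
  if (!length(rows)) return(data.frame(sequence = character(),
                                       start = integer(),
                                       missed = integer()))
  out <- do.call(rbind, rows)
  out[order(out$start, nchar(out$sequence)), ]
}

# Maximum non-overlapping distinct-peptide interval set by exhaustive
# bitmask enumeration over occurrence subsets.
oracle_max_nonoverlap <- function(occ) {
  n <- nrow(occ)
  if (n == 0) return(0L)
  stopifnot(n <= 16)
  masks <- 0:(2^n - 1)
  ok <- rep(TRUE, length(masks))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      conflict <- occ$peptide[i] == occ$peptide[j] ||
        (occ$start[i] < occ$end[j] && occ$start[j] < occ$end[i])
      if (conflict) {
        pm <- bitwOr(bitwShiftL(1L, i - 1L), bitwShiftL(1L, j - 1L))
        ok <- ok & bitwAnd(masks, pm) != pm
      }
    }
  }
  pop <- rowSums(sapply(seq_len(n), function(k)
    bitwAnd(masks, bitwShiftL(1L, k - 1L)) > 0))
  max(pop[ok])
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Upper-tail hypergeometric probability as a combinatorial sum.
oracle_hyper <- function(overlap, category, universe, selected) {
  i <- overlap:min(category, selected)
  sum(choose(category, i) * choose(universe - category, selected - i)) /
    choose(universe, selected)
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                      "I", "K", "L", "M", "N", "P", "Q",
                                      "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

small_sim_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_groups = 30, n_tissues = 5, n_celllines = 4,
         samples_per_context = 2, n_cancer = 16, n_normal = 8),
    list(...))
  do.call(sim_config, args)
}
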