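# Shared-peptide grouping, the non-overlap counting rule, median LFQ and
# the peptide-consistency diagnostics.

ev_from_map <- function(map, samples = c("s1", "s2")) {
  # map: named list peptide -> character vector of transcript ids
  entries <- vapply(map, function(tx)
    paste(orf_entry_id(tx, 0L, 0L), collapse = ";"), character(1))
  m <- matrix(1e6, length(map), length(samples),
              dimnames = list(NULL, samples))
  peptide_evidence(names(map), unname(entries), m)
}

test_that("transcripts with identical or subsumed peptide sets merge", {
  # identical sets
  g <- group_shared_peptides(ev_from_map(list(
    PEPAK = c("A", "B"), PEPBK = c("A", "B"))))
  expect_equal(nrow(g$groups), 1L)
  expect_equal(g$groups$members, "A;B")
  expect_equal(sort(g$unique_peptides[[1]]), c("PEPAK", "PEPBK"))

  # subsumption: B's set {p1} is inside A's {p1, p2}
  g <- group_shared_peptides(ev_from_map(list(
    PEPAK = c("A", "B"), PEPBK = "A")))
  expect_equal(nrow(g$groups), 1L)
  expect_equal(g$groups$group_id, "A")
  expect_equal(g$groups$members, "A;B")

  # partial overlap: two groups, shared peptide excluded from both
  g <- group_shared_peptides(ev_from_map(list(
    PEPAK = "A", PEPBK = c("A", "B"), PEPCK = "B")))
  expect_equal(nrow(g$groups), 2L)
  expect_equal(g$nonunique_peptides, "PEPBK")
  expect_equal(sort(unlist(g$unique_peptides)), c("PEPAK", "PEPCK"))
})

test_that("grouping is invariant to transcript/peptide input order", {
  map <- list(P1K = c("A", "B"), P2K = "A", P3K = c("C", "A"),
              P4K = "C", P5K = "D")
  g1 <- group_shared_peptides(ev_from_map(map))
  g2 <- group_shared_peptides(ev_from_map(rev(map)))
  o1 <- g1$groups[order(g1$groups$group_id), c("group_id", "members")]
  o2 <- g2$groups[order(g2$groups$group_id), c("group_id", "members")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("peptides mapping outside the lncRNA namespace are dropped", {
  ev <- peptide_evidence(c("AAAAK", "CCCCK"),
                         c("lncpep|A|F0|S0;P12345", "lncpep|A|F0|S0"),
                         matrix(1e6, 2, 1, dimnames = list(NULL, "s1")))
  g <- group_shared_peptides(ev)
  expect_equal(unlist(g$unique_peptides), "CCCCK")
})

test_that("non-overlap counting handles overlap, touching and alternatives", {
  occ <- data.frame(peptide = c("p1", "p2"), start = c(0, 4), end = c(8, 12))
  expect_equal(count_nonoverlapping_unique(occ), 1L)
  occ <- data.frame(peptide = c("p1", "p2", "p3"),
                    start = c(0, 4, 12), end = c(8, 12, 20))
  expect_equal(count_nonoverlapping_unique(occ), 2L)
  # touching intervals do not overlap
  occ <- data.frame(peptide = c("p1", "p2"), start = c(0, 8), end = c(8, 12))
  expect_equal(count_nonoverlapping_unique(occ), 2L)
  # a peptide with two candidate positions: its second placement wins
  occ <- data.frame(peptide = c("p1", "p1", "p2"),
                    start = c(0, 10, 2), end = c(6, 16, 8))
  expect_equal(count_nonoverlapping_unique(occ), 2L)
  expect_equal(count_nonoverlapping_unique(
    data.frame(peptide = character(), start = integer(), end = integer())),
    0L)
})

test_that("non-overlap counting equals exhaustive enumeration on random instances", {
  set.seed(201)
  for (rep in 1:100) {
    n <- sample(2:10, 1)
    occ <- data.frame(peptide = paste0("p", sample(1:5, n, replace = TRUE)),
                      start = sample(0:30, n, replace = TRUE))
    occ$end <- occ$start + sample(3:10, n, replace = TRUE)
    expect_equal(count_nonoverlapping_unique(occ),
                 oracle_max_nonoverlap(occ))
  }
})

test_that("median LFQ follows the stated conventions", {
  expect_equal(median_lfq(c(2, 4, 10)), 4)
  expect_equal(median_lfq(c(2, 4)), 3)
  expect_true(is.na(median_lfq(c(NA_real_, NA_real_))))
  # permutation invariance and stability when adding the current median
  set.seed(202)
  x <- rlnorm(7, 14, 1)
  expect_equal(median_lfq(sample(x)), median_lfq(x))
  expect_equal(median_lfq(c(x, median_lfq(x))), median_lfq(x))
})

test_that("group quantification enforces the two-non-overlapping-peptide rule", {
  # group A: two adjacent peptides; group B: only one peptide
  seqs <- c(`lncpep|A|F0|S0` = "AAAAKCCCCK", `lncpep|B|F0|S0` = "DDDDK")
  m <- matrix(c(2, 4, 10, NA, 8, NA), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("s1", "s2")))
  ev <- peptide_evidence(c("AAAAK", "CCCCK", "DDDDK"),
                         c("lncpep|A|F0|S0", "lncpep|A|F0|S0",
                           "lncpep|B|F0|S0"), m)
  g <- group_shared_peptides(ev)
  q <- quantify_groups(g, ev, seqs, min_nonoverlap = 2)
  expect_equal(rownames(q$abundance), "A")
  expect_equal(q$groups$n_nonoverlap, 2L)
  expect_equal(unname(q$abundance["A", "s1"]), 6)   # median of 2 and 10
  expect_equal(unname(q$abundance["A", "s2"]), 4)   # single quantified peptide
  expect_true(all(q$groups$n_nonoverlap >= 2))
})

test_that("percent CV matches the formula and is scale invariant", {
  expect_equal(peptide_cv(c(10, 10, 10)), 0)
  expect_equal(peptide_cv(c(1, 3)), 100 * sqrt(2) / 2)
  set.seed(203)
  x <- rlnorm(6, 10, 0.5)
  expect_equal(peptide_cv(5 * x), peptide_cv(x))
  expect_true(is.na(peptide_cv(c(7, NA))))
})

test_that("cross-context ANOVA reduces to t^2 for two contexts and detects shifts", {
  set.seed(204)
  x <- 2^rnorm(10, 20, 1)
  ctx <- rep(c("heart", "liver"), each = 5)
  res <- cross_context_peptide_anova(x, ctx)
  tt <- t.test(log2(x)[1:5], log2(x)[6:10], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)

  # +10 log2 shift in one context is overwhelming at n = 5 per group
  y <- c(2^rnorm(5, 30, 0.5), 2^rnorm(5, 20, 0.5))
  expect_lt(cross_context_peptide_anova(y, ctx)$p_value, 1e-6)

  # null simulation: p-values roughly uniform
  ctx3 <- rep(c("a", "b", "c"), each = 4)
  ps <- replicate(200, cross_context_peptide_anova(2^rnorm(12, 20, 1),
                                                   ctx3)$p_value)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)

  # degenerate: single context
  expect_true(is.na(cross_context_peptide_anova(x, rep("a", 10))$F))
})
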