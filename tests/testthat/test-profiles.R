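# Presence calling, specificity classes, universal expression,
# z-scoring, correlation, clustering and plasma ranks.

toy_abundance <- function() {
  ab <- matrix(NA_real_, 3, 6,
               dimnames = list(c("g1", "g2", "g3"),
                               c("h1", "h2", "h3", "l1", "l2", "l3")))
  ab["g1", "h2"] <- 1e6                 # one of three heart samples
  ab["g2", c("l1", "l2")] <- 2e6       # liver only
  ab["g3", c("h1", "l3")] <- 3e6       # both contexts
  ab
}

toy_annotation <- data.frame(
  sample_id = c("h1", "h2", "h3", "l1", "l2", "l3"),
  context = rep(c("heart", "liver"), each = 3),
  condition = "none", stage = NA_character_, pair_id = NA_character_)

test_that("presence calling uses the >=1-quantified-sample rule per context", {
  pres <- detect_presence(toy_abundance(), toy_annotation)
  expect_true(pres["g1", "heart"])
  expect_false(pres["g1", "liver"])
  expect_equal(unname(pres["g3", ]), c(TRUE, TRUE))
  # agrees with a direct brute-force scan of the matrix
  ab <- toy_abundance()
  for (g in rownames(ab)) {
    for (ctx in c("heart", "liver")) {
      ss <- toy_annotation$sample_id[toy_annotation$context == ctx]
      expect_equal(pres[g, ctx], any(!is.na(ab[g, ss])))
    }
  }
  expect_error(detect_presence(toy_abundance()[, 1:2, drop = FALSE],
                               toy_annotation[0, ]), "unannotated")
})

test_that("specificity labels partition the detected groups", {
  pres <- matrix(FALSE, 4, 14,
                 dimnames = list(paste0("g", 1:4), paste0("t", 1:14)))
  pres["g1", 3] <- TRUE
  pres["g2", ] <- TRUE
  pres["g3", 1:5] <- TRUE
  cls <- classify_specificity(pres)
  expect_equal(cls$label[cls$group_id == "g1"], "specific")
  expect_equal(cls$label[cls$group_id == "g2"], "ubiquitous")
  expect_equal(cls$label[cls$group_id == "g3"], "shared")
  expect_false("g4" %in% cls$group_id)  # detected nowhere
  expect_equal(sum(attr(cls, "counts")), nrow(cls))
})

test_that("universal expression is the exact intersection of panel-ubiquitous sets", {
  tissue7 <- c("LINC00969", "NUTM2A-AS1", "RP11-203J24.9", "RP11-29G8.3",
               "RP11-478C19.2", "RP11-793H13.8", "SEC22B")
  cell <- c("RP11-793H13.8", "RP11-203J24.9", "SEC22B", "LINC00969",
            "RP11-29G8.3", "KCNQ1OT1", "SENP3-EIF4A1")
  expect_equal(universal_expressed(tissue7, cell),
               sort(c("RP11-793H13.8", "RP11-203J24.9", "SEC22B",
                      "LINC00969", "RP11-29G8.3")))
  expect_equal(universal_expressed(tissue7, character(0)), character(0))
  expect_equal(universal_expressed(tissue7, tissue7), sort(tissue7))
  ue <- universal_expressed(tissue7, cell)
  expect_true(all(ue %in% tissue7) && all(ue %in% cell))
})

test_that("fraction of proteome is a guarded ratio", {
  expect_equal(fraction_of_proteome(15, 1000), 0.015)
  expect_equal(fraction_of_proteome(0, 1000), 0)
  expect_error(fraction_of_proteome(1, 0), "positive")
})

test_that("row z-scoring of log2 intensities is exact and guarded", {
  m <- matrix(c(4, 16), 1, 2, dimnames = list("g", c("a", "b")))
  z <- zscore_log2(m)
  expect_equal(unname(z["g", ]), c(-1, 1) / sqrt(2), tolerance = 1e-7)

  set.seed(301)
  m2 <- matrix(2^rnorm(50, 20, 2), 5, 10,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  m2[1, 3] <- NA
  z2 <- zscore_log2(m2)
  expect_true(all(abs(rowMeans(z2, na.rm = TRUE)) < 1e-12))
  expect_true(all(abs(apply(z2, 1, sd, na.rm = TRUE) - 1) < 1e-12))
  expect_true(is.na(z2[1, 3]))

  expect_warning(zc <- zscore_log2(matrix(c(8, 8, 8), 1, 3,
                                          dimnames = list("g", 1:3))),
                 "constant")
  expect_equal(unname(zc[1, ]), c(0, 0, 0))
})

test_that("correlation matches a direct formula computation", {
  x <- 1:10
  expect_equal(correlate(x, rank(x), "spearman")$estimate, 1)
  expect_equal(correlate(x, -x, "pearson")$estimate, -1)
  expect_equal(correlate(x, -x, "pearson")$p_value, 0)

  set.seed(302)
  a <- rnorm(10); b <- 0.5 * a + rnorm(10)
  res <- correlate(a, b, "pearson")
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 8), tolerance = 1e-12)
  rs <- correlate(a, b, "spearman")
  expect_equal(rs$estimate, cor(rank(a), rank(b)), tolerance = 1e-12)

  expect_true(is.na(correlate(c(1, 2, NA), c(1, NA, 2))$estimate))
})

test_that("hierarchical clustering merges identical columns first and is order-stable", {
  set.seed(303)
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  m[, "s2"] <- m[, "s1"]
  expect_error(hcluster(m[1, , drop = FALSE]), "at least 2")
  cl <- hcluster(m)
  leaves <- -cl$col$merge[1, ]
  expect_true(all(leaves > 0))
  expect_equal(sort(cl$col$labels[leaves]), c("s1", "s2"))

  # permutation of rows: same tree topology (distinct distances)
  m2 <- matrix(rnorm(50), 5, 10,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  c1 <- hcluster(m2)
  c2 <- hcluster(m2[sample(5), ])
  d1 <- cophenetic(c1$row); d2 <- cophenetic(c2$row)
  ord <- order(attr(d1, "Labels"))
  expect_equal(as.matrix(d1)[ord, ord],
               as.matrix(d2)[order(attr(d2, "Labels")),
                             order(attr(d2, "Labels"))],
               tolerance = 1e-12)

  # missing cells imputed to the row minimum before clustering
  m2[2, 4] <- NA
  expect_s3_class(hcluster(m2)$row, "hclust")

  skip_if_not_installed("ape")
  nwk <- as_newick(c1$row)
  expect_match(nwk, "^\\(.*g1.*\\);$")
})

test_that("plasma ranking is a sort with average ties and percentiles from the top", {
  ab <- c(a = 100, b = 90, c = 80, d = 70, e = 70, f = 60, g = 50, h = 40,
          i = 30, j = 20)
  pr <- plasma_rank(c("c", "d", "e", "zz"), ab)
  expect_equal(pr$rank, c(3, 4.5, 4.5, NA))
  expect_equal(pr$percentile[1], 30)
  expect_false(pr$present[4])
  # agrees with a full-sort oracle for untied values
  set.seed(304)
  v <- sample(1000, 20); names(v) <- paste0("x", 1:20)
  pr2 <- plasma_rank(names(v), v)
  expect_equal(pr2$rank, match(names(v), names(sort(v, decreasing = TRUE))))
})
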