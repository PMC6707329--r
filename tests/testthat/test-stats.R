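# Moderated t, BH adjustment, stage filter/ANOVA, early/late Welch test
# and hypergeometric enrichment.

null_matrix <- function(n, per_group = 6, sd = 1) {
  matrix(rnorm(n * 2 * per_group, 20, sd), n, 2 * per_group,
         dimnames = list(paste0("g", seq_len(n)),
                         paste0("s", seq_len(2 * per_group))))
}

two_groups <- function(per_group = 6) {
  factor(rep(c("normal", "cancer"), each = per_group),
         levels = c("normal", "cancer"))
}

test_that("moderated t collapses to the pooled t at zero prior df", {
  set.seed(401)
  m <- null_matrix(100)
  g <- two_groups()
  res <- moderated_t_test(m, g, prior_df = 0)
  ref_t <- apply(m, 1, function(x)
    unname(t.test(x[g == "cancer"], x[g == "normal"],
                  var.equal = TRUE)$statistic))
  ref_p <- apply(m, 1, function(x)
    t.test(x[g == "cancer"], x[g == "normal"], var.equal = TRUE)$p.value)
  expect_lt(max(abs(res$t_mod - ref_t)), 1e-10)
  expect_lt(max(abs(res$p_value - ref_p)), 1e-10)
})

test_that("infinite prior df gives every row the same posterior variance", {
  set.seed(402)
  m <- null_matrix(100)
  res <- moderated_t_test(m, two_groups(), prior_df = Inf)
  post_var <- (res$log2fc / res$t_mod)^2
  expect_lt(diff(range(post_var)), 1e-10)
})

test_that("moderated t agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(403)
  n <- 400
  sig2 <- 4 * 0.25 / rchisq(n, 4)   # heteroscedastic rows, finite prior df
  m <- t(sapply(sqrt(sig2), function(s) rnorm(12, 0, s))) + 20
  dimnames(m) <- list(paste0("g", 1:n), paste0("s", 1:12))
  g <- two_groups()
  res <- moderated_t_test(m, g)
  fit <- limma::eBayes(limma::lmFit(m, stats::model.matrix(~g)))
  expect_equal(attr(res, "df_prior"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(res, "s2_prior"), fit$s2.prior, tolerance = 1e-8)
  expect_lt(max(abs(res$t_mod - fit$t[, 2])), 1e-10)
  expect_lt(max(abs(res$p_value - fit$p.value[, 2])), 1e-10)
})

test_that("rows below the per-group minimum are excluded, not dropped", {
  set.seed(404)
  m <- null_matrix(10)
  m[3, 1:5] <- NA    # one normal value left
  res <- moderated_t_test(m, two_groups())
  expect_true(res$excluded[3])
  expect_true(is.na(res$p_value[3]))
  expect_equal(nrow(res), 10L)
  expect_error(moderated_t_test(m, factor(rep("a", 12))), "two levels")
})

test_that("BH adjustment matches the hand step-up and its bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(405)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    # invariant to permutation after inverse permutation
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], q)
  }
})

test_that("the 2-of-4 stage presence filter is exact", {
  stages <- rep(c("I", "II", "III", "IV"), times = c(4, 4, 4, 4))
  m <- matrix(1, 3, 16, dimnames = list(paste0("g", 1:3), NULL))
  m[2, 1:3] <- NA                        # stage I count 1 -> excluded
  m[3, c(1, 2, 5, 9, 10, 13)] <- NA      # counts 2,3,2,3 -> included
  inc <- stage_filter(m, stages)
  expect_equal(unname(inc), c(TRUE, FALSE, TRUE))
  expect_error(stage_filter(m, rep(c("I", "II", "III", "V"), 4)), "V")
  expect_error(stage_filter(m[, 1:8], rep(c("I", "II"), 4)), "III")
})

test_that("one-way ANOVA equals the squared pooled t for two groups", {
  set.seed(406)
  x <- rnorm(12, 5, 1)
  g <- rep(c("a", "b"), each = 6)
  res <- one_way_anova(x, g)
  tt <- t.test(x[1:6], x[7:12], var.equal = TRUE)
  expect_lt(abs(res$F - unname(tt$statistic)^2), 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_warning(r0 <- one_way_anova(rep(2, 8), rep(c("a", "b"), 4)),
                 "zero total variance")
  expect_equal(r0$p_value, 1)
})

test_that("stage ANOVA detects planted monotone trends and stays calibrated", {
  set.seed(407)
  stages <- rep(c("I", "II", "III", "IV"), each = 5)
  hits <- 0
  for (rep in 1:20) {
    m <- matrix(rnorm(30 * 20, 20, 0.5), 30, 20,
                dimnames = list(paste0("g", 1:30), NULL))
    trend <- 1:6
    shift <- matrix(rep(0.5 * (match(stages, c("I", "II", "III", "IV")) - 1),
                        each = 6), 6, 20)
    m[trend, ] <- m[trend, ] + shift
    sa <- stage_anova(m, stages)
    hits <- hits + sum(sa$adj_p[trend] < 0.05, na.rm = TRUE)
  }
  expect_gt(hits / (20 * 6), 0.8)

  ps <- replicate(300, one_way_anova(rnorm(20, 20, 0.5), stages)$p_value)
  expect_gt(ks.test(ps, punif)$p.value, 0.01)
})

test_that("the early/late Welch test is antisymmetric and calibrated", {
  set.seed(408)
  stages <- rep(c("I", "II", "III", "IV"), each = 5)
  m <- matrix(rnorm(5 * 20, 20, 0.5), 5, 20,
              dimnames = list(paste0("g", 1:5), NULL))
  el <- early_late_test(m, stages)
  swapped <- early_late_test(m, rep(c("III", "IV", "I", "II"), each = 5),
                             pooled = FALSE)
  expect_equal(el$t, -swapped$t, tolerance = 1e-12)
  expect_equal(el$p_value, swapped$p_value, tolerance = 1e-12)

  # planted +1 log2 shift in late stages is found decisively
  m2 <- matrix(rnorm(40, 20, 0.5), 2, 20,
               dimnames = list(c("a", "b"), NULL))
  m2[1, stages %in% c("III", "IV")] <- m2[1, stages %in% c("III", "IV")] + 1
  el2 <- early_late_test(m2, stages)
  expect_lt(el2$p_value[1], 1e-3)
  expect_equal(el2$log2fc[1], 1, tolerance = 0.5)

  # degenerate rows are flagged, not dropped
  m2[2, stages %in% c("I", "II")] <- NA
  m2[2, which(stages == "I")[1]] <- 20
  el3 <- early_late_test(m2, stages)
  expect_true(el3$excluded[2])
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  uni <- letters[1:10]
  res <- hypergeom_enrichment(letters[1:5], list(T1 = letters[1:4]), uni)
  expect_equal(res$p_value, 6 / 252, tolerance = 1e-12)

  # empty category and selected-equals-universe corner cases
  res0 <- hypergeom_enrichment(letters[1:5], list(T0 = character(0)), uni)
  expect_equal(res0$p_value, 1)
  resU <- hypergeom_enrichment(uni, list(T1 = letters[1:4]), uni)
  expect_equal(resU$overlap, 4L)
  expect_equal(resU$p_value, 1)

  set.seed(409)
  for (rep in 1:30) {
    n_uni <- sample(5:15, 1)
    uni <- paste0("id", seq_len(n_uni))
    sel <- sample(uni, sample(1:n_uni, 1))
    cat_ <- sample(uni, sample(0:n_uni, 1))
    res <- hypergeom_enrichment(sel, list(T = cat_), uni)
    k <- length(intersect(cat_, sel))
    p_exp <- if (k == 0) 1 else
      oracle_hyper(k, length(cat_), n_uni, length(sel))
    expect_equal(res$p_value, p_exp, tolerance = 1e-12)
  }
  expect_error(hypergeom_enrichment("zz", list(T = "a"), letters[1:3]),
               "outside")
  expect_error(hypergeom_enrichment("a", list(T = "a"), character(0)),
               "empty universe")
})
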