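# Differential abundance: empirical-Bayes moderated t, BH adjustment,
# stage presence filter, one-way stage ANOVA, early/late Welch test and
# hypergeometric enrichment.

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf); the iteration below converges for any y > 0).
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

# Moment-matching fit of a scaled inverse chi-square prior to observed
# per-row variances s2 with df degrees of freedom (Smyth's empirical-Bayes
# hierarchy): returns the prior df d0 and prior variance s02.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L)
    return(list(df_prior = Inf,
                s2_prior = if (length(s2)) mean(s2) else NA_real_))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(df / 2))
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per row of a log2 abundance matrix, computes the pooled two-sample
#' variance, shrinks it toward a prior estimated across rows by moment
#' matching on the log variances (the scaled inverse chi-square hierarchy
#' of the moderated t-statistic), and tests the group difference with
#' `df_row + df_prior` degrees of freedom. Rows with fewer than `min_n`
#' non-missing values in either group are excluded from testing (reported
#' with `excluded = TRUE`, not dropped). Benjamini-Hochberg adjusted
#' p-values are appended over the tested rows.
#'
#' @param matrix_log2 numeric matrix of log2 intensities, rows = polypeptide
#'   groups, columns = samples; `NA` = not quantified.
#' @param groups two-level factor over the columns; the log2 fold change is
#'   `mean(level 2) - mean(level 1)`.
#' @param min_n minimum non-missing values per group for a row to be tested
#'   (default 2).
#' @param prior_df optional override of the estimated prior degrees of
#'   freedom: `0` gives the ordinary pooled t-test, `Inf` fixes every row's
#'   variance at the prior variance.
#' @return data frame `group_id`, `log2fc`, `t_mod`, `p_value`, `adj_p`,
#'   `n1`, `n2`, `s2`, `df_total`, `excluded`, with attributes `df_prior`
#'   and `s2_prior`.
#' @export
moderated_t_test <- function(matrix_log2, groups, min_n = 2L,
                             prior_df = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly two levels, got ", nlevels(groups))
  stopifnot(ncol(matrix_log2) == length(groups))
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  m1 <- matrix_log2[, i1, drop = FALSE]
  m2 <- matrix_log2[, i2, drop = FALSE]
  n1 <- rowSums(!is.na(m1))
  n2 <- rowSums(!is.na(m2))
  mu1 <- rowMeans(m1, na.rm = TRUE)
  mu2 <- rowMeans(m2, na.rm = TRUE)
  v1 <- apply(m1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(m2, 1L, stats::var, na.rm = TRUE)
  df_row <- n1 + n2 - 2L
  s2 <- ifelse(df_row > 0,
               ((n1 - 1) * ifelse(n1 > 1, v1, 0) +
                (n2 - 1) * ifelse(n2 > 1, v2, 0)) / df_row, NA_real_)
  excluded <- n1 < min_n | n2 < min_n

  prior <- fit_variance_prior(s2[!excluded], df_row[!excluded])
  if (!is.null(prior_df)) prior$df_prior <- prior_df
  d0 <- prior$df_prior
  s02 <- prior$s2_prior
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (d0 * s02 + df_row * s2) / (d0 + df_row)
    df_total <- d0 + df_row
  }
  log2fc <- mu2 - mu1
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[excluded] <- NA_real_
  t_mod[excluded] <- NA_real_
  adj <- rep(NA_real_, length(p))
  adj[!excluded] <- bh_adjust(p[!excluded])
  out <- data.frame(group_id = rownames(matrix_log2),
                    log2fc = unname(log2fc),
                    t_mod = unname(t_mod),
                    p_value = unname(p),
                    adj_p = adj,
                    n1 = unname(n1), n2 = unname(n2),
                    s2 = unname(s2),
                    df_total = unname(df_total),
                    excluded = unname(excluded),
                    stringsAsFactors = FALSE)
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s02
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1, order-preserving. Validates that inputs are probabilities.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Stage presence filter
#'
#' A row is kept when every cancer stage has at least `min_per_stage`
#' non-missing values (the 2-of-4-per-stage rule applied before stage-wise
#' testing).
#'
#' @param matrix_log2 matrix, columns = cancer samples.
#' @param stages character/factor of stages I--IV per column.
#' @param min_per_stage minimum quantified samples per stage (default 2).
#' @return logical vector per row.
#' @export
stage_filter <- function(matrix_log2, stages, min_per_stage = 2L) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), .stage_levels)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  f <- factor(stages, levels = .stage_levels)
  absent <- .stage_levels[table(f) == 0L]
  if (length(absent))
    stop("stage(s) absent from the cohort: ", paste(absent, collapse = ", "))
  counts <- vapply(.stage_levels, function(s)
    rowSums(!is.na(matrix_log2[, f == s, drop = FALSE])),
    numeric(nrow(matrix_log2)))
  counts <- matrix(counts, nrow = nrow(matrix_log2))
  rowSums(counts >= min_per_stage) == length(.stage_levels)
}

#' Classical one-way ANOVA on log2 values
#'
#' @param x numeric vector (log2 scale; `NA` dropped).
#' @param g factor/character of group labels.
#' @return list with `F` and `p_value`. Zero total variance gives
#'   `F = 0, p = 1` with a warning; zero within-group variance with
#'   distinct means gives `F = Inf, p = 0`.
#' @export
one_way_anova <- function(x, g) {
  ok <- !is.na(x)
  x <- x[ok]
  g <- factor(as.character(g[ok]))
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (stats::var(x) == 0) {
    warning("zero total variance; returning p = 1")
    return(list(F = 0, p_value = 1))
  }
  gm <- tapply(x, g, mean)
  within_ss <- sum((x - gm[g])^2)
  if (within_ss == 0)
    return(list(F = Inf, p_value = 0))
  fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p_value = unname(fit$p.value))
}

#' Stage-wise ANOVA over a cohort matrix
#'
#' Applies [stage_filter()] and then a one-way ANOVA across stages I--IV to
#' each included row, with BH adjustment over the included rows.
#'
#' @inheritParams stage_filter
#' @return data frame `group_id`, `F`, `p_value`, `adj_p`, `included`.
#' @export
stage_anova <- function(matrix_log2, stages, min_per_stage = 2L) {
  inc <- stage_filter(matrix_log2, stages, min_per_stage)
  Fv <- rep(NA_real_, nrow(matrix_log2))
  pv <- rep(NA_real_, nrow(matrix_log2))
  for (i in which(inc)) {
    r <- one_way_anova(matrix_log2[i, ], stages)
    Fv[i] <- r$F; pv[i] <- r$p_value
  }
  adj <- rep(NA_real_, length(pv))
  adj[inc] <- bh_adjust(pv[inc])
  data.frame(group_id = rownames(matrix_log2), F = Fv, p_value = pv,
             adj_p = adj, included = inc, stringsAsFactors = FALSE)
}

#' Early- versus late-stage test
#'
#' Pools stages I+II (early) against III+IV (late) and tests each row with
#' an unpaired t-test on log2 values (Welch by default; `pooled = TRUE`
#' forces the equal-variance form). Rows with fewer than 2 values in either
#' pooled group are excluded.
#'
#' @inheritParams stage_filter
#' @param pooled use the pooled-variance t instead of Welch.
#' @return data frame `group_id`, `log2fc` (late - early), `t`, `p_value`,
#'   `adj_p`, `n_early`, `n_late`, `excluded`.
#' @export
early_late_test <- function(matrix_log2, stages, pooled = FALSE) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), .stage_levels)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  phase <- ifelse(stages %in% c("I", "II"), "early", "late")
  e <- matrix_log2[, phase == "early", drop = FALSE]
  l <- matrix_log2[, phase == "late", drop = FALSE]
  ne <- rowSums(!is.na(e)); nl <- rowSums(!is.na(l))
  excluded <- ne < 2L | nl < 2L
  tv <- pv <- fc <- rep(NA_real_, nrow(matrix_log2))
  for (i in which(!excluded)) {
    tt <- stats::t.test(l[i, ], e[i, ], var.equal = pooled)
    tv[i] <- unname(tt$statistic)
    pv[i] <- tt$p.value
    fc[i] <- mean(l[i, ], na.rm = TRUE) - mean(e[i, ], na.rm = TRUE)
  }
  adj <- rep(NA_real_, length(pv))
  adj[!excluded] <- bh_adjust(pv[!excluded])
  data.frame(group_id = rownames(matrix_log2), log2fc = fc, t = tv,
             p_value = pv, adj_p = adj, n_early = unname(ne),
             n_late = unname(nl), excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric test of each term's overlap with a selected
#' set against the universe of quantified ids, BH-adjusted across terms.
#'
#' @param selected character vector of selected ids (must be a subset of
#'   `universe`).
#' @param term_map named list: term id -> character vector of member ids
#'   (intersected with the universe).
#' @param universe character vector of all quantified ids.
#' @return data frame `term_id`, `overlap`, `selected_size`,
#'   `category_size`, `universe_size`, `p_value`, `adj_p`.
#' @export
hypergeom_enrichment <- function(selected, term_map, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!all(selected %in% universe))
    stop("selected ids outside the universe: ",
         paste(setdiff(selected, universe), collapse = ", "))
  selected <- unique(selected)
  n_sel <- length(selected)
  n_uni <- length(universe)
  rows <- lapply(names(term_map), function(tid) {
    cat_ids <- intersect(term_map[[tid]], universe)
    k <- length(intersect(cat_ids, selected))
    K <- length(cat_ids)
    p <- if (K == 0L || k == 0L) {
      # P(X >= 0) = 1; and K = 0 forces overlap 0
      if (k == 0L) 1 else NA_real_
    } else {
      stats::phyper(k - 1L, K, n_uni - K, n_sel, lower.tail = FALSE)
    }
    data.frame(term_id = tid, overlap = k, selected_size = n_sel,
               category_size = K, universe_size = n_uni, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  out
}
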