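# Presence calling, specificity classes, universal expression, z-scored
# log2 matrices, correlation, hierarchical clustering and plasma ranks.

#' Presence of polypeptide groups per context
#'
#' A group is called present in a context when it has a non-missing
#' abundance in at least `min_samples` of the context's samples.
#'
#' @param abundance group x sample matrix (linear scale, `NA` = missing).
#' @param annotation data frame with `sample_id` and `context`, covering
#'   every abundance column.
#' @param min_samples detection threshold per context (default 1).
#' @return logical matrix groups x contexts.
#' @export
detect_presence <- function(abundance, annotation, min_samples = 1L) {
  samples <- colnames(abundance)
  m <- match(samples, annotation$sample_id)
  if (anyNA(m))
    stop("unannotated sample(s): ", paste(samples[is.na(m)], collapse = ", "))
  ctx <- annotation$context[m]
  contexts <- unique(ctx)
  if (any(table(factor(ctx, levels = contexts)) == 0L))
    stop("context with zero samples")
  res <- matrix(FALSE, nrow(abundance), length(contexts),
                dimnames = list(rownames(abundance), contexts))
  for (cc in contexts) {
    res[, cc] <- rowSums(!is.na(abundance[, ctx == cc, drop = FALSE])) >=
      min_samples
  }
  res
}

#' Classify context specificity of polypeptide groups
#'
#' Labels each group `specific` (detected in exactly one context), `shared`
#' (more than one but not all) or `ubiquitous` (all contexts). Groups
#' detected nowhere are dropped from the output.
#'
#' @param presence logical group x context matrix from [detect_presence()].
#' @return data frame with `group_id`, `n_contexts`, `label`, plus an
#'   attribute `counts` (table of labels).
#' @export
classify_specificity <- function(presence) {
  stopifnot(is.matrix(presence), ncol(presence) >= 1L)
  n <- rowSums(presence)
  keep <- n > 0L
  label <- ifelse(n == 1L, "specific",
                  ifelse(n == ncol(presence), "ubiquitous", "shared"))
  out <- data.frame(group_id = rownames(presence)[keep],
                    n_contexts = unname(n[keep]),
                    label = unname(label[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(out$label,
                                      levels = c("specific", "shared",
                                                 "ubiquitous")))
  out
}

#' Universally expressed (UExp) polypeptides
#'
#' A polypeptide is universally expressed when it is ubiquitous in the
#' tissue panel and in the cell-line panel: the exact intersection of the
#' two ubiquitous sets.
#'
#' @param tissue_ubiquitous,cellline_ubiquitous character vectors of group
#'   ids ubiquitous within each panel.
#' @return character vector (sorted) of UExp group ids.
#' @export
universal_expressed <- function(tissue_ubiquitous, cellline_ubiquitous) {
  sort(intersect(tissue_ubiquitous, cellline_ubiquitous))
}

#' lncRNA peptidome as a fraction of the proteome
#'
#' @param n_lnc_polypeptides number of lncRNA polypeptides quantified.
#' @param n_proteins number of canonical proteins quantified in the same
#'   sample set.
#' @return the ratio.
#' @export
fraction_of_proteome <- function(n_lnc_polypeptides, n_proteins) {
  if (any(n_proteins <= 0)) stop("n_proteins must be positive")
  n_lnc_polypeptides / n_proteins
}

#' Row-wise z-score of a log2-transformed abundance matrix
#'
#' Per row: log2, subtract the row mean and divide by the row sample
#' standard deviation, both over non-missing cells; missing cells stay
#' missing. Rows with zero variance become rows of zeros with a warning;
#' rows with fewer than two non-missing values become all-`NA` with a
#' warning.
#'
#' @param abundance matrix of positive intensities (`NA` = missing).
#' @return matrix of the same shape.
#' @export
zscore_log2 <- function(abundance) {
  if (any(abundance <= 0, na.rm = TRUE))
    stop("non-positive intensity; matrix must be on the linear scale")
  lg <- log2(abundance)
  out <- lg
  few <- integer(0); flat <- integer(0)
  for (i in seq_len(nrow(lg))) {
    v <- lg[i, ]
    ok <- !is.na(v)
    if (sum(ok) < 2L) {
      out[i, ] <- NA_real_
      few <- c(few, i)
      next
    }
    s <- stats::sd(v[ok])
    if (s == 0) {
      out[i, ok] <- 0
      flat <- c(flat, i)
    } else {
      out[i, ok] <- (v[ok] - mean(v[ok])) / s
    }
  }
  if (length(few))
    warning(length(few), " row(s) with fewer than 2 non-missing values")
  if (length(flat))
    warning(length(flat), " constant row(s) z-scored to zero")
  out
}

#' Correlation with a t-based p-value
#'
#' Pairwise-complete Spearman or Pearson correlation; the p-value comes from
#' the t transform `r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom (two-sided).
#'
#' @param x,y numeric vectors.
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `estimate`, `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    return(list(estimate = NA_real_, p_value = NA_real_, n = n,
                method = method))
  r <- stats::cor(x[ok], y[ok], method = method)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(estimate = r, p_value = p, n = n, method = method)
}

#' Hierarchical clustering of an abundance matrix
#'
#' Clusters rows and columns after imputing missing cells to the row minimum
#' (absent quantification is treated as low abundance). Distances are
#' Euclidean or correlation (`1 - r`); linkage is average or complete.
#' Agglomeration is deterministic for a given input; equal-distance merges
#' follow [stats::hclust()]'s lowest-index-first convention.
#'
#' @param abundance numeric matrix (e.g. z-scored log2 intensities).
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"average"` or `"complete"`.
#' @return list of class `lnc_hclust` with `row`, `col` ([stats::hclust]
#'   trees), `row_order`, `col_order` (leaf labels) and the parameters.
#' @export
hcluster <- function(abundance, distance = c("euclidean", "correlation"),
                     linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (nrow(abundance) < 2L || ncol(abundance) < 2L)
    stop("need at least 2 rows and 2 columns to cluster")
  m <- abundance
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    if (all(is.na(v))) stop("row with no quantified cell: ",
                            rownames(m)[i])
    m[i, is.na(v)] <- min(v, na.rm = TRUE)
  }
  dfun <- function(mm) {
    if (distance == "euclidean") stats::dist(mm)
    else stats::as.dist(1 - stats::cor(t(mm)))
  }
  rt <- stats::hclust(dfun(m), method = linkage)
  ct <- stats::hclust(dfun(t(m)), method = linkage)
  structure(list(row = rt, col = ct,
                 row_order = rt$labels[rt$order],
                 col_order = ct$labels[ct$order],
                 distance = distance, linkage = linkage,
                 imputation = "row minimum"),
            class = "lnc_hclust")
}

#' @export
print.lnc_hclust <- function(x, ...) {
  cat("hierarchical clustering (", x$distance, " distance, ", x$linkage,
      " linkage, missing imputed to ", x$imputation, ")\n", sep = "")
  cat("  row leaf order:", paste(x$row_order, collapse = " "), "\n")
  cat("  col leaf order:", paste(x$col_order, collapse = " "), "\n")
  invisible(x)
}

#' Export a clustering tree as newick text
#'
#' @param tree an [stats::hclust] object (e.g. `$row` of [hcluster()]).
#' @return single newick string.
#' @export
as_newick <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for newick export")
  ape::write.tree(ape::as.phylo(tree))
}

#' Abundance rank of candidate polypeptides within a plasma profile
#'
#' Ranks are 1-based from the most abundant entry; ties share the average
#' rank. The percentile is the rank expressed as a percent of the profile
#' size (from the top), locating a candidate within the plasma dynamic
#' range.
#'
#' @param candidate_ids character vector of ids to look up.
#' @param plasma_abundance named numeric vector (id -> linear intensity) of
#'   the full plasma profile.
#' @return data frame `group_id`, `rank`, `percentile`, `present`
#'   (candidates absent from the profile are reported unranked).
#' @export
plasma_rank <- function(candidate_ids, plasma_abundance) {
  stopifnot(!is.null(names(plasma_abundance)))
  r <- rank(-plasma_abundance, ties.method = "average")
  idx <- match(candidate_ids, names(plasma_abundance))
  present <- !is.na(idx)
  data.frame(group_id = candidate_ids,
             rank = ifelse(present, r[idx], NA_real_),
             percentile = ifelse(present,
                                 100 * r[idx] / length(plasma_abundance),
                                 NA_real_),
             present = present,
             stringsAsFactors = FALSE)
}
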