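# Grouping of lncRNA database entries that share peptides, the
# two-non-overlapping-unique-peptide reporting rule, and median label-free
# quantification of polypeptide groups.

#' Group lncRNA entries by shared observed peptides
#'
#' Transcripts whose observed peptide sets are identical, or where one set is
#' a subset of another, are merged into one polypeptide group (subsumption
#' grouping, as protein-inference engines do). A peptide mapping to two
#' unmergeable groups is flagged non-unique and excluded from every group's
#' unique-peptide set. Peptides carrying any mapping outside the lncRNA
#' namespace are dropped up front.
#'
#' Transcripts are processed in decreasing peptide-set size (ties broken
#' lexicographically by transcript id) and attach to the first existing group
#' whose defining set contains theirs, which makes the grouping invariant to
#' input order. The group id is the transcript with the maximal peptide set.
#'
#' @param evidence a [peptide_evidence()] object.
#' @return object of class `polypeptide_groups`: a list with `groups`
#'   (data frame `group_id`, `members`, `n_unique`), `unique_peptides`
#'   (list of character vectors per group), `nonunique_peptides` and
#'   `peptide_groups` (named integer: group index per unique peptide).
#' @export
group_shared_peptides <- function(evidence) {
  stopifnot(inherits(evidence, "peptide_evidence"))
  entry_lists <- strsplit(evidence$peptides$proteins, ";", fixed = TRUE)
  lnc_only <- vapply(entry_lists,
                     function(e) length(e) > 0 && all(is_lnc_entry(e)),
                     logical(1))
  pep <- evidence$peptides$sequence[lnc_only]
  tx_of <- lapply(entry_lists[lnc_only],
                  function(e) unique(parse_entry_transcript(e)))
  # transcript -> set of observed peptides
  long_tx <- unlist(tx_of, use.names = FALSE)
  long_pep <- rep(pep, lengths(tx_of))
  tx_peps <- split(long_pep, long_tx)
  tx_peps <- lapply(tx_peps, unique)
  ord <- order(-lengths(tx_peps), names(tx_peps))
  tx_ids <- names(tx_peps)[ord]
  tx_peps <- tx_peps[ord]

  group_sets <- list()      # defining (maximal) peptide set per group
  group_members <- list()
  group_of_tx <- integer(0)
  for (i in seq_along(tx_ids)) {
    set_i <- tx_peps[[i]]
    placed <- FALSE
    for (g in seq_along(group_sets)) {
      if (all(set_i %in% group_sets[[g]])) {
        group_members[[g]] <- c(group_members[[g]], tx_ids[i])
        group_of_tx[tx_ids[i]] <- g
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      g <- length(group_sets) + 1L
      group_sets[[g]] <- set_i
      group_members[[g]] <- tx_ids[i]
      group_of_tx[tx_ids[i]] <- g
    }
  }

  # a peptide is unique iff all transcripts it maps to sit in one group
  pep_group <- vapply(seq_along(pep), function(j) {
    gs <- unique(group_of_tx[tx_of[[j]]])
    if (length(gs) == 1L) gs else NA_integer_
  }, integer(1))
  names(pep_group) <- pep
  nonunique <- unique(pep[is.na(pep_group)])
  uniq_by_group <- lapply(seq_along(group_sets), function(g)
    unique(pep[!is.na(pep_group) & pep_group == g]))

  groups <- data.frame(
    group_id = vapply(group_members, `[[`, character(1), 1L),
    members = vapply(group_members,
                     function(m) paste(sort(m), collapse = ";"),
                     character(1)),
    n_unique = lengths(uniq_by_group),
    stringsAsFactors = FALSE)
  pg <- pep_group[!is.na(pep_group)]
  structure(list(groups = groups,
                 unique_peptides = uniq_by_group,
                 nonunique_peptides = nonunique,
                 peptide_groups = pg),
            class = "polypeptide_groups")
}

#' @export
print.polypeptide_groups <- function(x, ...) {
  cat("polypeptide_groups:", nrow(x$groups), "groups,",
      length(x$peptide_groups), "unique peptides,",
      length(x$nonunique_peptides), "non-unique peptides excluded\n")
  invisible(x)
}

#' Maximum number of non-overlapping unique peptides
#'
#' Given candidate occurrence intervals of distinct peptides on a group's
#' representative polypeptide, returns the maximum cardinality of a set of
#' pairwise non-overlapping intervals that uses at most one interval per
#' distinct peptide sequence. Intervals are half-open, so `[0,8)` and
#' `[8,12)` do not overlap. The maximisation is exact (depth-first search
#' with an upper-bound prune); peptide counts per group are small enough
#' that this is instantaneous.
#'
#' @param occurrences data frame with columns `peptide`, `start`, `end`
#'   (0-based half-open). A peptide may have several candidate intervals.
#' @return integer count (0 for empty input).
#' @export
count_nonoverlapping_unique <- function(occurrences) {
  if (is.null(occurrences) || nrow(occurrences) == 0L) return(0L)
  stopifnot(all(c("peptide", "start", "end") %in% names(occurrences)),
            all(occurrences$end > occurrences$start))
  by_pep <- split(occurrences[c("start", "end")], occurrences$peptide)
  n_pep <- length(by_pep)
  best <- 0L
  recurse <- function(i, starts, ends, count) {
    if (count + (n_pep - i + 1L) <= best) return()
    if (i > n_pep) {
      if (count > best) best <<- count
      return()
    }
    iv <- by_pep[[i]]
    for (k in seq_len(nrow(iv))) {
      s <- iv$start[k]; e <- iv$end[k]
      if (!any(s < ends & starts < e))
        recurse(i + 1L, c(starts, s), c(ends, e), count + 1L)
    }
    recurse(i + 1L, starts, ends, count)  # skip this peptide
  }
  recurse(1L, numeric(0), numeric(0), 0L)
  best
}

#' Locate a group's unique peptides on its representative sequence
#'
#' The representative is the longest ORF polypeptide among the group's
#' members (ties broken lexicographically by entry id). All exact occurrence
#' intervals of each unique peptide on that sequence are returned; peptides
#' not found on the representative (possible after subsumption merges) get no
#' interval and cannot contribute to the non-overlap count.
#'
#' @param groups a `polypeptide_groups` object.
#' @param sequences named character vector of database sequences
#'   (names are `lncpep|...` entry ids), e.g. from [build_search_db()].
#' @return list per group of data frames `peptide`, `start`, `end`.
#' @export
locate_unique_peptides <- function(groups, sequences) {
  stopifnot(inherits(groups, "polypeptide_groups"))
  lnc_seqs <- sequences[is_lnc_entry(names(sequences))]
  tx_of_seq <- parse_entry_transcript(names(lnc_seqs))
  lapply(seq_len(nrow(groups$groups)), function(g) {
    members <- strsplit(groups$groups$members[g], ";", fixed = TRUE)[[1]]
    cand <- lnc_seqs[tx_of_seq %in% members]
    empty <- data.frame(peptide = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    if (!length(cand)) return(empty)
    cand <- cand[order(-nchar(cand), names(cand))]
    rep_seq <- cand[[1]]
    occ <- lapply(groups$unique_peptides[[g]], function(p) {
      m <- gregexpr(p, rep_seq, fixed = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      data.frame(peptide = p, start = as.integer(m) - 1L,
                 end = as.integer(m) - 1L + nchar(p),
                 stringsAsFactors = FALSE)
    })
    occ <- occ[!vapply(occ, is.null, logical(1))]
    if (!length(occ)) return(empty)
    do.call(rbind, occ)
  })
}

#' Median label-free quantification of one set of peptide intensities
#'
#' The polypeptide abundance in a sample is the median of the non-missing
#' intensities of its unique peptides (even counts: arithmetic mean of the
#' two central values); all-missing gives `NA`.
#'
#' @param x numeric vector of peptide intensities (linear scale, `NA` =
#'   not quantified).
#' @return the median, or `NA_real_` when no peptide is quantified.
#' @export
median_lfq <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  stats::median(x)
}

#' Quantify polypeptide groups and enforce the two-peptide rule
#'
#' Computes, per group and sample, the median intensity over the group's
#' unique peptides, and retains only groups with at least `min_nonoverlap`
#' non-overlapping unique peptides (the reporting rule for calling a
#' polypeptide). The rule is enforced per dataset: one passing group is
#' reported in every sample, with `NA` where no peptide was quantified.
#'
#' @param groups a `polypeptide_groups` object.
#' @param evidence the [peptide_evidence()] the groups were derived from.
#' @param sequences named character vector of database sequences used to
#'   place peptides for the non-overlap count (see
#'   [locate_unique_peptides()]).
#' @param min_nonoverlap minimum non-overlapping unique peptides (default 2).
#' @return list with `abundance` (group x sample matrix, linear scale) and
#'   `groups` (data frame `group_id`, `members`, `n_unique`, `n_nonoverlap`).
#' @export
quantify_groups <- function(groups, evidence, sequences,
                            min_nonoverlap = 2L) {
  stopifnot(inherits(groups, "polypeptide_groups"),
            inherits(evidence, "peptide_evidence"))
  occ <- locate_unique_peptides(groups, sequences)
  tab <- groups$groups
  tab$n_nonoverlap <- vapply(occ, count_nonoverlapping_unique, integer(1))
  keep <- which(tab$n_nonoverlap >= min_nonoverlap)
  ab <- matrix(NA_real_, length(keep), ncol(evidence$intensity),
               dimnames = list(tab$group_id[keep],
                               colnames(evidence$intensity)))
  for (i in seq_along(keep)) {
    g <- keep[i]
    peps <- intersect(groups$unique_peptides[[g]],
                      rownames(evidence$intensity))
    if (!length(peps)) next
    sub <- evidence$intensity[peps, , drop = FALSE]
    ab[i, ] <- apply(sub, 2L, median_lfq)
  }
  list(abundance = ab, groups = tab[keep, , drop = FALSE])
}

#' Percent coefficient of variation of peptide intensities
#'
#' Consistency diagnostic: peptides of one polypeptide measured in one
#' context should agree, giving a low %CV.
#'
#' @param x numeric vector of intensities (linear scale).
#' @return `100 * sd(x) / mean(x)` over non-missing values, or `NA_real_`
#'   when fewer than two values are available.
#' @export
peptide_cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

#' One-way ANOVA of a peptide's intensity across contexts
#'
#' Tests, on the log2 scale, whether a peptide's abundance differs across
#' tissues or cell lines (the factor driving peptide variability should be
#' the context of origin, not the peptide itself).
#'
#' @param intensity numeric vector of linear-scale intensities.
#' @param context factor/character of the same length giving each value's
#'   context.
#' @return list with `F` and `p_value`; both `NA` when fewer than two
#'   contexts have at least two non-missing values.
#' @export
cross_context_peptide_anova <- function(intensity, context) {
  keep <- !is.na(intensity)
  x <- log2(intensity[keep])
  g <- factor(as.character(context[keep]))
  counts <- table(g)
  if (sum(counts >= 2L) < 2L || nlevels(g) < 2L)
    return(list(F = NA_real_, p_value = NA_real_))
  if (stats::var(x) == 0)
    return(list(F = NA_real_, p_value = NA_real_))
  fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p_value = unname(fit$p.value))
}
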