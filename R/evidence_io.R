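# MaxQuant-style peptide evidence tables and sample annotations.
#
# Internally a peptide evidence table is a list with
#   $peptides  data.frame(sequence, proteins)  -- proteins ';'-separated
#   $intensity numeric matrix peptides x samples, NA = not quantified
# MaxQuant writes 0 for non-quantified cells; zeros are re-coded to NA on
# ingest so they cannot pollute medians or fold changes. Intensities stay on
# the raw linear scale; log2 happens only inside analysis operations.

#' Construct a peptide evidence table
#'
#' @param sequence character vector of peptide sequences (unique).
#' @param proteins character vector of mapped database entry ids,
#'   semicolon-separated per peptide.
#' @param intensity numeric matrix (peptides x samples) of linear-scale
#'   intensities; `0` is re-coded to `NA` (not quantified).
#' @return object of class `peptide_evidence`.
#' @export
peptide_evidence <- function(sequence, proteins, intensity) {
  stopifnot(is.character(sequence), is.character(proteins),
            is.matrix(intensity), length(sequence) == length(proteins),
            nrow(intensity) == length(sequence))
  if (anyDuplicated(sequence))
    stop("duplicate peptide sequence(s): ",
         paste(unique(sequence[duplicated(sequence)]), collapse = ", "))
  if (is.null(colnames(intensity)))
    stop("intensity matrix must have sample ids as column names")
  if (any(intensity < 0, na.rm = TRUE))
    stop("negative intensity value(s)")
  intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  rownames(intensity) <- sequence
  structure(list(peptides = data.frame(sequence = sequence,
                                       proteins = proteins,
                                       stringsAsFactors = FALSE),
                 intensity = intensity),
            class = "peptide_evidence")
}

#' @export
print.peptide_evidence <- function(x, ...) {
  cat("peptide_evidence:", nrow(x$intensity), "peptides x",
      ncol(x$intensity), "samples\n")
  cat("  quantified cells:", sum(!is.na(x$intensity)), "of",
      length(x$intensity), "\n")
  invisible(x)
}

#' Subset a peptide evidence table by peptide sequence
#'
#' @param evidence a `peptide_evidence` object.
#' @param keep character vector of peptide sequences to keep.
#' @return a `peptide_evidence` with the retained rows.
#' @export
subset_evidence <- function(evidence, keep) {
  stopifnot(inherits(evidence, "peptide_evidence"))
  idx <- evidence$peptides$sequence %in% keep
  peptide_evidence(evidence$peptides$sequence[idx],
                   evidence$peptides$proteins[idx],
                   evidence$intensity[idx, , drop = FALSE])
}

#' Read a peptide evidence table
#'
#' Two dialects are supported. `"maxquant"` is a peptides.txt-like wide TSV
#' with columns `Sequence`, `Proteins` (semicolon-separated entry ids) and
#' one `<intensity_prefix><sample>` column per sample. `"plain"` is a long
#' TSV with columns `peptide`, `entry_ids`, `sample`, `intensity`.
#'
#' @param path TSV file path.
#' @param dialect `"maxquant"` or `"plain"`.
#' @param intensity_prefix column prefix marking per-sample intensities in
#'   the maxquant dialect (default `"Intensity "`; set e.g. `"LFQ intensity "`
#'   when the table carries MaxLFQ columns instead).
#' @return a [peptide_evidence()] object.
#' @export
read_evidence <- function(path, dialect = c("maxquant", "plain"),
                          intensity_prefix = "Intensity ") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (dialect == "maxquant") {
    need <- c("Sequence", "Proteins")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("evidence table is missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    icols <- names(tab)[startsWith(names(tab), intensity_prefix)]
    if (!length(icols))
      stop("no intensity columns with prefix '", intensity_prefix, "'")
    m <- as.matrix(tab[icols])
    mode(m) <- "numeric"
    colnames(m) <- substring(icols, nchar(intensity_prefix) + 1L)
    peptide_evidence(tab$Sequence, tab$Proteins, m)
  } else {
    need <- c("peptide", "entry_ids", "sample", "intensity")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("evidence table is missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    peps <- unique(tab[c("peptide", "entry_ids")])
    if (anyDuplicated(peps$peptide))
      stop("peptide(s) with inconsistent entry mappings: ",
           paste(unique(peps$peptide[duplicated(peps$peptide)]),
                 collapse = ", "))
    samples <- unique(tab$sample)
    m <- matrix(NA_real_, nrow(peps), length(samples),
                dimnames = list(peps$peptide, samples))
    m[cbind(match(tab$peptide, peps$peptide),
            match(tab$sample, samples))] <- tab$intensity
    peptide_evidence(peps$peptide, peps$entry_ids, m)
  }
}

#' Write a peptide evidence table
#'
#' Inverse of [read_evidence()]; `NA` cells are written as 0 in the maxquant
#' dialect and omitted in the plain (long) dialect, so write-then-read is the
#' identity.
#'
#' @param evidence a `peptide_evidence` object.
#' @param path output TSV path.
#' @inheritParams read_evidence
#' @export
write_evidence <- function(evidence, path, dialect = c("maxquant", "plain"),
                           intensity_prefix = "Intensity ") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(evidence, "peptide_evidence"))
  if (dialect == "maxquant") {
    m <- evidence$intensity
    m[is.na(m)] <- 0
    df <- data.frame(Sequence = evidence$peptides$sequence,
                     Proteins = evidence$peptides$proteins,
                     stringsAsFactors = FALSE, check.names = FALSE)
    im <- as.data.frame(m, check.names = FALSE)
    names(im) <- paste0(intensity_prefix, colnames(m))
    df <- cbind(df, im)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    # every cell is written (0 = not quantified) so samples that happen to
    # be empty for all peptides survive the round trip
    m <- evidence$intensity
    m[is.na(m)] <- 0
    df <- data.frame(
      peptide = rep(evidence$peptides$sequence, times = ncol(m)),
      entry_ids = rep(evidence$peptides$proteins, times = ncol(m)),
      sample = rep(colnames(m), each = nrow(m)),
      intensity = as.vector(m),
      stringsAsFactors = FALSE)
    df <- df[order(match(df$peptide, evidence$peptides$sequence),
                   match(df$sample, colnames(m))), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.stage_levels <- c("I", "II", "III", "IV")

parse_stage <- function(x) {
  out <- toupper(trimws(x))
  out <- sub("^STAGE\\s*", "", out)
  out[out %in% c("", "NA", "NONE")] <- NA_character_
  bad <- !is.na(out) & !(out %in% .stage_levels)
  if (any(bad))
    stop("unknown stage token(s): ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read a sample annotation table
#'
#' TSV with header; mandatory columns `sample_id` and `context`, optional
#' `condition` (`normal`/`cancer`/`none`, default `none`), `stage`
#' (I--IV, parsed case-insensitively with an optional "Stage " prefix) and
#' `pair_id` for patient-matched designs. A stage may only be present for
#' cancer samples.
#'
#' @param path TSV file path.
#' @return data frame with columns `sample_id`, `context`, `condition`,
#'   `stage`, `pair_id`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "context")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(tab$condition)) tab$condition <- "none"
  if (is.null(tab$stage)) tab$stage <- NA_character_
  if (is.null(tab$pair_id)) tab$pair_id <- NA_character_
  tab$condition <- tolower(tab$condition)
  bad <- !(tab$condition %in% c("normal", "cancer", "none"))
  if (any(bad))
    stop("unknown condition value(s): ",
         paste(unique(tab$condition[bad]), collapse = ", "))
  tab$stage <- parse_stage(tab$stage)
  validate_annotation(tab[c("sample_id", "context", "condition", "stage",
                            "pair_id")])
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]),
               collapse = ", "))
  offend <- !is.na(ann$stage) & ann$condition != "cancer"
  if (any(offend))
    stop("stage given for non-cancer sample(s): ",
         paste(ann$sample_id[offend], collapse = ", "))
  ann
}

#' Check that every evidence sample is annotated
#'
#' @param evidence a `peptide_evidence` object.
#' @param annotation data frame as from [read_annotation()].
#' @return (invisibly) `TRUE`; errors naming any unannotated sample.
#' @export
validate_evidence <- function(evidence, annotation) {
  stopifnot(inherits(evidence, "peptide_evidence"))
  missing <- setdiff(colnames(evidence$intensity), annotation$sample_id)
  if (length(missing))
    stop("evidence sample(s) absent from annotation: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
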