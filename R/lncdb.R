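# Construction of the hypothetical lncRNA peptidome:
# three-frame translation, ORF segmentation, in-silico tryptic digestion
# and removal of peptides present in the canonical proteome.

LNC_PREFIX <- "lncpep|"

.valid_biotypes <- c("lincRNA", "antisense", "processed_transcript",
                     "sense_intronic", "sense_overlapping", "unknown")

#' Read lncRNA transcripts from a nucleotide FASTA
#'
#' Sequences are upper-cased and validated against the A/C/G/T/N alphabet.
#' An optional biotype table (TSV with columns `transcript_id` and `biotype`)
#' attaches a GENCODE-style lncRNA biotype to each transcript; transcripts
#' absent from the table get biotype `"unknown"`.
#'
#' @param fasta path to a nucleotide FASTA file.
#' @param biotype_tsv optional path to a tab-separated biotype table.
#' @return data frame with columns `transcript_id`, `biotype`, `sequence`.
#' @export
read_transcripts <- function(fasta, biotype_tsv = NULL) {
  # read as raw strings so invalid letters surface as a validation error
  # naming the record instead of being silently dropped
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  tx <- data.frame(transcript_id = ids,
                   biotype = "unknown",
                   sequence = toupper(as.character(seqs)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(tx$transcript_id))
    stop("duplicated transcript id(s): ",
         paste(unique(tx$transcript_id[duplicated(tx$transcript_id)]),
               collapse = ", "))
  if (!is.null(biotype_tsv)) {
    bt <- utils::read.delim(biotype_tsv, stringsAsFactors = FALSE)
    if (!all(c("transcript_id", "biotype") %in% names(bt)))
      stop("biotype table must have columns 'transcript_id' and 'biotype'")
    bad <- setdiff(unique(bt$biotype), .valid_biotypes)
    if (length(bad))
      stop("unknown biotype(s): ", paste(bad, collapse = ", "))
    m <- match(tx$transcript_id, bt$transcript_id)
    tx$biotype[!is.na(m)] <- bt$biotype[m[!is.na(m)]]
  }
  validate_transcripts(tx)
  tx
}

validate_transcripts <- function(tx) {
  stopifnot(is.data.frame(tx),
            all(c("transcript_id", "sequence") %in% names(tx)))
  if (any(!nzchar(tx$sequence))) {
    bad <- tx$transcript_id[!nzchar(tx$sequence)]
    stop("empty sequence for transcript(s): ", paste(bad, collapse = ", "))
  }
  ok <- !grepl("[^ACGTN]", tx$sequence)
  if (!all(ok))
    stop("non-nucleotide character (outside A/C/G/T/N) in transcript(s): ",
         paste(tx$transcript_id[!ok], collapse = ", "))
  invisible(tx)
}

#' Read a canonical proteome from an amino-acid FASTA
#'
#' @param fasta path to an amino-acid FASTA file.
#' @return named character vector of protein sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_proteome <- function(fasta) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  if (anyDuplicated(ids))
    stop("duplicated proteome id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(out)))
    stop("empty proteome sequence(s): ",
         paste(ids[!nzchar(out)], collapse = ", "))
  out
}

# Translate one frame of all sequences at once; trailing partial codons are
# dropped; codons containing N give 'X' unless unambiguous.
.translate_frame_set <- function(sequences, frame) {
  n_codon <- (nchar(sequences) - frame) %/% 3L
  out <- character(length(sequences))
  ok <- n_codon >= 1L
  if (any(ok)) {
    subs <- substr(sequences[ok], frame + 1L, frame + 3L * n_codon[ok])
    aa <- Biostrings::translate(Biostrings::DNAStringSet(subs),
                                if.fuzzy.codon = "solve",
                                no.init.codon = TRUE)
    out[ok] <- as.character(aa)
  }
  out
}

#' Three-frame translation with stop-codon segmentation
#'
#' Each transcript is translated in sense-strand frames 0, 1 and 2 using the
#' standard genetic code. The translation of each frame is split at stop
#' codons and every stop-free segment of at least `min_orf_len` residues is
#' returned. `aa_start` is the 0-based offset of the segment within the
#' frame's full translation, so the segment corresponds to transcript codons
#' starting at nucleotide `frame + 3 * aa_start`. `segment_index` numbers the
#' non-empty stop-delimited segments of a frame from 0 in order, before the
#' length filter, so indices are stable when `min_orf_len` changes.
#'
#' @param transcripts data frame as from [read_transcripts()], or a named
#'   character vector of nucleotide sequences.
#' @param min_orf_len minimum segment length in amino acids (default 8; a
#'   shorter segment cannot yield a 6-residue tryptic peptide with room for
#'   its termini).
#' @return data frame with columns `transcript_id`, `frame`, `segment_index`,
#'   `aa_start`, `sequence`.
#' @export
three_frame_translate <- function(transcripts, min_orf_len = 8L) {
  if (is.character(transcripts)) {
    transcripts <- data.frame(transcript_id = names(transcripts),
                              sequence = toupper(unname(transcripts)),
                              stringsAsFactors = FALSE)
  }
  stopifnot(min_orf_len >= 1L)
  validate_transcripts(transcripts)
  frame_aa <- lapply(0:2, function(f)
    .translate_frame_set(transcripts$sequence, f))
  out <- vector("list", 3L * nrow(transcripts))
  k <- 0L
  for (i in seq_len(nrow(transcripts))) {
    for (f in 0:2) {
      aa <- frame_aa[[f + 1L]][i]
      if (!nzchar(aa)) next
      m <- gregexpr("[^*]+", aa)[[1]]
      if (m[1] == -1L) next
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      keep <- lens >= min_orf_len
      if (!any(keep)) next
      k <- k + 1L
      out[[k]] <- data.frame(
        transcript_id = transcripts$transcript_id[i],
        frame = f,
        segment_index = which(keep) - 1L,
        aa_start = starts[keep] - 1L,
        sequence = substring(aa, starts[keep], starts[keep] + lens[keep] - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(transcript_id = character(), frame = integer(),
                      segment_index = integer(), aa_start = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Identifier of an ORF polypeptide entry in the merged search database
#'
#' @param transcript_id,frame,segment_index vectors describing the segment.
#' @return character vector `lncpep|<transcript_id>|F<frame>|S<segment_index>`.
#' @export
orf_entry_id <- function(transcript_id, frame, segment_index) {
  sprintf("%s%s|F%d|S%d", LNC_PREFIX, transcript_id,
          as.integer(frame), as.integer(segment_index))
}

# Parse transcript ids back out of lncpep entry identifiers.
parse_entry_transcript <- function(entry_id) {
  sub("^lncpep\\|(.+)\\|F[0-9]+\\|S[0-9]+$", "\\1", entry_id)
}

is_lnc_entry <- function(entry_id) startsWith(entry_id, LNC_PREFIX)

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the following residue is P, enumerating
#' all peptides with up to `max_missed` retained internal cleavage sites.
#' Coordinates are 0-based half-open on the parent sequence. Peptides shorter
#' than `min_len` and peptides containing `X` (untranslatable codons, not
#' matchable to spectra) are dropped.
#'
#' @param sequence amino-acid string of the parent polypeptide.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_len minimum peptide length (default 6).
#' @return data frame with columns `sequence`, `start`, `missed`.
#' @export
tryptic_digest <- function(sequence, max_missed = 2L, min_len = 6L) {
  stopifnot(length(sequence) == 1L, max_missed >= 0L, min_len >= 1L)
  if (grepl("*", sequence, fixed = TRUE))
    stop("stop symbol '*' in sequence passed to tryptic_digest")
  n <- nchar(sequence)
  res <- list(sequence = character(), start = integer(), missed = integer())
  if (n == 0L)
    return(data.frame(res, stringsAsFactors = FALSE))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  nb <- length(bounds)
  seqs <- character(); starts <- integer(); missed <- integer()
  for (a in seq_len(nb - 1L)) {
    b_max <- min(a + 1L + max_missed, nb)
    for (b in (a + 1L):b_max) {
      seqs <- c(seqs, substr(sequence, bounds[a] + 1L, bounds[b]))
      starts <- c(starts, bounds[a])
      missed <- c(missed, b - a - 1L)
    }
  }
  keep <- nchar(seqs) >= min_len & !grepl("X", seqs, fixed = TRUE)
  data.frame(sequence = seqs[keep], start = starts[keep],
             missed = missed[keep], stringsAsFactors = FALSE)
}

#' Digest a table of ORF polypeptides
#'
#' Applies [tryptic_digest()] to every ORF segment, attaching the database
#' entry id of the parent.
#'
#' @param orfs data frame as returned by [three_frame_translate()].
#' @inheritParams tryptic_digest
#' @return data frame with columns `sequence`, `parent_id`, `start`, `missed`.
#' @export
digest_orfs <- function(orfs, max_missed = 2L, min_len = 6L) {
  pieces <- lapply(seq_len(nrow(orfs)), function(i) {
    d <- tryptic_digest(orfs$sequence[i], max_missed, min_len)
    if (nrow(d) == 0L) return(NULL)
    d$parent_id <- orf_entry_id(orfs$transcript_id[i], orfs$frame[i],
                                orfs$segment_index[i])
    d
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces))
    return(data.frame(sequence = character(), start = integer(),
                      missed = integer(), parent_id = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res[c("sequence", "parent_id", "start", "missed")]
}

#' Build the merged search database
#'
#' Translates the lncRNA transcripts in three frames and merges the resulting
#' ORF polypeptides (namespaced `lncpep|...` headers) with the canonical
#' proteome entries, unchanged. The merged collection is what a spectrum
#' search engine would be pointed at.
#'
#' @param transcripts data frame as from [read_transcripts()].
#' @param proteome named character vector as from [read_proteome()].
#' @param min_orf_len minimum ORF segment length (amino acids).
#' @param path optional output FASTA path; when given the collection is
#'   written with [Biostrings::writeXStringSet()].
#' @return (invisibly) named character vector of all database sequences.
#' @export
build_search_db <- function(transcripts, proteome, min_orf_len = 8L,
                            path = NULL) {
  if (any(is_lnc_entry(names(proteome))))
    stop("proteome id(s) collide with the '", LNC_PREFIX, "' namespace: ",
         paste(names(proteome)[is_lnc_entry(names(proteome))], collapse = ", "))
  orfs <- three_frame_translate(transcripts, min_orf_len)
  lnc <- orfs$sequence
  names(lnc) <- orf_entry_id(orfs$transcript_id, orfs$frame,
                             orfs$segment_index)
  db <- c(lnc, proteome)
  if (anyDuplicated(names(db)))
    stop("duplicate database ids after merge")
  if (!is.null(path))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(db), path)
  invisible(db)
}

#' Novelty filter: discard peptides found in the canonical proteome
#'
#' A peptide is discarded iff its sequence occurs as a contiguous substring
#' of any proteome entry. With `collapse_il = TRUE` (default) isoleucine and
#' leucine are treated as indistinguishable on both sides before matching,
#' because isobaric I/L cannot be told apart by mass spectrometry.
#'
#' @param peptides character vector of peptide sequences, or a data frame
#'   with a `sequence` column (e.g. from [digest_orfs()]).
#' @param proteome named character vector of protein sequences.
#' @param collapse_il treat I and L as equivalent (default `TRUE`).
#' @return list with elements `retained` and `discarded`, each the same type
#'   as the input (subset of rows for a data frame input).
#' @export
novelty_filter <- function(peptides, proteome, collapse_il = TRUE) {
  seqs <- if (is.data.frame(peptides)) peptides$sequence else peptides
  stopifnot(is.character(seqs))
  if (length(proteome) == 0L) {
    hit <- rep(FALSE, length(seqs))
  } else {
    haystack <- paste(unname(proteome), collapse = "*")
    needles <- seqs
    if (collapse_il) {
      haystack <- chartr("I", "L", haystack)
      needles <- chartr("I", "L", needles)
    }
    uniq <- unique(needles)
    uhit <- vapply(uniq, function(p) grepl(p, haystack, fixed = TRUE),
                   logical(1), USE.NAMES = TRUE)
    hit <- unname(uhit[needles])
  }
  if (is.data.frame(peptides)) {
    list(retained = peptides[!hit, , drop = FALSE],
         discarded = peptides[hit, , drop = FALSE])
  } else {
    list(retained = peptides[!hit], discarded = peptides[hit])
  }
}
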