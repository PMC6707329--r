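# Synthetic cohorts with known ground truth: lncRNA transcripts carrying
# planted ORFs, a canonical proteome (optionally seeded with decoy copies of
# planted peptides), and peptide-evidence panels for tissues, cell lines and
# a staged cancer cohort.

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

# Codons of the standard genetic code per amino acid (no stops).
.codon_table <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"),
  F = c("TTT", "TTC"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"), L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = "ATG", N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"), Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))

reverse_translate <- function(aa) {
  codons <- vapply(strsplit(aa, "", fixed = TRUE)[[1]], function(a) {
    opts <- .codon_table[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: 14 tissues and 11
#' cell lines with a few runs each, a 92-cancer / 30-normal staged cohort,
#' log-normal peptide intensities with shared group-level signal, MCAR
#' dropout, planted specificity classes, fold changes and monotone stage
#' trends.
#'
#' @param seed integer RNG seed.
#' @param n_tissues,n_celllines number of contexts per panel.
#' @param samples_per_context runs per context.
#' @param n_groups number of planted polypeptide groups.
#' @param fraction_specific,fraction_ubiquitous,fraction_uexp disjoint class
#'   fractions: context-specific, tissue-ubiquitous (but not universal), and
#'   universally expressed in both panels; the remainder are shared.
#' @param fraction_subsumed fraction of groups given a second transcript
#'   whose peptide set is a subset of the primary's (shared-peptide
#'   degeneracy exercising subsumption grouping).
#' @param peptides_per_group peptides planted per polypeptide (>= 2 so
#'   groups can pass the reporting rule).
#' @param peptide_len_range min/max planted peptide length (residues).
#' @param log2_mean,log2_sd baseline log2 intensity and sample-level noise
#'   sd; peptide-level noise sd is fixed at `0.1 * log2_sd` so peptides of
#'   one group track each other (low within-context %CV).
#' @param dropout_prob probability a quantified cell is missing.
#' @param missing_mode `"mcar"` (default) or `"censor"` (logistic in log2
#'   intensity, emulating left-censored label-free missingness).
#' @param n_cancer,n_normal cancer-cohort sizes.
#' @param de_fraction,de_log2fc fraction of groups upregulated in cancer and
#'   their log2 fold change.
#' @param stage_slope added log2 abundance per stage step (I -> IV) for the
#'   differential groups.
#' @param decoy_fraction fraction of planted peptides copied verbatim into
#'   proteome entries (exercises the novelty filter).
#' @param n_proteins,protein_len canonical proteome size.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tissues = 14L, n_celllines = 11L,
                       samples_per_context = 3L,
                       n_groups = 150L,
                       fraction_specific = 0.40,
                       fraction_ubiquitous = 0.08,
                       fraction_uexp = 0.04,
                       fraction_subsumed = 0.10,
                       peptides_per_group = 3L,
                       peptide_len_range = c(8L, 12L),
                       log2_mean = 25, log2_sd = 1,
                       dropout_prob = 0.1,
                       missing_mode = c("mcar", "censor"),
                       n_cancer = 92L, n_normal = 30L,
                       de_fraction = 0.1, de_log2fc = 2,
                       stage_slope = 0.5,
                       decoy_fraction = 0,
                       n_proteins = 100L, protein_len = 300L) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(seed = as.integer(seed), n_tissues = as.integer(n_tissues),
              n_celllines = as.integer(n_celllines),
              samples_per_context = as.integer(samples_per_context),
              n_groups = as.integer(n_groups),
              fraction_specific = fraction_specific,
              fraction_ubiquitous = fraction_ubiquitous,
              fraction_uexp = fraction_uexp,
              fraction_subsumed = fraction_subsumed,
              peptides_per_group = as.integer(peptides_per_group),
              peptide_len_range = as.integer(peptide_len_range),
              log2_mean = log2_mean, log2_sd = log2_sd,
              dropout_prob = dropout_prob, missing_mode = missing_mode,
              n_cancer = as.integer(n_cancer),
              n_normal = as.integer(n_normal),
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              stage_slope = stage_slope, decoy_fraction = decoy_fraction,
              n_proteins = as.integer(n_proteins),
              protein_len = as.integer(protein_len))
  if (cfg$peptides_per_group < 2L)
    stop("peptides_per_group must be >= 2 (reporting rule is 2 peptides)")
  if (fraction_specific + fraction_ubiquitous + fraction_uexp > 1)
    stop("class fractions must sum to <= 1")
  if (any(cfg$peptide_len_range < 6L))
    stop("planted peptides must be at least 6 residues")
  if (cfg$n_cancer < 8L)
    stop("n_cancer must allow >= 2 samples in each of 4 stages")
  structure(cfg, class = "sim_config")
}

# Sample one tryptic peptide: body without K/R/P (so the peptide holds no
# internal cleavage site and never precedes a proline boundary), C-terminal
# K or R.
.sample_peptide <- function(len) {
  body <- sample(setdiff(.aa20, c("K", "R", "P")), len - 1L, replace = TRUE)
  paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
}

#' Simulate lncRNA transcripts and a canonical proteome
#'
#' Plants, per group, a polypeptide built from `peptides_per_group`
#' concatenated tryptic peptides, reverse-translates it (random synonymous
#' codons) into a frame-0 ORF terminated by a stop codon, and samples a
#' random canonical proteome guaranteed (after I/L collapsing) not to
#' contain any planted peptide -- except a `decoy_fraction` of peptides
#' copied verbatim into proteome entries, recorded in the truth manifest.
#' A `fraction_subsumed` of groups get a second transcript encoding a
#' prefix of the polypeptide, so its peptide set is subsumed by the
#' primary's. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `transcripts` (data frame for [three_frame_translate()]),
#'   `proteome` (named character) and `truth` (transcript roles, planted
#'   peptides with novelty status, planted polypeptide sequences).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_groups
  ppg <- config$peptides_per_group
  lens <- config$peptide_len_range

  peptides <- character(n * ppg)
  repeat {
    need <- which(peptides == "" | duplicated(peptides))
    if (!length(need)) break
    peptides[need] <- vapply(need, function(i)
      .sample_peptide(sample(seq(lens[1], lens[2]), 1L)), character(1))
  }
  pep_group <- rep(seq_len(n), each = ppg)
  group_ids <- sprintf("SIMLNC%04d", seq_len(n))
  polypeptides <- vapply(split(peptides, pep_group), paste, character(1),
                         collapse = "")
  names(polypeptides) <- group_ids

  # canonical proteome free of planted peptides (I/L collapsed comparison)
  collapsed_peps <- chartr("I", "L", peptides)
  proteome <- vapply(seq_len(config$n_proteins), function(i)
    paste(sample(.aa20, config$protein_len, replace = TRUE),
          collapse = ""), character(1))
  names(proteome) <- sprintf("SIMPROT%04d", seq_len(config$n_proteins))
  repeat {
    coll_prot <- chartr("I", "L", proteome)
    hit_peps <- collapsed_peps[vapply(collapsed_peps, function(p)
      any(grepl(p, coll_prot, fixed = TRUE)), logical(1))]
    if (!length(hit_peps)) break
    # regenerate exactly the colliding proteins, keeping the peptides fixed
    idx <- which(vapply(coll_prot, function(pr)
      any(vapply(hit_peps, function(p) grepl(p, pr, fixed = TRUE),
                 logical(1))), logical(1)))
    proteome[idx] <- vapply(idx, function(i)
      paste(sample(.aa20, config$protein_len, replace = TRUE),
            collapse = ""), character(1))
  }

  # decoys: copy selected planted peptides into random proteome entries
  n_decoy <- round(config$decoy_fraction * length(peptides))
  decoy_idx <- if (n_decoy > 0) sample(seq_along(peptides), n_decoy)
               else integer(0)
  novel <- rep(TRUE, length(peptides))
  if (n_decoy > 0) {
    novel[decoy_idx] <- FALSE
    placed <- integer(0)
    for (j in decoy_idx) {
      for (attempt in 1:50) {
        pi <- sample.int(length(proteome), 1L)
        pos <- sample.int(nchar(proteome[pi]) + 1L, 1L) - 1L
        cand <- proteome
        cand[pi] <- paste0(substr(cand[pi], 1L, pos), peptides[j],
                           substr(cand[pi], pos + 1L, nchar(cand[pi])))
        hay <- chartr("I", "L", paste(cand, collapse = "*"))
        # no accidental match of a still-novel peptide, and no earlier
        # decoy copy destroyed by inserting inside it
        ok <- !any(vapply(collapsed_peps[novel],
                          function(p) grepl(p, hay, fixed = TRUE),
                          logical(1))) &&
          all(vapply(collapsed_peps[c(placed, j)],
                     function(p) grepl(p, hay, fixed = TRUE), logical(1)))
        if (ok) { proteome <- cand; placed <- c(placed, j); break }
      }
    }
  }

  # transcripts: reverse-translated ORF + stop; subsumed twins encode a
  # peptide prefix of the primary polypeptide
  stops <- c("TAA", "TAG", "TGA")
  tx_seq <- vapply(polypeptides, function(pp)
    paste0(reverse_translate(pp), stops[sample.int(3L, 1L)]), character(1))
  biotype <- sample(c("lincRNA", "antisense", "processed_transcript",
                      "sense_intronic", "sense_overlapping"),
                    n, replace = TRUE,
                    prob = c(0.49, 0.37, 0.09, 0.03, 0.02))
  transcripts <- data.frame(transcript_id = group_ids, biotype = biotype,
                            sequence = unname(tx_seq),
                            stringsAsFactors = FALSE)
  roles <- data.frame(transcript_id = group_ids, group = group_ids,
                      role = "primary", stringsAsFactors = FALSE)
  n_sub <- round(config$fraction_subsumed * n)
  if (n_sub > 0) {
    sub_groups <- sample(seq_len(n), n_sub)
    twin_pp <- vapply(sub_groups, function(g) {
      paste(peptides[pep_group == g][seq_len(ppg - 1L)], collapse = "")
    }, character(1))
    twin_ids <- paste0(group_ids[sub_groups], "B")
    twin_seq <- vapply(twin_pp, function(pp)
      paste0(reverse_translate(pp), stops[sample.int(3L, 1L)]), character(1))
    transcripts <- rbind(transcripts, data.frame(
      transcript_id = twin_ids,
      biotype = biotype[sub_groups],
      sequence = unname(twin_seq), stringsAsFactors = FALSE))
    roles <- rbind(roles, data.frame(transcript_id = twin_ids,
                                     group = group_ids[sub_groups],
                                     role = "subsumed",
                                     stringsAsFactors = FALSE))
  }

  pp_start <- unlist(lapply(split(nchar(peptides), pep_group), function(l)
    cumsum(c(0L, l[-length(l)]))), use.names = FALSE)
  truth <- list(
    transcripts = roles,
    peptides = data.frame(sequence = peptides,
                          group = group_ids[pep_group],
                          index_in_group = rep(seq_len(ppg), n),
                          start = pp_start,
                          novel = novel, stringsAsFactors = FALSE),
    polypeptides = polypeptides,
    config = config)
  list(transcripts = transcripts, proteome = proteome, truth = truth)
}

# presence pattern helpers -------------------------------------------------

.assign_classes <- function(config) {
  n <- config$n_groups
  n_uexp <- round(config$fraction_uexp * n)
  n_ubiq <- round(config$fraction_ubiquitous * n)
  n_spec <- round(config$fraction_specific * n)
  cls <- rep("shared", n)
  pool <- sample(n)
  cls[pool[seq_len(n_uexp)]] <- "uexp"
  cls[pool[n_uexp + seq_len(n_ubiq)]] <- "ubiquitous"
  cls[pool[n_uexp + n_ubiq + seq_len(n_spec)]] <- "specific"
  cls
}

# logical n_groups x n_contexts presence matrix for one panel
.presence_pattern <- function(cls, n_ctx, panel) {
  n <- length(cls)
  pres <- matrix(FALSE, n, n_ctx)
  for (g in seq_len(n)) {
    pres[g, ] <- switch(
      cls[g],
      uexp = rep(TRUE, n_ctx),
      ubiquitous = if (panel == "tissue") rep(TRUE, n_ctx) else {
        # tissue-ubiquitous but not universal: miss >= 1 cell line
        out <- rep(FALSE, n_ctx)
        out[sample.int(n_ctx, sample(seq_len(n_ctx - 1L), 1L))] <- TRUE
        out
      },
      specific = if (panel == "tissue") {
        out <- rep(FALSE, n_ctx); out[sample.int(n_ctx, 1L)] <- TRUE; out
      } else rep(FALSE, n_ctx),
      shared = {
        out <- rep(FALSE, n_ctx)
        if (panel == "tissue") {
          out[sample.int(n_ctx, sample(2:(n_ctx - 1L), 1L))] <- TRUE
        } else if (stats::runif(1) < 0.1) {
          out[] <- TRUE        # some cell-line-ubiquitous non-UExp groups
        } else {
          k <- sample(0:(n_ctx - 1L), 1L)
          if (k > 0) out[sample.int(n_ctx, k)] <- TRUE
        }
        out
      })
  }
  pres
}

# build one evidence panel from planted per-group/sample log2 means
.panel_evidence <- function(config, truth, mu, present_cells, samples,
                            panel_name) {
  peps <- truth$peptides
  entry <- orf_entry_id(peps$group, 0L, 0L)
  roles <- truth$transcripts
  twin_of <- roles$transcript_id[roles$role == "subsumed"]
  names(twin_of) <- roles$group[roles$role == "subsumed"]
  has_twin <- peps$group %in% names(twin_of)
  ppg <- config$peptides_per_group
  shared_with_twin <- has_twin & peps$index_in_group < ppg
  entry[shared_with_twin] <- paste0(
    entry[shared_with_twin], ";",
    orf_entry_id(twin_of[peps$group[shared_with_twin]], 0L, 0L))

  pep_sd <- 0.1 * config$log2_sd
  n_pep <- nrow(peps)
  n_s <- length(samples)
  g_idx <- match(peps$group, rownames(mu))
  inten <- matrix(NA_real_, n_pep, n_s, dimnames = list(peps$sequence,
                                                        samples))
  noise <- matrix(stats::rnorm(n_pep * n_s, 0, pep_sd), n_pep, n_s)
  for (s in seq_len(n_s)) {
    on <- present_cells[g_idx, s]
    inten[on, s] <- 2^(mu[g_idx[on], s] + noise[on, s])
  }
  if (config$dropout_prob > 0) {
    obs <- which(!is.na(inten))
    if (config$missing_mode == "mcar") {
      drop <- obs[stats::runif(length(obs)) < config$dropout_prob]
    } else {
      # left-censored: logistic dropout in log2 intensity, centred so the
      # marginal rate is close to dropout_prob
      lg <- log2(inten[obs])
      thr <- stats::quantile(lg, probs = config$dropout_prob) + 0.25
      pmiss <- stats::plogis((thr - lg) / 0.5)
      drop <- obs[stats::runif(length(obs)) < pmiss]
    }
    inten[drop] <- NA_real_
  }
  keep <- rowSums(!is.na(inten)) > 0L
  peptide_evidence(peps$sequence[keep], entry[keep],
                   inten[keep, , drop = FALSE])
}

#' Simulate peptide-evidence panels with known ground truth
#'
#' Generates three evidence tables (tissue panel, cell-line panel, staged
#' cancer cohort) plus annotations. Peptide log2 intensity is
#' `log2_mean + group effect + context effect + sample-level noise`, shared
#' by all peptides of a group in a sample up to small peptide-level noise
#' (sd `0.1 * log2_sd`), exponentiated to the linear scale. Specific groups
#' have intensity only in their context; differential groups gain
#' `de_log2fc` in cancer samples plus `stage_slope * (stage - 1)`.
#' Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_transcriptome()] for the same config.
#' @return list with `evidence` (named list of [peptide_evidence()]:
#'   `tissue`, `cellline`, `cancer`), `annotation` (matching data frames)
#'   and `truth` (planted classes, per-panel presence patterns and planted
#'   linear-scale group abundance matrices).
#' @export
simulate_evidence <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_groups
  gid <- names(sim$truth$polypeptides)
  cls <- .assign_classes(config)

  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  cells <- sprintf("cellline_%02d", seq_len(config$n_celllines))
  spc <- config$samples_per_context
  t_samples <- paste0(rep(tissues, each = spc), "_r", seq_len(spc))
  c_samples <- paste0(rep(cells, each = spc), "_r", seq_len(spc))
  t_ctx <- rep(tissues, each = spc)
  c_ctx <- rep(cells, each = spc)

  pres_t <- .presence_pattern(cls, config$n_tissues, "tissue")
  pres_c <- .presence_pattern(cls, config$n_celllines, "cellline")
  dimnames(pres_t) <- list(gid, tissues)
  dimnames(pres_c) <- list(gid, cells)

  b_g <- stats::rnorm(n, 0, 1.5)
  ctx_eff_t <- stats::rnorm(config$n_tissues, 0, 1)
  ctx_eff_c <- stats::rnorm(config$n_celllines, 0, 1)

  mu_t <- outer(b_g, rep(0, length(t_samples)), `+`) +
    matrix(ctx_eff_t[match(t_ctx, tissues)], n, length(t_samples),
           byrow = TRUE) +
    matrix(stats::rnorm(n * length(t_samples), 0, config$log2_sd),
           n, length(t_samples)) + config$log2_mean
  mu_c <- outer(b_g, rep(0, length(c_samples)), `+`) +
    matrix(ctx_eff_c[match(c_ctx, cells)], n, length(c_samples),
           byrow = TRUE) +
    matrix(stats::rnorm(n * length(c_samples), 0, config$log2_sd),
           n, length(c_samples)) + config$log2_mean
  dimnames(mu_t) <- list(gid, t_samples)
  dimnames(mu_c) <- list(gid, c_samples)

  # cancer cohort: all groups structurally present; DE groups upregulated
  # with a monotone stage trend
  k_samples <- sprintf("COAD_%03d", seq_len(config$n_cancer))
  n_samples_ <- sprintf("NORM_%03d", seq_len(config$n_normal))
  stages <- rep_len(.stage_levels, config$n_cancer)
  de <- rep(FALSE, n)
  de[sample(n, round(config$de_fraction * n))] <- TRUE
  all_k <- c(k_samples, n_samples_)
  mu_k <- outer(b_g, rep(0, length(all_k)), `+`) + config$log2_mean +
    matrix(stats::rnorm(n * length(all_k), 0, config$log2_sd),
           n, length(all_k))
  stage_num <- c(match(stages, .stage_levels), rep(0L, config$n_normal))
  is_cancer <- c(rep(TRUE, config$n_cancer), rep(FALSE, config$n_normal))
  bump <- outer(as.numeric(de),
                ifelse(is_cancer, 1, 0) * config$de_log2fc +
                  pmax(stage_num - 1L, 0L) * config$stage_slope)
  mu_k <- mu_k + bump
  dimnames(mu_k) <- list(gid, all_k)
  pres_k <- matrix(TRUE, n, length(all_k), dimnames = list(gid, all_k))

  ev_t <- .panel_evidence(config, sim$truth, mu_t,
                          pres_t[, match(t_ctx, tissues), drop = FALSE],
                          t_samples, "tissue")
  ev_c <- .panel_evidence(config, sim$truth, mu_c,
                          pres_c[, match(c_ctx, cells), drop = FALSE],
                          c_samples, "cellline")
  ev_k <- .panel_evidence(config, sim$truth, mu_k, pres_k, all_k, "cancer")

  ann_t <- data.frame(sample_id = t_samples, context = t_ctx,
                      condition = "none", stage = NA_character_,
                      pair_id = NA_character_, stringsAsFactors = FALSE)
  ann_c <- data.frame(sample_id = c_samples, context = c_ctx,
                      condition = "none", stage = NA_character_,
                      pair_id = NA_character_, stringsAsFactors = FALSE)
  ann_k <- data.frame(sample_id = all_k,
                      context = ifelse(is_cancer, "COAD", "normal colon"),
                      condition = ifelse(is_cancer, "cancer", "normal"),
                      stage = c(stages, rep(NA_character_,
                                            config$n_normal)),
                      pair_id = NA_character_, stringsAsFactors = FALSE)

  truth <- list(
    classes = data.frame(
      group_id = gid, tissue_class = cls,
      n_tissue_contexts = rowSums(pres_t),
      cellline_ubiquitous = rowSums(pres_c) == config$n_celllines,
      uexp = cls == "uexp", de = de, stringsAsFactors = FALSE),
    presence = list(tissue = pres_t, cellline = pres_c),
    abundance = list(tissue = 2^mu_t, cellline = 2^mu_c, cancer = 2^mu_k),
    stages = stages, de_groups = gid[de])
  list(evidence = list(tissue = ev_t, cellline = ev_c, cancer = ev_k),
       annotation = list(tissue = ann_t, cellline = ann_c, cancer = ann_k),
       truth = truth)
}

#' Write a simulated study to disk
#'
#' Writes the lncRNA FASTA, biotype TSV, proteome FASTA, per-panel evidence
#' TSVs (maxquant dialect), annotation TSVs and a JSON truth manifest, all
#' consumable by [run_pipeline()].
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) named list of written paths plus the in-memory
#'   simulation objects.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_transcriptome(config)
  ev <- simulate_evidence(config, sim)
  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(structure(sim$transcripts$sequence,
                                       names = sim$transcripts$transcript_id)),
    p("lncrna.fasta"))
  utils::write.table(sim$transcripts[c("transcript_id", "biotype")],
                     p("biotypes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$proteome),
                              p("proteome.fasta"))
  paths <- list(lncrna_fasta = p("lncrna.fasta"),
                biotype_tsv = p("biotypes.tsv"),
                proteome_fasta = p("proteome.fasta"),
                evidence = list(), annotation = list())
  for (panel in names(ev$evidence)) {
    epath <- p(paste0("evidence_", panel, ".tsv"))
    apath <- p(paste0("annotation_", panel, ".tsv"))
    write_evidence(ev$evidence[[panel]], epath)
    utils::write.table(ev$annotation[[panel]], apath, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    paths$evidence[[panel]] <- epath
    paths$annotation[[panel]] <- apath
  }
  truth_json <- list(classes = ev$truth$classes,
                     peptides = sim$truth$peptides,
                     de_groups = ev$truth$de_groups)
  jsonlite::write_json(truth_json, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  paths$truth <- p("truth.json")
  invisible(c(paths, list(sim = sim, cohort = ev)))
}
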