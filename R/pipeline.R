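# End-to-end orchestration: build-db -> digest -> novelty-filter ->
# validate -> quantify -> classify -> diff (-> enrich), with a run manifest.
# Every stage is deterministic, so re-running an identical config gives
# byte-identical outputs.

default_params <- function() {
  list(min_orf_len = 8L, min_peptide_len = 6L, max_missed = 2L,
       min_nonoverlap = 2L, collapse_il = TRUE, adj_p_threshold = 0.05,
       min_per_stage = 2L, dialect = "maxquant",
       intensity_prefix = "Intensity ")
}

#' Read a pipeline configuration file
#'
#' YAML with keys `lncrna_fasta`, `proteome_fasta`, optional `biotype_tsv`
#' and `term_map_tsv`, `evidence:` and `annotation:` (panel name -> path;
#' panels named `tissue`, `cellline` and `cancer` get the corresponding
#' downstream analyses), and an optional `params:` block overriding
#' thresholds (`min_orf_len`, `min_peptide_len`, `max_missed`,
#' `min_nonoverlap`, `collapse_il`, `adj_p_threshold`, `min_per_stage`,
#' `dialect`, `intensity_prefix`). Defaults follow the reporting criteria
#' of the workflow: peptides of >= 6 residues, <= 2 missed cleavages,
#' >= 2 non-overlapping unique peptides, BH-adjusted p < 0.05, >= 2
#' quantified samples per stage.
#'
#' @param path YAML file path.
#' @return config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$params <- utils::modifyList(default_params(),
                                  as.list(cfg$params))
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full lncRNA-peptidome pipeline
#'
#' Executes database construction, in-silico digestion, the proteome
#' novelty filter, evidence validation, grouping and median-LFQ
#' quantification, specificity/UExp classification and (for a panel named
#' `cancer`) differential-abundance, stage-ANOVA and early/late analyses;
#' a hypergeometric enrichment stage runs when a term map is configured.
#' All outputs are TSV/FASTA/JSON files under `out_dir`; a `manifest.json`
#' records parameters, input checksums and per-stage outputs.
#'
#' @param config list as from [read_pipeline_config()], or built in code.
#' @param out_dir output directory (created).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- utils::modifyList(default_params(), as.list(config$params))
  p <- function(f) file.path(out_dir, f)
  manifest <- list(package = "lncpeptidome",
                   version = as.character(utils::packageVersion("lncpeptidome")),
                   parameters = params, inputs = list(), stages = list())

  input_paths <- c(lncrna_fasta = config$lncrna_fasta,
                   proteome_fasta = config$proteome_fasta,
                   unlist(config$evidence), unlist(config$annotation))
  manifest$inputs <- as.list(unname(tools::md5sum(input_paths)))
  names(manifest$inputs) <- names(input_paths)

  # 1. build-db ------------------------------------------------------------
  db <- .stage("build_db", {
    tx <- read_transcripts(config$lncrna_fasta, config$biotype_tsv)
    prot <- read_proteome(config$proteome_fasta)
    db <- build_search_db(tx, prot, params$min_orf_len, p("search_db.fasta"))
    orfs <- three_frame_translate(tx, params$min_orf_len)
    write_tsv(orfs, p("orfs.tsv"))
    list(db = db, orfs = orfs, proteome = prot, transcripts = tx)
  })
  manifest$stages$build_db <- list(outputs = c("search_db.fasta", "orfs.tsv"),
                                   n_orfs = nrow(db$orfs),
                                   n_proteins = length(db$proteome))

  # 2. digest --------------------------------------------------------------
  digest <- .stage("digest", {
    d <- digest_orfs(db$orfs, params$max_missed, params$min_peptide_len)
    write_tsv(d, p("digest.tsv"))
    d
  })
  manifest$stages$digest <- list(outputs = "digest.tsv",
                                 n_peptides = nrow(digest))

  # 3. novelty-filter ------------------------------------------------------
  novelty <- .stage("novelty_filter", {
    nf <- novelty_filter(digest, db$proteome, params$collapse_il)
    write_tsv(nf$retained, p("peptides_retained.tsv"))
    write_tsv(nf$discarded, p("peptides_discarded.tsv"))
    nf
  })
  manifest$stages$novelty_filter <- list(
    outputs = c("peptides_retained.tsv", "peptides_discarded.tsv"),
    n_retained = nrow(novelty$retained),
    n_discarded = nrow(novelty$discarded))

  # 4. validate evidence ---------------------------------------------------
  panels <- .stage("validate", {
    out <- list()
    for (panel in names(config$evidence)) {
      ev <- read_evidence(config$evidence[[panel]], params$dialect,
                          params$intensity_prefix)
      ann <- read_annotation(config$annotation[[panel]])
      validate_evidence(ev, ann)
      out[[panel]] <- list(evidence = ev, annotation = ann)
    }
    out
  })
  manifest$stages$validate <- list(
    panels = names(panels),
    n_samples = vapply(panels, function(x) ncol(x$evidence$intensity),
                       integer(1)))

  # 5. quantify ------------------------------------------------------------
  quant <- .stage("quantify", {
    retained <- unique(novelty$retained$sequence)
    out <- list()
    for (panel in names(panels)) {
      ev <- subset_evidence(panels[[panel]]$evidence, retained)
      grp <- group_shared_peptides(ev)
      q <- quantify_groups(grp, ev, db$db, params$min_nonoverlap)
      write_tsv(q$groups, p(paste0("groups_", panel, ".tsv")))
      ab <- data.frame(group_id = rownames(q$abundance),
                       q$abundance, check.names = FALSE,
                       stringsAsFactors = FALSE)
      write_tsv(ab, p(paste0("abundance_", panel, ".tsv")))
      out[[panel]] <- q
    }
    out
  })
  manifest$stages$quantify <- list(
    outputs = as.vector(vapply(names(quant), function(panel)
      c(paste0("groups_", panel, ".tsv"),
        paste0("abundance_", panel, ".tsv")), character(2))),
    n_groups = vapply(quant, function(q) nrow(q$abundance), integer(1)))

  # 6. classify ------------------------------------------------------------
  cls <- .stage("classify", {
    out <- list()
    for (panel in names(quant)) {
      ann <- panels[[panel]]$annotation
      if (!all(ann$condition == "none")) next
      pres <- detect_presence(quant[[panel]]$abundance, ann)
      sp <- classify_specificity(pres)
      write_tsv(sp, p(paste0("specificity_", panel, ".tsv")))
      out[[panel]] <- sp
    }
    if (all(c("tissue", "cellline") %in% names(out))) {
      ue <- universal_expressed(
        out$tissue$group_id[out$tissue$label == "ubiquitous"],
        out$cellline$group_id[out$cellline$label == "ubiquitous"])
      writeLines(ue, p("uexp.txt"))
      out$uexp <- ue
    }
    out
  })
  manifest$stages$classify <- list(
    outputs = c(paste0("specificity_",
                       setdiff(names(cls), "uexp"), ".tsv"),
                if (!is.null(cls$uexp)) "uexp.txt"),
    n_uexp = if (!is.null(cls$uexp)) length(cls$uexp))

  # 7. diff ----------------------------------------------------------------
  diff_res <- .stage("diff", {
    out <- list()
    if ("cancer" %in% names(quant)) {
      ann <- panels$cancer$annotation
      ab <- quant$cancer$abundance
      lg <- log2(ab)
      cond <- factor(ann$condition[match(colnames(ab), ann$sample_id)],
                     levels = c("normal", "cancer"))
      dt <- moderated_t_test(lg, cond)
      write_tsv(dt, p("diff_cancer_vs_normal.tsv"))
      out$cancer_vs_normal <- dt
      k_idx <- which(cond == "cancer")
      stages_k <- ann$stage[match(colnames(ab)[k_idx], ann$sample_id)]
      sa <- stage_anova(lg[, k_idx, drop = FALSE], stages_k,
                        params$min_per_stage)
      write_tsv(sa, p("stage_anova.tsv"))
      out$stage_anova <- sa
      el <- early_late_test(lg[, k_idx, drop = FALSE], stages_k)
      write_tsv(el, p("early_late.tsv"))
      out$early_late <- el
    }
    out
  })
  manifest$stages$diff <- list(
    outputs = if (length(diff_res))
      c("diff_cancer_vs_normal.tsv", "stage_anova.tsv", "early_late.tsv"),
    n_significant = if (!is.null(diff_res$cancer_vs_normal))
      sum(diff_res$cancer_vs_normal$adj_p < params$adj_p_threshold,
          na.rm = TRUE))

  # 8. enrich (optional) ---------------------------------------------------
  if (!is.null(config$term_map_tsv) &&
      !is.null(diff_res$cancer_vs_normal)) {
    enr <- .stage("enrich", {
      tm <- utils::read.delim(config$term_map_tsv,
                              stringsAsFactors = FALSE)
      term_map <- split(tm$group_id, tm$term_id)
      dt <- diff_res$cancer_vs_normal
      sel <- dt$group_id[!is.na(dt$adj_p) &
                           dt$adj_p < params$adj_p_threshold]
      uni <- dt$group_id[!dt$excluded]
      e <- hypergeom_enrichment(sel, term_map, uni)
      write_tsv(e, p("enrichment.tsv"))
      e
    })
    manifest$stages$enrich <- list(outputs = "enrichment.tsv",
                                   n_terms = nrow(enr))
  }

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
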