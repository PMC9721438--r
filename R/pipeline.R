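# End-to-end orchestration: reference -> transcripts -> ORFs -> protein
# classes -> hybrid database -> peptide evidence, with one threshold set and
# a run report mirroring the pipeline's bookkeeping tables.

#' Default pipeline thresholds
#'
#' All decision constants in one place: minimum transcript abundance (1 CPM),
#' co-expression floor (3 CPM per isoform), hybrid high-confidence gene rules
#' (>= 3 CPM and 1--4 kb mean annotated length), nomination floor (25 CPM),
#' minimum ORF length (50 nt), NMD junction limit (more than 2 junctions
#' after the stop codon), peptide FDR tiers (q <= 0.01 reporting, q < 0.001
#' novel), and tryptic missed cleavages (2).
#'
#' @param ... overrides by name.
#' @return named list of thresholds.
#' @export
default_thresholds <- function(...) {
  th <- list(min_transcript_cpm = 1, coexpression_min_cpm = 3,
             hybrid_min_gene_cpm = 3, hybrid_length_window_nt = c(1000, 4000),
             nomination_min_cpm = 25, min_orf_nt = 50,
             nmd_max_junctions_after_stop = 2, peptide_q_max = 0.01,
             novel_peptide_q_strict = 0.001, missed_cleavages = 2)
  ov <- list(...)
  bad <- setdiff(names(ov), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  utils::modifyList(th, ov)
}

#' Run the full long-read proteogenomics pipeline
#'
#' Executes every stage in order on file inputs and returns a `run_report`
#' plus all intermediate objects. Stage outputs (classification table, gene
#' summary, hybrid FASTA, gene-source map, removal ledger, BED12 track,
#' mapping/evidence/novel-peptide tables) are written to `out_dir` when
#' given.
#'
#' @param annotation_gtf,genome_fasta reference annotation and genome.
#' @param transcripts_gtf,counts_tsv long-read models and full-length counts.
#' @param peptides_tsv peptide identification table (sequence, q_value,
#'   psm_count).
#' @param appris_tsv optional APPRIS principal table.
#' @param contaminants_fasta optional contaminant FASTA.
#' @param uniprot_fasta optional second reference protein FASTA for the
#'   novel-peptide check.
#' @param thresholds list from [default_thresholds()].
#' @param out_dir optional output directory.
#' @return list of class `lrp_run` with `report` and intermediate objects.
#' @export
run_pipeline <- function(annotation_gtf, genome_fasta, transcripts_gtf,
                         counts_tsv, peptides_tsv, appris_tsv = NULL,
                         contaminants_fasta = NULL, uniprot_fasta = NULL,
                         thresholds = default_thresholds(), out_dir = NULL) {
  th <- thresholds
  catalog <- load_annotation(annotation_gtf, genome_fasta, appris_tsv)
  lr <- read_longread_models(transcripts_gtf, counts_tsv, catalog)
  lr$transcripts <- filter_min_abundance(lr$transcripts, th$min_transcript_cpm)
  lr$exons <- lr$exons[lr$exons$transcript_id %in% lr$transcripts$pb_accession, ]
  lr$seqs <- lr$seqs[lr$transcripts$pb_accession]
  lr <- classify_transcripts(lr, catalog)
  summaries <- summarize_gene_expression(lr, catalog)
  concord <- major_principal_concordance(summaries)

  orfs <- call_orfs(lr, catalog, min_nt = th$min_orf_nt)
  orfs <- classify_proteins(orfs, lr, catalog)
  filt <- filter_protein_isoforms(orfs, th$nmd_max_junctions_after_stop)
  grouped <- group_orfs_by_sequence(filt$retained, lr)
  high_conf <- select_high_confidence_genes(summaries, catalog,
                                            th$hybrid_min_gene_cpm,
                                            th$hybrid_length_window_nt)
  contaminants <- if (!is.null(contaminants_fasta))
    read_fasta(contaminants_fasta, "aa") else NULL
  db <- build_hybrid_database(grouped, catalog, high_conf, contaminants,
                              thresholds = th)

  peptides <- read_tsv(peptides_tsv)
  filtered <- filter_identifications(peptides, th$peptide_q_max)
  mappings <- map_peptides(filtered, db, th$missed_cleavages)
  evidence <- classify_gene_scenarios(mappings, db)
  evidence <- nominate_by_transcript_abundance(evidence, db,
                                               th$nomination_min_cpm)
  refp <- group_reference_proteins(catalog)
  ref_digests <- list(gencode = digest_reference(refp$sequence,
                                                 th$missed_cleavages))
  if (!is.null(uniprot_fasta)) {
    ref_digests$uniprot <- digest_reference(read_fasta(uniprot_fasta, "aa"),
                                            th$missed_cleavages)
  }
  novel <- detect_novel_peptides(mappings, ref_digests,
                                 th$novel_peptide_q_strict)
  novel$event <- vapply(seq_len(nrow(novel)), function(i) {
    lab <- strsplit(novel$entries[i], ";")[[1]][1]
    annotate_novel_event(novel$sequence[i], lab, db, orfs, lr, catalog)
  }, "")
  corr <- tryCatch(rna_protein_correlation(summaries, mappings),
                   error = function(e) NULL)

  report <- build_run_report(lr, summaries, concord, orfs, filt, db, evidence,
                             novel, corr, th)
  run <- structure(list(report = report, catalog = catalog, lr = lr,
                        summaries = summaries, orfs = orfs, filt = filt,
                        grouped = grouped, high_conf = high_conf, db = db,
                        mappings = mappings, evidence = evidence,
                        novel = novel, correlation = corr, thresholds = th),
                   class = "lrp_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

build_run_report <- function(lr, summaries, concord, orfs, filt, db, evidence,
                             novel, corr, th) {
  t <- lr$transcripts
  cls <- table(factor(t$category, c("FSM", "NIC", "NNC", "OTHER")))
  n_tx <- nrow(t)
  n_novel_tx <- sum(t$category %in% c("NIC", "NNC"))
  scen <- table(factor(evidence$scenario,
                       c("SINGLE_ISOFORM_IN_DB", "SHARED_ONLY",
                         "ONE_CONFIRMED", "MULTI_CONFIRMED")))
  src <- table(factor(db$entries$source, c("PACBIO", "GENCODE", "CONTAMINANT")))
  report <- list(
    transcripts = list(
      n = n_tx, by_class = as.list(cls),
      n_novel = n_novel_tx,
      pct_fsm = if (n_tx) pct_round(cls[["FSM"]], n_tx) else NA,
      pct_novel = if (n_tx) pct_round(n_novel_tx, n_tx) else NA,
      pct_nic_of_novel = if (n_novel_tx) pct_round(cls[["NIC"]], n_novel_tx) else NA,
      pct_nnc_of_novel = if (n_novel_tx) pct_round(cls[["NNC"]], n_novel_tx) else NA),
    genes = list(
      n = nrow(summaries),
      n_multi_isoform = sum(summaries$n_isoforms >= 2),
      pct_multi_isoform = pct_round(sum(summaries$n_isoforms >= 2),
                                    nrow(summaries)),
      n_single_isoform = sum(summaries$n_isoforms == 1)),
    major_vs_principal = list(
      n_genes = concord$n_genes, n_mismatch = concord$n_mismatch,
      fraction = concord$fraction,
      pct = if (concord$n_genes) pct_round(concord$n_mismatch,
                                           concord$n_genes) else NA),
    orf_filter = list(
      n_input = nrow(filt$ledger),
      n_retained = sum(is.na(filt$ledger$reason)),
      removed = as.list(table(filt$ledger$reason))),
    database = list(
      entries_by_source = as.list(src),
      genes_pacbio = sum(db$gene_source == "PACBIO"),
      genes_gencode = sum(db$gene_source == "GENCODE"),
      genes_total = length(db$gene_source),
      total_excl_contaminants = sum(src) - src[["CONTAMINANT"]],
      total_incl_contaminants = sum(src)),
    evidence = list(
      n_evidenced_genes = nrow(evidence),
      by_scenario = as.list(scen),
      n_unique_evidence = sum(evidence$scenario %in%
                                c("SINGLE_ISOFORM_IN_DB", "ONE_CONFIRMED",
                                  "MULTI_CONFIRMED")),
      nominations = as.list(table(factor(evidence$nomination,
                                         c("NONE", "NOMINATED_AMBIGUOUS",
                                           "NOMINATED_ADDITIONAL")))),
      n_coexpression_nominated = sum(evidence$coexpression_nominated)),
    novel_peptides = list(
      n = nrow(novel),
      by_event = if (nrow(novel)) as.list(table(novel$event)) else list()),
    correlation = if (!is.null(corr))
      list(r_squared = corr$r_squared, n = corr$n, slope = corr$slope)
    else NULL,
    thresholds = th)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Long-read proteogenomics run report\n")
  cat(sprintf("  Transcripts: %d (FSM %d, NIC %d, NNC %d, OTHER %d); %d%% novel\n",
              x$transcripts$n, x$transcripts$by_class$FSM,
              x$transcripts$by_class$NIC, x$transcripts$by_class$NNC,
              x$transcripts$by_class$OTHER, x$transcripts$pct_novel))
  cat(sprintf("  Genes: %d (%d%% multi-isoform); major != principal for %s%% of multi-isoform genes\n",
              x$genes$n, x$genes$pct_multi_isoform,
              x$major_vs_principal$pct))
  cat(sprintf("  ORF filter: %d -> %d retained (%s)\n",
              x$orf_filter$n_input, x$orf_filter$n_retained,
              paste(names(x$orf_filter$removed), unlist(x$orf_filter$removed),
                    sep = ": ", collapse = ", ")))
  cat(sprintf("  Database: PacBio %d, GENCODE %d, contaminants %d entries; %d/%d PacBio-sourced genes\n",
              x$database$entries_by_source$PACBIO,
              x$database$entries_by_source$GENCODE,
              x$database$entries_by_source$CONTAMINANT,
              x$database$genes_pacbio, x$database$genes_total))
  cat(sprintf("  Evidence: %d genes (%s)\n", x$evidence$n_evidenced_genes,
              paste(names(x$evidence$by_scenario),
                    unlist(x$evidence$by_scenario), sep = ": ",
                    collapse = ", ")))
  cat(sprintf("  Novel peptides: %d\n", x$novel_peptides$n))
  if (!is.null(x$correlation)) {
    cat(sprintf("  RNA-protein correlation: R^2 = %.3f over %d genes\n",
                x$correlation$r_squared, x$correlation$n))
  }
  invisible(x)
}

#' @export
print.lrp_run <- function(x, ...) print(x$report)

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(run$lr$transcripts, file.path(out_dir, "transcript_classification.tsv"))
  write_tsv(run$summaries, file.path(out_dir, "gene_summary.tsv"))
  write_tsv(run$orfs, file.path(out_dir, "orf_table.tsv"))
  write_tsv(run$filt$ledger, file.path(out_dir, "removal_ledger.tsv"))
  write_protein_fasta(run$db, file.path(out_dir, "hybrid_database.fa"))
  write_tsv(data.frame(gene_id = names(run$db$gene_source),
                       source = unname(run$db$gene_source)),
            file.path(out_dir, "gene_source_map.tsv"))
  write_browser_tracks(run$lr, file.path(out_dir, "transcripts.bed12"))
  write_tsv(run$mappings, file.path(out_dir, "peptide_mappings.tsv"))
  write_tsv(run$evidence, file.path(out_dir, "gene_evidence.tsv"))
  write_tsv(run$novel, file.path(out_dir, "novel_peptides.tsv"))
  if (!is.null(run$correlation)) {
    write_tsv(run$correlation$table, file.path(out_dir, "rna_protein_pairs.tsv"))
  }
  render_report(run$report, file.path(out_dir, "run_report"))
  invisible(out_dir)
}

#' Render a run report to disk
#'
#' Writes a human-readable text summary (`<path>.txt`), a flat TSV of counts
#' (`<path>.tsv`), and, when jsonlite is installed, a JSON rendering
#' (`<path>.json`). Percentages use nearest-integer rounding (half away from
#' zero); raw fractions are kept alongside.
#'
#' @param report a `run_report`.
#' @param path output path stem.
#' @export
render_report <- function(report, path) {
  txt <- utils::capture.output(print(report))
  writeLines(txt, paste0(path, ".txt"))
  flat <- unlist(report[setdiff(names(report), "thresholds")])
  write_tsv(data.frame(key = names(flat), value = as.character(flat)),
            paste0(path, ".tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  }
  invisible(path)
}
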