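# Hybrid protein database construction: filter predicted proteins, group
# identical sequences with summed CPM, pick the per-gene source (PacBio for
# high-confidence genes, reference elsewhere), and emit the search FASTA.

#' Filter predicted protein isoforms
#'
#' Removal rules, applied in order with the first matching reason recorded:
#' (1) ORFs without a stop codon (possible truncations); (2) protein class
#' outside pFSM/pNIC/pNNC; (3) pNNC isoforms with more than
#' `nmd_max_junctions` junctions after the stop codon (NMD suspects — the
#' NMD rule is scoped to novel-splice-site isoforms only, so pFSM/pNIC are
#' exempt).
#'
#' @param orfs classified best-ORF table (see [classify_proteins()]).
#' @param nmd_max_junctions maximum allowed junctions after the stop codon
#'   for pNNC isoforms (default 2; more than two is removed).
#' @return list(retained, ledger) where ledger has pb_accession and reason
#'   in {truncation, class, NMD}.
#' @export
filter_protein_isoforms <- function(orfs, nmd_max_junctions = 2) {
  reason <- rep(NA_character_, nrow(orfs))
  reason[!orfs$has_stop] <- "truncation"
  sel <- is.na(reason) & !(orfs$pclass %in% c("pFSM", "pNIC", "pNNC"))
  reason[sel] <- "class"
  sel <- is.na(reason) & orfs$pclass == "pNNC" &
    orfs$junctions_after_stop > nmd_max_junctions
  reason[sel] <- "NMD"
  list(retained = orfs[is.na(reason), , drop = FALSE],
       ledger = data.frame(pb_accession = orfs$pb_accession, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Group retained ORFs producing identical protein sequences
#'
#' One entry per (gene, protein sequence); the entry's abundance is the sum
#' of member transcript CPMs. The representative accession is the
#' highest-CPM member (ties to the smaller accession numeric suffix) and the
#' entry takes the representative's protein class.
#'
#' @param retained retained ORFs from [filter_protein_isoforms()].
#' @param lr the `lr_transcripts` providing per-transcript CPM.
#' @return data.frame: gene_id, sequence, cpm_sum, representative, pclass,
#'   members (`;`-separated), n_members.
#' @export
group_orfs_by_sequence <- function(retained, lr) {
  if (nrow(retained) == 0L) {
    return(data.frame(gene_id = character(0), sequence = character(0),
                      cpm_sum = numeric(0), representative = character(0),
                      pclass = character(0), members = character(0),
                      n_members = integer(0)))
  }
  cpm <- lr$transcripts[retained$pb_accession, "cpm"]
  key <- paste(retained$gene_id, retained$protein, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(retained)), key), function(ix) {
    m <- retained[ix, , drop = FALSE]
    mc <- cpm[ix]
    o <- order(-mc, pb_suffix(m$pb_accession))
    data.frame(gene_id = m$gene_id[1], sequence = m$protein[1],
               cpm_sum = sum(mc), representative = m$pb_accession[o[1]],
               pclass = m$pclass[o[1]],
               members = paste(m$pb_accession[o], collapse = ";"),
               n_members = nrow(m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Select high-confidence genes for PacBio-sourced database entries
#'
#' A gene qualifies when its aggregated transcript abundance is at least
#' `min_cpm` (default 3 CPM) and the mean annotated reference transcript
#' length lies in `len_window` (default 1--4 kbp, boundaries inclusive).
#'
#' @param summaries output of [summarize_gene_expression()].
#' @param catalog a `ref_catalog` (provides per-gene mean annotated length).
#' @param min_cpm inclusive CPM floor on total gene abundance.
#' @param len_window inclusive \[lower, upper\] window on mean annotated
#'   spliced transcript length, in nt.
#' @return character vector of gene ids.
#' @export
select_high_confidence_genes <- function(summaries, catalog, min_cpm = 3,
                                         len_window = c(1000, 4000)) {
  known <- summaries$gene_id %in% rownames(catalog$genes)
  if (any(!known)) {
    warning("gene(s) absent from catalog excluded: ",
            paste(summaries$gene_id[!known], collapse = ", "))
  }
  s <- summaries[known, , drop = FALSE]
  ml <- catalog$genes[s$gene_id, "mean_len"]
  sort(s$gene_id[s$total_gene_cpm >= min_cpm &
                   ml >= len_window[1] & ml <= len_window[2]])
}

format_cpm <- function(cpm) sprintf("%.1f", cpm)

#' Build the hybrid protein search database
#'
#' High-confidence genes contribute their grouped PacBio-derived entries,
#' labelled `<Gene>|<PB accession>|<SQANTI Protein class>|<CPM>`; every other
#' catalog gene (including genes absent from the long-read data) contributes
#' its grouped reference entries; contaminants are appended verbatim. A
#' high-confidence gene with no surviving PacBio entry falls back to its
#' reference entries so the gene-source map stays total over catalog genes.
#'
#' @param grouped grouped PacBio entries from [group_orfs_by_sequence()].
#' @param catalog a `ref_catalog`.
#' @param high_confidence gene ids from [select_high_confidence_genes()].
#' @param contaminants optional named character vector of contaminant protein
#'   sequences (names become labels, passed through verbatim).
#' @param thresholds list recorded on the object for reporting.
#' @return object of class `hybrid_db`: `entries` (label, gene_id, gene_name,
#'   sequence, source, pclass, cpm_sum, representative, members) and
#'   `gene_source` (named vector over catalog genes).
#' @export
build_hybrid_database <- function(grouped, catalog, high_confidence,
                                  contaminants = NULL, thresholds = list()) {
  gname <- function(gid) catalog$genes[gid, "gene_name"]
  pacbio_genes <- intersect(high_confidence, unique(grouped$gene_id))
  pb <- grouped[grouped$gene_id %in% pacbio_genes, , drop = FALSE]
  pb_entries <- if (nrow(pb)) data.frame(
    label = paste(gname(pb$gene_id), pb$representative, pb$pclass,
                  format_cpm(pb$cpm_sum), sep = "|"),
    gene_id = pb$gene_id, gene_name = gname(pb$gene_id),
    sequence = pb$sequence, source = "PACBIO", pclass = pb$pclass,
    cpm_sum = pb$cpm_sum, representative = pb$representative,
    members = pb$members, stringsAsFactors = FALSE
  ) else NULL

  ref_genes <- setdiff(rownames(catalog$genes), pacbio_genes)
  refp <- group_reference_proteins(catalog)
  refp <- refp[refp$gene_id %in% ref_genes, , drop = FALSE]
  ref_entries <- if (nrow(refp)) data.frame(
    label = paste(refp$gene_name, refp$accession, sep = "|"),
    gene_id = refp$gene_id, gene_name = refp$gene_name,
    sequence = refp$sequence, source = "GENCODE", pclass = NA_character_,
    cpm_sum = NA_real_, representative = refp$accession,
    members = refp$member_transcripts, stringsAsFactors = FALSE
  ) else NULL

  cont_entries <- if (!is.null(contaminants) && length(contaminants)) data.frame(
    label = names(contaminants), gene_id = NA_character_,
    gene_name = NA_character_, sequence = unname(contaminants),
    source = "CONTAMINANT", pclass = NA_character_, cpm_sum = NA_real_,
    representative = NA_character_, members = NA_character_,
    stringsAsFactors = FALSE
  ) else NULL

  entries <- rbind(pb_entries, ref_entries, cont_entries)
  if (anyDuplicated(entries$label)) {
    stop("duplicate database label: ",
         entries$label[duplicated(entries$label)][1])
  }
  rownames(entries) <- entries$label
  gene_source <- stats::setNames(
    ifelse(rownames(catalog$genes) %in% pacbio_genes, "PACBIO", "GENCODE"),
    rownames(catalog$genes))
  structure(list(entries = entries, gene_source = gene_source,
                 thresholds = thresholds), class = "hybrid_db")
}

#' @export
print.hybrid_db <- function(x, ...) {
  tab <- table(x$entries$source)
  cat("Hybrid protein database:", nrow(x$entries), "entries (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ") over",
      length(x$gene_source), "genes;",
      sum(x$gene_source == "PACBIO"), "PacBio-sourced\n")
  invisible(x)
}

#' Write the hybrid database to FASTA
#'
#' Headers are the entry labels (CPM printed with one decimal).
#'
#' @param db a `hybrid_db`.
#' @param path output path.
#' @export
write_protein_fasta <- function(db, path) {
  write_fasta(stats::setNames(db$entries$sequence, db$entries$label), path)
}

#' Write genome-browser tracks for transcript models
#'
#' @param lr an `lr_transcripts` object.
#' @param path BED12 output path.
#' @export
write_browser_tracks <- function(lr, path) {
  write_bed12(lr$exons, path,
              score = stats::setNames(lr$transcripts$cpm,
                                      lr$transcripts$pb_accession))
}
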