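# SQANTI-Protein classification: each predicted protein is compared to the
# gene's annotated coding models on three elements — the N-terminus (start
# codon position), the CDS-internal splice chain, and the C-terminus (stop
# codon position). Any entirely novel element makes the protein pNNC; all
# elements known but combined in an unannotated way makes it pNIC; a full
# match of start + CDS junction chain + stop to one reference coding
# transcript makes it pFSM.

#' Classify one predicted protein against reference protein models
#'
#' @param orf one row of a best-ORF table (see [call_orfs()]).
#' @param exons exon table of the host transcript.
#' @param category the transcript-level class (OTHER transcripts are pOTHER).
#' @param catalog a `ref_catalog`.
#' @return list(category, nterm_status, cterm_status, cds_splice_status,
#'   matched_ref_protein, reason). Statuses are "known", "novel-combination"
#'   or "novel-element".
#' @export
classify_protein <- function(orf, exons, category, catalog) {
  pother <- function(reason) {
    list(category = "pOTHER", nterm_status = NA_character_,
         cterm_status = NA_character_, cds_splice_status = NA_character_,
         matched_ref_protein = NA_character_, reason = reason)
  }
  gid <- orf$gene_id
  if (identical(category, "OTHER") || is.na(gid)) {
    return(pother("transcript classified OTHER"))
  }
  ref_cds <- catalog$gene_cds[[gid]]
  if (is.null(ref_cds) || nrow(ref_cds) == 0L) {
    return(pother("gene has no reference coding transcript"))
  }
  strand <- exons$strand[1]
  minus <- identical(strand, "-")

  nterm <- if (orf$start_genomic %in% catalog$gene_starts[[gid]])
    "known" else "novel-element"
  cterm <- if (orf$has_stop && orf$stop_genomic %in% catalog$gene_stops[[gid]])
    "known" else "novel-element"

  # CDS-internal junctions: transcript junctions strictly inside the ORF
  jx <- tx_junction_offsets(exons)
  intr <- exons_to_introns(exons)
  # tx_junction_offsets and exons_to_introns both order introns; align them
  # in transcript orientation
  if (minus && nrow(intr) > 1L) intr <- intr[rev(seq_len(nrow(intr))), , drop = FALSE]
  inside <- jx > orf$start_nt & jx < orf$stop_nt
  cds_chain <- chain_key(intr$lower[inside], intr$upper[inside])
  don <- intr$donor[inside]; acc <- intr$acceptor[inside]
  splice <- if (any(!(don %in% catalog$gene_cds_donors[[gid]])) ||
                any(!(acc %in% catalog$gene_cds_acceptors[[gid]]))) {
    "novel-element"
  } else if (cds_chain %in% ref_cds$cds_chain) "known" else "novel-combination"

  match_idx <- which(ref_cds$cds_chain == cds_chain &
                       ref_cds$start_pos == orf$start_genomic &
                       !is.na(orf$stop_genomic) &
                       ref_cds$stop_pos == orf$stop_genomic & orf$has_stop)
  statuses <- c(nterm, cterm, splice)
  cat_out <- if (length(match_idx) && all(statuses == "known")) "pFSM"
  else if (any(statuses == "novel-element")) "pNNC"
  else "pNIC"
  matched <- if (cat_out == "pFSM") {
    accs <- ref_cds$protein_accession[match_idx]
    sort(accs)[1]
  } else NA_character_
  list(category = cat_out, nterm_status = nterm, cterm_status = cterm,
       cds_splice_status = splice, matched_ref_protein = matched,
       reason = NA_character_)
}

#' Classify every called protein
#'
#' @param orfs best-ORF table from [call_orfs()].
#' @param lr the classified `lr_transcripts` the ORFs were called on.
#' @param catalog a `ref_catalog`.
#' @return `orfs` with pclass, nterm_status, cterm_status, cds_splice_status
#'   and matched_ref_protein columns added.
#' @export
classify_proteins <- function(orfs, lr, catalog) {
  ex_by_tx <- split(lr$exons, lr$exons$transcript_id)
  res <- lapply(seq_len(nrow(orfs)), function(i) {
    id <- orfs$pb_accession[i]
    classify_protein(orfs[i, ], ex_by_tx[[id]],
                     lr$transcripts[id, "category"], catalog)
  })
  orfs$pclass <- vapply(res, `[[`, "", "category")
  orfs$nterm_status <- vapply(res, `[[`, "", "nterm_status")
  orfs$cterm_status <- vapply(res, `[[`, "", "cterm_status")
  orfs$cds_splice_status <- vapply(res, `[[`, "", "cds_splice_status")
  orfs$matched_ref_protein <- vapply(res, `[[`, "", "matched_ref_protein")
  orfs
}
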