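# Peptide evidence: map externally identified peptides onto the hybrid
# database under tryptic-digest rules, derive per-gene evidence scenarios,
# abundance-based isoform nominations, novel-peptide calls with event
# annotation, and the gene-level RNA-protein correlation.

#' Filter peptide identifications by q-value
#'
#' The reporting tier retains peptides with q <= `q_max` (default 0.01, i.e.
#' 1% FDR, inclusive at the threshold). The novel-peptide tier is stricter
#' and exclusive: q strictly below `q_strict` (see
#' [detect_novel_peptides()]).
#'
#' @param peptides data.frame with sequence, q_value, psm_count.
#' @param q_max inclusive q-value ceiling.
#' @return the retained rows.
#' @export
filter_identifications <- function(peptides, q_max = 0.01) {
  peptides[peptides$q_value <= q_max, , drop = FALSE]
}

#' Tryptic digestion of a protein sequence
#'
#' Cleaves after K or R except when the next residue is P, emitting peptides
#' with up to `missed_cleavages` internal missed sites and lengths within
#' `[min_len, max_len]`.
#'
#' @param seq amino-acid string.
#' @param missed_cleavages maximum internal missed cleavage sites.
#' @param min_len,max_len peptide length bounds (amino acids).
#' @return character vector of distinct peptides.
#' @export
digest_protein <- function(seq, missed_cleavages = 2, min_len = 7, max_len = 50) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  cut <- as.integer(gregexpr("[KR](?!P)", seq, perl = TRUE)[[1]])
  cut <- cut[cut > 0 & cut < n]
  bounds <- c(0L, cut, n)  # fragment i = (bounds[i], bounds[i+1]]
  nf <- length(bounds) - 1L
  peps <- character(0)
  for (i in seq_len(nf)) {
    jmax <- min(nf, i + missed_cleavages)
    for (j in i:jmax) {
      len <- bounds[j + 1L] - bounds[i]
      if (len >= min_len && len <= max_len) {
        peps <- c(peps, substring(seq, bounds[i] + 1L, bounds[j + 1L]))
      }
    }
  }
  unique(peps)
}

#' Digest a set of reference proteins into a peptide universe
#'
#' @param seqs character vector of protein sequences.
#' @param missed_cleavages,min_len,max_len digestion parameters as in
#'   [digest_protein()].
#' @return character vector of distinct peptides across all proteins.
#' @export
digest_reference <- function(seqs, missed_cleavages = 2, min_len = 7,
                             max_len = 50) {
  unique(unlist(lapply(seqs, digest_protein,
                       missed_cleavages = missed_cleavages,
                       min_len = min_len, max_len = max_len),
                use.names = FALSE))
}

# Peptide -> entry index over a hybrid database, under the digestion rule.
build_peptide_index <- function(db, missed_cleavages = 2, min_len = 7,
                                max_len = 50) {
  idx <- new.env(parent = emptyenv(), size = 1024L)
  for (i in seq_len(nrow(db$entries))) {
    peps <- digest_protein(db$entries$sequence[i], missed_cleavages,
                           min_len, max_len)
    for (p in peps) {
      assign(p, c(if (exists(p, idx, inherits = FALSE)) get(p, idx), i), idx)
    }
  }
  idx
}

#' Map identified peptides onto the hybrid database
#'
#' A peptide hits an entry when it occurs in the entry's tryptic digest
#' (digest-legal termini, the same rule as [digest_reference()]); free
#' substring matching is available via `substring_mode`. Uniqueness is
#' evaluated at the isoform level within a gene; peptides hitting entries of
#' more than one gene are flagged `multi_gene` and excluded from isoform
#' evidence downstream.
#'
#' @param peptides filtered identification table (sequence, q_value,
#'   psm_count).
#' @param db a `hybrid_db`.
#' @param missed_cleavages,min_len,max_len digestion parameters.
#' @param substring_mode if TRUE, match peptides as free substrings instead
#'   of digest-legal peptides.
#' @return data.frame per input peptide: sequence, q_value, psm_count,
#'   mapped, n_entries, n_genes, entries, genes, unique_isoform, multi_gene.
#' @export
map_peptides <- function(peptides, db, missed_cleavages = 2, min_len = 7,
                         max_len = 50, substring_mode = FALSE) {
  if (substring_mode) {
    hit_list <- lapply(peptides$sequence, function(p)
      which(grepl(p, db$entries$sequence, fixed = TRUE)))
  } else {
    idx <- build_peptide_index(db, missed_cleavages, min_len, max_len)
    hit_list <- lapply(peptides$sequence, function(p)
      if (exists(p, idx, inherits = FALSE)) get(p, idx) else integer(0))
  }
  rows <- lapply(seq_len(nrow(peptides)), function(k) {
    hits <- hit_list[[k]]
    ent <- db$entries[hits, , drop = FALSE]
    genes <- unique(ent$gene_id[!is.na(ent$gene_id)])
    contaminant_only <- nrow(ent) > 0 && all(ent$source == "CONTAMINANT")
    data.frame(sequence = peptides$sequence[k],
               q_value = peptides$q_value[k],
               psm_count = peptides$psm_count[k],
               mapped = length(hits) > 0L,
               n_entries = length(hits), n_genes = length(genes),
               entries = paste(ent$label, collapse = ";"),
               genes = paste(genes, collapse = ";"),
               unique_isoform = length(genes) == 1L && nrow(ent) == 1L &&
                 !contaminant_only,
               multi_gene = length(genes) > 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify per-gene peptide-evidence scenarios
#'
#' Over genes with any (single-gene) mapped peptide: SINGLE_ISOFORM_IN_DB
#' when the gene has one database entry; otherwise MULTI_CONFIRMED when two
#' or more entries each carry a uniquely mapping peptide; ONE_CONFIRMED when
#' exactly one does; SHARED_ONLY when none does.
#'
#' @param mappings output of [map_peptides()].
#' @param db a `hybrid_db`.
#' @return data.frame: gene_id, scenario, n_entries, n_confirmed,
#'   confirmed_entries.
#' @export
classify_gene_scenarios <- function(mappings, db) {
  m <- mappings[mappings$mapped & !mappings$multi_gene & mappings$n_genes == 1L, ,
                drop = FALSE]
  ev_genes <- sort(unique(m$genes))
  n_entries_by_gene <- table(db$entries$gene_id[!is.na(db$entries$gene_id)])
  out <- do.call(rbind, lapply(ev_genes, function(g) {
    mg <- m[m$genes == g, , drop = FALSE]
    conf <- sort(unique(mg$entries[mg$unique_isoform]))
    ne <- as.integer(n_entries_by_gene[g])
    scen <- if (!is.na(ne) && ne == 1L) "SINGLE_ISOFORM_IN_DB"
    else if (length(conf) >= 2L) "MULTI_CONFIRMED"
    else if (length(conf) == 1L) "ONE_CONFIRMED"
    else "SHARED_ONLY"
    data.frame(gene_id = g, scenario = scen, n_entries = ne,
               n_confirmed = length(conf),
               confirmed_entries = paste(conf, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$gene_id
  out
}

#' Nominate isoforms from transcript abundance
#'
#' SHARED_ONLY genes with at least one PacBio entry at `cpm_min` or higher
#' become NOMINATED_AMBIGUOUS (with a co-expression flag when two or more
#' entries qualify); ONE_CONFIRMED genes with at least one unconfirmed
#' PacBio entry at `cpm_min` or higher become NOMINATED_ADDITIONAL. Genes
#' with only reference-sourced entries carry no abundance and stay NONE.
#'
#' @param evidence output of [classify_gene_scenarios()].
#' @param db a `hybrid_db`.
#' @param cpm_min inclusive CPM floor for nomination (default 25).
#' @return `evidence` with nomination, nominated_entries and
#'   coexpression_nominated columns added.
#' @export
nominate_by_transcript_abundance <- function(evidence, db, cpm_min = 25) {
  ent <- db$entries
  evidence$nomination <- "NONE"
  evidence$nominated_entries <- ""
  evidence$coexpression_nominated <- FALSE
  for (i in seq_len(nrow(evidence))) {
    g <- evidence$gene_id[i]
    pac <- ent[!is.na(ent$gene_id) & ent$gene_id == g & ent$source == "PACBIO", ,
               drop = FALSE]
    if (nrow(pac) == 0L) next
    if (evidence$scenario[i] == "SHARED_ONLY") {
      nom <- pac$label[pac$cpm_sum >= cpm_min]
      if (length(nom)) {
        evidence$nomination[i] <- "NOMINATED_AMBIGUOUS"
        evidence$nominated_entries[i] <- paste(sort(nom), collapse = ";")
        evidence$coexpression_nominated[i] <- length(nom) >= 2L
      }
    } else if (evidence$scenario[i] == "ONE_CONFIRMED") {
      conf <- strsplit(evidence$confirmed_entries[i], ";", fixed = TRUE)[[1]]
      cand <- pac[!(pac$label %in% conf), , drop = FALSE]
      nom <- cand$label[cand$cpm_sum >= cpm_min]
      if (length(nom)) {
        evidence$nomination[i] <- "NOMINATED_ADDITIONAL"
        evidence$nominated_entries[i] <- paste(sort(nom), collapse = ";")
      }
    }
  }
  evidence
}

#' Detect novel peptides
#'
#' A peptide is novel when it passes the strict q-value tier (q strictly
#' below `q_strict`), maps to at least one sample-database entry, and is
#' absent — as an exact sequence, or up to I/L equivalence when
#' `il_equivalent` — from both reference peptide digests.
#'
#' @param mappings output of [map_peptides()] (unfiltered or 1%-FDR
#'   filtered; the strict tier is applied here).
#' @param reference_digests list of character vectors (e.g. GENCODE-style
#'   and UniProt-style digests from [digest_reference()]).
#' @param q_strict exclusive q-value ceiling (default 0.001).
#' @param il_equivalent treat isoleucine and leucine as identical in the
#'   novelty comparison.
#' @return data.frame of novel peptides: sequence, q_value, psm_count,
#'   entries.
#' @export
detect_novel_peptides <- function(mappings, reference_digests,
                                  q_strict = 0.001, il_equivalent = FALSE) {
  cand <- mappings[mappings$q_value < q_strict & mappings$mapped, , drop = FALSE]
  norm <- function(x) if (il_equivalent) gsub("I", "L", x, fixed = TRUE) else x
  refs <- unique(norm(unlist(reference_digests, use.names = FALSE)))
  novel <- !(norm(cand$sequence) %in% refs)
  out <- cand[novel, c("sequence", "q_value", "psm_count", "entries"),
              drop = FALSE]
  rownames(out) <- NULL
  out
}

# Frame phases (offset mod 3 within the CDS) of genomic base g across a
# gene's reference coding transcripts whose CDS covers g.
ref_cds_phases <- function(gid, g, catalog) {
  cod <- catalog$transcripts[catalog$transcripts$gene_id == gid &
                               catalog$transcripts$coding, , drop = FALSE]
  phases <- integer(0)
  for (id in cod$transcript_id) {
    trow <- cod[cod$transcript_id == id, ]
    cmin <- min(trow$start_pos, trow$stop_pos)
    cmax <- max(trow$start_pos, trow$stop_pos) + 1L
    if (g < cmin || g >= cmax) next
    e <- catalog$exons[catalog$exons$transcript_id == id, , drop = FALSE]
    e$start <- pmax(e$start, cmin); e$end <- pmin(e$end, cmax)
    e <- e[e$start < e$end, , drop = FALSE]
    e <- order_tx(e)
    w <- e$end - e$start
    inex <- which(g >= e$start & g < e$end)
    if (!length(inex)) next
    off_in <- if (identical(e$strand[1], "-")) e$end[inex] - 1L - g else g - e$start[inex]
    off <- sum(w[seq_len(inex - 1L)]) + off_in
    phases <- c(phases, off %% 3L)
  }
  phases
}

#' Annotate the splicing/transcription event supported by a novel peptide
#'
#' The peptide is located on its entry's representative protein, projected
#' to genomic intervals through the transcript's exon chain, and labelled by
#' overlap with catalog features: wholly within unannotated intronic
#' sequence contiguous with annotated exons -> `intron_retention`; within
#' exonic sequence absent from all reference exons -> `novel_exon`; spanning
#' a junction with an unannotated acceptor or donor -> `novel_acceptor` /
#' `novel_donor`; within annotated exons but out of frame with every
#' reference CDS -> `frameshift`; anything else -> `other`.
#'
#' @param peptide peptide sequence.
#' @param entry_label database entry label the peptide maps to.
#' @param db a `hybrid_db`.
#' @param orfs best-ORF table used to build the database.
#' @param lr the `lr_transcripts` object.
#' @param catalog a `ref_catalog`.
#' @return event label string.
#' @export
annotate_novel_event <- function(peptide, entry_label, db, orfs, lr, catalog) {
  ent <- db$entries[entry_label, ]
  if (is.na(ent$label) || ent$source != "PACBIO") {
    warning("entry ", entry_label, " is not a PacBio-derived entry")
    return("other")
  }
  pb <- ent$representative
  orf <- orfs[pb, ]
  aa_off <- regexpr(peptide, orf$protein, fixed = TRUE)[1]
  if (aa_off < 0) {
    warning("peptide not found on protein of ", pb)
    return("other")
  }
  exons <- lr$exons[lr$exons$transcript_id == pb, , drop = FALSE]
  nt0 <- orf$start_nt + 3L * (aa_off - 1L)
  nt1 <- nt0 + 3L * nchar(peptide)  # exclusive
  gpos <- tx_to_genomic(exons, nt0:(nt1 - 1L))
  gid <- orf$gene_id
  chrom <- exons$chrom[1]; strand <- exons$strand[1]

  ref_ex <- catalog$exons[catalog$exons$gene_id == gid, , drop = FALSE]
  in_ref_exon <- vapply(gpos, function(g)
    any(g >= ref_ex$start & g < ref_ex$end), TRUE)
  gene_lo <- min(ref_ex$start); gene_hi <- max(ref_ex$end)
  in_gene <- gpos >= gene_lo & gpos < gene_hi

  if (any(!in_ref_exon)) {
    # unannotated (intronic or flanking) sequence: retained intron when the
    # host exon also overlaps annotated exons; novel exon when it does not
    e <- order_tx(exons)
    host <- unique(unlist(lapply(gpos[!in_ref_exon], function(g)
      which(g >= e$start & g < e$end))))
    host_overlaps_ref <- vapply(host, function(k)
      any(pmin(e$end[k], ref_ex$end) > pmax(e$start[k], ref_ex$start)), TRUE)
    return(if (any(host_overlaps_ref) && all(in_gene)) "intron_retention"
           else "novel_exon")
  }

  jx <- tx_junction_offsets(exons)
  intr <- exons_to_introns(exons)
  if (identical(strand, "-") && nrow(intr) > 1L)
    intr <- intr[rev(seq_len(nrow(intr))), , drop = FALSE]
  spanned <- which(jx > nt0 & jx < nt1)
  for (k in spanned) {
    if (!site_known(catalog$acceptors, chrom, strand, intr$acceptor[k]))
      return("novel_acceptor")
    if (!site_known(catalog$donors, chrom, strand, intr$donor[k]))
      return("novel_donor")
  }

  # annotated exons, annotated sites: check reading-frame agreement
  phase_sample <- (nt0 - orf$start_nt) %% 3L
  ref_ph <- ref_cds_phases(gid, gpos[1], catalog)
  if (length(ref_ph) && !(phase_sample %in% ref_ph)) return("frameshift")
  "other"
}

#' Gene-level RNA-protein abundance correlation
#'
#' Ordinary least squares of log10(PSM + 1) on log10(CPM + 1) across genes
#' present in both datasets; PSM counts are summed over single-gene mapped
#' peptides passing the reporting FDR tier.
#'
#' @param summaries output of [summarize_gene_expression()] (or any table
#'   with gene_id and total_gene_cpm).
#' @param mappings output of [map_peptides()] (1%-FDR filtered).
#' @return list(r_squared, n, slope, se_slope, intercept, table, fit).
#' @export
rna_protein_correlation <- function(summaries, mappings) {
  m <- mappings[mappings$mapped & !mappings$multi_gene & mappings$n_genes == 1L, ,
                drop = FALSE]
  psm <- tapply(m$psm_count, m$genes, sum)
  genes <- intersect(names(psm), summaries$gene_id)
  if (length(genes) < 3L) stop("insufficient pairs: need >= 3 genes in both datasets")
  tab <- data.frame(gene_id = genes,
                    cpm = summaries$total_gene_cpm[match(genes, summaries$gene_id)],
                    psm = as.numeric(psm[genes]))
  fit <- stats::lm(log10(psm + 1) ~ log10(cpm + 1), data = tab)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (stats::var(log10(tab$psm + 1)) == 0) r2 <- 0  # flat response: no signal
  list(r_squared = r2, n = nrow(tab),
       slope = unname(stats::coef(fit)[2]),
       se_slope = sm$coefficients[2, 2],
       intercept = unname(stats::coef(fit)[1]),
       table = tab, fit = fit)
}
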