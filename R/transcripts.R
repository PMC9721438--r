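# Long-read transcript catalog: ingest observed transcript models and
# full-length read counts, compute CPM, classify against the reference
# (FSM / NIC / NNC / OTHER), and summarize per-gene expression.

#' Full-length read counts per million
#'
#' CPM for a transcript is its full-length read count divided by the total
#' number of full-length reads, times 1e6. The denominator is the total over
#' the supplied counts, so CPM values always sum to 1e6.
#'
#' @param fl_counts numeric vector of per-transcript full-length read counts.
#' @return numeric vector of CPM values (names preserved).
#' @export
compute_cpm <- function(fl_counts) {
  if (any(fl_counts < 0)) stop("negative full-length read count")
  total <- sum(fl_counts)
  if (total == 0) stop("empty dataset: total full-length read count is zero")
  fl_counts / total * 1e6
}

#' Keep transcripts at or above a minimum abundance
#'
#' @param transcripts data.frame with a `cpm` column.
#' @param min_cpm inclusive CPM floor (default 1, i.e. a minimum abundance of
#'   one full-length read count per million).
#' @return the retained rows.
#' @export
filter_min_abundance <- function(transcripts, min_cpm = 1) {
  transcripts[transcripts$cpm >= min_cpm, , drop = FALSE]
}

#' Read long-read transcript models and counts
#'
#' Loads a GTF of observed exon chains (transcript_id = PB accession) and a
#' counts TSV (`pb_accession`, `fl_count`), computes CPM over the loaded
#' models, assigns each transcript to the reference gene with the largest
#' same-strand exonic overlap (ties to the gene sharing more splice sites),
#' and extracts spliced sequences from the genome.
#'
#' @param gtf_path long-read transcript models (exon features).
#' @param counts_path TSV with pb_accession and fl_count columns.
#' @param catalog a `ref_catalog` (provides gene models and genome).
#' @return list of class `lr_transcripts`: `transcripts` data.frame (with
#'   pb_accession, gene_id, chrom, strand, n_exons, chain, fl_count, cpm,
#'   spliced_len), `exons`, and `seqs` (named spliced sequences).
#' @export
read_longread_models <- function(gtf_path, counts_path, catalog) {
  feats <- read_gtf(gtf_path)
  exons <- feats[feats$type == "exon", , drop = FALSE]
  exons$transcript_id <- exons$transcript_id
  counts <- read_tsv(counts_path)
  stopifnot(all(c("pb_accession", "fl_count") %in% names(counts)))
  cpm <- compute_cpm(stats::setNames(counts$fl_count, counts$pb_accession))

  ex_by_tx <- split(exons, exons$transcript_id)
  ids <- names(ex_by_tx)
  gene_ids <- assign_genes(ex_by_tx, catalog)
  seqs <- vapply(ids, function(id) spliced_sequence(ex_by_tx[[id]], catalog$genome), "")

  tx <- do.call(rbind, lapply(ids, function(id) {
    e <- ex_by_tx[[id]]
    intr <- exons_to_introns(e)
    data.frame(pb_accession = id, gene_id = gene_ids[[id]],
               chrom = e$chrom[1], strand = e$strand[1], n_exons = nrow(e),
               chain = chain_key(intr$lower, intr$upper),
               fl_count = counts$fl_count[match(id, counts$pb_accession)],
               cpm = unname(cpm[id]),
               spliced_len = sum(e$end - e$start), stringsAsFactors = FALSE)
  }))
  if (any(is.na(tx$fl_count))) {
    stop("transcript(s) missing from counts table: ",
         paste(tx$pb_accession[is.na(tx$fl_count)][1:3], collapse = ", "))
  }
  rownames(tx) <- tx$pb_accession
  structure(list(transcripts = tx, exons = exons, seqs = seqs),
            class = "lr_transcripts")
}

# Reference gene with the largest same-strand exonic overlap; ties broken by
# the number of shared splice sites, then gene id.
assign_genes <- function(ex_by_tx, catalog) {
  re <- catalog$exons
  ref_gr <- GenomicRanges::GRanges(re$chrom,
                                   IRanges::IRanges(re$start + 1L, re$end),
                                   strand = re$strand)
  out <- lapply(ex_by_tx, function(e) {
    q <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start + 1L, e$end),
                                strand = e$strand)
    hits <- GenomicRanges::findOverlaps(q, ref_gr)
    if (length(hits) == 0L) return(NA_character_)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      q[S4Vectors::queryHits(hits)], ref_gr[S4Vectors::subjectHits(hits)]))
    gene <- re$gene_id[S4Vectors::subjectHits(hits)]
    tot <- tapply(ov, gene, sum)
    best <- names(tot)[tot == max(tot)]
    if (length(best) > 1L) {
      intr <- exons_to_introns(e)
      sites <- c(intr$donor, intr$acceptor)
      shared <- vapply(best, function(g) {
        gintr <- do.call(rbind, lapply(
          split(re[re$gene_id == g, ], re$transcript_id[re$gene_id == g]),
          exons_to_introns))
        sum(sites %in% c(gintr$donor, gintr$acceptor))
      }, 0)
      best <- best[order(-shared, best)]
    }
    best[1]
  })
  out
}

#' Classify a long-read transcript against the reference
#'
#' Decision order for multi-exonic transcripts: any donor or acceptor absent
#' from the catalog's per-(chrom, strand) site sets makes the transcript NNC;
#' otherwise an exact ordered junction-chain match to a reference transcript
#' makes it FSM; otherwise NIC (a novel combination of known sites).
#' Mono-exonic transcripts are FSM when fully contained within a mono-exonic
#' reference transcript of the same gene and OTHER otherwise; transcripts
#' overlapping no reference gene are OTHER ("intergenic").
#'
#' @param exons exon table of one transcript (0-based half-open).
#' @param gene_id assigned reference gene (NA for intergenic).
#' @param catalog a `ref_catalog`.
#' @return list(category, matched_ref, novel_sites, reason).
#' @export
classify_transcript <- function(exons, gene_id, catalog) {
  if (is.na(gene_id) || !(gene_id %in% rownames(catalog$genes))) {
    return(list(category = "OTHER", matched_ref = NA_character_,
                novel_sites = integer(0), reason = "intergenic"))
  }
  e <- exons
  chrom <- e$chrom[1]; strand <- e$strand[1]
  if (nrow(e) == 1L) {
    rt <- catalog$transcripts
    mono <- rt[rt$gene_id == gene_id & rt$n_exons == 1L, , drop = FALSE]
    contained <- FALSE; match_id <- NA_character_
    for (id in mono$transcript_id) {
      me <- catalog$exons[catalog$exons$transcript_id == id, ]
      if (e$start >= me$start && e$end <= me$end) { contained <- TRUE; match_id <- id; break }
    }
    return(if (contained)
      list(category = "FSM", matched_ref = match_id, novel_sites = integer(0),
           reason = NA_character_)
    else
      list(category = "OTHER", matched_ref = NA_character_,
           novel_sites = integer(0), reason = "mono-exonic unmatched"))
  }
  intr <- exons_to_introns(e)
  novel <- c(intr$donor[!site_known(catalog$donors, chrom, strand, intr$donor)],
             intr$acceptor[!site_known(catalog$acceptors, chrom, strand, intr$acceptor)])
  if (length(novel)) {
    return(list(category = "NNC", matched_ref = NA_character_,
                novel_sites = sort(unique(novel)), reason = NA_character_))
  }
  ch <- chain_key(intr$lower, intr$upper)
  chains <- catalog$gene_chains[[gene_id]]
  hit <- names(chains)[chains == ch]
  if (length(hit)) {
    return(list(category = "FSM", matched_ref = sort(hit)[1],
                novel_sites = integer(0), reason = NA_character_))
  }
  list(category = "NIC", matched_ref = NA_character_, novel_sites = integer(0),
       reason = NA_character_)
}

#' Classify every transcript in a long-read catalog
#'
#' @param lr an `lr_transcripts` object.
#' @param catalog a `ref_catalog`.
#' @return `lr` with `category`, `matched_ref` and `novel_sites` columns added.
#' @export
classify_transcripts <- function(lr, catalog) {
  ex_by_tx <- split(lr$exons, lr$exons$transcript_id)
  res <- lapply(lr$transcripts$pb_accession, function(id) {
    classify_transcript(ex_by_tx[[id]], lr$transcripts[id, "gene_id"], catalog)
  })
  lr$transcripts$category <- vapply(res, `[[`, "", "category")
  lr$transcripts$matched_ref <- vapply(res, `[[`, "", "matched_ref")
  lr$transcripts$novel_sites <- vapply(res, function(r)
    paste(r$novel_sites, collapse = ";"), "")
  lr
}

#' Per-gene expression summary with major/minor isoform calls
#'
#' The major isoform is the most abundant by CPM (ties: larger full-length
#' read count, then smaller PB accession numeric suffix); all others are
#' minor. `major_matches_principal` is TRUE when the major isoform is an FSM
#' whose matched reference transcript carries the APPRIS principal flag.
#'
#' @param lr a classified `lr_transcripts`.
#' @param catalog a `ref_catalog`.
#' @return data.frame, one row per gene with >= 1 assigned transcript.
#' @export
summarize_gene_expression <- function(lr, catalog) {
  t <- lr$transcripts
  t <- t[!is.na(t$gene_id), , drop = FALSE]
  out <- do.call(rbind, lapply(split(t, t$gene_id), function(g) {
    o <- order(-g$cpm, -g$fl_count, pb_suffix(g$pb_accession))
    g <- g[o, , drop = FALSE]
    principal <- catalog$transcripts$transcript_id[
      catalog$transcripts$gene_id == g$gene_id[1] & catalog$transcripts$is_principal]
    principal <- if (length(principal)) principal[1] else NA_character_
    data.frame(gene_id = g$gene_id[1], n_isoforms = nrow(g),
               major_isoform = g$pb_accession[1], major_cpm = g$cpm[1],
               minor_isoforms = paste(g$pb_accession[-1], collapse = ";"),
               total_gene_cpm = sum(g$cpm),
               principal_transcript = principal,
               major_matches_principal = identical(g$category[1], "FSM") &&
                 !is.na(principal) && identical(g$matched_ref[1], principal),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$gene_id
  out
}

#' Fraction of multi-isoform genes whose major isoform is not the principal
#'
#' Genes expressing a single isoform are excluded from the denominator.
#'
#' @param summaries output of [summarize_gene_expression()].
#' @param min_isoforms minimum isoform count for inclusion (default 2).
#' @return list(n_genes, n_mismatch, fraction).
#' @export
major_principal_concordance <- function(summaries, min_isoforms = 2) {
  s <- summaries[summaries$n_isoforms >= min_isoforms, , drop = FALSE]
  n <- nrow(s)
  mism <- sum(!s$major_matches_principal)
  list(n_genes = n, n_mismatch = mism,
       fraction = if (n > 0) mism / n else NA_real_)
}

#' Genes co-expressing multiple isoforms above an abundance floor
#'
#' A gene qualifies when at least `min_isoforms` of its isoforms each reach
#' `min_cpm` (default: two or more isoforms at three or more CPM).
#'
#' @param lr a classified `lr_transcripts`.
#' @param min_isoforms,min_cpm inclusive thresholds.
#' @return character vector of gene ids.
#' @export
coexpressed_isoform_genes <- function(lr, min_isoforms = 2, min_cpm = 3) {
  t <- lr$transcripts[!is.na(lr$transcripts$gene_id), , drop = FALSE]
  n_ok <- tapply(t$cpm >= min_cpm, t$gene_id, sum)
  sort(names(n_ok)[n_ok >= min_isoforms])
}

#' Rank a curated gene set by total transcript abundance
#'
#' @param summaries output of [summarize_gene_expression()].
#' @param gene_list gene ids (or names) of interest, e.g. annotated splice
#'   factors or endothelial genes.
#' @param catalog optional `ref_catalog` for resolving gene names to ids.
#' @return data.frame (gene_id, total_gene_cpm) sorted by CPM descending,
#'   ties by gene id; genes with no detected transcripts are omitted.
#' @export
rank_gene_set_by_abundance <- function(summaries, gene_list, catalog = NULL) {
  ids <- gene_list
  if (!is.null(catalog)) {
    byname <- catalog$genes$gene_id[match(gene_list, catalog$genes$gene_name)]
    ids <- ifelse(gene_list %in% summaries$gene_id, gene_list,
                  ifelse(is.na(byname), gene_list, byname))
  }
  s <- summaries[summaries$gene_id %in% ids, c("gene_id", "total_gene_cpm")]
  s <- s[order(-s$total_gene_cpm, s$gene_id), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Protein length deltas of novel isoforms versus a comparator
#'
#' For each novel (NIC/NNC) isoform with a called protein, the delta is the
#' novel protein length minus the comparator protein length, where the
#' comparator is the gene's APPRIS principal protein or, alternatively, the
#' protein of the sample's major isoform. Shortenings (negative deltas) and
#' gains (positive deltas) are summarized separately.
#'
#' @param orfs best-ORF table (see [call_orfs()]) joined with categories.
#' @param lr a classified `lr_transcripts`.
#' @param catalog a `ref_catalog`.
#' @param comparator `"principal"` or `"major"`.
#' @param summaries required when comparator = "major".
#' @return list(deltas, median_shortening, mean_gain, n).
#' @export
length_deltas_vs_reference <- function(orfs, lr, catalog,
                                       comparator = c("principal", "major"),
                                       summaries = NULL) {
  comparator <- match.arg(comparator)
  t <- lr$transcripts
  novel <- orfs[orfs$pb_accession %in% t$pb_accession[t$category %in% c("NIC", "NNC")], ,
                drop = FALSE]
  deltas <- numeric(0); pbs <- character(0)
  for (i in seq_len(nrow(novel))) {
    gid <- novel$gene_id[i]
    comp_len <- NA_real_
    if (comparator == "principal") {
      pt <- catalog$transcripts[catalog$transcripts$gene_id == gid &
                                  catalog$transcripts$is_principal, , drop = FALSE]
      if (nrow(pt) && pt$coding[1]) comp_len <- nchar(pt$protein[1])
    } else {
      stopifnot(!is.null(summaries))
      mj <- summaries[summaries$gene_id == gid, "major_isoform"]
      comp <- orfs[orfs$pb_accession == mj, , drop = FALSE]
      if (nrow(comp)) comp_len <- nchar(comp$protein[1])
    }
    if (is.na(comp_len)) {
      warning("gene ", gid, " lacks a ", comparator, " protein; isoform ",
              novel$pb_accession[i], " skipped")
      next
    }
    deltas <- c(deltas, nchar(novel$protein[i]) - comp_len)
    pbs <- c(pbs, novel$pb_accession[i])
  }
  neg <- deltas[deltas < 0]; pos <- deltas[deltas > 0]
  list(deltas = data.frame(pb_accession = pbs, delta_aa = deltas),
       median_shortening = if (length(neg)) stats::median(-neg) else NA_real_,
       mean_gain = if (length(pos)) mean(pos) else NA_real_,
       n = length(deltas))
}

#' @export
print.lr_transcripts <- function(x, ...) {
  t <- x$transcripts
  cat("Long-read transcript catalog:", nrow(t), "transcripts")
  if ("category" %in% names(t)) {
    tab <- table(t$category)
    cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}
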