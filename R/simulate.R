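# Ground-truthed synthetic data: a toy genome with multi-isoform gene models,
# long-read transcript models carrying labelled novelty events (exon skip,
# novel combination, intron retention, acceptor/donor shifts in frame-
# preserving and frame-shifting variants, novel exons), abundances with
# planted CPM levels, and peptide identifications with known uniqueness,
# novelty and q-value structure. Every label is fixed at construction time so
# downstream recovery can be audited exactly.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: a library of
#' 3,608,972 full-length reads, lognormal-style abundance spread with planted
#' low (3--20 CPM) and moderate-to-high (30--2,000 CPM) novel-isoform levels
#' that stay clear of the 1, 3 and 25 CPM decision boundaries, and peptide
#' detectability increasing with transcript abundance on a log-log scale.
#'
#' @param seed integer seed; fully determines all generator output.
#' @param n_genes number of genes (>= 4).
#' @param frac_three_isoform fraction of full-architecture genes annotated
#'   with three reference isoforms (rest have two).
#' @param dup_frac fraction of genes given a UTR-only isoform duplicating the
#'   principal protein (exercises reference protein grouping).
#' @param frac_short_genes fraction of genes built short (mean annotated
#'   length < 1 kb, outside the hybrid high-confidence window).
#' @param low_expr_gene_frac fraction of genes planted below 3 CPM total.
#' @param novelty_rates per-gene probabilities for each novelty event.
#' @param frameshift_frac fraction of acceptor/donor shifts that break frame
#'   (shift of 8 nt rather than 9).
#' @param novel_low_frac fraction of novel transcripts planted at low
#'   (3--20 CPM) rather than moderate-to-high abundance.
#' @param sub_cpm_frac fraction of novel transcripts planted below 1 CPM
#'   (removed by the abundance filter).
#' @param major_mismatch_rate fraction of multi-isoform genes whose major
#'   isoform is planted on a non-principal reference transcript.
#' @param library_size total full-length read count.
#' @param intergenic_count mono-exonic intergenic transcripts (class OTHER).
#' @param scenario_probs plan probabilities for SHARED_ONLY / ONE_CONFIRMED /
#'   MULTI_CONFIRMED among multi-entry genes with peptide emission.
#' @param evidenced_frac fraction of database genes emitting any peptide.
#' @param shared_per_gene shared peptides emitted per evidenced gene.
#' @param novel_peptide_count novel peptides injected at the strict q tier.
#' @param decoy_count peptide rows planted above the 1% FDR threshold.
#' @param unmapped_count low-q peptide rows mapping to no database entry.
#' @param psm_intercept,psm_slope,psm_sigma log10 PSM ~ log10(CPM + 1) model.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 30, frac_three_isoform = 0.5,
                       dup_frac = 0.3, frac_short_genes = 0.15,
                       low_expr_gene_frac = 0.08,
                       novelty_rates = list(exon_skip = 0.5,
                                            novel_combination = 0.5,
                                            intron_retention = 0.35,
                                            novel_acceptor = 0.35,
                                            novel_donor = 0.3,
                                            novel_exon = 0.3),
                       frameshift_frac = 0.4, novel_low_frac = 0.35,
                       sub_cpm_frac = 0.08, major_mismatch_rate = 0.3,
                       library_size = 3608972L, intergenic_count = 2,
                       scenario_probs = c(SHARED_ONLY = 0.4,
                                          ONE_CONFIRMED = 0.35,
                                          MULTI_CONFIRMED = 0.25),
                       evidenced_frac = 0.85, shared_per_gene = 2,
                       novel_peptide_count = 12, decoy_count = 15,
                       unmapped_count = 3,
                       psm_intercept = 0.3, psm_slope = 0.8, psm_sigma = 0.25) {
  cfg <- as.list(environment())
  rates <- unlist(cfg$novelty_rates)
  if (any(rates < 0 | rates > 1)) stop("novelty rates must lie in [0, 1]")
  if (n_genes < 4) stop("infeasible configuration: need at least 4 genes")
  if (abs(sum(scenario_probs) - 1) > 1e-8) stop("scenario_probs must sum to 1")
  structure(cfg, class = "sim_config")
}

#' Smoke-test configuration
#'
#' A small preset (30 genes) that runs the full pipeline in seconds.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @export
smoke_config <- function(seed = 1, ...) sim_config(seed = seed, n_genes = 30, ...)

rand_nt <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# n random codons avoiding stop codons (and so safe to splice in-frame)
rand_codons <- function(n) {
  pool <- setdiff(mkAllStrings <- do.call(paste0, expand.grid(
    c("A", "C", "G", "T"), c("A", "C", "G", "T"), c("A", "C", "G", "T"))),
    STOP_CODONS)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# UTR sequence free of G, hence free of ATG and of stop codons in any frame
rand_utr <- function(n) rand_nt(n, c("A", "C", "T"))

#' Generate a synthetic reference (genome, annotation, proteins, APPRIS)
#'
#' Each full-architecture gene has seven exons with codon-aligned CDS
#' boundaries, a G-free 5' UTR (so the annotated AUG is the first AUG), two
#' designated skippable internal exons with annotated skip isoforms, and a
#' codon-safe designated retention intron. Short genes fall outside the 1--4
#' kb mean-length window. One transcript per gene is flagged APPRIS
#' principal. Strands alternate so both orientations are exercised.
#'
#' @param config a `sim_config`.
#' @param dir optional directory; when given, genome.fa, annotation.gtf,
#'   appris.tsv, reference_proteins.fa, uniprot_synthetic.fa and
#'   contaminants_synthetic.fa are written there.
#' @return list of class `sim_reference` with genome, exon/CDS tables, the
#'   APPRIS table, and the per-gene construction plan used by
#'   [simulate_long_reads()].
#' @export
generate_reference <- function(config, dir = NULL) {
  with_seed(config$seed, {
    n <- config$n_genes
    n_short <- round(config$frac_short_genes * n)
    is_short <- seq_len(n) %in% sample(n, n_short)
    strands <- rep(c("+", "-"), length.out = n)
    chroms <- paste0("chr", ((seq_len(n) - 1L) %% 4L) + 1L)
    cursor <- stats::setNames(rep(1000L, 4L), paste0("chr", 1:4))
    # chromosome pads carry a plantable ORF so intergenic transcript models
    # (class OTHER) have a candidate ORF to call
    genome_parts <- stats::setNames(
      lapply(paste0("chr", 1:4), function(ch)
        paste0(rand_utr(150L), "ATG", rand_codons(120L), "TAA", rand_utr(484L))),
      paste0("chr", 1:4))

    plans <- vector("list", n)
    for (gi in seq_len(n)) {
      gid <- sprintf("G%03d", gi)
      strand <- strands[gi]; chrom <- chroms[gi]
      if (is_short[gi]) {
        n_ex <- 4L
        codons <- c(10L, 25L, 25L, 10L)
      } else {
        n_ex <- 7L
        codons <- c(sample(12:20, 1), sample(70:110, 5, replace = TRUE),
                    sample(12:20, 1))
      }
      utr5 <- rand_utr(60L); utr3 <- rand_utr(80L)
      exon_seq <- lapply(seq_len(n_ex), function(k) rand_codons(codons[k]))
      exon_seq[[1]] <- paste0("ATG", substring(exon_seq[[1]], 4L))
      cds_codons <- unlist(exon_seq)
      exon_seq[[1]] <- paste0(utr5, exon_seq[[1]])
      exon_seq[[n_ex]] <- paste0(exon_seq[[n_ex]], "TAA", utr3)
      intron_len <- sample(120:300, n_ex - 1L, replace = TRUE)
      # introns 3 and 5 are codon-safe (length a multiple of 3, no in-frame
      # stops) so intron retention and novel-exon insertion preserve frame
      intron_seq <- lapply(seq_len(n_ex - 1L), function(k) {
        if (!is_short[gi] && k %in% c(3L, 5L)) rand_codons(intron_len[k] %/% 3L)
        else rand_nt(intron_len[k])
      })
      segs <- character(2L * n_ex - 1L)
      segs[seq(1L, by = 2L, length.out = n_ex)] <- unlist(exon_seq)
      segs[seq(2L, by = 2L, length.out = n_ex - 1L)] <- unlist(intron_seq)
      block <- paste(segs, collapse = "")
      widths <- nchar(segs)
      tx_start <- cumsum(c(0L, widths))[seq(1L, by = 2L, length.out = n_ex)]
      tx_end <- tx_start + widths[seq(1L, by = 2L, length.out = n_ex)]
      L <- nchar(block)
      g0 <- cursor[[chrom]]
      if (strand == "+") {
        ex_start <- g0 + tx_start; ex_end <- g0 + tx_end
        genome_parts[[chrom]] <- paste0(genome_parts[[chrom]], block, rand_nt(500L))
      } else {
        ex_start <- g0 + L - tx_end; ex_end <- g0 + L - tx_start
        genome_parts[[chrom]] <- paste0(genome_parts[[chrom]], revcomp(block),
                                        rand_nt(500L))
      }
      cursor[[chrom]] <- g0 + L + 500L
      # exon table in transcript (5'->3') order
      exons <- data.frame(chrom = chrom, start = ex_start, end = ex_end,
                          strand = strand, stringsAsFactors = FALSE)
      cds0 <- 60L
      cds1 <- 60L + sum(codons) * 3L + 3L  # includes stop codon
      n_iso <- if (is_short[gi]) 1L
      else if (stats::runif(1) < config$frac_three_isoform) 3L else 2L
      has_dup <- !is_short[gi] && stats::runif(1) < config$dup_frac
      plans[[gi]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                          short = is_short[gi], exons = exons,
                          exon_widths = tx_end - tx_start,
                          codons = codons, cds_codons = cds_codons,
                          intron_len = nchar(unlist(intron_seq)),
                          cds0 = cds0, cds1 = cds1,
                          n_iso = n_iso, has_dup = has_dup)
    }

    genome <- vapply(genome_parts, identity, "")

    # assemble annotated transcripts from the plans
    ex_rows <- list(); cds_rows <- list(); appris <- list()
    proteins <- character(0)
    k <- 0L
    for (p in plans) {
      iso <- list(`201` = seq_len(nrow(p$exons)))
      if (p$n_iso >= 2L) iso$`202` <- setdiff(seq_len(nrow(p$exons)), 3L)
      if (p$n_iso >= 3L) iso$`203` <- setdiff(seq_len(nrow(p$exons)), 5L)
      for (nm in names(iso)) {
        tid <- paste0(p$gene_id, "-", nm)
        proteins[[tid]] <- translate_cds(
          paste(p$cds_codons[iso[[nm]]], collapse = ""))$protein
        e <- p$exons[iso[[nm]], , drop = FALSE]
        w <- p$exon_widths[iso[[nm]]]
        skipped_nt <- sum(p$exon_widths) - sum(w)
        cds_hi <- p$cds1 - skipped_nt
        k <- k + 1L
        ex_rows[[k]] <- data.frame(transcript_id = tid, gene_id = p$gene_id,
                                   gene_name = p$gene_id, e)
        cds_rows[[k]] <- cbind(transcript_id = tid, gene_id = p$gene_id,
                               gene_name = p$gene_id,
                               tx_interval_to_genomic(e, p$cds0, cds_hi))
        appris[[k]] <- data.frame(gene_id = p$gene_id, transcript_id = tid,
                                  appris_label = if (nm == "201") "PRINCIPAL:1"
                                  else "ALTERNATIVE:1")
      }
      if (p$has_dup) {
        # UTR-only variant: identical protein, extra junction in the 3' UTR
        e <- p$exons
        last <- nrow(e)
        # split the final 20 nt of the 3' UTR off as its own exon with a
        # 40-nt intron; the stop codon (80 nt from the end) is untouched
        gap <- 40L
        minus <- p$strand == "-"
        if (minus) {
          e_last1 <- e[last, ]; e_last1$start <- e$start[last] + 20L + gap
          e_new <- e[last, ]; e_new$end <- e$start[last] + 20L
        } else {
          e_last1 <- e[last, ]; e_last1$end <- e$end[last] - 20L - gap
          e_new <- e[last, ]; e_new$start <- e$end[last] - 20L
        }
        e2 <- rbind(e[-last, ], e_last1, e_new)
        tid <- paste0(p$gene_id, "-204")
        proteins[[tid]] <- proteins[[paste0(p$gene_id, "-201")]]
        k <- k + 1L
        ex_rows[[k]] <- data.frame(transcript_id = tid, gene_id = p$gene_id,
                                   gene_name = p$gene_id, e2)
        cds_rows[[k]] <- cbind(transcript_id = tid, gene_id = p$gene_id,
                               gene_name = p$gene_id,
                               tx_interval_to_genomic(e2, p$cds0, p$cds1))
        appris[[k]] <- data.frame(gene_id = p$gene_id, transcript_id = tid,
                                  appris_label = "ALTERNATIVE:2")
      }
    }
    exons <- do.call(rbind, ex_rows)
    cds <- do.call(rbind, cds_rows)
    appris <- do.call(rbind, appris)

    # UniProt-style second reference database (same protein space, synthetic
    # accessions) and a small synthetic contaminant set
    uniq <- proteins[!duplicated(proteins)]
    uniprot <- stats::setNames(unname(uniq),
                               sprintf("sp|P%05d|%s_SYN", seq_along(uniq),
                                       sub("-.*", "", names(uniq))))
    contaminants <- stats::setNames(
      vapply(1:3, function(i) translate_cds(rand_codons(200L))$protein, ""),
      sprintf("CONT_%03d|synthetic contaminant", 1:3))

    ref <- structure(list(genome = genome, exons = exons, cds = cds,
                          appris = appris, proteins = proteins,
                          uniprot = uniprot, contaminants = contaminants,
                          plans = plans, config = config),
                     class = "sim_reference")
    if (!is.null(dir)) write_reference_files(ref, dir)
    ref
  })
}

# Map a transcript-coordinate interval [lo, hi) to genomic segments.
tx_interval_to_genomic <- function(exons, lo, hi) {
  e <- order_tx(exons)
  w <- e$end - e$start
  ca <- cumsum(c(0L, w))
  out <- list()
  for (k in seq_len(nrow(e))) {
    a <- max(lo, ca[k]); b <- min(hi, ca[k + 1L])
    if (a >= b) next
    if (identical(e$strand[1], "-")) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = e$chrom[k], start = e$end[k] - (b - ca[k]),
        end = e$end[k] - (a - ca[k]), strand = e$strand[k])
    } else {
      out[[length(out) + 1L]] <- data.frame(
        chrom = e$chrom[k], start = e$start[k] + (a - ca[k]),
        end = e$start[k] + (b - ca[k]), strand = e$strand[k])
    }
  }
  do.call(rbind, out)
}

write_reference_files <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(ref$genome, file.path(dir, "genome.fa"))
  write_gtf(ref$exons, file.path(dir, "annotation.gtf"), cds = ref$cds)
  write_tsv(ref$appris, file.path(dir, "appris.tsv"))
  write_fasta(ref$proteins, file.path(dir, "reference_proteins.fa"))
  write_fasta(ref$uniprot, file.path(dir, "uniprot_synthetic.fa"))
  write_fasta(ref$contaminants, file.path(dir, "contaminants_synthetic.fa"))
  invisible(dir)
}
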