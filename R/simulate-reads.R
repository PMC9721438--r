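# Long-read simulation: observed transcript models with labelled novelty
# events and planted abundances.

#' Simulate long-read transcript models with ground truth
#'
#' Every annotated isoform is observed as an FSM model; full-architecture
#' genes additionally receive novelty events at the configured rates: exon
#' skip and novel combinations of annotated skips (NIC), retention of the
#' codon-safe intron (NIC), acceptor/donor shifts of 9 nt (frame-preserving)
#' or 8 nt (frame-shifting) into an internal exon (NNC), and a 36-nt novel
#' exon inserted in a codon-safe intron (NNC). Counts place planted CPM
#' levels away from the 1, 3 and 25 CPM decision boundaries; designated
#' low-expression genes stay below 3 CPM total, and a configured fraction of
#' novel transcripts is planted below 1 CPM to exercise the abundance filter.
#'
#' @param config a `sim_config`.
#' @param ref output of [generate_reference()].
#' @param dir optional directory; writes transcripts.gtf, fl_counts.tsv and
#'   truth tables when given.
#' @return list of class `sim_reads`: exons, counts, truth_tx, truth_genes,
#'   novel_meta.
#' @export
simulate_long_reads <- function(config, ref, dir = NULL) {
  with_seed(config$seed + 7L, {
    ann_by_tx <- split(ref$exons, ref$exons$transcript_id)
    plans <- ref$plans
    gene_of <- vapply(plans, `[[`, "", "gene_id")
    n_low <- round(config$low_expr_gene_frac * length(plans))
    eligible <- which(!vapply(plans, `[[`, TRUE, "short"))
    low_genes <- gene_of[sample(eligible, min(n_low, length(eligible)))]

    tx <- list(); meta <- list()
    add_tx <- function(pb, gene, exons, base, cls, event, frameshift, planted,
                       jx = NA_integer_, region = c(NA_integer_, NA_integer_)) {
      tx[[length(tx) + 1L]] <<- list(pb = pb, gene = gene, exons = exons,
                                     base = base, cls = cls, event = event,
                                     frameshift = frameshift, planted = planted)
      meta[[length(meta) + 1L]] <<- data.frame(
        pb_accession = pb, event = event, frameshift = frameshift,
        jx_novel = jx, region_lo = region[1], region_hi = region[2],
        stringsAsFactors = FALSE)
    }

    for (gi in seq_along(plans)) {
      p <- plans[[gi]]
      gid <- p$gene_id
      ann <- ref$appris$transcript_id[ref$appris$gene_id == gid]
      low <- gid %in% low_genes
      ct <- 0L
      nxt <- function() { ct <<- ct + 1L; sprintf("PB.%d.%d", gi, ct) }
      for (tid in ann) {
        if (low && tid != paste0(gid, "-201")) next
        add_tx(nxt(), gid, ann_by_tx[[tid]], tid, "FSM", "", FALSE,
               if (low) "low_gene" else if (tid == paste0(gid, "-201"))
                 "principal" else "fsm")
      }
      if (p$short || low) next
      e1 <- order_tx(ann_by_tx[[paste0(gid, "-201")]])[, c("chrom", "start",
                                                           "end", "strand")]
      w <- p$exon_widths; il <- p$intron_len
      minus <- p$strand == "-"
      rates <- config$novelty_rates
      shift_d <- function() if (stats::runif(1) < config$frameshift_frac) 8L else 9L

      if (p$n_iso == 2L && stats::runif(1) < rates$exon_skip) {
        add_tx(nxt(), gid, e1[-5L, ], NA, "NIC", "exon_skip", FALSE, "novel")
      }
      if (p$n_iso >= 3L && stats::runif(1) < rates$novel_combination) {
        add_tx(nxt(), gid, e1[-c(3L, 5L), ], NA, "NIC", "novel_combination",
               FALSE, "novel")
      }
      if (stats::runif(1) < rates$intron_retention) {
        e <- e1
        e$start[3L] <- min(e$start[3L], e$start[4L])
        e$end[3L] <- max(e$end[3L], e$end[4L])
        e <- e[-4L, ]
        c3 <- sum(w[1:3])
        add_tx(nxt(), gid, e, NA, "NIC", "intron_retention", FALSE, "novel",
               region = c(c3, c3 + il[3L]))
      }
      if (stats::runif(1) < rates$novel_acceptor) {
        d <- shift_d()
        e <- e1
        if (minus) e$end[4L] <- e$end[4L] - d else e$start[4L] <- e$start[4L] + d
        add_tx(nxt(), gid, e, NA, "NNC", "novel_acceptor", d %% 3L != 0L,
               "novel", jx = sum(w[1:3]))
      }
      if (stats::runif(1) < rates$novel_donor) {
        d <- shift_d()
        e <- e1
        if (minus) e$start[4L] <- e$start[4L] + d else e$end[4L] <- e$end[4L] - d
        add_tx(nxt(), gid, e, NA, "NNC", "novel_donor", d %% 3L != 0L,
               "novel", jx = sum(w[1:4]) - d)
      }
      if (stats::runif(1) < rates$novel_exon) {
        e <- e1
        if (minus) {
          ne <- data.frame(chrom = p$chrom, start = e$start[5L] - 30L - 36L,
                           end = e$start[5L] - 30L, strand = p$strand)
        } else {
          ne <- data.frame(chrom = p$chrom, start = e$end[5L] + 30L,
                           end = e$end[5L] + 30L + 36L, strand = p$strand)
        }
        e <- rbind(e[1:5, ], ne, e[6:7, ])
        s5 <- sum(w[1:5])
        add_tx(nxt(), gid, e, NA, "NNC", "novel_exon", FALSE, "novel",
               region = c(s5, s5 + 36L))
      }
    }

    # intergenic mono-exonic models (class OTHER) on the chromosome pads
    for (k in seq_len(config$intergenic_count)) {
      ch <- paste0("chr", k)
      add_tx(sprintf("PB.%d.1", length(plans) + k), NA_character_,
             data.frame(chrom = ch, start = 50L, end = 950L, strand = "+"),
             NA, "OTHER", "", FALSE, "intergenic")
    }

    # counts: planted CPM targets for novel/low/intergenic models, the rest
    # multinomial over weights with the designated major dominating
    n_tx <- length(tx)
    pb <- vapply(tx, `[[`, "", "pb")
    gene <- vapply(tx, `[[`, "", "gene")
    planted <- vapply(tx, `[[`, "", "planted")
    lib <- config$library_size
    counts <- rep(NA_real_, n_tx)

    mism_genes <- character(0)
    multi <- unique(gene[!is.na(gene) & planted %in% c("fsm", "novel")])
    if (length(multi)) {
      mism_genes <- multi[stats::runif(length(multi)) < config$major_mismatch_rate]
    }
    for (i in seq_len(n_tx)) {
      counts[i] <- switch(planted[i],
        low_gene = sample(5:9, 1),
        intergenic = 150,
        novel = {
          t_cpm <- if (stats::runif(1) < config$sub_cpm_frac)
            stats::runif(1, 0.3, 0.7)
          else if (stats::runif(1) < config$novel_low_frac)
            stats::runif(1, 3.5, 20)
          else stats::runif(1, 30, 900)
          max(1, round(t_cpm * lib / 1e6))
        },
        NA_real_)
    }
    free <- which(is.na(counts))
    wts <- vapply(free, function(i) {
      mis <- gene[i] %in% mism_genes
      if (planted[i] == "principal") { if (mis) 60 else 150 }
      else if (grepl("-202$", tx[[i]]$base %||% "")) { if (mis) 220 else sample(30:70, 1) }
      else sample(15:60, 1)
    }, 0)
    leftover <- lib - sum(counts, na.rm = TRUE)
    counts[free] <- as.numeric(stats::rmultinom(1, leftover, wts))
    cpm <- counts / sum(counts) * 1e6

    # construction-level protein truth: translate from the annotated start
    truth_rows <- lapply(seq_len(n_tx), function(i) {
      e <- tx[[i]]$exons
      e$transcript_id <- pb[i]
      seq <- spliced_sequence(e, ref$genome)
      cds0 <- if (tx[[i]]$cls == "OTHER") 100L else 60L
      tr <- translate_cds(substring(seq, cds0 + 1L))
      stop_nt <- cds0 + nchar(tr$protein) * 3L + if (tr$stopped) 3L else 0L
      jx <- tx_junction_offsets(e)
      jas <- if (tr$stopped) sum(jx >= stop_nt) else NA_integer_
      pclass <- switch(tx[[i]]$cls,
                       FSM = "pFSM", OTHER = "pOTHER",
                       NIC = "pNIC",
                       NNC = "pNNC")
      if (tx[[i]]$cls %in% c("NIC", "NNC") && tx[[i]]$frameshift) pclass <- "pNNC"
      removed <- if (!tr$stopped) "truncation"
      else if (pclass == "pOTHER") "class"
      else if (pclass == "pNNC" && jas > 2L) "NMD"
      else NA_character_
      data.frame(pb_accession = pb[i], gene_id = gene[i],
                 base_transcript = tx[[i]]$base %||% NA_character_,
                 true_class = tx[[i]]$cls, event = tx[[i]]$event,
                 frameshift = tx[[i]]$frameshift,
                 fl_count = counts[i], cpm = cpm[i], retained = cpm[i] >= 1,
                 true_protein = tr$protein, true_has_stop = tr$stopped,
                 true_stop_nt = stop_nt, true_junctions_after_stop = jas,
                 true_pclass = pclass, true_removed = removed,
                 stringsAsFactors = FALSE)
    })
    truth_tx <- do.call(rbind, truth_rows)

    # per-gene truth over retained transcripts
    ret <- truth_tx[truth_tx$retained & !is.na(truth_tx$gene_id), , drop = FALSE]
    ann_len <- tapply(ref$exons$end - ref$exons$start, ref$exons$transcript_id, sum)
    gene_of_ann <- tapply(ref$exons$gene_id, ref$exons$transcript_id,
                          function(x) x[1])
    mean_len <- tapply(as.numeric(ann_len), gene_of_ann[names(ann_len)], mean)
    truth_genes <- do.call(rbind, lapply(split(ret, ret$gene_id), function(g) {
      o <- order(-g$fl_count, pb_suffix(g$pb_accession))
      major <- g[o[1], ]
      principal <- paste0(g$gene_id[1], "-201")
      data.frame(gene_id = g$gene_id[1], n_retained = nrow(g),
                 total_cpm = sum(g$cpm), true_major = major$pb_accession,
                 true_mismatch = !(identical(major$true_class, "FSM") &&
                                     identical(major$base_transcript, principal)),
                 mean_ref_len = as.numeric(mean_len[g$gene_id[1]]),
                 true_high_confidence = sum(g$cpm) >= 3 &&
                   mean_len[g$gene_id[1]] >= 1000 &&
                   mean_len[g$gene_id[1]] <= 4000,
                 stringsAsFactors = FALSE)
    }))
    rownames(truth_genes) <- truth_genes$gene_id

    exon_rows <- do.call(rbind, lapply(seq_len(n_tx), function(i) {
      e <- tx[[i]]$exons
      data.frame(transcript_id = pb[i], gene_id = pb[i], gene_name = pb[i],
                 e[, c("chrom", "start", "end", "strand")],
                 stringsAsFactors = FALSE)
    }))
    counts_df <- data.frame(pb_accession = pb, fl_count = as.integer(counts))
    novel_meta <- do.call(rbind, meta)
    novel_meta <- novel_meta[nzchar(novel_meta$event), , drop = FALSE]

    out <- structure(list(exons = exon_rows, counts = counts_df,
                          truth_tx = truth_tx, truth_genes = truth_genes,
                          novel_meta = novel_meta),
                     class = "sim_reads")
    if (!is.null(dir)) {
      write_gtf(exon_rows, file.path(dir, "transcripts.gtf"))
      write_tsv(counts_df, file.path(dir, "fl_counts.tsv"))
      write_tsv(truth_tx, file.path(dir, "truth_transcripts.tsv"))
      write_tsv(truth_genes, file.path(dir, "truth_genes.tsv"))
    }
    out
  })
}
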