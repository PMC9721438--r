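# Peptide-identification simulation over a built hybrid database, plus the
# end-to-end fixture bundle and a direct expression-pair simulator for the
# RNA-protein correlation model.

#' Simulate peptide identifications with ground truth
#'
#' Peptides are sampled from database entry digests: per evidenced gene a
#' planned scenario (shared-only, one confirmed, multiple confirmed) decides
#' which entries emit uniquely mapping peptides; novel peptides are drawn
#' only from novel-class PacBio entries' event regions and are verified
#' absent from both reference digests; decoy rows sit above the 1% FDR
#' threshold and a few low-q rows map nowhere. PSM counts follow a log-log
#' model of gene transcript abundance. The achieved (not merely planned)
#' scenario and nomination labels are recorded as truth.
#'
#' @param config a `sim_config`.
#' @param db a `hybrid_db` built from the simulated transcripts.
#' @param reads a `sim_reads` object (provides abundance and event truth).
#' @param ref the `sim_reference` (provides reference/UniProt protein space).
#' @param dir optional output directory (peptides.tsv + truth tables).
#' @return list of class `sim_peptides`: peptides, truth_peptides,
#'   truth_scenarios.
#' @export
simulate_peptide_identifications <- function(config, db, reads, ref, dir = NULL) {
  with_seed(config$seed + 13L, {
    ent <- db$entries
    digests <- lapply(ent$sequence, digest_protein)
    occ <- new.env(parent = emptyenv(), size = 4096L)
    for (i in seq_along(digests)) {
      for (p in digests[[i]]) {
        assign(p, c(if (exists(p, occ, inherits = FALSE)) get(p, occ), i), occ)
      }
    }
    n_occ <- function(p) length(get(p, occ))
    genes_of <- function(p) unique(ent$gene_id[get(p, occ)])

    ref_digest <- digest_reference(unique(c(ref$proteins, ref$uniprot)))

    gene_cpm <- stats::setNames(reads$truth_genes$total_cpm,
                                reads$truth_genes$gene_id)
    db_genes <- sort(unique(ent$gene_id[!is.na(ent$gene_id)]))
    evid <- sort(sample(db_genes, round(config$evidenced_frac * length(db_genes))))

    used <- new.env(parent = emptyenv())
    take <- function(p) { assign(p, TRUE, used); p }
    free_pep <- function(peps) peps[!vapply(peps, exists, TRUE, envir = used)]

    pep_rows <- list(); truth_pep <- list(); scen_rows <- list()
    emit <- function(seq, q, gene, entry, type, event = "") {
      pep_rows[[length(pep_rows) + 1L]] <<- data.frame(
        sequence = take(seq), q_value = q, psm_count = 1L,
        stringsAsFactors = FALSE)
      truth_pep[[length(truth_pep) + 1L]] <<- data.frame(
        sequence = seq, type = type, gene_id = gene, entry = entry,
        event = event, stringsAsFactors = FALSE)
    }
    # ordinary identifications sit inside the 1% tier but above the strict
    # novel tier, so the planted novel set is exactly the sub-0.001 stratum
    q_true <- function() stats::runif(1, 0.0015, 0.009)

    for (g in evid) {
      ix <- which(!is.na(ent$gene_id) & ent$gene_id == g)
      # peptides confined to this gene
      pool <- free_pep(unique(unlist(digests[ix])))
      pool <- pool[vapply(pool, function(p) identical(genes_of(p), g), TRUE)]
      if (!length(pool)) next
      n_in_gene <- vapply(pool, n_occ, 0L)
      uniq_by_entry <- lapply(ix, function(i)
        pool[n_in_gene == 1L & pool %in% digests[[i]]])
      shared <- pool[n_in_gene >= 2L]

      if (length(ix) == 1L) {
        peps <- utils::head(uniq_by_entry[[1]], 2L)
        if (!length(peps)) next
        for (p in peps) emit(p, q_true(), g, ent$label[ix[1]], "single")
        scen <- "SINGLE_ISOFORM_IN_DB"; conf <- ent$label[ix[1]]
      } else {
        plan <- sample(names(config$scenario_probs), 1,
                       prob = config$scenario_probs)
        have_uniq <- which(lengths(uniq_by_entry) > 0L)
        n_conf <- switch(plan, SHARED_ONLY = 0L, ONE_CONFIRMED = 1L,
                         MULTI_CONFIRMED = 2L)
        n_conf <- min(n_conf, length(have_uniq))
        sh <- utils::head(shared, config$shared_per_gene)
        if (!length(sh) && n_conf == 0L) n_conf <- min(1L, length(have_uniq))
        if (!length(sh) && n_conf == 0L) next
        for (p in sh) emit(p, q_true(), g, "", "shared")
        conf <- character(0)
        for (k in utils::head(have_uniq, n_conf)) {
          p <- uniq_by_entry[[k]][1]
          emit(p, q_true(), g, ent$label[ix[k]], "unique")
          conf <- c(conf, ent$label[ix[k]])
        }
        scen <- if (length(conf) >= 2L) "MULTI_CONFIRMED"
        else if (length(conf) == 1L) "ONE_CONFIRMED" else "SHARED_ONLY"
      }
      scen_rows[[length(scen_rows) + 1L]] <- data.frame(
        gene_id = g, true_scenario = scen,
        confirmed_entries = paste(sort(conf), collapse = ";"),
        stringsAsFactors = FALSE)
    }

    # novel peptides: from novel-class PacBio entries, inside the planted
    # event's transcript footprint, absent from both reference digests
    nm <- reads$novel_meta
    nm <- nm[nm$event %in% c("intron_retention", "novel_exon",
                             "novel_acceptor", "novel_donor"), , drop = FALSE]
    novel_ix <- which(ent$source == "PACBIO" & ent$pclass %in% c("pNIC", "pNNC") &
                        ent$representative %in% nm$pb_accession)
    n_novel <- 0L
    novel_hits <- list()
    for (i in novel_ix) {
      if (n_novel >= config$novel_peptide_count) break
      pbid <- ent$representative[i]
      m <- nm[nm$pb_accession == pbid, ][1, ]
      tr <- reads$truth_tx[reads$truth_tx$pb_accession == pbid, ][1, ]
      cand <- free_pep(setdiff(digests[[i]], ref_digest))
      if (!length(cand)) next
      prot <- ent$sequence[i]
      ok <- vapply(cand, function(p) {
        a <- regexpr(p, prot, fixed = TRUE)[1]
        if (a < 0) return(FALSE)
        nt0 <- 60L + 3L * (a - 1L); nt1 <- nt0 + 3L * nchar(p)
        if (m$event %in% c("intron_retention", "novel_exon"))
          return(nt0 >= m$region_lo && nt1 <= m$region_hi)
        if (tr$frameshift)  # downstream of the shifted junction, before stop
          return(nt0 >= m$jx_novel && nt1 <= tr$true_stop_nt - 3L)
        nt0 < m$jx_novel && nt1 > m$jx_novel  # spans the novel junction
      }, TRUE)
      if (!any(ok)) next
      ev <- if (m$event %in% c("novel_acceptor", "novel_donor") && tr$frameshift)
        "frameshift" else m$event
      p <- cand[ok][1]
      novel_hits[[length(novel_hits) + 1L]] <- list(
        gene = ent$gene_id[i], entry = ent$label[i], unique = n_occ(p) == 1L)
      emit(p, stats::runif(1, 1e-5, 9e-4), ent$gene_id[i],
           ent$label[i], "novel", event = ev)
      n_novel <- n_novel + 1L
    }

    # fold novel-peptide evidence into the achieved scenario truth
    scen <- do.call(rbind, scen_rows)
    n_entries_gene <- table(ent$gene_id[!is.na(ent$gene_id)])
    for (h in novel_hits) {
      r <- which(scen$gene_id == h$gene)
      if (!length(r)) {
        scen <- rbind(scen, data.frame(gene_id = h$gene, true_scenario = "",
                                       confirmed_entries = "",
                                       stringsAsFactors = FALSE))
        r <- nrow(scen)
      }
      conf <- setdiff(strsplit(scen$confirmed_entries[r], ";")[[1]], "")
      if (h$unique) conf <- union(conf, h$entry)
      scen$confirmed_entries[r] <- paste(sort(conf), collapse = ";")
      scen$true_scenario[r] <-
        if (as.integer(n_entries_gene[h$gene]) == 1L) "SINGLE_ISOFORM_IN_DB"
        else if (length(conf) >= 2L) "MULTI_CONFIRMED"
        else if (length(conf) == 1L) "ONE_CONFIRMED"
        else "SHARED_ONLY"
    }

    # achieved nomination truth from scenarios + entry abundances
    scen$true_nomination <- "NONE"
    scen$true_nominated <- ""
    scen$true_coexpression <- FALSE
    for (r in seq_len(nrow(scen))) {
      g <- scen$gene_id[r]
      pac <- ent[!is.na(ent$gene_id) & ent$gene_id == g &
                   ent$source == "PACBIO", , drop = FALSE]
      if (!nrow(pac)) next
      if (scen$true_scenario[r] == "SHARED_ONLY") {
        nom <- pac$label[pac$cpm_sum >= 25]
        if (length(nom)) {
          scen$true_nomination[r] <- "NOMINATED_AMBIGUOUS"
          scen$true_nominated[r] <- paste(sort(nom), collapse = ";")
          scen$true_coexpression[r] <- length(nom) >= 2L
        }
      } else if (scen$true_scenario[r] == "ONE_CONFIRMED") {
        conf <- strsplit(scen$confirmed_entries[r], ";")[[1]]
        nom <- setdiff(pac$label[pac$cpm_sum >= 25], conf)
        if (length(nom)) {
          scen$true_nomination[r] <- "NOMINATED_ADDITIONAL"
          scen$true_nominated[r] <- paste(sort(nom), collapse = ";")
        }
      }
    }

    # decoys above threshold and low-q peptides mapping nowhere
    rand_pep <- function() {
      repeat {
        p <- paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                          sample(10:16, 1), replace = TRUE), collapse = "")
        if (!exists(p, occ, inherits = FALSE) &&
            !exists(p, used, inherits = FALSE)) return(p)
      }
    }
    for (k in seq_len(config$decoy_count)) {
      emit(rand_pep(), stats::runif(1, 0.02, 0.5), NA_character_, "", "decoy")
    }
    for (k in seq_len(config$unmapped_count)) {
      emit(rand_pep(), q_true(), NA_character_, "", "unmapped")
    }

    peptides <- do.call(rbind, pep_rows)
    truth_peptides <- do.call(rbind, truth_pep)

    # PSM counts from the log-log abundance model, summed per gene and
    # spread over that gene's peptides
    by_gene <- split(seq_len(nrow(peptides)), truth_peptides$gene_id)
    for (g in names(by_gene)) {
      cg <- gene_cpm[g]
      mu <- config$psm_intercept +
        config$psm_slope * log10((if (is.na(cg)) 5 else cg) + 1)
      tot <- max(length(by_gene[[g]]),
                 round(10^(mu + stats::rnorm(1, 0, config$psm_sigma))))
      alloc <- as.integer(stats::rmultinom(
        1, tot - length(by_gene[[g]]), rep(1, length(by_gene[[g]])))) + 1L
      peptides$psm_count[by_gene[[g]]] <- alloc
    }
    # shared peptides without a single gene id keep psm 1
    peptides <- peptides[sample(nrow(peptides)), , drop = FALSE]
    rownames(peptides) <- NULL

    out <- structure(list(peptides = peptides, truth_peptides = truth_peptides,
                          truth_scenarios = scen),
                     class = "sim_peptides")
    if (!is.null(dir)) {
      write_tsv(peptides, file.path(dir, "peptides.tsv"))
      write_tsv(truth_peptides, file.path(dir, "truth_peptides.tsv"))
      write_tsv(scen, file.path(dir, "truth_scenarios.tsv"))
    }
    out
  })
}

#' Generate a complete pipeline fixture with ground truth
#'
#' Writes every input the pipeline consumes (genome, annotation, APPRIS
#' table, long-read transcript GTF and counts, contaminant and UniProt-style
#' FASTAs, peptide identifications) plus truth tables, running the pipeline's
#' own stages to produce the hybrid database the peptide simulator samples
#' from.
#'
#' @param config a `sim_config`.
#' @param dir output directory.
#' @return list with `paths` (named input files), `truth` tables, and the
#'   intermediate `objects` (catalog, lr, summaries, orfs, db, ...).
#' @export
end_to_end_fixture <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(config, dir = dir)
  reads <- simulate_long_reads(config, ref, dir = dir)

  catalog <- load_annotation(file.path(dir, "annotation.gtf"),
                             file.path(dir, "genome.fa"),
                             file.path(dir, "appris.tsv"))
  lr <- read_longread_models(file.path(dir, "transcripts.gtf"),
                             file.path(dir, "fl_counts.tsv"), catalog)
  lr$transcripts <- filter_min_abundance(lr$transcripts)
  lr$exons <- lr$exons[lr$exons$transcript_id %in% lr$transcripts$pb_accession, ]
  lr$seqs <- lr$seqs[lr$transcripts$pb_accession]
  lr <- classify_transcripts(lr, catalog)
  summaries <- summarize_gene_expression(lr, catalog)
  orfs <- call_orfs(lr, catalog)
  orfs <- classify_proteins(orfs, lr, catalog)
  filt <- filter_protein_isoforms(orfs)
  grouped <- group_orfs_by_sequence(filt$retained, lr)
  high_conf <- select_high_confidence_genes(summaries, catalog)
  db <- build_hybrid_database(grouped, catalog, high_conf,
                              contaminants = ref$contaminants)
  peps <- simulate_peptide_identifications(config, db, reads, ref, dir = dir)

  list(paths = list(genome = file.path(dir, "genome.fa"),
                    annotation = file.path(dir, "annotation.gtf"),
                    appris = file.path(dir, "appris.tsv"),
                    transcripts = file.path(dir, "transcripts.gtf"),
                    counts = file.path(dir, "fl_counts.tsv"),
                    uniprot = file.path(dir, "uniprot_synthetic.fa"),
                    contaminants = file.path(dir, "contaminants_synthetic.fa"),
                    peptides = file.path(dir, "peptides.tsv")),
       truth = list(transcripts = reads$truth_tx, genes = reads$truth_genes,
                    novel_meta = reads$novel_meta,
                    peptides = peps$truth_peptides,
                    scenarios = peps$truth_scenarios),
       objects = list(ref = ref, reads = reads, catalog = catalog, lr = lr,
                      summaries = summaries, orfs = orfs, filt = filt,
                      grouped = grouped, high_conf = high_conf, db = db,
                      peptides = peps))
}

#' Simulate gene-level expression pairs from the log-log model
#'
#' Draws log10(CPM + 1) uniformly on \[0, 3.5\] and log10(PSM + 1) from the
#' linear model with Gaussian noise; the defaults give an expected
#' coefficient of determination near 0.66. Used to study recovery of the
#' RNA-protein correlation at large n without running the full pipeline.
#'
#' @param n number of genes.
#' @param slope,intercept,sigma model parameters on the log10 scale.
#' @param seed integer seed.
#' @return data.frame with gene_id, cpm, psm (continuous abundances).
#' @export
simulate_expression_pairs <- function(n = 2000, slope = 0.8, intercept = 0.3,
                                      sigma = 0.58, seed = 1) {
  with_seed(seed, {
    x <- stats::runif(n, 0, 3.5)
    y <- intercept + slope * x + stats::rnorm(n, 0, sigma)
    data.frame(gene_id = sprintf("G%05d", seq_len(n)),
               cpm = 10^x - 1, psm = pmax(0, 10^y - 1))
  })
}
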