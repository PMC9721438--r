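# Reference catalog: the indexed view of the annotation (GTF + genome +
# APPRIS) that every downstream stage queries. Coordinates are 0-based
# half-open; donor/acceptor roles are strand-aware.

order_tx <- function(exons) {
  # exon rows of one transcript in 5'->3' transcript order
  if (identical(exons$strand[1], "-")) exons[order(-exons$start), , drop = FALSE]
  else exons[order(exons$start), , drop = FALSE]
}

# Spliced (exonic) sequence of one transcript, 5'->3'.
spliced_sequence <- function(exons, genome) {
  e <- exons[order(exons$start), , drop = FALSE]
  chrom <- e$chrom[1]
  if (is.null(genome[[chrom]])) stop("chromosome '", chrom, "' absent from genome")
  s <- paste(substring(genome[[chrom]], e$start + 1L, e$end), collapse = "")
  if (identical(e$strand[1], "-")) revcomp(s) else s
}

# Map transcript offsets (0-based, 5'->3') to genomic positions (0-based).
tx_to_genomic <- function(exons, pos) {
  e <- order_tx(exons)
  w <- e$end - e$start
  cum <- cumsum(w)
  k <- findInterval(pos, c(0L, cum))
  off <- pos - c(0L, cum)[k]
  if (identical(e$strand[1], "-")) e$end[k] - 1L - off else e$start[k] + off
}

# Transcript offsets of the junction points: junction i sits after cumulative
# exon length c_i (i = 1..n-1), in transcript order.
tx_junction_offsets <- function(exons) {
  e <- order_tx(exons)
  w <- e$end - e$start
  if (nrow(e) < 2L) integer(0) else cumsum(w)[-nrow(e)]
}

#' Load a reference annotation into an indexed catalog
#'
#' Reads a GENCODE-style GTF, the genome FASTA, and optionally an APPRIS
#' principal-isoform table, and builds the catalog used throughout the
#' pipeline: per-transcript exon chains and junction chains, per-(chrom,
#' strand) donor/acceptor/junction indices, per-gene junction-chain sets,
#' annotated start/stop codon positions, CDS junction structures, reference
#' protein sequences (translated from the genome), and per-gene mean annotated
#' spliced transcript length.
#'
#' Coding regions are taken as the union of `CDS` and `stop_codon` features so
#' both GENCODE-style (stop excluded from CDS) and plain GTFs load correctly.
#'
#' @param gtf_path annotation GTF.
#' @param genome_fasta_path genome FASTA containing every referenced chrom.
#' @param appris_table_path optional TSV with columns gene_id, transcript_id,
#'   appris_label; rows labelled PRINCIPAL flag the gene's principal isoform
#'   (ties broken by lowest principal rank, then transcript id).
#' @return An object of class `ref_catalog`.
#' @export
load_annotation <- function(gtf_path, genome_fasta_path, appris_table_path = NULL) {
  feats <- read_gtf(gtf_path)
  genome <- read_fasta(genome_fasta_path, "dna")
  missing_chrom <- setdiff(unique(feats$chrom), names(genome))
  if (length(missing_chrom)) {
    stop("chromosome '", missing_chrom[1], "' referenced in GTF but absent from genome")
  }
  exons <- feats[feats$type == "exon", , drop = FALSE]
  cds <- feats[feats$type %in% c("CDS", "stop_codon"), , drop = FALSE]
  if (nrow(exons) == 0L) stop("no exon features in ", gtf_path)

  ex_by_tx <- split(exons, exons$transcript_id)
  cds_by_tx <- split(cds, cds$transcript_id)
  ids <- names(ex_by_tx)

  rows <- lapply(ids, function(id) {
    e <- ex_by_tx[[id]]
    intr <- exons_to_introns(e)
    cd <- cds_by_tx[[id]]
    coding <- !is.null(cd) && nrow(cd) > 0
    cds_chain <- NA_character_; start_pos <- NA_integer_; stop_pos <- NA_integer_
    protein <- NA_character_
    if (coding) {
      cmin <- min(cd$start); cmax <- max(cd$end)
      inside <- intr$lower >= cmin & intr$upper <= cmax
      cds_chain <- chain_key(intr$lower[inside], intr$upper[inside])
      minus <- identical(e$strand[1], "-")
      start_pos <- if (minus) cmax - 1L else cmin
      stop_pos <- if (minus) cmin else cmax - 1L
      cds_ex <- e
      cds_ex$start <- pmax(cds_ex$start, cmin)
      cds_ex$end <- pmin(cds_ex$end, cmax)
      cds_ex <- cds_ex[cds_ex$start < cds_ex$end, , drop = FALSE]
      tr <- translate_cds(spliced_sequence(cds_ex, genome))
      protein <- tr$protein
      if (!nzchar(protein)) { coding <- FALSE; protein <- NA_character_ }
    }
    data.frame(
      transcript_id = id, gene_id = e$gene_id[1], gene_name = e$gene_name[1],
      chrom = e$chrom[1], strand = e$strand[1], n_exons = nrow(e),
      spliced_len = sum(e$end - e$start),
      chain = chain_key(intr$lower, intr$upper),
      coding = coding, cds_chain = cds_chain,
      start_pos = start_pos, stop_pos = stop_pos,
      protein = protein,
      protein_accession = if (coding) (cds_by_tx[[id]]$protein_id[1] %||% id) else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  tx <- do.call(rbind, rows)
  tx$protein_accession[tx$coding & is.na(tx$protein_accession)] <-
    tx$transcript_id[tx$coding & is.na(tx$protein_accession)]
  tx$is_principal <- FALSE

  if (!is.null(appris_table_path)) {
    app <- read_tsv(appris_table_path)
    app <- app[grepl("^PRINCIPAL", app$appris_label), , drop = FALSE]
    if (nrow(app)) {
      known <- app$transcript_id %in% tx$transcript_id
      if (any(!known)) {
        warning("APPRIS transcript id(s) absent from GTF, flag skipped: ",
                paste(app$transcript_id[!known], collapse = ", "))
        app <- app[known, , drop = FALSE]
      }
      app$rank <- suppressWarnings(as.integer(sub("^PRINCIPAL:?", "", app$appris_label)))
      app$rank[is.na(app$rank)] <- 99L
      app <- app[order(app$gene_id, app$rank, app$transcript_id), , drop = FALSE]
      app <- app[!duplicated(app$gene_id), , drop = FALSE]
      tx$is_principal <- tx$transcript_id %in% app$transcript_id
    }
  }

  # gene table with mean annotated spliced length over all transcripts
  g <- split(tx, tx$gene_id)
  genes <- do.call(rbind, lapply(g, function(t) {
    data.frame(gene_id = t$gene_id[1], gene_name = t$gene_name[1],
               chrom = t$chrom[1], strand = t$strand[1],
               n_transcripts = nrow(t), mean_len = mean(t$spliced_len),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- genes$gene_id

  # site and junction indices
  donors <- new.env(parent = emptyenv())
  acceptors <- new.env(parent = emptyenv())
  junctions <- new.env(parent = emptyenv())
  add_site <- function(env, key, vals) {
    assign(key, unique(c(if (exists(key, env)) get(key, env), vals)), env)
  }
  gene_chains <- list(); gene_starts <- list(); gene_stops <- list()
  gene_cds <- list(); gene_cds_donors <- list(); gene_cds_acceptors <- list()

  for (gid in names(g)) {
    t <- g[[gid]]
    key <- site_key(t$chrom[1], t$strand[1])
    ch <- t$chain; names(ch) <- t$transcript_id
    gene_chains[[gid]] <- ch
    cdon <- integer(0); cacc <- integer(0)
    for (id in t$transcript_id) {
      intr <- exons_to_introns(ex_by_tx[[id]])
      if (nrow(intr)) {
        add_site(donors, key, intr$donor)
        add_site(acceptors, key, intr$acceptor)
        add_site(junctions, key, paste(intr$lower, intr$upper, sep = "-"))
      }
      trow <- tx[tx$transcript_id == id, ]
      if (trow$coding) {
        ci <- chain_to_introns(trow$cds_chain)
        if (nrow(ci)) {
          minus <- identical(trow$strand, "-")
          cdon <- c(cdon, if (minus) ci$upper else ci$lower)
          cacc <- c(cacc, if (minus) ci$lower else ci$upper)
        }
      }
    }
    cod <- tx[tx$gene_id == gid & tx$coding, , drop = FALSE]
    gene_starts[[gid]] <- unique(cod$start_pos)
    gene_stops[[gid]] <- unique(cod$stop_pos)
    gene_cds[[gid]] <- cod[, c("transcript_id", "cds_chain", "start_pos",
                               "stop_pos", "protein", "protein_accession")]
    gene_cds_donors[[gid]] <- unique(cdon)
    gene_cds_acceptors[[gid]] <- unique(cacc)
  }

  structure(list(
    transcripts = tx, exons = exons[, c("transcript_id", "gene_id", "gene_name",
                                        "chrom", "start", "end", "strand")],
    genes = genes, genome = genome,
    donors = donors, acceptors = acceptors, junctions = junctions,
    gene_chains = gene_chains, gene_starts = gene_starts,
    gene_stops = gene_stops, gene_cds = gene_cds,
    gene_cds_donors = gene_cds_donors, gene_cds_acceptors = gene_cds_acceptors
  ), class = "ref_catalog")
}

#' @export
print.ref_catalog <- function(x, ...) {
  cat("Reference catalog:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts (",
      sum(x$transcripts$coding), "coding ),",
      sum(x$transcripts$is_principal), "principal flags\n")
  invisible(x)
}

site_known <- function(env, chrom, strand, pos) {
  key <- site_key(chrom, strand)
  if (!exists(key, env)) return(rep(FALSE, length(pos)))
  pos %in% get(key, env)
}

#' Group identical reference protein sequences per gene
#'
#' Within each gene, coding transcripts yielding the same protein sequence are
#' merged into one entry whose accession is the alphanumerically first member
#' protein accession. Non-coding transcripts are skipped.
#'
#' @param catalog a `ref_catalog`.
#' @return data.frame with accession, gene_id, gene_name, sequence,
#'   member_transcripts (`;`-separated), n_members.
#' @export
group_reference_proteins <- function(catalog) {
  tx <- catalog$transcripts
  cod <- tx[tx$coding, , drop = FALSE]
  if (nrow(cod) == 0L) {
    return(data.frame(accession = character(0), gene_id = character(0),
                      gene_name = character(0), sequence = character(0),
                      member_transcripts = character(0), n_members = integer(0)))
  }
  key <- paste(cod$gene_id, cod$protein, sep = "\r")
  out <- do.call(rbind, lapply(split(cod, key), function(m) {
    data.frame(accession = sort(m$protein_accession)[1],
               gene_id = m$gene_id[1], gene_name = m$gene_name[1],
               sequence = m$protein[1],
               member_transcripts = paste(sort(m$transcript_id), collapse = ";"),
               n_members = nrow(m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id, out$accession), , drop = FALSE]
}

#' Write the catalog's transcript models back to GTF
#'
#' @param catalog a `ref_catalog`.
#' @param path output path.
#' @export
write_catalog_gtf <- function(catalog, path) {
  cds <- NULL
  tx <- catalog$transcripts
  cod <- tx[tx$coding, , drop = FALSE]
  if (nrow(cod)) {
    cds <- do.call(rbind, lapply(cod$transcript_id, function(id) {
      e <- catalog$exons[catalog$exons$transcript_id == id, , drop = FALSE]
      trow <- tx[tx$transcript_id == id, ]
      lo <- min(trow$start_pos, trow$stop_pos)
      hi <- max(trow$start_pos, trow$stop_pos) + 1L
      e$start <- pmax(e$start, lo); e$end <- pmin(e$end, hi)
      e[e$start < e$end, , drop = FALSE]
    }))
  }
  write_gtf(catalog$exons, path, cds = cds)
}
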