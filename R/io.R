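# File-format boundary: GTF, FASTA, TSV and BED12. GTF parsing is done by
# rtracklayer after a light structural validation pass (rtracklayer does not
# report offending line numbers); everything downstream works on plain
# data.frames in 0-based half-open coordinates.

#' Read exon (and CDS) structures from a GTF file
#'
#' Accepts the Ensembl/GENCODE GTF dialect with `gene_id` and `transcript_id`
#' attributes. Returns a data.frame of features with 0-based half-open
#' coordinates. `stop_codon` features are retained so the coding region can be
#' taken as the union of `CDS` and `stop_codon`.
#'
#' @param path path to a GTF file.
#' @return data.frame with columns chrom, source, type, start, end, strand,
#'   gene_id, transcript_id, gene_name, protein_id (NA where absent).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    bad <- which(keep)[which(nfield < 9L)[1]]
    stop("malformed GTF line ", bad, " in ", path, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    source = as.character(gr$source %||% NA_character_),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  m <- S4Vectors::mcols(gr)
  df$gene_id <- as.character(m$gene_id %||% NA_character_)
  df$transcript_id <- as.character(m$transcript_id %||% NA_character_)
  df$gene_name <- if ("gene_name" %in% names(m)) as.character(m$gene_name) else df$gene_id
  df$gene_name[is.na(df$gene_name)] <- df$gene_id[is.na(df$gene_name)]
  df$protein_id <- if ("protein_id" %in% names(m)) as.character(m$protein_id) else NA_character_
  df
}

#' Write transcript models to GTF
#'
#' Emits `transcript`, `exon` and (where present) `CDS` features in 1-based
#' inclusive coordinates. Input exon table uses the package's internal 0-based
#' half-open convention.
#'
#' @param exons data.frame with transcript_id, gene_id, chrom, start, end,
#'   strand and optional gene_name.
#' @param path output path.
#' @param cds optional data.frame with the same layout for CDS segments.
#' @param source feature source column value.
#' @export
write_gtf <- function(exons, path, cds = NULL, source = "protiso") {
  fmt <- function(df, type) {
    gn <- df$gene_name %||% df$gene_id
    sprintf('%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
            df$chrom, source, type, df$start + 1L, df$end, df$strand,
            df$gene_id, df$transcript_id, gn)
  }
  o <- order(exons$transcript_id, exons$start)
  exons <- exons[o, , drop = FALSE]
  tx <- do.call(rbind, lapply(split(exons, exons$transcript_id), function(e) {
    data.frame(chrom = e$chrom[1], start = min(e$start), end = max(e$end),
               strand = e$strand[1], gene_id = e$gene_id[1],
               transcript_id = e$transcript_id[1],
               gene_name = (e$gene_name %||% e$gene_id)[1])
  }))
  out <- c(fmt(tx, "transcript"), fmt(exons, "exon"))
  if (!is.null(cds) && nrow(cds) > 0) out <- c(out, fmt(cds, "CDS"))
  writeLines(out, path)
  invisible(path)
}

read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write transcript models as a BED12 genome-browser track
#'
#' One BED12 record per transcript; block structure reproduces the exon chain
#' exactly (sum of blockSizes equals the spliced length).
#'
#' @param exons exon table (0-based half-open) with transcript_id, chrom,
#'   start, end, strand.
#' @param path output path.
#' @param name_col column used for the BED name field.
#' @param score optional named vector of scores (e.g. CPM), indexed by name.
#' @export
write_bed12 <- function(exons, path, name_col = "transcript_id", score = NULL) {
  recs <- vapply(split(exons, exons[[name_col]]), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    chromStart <- min(e$start); chromEnd <- max(e$end)
    sizes <- e$end - e$start
    offsets <- e$start - chromStart
    nm <- e[[name_col]][1]
    sc <- if (is.null(score)) 0 else min(1000, round(score[[nm]] %||% 0))
    paste(e$chrom[1], chromStart, chromEnd, nm, sc, e$strand[1],
          chromStart, chromEnd, "0,0,0", nrow(e),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offsets, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(unname(recs), path)
  invisible(path)
}
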