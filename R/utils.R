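# Shared helpers: coordinate conventions, junction-chain keys, rounding.
#
# All genomic intervals are held internally as 0-based half-open [start, end);
# GTF I/O converts to/from the 1-based inclusive convention at the boundary.

#' Round a fraction to a whole percentage
#'
#' Nearest-integer rounding with halves rounded away from zero, the convention
#' used for every percentage in run reports (e.g. 81.74 -> 82, 58.79 -> 59).
#'
#' @param numerator,denominator components of the fraction.
#' @return Integer percentage.
#' @export
#' @examples
#' pct_round(8522, 10426)   # 82
pct_round <- function(numerator, denominator) {
  p <- 100 * numerator / denominator
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

# Canonical junction-chain key: introns in genomic-ascending order as
# "lower-upper;lower-upper;...". Mono-exonic transcripts have the empty chain.
chain_key <- function(lower, upper) {
  if (length(lower) == 0L) return("")
  o <- order(lower)
  paste(lower[o], upper[o], sep = "-", collapse = ";")
}

chain_to_introns <- function(chain) {
  if (is.na(chain) || !nzchar(chain)) {
    return(data.frame(lower = integer(0), upper = integer(0)))
  }
  parts <- strsplit(strsplit(chain, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  data.frame(lower = as.integer(vapply(parts, `[`, "", 1L)),
             upper = as.integer(vapply(parts, `[`, "", 2L)))
}

# Introns of one transcript from its exon table (0-based half-open, any row
# order). Donor/acceptor roles are strand-aware: the donor is the intron's
# 5' boundary in transcript orientation.
exons_to_introns <- function(exons) {
  stopifnot(nrow(exons) >= 1L)
  o <- order(exons$start)
  st <- exons$start[o]; en <- exons$end[o]
  n <- length(st)
  if (n == 1L) {
    return(data.frame(lower = integer(0), upper = integer(0),
                      donor = integer(0), acceptor = integer(0)))
  }
  lower <- en[-n]
  upper <- st[-1L]
  if (any(upper <= lower)) {
    stop("overlapping or abutting exons in transcript ", exons$transcript_id[1])
  }
  minus <- identical(exons$strand[1], "-")
  data.frame(lower = lower, upper = upper,
             donor = if (minus) upper else lower,
             acceptor = if (minus) lower else upper)
}

site_key <- function(chrom, strand) paste(chrom, strand, sep = "|")

# Numeric suffix of a PB-style accession (PB.<cluster>.<n> -> n); used as the
# deterministic tie-break for equally abundant isoforms.
pb_suffix <- function(pb) {
  suppressWarnings(as.integer(sub(".*\\.", "", pb)))
}

# Run code under a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All generator randomness flows through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Translate a nucleotide string (assumed in-frame from position 1) into amino
# acids, stopping before the first stop codon or the first untranslatable
# codon (any codon containing a base outside ACGT). Returns the peptide and
# whether a stop codon was reached.
translate_cds <- function(nt) {
  n <- (nchar(nt) %/% 3L) * 3L
  if (n == 0L) return(list(protein = "", stopped = FALSE))
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  bad <- is.na(aa)
  stop_at <- which(aa == "*" & !bad)[1]
  cut <- suppressWarnings(min(which(bad)[1], stop_at, na.rm = TRUE))
  if (is.infinite(cut)) {
    list(protein = paste(aa, collapse = ""), stopped = FALSE)
  } else {
    list(protein = if (cut > 1) paste(aa[seq_len(cut - 1L)], collapse = "") else "",
         stopped = !is.na(stop_at) && cut == stop_at)
  }
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
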