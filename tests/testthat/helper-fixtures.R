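# Shared fixtures and independent brute-force oracles. The smoke fixture is
# generated once per test run and cached; every oracle below is written from
# first principles (no package helpers) so it can referee the implementation.

.fixture_cache <- new.env(parent = emptyenv())

smoke_fixture <- function(seed = 1) {
  key <- paste0("fx", seed)
  if (!exists(key, .fixture_cache)) {
    dir <- file.path(tempdir(), paste0("protiso-fixture-", seed))
    assign(key, end_to_end_fixture(smoke_config(seed = seed), dir),
           .fixture_cache)
  }
  get(key, .fixture_cache)
}

# --- toy two-gene annotation written as real files -------------------------

toy_reference_files <- function() {
  if (exists("toy", .fixture_cache)) return(get("toy", .fixture_cache))
  dir <- file.path(tempdir(), "protiso-toy")
  dir.create(dir, showWarnings = FALSE)
  # gene A (+ strand, chrT1): three transcripts; gene B (- strand, chrT2):
  # a coding two-exon transcript and a mono-exonic non-coding transcript
  genome <- c(
    chrT1 = paste0(strrep("ACT", 40),                       # 120 pad
                   "ATG", strrep("GCT", 9), "AAA",          # exon A1 CDS part
                   strrep("T", 50),                          # intron 1
                   strrep("GAC", 10),                        # exon A2
                   strrep("C", 60),                          # intron 2
                   strrep("GGA", 8), "TAA", strrep("TCA", 10), # exon A3 + stop
                   strrep("A", 100)),
    chrT2 = paste0(strrep("T", 100),
                   strrep("A", 400),
                   strrep("G", 100)))
  # chrT1 layout (0-based): exon1 [120,153), intron1 [153,203),
  # exon2 [203,233), intron2 [233,293), exon3 [293,350)
  gtf <- c(
    sprintf('chrT1\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-201";', 121, 153),
    sprintf('chrT1\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-201";', 204, 233),
    sprintf('chrT1\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-201";', 294, 350),
    sprintf('chrT1\ttoy\tCDS\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-201";', 121, 153),
    sprintf('chrT1\ttoy\tCDS\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-201";', 204, 233),
    sprintf('chrT1\ttoy\tCDS\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-201";', 294, 320),
    # GA-202 skips exon 2
    sprintf('chrT1\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-202";', 121, 153),
    sprintf('chrT1\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-202";', 294, 350),
    sprintf('chrT1\ttoy\tCDS\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-202";', 121, 153),
    sprintf('chrT1\ttoy\tCDS\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-202";', 294, 320),
    # GA-203: non-coding, alternative 3' exon start
    sprintf('chrT1\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-203";', 121, 153),
    sprintf('chrT1\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id "GA"; transcript_id "GA-203";', 204, 350),
    # gene B: two-exon coding on minus strand
    sprintf('chrT2\ttoy\texon\t%d\t%d\t.\t-\t.\tgene_id "GB"; transcript_id "GB-201";', 151, 300),
    sprintf('chrT2\ttoy\texon\t%d\t%d\t.\t-\t.\tgene_id "GB"; transcript_id "GB-201";', 401, 500),
    # GB-202: mono-exonic
    sprintf('chrT2\ttoy\texon\t%d\t%d\t.\t-\t.\tgene_id "GB"; transcript_id "GB-202";', 181, 300))
  gtf_path <- file.path(dir, "toy.gtf")
  writeLines(gtf, gtf_path)
  fa_path <- file.path(dir, "toy.fa")
  writeLines(c(">chrT1", genome[["chrT1"]], ">chrT2", genome[["chrT2"]]),
             fa_path)
  appris_path <- file.path(dir, "toy_appris.tsv")
  writeLines(c("gene_id\ttranscript_id\tappris_label",
               "GA\tGA-201\tPRINCIPAL:1"), appris_path)
  out <- list(gtf = gtf_path, genome = fa_path, appris = appris_path,
              dir = dir)
  assign("toy", out, .fixture_cache)
  out
}

toy_catalog <- function() {
  f <- toy_reference_files()
  load_annotation(f$gtf, f$genome, f$appris)
}

# --- independent oracles ---------------------------------------------------

# tryptic digest by exhaustive enumeration over cleavage-site windows
oracle_digest <- function(seq, missed = 2, min_len = 7, max_len = 50) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sites <- integer(0)
  for (i in seq_len(max(0, n - 1))) {
    if (ch[i] %in% c("K", "R") && ch[i + 1] != "P") sites <- c(sites, i)
  }
  bounds <- c(0, sites, n)
  out <- character(0)
  for (a in seq_len(length(bounds) - 1)) {
    for (b in a:min(length(bounds) - 1, a + missed)) {
      p <- paste(ch[(bounds[a] + 1):bounds[b + 1]], collapse = "")
      if (nchar(p) >= min_len && nchar(p) <= max_len) out <- c(out, p)
    }
  }
  unique(out)
}

# ORF enumeration by scanning every position and walking codons
oracle_orfs <- function(seq, min_nt = 50) {
  n <- nchar(seq)
  out <- list()
  n_aug <- 0L
  for (p in seq_len(max(0, n - 2))) {
    if (substring(seq, p, p + 2) != "ATG") next
    n_aug <- n_aug + 1L
    prot <- ""
    q <- p
    has_stop <- FALSE
    end <- n  # default: transcript end
    while (q + 2 <= n) {
      codon <- substring(seq, q, q + 2)
      if (grepl("[^ACGT]", codon)) { end <- q - 1; break }
      aa <- Biostrings::GENETIC_CODE[[codon]]
      if (aa == "*") { has_stop <- TRUE; end <- q + 2; break }
      prot <- paste0(prot, aa)
      q <- q + 3
    }
    len <- end - p + 1
    if (len >= min_nt && nchar(prot) > 0) {
      out[[length(out) + 1]] <- data.frame(
        start_nt = p - 1L, stop_nt = end, has_stop = has_stop,
        orf_nt_length = len, protein = prot,
        upstream_augs_skipped = n_aug - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start_nt = integer(0), stop_nt = integer(0),
                      has_stop = logical(0), orf_nt_length = integer(0),
                      protein = character(0),
                      upstream_augs_skipped = integer(0)))
  }
  do.call(rbind, out)
}

# transcript classification by enumerating every reference chain and site
oracle_classify <- function(exons, gene_id, catalog) {
  ref_ex <- catalog$exons
  if (is.na(gene_id)) return("OTHER")
  if (nrow(exons) == 1L) {
    ok <- FALSE
    for (tid in unique(ref_ex$transcript_id[ref_ex$gene_id == gene_id])) {
      re <- ref_ex[ref_ex$transcript_id == tid, ]
      if (nrow(re) == 1L && exons$start >= re$start && exons$end <= re$end)
        ok <- TRUE
    }
    return(if (ok) "FSM" else "OTHER")
  }
  introns_of <- function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    data.frame(lo = e$end[-nrow(e)], hi = e$start[-1])
  }
  q <- introns_of(exons)
  # all annotated boundary positions on this chrom/strand, with roles
  donors <- integer(0); acceptors <- integer(0)
  for (tid in unique(ref_ex$transcript_id)) {
    re <- ref_ex[ref_ex$transcript_id == tid, ]
    if (re$chrom[1] != exons$chrom[1] || re$strand[1] != exons$strand[1]) next
    ri <- introns_of(re)
    if (is.null(ri)) next
    if (re$strand[1] == "+") {
      donors <- c(donors, ri$lo); acceptors <- c(acceptors, ri$hi)
    } else {
      donors <- c(donors, ri$hi); acceptors <- c(acceptors, ri$lo)
    }
  }
  qd <- if (exons$strand[1] == "+") q$lo else q$hi
  qa <- if (exons$strand[1] == "+") q$hi else q$lo
  if (any(!(qd %in% donors)) || any(!(qa %in% acceptors))) return("NNC")
  chain <- paste(q$lo, q$hi, collapse = ";")
  for (tid in unique(ref_ex$transcript_id[ref_ex$gene_id == gene_id])) {
    ri <- introns_of(ref_ex[ref_ex$transcript_id == tid, ])
    if (!is.null(ri) && identical(paste(ri$lo, ri$hi, collapse = ";"), chain))
      return("FSM")
  }
  "NIC"
}

# random amino-acid string
rand_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# minimal hybrid_db for handcrafted evidence tests
make_toy_db <- function(entries) {
  entries$label <- entries$label
  rownames(entries) <- entries$label
  genes <- unique(entries$gene_id[!is.na(entries$gene_id)])
  structure(list(entries = entries,
                 gene_source = stats::setNames(rep("PACBIO", length(genes)),
                                               genes),
                 thresholds = list()), class = "hybrid_db")
}
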