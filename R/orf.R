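# ORF calling: enumerate AUG-initiated candidate ORFs on spliced transcript
# sequences, score coding potential, and select the most plausible ORF per
# transcript by a strict lexicographic rule (annotated start first, then
# fewest upstream AUGs skipped, coding potential, length, position).

#' Enumerate candidate open reading frames
#'
#' Scans the sense strand of a spliced transcript sequence for AUG-initiated
#' ORFs. Each candidate runs from an AUG to the first in-frame stop codon
#' (`has_stop = TRUE`) or to the transcript end (`has_stop = FALSE`). The
#' length filter counts start through stop codon inclusive. Nested ORFs that
#' share a stop but start at different AUGs are distinct candidates. A codon
#' containing a non-ACGT base is untranslatable and truncates the candidate
#' before it.
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @param min_nt minimum ORF length in nucleotides (default 50).
#' @return data.frame with start_nt, stop_nt (0-based; stop_nt is the first
#'   base after the stop codon, or the scan end), has_stop, orf_nt_length,
#'   protein, upstream_augs_skipped.
#' @export
enumerate_candidate_orfs <- function(seq, min_nt = 50) {
  L <- nchar(seq)
  empty <- data.frame(start_nt = integer(0), stop_nt = integer(0),
                      has_stop = logical(0), orf_nt_length = integer(0),
                      protein = character(0), upstream_augs_skipped = integer(0))
  if (L < 3L) return(empty)
  augs <- as.integer(gregexpr("ATG", seq, fixed = TRUE)[[1]])
  if (augs[1] == -1L) return(empty)
  augs <- augs - 1L  # 0-based
  rows <- lapply(seq_along(augs), function(i) {
    p <- augs[i]
    tr <- translate_cds(substring(seq, p + 1L, L))
    prot_nt <- nchar(tr$protein) * 3L
    stop_nt <- if (tr$stopped) p + prot_nt + 3L else {
      # no stop: measured to transcript end (or to the untranslatable codon)
      p + if (grepl("N", substring(seq, p + 1L, L), fixed = TRUE))
        prot_nt else (L - p)
    }
    len <- stop_nt - p
    data.frame(start_nt = p, stop_nt = stop_nt, has_stop = tr$stopped,
               orf_nt_length = len, protein = tr$protein,
               upstream_augs_skipped = i - 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$orf_nt_length >= min_nt & nchar(out$protein) > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fickett-style codon-position composition score in [0, 1): mean positional
# asymmetry of the four bases across the three codon positions, plus nothing
# else. Higher values indicate stronger periodic base usage, a hallmark of
# coding sequence.
fickett_score <- function(nt) {
  n <- (nchar(nt) %/% 3L) * 3L
  if (n < 3L) return(0)
  ch <- strsplit(substring(nt, 1L, n), "")[[1]]
  pos <- rep(1:3, length.out = n)
  asym <- vapply(c("A", "C", "G", "T"), function(b) {
    cnt <- tabulate(pos[ch == b], 3L)
    mx <- max(cnt); mn <- min(cnt)
    (mx - mn) / (mx + mn + 1)
  }, 0)
  mean(asym)
}

#' Coding-potential score for a candidate ORF
#'
#' A deterministic logistic model of three features: ORF coverage of the
#' transcript, ORF length in codons (capped contribution at 100 codons), and
#' a Fickett-style codon-position composition score. The score is monotone
#' non-decreasing in ORF coverage for fixed composition. The scorer is
#' pluggable: pass `score_table` to [call_orfs()] to substitute externally
#' computed scores keyed by (transcript, start).
#'
#' @param orf_seq the ORF nucleotide sequence (start through stop).
#' @param transcript_len length of the host transcript in nt.
#' @param coef named coefficients (intercept, coverage, length, composition).
#' @return score in \[0, 1\].
#' @export
score_coding_potential <- function(orf_seq, transcript_len,
                                   coef = c(intercept = -4, coverage = 3,
                                            length = 2.5, composition = 2)) {
  coverage <- nchar(orf_seq) / transcript_len
  len_feat <- min(nchar(orf_seq) / 3 / 100, 1)
  comp <- fickett_score(orf_seq)
  eta <- coef[["intercept"]] + coef[["coverage"]] * coverage +
    coef[["length"]] * len_feat + coef[["composition"]] * comp
  1 / (1 + exp(-eta))
}

#' Select the best ORF among candidates
#'
#' Strict lexicographic ranking: (1) start codon at an annotated reference
#' start position; (2) fewer upstream AUGs skipped; (3) higher coding
#' potential; (4) longer ORF; (5) smaller start position. The returned row
#' carries `selection_tier`, the first rule that separated the winner from
#' the runner-up (`"only"` for a single candidate).
#'
#' @param candidates data.frame with start_matches_reference,
#'   upstream_augs_skipped, coding_potential, orf_nt_length, start_nt.
#' @return the winning row with a `selection_tier` column.
#' @export
select_best_orf <- function(candidates) {
  stopifnot(nrow(candidates) >= 1L)
  o <- order(-candidates$start_matches_reference,
             candidates$upstream_augs_skipped,
             -candidates$coding_potential,
             -candidates$orf_nt_length,
             candidates$start_nt)
  best <- candidates[o[1], , drop = FALSE]
  if (nrow(candidates) == 1L) {
    best$selection_tier <- "only"
    return(best)
  }
  second <- candidates[o[2], , drop = FALSE]
  tier <- if (best$start_matches_reference != second$start_matches_reference)
    "reference-start"
  else if (best$upstream_augs_skipped != second$upstream_augs_skipped)
    "fewest-skipped"
  else if (best$coding_potential != second$coding_potential)
    "coding-potential"
  else if (best$orf_nt_length != second$orf_nt_length)
    "length"
  else "accession-order"
  best$selection_tier <- tier
  best
}

#' Locate the stop codon genomically and count downstream junctions
#'
#' Maps the last base of the stop codon through the exon chain and counts the
#' transcript's junctions strictly 3' (in transcript orientation) of that
#' base — the quantity used to flag NMD suspects (more than two junctions
#' after the stop codon).
#'
#' @param stop_nt transcript offset of the first base after the stop codon.
#' @param exons exon table of the transcript.
#' @param has_stop whether the ORF ends in a stop codon.
#' @return list(stop_genomic, junctions_after_stop); `junctions_after_stop`
#'   is NA for stop-less ORFs.
#' @export
locate_stop_and_junctions <- function(stop_nt, exons, has_stop = TRUE) {
  stop_genomic <- tx_to_genomic(exons, stop_nt - 1L)
  if (!has_stop) {
    return(list(stop_genomic = stop_genomic, junctions_after_stop = NA_integer_))
  }
  jx <- tx_junction_offsets(exons)
  list(stop_genomic = stop_genomic,
       junctions_after_stop = sum(jx >= stop_nt))
}

#' Call the best ORF for every transcript
#'
#' Runs candidate enumeration, reference-start annotation, coding-potential
#' scoring and lexicographic selection per transcript, then locates the stop
#' codon genomically. Transcripts with no candidate ORF are marked non-coding
#' and excluded from the output.
#'
#' @param lr an `lr_transcripts` object (gene-assigned).
#' @param catalog a `ref_catalog`.
#' @param min_nt minimum candidate ORF length (nt).
#' @param score_table optional data.frame (pb_accession, start_nt, score)
#'   replacing the built-in coding-potential model where keyed.
#' @return data.frame of best ORFs: pb_accession, gene_id, start_nt, stop_nt,
#'   has_stop, orf_nt_length, protein, coding_potential,
#'   start_matches_reference, upstream_augs_skipped, start_genomic,
#'   stop_genomic, junctions_after_stop, selection_tier.
#' @export
call_orfs <- function(lr, catalog, min_nt = 50, score_table = NULL) {
  ex_by_tx <- split(lr$exons, lr$exons$transcript_id)
  rows <- lapply(lr$transcripts$pb_accession, function(id) {
    cand <- enumerate_candidate_orfs(lr$seqs[[id]], min_nt = min_nt)
    if (nrow(cand) == 0L) return(NULL)
    exons <- ex_by_tx[[id]]
    gid <- lr$transcripts[id, "gene_id"]
    cand$start_genomic <- tx_to_genomic(exons, cand$start_nt)
    starts <- if (!is.na(gid)) catalog$gene_starts[[gid]] else integer(0)
    cand$start_matches_reference <- cand$start_genomic %in% starts
    cand$coding_potential <- vapply(seq_len(nrow(cand)), function(i) {
      ext <- NULL
      if (!is.null(score_table)) {
        hit <- score_table$score[score_table$pb_accession == id &
                                   score_table$start_nt == cand$start_nt[i]]
        if (length(hit)) ext <- hit[1]
      }
      if (!is.null(ext)) ext else
        score_coding_potential(substring(lr$seqs[[id]], cand$start_nt[i] + 1L,
                                         cand$stop_nt[i]),
                               nchar(lr$seqs[[id]]))
    }, 0)
    best <- select_best_orf(cand)
    loc <- locate_stop_and_junctions(best$stop_nt, exons, best$has_stop)
    cbind(data.frame(pb_accession = id, gene_id = gid, stringsAsFactors = FALSE),
          best[, c("start_nt", "stop_nt", "has_stop", "orf_nt_length", "protein",
                   "coding_potential", "start_matches_reference",
                   "upstream_augs_skipped", "start_genomic", "selection_tier")],
          data.frame(stop_genomic = loc$stop_genomic,
                     junctions_after_stop = loc$junctions_after_stop))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  rownames(out) <- out$pb_accession
  out
}
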