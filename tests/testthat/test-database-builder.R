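mk_orfs <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df
}

test_that("protein filtering applies truncation, class and NMD rules in order", {
  orfs <- mk_orfs(
    pb_accession = paste0("PB.1.", 1:6),
    has_stop = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    pclass = c("pNNC", "pOTHER", "pNNC", "pNNC", "pFSM", "pNIC"),
    junctions_after_stop = c(NA, 0, 3, 2, 3, 5))
  f <- filter_protein_isoforms(orfs)
  expect_equal(f$ledger$reason,
               c("truncation", "class", "NMD", NA, NA, NA))
  # pNNC with exactly 2 junctions after stop retained ("more than two")
  expect_true("PB.1.4" %in% f$retained$pb_accession)
  # NMD scope: pFSM/pNIC exempt even with 3+ junctions after the stop
  expect_true(all(c("PB.1.5", "PB.1.6") %in% f$retained$pb_accession))
  # conservation: retained + removals partition the input
  expect_equal(nrow(f$retained) + sum(!is.na(f$ledger$reason)), nrow(orfs))
})

test_that("grouping identical ORF sequences sums CPM and picks the top member", {
  lr <- list(transcripts = data.frame(
    pb_accession = c("PB.9356.17", "PB.9356.21", "PB.1.3"),
    cpm = c(103.8, 68.4, 7),
    row.names = c("PB.9356.17", "PB.9356.21", "PB.1.3")))
  class(lr) <- "lr_transcripts"
  ret <- mk_orfs(pb_accession = c("PB.9356.17", "PB.9356.21", "PB.1.3"),
                 gene_id = c("SRSF5", "SRSF5", "G1"),
                 protein = c("MKLV", "MKLV", "MAAA"),
                 pclass = c("pFSM", "pFSM", "pNIC"))
  g <- group_orfs_by_sequence(ret, lr)
  srsf5 <- g[g$gene_id == "SRSF5", ]
  expect_equal(nrow(srsf5), 1)
  expect_equal(srsf5$cpm_sum, 172.2)
  expect_equal(srsf5$representative, "PB.9356.17")  # highest CPM member
  expect_equal(nrow(g), 2)
  # all-distinct sequences: one entry per input
  ret2 <- ret; ret2$protein <- c("MKLV", "MXLV", "MAAA")
  expect_equal(nrow(group_orfs_by_sequence(ret2, lr)), 3)
})

test_that("high-confidence gene selection uses inclusive CPM and length bounds", {
  fx <- smoke_fixture()
  cat <- fx$objects$catalog
  pick_len <- cat$genes$gene_id[cat$genes$mean_len >= 1000 &
                                  cat$genes$mean_len <= 4000][1]
  s <- data.frame(gene_id = rep(pick_len, 3), total_gene_cpm = c(3.0, 2.9, 50))
  expect_equal(select_high_confidence_genes(s[1, ], cat), pick_len)   # 3.0 in
  expect_equal(select_high_confidence_genes(s[2, ], cat), character(0))
  short <- cat$genes$gene_id[cat$genes$mean_len < 1000][1]
  s2 <- data.frame(gene_id = short, total_gene_cpm = 50)
  expect_equal(select_high_confidence_genes(s2, cat), character(0))
  expect_warning(
    select_high_confidence_genes(data.frame(gene_id = "NOPE",
                                            total_gene_cpm = 9), cat),
    "absent")
})

test_that("hybrid database partitions genes by source and formats labels", {
  fx <- smoke_fixture()
  cat <- fx$objects$catalog
  grouped <- fx$objects$grouped
  db <- fx$objects$db
  # partition: every catalog gene appears exactly once in the source map
  expect_equal(sort(names(db$gene_source)), sort(cat$genes$gene_id))
  # each gene's entries come from exactly one source
  gent <- db$entries[!is.na(db$entries$gene_id), ]
  by_gene <- split(gent$source, gent$gene_id)
  expect_true(all(vapply(by_gene, function(x) length(unique(x)) == 1, TRUE)))
  # PacBio label format <Gene>|<PB accession>|<class>|<CPM, one decimal>
  pb <- db$entries[db$entries$source == "PACBIO", ]
  expect_true(all(grepl("^[^|]+\\|PB\\.\\d+\\.\\d+\\|p(FSM|NIC|NNC)\\|\\d+\\.\\d$",
                        pb$label)))
  # within any gene, entry sequences are pairwise distinct, and PacBio
  # cpm_sum totals the gene's protein-yielding retained transcripts
  for (g in unique(pb$gene_id)) {
    seqs <- db$entries$sequence[!is.na(db$entries$gene_id) &
                                  db$entries$gene_id == g]
    expect_equal(anyDuplicated(seqs), 0)
    ret <- fx$objects$filt$retained
    members <- ret$pb_accession[ret$gene_id == g]
    expect_equal(sum(pb$cpm_sum[pb$gene_id == g]),
                 sum(fx$objects$lr$transcripts[members, "cpm"]),
                 tolerance = 1e-9)
  }
  # genes absent from the long-read data carry reference entries
  absent <- setdiff(cat$genes$gene_id, fx$objects$lr$transcripts$gene_id)
  if (length(absent)) {
    expect_true(all(db$gene_source[absent] == "GENCODE"))
    expect_true(all(absent %in% db$entries$gene_id))
  }
  # duplicate labels are a hard error
  dup <- grouped[grouped$gene_id %in% fx$objects$high_conf, ][1, ]
  expect_error(build_hybrid_database(rbind(grouped, dup), cat,
                                     fx$objects$high_conf),
               "duplicate")
})

test_that("empty long-read input degenerates to reference plus contaminants", {
  cat <- toy_catalog()
  empty <- group_orfs_by_sequence(
    data.frame(pb_accession = character(0), gene_id = character(0),
               protein = character(0), pclass = character(0)),
    structure(list(transcripts = data.frame(pb_accession = character(0),
                                            cpm = numeric(0))),
              class = "lr_transcripts"))
  db <- build_hybrid_database(empty, cat, character(0),
                              contaminants = c("CONT_1|x" = "MKKKKKKRRRR"))
  expect_equal(sort(unique(db$entries$source)), c("CONTAMINANT", "GENCODE"))
  expect_true(all(db$gene_source == "GENCODE"))
})

test_that("FASTA and BED12 writers round-trip structure exactly", {
  entry <- data.frame(label = "CDH5|PB.10443.2|pFSM|2402.9", gene_id = "g",
                      gene_name = "CDH5", sequence = "MKLVVDE",
                      source = "PACBIO", pclass = "pFSM", cpm_sum = 2402.9,
                      representative = "PB.10443.2", members = "PB.10443.2")
  db <- make_toy_db(entry)
  # label formatting straight from the grouped entry fields
  grouped <- data.frame(gene_id = "g", sequence = "MKLVVDE", cpm_sum = 2402.9,
                        representative = "PB.10443.2", pclass = "pFSM",
                        members = "PB.10443.2", n_members = 1)
  cat <- toy_catalog()
  cat$genes <- rbind(cat$genes,
                     data.frame(gene_id = "g", gene_name = "CDH5",
                                chrom = "chrT1", strand = "+",
                                n_transcripts = 0, mean_len = 2000,
                                row.names = "g"))
  db2 <- build_hybrid_database(grouped, cat, "g")
  expect_true("CDH5|PB.10443.2|pFSM|2402.9" %in% db2$entries$label)

  fa <- tempfile(fileext = ".fa")
  write_protein_fasta(db, fa)
  back <- read_fasta(fa, "aa")
  expect_equal(names(back), db$entries$label)
  expect_equal(unname(back), db$entries$sequence)

  bed <- tempfile(fileext = ".bed")
  exons <- data.frame(transcript_id = "PB.1.1", chrom = "chr1",
                      start = c(100, 300, 600), end = c(200, 400, 700),
                      strand = "+")
  write_bed12(exons, bed)
  rec <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(rec[10]), 3)  # blockCount
  sizes <- as.integer(strsplit(rec[11], ",")[[1]])
  expect_equal(sum(sizes), sum(exons$end - exons$start))
  starts <- as.integer(strsplit(rec[12], ",")[[1]])
  expect_equal(as.integer(rec[2]) + starts + sizes,
               c(200, 400, 700))
})
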