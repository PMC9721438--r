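test_that("q-value tiers: inclusive 1% reporting, strict novel tier", {
  p <- data.frame(sequence = c("a", "b", "c"), q_value = c(0.01, 0.011, 0.001),
                  psm_count = 1)
  expect_equal(filter_identifications(p)$sequence, c("a", "c"))
  # strict tier is exclusive at 0.001
  m <- data.frame(sequence = c("x", "y"), q_value = c(0.001, 0.0009),
                  psm_count = 1, mapped = TRUE, entries = "E", n_entries = 1,
                  n_genes = 1, genes = "g", unique_isoform = TRUE,
                  multi_gene = FALSE)
  nov <- detect_novel_peptides(m, list(character(0)))
  expect_equal(nov$sequence, "y")
  # counting: 100 synthetic peptides, 7 above threshold
  set.seed(1)
  p2 <- data.frame(sequence = sprintf("P%03d", 1:100),
                   q_value = c(runif(93, 0, 0.01), runif(7, 0.02, 0.2)),
                   psm_count = 1)
  expect_equal(nrow(filter_identifications(p2)), 93)
})

test_that("tryptic digestion follows K/R-not-before-P with missed cleavages", {
  expect_setequal(digest_protein("AAKBBRPCC", 0, min_len = 1, max_len = 50),
                  c("AAK", "BBRPCC"))
  expect_setequal(digest_protein("AAKBBRPCC", 1, min_len = 1, max_len = 50),
                  c("AAK", "BBRPCC", "AAKBBRPCC"))
  # brute-force enumeration oracle on random proteins
  set.seed(2)
  for (i in 1:200) {
    prot <- rand_protein(sample(30:300, 1))
    expect_setequal(digest_protein(prot), oracle_digest(prot))
  }
  # digest_reference is the union over proteins
  prots <- replicate(5, rand_protein(100))
  expect_setequal(digest_reference(prots),
                  unique(unlist(lapply(prots, oracle_digest))))
})

test_that("peptide mapping equals a naive digest-legal scan and flags uniqueness", {
  entries <- data.frame(
    label = c("g1|E1", "g1|E2", "g2|E3", "CONT"),
    gene_id = c("g1", "g1", "g2", NA),
    gene_name = c("g1", "g1", "g2", NA),
    sequence = c("MAAAKLLLRDDDK", "MAAAKWWWRDDDK", "MCCCKLLLR", "MPPPKFFFR"),
    source = c("PACBIO", "PACBIO", "GENCODE", "CONTAMINANT"),
    pclass = c("pFSM", "pNIC", NA, NA), cpm_sum = c(10, 30, NA, NA),
    representative = c("PB.1.1", "PB.1.2", "T1", NA),
    members = "")
  db <- make_toy_db(entries)
  peps <- data.frame(sequence = c("LLLR", "DDDK", "WWWR", "NOPEK", "LLLRDDDK"),
                     q_value = 0.001, psm_count = 2)
  m <- map_peptides(peps, db, min_len = 4)
  # naive oracle: digest every entry and scan
  for (i in seq_len(nrow(peps))) {
    hits <- which(vapply(entries$sequence, function(s)
      peps$sequence[i] %in% oracle_digest(s, 2, 4, 50), TRUE))
    expect_equal(m$n_entries[i], length(hits))
    expect_setequal(strsplit(m$entries[i], ";")[[1]],
                    entries$label[hits])
  }
  expect_true(m$multi_gene[m$sequence == "LLLR"])   # g1 and g2
  expect_true(m$unique_isoform[m$sequence == "WWWR"])
  expect_false(m$mapped[m$sequence == "NOPEK"])
  expect_true(m$unique_isoform[m$sequence == "LLLRDDDK"])  # E1 only, 1 missed
  # substring mode relaxes termini
  m2 <- map_peptides(data.frame(sequence = "AAAKLL", q_value = 0, psm_count = 1),
                     db, substring_mode = TRUE)
  expect_true(m2$mapped)
})

test_that("gene scenarios partition evidenced genes", {
  entries <- data.frame(
    label = c("gS|E0", "gA|E1", "gA|E2", "gB|E3", "gB|E4", "gC|E5", "gC|E6"),
    gene_id = c("gS", "gA", "gA", "gB", "gB", "gC", "gC"),
    gene_name = NA, sequence = c(
      "MSSSKDDDR",
      "MAAAKCCCRDDDK", "MAAAKWWWRDDDK",
      "MFFFKCCCR", "MFFFKYYYR",
      "MGGGKHHHR", "MGGGKIIIR"),
    source = "PACBIO", pclass = "pFSM",
    cpm_sum = c(5, 40, 10, 30, 24.9, 100, 26),
    representative = paste0("PB.", 1:7, ".1"), members = "")
  db <- make_toy_db(entries)
  peps <- data.frame(
    sequence = c("MSSSK",           # gS: single-entry gene
                 "MAAAK",           # gA: shared between E1/E2
                 "MFFFK", "CCCR",   # gB: shared + unique to E3 (CCCR also gA E1!)
                 "HHHR", "IIIR"),   # gC: unique to both entries
    q_value = 0.001, psm_count = 3)
  m <- map_peptides(peps, db, min_len = 4)
  sc <- classify_gene_scenarios(m, db)
  expect_equal(sc["gS", "scenario"], "SINGLE_ISOFORM_IN_DB")
  expect_equal(sc["gA", "scenario"], "SHARED_ONLY")
  expect_equal(sc["gC", "scenario"], "MULTI_CONFIRMED")
  # CCCR occurs in gA and gB -> multi-gene, excluded; gB left shared-only
  expect_equal(sc["gB", "scenario"], "SHARED_ONLY")
  expect_equal(nrow(sc), 4)

  # nominations at the inclusive 25-CPM boundary
  sc2 <- nominate_by_transcript_abundance(sc, db)
  expect_equal(sc2["gA", "nomination"], "NOMINATED_AMBIGUOUS")
  expect_equal(sc2["gA", "nominated_entries"], "gA|E1")  # 40 in, 10 out
  # gB: 30 nominated, 24.9 below the floor
  expect_equal(sc2["gB", "nominated_entries"], "gB|E3")
  expect_false(sc2["gB", "coexpression_nominated"])
  # MULTI_CONFIRMED genes are not nominated
  expect_equal(sc2["gC", "nomination"], "NONE")
  # exactly 25 qualifies; 24.9 does not
  db25 <- db
  db25$entries$cpm_sum[db25$entries$label == "gB|E4"] <- 25
  sc25 <- nominate_by_transcript_abundance(sc, db25)
  expect_setequal(strsplit(sc25["gB", "nominated_entries"], ";")[[1]],
                  c("gB|E3", "gB|E4"))
  expect_true(sc25["gB", "coexpression_nominated"])
  # monotonicity: raising cpm_min never adds nominations
  n_nom <- vapply(c(10, 25, 40, 200), function(cm) {
    s <- nominate_by_transcript_abundance(sc, db, cm)
    sum(nchar(s$nominated_entries) > 0)
  }, 0)
  expect_true(all(diff(n_nom) <= 0))
})

test_that("ONE_CONFIRMED genes nominate only unconfirmed abundant entries", {
  entries <- data.frame(
    label = c("gP|E1", "gP|E2", "gP|E3", "gP|E4"),
    gene_id = "gP", gene_name = NA,
    sequence = c("MAAAKSDSR", "MAAAKTTTR", "MAAAKVVVR", "MAAAKQQQR"),
    source = "PACBIO", pclass = "pNIC",
    cpm_sum = c(12, 75, 79, 543),
    representative = paste0("PB.9.", 1:4), members = "")
  db <- make_toy_db(entries)
  peps <- data.frame(sequence = c("MAAAK", "SDSR"), q_value = 1e-4,
                     psm_count = 5)
  m <- map_peptides(peps, db, min_len = 4)
  sc <- nominate_by_transcript_abundance(classify_gene_scenarios(m, db), db)
  expect_equal(sc$scenario, "ONE_CONFIRMED")
  expect_equal(sc$nomination, "NOMINATED_ADDITIONAL")
  # the confirmed entry (E1) is excluded; the three abundant others nominated
  expect_setequal(strsplit(sc$nominated_entries, ";")[[1]],
                  c("gP|E2", "gP|E3", "gP|E4"))
})

test_that("novel peptides are sound against reference digests", {
  fx <- smoke_fixture()
  db <- fx$objects$db
  catalog <- fx$objects$catalog
  peps <- fx$objects$peptides$peptides
  mp <- map_peptides(filter_identifications(peps), db)
  gdig <- digest_reference(group_reference_proteins(catalog)$sequence)
  udig <- digest_reference(read_fasta(fx$paths$uniprot, "aa"))
  nov <- detect_novel_peptides(mp, list(gdig, udig))
  # soundness: every reported novel peptide is absent from both digests
  expect_true(all(!(nov$sequence %in% gdig)))
  expect_true(all(!(nov$sequence %in% udig)))
  expect_true(all(nov$q_value < 0.001))
  # replacing the sample database by the reference yields zero novels
  refp <- group_reference_proteins(catalog)
  ref_entries <- data.frame(label = paste0(refp$gene_id, "|", refp$accession),
                            gene_id = refp$gene_id, gene_name = refp$gene_name,
                            sequence = refp$sequence, source = "GENCODE",
                            pclass = NA, cpm_sum = NA,
                            representative = refp$accession, members = "")
  ref_db <- make_toy_db(ref_entries)
  mp_ref <- map_peptides(filter_identifications(peps), ref_db)
  expect_equal(nrow(detect_novel_peptides(mp_ref, list(gdig, udig))), 0)
  # I/L equivalence collapses I-for-L substitutions
  m_il <- data.frame(sequence = "MILK", q_value = 1e-4, psm_count = 1,
                     mapped = TRUE, entries = "E", n_entries = 1, n_genes = 1,
                     genes = "g", unique_isoform = TRUE, multi_gene = FALSE)
  expect_equal(nrow(detect_novel_peptides(m_il, list("MLLK"))), 1)
  expect_equal(nrow(detect_novel_peptides(m_il, list("MLLK"),
                                          il_equivalent = TRUE)), 0)
})

test_that("RNA-protein correlation is an OLS fit in log-log space", {
  s <- data.frame(gene_id = sprintf("g%d", 1:10),
                  total_gene_cpm = 10^seq(0, 3, length.out = 10) - 1)
  m <- data.frame(sequence = sprintf("P%d", 1:10), q_value = 0.001,
                  psm_count = 10^(0.5 + 0.9 * log10(s$total_gene_cpm + 1)) - 1,
                  mapped = TRUE, entries = "E", n_entries = 1, n_genes = 1,
                  genes = s$gene_id, unique_isoform = TRUE, multi_gene = FALSE)
  r <- suppressWarnings(rna_protein_correlation(s, m))  # exact fit warns
  expect_equal(r$r_squared, 1)          # exact linear relation
  expect_equal(r$slope, 0.9, tolerance = 1e-8)
  # constant PSM counts carry no signal
  m$psm_count <- 7
  expect_equal(suppressWarnings(rna_protein_correlation(s, m))$r_squared, 0)
  expect_error(rna_protein_correlation(s[1:2, ], m[1:2, ]),
               "insufficient pairs")
})
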