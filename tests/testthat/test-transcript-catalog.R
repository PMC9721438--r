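test_that("CPM definition, conservation, and the >= 1 CPM filter boundary", {
  expect_equal(unname(compute_cpm(c(t1 = 7))), 1e6)
  expect_equal(unname(compute_cpm(c(t1 = 3, t2 = 1))), c(750000, 250000))
  expect_error(compute_cpm(c(a = 0, b = 0)), "empty dataset")
  # at the study's printed read total, the smallest count reaching 1 CPM
  total <- 3608972
  min_count <- ceiling(total / 1e6)
  expect_equal(min_count, 4)
  cpm <- compute_cpm(stats::setNames(c(min_count, min_count - 1, total - 2 * min_count + 1),
                                     c("a", "b", "rest")))
  expect_true(cpm[["a"]] >= 1)
  expect_true(cpm[["b"]] < 1)
  expect_equal(sum(cpm), 1e6, tolerance = 1e-9)

  tr <- data.frame(pb = c("x", "y", "z"), cpm = c(1.0, 0.9, 5))
  kept <- filter_min_abundance(tr)
  expect_equal(kept$pb, c("x", "z"))  # boundary 1.0 retained, 0.9 removed
  # brute-force count on a simulated batch
  set.seed(42)
  cpms <- c(runif(40, 0.01, 0.99), runif(60, 1, 50))
  tr2 <- data.frame(cpm = sample(cpms))
  expect_equal(nrow(filter_min_abundance(tr2)), sum(cpms >= 1))
  # monotonicity: raising the floor never grows the retained set
  for (m in c(1, 2, 5, 10)) {
    expect_true(nrow(filter_min_abundance(tr2, m + 1)) <=
                  nrow(filter_min_abundance(tr2, m)))
  }
})

test_that("classification handles FSM identity, NIC combinations, NNC novel sites", {
  cat <- toy_catalog()
  e201 <- cat$exons[cat$exons$transcript_id == "GA-201",
                    c("transcript_id", "chrom", "start", "end", "strand")]
  cls <- classify_transcript(e201, "GA", cat)
  expect_equal(cls$category, "FSM")
  expect_equal(cls$matched_ref, "GA-201")
  # novel combination of known junctions: GA-203's first junction is
  # [153,203) and GA-202 contributes [153,293); combine known sites into an
  # unseen chain [233,293) alone -> all sites known, chain unseen
  e_nic <- e201[-1, ]
  cls2 <- classify_transcript(e_nic, "GA", cat)
  expect_equal(cls2$category, "NIC")
  # acceptor shifted 27 nt into the exon: site absent from the catalog
  e_nnc <- e201
  e_nnc$start[3] <- e_nnc$start[3] + 27
  cls3 <- classify_transcript(e_nnc, "GA", cat)
  expect_equal(cls3$category, "NNC")
  expect_equal(cls3$novel_sites, e201$start[3] + 27)
  # intergenic
  cls4 <- classify_transcript(e201, NA, cat)
  expect_equal(cls4$category, "OTHER")
  expect_equal(cls4$reason, "intergenic")
  # mono-exonic: FSM iff contained in a mono-exonic reference of the gene
  m_in <- data.frame(transcript_id = "m", chrom = "chrT2", start = 200,
                     end = 290, strand = "-")
  expect_equal(classify_transcript(m_in, "GB", cat)$category, "FSM")
  m_out <- data.frame(transcript_id = "m", chrom = "chrT2", start = 100,
                      end = 290, strand = "-")
  expect_equal(classify_transcript(m_out, "GB", cat)$category, "OTHER")
})

test_that("classification agrees with a brute-force oracle on random transcripts", {
  fx <- smoke_fixture()
  cat <- fx$objects$catalog
  set.seed(7)
  genes <- cat$genes$gene_id
  n_checked <- 0
  for (rep in 1:500) {
    gid <- sample(genes, 1)
    base_tid <- sample(cat$transcripts$transcript_id[cat$transcripts$gene_id == gid], 1)
    e <- cat$exons[cat$exons$transcript_id == base_tid,
                   c("transcript_id", "chrom", "start", "end", "strand")]
    op <- sample(c("keep", "skip", "shift_start", "shift_end", "merge"), 1)
    if (op == "skip" && nrow(e) > 2) {
      e <- e[-sample(2:(nrow(e) - 1), 1), ]
    } else if (op == "shift_start" && nrow(e) > 1) {
      k <- sample(2:nrow(e), 1)
      e$start[k] <- e$start[k] + sample(c(-5, 5, 9, 27), 1)
    } else if (op == "shift_end" && nrow(e) > 1) {
      k <- sample(1:(nrow(e) - 1), 1)
      e$end[k] <- e$end[k] - sample(c(5, 8, 9), 1)
    } else if (op == "merge" && nrow(e) > 2) {
      e <- e[order(e$start), ]
      e$end[1] <- e$end[2]
      e <- e[-2, ]
    }
    e <- e[order(e$start), ]
    if (any(e$start >= e$end) || any(e$end[-nrow(e)] >= e$start[-1])) next
    got <- classify_transcript(e, gid, cat)$category
    expect_equal(got, oracle_classify(e, gid, cat),
                 info = paste(base_tid, op))
    expect_true(got %in% c("FSM", "NIC", "NNC", "OTHER"))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 450)
})

test_that("every retained transcript gets exactly one category and CPM is conserved", {
  fx <- smoke_fixture()
  t <- fx$objects$lr$transcripts
  expect_true(all(t$category %in% c("FSM", "NIC", "NNC", "OTHER")))
  expect_equal(sum(fx$truth$transcripts$cpm), 1e6, tolerance = 1e-6)
  # FSM <-> matched reference set; NNC <-> novel sites recorded
  expect_true(all((t$category == "FSM") == !is.na(t$matched_ref)))
  expect_true(all((t$category == "NNC") == nzchar(t$novel_sites)))
})

test_that("gene expression summaries call major/minor with stated tie-breaks", {
  cat <- toy_catalog()
  mk_lr <- function(tab) {
    ex <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      e <- cat$exons[cat$exons$transcript_id == tab$base[i],
                     c("chrom", "start", "end", "strand")]
      e$transcript_id <- tab$pb[i]
      e
    }))
    lr <- list(transcripts = data.frame(
      pb_accession = tab$pb, gene_id = "GA", fl_count = tab$count,
      cpm = tab$cpm, row.names = tab$pb), exons = ex)
    class(lr) <- "lr_transcripts"
    lr$transcripts$category <- tab$category
    lr$transcripts$matched_ref <- tab$matched
    lr
  }
  tab <- data.frame(pb = c("PB.1.2", "PB.1.10"), base = c("GA-201", "GA-202"),
                    count = c(10, 10), cpm = c(500000, 500000),
                    category = "FSM", matched = c("GA-201", "GA-202"))
  s <- summarize_gene_expression(mk_lr(tab), cat)
  # equal CPM and count: smaller numeric suffix wins (2 < 10)
  expect_equal(s$major_isoform, "PB.1.2")
  expect_true(s$major_matches_principal)
  expect_equal(s$n_isoforms, 2)
  # single isoform gene
  s1 <- summarize_gene_expression(mk_lr(tab[1, ]), cat)
  expect_equal(s1$major_isoform, "PB.1.2")
  expect_equal(s1$minor_isoforms, "")
})

test_that("major/principal concordance matches planted ground truth", {
  s <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  n_isoforms = c(2, 3, 2, 1),
                  major_matches_principal = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(major_principal_concordance(s)$fraction, 0)  # g4 excluded
  s$major_matches_principal[1] <- FALSE
  expect_equal(major_principal_concordance(s)$fraction, 1 / 3)
  s2 <- rbind(s, data.frame(gene_id = "g5", n_isoforms = 2,
                            major_matches_principal = TRUE))
  expect_equal(major_principal_concordance(s2)$fraction, 0.25)

  fx <- smoke_fixture()
  conc <- major_principal_concordance(fx$objects$summaries)
  tg <- fx$truth$genes[fx$truth$genes$n_retained >= 2, ]
  expect_equal(conc$n_genes, nrow(tg))
  expect_equal(conc$fraction, mean(tg$true_mismatch))
})

test_that("co-expression filter applies inclusive per-isoform CPM floors", {
  mk <- function(cpms, gene = "g") {
    lr <- list(transcripts = data.frame(
      pb_accession = paste0("PB.1.", seq_along(cpms)), gene_id = gene,
      cpm = cpms))
    class(lr) <- "lr_transcripts"
    lr
  }
  # FLT1-style isoform CPMs from the co-expression example: all >= 3
  expect_equal(coexpressed_isoform_genes(mk(c(42.9, 23.7, 9.4, 29.7, 6.4))), "g")
  expect_equal(coexpressed_isoform_genes(mk(c(10.0, 2.9))), character(0))
  expect_equal(coexpressed_isoform_genes(mk(c(3.0, 3.0))), "g")
  # monotonicity: raising the floor never grows the gene list
  fx <- smoke_fixture()
  lens <- vapply(c(3, 5, 10, 25),
                 function(m) length(coexpressed_isoform_genes(fx$objects$lr,
                                                              min_cpm = m)), 0)
  expect_true(all(diff(lens) <= 0))
})

test_that("gene sets rank by summed CPM with detected-only membership", {
  s <- data.frame(gene_id = c("A", "B", "D"),
                  total_gene_cpm = c(50, 300, 10))
  r <- rank_gene_set_by_abundance(s, c("A", "B", "C"))
  expect_equal(r$gene_id, c("B", "A"))
  expect_equal(r$total_gene_cpm, c(300, 50))
  expect_equal(nrow(rank_gene_set_by_abundance(s, "D")), 1)
  # summing printed per-isoform abundances: SRSF5-style rows
  expect_equal(sum(c(10.5, 103.8, 68.4, 15.8)), 198.5)
})

test_that("novel-isoform length deltas versus principal recover planted truth", {
  expect_equal(300 - 459, -159)
  fx <- smoke_fixture()
  d <- length_deltas_vs_reference(fx$objects$orfs, fx$objects$lr,
                                  fx$objects$catalog)
  tt <- fx$truth$transcripts
  tt <- tt[tt$retained & tt$true_class %in% c("NIC", "NNC"), ]
  principal_len <- nchar(fx$objects$ref$proteins[paste0(tt$gene_id, "-201")])
  truth_delta <- nchar(tt$true_protein) - principal_len
  expect_equal(sort(d$deltas$delta_aa), sort(unname(truth_delta)))
  neg <- truth_delta[truth_delta < 0]; pos <- truth_delta[truth_delta > 0]
  if (length(neg)) expect_equal(d$median_shortening, median(-neg))
  if (length(pos)) expect_equal(d$mean_gain, mean(pos))
})
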