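test_that("merge_sources unifies accessions and removes duplicates", {
  rev <- source_annotation("P1", "1.1.1.1", "reviewed")
  exp <- source_annotation("B9", "1.1.1.1", "experimental")
  links <- data.frame(experimental_accession = "B9", reviewed_accession = "P1")
  m <- merge_sources(rev, exp, links)
  expect_equal(nrow(m), 1L)
  expect_equal(m$accession, "P1")
  expect_equal(m$provenance, "experimental,reviewed")

  # disjoint sources, no links -> plain union
  rev2 <- source_annotation(c("P1", "P2"), c("1.1.1.1", "2.2.2.2"), "reviewed")
  exp2 <- source_annotation("B2", "3.3.3.3", "experimental")
  m2 <- merge_sources(rev2, exp2)
  expect_equal(nrow(m2), 3L)
  expect_true("B2" %in% m2$accession)  # unlinked accession kept as-is

  # conflicting cross-links are an error, not a silent choice
  bad <- data.frame(experimental_accession = c("B9", "B9"),
                    reviewed_accession = c("P1", "P2"))
  expect_error(merge_sources(rev, exp, bad), "ambiguous.*B9")
})

test_that("filter_hits applies inclusive cutoffs and is monotone", {
  h <- alignment_hits(c("q1", "q2", "q3"), c("t1", "t2", "t3"),
                      percent_identity = c(96.0, 95.9, 99.0),
                      evalue = c(1e-20, 1e-30, 1e-19),
                      bitscore = c(100, 100, 100))
  kept <- filter_hits(h)
  expect_equal(kept$query_accession, "q1")  # both boundaries pass exactly

  set.seed(11)
  rh <- alignment_hits(sprintf("q%03d", 1:200), sprintf("t%03d", 1:200),
                       runif(200, 80, 100), 10^runif(200, -60, -5),
                       runif(200, 50, 500))
  loose <- filter_hits(rh, 90, 1e-10)
  tight_id <- filter_hits(rh, 95, 1e-10)
  tight_ev <- filter_hits(rh, 90, 1e-25)
  expect_true(all(tight_id$query_accession %in% loose$query_accession))
  expect_true(all(tight_ev$query_accession %in% loose$query_accession))
})

test_that("best_hit_per_query is deterministic with documented tie-breaks", {
  h <- alignment_hits(
    query_accession = c("Q", "Q", "Q2", "Q2", "Q3"),
    subject_protein_id = c("tB", "tA", "t1", "t2", "t9"),
    percent_identity = rep(99, 5),
    evalue = c(1e-50, 1e-40, 1e-50, 1e-50, 1e-10),
    bitscore = c(200, 150, 200, 200, 77))
  best <- best_hit_per_query(h)
  expect_equal(best$subject_protein_id[best$query_accession == "Q"], "tB")
  # equal bitscore and evalue -> lexicographically smallest subject
  expect_equal(best$subject_protein_id[best$query_accession == "Q2"], "t1")
  # single hit maps to itself
  expect_equal(best$subject_protein_id[best$query_accession == "Q3"], "t9")
  # permutation invariance
  set.seed(5)
  perm <- h[sample(nrow(h)), ]
  expect_identical(best_hit_per_query(perm), best)

  # bitscore ties broken by lowest evalue
  h2 <- alignment_hits(c("Q", "Q"), c("tX", "tY"), c(99, 99),
                       c(1e-50, 1e-40), c(200, 200))
  expect_equal(best_hit_per_query(h2)$subject_protein_id, "tX")
})

test_that("consolidate_to_genes unions isoform labels at the gene level", {
  ann <- data.frame(accession = c("A1", "A2"),
                    ec_label = c("1.1.1.1", "2.2.2.2"),
                    provenance = c("reviewed", "experimental"))
  best <- alignment_hits(c("A1", "A2"), c("T1", "T2"), c(99, 99),
                         c(1e-50, 1e-50), c(200, 210))
  p2g <- c(T1 = "G", T2 = "G")
  g <- consolidate_to_genes(ann, best, p2g)
  expect_equal(annotation_count(g), 2L)
  expect_equal(g$ec_label, c("1.1.1.1", "2.2.2.2"))

  # both isoforms carrying the same label collapse to one annotation
  ann2 <- data.frame(accession = c("A1", "A2"),
                     ec_label = c("1.1.1.1", "1.1.1.1"),
                     provenance = c("reviewed", "experimental"))
  g2 <- consolidate_to_genes(ann2, best, p2g)
  expect_equal(annotation_count(g2), 1L)
  expect_equal(g2$provenance, "experimental,reviewed")

  # subject protein missing from the map is an error naming the protein
  expect_error(consolidate_to_genes(ann, best, c(T1 = "G")), "T2")
})

test_that("consolidation matches a brute-force group-by-union oracle", {
  set.seed(97)
  n_acc <- 100L
  acc <- sprintf("ACC%03d", seq_len(n_acc))
  labels <- sprintf("%d.%d.%d.%d", sample(1:6, n_acc, TRUE),
                    sample(1:9, n_acc, TRUE), sample(1:9, n_acc, TRUE),
                    sample(1:20, n_acc, TRUE))
  subj <- sprintf("T%03d", seq_len(n_acc))
  gene <- sprintf("G%02d", sample(1:40, n_acc, TRUE))
  ann <- data.frame(accession = acc, ec_label = labels,
                    provenance = sample(c("reviewed", "experimental"),
                                        n_acc, TRUE))
  best <- alignment_hits(acc, subj, rep(99, n_acc), rep(1e-40, n_acc),
                         runif(n_acc, 100, 500))
  gold <- consolidate_to_genes(ann, best, stats::setNames(gene, subj))

  # independent oracle: per-gene set union by explicit loop
  expected <- list()
  for (i in seq_len(n_acc)) {
    g <- gene[i]
    expected[[g]] <- sort(unique(c(expected[[g]], labels[i])))
  }
  got <- split(gold$ec_label, gold$gene_id)
  expect_identical(got[order(names(got))], expected[order(names(expected))])
  # consolidation never invents labels
  expect_lte(annotation_count(gold), n_acc)
})

test_that("single-isoform single-label accessions give one annotation per surviving hit", {
  set.seed(3)
  n <- 60L
  acc <- sprintf("A%02d", seq_len(n))
  hits <- alignment_hits(acc, sprintf("T%02d", seq_len(n)),
                         runif(n, 90, 100), 10^runif(n, -40, -10),
                         runif(n, 100, 300))
  surviving <- filter_hits(hits)
  ann <- data.frame(accession = acc,
                    ec_label = sprintf("1.1.1.%d", seq_len(n)),
                    provenance = "reviewed")
  gold <- consolidate_to_genes(ann, best_hit_per_query(surviving),
                               stats::setNames(sprintf("G%02d", seq_len(n)),
                                               sprintf("T%02d", seq_len(n))))
  expect_equal(annotation_count(gold), nrow(surviving))
})

test_that("gold standard and source tables round-trip through TSV", {
  d <- withr::local_tempdir()
  gold <- gold_standard(c("G1", "G1", "G2"),
                        c("1.1.1.1", "2.2.2.2", "1.1.1.1"),
                        c("reviewed", "experimental", "experimental,reviewed"))
  path <- file.path(d, "gold.tsv")
  write_gold_standard(gold, path)
  expect_identical(read_gold_standard(path), gold)

  src <- source_annotation(c("P1", "P2"), c("EC-1.1.1.1", "2.2"), "reviewed")
  sp <- file.path(d, "src.tsv")
  utils::write.table(as.data.frame(src), sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_identical(read_annotation_tsv(sp), src)
})
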