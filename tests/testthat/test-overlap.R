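test_that("annotated_genes requires a GO term or a catalyzing protein", {
  p <- pgdb(
    "x",
    genes = data.frame(
      gene_id = c("G1", "G2", "G3"),
      protein_ids = I(list(character(0), "G2_P1", "G3_P1")),
      go_terms = I(list("GO:0008150", character(0), character(0)))),
    proteins = data.frame(
      protein_id = c("G2_P1", "G3_P1"), gene_id = c("G2", "G3"),
      catalyzed_reaction_ids = I(list("R1", character(0)))),
    reactions = data.frame(reaction_id = "R1", ec_number = NA_character_,
                           substrate_ids = I(list(character(0))),
                           product_ids = I(list(character(0)))))
  expect_equal(annotated_genes(p), c("G1", "G2"))  # G3 has neither
  expect_equal(reaction_mapped_genes(p), "G2")
  expect_equal(reaction_mapped_proteins(p), "G2_P1")
})

test_that("venn partitions identifier sets and matches a brute-force tally", {
  v <- venn(c("x", "y"), c("x", "y"))
  expect_equal(c(v$unique_a, v$shared, v$unique_b), c(0L, 2L, 0L))
  v2 <- venn("x", "y")
  expect_equal(c(v2$unique_a, v2$shared, v2$unique_b), c(1L, 0L, 1L))

  set.seed(19)
  ids <- sprintf("id%03d", 1:200)
  in_a <- runif(200) < 0.7
  in_b <- ifelse(in_a, runif(200) < 0.4, runif(200) < 0.5)
  a <- ids[in_a]; b <- ids[in_b]
  v3 <- venn(a, b)
  # brute-force membership tally
  ua <- sh <- ub <- 0L
  for (id in ids) {
    if (id %in% a && id %in% b) sh <- sh + 1L
    else if (id %in% a) ua <- ua + 1L
    else if (id %in% b) ub <- ub + 1L
  }
  expect_equal(c(v3$unique_a, v3$shared, v3$unique_b), c(ua, sh, ub))
  # partition invariants
  expect_equal(v3$unique_a + v3$shared, length(unique(a)))
  expect_equal(v3$unique_b + v3$shared, length(unique(b)))
  expect_length(intersect(v3$a_only, v3$b_only), 0L)
  expect_length(intersect(v3$a_only, v3$both), 0L)
  # symmetry up to swapping the unique sides
  v4 <- venn(b, a)
  expect_equal(v4$unique_a, v3$unique_b)
  expect_equal(v4$unique_b, v3$unique_a)
  expect_identical(v4$both, v3$both)
})

test_that("ec_distribution counts reactions by top-level class", {
  d <- ec_distribution(c("1.1.1.1", "1.2.3.4", "6.3.1.2", NA))
  expect_equal(d[["1"]], 2L)
  expect_equal(d[["6"]], 1L)
  expect_equal(d[["unclassified"]], 1L)
  expect_equal(sum(d), 4L)
  expect_equal(sum(d[c("2", "3", "4", "5", "7")]), 0L)
  d0 <- ec_distribution(character(0))
  expect_equal(sum(d0), 0L)
  # partial labels classify by their first field; class 7 is its own bucket
  expect_equal(ec_distribution(c("7.1.-.-", "2.-.-.-"))[["7"]], 1L)
})

test_that("compare_pgdbs applies per-class filters and self-comparison is zero", {
  pair <- toy_pgdb_pair()
  rep <- compare_pgdbs(pair$a, pair$b)
  # annotated genes: A = {G1 (catalyzes), G2 (GO)}, B = {G1, G3}
  expect_equal(c(rep$venn$annotated_genes$unique_a,
                 rep$venn$annotated_genes$shared,
                 rep$venn$annotated_genes$unique_b), c(1L, 1L, 1L))
  expect_equal(rep$venn$reactions$shared, 1L)
  expect_equal(rep$venn$pathways$shared, 1L)
  # EC distributions of the reaction partitions
  expect_equal(rep$ec$shared[["2"]], 1L)
  expect_equal(rep$ec$unique_a[["1"]], 1L)
  expect_equal(rep$ec$unique_b[["unclassified"]], 1L)

  self <- compare_pgdbs(pair$a, pair$a)
  for (v in self$venn) {
    expect_equal(v$unique_a, 0L)
    expect_equal(v$unique_b, 0L)
  }

  # macromolecules and elements are excluded from the compound comparison
  a <- pgdb("a", compounds = data.frame(
    compound_id = c("C1", "P1", "E1"),
    kind = c("small-molecule", "macromolecule", "element")))
  b <- pgdb("b", compounds = data.frame(compound_id = "C1",
                                        kind = "small-molecule"))
  cv <- compare_pgdbs(a, b)$venn$small_molecule_compounds
  expect_equal(c(cv$unique_a, cv$shared, cv$unique_b), c(0L, 1L, 0L))
})

test_that("reaction-partition EC totals sum to the size of the reaction union", {
  syn <- generate(small_config(seed = 8))
  rep <- compare_pgdbs(syn$pgdb_a, syn$pgdb_b)
  union_n <- length(union(syn$pgdb_a$reactions$reaction_id,
                          syn$pgdb_b$reactions$reaction_id))
  expect_equal(sum(rep$ec$shared) + sum(rep$ec$unique_a) +
                 sum(rep$ec$unique_b), union_n)
})

test_that("compare_pgdbs is invariant to input record ordering", {
  syn <- generate(small_config(seed = 13))
  d <- withr::local_tempdir()
  write_pgdb(syn$pgdb_a, d)
  # shuffle the record order of genes.dat and reparse
  lines <- readLines(file.path(d, "genes.dat"))
  ends <- which(lines == "//")
  starts <- c(1L, head(ends, -1L) + 1L)
  set.seed(1)
  perm <- sample(length(ends))
  shuffled <- unlist(lapply(perm, function(i) lines[starts[i]:ends[i]]))
  writeLines(shuffled, file.path(d, "genes.dat"))
  p2 <- parse_pgdb(d, "ResourceA")
  expect_true(pgdb_equal(syn$pgdb_a, p2))
  r1 <- compare_pgdbs(syn$pgdb_a, syn$pgdb_b)
  r2 <- compare_pgdbs(p2, syn$pgdb_b)
  expect_identical(r1$venn, r2$venn)
  expect_identical(r1$ec, r2$ec)
})

test_that("overlap reports serialize to TSV and JSON", {
  pair <- toy_pgdb_pair()
  rep <- compare_pgdbs(pair$a, pair$b)
  d <- withr::local_tempdir()
  write_overlap_tsv(rep, file.path(d, "o.tsv"))
  tab <- utils::read.delim(file.path(d, "o.tsv"))
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$shared[tab$class == "reactions"], 1L)
  write_overlap_json(rep, file.path(d, "o.json"))
  js <- jsonlite::read_json(file.path(d, "o.json"))
  expect_equal(js$venn$pathways$shared, 1L)
  expect_equal(js$venn$pathways$both[[1]], "PWY1")
})
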