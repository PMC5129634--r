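# In-code fixtures shared across test files.

# Two tiny hand-built resources with known content:
#   shared: gene G1 (protein G1_P1 catalyzing R1), reaction R1, compound C1,
#           pathway PWY1 = {R1}
#   A only: gene G2 + GO-annotated, reaction R2 (EC 1.1.1.1), compound C2
#   B only: gene G3 with protein catalyzing R3, reaction R3 (no EC)
toy_pgdb_pair <- function() {
  a <- pgdb(
    "A",
    genes = data.frame(gene_id = c("G1", "G2"),
                       protein_ids = I(list("G1_P1", "G2_P1")),
                       go_terms = I(list(character(0), "GO:0008150"))),
    proteins = data.frame(protein_id = c("G1_P1", "G2_P1"),
                          gene_id = c("G1", "G2"),
                          catalyzed_reaction_ids = I(list("R1", character(0)))),
    reactions = data.frame(reaction_id = c("R1", "R2"),
                           ec_number = c("2.7.7.7", "1.1.1.1"),
                           substrate_ids = I(list("C1", "C2")),
                           product_ids = I(list("C1", "C2"))),
    compounds = data.frame(compound_id = c("C1", "C2"),
                           kind = c("small-molecule", "small-molecule")),
    pathways = data.frame(pathway_id = "PWY1", reaction_ids = I(list("R1"))))
  b <- pgdb(
    "B",
    genes = data.frame(gene_id = c("G1", "G3"),
                       protein_ids = I(list("G1_P1", "G3_P1")),
                       go_terms = I(list(character(0), character(0)))),
    proteins = data.frame(protein_id = c("G1_P1", "G3_P1"),
                          gene_id = c("G1", "G3"),
                          catalyzed_reaction_ids = I(list("R1", "R3"))),
    reactions = data.frame(reaction_id = c("R1", "R3"),
                           ec_number = c("2.7.7.7", NA),
                           substrate_ids = I(list("C1", "C1")),
                           product_ids = I(list("C1", "C1"))),
    compounds = data.frame(compound_id = "C1", kind = "small-molecule"),
    pathways = data.frame(pathway_id = "PWY1", reaction_ids = I(list("R1"))))
  list(a = a, b = b)
}

# small synthesis configuration used where full scale is unnecessary
small_config <- function(seed = 42, ...) {
  synthesis_config(seed = seed, n_genes = 400, n_gold_genes = 60,
                   missing_gene_fn = c(a = 4, b = 1), n_reactions = 120,
                   n_compounds = 100, n_pathways = 8,
                   mean_labels_per_gold_gene = 1.1, ...)
}

write_dat <- function(dir, file, lines) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, file.path(dir, file))
  dir
}
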