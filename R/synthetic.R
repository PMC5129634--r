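#' Configuration for the synthetic-data generator
#'
#' Describes paired synthetic pathway/genome databases, a planted gold
#' standard and prediction sets. The defaults emulate the study conditions
#' of the maize resource comparison at desk scale: 1.6 isoforms per gene on
#' average; one resource that is reaction-centric (GO terms on ~0.1% of
#' genes, 99.1% reaction-mapped) against one that is GO-centric (53.1%
#' GO-annotated, 19.8% reaction-mapped); planted precision/recall of
#' 0.86/0.90 and 0.74/0.84; a gold standard of 1,450 genes carrying ~1,475
#' annotations of which 86 and 2 fall on genes missing from the respective
#' resource; and a top-level EC class mix matching the published reaction
#' statistics.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param n_genes number of genes in the organism-wide pool.
#' @param mean_isoforms_per_gene mean number of protein products per gene
#'   (isoform count is 1 + a geometric draw with this mean).
#' @param go_fraction_a,go_fraction_b fraction of each resource's genes
#'   given at least one GO term.
#' @param reaction_map_fraction_a,reaction_map_fraction_b fraction of each
#'   resource's genes mapped to at least one reaction.
#' @param entity_overlap named proportions of shared identifiers per entity
#'   class (`gene`, `compound`, `reaction`, `pathway`), each the fraction of
#'   one resource's entities also present in the other. Protein overlap is
#'   emergent from gene overlap and isoform structure.
#' @param n_gold_genes number of gold-standard genes (drawn from the pool).
#' @param mean_labels_per_gold_gene mean gold labels per gene; the total
#'   annotation count is fixed to
#'   `round(n_gold_genes * mean_labels_per_gold_gene)`.
#' @param planted_precision,planted_recall named (`a`, `b`) target rates
#'   used to derive planted confusion counts when `planted_counts` is
#'   `NULL`.
#' @param planted_counts optional list with elements `a` and/or `b`, each a
#'   named vector `c(tp=, fp=, fn=)`, planting exact confusion counts
#'   (requires `tp + fn` equal to the gold annotation count).
#' @param missing_gene_fn named (`a`, `b`) counts of gold annotations
#'   planted on genes absent from the resource's gene universe; these are
#'   realized as single-label gold genes placed in the other resource's
#'   unique gene region.
#' @param ec_class_weights probability vector over top-level EC classes
#'   `"1"`..`"6"` and `"unclassified"` used to draw reaction EC numbers.
#' @param n_reactions,n_compounds,n_pathways per-resource entity counts
#'   (defaults scale with `n_genes`).
#' @param n_offgold_predictions per-resource number of noise predictions on
#'   genes without gold annotations (unscorable by design).
#' @param resource_names character(2) names for the two resources.
#' @return validated object of class `synthesis_config`.
#' @export
synthesis_config <- function(
    seed = 1L,
    n_genes = 5000L,
    mean_isoforms_per_gene = 1.6,
    go_fraction_a = 9 / 9142,
    go_fraction_b = 0.531,
    reaction_map_fraction_a = 0.991,
    reaction_map_fraction_b = 0.198,
    entity_overlap = c(gene = 0.70, compound = 0.70,
                       reaction = 0.60, pathway = 0.65),
    n_gold_genes = 1450L,
    mean_labels_per_gold_gene = 1475 / 1450,
    planted_precision = c(a = 0.86, b = 0.74),
    planted_recall = c(a = 0.90, b = 0.84),
    planted_counts = NULL,
    missing_gene_fn = c(a = 86L, b = 2L),
    ec_class_weights = c(`1` = 961, `2` = 995, `3` = 532, `4` = 232,
                         `5` = 108, `6` = 123, unclassified = 586) / 3537,
    n_reactions = NULL,
    n_compounds = NULL,
    n_pathways = NULL,
    n_offgold_predictions = NULL,
    resource_names = c("ResourceA", "ResourceB")) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    mean_isoforms_per_gene = mean_isoforms_per_gene,
    go_fraction_a = go_fraction_a, go_fraction_b = go_fraction_b,
    reaction_map_fraction_a = reaction_map_fraction_a,
    reaction_map_fraction_b = reaction_map_fraction_b,
    entity_overlap = entity_overlap,
    n_gold_genes = as.integer(n_gold_genes),
    mean_labels_per_gold_gene = mean_labels_per_gold_gene,
    planted_precision = planted_precision,
    planted_recall = planted_recall,
    planted_counts = planted_counts,
    missing_gene_fn = c(a = as.integer(missing_gene_fn[["a"]]),
                        b = as.integer(missing_gene_fn[["b"]])),
    ec_class_weights = ec_class_weights,
    n_reactions = as.integer(n_reactions %||% max(20L, round(0.35 * n_genes))),
    n_compounds = as.integer(n_compounds %||% max(20L, round(0.28 * n_genes))),
    n_pathways = as.integer(n_pathways %||% max(4L, round(0.018 * n_genes))),
    n_offgold_predictions =
      as.integer(n_offgold_predictions %||%
                   round(0.10 * n_gold_genes * mean_labels_per_gold_gene)),
    resource_names = as.character(resource_names)
  )
  validate_synthesis_config(cfg)
  class(cfg) <- "synthesis_config"
  cfg
}

validate_synthesis_config <- function(cfg) {
  props <- c(cfg$go_fraction_a, cfg$go_fraction_b,
             cfg$reaction_map_fraction_a, cfg$reaction_map_fraction_b,
             cfg$entity_overlap,
             cfg$planted_precision, cfg$planted_recall)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must be in [0, 1]", call. = FALSE)
  }
  need <- c("gene", "compound", "reaction", "pathway")
  if (!all(need %in% names(cfg$entity_overlap))) {
    stop("entity_overlap must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  w <- cfg$ec_class_weights
  if (!all(names(w) %in% c(as.character(1:7), "unclassified")) ||
      abs(sum(w) - 1) > 1e-8 || any(w < 0)) {
    stop("ec_class_weights must be a probability vector over EC classes ",
         "and 'unclassified'", call. = FALSE)
  }
  if (cfg$n_gold_genes > cfg$n_genes) {
    stop("n_gold_genes must not exceed n_genes", call. = FALSE)
  }
  if (cfg$n_genes < 1L || cfg$mean_isoforms_per_gene < 1) {
    stop("n_genes must be positive and mean_isoforms_per_gene >= 1",
         call. = FALSE)
  }
  if (cfg$mean_labels_per_gold_gene < 1) {
    stop("mean_labels_per_gold_gene must be >= 1", call. = FALSE)
  }
  if (length(cfg$resource_names) != 2L ||
      cfg$resource_names[1] == cfg$resource_names[2]) {
    stop("resource_names must be two distinct names", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synthesis_config <- function(x, ...) {
  cat(sprintf("<synthesis_config> seed %d: %d genes, %d gold genes, %d reactions/resource\n",
              x$seed, x$n_genes, x$n_gold_genes, x$n_reactions))
  invisible(x)
}

random_ec <- function(n, classes) {
  paste(classes,
        sample.int(99L, n, replace = TRUE),
        sample.int(99L, n, replace = TRUE),
        sample.int(999L, n, replace = TRUE), sep = ".")
}

# Draws n distinct EC labels per requested gene (k labels each), classes 1-6.
draw_label_sets <- function(ks, weights) {
  cls_lev <- setdiff(names(weights), "unclassified")
  w <- weights[cls_lev] / sum(weights[cls_lev])
  lapply(ks, function(k) {
    labs <- character(0)
    while (length(labs) < k) {
      cls <- sample(cls_lev, k, replace = TRUE, prob = w)
      labs <- unique(c(labs, random_ec(k, cls)))
    }
    sort(labs[seq_len(k)])
  })
}

plant_counts_for <- function(cfg, which, n_total) {
  pc <- cfg$planted_counts[[which]]
  if (!is.null(pc)) {
    pc <- c(tp = as.integer(pc[["tp"]]), fp = as.integer(pc[["fp"]]),
            fn = as.integer(pc[["fn"]]))
    if (pc[["tp"]] + pc[["fn"]] != n_total) {
      stop("infeasible config: planted tp + fn for resource '", which,
           "' (", pc[["tp"]] + pc[["fn"]],
           ") must equal the gold annotation count (", n_total, ")",
           call. = FALSE)
    }
    return(pc)
  }
  tp <- round(cfg$planted_recall[[which]] * n_total)
  fn <- n_total - tp
  prec <- cfg$planted_precision[[which]]
  if (prec <= 0) stop("infeasible config: planted_precision must be > 0",
                      call. = FALSE)
  fp <- round(tp * (1 - prec) / prec)
  c(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Generate paired synthetic PGDBs with planted truth
#'
#' Builds two synthetic pathway/genome databases with controlled identifier
#' overlap per entity class, a gold standard, and one prediction set per
#' resource whose confusion counts against the gold standard are planted by
#' construction (labels are copied, corrupted, withheld, or placed on genes
#' omitted from a resource's universe), so downstream scoring can be checked
#' exactly. The `expected` ledger records every planted quantity: confusion
#' counts per resource (and for the merged predictions), Venn counts per
#' entity class, EC-class distributions of the three reaction partitions,
#' the gold annotation count, and pass/fail labels for the generated
#' alignment hits.
#'
#' Output is deterministic given `config$seed`: regenerating with the same
#' config and writing with [write_synthesis()] yields byte-identical files.
#'
#' @param config a [synthesis_config()].
#' @return object of class `synthesis_output`: list with `pgdb_a`, `pgdb_b`,
#'   `gold`, `predictions_a`, `predictions_b`, `hits`, `hit_ledger`,
#'   `expected` and `config`.
#' @export
generate <- function(config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  cfg <- config
  set.seed(cfg$seed)

  # ---- gene pool: shared / unique-to-A / unique-to-B regions
  n <- cfg$n_genes
  shared_g <- round(cfg$entity_overlap[["gene"]] * n)
  ua <- (n - shared_g) %/% 2L
  ub <- n - shared_g - ua
  gene_ids <- sprintf("G%06d", seq_len(n))
  region <- rep(c("shared", "a", "b"), c(shared_g, ua, ub))
  genes_a <- gene_ids[region != "b"]
  genes_b <- gene_ids[region != "a"]

  # ---- isoforms (shared across resources for shared genes)
  iso_n <- 1L + stats::rgeom(n, prob = 1 / cfg$mean_isoforms_per_gene)
  protein_ids <- lapply(seq_len(n), function(i) {
    sprintf("%s_P%02d", gene_ids[i], seq_len(iso_n[i]))
  })
  names(protein_ids) <- gene_ids

  # ---- gold standard with planted missing genes
  m_a <- cfg$missing_gene_fn[["a"]]; m_b <- cfg$missing_gene_fn[["b"]]
  n_gold <- cfg$n_gold_genes
  if (m_a > ub || m_b > ua || n_gold - m_a - m_b > shared_g ||
      n_gold < m_a + m_b) {
    stop("infeasible config: missing_gene_fn counts do not fit the gene ",
         "regions implied by n_genes, entity_overlap['gene'] and ",
         "n_gold_genes", call. = FALSE)
  }
  miss_a_genes <- sample(gene_ids[region == "b"], m_a)  # absent from A
  miss_b_genes <- sample(gene_ids[region == "a"], m_b)  # absent from B
  core_genes <- sample(gene_ids[region == "shared"], n_gold - m_a - m_b)
  gold_genes <- c(core_genes, miss_a_genes, miss_b_genes)
  n_total <- round(cfg$n_gold_genes * cfg$mean_labels_per_gold_gene)
  # every gold gene gets one label; extras go to non-missing genes so the
  # planted missing-gene FN counts stay exact (one annotation per miss gene)
  k <- stats::setNames(rep(1L, n_gold), gold_genes)
  n_extra <- n_total - n_gold
  if (n_extra > 0) {
    if (!length(core_genes)) {
      stop("infeasible config: extra gold labels but no non-missing gold genes",
           call. = FALSE)
    }
    extra <- table(sample(core_genes, n_extra, replace = TRUE))
    k[names(extra)] <- k[names(extra)] + as.integer(extra)
  }
  label_sets <- draw_label_sets(as.integer(k), cfg$ec_class_weights)
  gold_df <- data.frame(gene_id = rep(names(k), as.integer(k)),
                        ec_label = unlist(label_sets, use.names = FALSE),
                        stringsAsFactors = FALSE)
  gold <- gold_standard(gold_df$gene_id, gold_df$ec_label,
                        provenance = sample(c("reviewed", "experimental",
                                              "experimental,reviewed"),
                                            nrow(gold_df), replace = TRUE,
                                            prob = c(0.55, 0.35, 0.10)))
  n_total <- nrow(gold)  # equal to the planned count by construction

  # ---- planted predictions per resource
  gkey <- paste(gold$gene_id, gold$ec_label, sep = "\t")
  build_predictions <- function(which, universe, missing_genes) {
    counts <- plant_counts_for(cfg, which, n_total)
    miss_fn <- sum(gold$gene_id %in% missing_genes)
    fn_free <- counts[["fn"]] - miss_fn
    avail <- which(!(gold$gene_id %in% missing_genes))
    if (fn_free < 0 || fn_free > length(avail)) {
      stop("infeasible config: planted fn for resource '", which,
           "' is smaller than the planted missing-gene annotations or ",
           "larger than the available gold labels", call. = FALSE)
    }
    withheld <- sample(avail, fn_free)
    tp_rows <- setdiff(avail, withheld)
    stopifnot(length(tp_rows) == counts[["tp"]])
    tp_df <- gold[tp_rows, c("gene_id", "ec_label")]
    # false positives: corrupted labels on scoreable gold genes
    scoreable <- setdiff(unique(gold$gene_id), missing_genes)
    fp_needed <- counts[["fp"]]
    fp_df <- data.frame(gene_id = character(0), ec_label = character(0))
    guard <- 0L
    while (nrow(fp_df) < fp_needed) {
      guard <- guard + 1L
      if (guard > 50L) stop("failed to draw false-positive labels",
                            call. = FALSE)
      need <- fp_needed - nrow(fp_df)
      g <- sample(scoreable, need, replace = TRUE)
      cls_lev <- setdiff(names(cfg$ec_class_weights), "unclassified")
      lab <- random_ec(need, sample(cls_lev, need, replace = TRUE,
                                    prob = cfg$ec_class_weights[cls_lev]))
      cand <- unique(rbind(fp_df, data.frame(gene_id = g, ec_label = lab,
                                             stringsAsFactors = FALSE)))
      key <- paste(cand$gene_id, cand$ec_label, sep = "\t")
      fp_df <- cand[!(key %in% gkey), , drop = FALSE]
    }
    fp_df <- fp_df[seq_len(fp_needed), , drop = FALSE]
    # unscorable noise on non-gold genes of the universe
    offgold_pool <- setdiff(universe, unique(gold$gene_id))
    n_off <- min(cfg$n_offgold_predictions, length(offgold_pool))
    off_df <- if (n_off > 0) {
      og <- sample(offgold_pool, n_off)
      cls_lev <- setdiff(names(cfg$ec_class_weights), "unclassified")
      data.frame(gene_id = og,
                 ec_label = random_ec(n_off,
                                      sample(cls_lev, n_off, replace = TRUE)),
                 stringsAsFactors = FALSE)
    } else data.frame(gene_id = character(0), ec_label = character(0))
    nm <- cfg$resource_names[[if (which == "a") 1L else 2L]]
    list(pred = prediction_set(nm, rbind(tp_df, fp_df, off_df), universe),
         counts = counts,
         tp_keys = paste(tp_df$gene_id, tp_df$ec_label, sep = "\t"),
         fp_keys = paste(fp_df$gene_id, fp_df$ec_label, sep = "\t"))
  }
  pa <- build_predictions("a", genes_a, miss_a_genes)
  pb <- build_predictions("b", genes_b, miss_b_genes)
  merged_tp <- length(union(pa$tp_keys, pb$tp_keys))
  merged_fp <- length(union(pa$fp_keys, pb$fp_keys))
  merged_counts <- c(tp = merged_tp, fp = merged_fp,
                     fn = n_total - merged_tp)

  # ---- reactions with EC classes drawn from the configured mix
  n_r <- cfg$n_reactions
  shared_r <- round(cfg$entity_overlap[["reaction"]] * n_r)
  uniq_r <- n_r - shared_r
  rxn_ids <- sprintf("RXN-%06d", seq_len(shared_r + 2L * uniq_r))
  rxn_region <- rep(c("shared", "a", "b"), c(shared_r, uniq_r, uniq_r))
  cls <- sample(names(cfg$ec_class_weights), length(rxn_ids), replace = TRUE,
                prob = cfg$ec_class_weights)
  rxn_ec <- ifelse(cls == "unclassified", NA_character_,
                   random_ec(length(rxn_ids), cls))
  ec_lev <- c(as.character(1:7), "unclassified")
  tally_cls <- function(sel) {
    out <- stats::setNames(integer(length(ec_lev)), ec_lev)
    t <- table(cls[sel])
    out[names(t)] <- as.integer(t)
    out
  }
  rxn_a <- rxn_region != "b"
  rxn_b <- rxn_region != "a"

  # ---- compounds: planted small-molecule overlap plus shared macro/element
  n_c <- cfg$n_compounds
  shared_c <- round(cfg$entity_overlap[["compound"]] * n_c)
  uniq_c <- n_c - shared_c
  cpd_ids <- sprintf("CPD-%06d", seq_len(shared_c + 2L * uniq_c))
  cpd_region <- rep(c("shared", "a", "b"), c(shared_c, uniq_c, uniq_c))
  n_macro <- max(2L, round(0.03 * n_c)); n_elem <- max(1L, round(0.01 * n_c))
  extra_ids <- c(sprintf("MACRO-%04d", seq_len(n_macro)),
                 sprintf("ELEM-%04d", seq_len(n_elem)))
  extra_kind <- rep(c("macromolecule", "element"), c(n_macro, n_elem))
  cpd_a <- cpd_region != "b"
  cpd_b <- cpd_region != "a"

  draw_sides <- function(pool) {
    # substrates/products for one reaction from an allowed compound pool
    k <- sample(1:3, 2L, replace = TRUE)
    s <- sample(pool, min(sum(k), length(pool)))
    list(left = s[seq_len(min(k[1], length(s)))],
         right = s[setdiff(seq_along(s), seq_len(min(k[1], length(s))))])
  }
  pools <- list(shared = cpd_ids[cpd_region == "shared"],
                a = cpd_ids[cpd_a], b = cpd_ids[cpd_b])
  sides <- lapply(seq_along(rxn_ids), function(i) {
    draw_sides(pools[[rxn_region[i]]])
  })

  # ---- pathways over the compatible reaction partitions
  n_p <- cfg$n_pathways
  shared_p <- round(cfg$entity_overlap[["pathway"]] * n_p)
  uniq_p <- n_p - shared_p
  pwy_ids <- sprintf("PWY-%05d", seq_len(shared_p + 2L * uniq_p))
  pwy_region <- rep(c("shared", "a", "b"), c(shared_p, uniq_p, uniq_p))
  rxn_pools <- list(shared = rxn_ids[rxn_region == "shared"],
                    a = rxn_ids[rxn_a], b = rxn_ids[rxn_b])
  pwy_members <- lapply(seq_along(pwy_ids), function(i) {
    pool <- rxn_pools[[pwy_region[i]]]
    sort(sample(pool, min(sample(3:8, 1L), length(pool))))
  })
  pwy_a <- pwy_region != "b"
  pwy_b <- pwy_region != "a"

  # ---- per-resource GO terms and catalysis links
  assign_go <- function(genes, fraction) {
    n_go <- round(fraction * length(genes))
    chosen <- sample(genes, n_go)
    k <- sample(1:3, n_go, replace = TRUE)
    ids <- sample.int(9999999L, sum(k), replace = TRUE)
    terms <- unname(split(sprintf("GO:%07d", ids),
                          rep(seq_len(n_go), k)))
    stats::setNames(lapply(terms, function(t) sort(unique(t))), chosen)
  }
  assign_catalysis <- function(genes, fraction, rxns) {
    n_map <- round(fraction * length(genes))
    chosen <- sample(genes, n_map)
    links <- lapply(chosen, function(g) {
      iso <- protein_ids[[g]]
      prot <- sample(iso, 1L)
      stats::setNames(list(sort(sample(rxns, min(sample(1:2, 1L),
                                                 length(rxns))))), prot)
    })
    stats::setNames(links, chosen)
  }
  go_a <- assign_go(genes_a, cfg$go_fraction_a)
  go_b <- assign_go(genes_b, cfg$go_fraction_b)
  cat_a <- assign_catalysis(genes_a, cfg$reaction_map_fraction_a,
                            rxn_ids[rxn_a])
  cat_b <- assign_catalysis(genes_b, cfg$reaction_map_fraction_b,
                            rxn_ids[rxn_b])

  build_pgdb <- function(name, genes, go, cat, rxn_sel, cpd_sel, pwy_sel) {
    cat_by_prot <- unlist(unname(cat), recursive = FALSE)
    prot_df <- data.frame(
      protein_id = unlist(protein_ids[genes], use.names = FALSE),
      gene_id = rep(genes, lengths(protein_ids[genes])),
      stringsAsFactors = FALSE)
    prot_df$catalyzed_reaction_ids <-
      I(unname(cat_by_prot[prot_df$protein_id]))
    gene_df <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    gene_df$protein_ids <- I(unname(protein_ids[genes]))
    gene_df$go_terms <- I(unname(go[genes]))
    rxn_df <- data.frame(reaction_id = rxn_ids[rxn_sel],
                         ec_number = rxn_ec[rxn_sel],
                         stringsAsFactors = FALSE)
    rxn_df$substrate_ids <- I(lapply(sides[rxn_sel], `[[`, "left"))
    rxn_df$product_ids <- I(lapply(sides[rxn_sel], `[[`, "right"))
    cpd_df <- data.frame(
      compound_id = c(cpd_ids[cpd_sel], extra_ids),
      kind = c(rep("small-molecule", sum(cpd_sel)), extra_kind),
      stringsAsFactors = FALSE)
    pwy_df <- data.frame(pathway_id = pwy_ids[pwy_sel],
                         stringsAsFactors = FALSE)
    pwy_df$reaction_ids <- I(pwy_members[pwy_sel])
    pgdb(name, genes = gene_df, proteins = prot_df, reactions = rxn_df,
         compounds = cpd_df, pathways = pwy_df)
  }
  pgdb_a <- build_pgdb(cfg$resource_names[1], genes_a, go_a, cat_a,
                       rxn_a, cpd_a, pwy_a)
  pgdb_b <- build_pgdb(cfg$resource_names[2], genes_b, go_b, cat_b,
                       rxn_b, cpd_b, pwy_b)

  # ---- expected ledger (generator's own bookkeeping, not pipeline calls)
  venn_of <- function(sa, sb) {
    c(unique_a = length(setdiff(sa, sb)), shared = length(intersect(sa, sb)),
      unique_b = length(setdiff(sb, sa)))
  }
  annotated_a <- union(names(go_a), names(cat_a))
  annotated_b <- union(names(go_b), names(cat_b))
  prot_of <- function(cat) {
    unlist(lapply(cat, names), use.names = FALSE)
  }
  expected <- list(
    gold_annotation_count = n_total,
    confusion = list(a = pa$counts, b = pb$counts, merged = merged_counts),
    venn = list(
      annotated_genes = venn_of(annotated_a, annotated_b),
      reaction_mapped_proteins = venn_of(prot_of(cat_a), prot_of(cat_b)),
      small_molecule_compounds = c(unique_a = uniq_c, shared = shared_c,
                                   unique_b = uniq_c),
      reactions = c(unique_a = uniq_r, shared = shared_r, unique_b = uniq_r),
      pathways = c(unique_a = uniq_p, shared = shared_p, unique_b = uniq_p)
    ),
    ec = list(shared = tally_cls(rxn_region == "shared"),
              unique_a = tally_cls(rxn_region == "a"),
              unique_b = tally_cls(rxn_region == "b"))
  )
  stopifnot(expected$confusion$a[["tp"]] + expected$confusion$a[["fn"]] ==
              n_total,
            expected$confusion$b[["tp"]] + expected$confusion$b[["fn"]] ==
              n_total)

  hits <- generate_hits(cfg)
  out <- list(pgdb_a = pgdb_a, pgdb_b = pgdb_b, gold = gold,
              predictions_a = pa$pred, predictions_b = pb$pred,
              hits = hits, hit_ledger = attr(hits, "ledger"),
              expected = expected, config = cfg)
  class(out) <- "synthesis_output"
  out
}

#' @export
print.synthesis_output <- function(x, ...) {
  cat("<synthesis_output>\n")
  print(x$pgdb_a); print(x$pgdb_b); print(x$gold)
  print(x$predictions_a); print(x$predictions_b)
  cat(sprintf("  %d alignment hits (%d planted to pass the filters)\n",
              nrow(x$hits), sum(x$hit_ledger$pass)))
  invisible(x)
}

#' Generate alignment hits straddling the filter cutoffs
#'
#' Emits BLAST-like hits covering all four pass/fail quadrants of the
#' identity (96%) and e-value (1e-20) cutoffs, including hits exactly on
#' both boundaries (which pass, since the cutoffs are inclusive). The
#' pass/fail label of every hit is recorded in the `"ledger"` attribute, a
#' data.frame with columns `query_accession` and `pass`.
#'
#' @param config a [synthesis_config()]; the seed is taken from it.
#' @return an [alignment_hits()] table with a `"ledger"` attribute.
#' @export
generate_hits <- function(config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  set.seed(config$seed + 1000003L)
  quadrant <- rep(c("pass", "low_identity", "high_evalue", "fail_both"),
                  each = 10L)
  n <- length(quadrant)
  pid <- ifelse(quadrant %in% c("pass", "high_evalue"),
                stats::runif(n, 96, 100), stats::runif(n, 50, 95.99))
  ev <- ifelse(quadrant %in% c("pass", "low_identity"),
               10^stats::runif(n, -80, -20), 10^stats::runif(n, -19.9, -2))
  # exact boundary hits: both cutoffs met with equality => pass
  pid[1] <- 96; ev[1] <- 1e-20
  query <- sprintf("ACC%05d", seq_len(n))
  # a few queries with secondary hits to exercise top-hit selection
  extra_q <- query[quadrant == "pass"][1:3]
  hits <- alignment_hits(
    query_accession = c(query, extra_q),
    subject_protein_id = sprintf("T%05d", sample.int(99999L, n + 3L)),
    percent_identity = c(pid, stats::runif(3, 96, 100)),
    evalue = c(ev, 10^stats::runif(3, -60, -21)),
    bitscore = round(c(stats::runif(n, 100, 2000), stats::runif(3, 10, 99)), 1))
  ledger <- data.frame(
    query_accession = hits$query_accession,
    pass = hits$percent_identity >= 96 & hits$evalue <= 1e-20,
    stringsAsFactors = FALSE)
  attr(hits, "ledger") <- ledger
  hits
}

#' Write a synthesis output to disk
#'
#' Writes the two PGDBs as flat-file directories (`pgdb_a/`, `pgdb_b/`), the
#' gold standard and prediction sets as TSV, the alignment hits as
#' 12-column BLAST tabular, the expected ledger as `expected.json` and the
#' configuration echo as `config.json`. Output is deterministic, enabling
#' byte-level reproducibility checks.
#'
#' @param x a [generate()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthesis <- function(x, dir) {
  stopifnot(inherits(x, "synthesis_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pgdb(x$pgdb_a, file.path(dir, "pgdb_a"))
  write_pgdb(x$pgdb_b, file.path(dir, "pgdb_b"))
  write_gold_standard(x$gold, file.path(dir, "gold_standard.tsv"))
  write_prediction_set(x$predictions_a, dir)
  write_prediction_set(x$predictions_b, dir)
  blast <- data.frame(x$hits$query_accession, x$hits$subject_protein_id,
                      x$hits$percent_identity, 100L, 0L, 0L, 1L, 100L, 1L,
                      100L, vapply(x$hits$evalue, format, character(1),
                                   digits = 8, scientific = TRUE),
                      x$hits$bitscore)
  utils::write.table(blast, file.path(dir, "hits.blast.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(x$expected, file.path(dir, "expected.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cfg <- x$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
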