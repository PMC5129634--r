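#' Annotated genes of a PGDB
#'
#' A gene counts as annotated if it has at least one GO term or is
#' associated with a protein that catalyzes at least one reaction. This is
#' the gene-content criterion used for cross-resource comparison, since one
#' resource may list many genes that carry no annotation at all.
#'
#' @param p a [pgdb()] object.
#' @return sorted character vector of gene identifiers.
#' @export
annotated_genes <- function(p) {
  has_go <- p$genes$gene_id[lengths(p$genes$go_terms) > 0L]
  mapped <- reaction_mapped_genes(p)
  sort(unique(c(has_go, mapped)))
}

#' Reaction-mapped genes and proteins
#'
#' A protein is reaction-mapped if it catalyzes at least one reaction; a
#' gene is reaction-mapped if one of its proteins is. Spontaneous reactions
#' (no catalyzing protein) map nothing.
#'
#' @param p a [pgdb()] object.
#' @return sorted character vector of identifiers.
#' @export
reaction_mapped_proteins <- function(p) {
  sort(p$proteins$protein_id[lengths(p$proteins$catalyzed_reaction_ids) > 0L])
}

#' @rdname reaction_mapped_proteins
#' @export
reaction_mapped_genes <- function(p) {
  sort(unique(p$proteins$gene_id[lengths(p$proteins$catalyzed_reaction_ids) > 0L]))
}

#' Small-molecule compounds of a PGDB
#'
#' Compound comparisons are restricted to small, non-elemental molecules;
#' macromolecules (proteins, DNA/RNA) and elements are excluded.
#'
#' @param p a [pgdb()] object.
#' @return sorted character vector of compound identifiers.
#' @export
small_molecule_compounds <- function(p) {
  sort(p$compounds$compound_id[p$compounds$kind == "small-molecule"])
}

#' Two-set Venn partition
#'
#' Partitions two identifier sets into unique-to-A, shared, and unique-to-B,
#' the three counts shown in a pairwise Venn diagram.
#'
#' @param ids_a,ids_b character vectors (de-duplicated internally).
#' @return object of class `venn_counts`: list with counts `unique_a`,
#'   `shared`, `unique_b` and the underlying sorted identifier sets
#'   `a_only`, `both`, `b_only`.
#' @export
venn <- function(ids_a, ids_b) {
  a <- unique(as.character(ids_a))
  b <- unique(as.character(ids_b))
  both <- sort(intersect(a, b))
  a_only <- sort(setdiff(a, b))
  b_only <- sort(setdiff(b, a))
  structure(list(unique_a = length(a_only), shared = length(both),
                 unique_b = length(b_only),
                 a_only = a_only, both = both, b_only = b_only),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("<venn_counts> unique A: %d  shared: %d  unique B: %d\n",
              x$unique_a, x$shared, x$unique_b))
  invisible(x)
}

#' Distribution of reactions over top-level EC classes
#'
#' Counts each reaction once, under the top-level class of its EC number
#' (classes 1-7), or under `unclassified` when no EC number is assigned.
#'
#' @param ec character vector of normalized EC numbers with `NA` for
#'   reactions lacking one, or a reactions data.frame with an `ec_number`
#'   column, or a [pgdb()].
#' @return object of class `ec_distribution`: named integer vector over
#'   `"1"`..`"7"`, `"unclassified"`; the sum equals the number of reactions
#'   supplied.
#' @export
ec_distribution <- function(ec) {
  if (inherits(ec, "pgdb")) ec <- ec$reactions$ec_number
  if (is.data.frame(ec)) ec <- ec$ec_number
  lev <- c(as.character(1:7), "unclassified")
  cls <- ec_top_class(ec)
  if (length(cls) && !all(cls %in% lev)) {
    bad <- setdiff(unique(cls), lev)
    stop("EC top-level class outside 1-7: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(cls, levels = lev))
  structure(stats::setNames(as.integer(counts), lev),
            class = "ec_distribution")
}

#' @export
print.ec_distribution <- function(x, ...) {
  cat("<ec_distribution> (top-level EC class: reactions)\n")
  print(stats::setNames(as.integer(x), names(unclass(x))))
  invisible(x)
}

#' Compare the content of two PGDBs
#'
#' Computes the cross-resource overlap report: Venn partitions of annotated
#' genes (see [annotated_genes()]), reaction-mapped proteins, small-molecule
#' compounds, reactions and pathways (matched by exact shared identifier),
#' plus the top-level EC-class distribution of the shared, unique-to-A and
#' unique-to-B reaction partitions.
#'
#' @param a,b [pgdb()] objects.
#' @return object of class `overlap_report`: list with `name_a`, `name_b`,
#'   `venn` (named list of [venn()] results per entity class) and
#'   `ec` (named list of [ec_distribution()]s for `shared`, `unique_a`,
#'   `unique_b` reactions).
#' @export
compare_pgdbs <- function(a, b) {
  stopifnot(inherits(a, "pgdb"), inherits(b, "pgdb"))
  vv <- list(
    annotated_genes = venn(annotated_genes(a), annotated_genes(b)),
    reaction_mapped_proteins = venn(reaction_mapped_proteins(a),
                                    reaction_mapped_proteins(b)),
    small_molecule_compounds = venn(small_molecule_compounds(a),
                                    small_molecule_compounds(b)),
    reactions = venn(a$reactions$reaction_id, b$reactions$reaction_id),
    pathways = venn(a$pathways$pathway_id, b$pathways$pathway_id)
  )
  ec_of <- function(ids) {
    pool <- rbind(a$reactions[, c("reaction_id", "ec_number")],
                  b$reactions[, c("reaction_id", "ec_number")])
    pool <- pool[!duplicated(pool$reaction_id), , drop = FALSE]
    ec_distribution(pool$ec_number[match(ids, pool$reaction_id)])
  }
  rv <- vv$reactions
  structure(list(name_a = a$name, name_b = b$name, venn = vv,
                 ec = list(shared = ec_of(rv$both),
                           unique_a = ec_of(rv$a_only),
                           unique_b = ec_of(rv$b_only))),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %s vs %s\n", x$name_a, x$name_b))
  for (cls in names(x$venn)) {
    v <- x$venn[[cls]]
    cat(sprintf("  %-26s unique %s: %s  shared: %s  unique %s: %s\n",
                cls, x$name_a, format(v$unique_a, big.mark = ","),
                format(v$shared, big.mark = ","),
                x$name_b, format(v$unique_b, big.mark = ",")))
  }
  cat("  reactions by top-level EC class (shared / unique A / unique B):\n")
  lev <- names(unclass(x$ec$shared))
  for (cl in lev) {
    cat(sprintf("    EC %-13s %5d %5d %5d\n", cl,
                x$ec$shared[[cl]], x$ec$unique_a[[cl]], x$ec$unique_b[[cl]]))
  }
  invisible(x)
}

#' Serialize an overlap report
#'
#' `write_overlap_tsv()` writes one row per entity class with the three Venn
#' counts; `write_overlap_json()` writes the full report including the
#' identifier sets and EC distributions.
#'
#' @param report an [compare_pgdbs()] report.
#' @param path output path.
#' @export
write_overlap_tsv <- function(report, path) {
  rows <- do.call(rbind, lapply(names(report$venn), function(cls) {
    v <- report$venn[[cls]]
    data.frame(class = cls, unique_a = v$unique_a, shared = v$shared,
               unique_b = v$unique_b, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_overlap_tsv
#' @export
write_overlap_json <- function(report, path) {
  obj <- list(
    resource_a = report$name_a, resource_b = report$name_b,
    venn = lapply(report$venn, function(v) {
      list(unique_a = v$unique_a, shared = v$shared, unique_b = v$unique_b,
           a_only = v$a_only, both = v$both, b_only = v$b_only)
    }),
    ec_distribution = lapply(report$ec, function(d) {
      as.list(stats::setNames(as.integer(d), names(unclass(d))))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
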