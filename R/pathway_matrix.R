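gene_reaction_pairs <- function(p, reaction_ids) {
  # (gene, reaction) pairs restricted to the given reactions: a gene pairs
  # with a reaction iff one of its proteins catalyzes it
  pr <- p$proteins
  len <- lengths(pr$catalyzed_reaction_ids)
  if (!sum(len)) {
    return(data.frame(gene_id = character(0), reaction_id = character(0)))
  }
  df <- data.frame(gene_id = rep(pr$gene_id, len),
                   reaction_id = unlist(pr$catalyzed_reaction_ids,
                                        use.names = FALSE),
                   stringsAsFactors = FALSE)
  df <- df[df$reaction_id %in% reaction_ids, , drop = FALSE]
  unique(df)
}

#' Per-pathway gene-reaction pairing matrix for two resources
#'
#' For one pathway, builds the matrix whose columns are the pathway's
#' reactions (union of the pathway's reaction lists in both resources) and
#' whose rows are the genes paired with at least one of those reactions in
#' either resource. A gene pairs with a reaction in a resource iff some
#' protein of the gene catalyzes the reaction there. Each cell records where
#' the pairing is asserted: `"a_only"`, `"b_only"`, `"both"` or `"absent"`.
#' Rows and columns are sorted lexicographically.
#'
#' @param pathway_id pathway frame identifier; must exist in at least one
#'   resource.
#' @param a,b [pgdb()] objects.
#' @return object of class `pairing_matrix`: list with `pathway_id`,
#'   `name_a`, `name_b`, `gene_ids`, `reaction_ids` and `cells` (character
#'   matrix gene x reaction).
#' @export
gene_reaction_matrix <- function(pathway_id, a, b) {
  rx_in <- function(p) {
    i <- match(pathway_id, p$pathways$pathway_id)
    if (is.na(i)) NULL else p$pathways$reaction_ids[[i]]
  }
  ra <- rx_in(a); rb <- rx_in(b)
  if (is.null(ra) && is.null(rb)) {
    stop("pathway '", pathway_id, "' not found in either resource",
         call. = FALSE)
  }
  reactions <- sort(unique(c(ra, rb)))
  pa <- gene_reaction_pairs(a, reactions)
  pb <- gene_reaction_pairs(b, reactions)
  genes <- sort(unique(c(pa$gene_id, pb$gene_id)))
  cells <- matrix("absent", nrow = length(genes), ncol = length(reactions),
                  dimnames = list(genes, reactions))
  in_a <- matrix(FALSE, length(genes), length(reactions),
                 dimnames = dimnames(cells))
  in_b <- in_a
  if (nrow(pa)) in_a[cbind(pa$gene_id, pa$reaction_id)] <- TRUE
  if (nrow(pb)) in_b[cbind(pb$gene_id, pb$reaction_id)] <- TRUE
  cells[in_a & !in_b] <- "a_only"
  cells[!in_a & in_b] <- "b_only"
  cells[in_a & in_b] <- "both"
  structure(list(pathway_id = pathway_id, name_a = a$name, name_b = b$name,
                 gene_ids = genes, reaction_ids = reactions, cells = cells),
            class = "pairing_matrix")
}

pairing_codes <- c(absent = ".", a_only = "c", b_only = "m", both = "cm")

#' @export
print.pairing_matrix <- function(x, codes = pairing_codes, ...) {
  cat(sprintf("<pairing_matrix> pathway %s: %d genes x %d reactions (%s = '%s', %s = '%s')\n",
              x$pathway_id, length(x$gene_ids), length(x$reaction_ids),
              x$name_a, codes[["a_only"]], x$name_b, codes[["b_only"]]))
  if (length(x$gene_ids)) {
    m <- matrix(codes[x$cells], nrow = nrow(x$cells),
                dimnames = dimnames(x$cells))
    print(as.data.frame(m))
  }
  invisible(x)
}

#' Serialize a pairing matrix
#'
#' The TSV has genes as rows and reactions as columns, with cell codes
#' marking which resource asserts each gene-reaction pairing: `"."` absent,
#' `"c"` first resource only, `"m"` second resource only, `"cm"` both. The
#' JSON form carries the full structure.
#'
#' @param x a [gene_reaction_matrix()] result.
#' @param path output path.
#' @param codes named character vector mapping
#'   `absent`/`a_only`/`b_only`/`both` to cell codes.
#' @export
write_pairing_matrix_tsv <- function(x, path, codes = pairing_codes) {
  m <- matrix(codes[x$cells], nrow = nrow(x$cells),
              dimnames = dimnames(x$cells))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairing_matrix_tsv
#' @export
write_pairing_matrix_json <- function(x, path) {
  obj <- list(pathway_id = x$pathway_id, resource_a = x$name_a,
              resource_b = x$name_b, gene_ids = x$gene_ids,
              reaction_ids = x$reaction_ids,
              cells = apply(x$cells, 1L, as.list, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
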