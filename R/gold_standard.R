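#' Source annotation and cross-link tables
#'
#' A source annotation table holds protein-level EC labels from one
#' annotation source: a data.frame with columns `accession`, `ec_label`
#' (normalized on construction) and `provenance` (`"reviewed"` for manually
#' reviewed entries, `"experimental"` for experimentally verified ones). A
#' cross-link table maps accessions of the experimental source to the
#' reviewed source's accessions, so the same protein annotated in both is
#' counted once.
#'
#' @param accession character vector of protein accessions.
#' @param ec_label character vector of EC labels (normalized with
#'   [normalize_ec()]).
#' @param provenance `"reviewed"` or `"experimental"` (recycled).
#' @return data.frame of class `source_annotation`.
#' @export
source_annotation <- function(accession, ec_label, provenance) {
  provenance <- rep_len(as.character(provenance), length(accession))
  if (!all(provenance %in% c("reviewed", "experimental"))) {
    stop("provenance must be 'reviewed' or 'experimental'", call. = FALSE)
  }
  df <- data.frame(accession = as.character(accession),
                   ec_label = normalize_ec(ec_label),
                   provenance = provenance,
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$accession, df$ec_label, df$provenance), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("source_annotation", "data.frame")
  df
}

#' Merge reviewed and experimental annotation sources
#'
#' Unifies accessions using the cross-link table (experimental accessions
#' with a link are re-keyed to the linked reviewed accession), then takes the
#' set union over (accession, EC label) pairs, merging provenance per pair.
#' Duplicate annotations present in both sources therefore collapse to one
#' pair carrying both provenance tags. An experimental accession linked to
#' two different reviewed accessions is ambiguous and raises an error.
#'
#' @param reviewed,experimental [source_annotation()] tables.
#' @param links data.frame with columns `experimental_accession`,
#'   `reviewed_accession` (may have zero rows).
#' @return data.frame with columns `accession`, `ec_label`, `provenance`
#'   (comma-joined sorted set per pair), one row per unified
#'   (accession, label) pair.
#' @export
merge_sources <- function(reviewed, experimental,
                          links = data.frame(experimental_accession = character(0),
                                             reviewed_accession = character(0))) {
  stopifnot(all(c("experimental_accession", "reviewed_accession") %in% names(links)))
  lk <- unique(links[, c("experimental_accession", "reviewed_accession")])
  conflicted <- unique(lk$experimental_accession[duplicated(lk$experimental_accession)])
  if (length(conflicted)) {
    stop("ambiguous cross-link(s) for experimental accession(s): ",
         paste(conflicted, collapse = ", "), call. = FALSE)
  }
  map <- stats::setNames(lk$reviewed_accession, lk$experimental_accession)
  exp2 <- experimental
  hit <- exp2$accession %in% names(map)
  exp2$accession[hit] <- unname(map[exp2$accession[hit]])
  all_ann <- rbind(as.data.frame(reviewed), as.data.frame(exp2))
  key <- paste(all_ann$accession, all_ann$ec_label, sep = "\t")
  prov <- vapply(split(all_ann$provenance, key),
                 function(p) paste(sort(unique(p)), collapse = ","),
                 character(1))
  uk <- strsplit(names(prov), "\t", fixed = TRUE)
  out <- data.frame(accession = vapply(uk, `[[`, character(1), 1L),
                    ec_label = vapply(uk, `[[`, character(1), 2L),
                    provenance = unname(prov),
                    stringsAsFactors = FALSE)
  out <- out[order(out$accession, out$ec_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct an alignment-hit table
#'
#' @param query_accession,subject_protein_id character vectors.
#' @param percent_identity numeric in \[0, 100\].
#' @param evalue non-negative numeric.
#' @param bitscore positive numeric.
#' @return data.frame of class `alignment_hits`.
#' @export
alignment_hits <- function(query_accession, subject_protein_id,
                           percent_identity, evalue, bitscore) {
  if (any(percent_identity < 0 | percent_identity > 100)) {
    stop("percent_identity must be in [0, 100]", call. = FALSE)
  }
  if (any(evalue < 0)) stop("evalue must be non-negative", call. = FALSE)
  if (any(bitscore <= 0)) stop("bitscore must be positive", call. = FALSE)
  df <- data.frame(query_accession = as.character(query_accession),
                   subject_protein_id = as.character(subject_protein_id),
                   percent_identity = as.numeric(percent_identity),
                   evalue = as.numeric(evalue),
                   bitscore = as.numeric(bitscore),
                   stringsAsFactors = FALSE)
  class(df) <- c("alignment_hits", "data.frame")
  df
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Reads 12-column BLAST tabular output and keeps the columns the gold
#' standard build consumes: query, subject, percent identity, e-value and
#' bitscore.
#'
#' @param path path to a 12-column tab-separated file without header.
#' @return an [alignment_hits()] table.
#' @export
read_blast_tabular <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) {
    stop("expected 12-column BLAST tabular output, got ", ncol(df),
         " columns", call. = FALSE)
  }
  alignment_hits(df[[1]], df[[2]], df[[3]], df[[11]], df[[12]])
}

#' Filter alignment hits at identity and e-value cutoffs
#'
#' Keeps exactly the hits with `percent_identity >= min_identity` and
#' `evalue <= max_evalue`; both bounds are inclusive, so a hit sitting
#' exactly on a cutoff passes. The defaults are the cutoffs used to match
#' curated protein annotations to translated gene models: 96% identity and
#' e-value 1e-20.
#'
#' @param hits an [alignment_hits()] table.
#' @param min_identity minimum percent identity (default 96).
#' @param max_evalue maximum e-value (default 1e-20).
#' @return the surviving subset, same class.
#' @export
filter_hits <- function(hits, min_identity = 96, max_evalue = 1e-20) {
  stopifnot(is.finite(min_identity), is.finite(max_evalue),
            min_identity >= 0, min_identity <= 100)
  keep <- hits$percent_identity >= min_identity & hits$evalue <= max_evalue
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-scoring hit per query
#'
#' For each query accession, keeps the single hit with the highest bitscore;
#' ties are broken by lowest e-value, then by lexicographically smallest
#' subject identifier, so the result is deterministic under any input
#' ordering.
#'
#' @param hits an [alignment_hits()] table (typically already filtered).
#' @return one-row-per-query subset, sorted by query accession.
#' @export
best_hit_per_query <- function(hits) {
  if (!nrow(hits)) {
    out <- hits[0, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  o <- order(hits$query_accession, -hits$bitscore, hits$evalue,
             hits$subject_protein_id)
  h <- hits[o, , drop = FALSE]
  out <- h[!duplicated(h$query_accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consolidate protein-level annotations to a gene-level gold standard
#'
#' Attaches each source accession's EC labels to the gene of its best-hit
#' subject protein, then unions the labels of all isoforms (alternative
#' transcript/protein products) of a gene into one gene-level label set.
#' Provenance is preserved per (gene, label) pair as the union of provenance
#' tags of the contributing accessions. Accessions without a best hit are
#' dropped; a best-hit subject protein missing from `protein_to_gene` is an
#' error.
#'
#' @param annotations merged annotations from [merge_sources()] (columns
#'   `accession`, `ec_label`, `provenance`).
#' @param best_hits output of [best_hit_per_query()]: one hit per accession.
#' @param protein_to_gene named character vector mapping
#'   `subject_protein_id` to `gene_id`.
#' @return a [gold_standard()] object.
#' @export
consolidate_to_genes <- function(annotations, best_hits, protein_to_gene) {
  hit_map <- stats::setNames(best_hits$subject_protein_id,
                             best_hits$query_accession)
  ann <- annotations[annotations$accession %in% names(hit_map), , drop = FALSE]
  subj <- unname(hit_map[ann$accession])
  missing <- setdiff(unique(subj), names(protein_to_gene))
  if (length(missing)) {
    stop("best-hit subject protein(s) not in protein-to-gene map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gene <- unname(protein_to_gene[subj])
  gold_standard(gene_id = gene, ec_label = ann$ec_label,
                provenance = ann$provenance)
}

#' Gene-level gold standard of EC annotations
#'
#' Holds experimentally verified or manually reviewed EC labels consolidated
#' at the gene level: one row per (gene, EC label) pair with its merged
#' provenance set. The total annotation count (the quantity conserved as
#' TP + FN in [classify()]) is the number of rows.
#'
#' @param gene_id,ec_label character vectors (labels normalized on
#'   construction).
#' @param provenance per-row provenance: comma-joined subsets of
#'   `reviewed`/`experimental`; multiple rows for the same (gene, label) are
#'   merged and their provenance unioned.
#' @return object of class `gold_standard`: a data.frame with columns
#'   `gene_id`, `ec_label`, `provenance`.
#' @export
gold_standard <- function(gene_id, ec_label, provenance = "experimental") {
  provenance <- rep_len(as.character(provenance), length(gene_id))
  df <- data.frame(gene_id = as.character(gene_id),
                   ec_label = normalize_ec(ec_label),
                   provenance = provenance, stringsAsFactors = FALSE)
  key <- paste(df$gene_id, df$ec_label, sep = "\t")
  prov <- vapply(split(df$provenance, key), function(p) {
    paste(sort(unique(unlist(strsplit(p, ",", fixed = TRUE)))), collapse = ",")
  }, character(1))
  uk <- strsplit(names(prov), "\t", fixed = TRUE)
  out <- data.frame(gene_id = vapply(uk, `[[`, character(1), 1L),
                    ec_label = vapply(uk, `[[`, character(1), 2L),
                    provenance = unname(prov), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$ec_label), , drop = FALSE]
  rownames(out) <- NULL
  bad_prov <- !vapply(strsplit(out$provenance, ",", fixed = TRUE),
                      function(p) length(p) >= 1L &&
                        all(p %in% c("reviewed", "experimental")),
                      logical(1))
  if (any(bad_prov)) {
    stop("provenance entries must be subsets of {reviewed, experimental}",
         call. = FALSE)
  }
  class(out) <- c("gold_standard", "data.frame")
  out
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> %d annotations across %d genes\n",
              nrow(x), length(unique(x$gene_id))))
  invisible(x)
}

#' Total annotation count of a gold standard
#'
#' @param gold a [gold_standard()] object.
#' @return number of (gene, EC label) pairs.
#' @export
annotation_count <- function(gold) nrow(gold)

#' Read / write gold-standard and annotation-source TSV files
#'
#' `read_annotation_tsv()` reads a source table with header columns
#' `accession`, `ec_label`, `provenance`. `read_crosslink_tsv()` reads a
#' table with columns `experimental_accession`, `reviewed_accession`.
#' `write_gold_standard()` / `read_gold_standard()` round-trip the
#' gene-level gold standard (`gene_id`, `ec_label`, `provenance`).
#'
#' @param path file path.
#' @return the corresponding table.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("accession", "ec_label", "provenance")
  if (!all(req %in% names(df))) {
    stop(path, ": header must contain ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  source_annotation(df$accession, df$ec_label, df$provenance)
}

#' @rdname read_annotation_tsv
#' @export
read_crosslink_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("experimental_accession", "reviewed_accession")
  if (!all(req %in% names(df))) {
    stop(path, ": header must contain ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$experimental_accession == "" | df$reviewed_accession == "")) {
    stop(path, ": empty accession in cross-link table", call. = FALSE)
  }
  df
}

#' @rdname read_annotation_tsv
#' @param gold a [gold_standard()] object.
#' @export
write_gold_standard <- function(gold, path) {
  utils::write.table(as.data.frame(gold), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_annotation_tsv
#' @export
read_gold_standard <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gold_standard(df$gene_id, df$ec_label, df$provenance)
}

#' Build a gold standard from source files
#'
#' Convenience wrapper chaining [merge_sources()], [filter_hits()],
#' [best_hit_per_query()] and [consolidate_to_genes()].
#'
#' @param reviewed,experimental [source_annotation()] tables.
#' @param links cross-link data.frame.
#' @param hits an [alignment_hits()] table (unfiltered).
#' @param protein_to_gene named character vector.
#' @param min_identity,max_evalue passed to [filter_hits()].
#' @return a [gold_standard()] object.
#' @export
build_gold_standard <- function(reviewed, experimental, links, hits,
                                protein_to_gene,
                                min_identity = 96, max_evalue = 1e-20) {
  merged <- merge_sources(reviewed, experimental, links)
  best <- best_hit_per_query(filter_hits(hits, min_identity, max_evalue))
  consolidate_to_genes(merged, best, protein_to_gene)
}
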