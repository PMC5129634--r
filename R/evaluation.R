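#' Predicted annotation set of one resource
#'
#' Bundles a resource's computationally predicted gene-level EC annotations
#' with its gene universe (every gene the resource contains). The universe
#' is what makes the missing-gene false-negative rule expressible: a gold
#' gene outside the universe has no predictions by construction, so all its
#' gold labels count as false negatives.
#'
#' @param name resource name.
#' @param predictions data.frame with columns `gene_id`, `ec_label`, or a
#'   named list of character label vectors keyed by gene.
#' @param gene_universe character vector of every gene identifier in the
#'   resource; must contain all predicted genes.
#' @return object of class `prediction_set`: list with `name`,
#'   `predictions` (canonical data.frame, one row per (gene, label) pair)
#'   and `gene_universe` (sorted unique character vector).
#' @export
prediction_set <- function(name, predictions, gene_universe) {
  if (is.list(predictions) && !is.data.frame(predictions)) {
    predictions <- data.frame(
      gene_id = rep(names(predictions), lengths(predictions)),
      ec_label = unlist(predictions, use.names = FALSE) %||% character(0),
      stringsAsFactors = FALSE)
  }
  df <- data.frame(gene_id = as.character(predictions$gene_id),
                   ec_label = normalize_ec(predictions$ec_label),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$gene_id, df$ec_label), , drop = FALSE]
  rownames(df) <- NULL
  universe <- sort(unique(as.character(gene_universe)))
  outside <- setdiff(df$gene_id, universe)
  if (length(outside)) {
    stop("predicted gene(s) not in the gene universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(name = as.character(name), predictions = df,
                 gene_universe = universe),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %s: %d predictions on %d genes (universe %d)\n",
              x$name, nrow(x$predictions), length(unique(x$predictions$gene_id)),
              length(x$gene_universe)))
  invisible(x)
}

#' Merge two prediction sets
#'
#' Takes the per-gene union of predicted labels and the union of the gene
#' universes, emulating a resource built from the pooled enzymatic
#' assignments of both inputs.
#'
#' @param a,b [prediction_set()] objects.
#' @return a [prediction_set()] named `"<a>+<b>"`.
#' @export
merge_predictions <- function(a, b) {
  stopifnot(inherits(a, "prediction_set"), inherits(b, "prediction_set"))
  nm <- if (identical(a$name, b$name)) a$name else paste(a$name, b$name, sep = "+")
  prediction_set(nm,
                 rbind(a$predictions, b$predictions),
                 c(a$gene_universe, b$gene_universe))
}

#' Score predictions against a gold standard
#'
#' Applies the confusion rules for gene-level enzyme annotation: evaluation
#' is restricted to gold-standard genes. For each gold gene *g*, a true
#' positive is a predicted label also in the gold label set, a false
#' positive a predicted label not supported by any gold label of *g*, and a
#' false negative a gold label that is not predicted. A gold gene absent
#' from the resource's gene universe has an empty prediction set, so all its
#' gold labels are false negatives (the missing-gene rule). Predictions on
#' genes without gold annotations are not scored: true negatives cannot be
#' counted, so such predictions contribute nothing.
#'
#' Labels are compared by exact four-field string equality after
#' normalization; a partial label such as `"2.7.7.-"` matches only an
#' identical partial label.
#'
#' By construction `tp + fn` equals the gold annotation count; the returned
#' object records this conservation identity so externally supplied counts
#' can be audited with [check_conservation()].
#'
#' @param pred a [prediction_set()].
#' @param gold a [gold_standard()].
#' @return object of class `ec_confusion`: list with integers `tp`, `fp`,
#'   `fn`, the `resource` name, `gold_total` (gold annotation count) and
#'   `per_gene` (data.frame `gene_id`, `tp`, `fp`, `fn`, `in_universe`, one
#'   row per gold gene).
#' @export
classify <- function(pred, gold) {
  stopifnot(inherits(pred, "prediction_set"), inherits(gold, "gold_standard"))
  gold_genes <- sort(unique(gold$gene_id))
  gkey <- paste(gold$gene_id, gold$ec_label, sep = "\t")
  p <- pred$predictions[pred$predictions$gene_id %in% gold_genes, , drop = FALSE]
  pkey <- paste(p$gene_id, p$ec_label, sep = "\t")
  tp_gene <- p$gene_id[pkey %in% gkey]
  fp_gene <- p$gene_id[!(pkey %in% gkey)]
  fn_gene <- gold$gene_id[!(gkey %in% pkey)]
  tab <- function(g) {
    v <- integer(length(gold_genes))
    if (length(g)) {
      t <- table(factor(g, levels = gold_genes))
      v <- as.integer(t)
    }
    v
  }
  per_gene <- data.frame(gene_id = gold_genes,
                         tp = tab(tp_gene), fp = tab(fp_gene),
                         fn = tab(fn_gene),
                         in_universe = gold_genes %in% pred$gene_universe,
                         stringsAsFactors = FALSE)
  confusion_counts(tp = sum(per_gene$tp), fp = sum(per_gene$fp),
                   fn = sum(per_gene$fn), resource = pred$name,
                   gold_total = nrow(gold), per_gene = per_gene)
}

#' Construct confusion counts
#'
#' Builds an `ec_confusion` object directly from TP/FP/FN counts, e.g. from
#' a published performance table, so [metrics()] and [check_conservation()]
#' can be applied to printed counts as well as to [classify()] output.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @param resource optional resource name.
#' @param gold_total optional gold annotation count for the conservation
#'   check (defaults to `tp + fn`).
#' @param per_gene optional per-gene detail data.frame.
#' @return object of class `ec_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, resource = NA_character_,
                             gold_total = tp + fn, per_gene = NULL) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 resource = resource, gold_total = as.integer(gold_total),
                 per_gene = per_gene),
            class = "ec_confusion")
}

#' @export
print.ec_confusion <- function(x, ...) {
  cat(sprintf("<ec_confusion> %s: TP %s  FP %s  FN %s\n",
              if (is.na(x$resource)) "(unnamed)" else x$resource,
              format(x$tp, big.mark = ","), format(x$fp, big.mark = ","),
              format(x$fn, big.mark = ",")))
  if (!check_conservation(x)) {
    cat(sprintf("  WARNING: TP + FN = %d differs from gold annotation count %d\n",
                x$tp + x$fn, x$gold_total))
  }
  invisible(x)
}

#' Conservation check: TP + FN equals the gold annotation count
#'
#' Every gold label is either recovered (TP) or missed (FN), so for any
#' prediction set `tp + fn` must equal the gold standard's annotation count.
#' [classify()] satisfies this by construction; for externally supplied
#' counts the check can fail and flags an inconsistent table.
#'
#' @param x an `ec_confusion` object.
#' @param gold_total gold annotation count; defaults to the one recorded in
#'   `x`.
#' @return `TRUE` if `tp + fn == gold_total`, else `FALSE`.
#' @export
check_conservation <- function(x, gold_total = x$gold_total) {
  (x$tp + x$fn) == gold_total
}

#' Precision, recall and F-measure from confusion counts
#'
#' `precision = TP / (TP + FP)` (correct predictions among all predictions),
#' `recall = TP / (TP + FN)` (correct predictions among all possible correct
#' classes), and `F = 2 * precision * recall / (precision + recall)`.
#' Degenerate zero denominators yield 0. Values are kept at full precision;
#' the print method rounds to two decimals for display.
#'
#' @param x an `ec_confusion` object, or TP count if `fp`/`fn` given.
#' @param fp,fn optional counts when `x` is a plain TP count.
#' @return object of class `ec_metrics`: list with `precision`, `recall`,
#'   `f_measure` in \[0, 1\] plus the originating counts.
#' @export
metrics <- function(x, fp = NULL, fn = NULL) {
  if (!inherits(x, "ec_confusion")) {
    stopifnot(!is.null(fp), !is.null(fn))
    x <- confusion_counts(x, fp, fn)
  }
  tp <- x$tp
  precision <- if (tp + x$fp > 0) tp / (tp + x$fp) else 0
  recall <- if (tp + x$fn > 0) tp / (tp + x$fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(precision = precision, recall = recall, f_measure = f,
                 tp = tp, fp = x$fp, fn = x$fn, resource = x$resource),
            class = "ec_metrics")
}

#' @export
print.ec_metrics <- function(x, digits = 2, ...) {
  cat(sprintf("<ec_metrics> %s: precision %.2f  recall %.2f  F-measure %.2f\n",
              if (is.na(x$resource)) "(unnamed)" else x$resource,
              round(x$precision, digits), round(x$recall, digits),
              round(x$f_measure, digits)))
  invisible(x)
}

#' Read / write prediction sets and confusion tables as TSV
#'
#' A prediction set is stored as a two-column TSV (`gene_id`, `ec_label`)
#' plus a universe file listing one gene identifier per line. Confusion
#' results are written one resource per row with counts and metrics.
#'
#' @param name resource name.
#' @param predictions_path two-column TSV with header `gene_id`, `ec_label`.
#' @param universe_path plain list of gene identifiers, one per line.
#' @return a [prediction_set()].
#' @export
read_prediction_set <- function(name, predictions_path, universe_path) {
  df <- utils::read.delim(predictions_path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "ec_label") %in% names(df))) {
    stop(predictions_path, ": header must contain gene_id, ec_label",
         call. = FALSE)
  }
  universe <- readLines(universe_path, warn = FALSE)
  universe <- universe[nzchar(universe)]
  prediction_set(name, df, universe)
}

#' @rdname read_prediction_set
#' @param pred a [prediction_set()].
#' @param dir output directory; writes `<name>.predictions.tsv` and
#'   `<name>.universe.txt`.
#' @export
write_prediction_set <- function(pred, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- gsub("[^A-Za-z0-9._+-]", "_", pred$name)
  utils::write.table(pred$predictions,
                     file.path(dir, paste0(base, ".predictions.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(pred$gene_universe,
             file.path(dir, paste0(base, ".universe.txt")))
  invisible(dir)
}

#' @rdname read_prediction_set
#' @param confusions list of `ec_confusion` objects.
#' @param path output TSV path.
#' @export
write_confusion_tsv <- function(confusions, path) {
  rows <- lapply(confusions, function(cf) {
    m <- metrics(cf)
    data.frame(resource = cf$resource, tp = cf$tp, fp = cf$fp, fn = cf$fn,
               precision = m$precision, recall = m$recall,
               f_measure = m$f_measure, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
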