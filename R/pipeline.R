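read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file: ", path, call. = FALSE)
  }
}

config_to_synthesis <- function(s) {
  args <- s[intersect(names(s), names(formals(synthesis_config)))]
  for (nm in c("entity_overlap", "planted_precision", "planted_recall",
               "missing_gene_fn", "ec_class_weights")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(synthesis_config, args)
}

#' Run the full comparison pipeline
#'
#' Chains the pipeline stages according to a configuration: obtain the two
#' resources and the gold standard (either generated by the synthetic-data
#' module or loaded from files), score each prediction set and their merge
#' against the gold standard, compare the two PGDBs, and build any requested
#' per-pathway gene-reaction matrices. All serialized outputs (confusion
#' TSV, overlap TSV + JSON, pairing matrices, report JSON) are written under
#' `out_dir`.
#'
#' The configuration is a list (or YAML/JSON file) with sections:
#' \describe{
#'   \item{synthesis}{arguments for [synthesis_config()]; mutually exclusive
#'     with `sources`/`resources`.}
#'   \item{sources}{paths `reviewed`, `experimental`, `crosslinks`, `hits`,
#'     `protein_to_gene` (two-column TSV protein_id, gene_id) and optional
#'     `min_identity`, `max_evalue` for the gold-standard build; or a
#'     pre-built `gold` TSV.}
#'   \item{resources}{list of two entries, each with `name`, `pgdb` (flat
#'     file directory), `predictions` and `universe` paths.}
#'   \item{matrices}{character vector of pathway identifiers.}
#' }
#' Every number in the returned report is the corresponding module output at
#' full precision; rounding happens only in print methods. Invariant
#' violations (e.g. TP + FN differing from the gold annotation count) are
#' collected as diagnostics, never silently dropped.
#'
#' @param config list, or path to a YAML/JSON config file.
#' @param out_dir output directory for serialized results.
#' @param seed optional integer overriding the synthesis seed.
#' @return object of class `run_report`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("pgdbcompare_run_"),
                         seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  diagnostics <- character(0)

  if (!is.null(config$synthesis)) {
    s <- config$synthesis
    if (isTRUE(s)) s <- list()
    if (!is.null(seed)) s$seed <- as.integer(seed)
    scfg <- config_to_synthesis(s)
    syn <- generate(scfg)
    write_synthesis(syn, file.path(out_dir, "synthetic"))
    pgdb_a <- syn$pgdb_a; pgdb_b <- syn$pgdb_b
    gold <- syn$gold
    pred_a <- syn$predictions_a; pred_b <- syn$predictions_b
  } else {
    res <- config$resources
    if (is.null(res) || length(res) != 2L) {
      stop("config must provide either a 'synthesis' section or exactly ",
           "two 'resources'", call. = FALSE)
    }
    need_file <- function(path, what) {
      if (is.null(path) || !file.exists(path)) {
        stop("missing ", what, " file: ",
             if (is.null(path)) "(not configured)" else path, call. = FALSE)
      }
      path
    }
    src <- config$sources
    gold <- if (!is.null(src$gold)) {
      read_gold_standard(need_file(src$gold, "gold standard"))
    } else {
      p2g <- utils::read.delim(need_file(src$protein_to_gene,
                                         "protein-to-gene map"),
                               stringsAsFactors = FALSE)
      build_gold_standard(
        reviewed = read_annotation_tsv(need_file(src$reviewed,
                                                 "reviewed annotations")),
        experimental = read_annotation_tsv(need_file(src$experimental,
                                                     "experimental annotations")),
        links = read_crosslink_tsv(need_file(src$crosslinks, "cross-links")),
        hits = read_blast_tabular(need_file(src$hits, "alignment hits")),
        protein_to_gene = stats::setNames(p2g$gene_id, p2g$protein_id),
        min_identity = src$min_identity %||% 96,
        max_evalue = src$max_evalue %||% 1e-20)
    }
    load_res <- function(r) {
      list(pgdb = parse_pgdb(need_file(r$pgdb, "PGDB directory") , r$name),
           pred = read_prediction_set(r$name,
                                      need_file(r$predictions, "predictions"),
                                      need_file(r$universe, "gene universe")))
    }
    ra <- load_res(res[[1]]); rb <- load_res(res[[2]])
    pgdb_a <- ra$pgdb; pgdb_b <- rb$pgdb
    pred_a <- ra$pred; pred_b <- rb$pred
    write_gold_standard(gold, file.path(out_dir, "gold_standard.tsv"))
  }

  diagnostics <- c(diagnostics,
                   sprintf("[%s] %s", pgdb_a$name, pgdb_a$diagnostics),
                   sprintf("[%s] %s", pgdb_b$name, pgdb_b$diagnostics))

  confusions <- list(classify(pred_a, gold), classify(pred_b, gold),
                     classify(merge_predictions(pred_a, pred_b), gold))
  for (cf in confusions) {
    if (!check_conservation(cf)) {
      diagnostics <- c(diagnostics, sprintf(
        "conservation violation for %s: TP + FN = %d but gold annotation count is %d",
        cf$resource, cf$tp + cf$fn, cf$gold_total))
    }
  }
  evaluation <- lapply(confusions, function(cf) {
    list(confusion = cf, metrics = metrics(cf))
  })
  names(evaluation) <- vapply(confusions, `[[`, character(1), "resource")
  write_confusion_tsv(confusions, file.path(out_dir, "evaluation.tsv"))

  overlap <- compare_pgdbs(pgdb_a, pgdb_b)
  write_overlap_tsv(overlap, file.path(out_dir, "overlap.tsv"))
  write_overlap_json(overlap, file.path(out_dir, "overlap.json"))

  matrices <- list()
  for (pid in config$matrices %||% character(0)) {
    m <- gene_reaction_matrix(pid, pgdb_a, pgdb_b)
    matrices[[pid]] <- m
    write_pairing_matrix_tsv(m, file.path(out_dir,
                                          paste0("matrix_", pid, ".tsv")))
    write_pairing_matrix_json(m, file.path(out_dir,
                                           paste0("matrix_", pid, ".json")))
  }

  report <- structure(list(
    version = as.character(utils::packageVersion("pgdbcompare")),
    config = config,
    gold_annotation_count = nrow(gold),
    evaluation = evaluation,
    overlap = overlap,
    matrices = matrices,
    diagnostics = diagnostics,
    out_dir = out_dir
  ), class = "run_report")
  write_run_report_json(report, file.path(out_dir, "report.json"))
  report
}

run_report_as_list <- function(x) {
  list(
    version = x$version,
    gold_annotation_count = x$gold_annotation_count,
    evaluation = lapply(x$evaluation, function(e) {
      list(tp = e$confusion$tp, fp = e$confusion$fp, fn = e$confusion$fn,
           precision = e$metrics$precision, recall = e$metrics$recall,
           f_measure = e$metrics$f_measure)
    }),
    overlap = list(
      venn = lapply(x$overlap$venn, function(v) {
        list(unique_a = v$unique_a, shared = v$shared, unique_b = v$unique_b)
      }),
      ec_distribution = lapply(x$overlap$ec, function(d) {
        as.list(stats::setNames(as.integer(d), names(unclass(d))))
      })
    ),
    matrices = lapply(x$matrices, function(m) {
      list(pathway_id = m$pathway_id, genes = length(m$gene_ids),
           reactions = length(m$reaction_ids))
    }),
    diagnostics = x$diagnostics
  )
}

write_run_report_json <- function(x, path) {
  jsonlite::write_json(run_report_as_list(x), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("== pgdbcompare run report (v%s) ==\n", x$version))
  cat(sprintf("gold standard: %s annotations\n",
              format(x$gold_annotation_count, big.mark = ",")))
  cat("\n-- prediction performance --\n")
  cat(sprintf("%-24s %8s %8s %8s %10s %8s %10s\n", "resource", "TP", "FP",
              "FN", "precision", "recall", "F-measure"))
  for (nm in names(x$evaluation)) {
    e <- x$evaluation[[nm]]
    cat(sprintf("%-24s %8s %8s %8s %10.2f %8.2f %10.2f\n", nm,
                format(e$confusion$tp, big.mark = ","),
                format(e$confusion$fp, big.mark = ","),
                format(e$confusion$fn, big.mark = ","),
                e$metrics$precision, e$metrics$recall, e$metrics$f_measure))
  }
  cat("\n-- content overlap --\n")
  print(x$overlap)
  if (length(x$matrices)) {
    cat("\n-- pathway gene-reaction matrices --\n")
    for (m in x$matrices) print(m)
  }
  if (length(x$diagnostics)) {
    cat("\n!! diagnostics !!\n")
    cat(paste0("  - ", x$diagnostics, collapse = "\n"), "\n")
  }
  invisible(x)
}
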