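#' Normalize Enzyme Commission (EC) numbers
#'
#' Canonicalizes EC labels to the four-field form used throughout the
#' package: an optional `"EC-"` or `"EC "` prefix is stripped, missing
#' trailing fields are padded with `"-"`, and each field must be a positive
#' integer or `"-"`. Top-level classes 1-7 (translocases included) are
#' accepted. `NA` values pass through unchanged, so reaction tables with
#' absent EC numbers can be normalized in one call.
#'
#' @param raw character vector of raw EC labels (e.g. `"EC-1.1.1.1"`,
#'   `"2.7.7.-"`, `"3.4"`).
#' @return character vector of normalized four-field EC strings
#'   (e.g. `"3.4.-.-"`), with `NA` preserved.
#' @examples
#' normalize_ec(c("EC-1.1.1.1", "2.7.7.-", "3.4"))
#' @export
normalize_ec <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  out <- as.character(raw)
  idx <- which(!is.na(out))
  if (length(idx) == 0L) return(out)
  x <- trimws(out[idx])
  if (any(x == "")) {
    stop("invalid EC number: empty string", call. = FALSE)
  }
  x <- sub("^EC[- ]\\s*", "", x, ignore.case = FALSE)
  parts <- strsplit(x, ".", fixed = TRUE)
  norm <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) > 4L) {
      stop("invalid EC number '", x[i], "': more than four fields",
           call. = FALSE)
    }
    ok <- grepl("^([0-9]+|-)$", p)
    if (length(p) == 0L || !all(ok)) {
      stop("invalid EC number '", x[i], "': field must be an integer or '-'",
           call. = FALSE)
    }
    num <- p != "-"
    if (any(num) && any(as.integer(p[num]) <= 0L)) {
      stop("invalid EC number '", x[i], "': fields must be positive",
           call. = FALSE)
    }
    paste(c(p, rep("-", 4L - length(p))), collapse = ".")
  }, character(1))
  out[idx] <- norm
  out
}

#' Top-level EC class of normalized EC numbers
#'
#' @param ec character vector of normalized EC numbers (`NA` allowed).
#' @return character vector: the first field (`"1"`..`"7"`), or
#'   `"unclassified"` where the EC number is absent or its first field is
#'   `"-"`.
#' @export
ec_top_class <- function(ec) {
  cls <- sub("\\..*$", "", ec)
  cls[is.na(ec) | cls == "-"] <- "unclassified"
  cls
}

go_pattern <- "^GO:[0-9]{7}$"

`%||%` <- function(a, b) if (is.null(a)) b else a

as_id_set <- function(x) {
  x <- unlist(x, use.names = FALSE)
  if (is.null(x)) return(character(0))
  sort(unique(as.character(x[!is.na(x) & x != ""])))
}

canonical_entity_df <- function(df, id_col, list_cols = character(0)) {
  stopifnot(is.data.frame(df))
  for (col in list_cols) {
    df[[col]] <- lapply(
      if (is.null(df[[col]])) vector("list", nrow(df)) else df[[col]],
      as_id_set
    )
  }
  df <- df[order(df[[id_col]]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_entities <- function() {
  list(
    genes = data.frame(gene_id = character(0),
                       protein_ids = I(list()), go_terms = I(list())),
    proteins = data.frame(protein_id = character(0), gene_id = character(0),
                          catalyzed_reaction_ids = I(list())),
    reactions = data.frame(reaction_id = character(0), ec_number = character(0),
                           substrate_ids = I(list()), product_ids = I(list())),
    compounds = data.frame(compound_id = character(0), kind = character(0)),
    pathways = data.frame(pathway_id = character(0), reaction_ids = I(list()))
  )
}

compound_kinds <- c("small-molecule", "macromolecule", "element")

#' Construct a pathway/genome database (PGDB) container
#'
#' A `pgdb` bundles the five entity classes of one metabolic resource
#' (e.g. one BioCyc-style database): genes, proteins (gene products /
#' isoforms), reactions, compounds and pathways, linked by frame
#' identifiers. Identifiers are case-sensitive and must be unique within
#' each entity class. Cross-references that do not resolve are recorded as
#' diagnostics on the object rather than dropped (see
#' [check_references()]).
#'
#' @param name resource name (e.g. `"CornCyc"`).
#' @param genes data.frame with columns `gene_id` (character) and list
#'   columns `protein_ids`, `go_terms`. GO terms must match
#'   `GO:` + 7 digits.
#' @param proteins data.frame with columns `protein_id`, `gene_id` and list
#'   column `catalyzed_reaction_ids`.
#' @param reactions data.frame with columns `reaction_id`, `ec_number`
#'   (normalized EC string or `NA`) and list columns `substrate_ids`,
#'   `product_ids`.
#' @param compounds data.frame with columns `compound_id` and `kind`
#'   (one of `"small-molecule"`, `"macromolecule"`, `"element"`).
#' @param pathways data.frame with columns `pathway_id` and list column
#'   `reaction_ids`.
#' @return an object of class `pgdb`: a list with the five canonicalized
#'   entity tables (rows sorted by identifier, set-valued columns sorted and
#'   de-duplicated), the resource `name`, and a `diagnostics` character
#'   vector of unresolved cross-references.
#' @seealso [parse_pgdb()], [write_pgdb()], [check_references()]
#' @export
pgdb <- function(name, genes = NULL, proteins = NULL, reactions = NULL,
                 compounds = NULL, pathways = NULL) {
  defaults <- empty_entities()
  x <- list(
    name = as.character(name),
    genes = canonical_entity_df(genes %||% defaults$genes, "gene_id",
                                c("protein_ids", "go_terms")),
    proteins = canonical_entity_df(proteins %||% defaults$proteins,
                                   "protein_id", "catalyzed_reaction_ids"),
    reactions = canonical_entity_df(reactions %||% defaults$reactions,
                                    "reaction_id",
                                    c("substrate_ids", "product_ids")),
    compounds = canonical_entity_df(compounds %||% defaults$compounds,
                                    "compound_id"),
    pathways = canonical_entity_df(pathways %||% defaults$pathways,
                                   "pathway_id", "reaction_ids")
  )
  validate_pgdb(x)
  x$diagnostics <- check_references(x)
  class(x) <- "pgdb"
  x
}

validate_pgdb <- function(x) {
  ids <- list(gene = x$genes$gene_id, protein = x$proteins$protein_id,
              reaction = x$reactions$reaction_id,
              compound = x$compounds$compound_id,
              pathway = x$pathways$pathway_id)
  for (cls in names(ids)) {
    v <- ids[[cls]]
    if (any(is.na(v) | v == "")) {
      stop("empty ", cls, " identifier", call. = FALSE)
    }
    if (anyDuplicated(v)) {
      stop("duplicate ", cls, " identifier: ",
           paste(unique(v[duplicated(v)]), collapse = ", "), call. = FALSE)
    }
  }
  go <- unlist(x$genes$go_terms, use.names = FALSE)
  if (length(go) && !all(grepl(go_pattern, go))) {
    bad <- go[!grepl(go_pattern, go)]
    stop("malformed GO term(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  ec <- x$reactions$ec_number
  ec <- ec[!is.na(ec)]
  if (length(ec)) normalize_ec(ec)  # errors on malformed labels
  kind <- x$compounds$kind
  if (length(kind) && !all(kind %in% compound_kinds)) {
    stop("compound kind must be one of: ",
         paste(compound_kinds, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Check referential integrity of a PGDB
#'
#' Verifies that every cross-reference resolves: gene product identifiers to
#' proteins, a protein's gene to a gene record, catalyzed reactions to
#' reactions, reaction substrates/products to compounds, and pathway members
#' to reactions. The diagnostic vector is empty exactly when every reference
#' resolves.
#'
#' @param x a [pgdb()] object (or a bare list with the same entity tables).
#' @return character vector of human-readable diagnostics, one per
#'   unresolved reference.
#' @export
check_references <- function(x) {
  diags <- character(0)
  report <- function(from, from_id, to, missing) {
    if (length(missing)) {
      sprintf("%s %s references unknown %s %s", from, from_id, to, missing)
    } else character(0)
  }
  check_list <- function(tab, id_col, list_col, from, to, universe) {
    n <- nrow(tab)
    if (!n) return(character(0))
    refs <- tab[[list_col]]
    len <- lengths(refs)
    if (!sum(len)) return(character(0))
    flat <- unlist(refs, use.names = FALSE)
    owner <- rep(tab[[id_col]], len)
    bad <- !(flat %in% universe)
    sprintf("%s %s references unknown %s %s",
            from, owner[bad], to, flat[bad])
  }
  diags <- c(diags,
    check_list(x$genes, "gene_id", "protein_ids", "gene", "protein",
               x$proteins$protein_id),
    check_list(x$proteins, "protein_id", "catalyzed_reaction_ids",
               "protein", "reaction", x$reactions$reaction_id),
    check_list(x$reactions, "reaction_id", "substrate_ids",
               "reaction", "compound", x$compounds$compound_id),
    check_list(x$reactions, "reaction_id", "product_ids",
               "reaction", "compound", x$compounds$compound_id),
    check_list(x$pathways, "pathway_id", "reaction_ids",
               "pathway", "reaction", x$reactions$reaction_id))
  if (nrow(x$proteins)) {
    bad <- !(x$proteins$gene_id %in% x$genes$gene_id)
    diags <- c(diags, sprintf("protein %s references unknown gene %s",
                              x$proteins$protein_id[bad],
                              x$proteins$gene_id[bad]))
  }
  diags
}

#' @export
print.pgdb <- function(x, ...) {
  cat(sprintf("<pgdb> %s\n", x$name))
  cat(sprintf("  genes: %d  proteins: %d  reactions: %d  compounds: %d  pathways: %d\n",
              nrow(x$genes), nrow(x$proteins), nrow(x$reactions),
              nrow(x$compounds), nrow(x$pathways)))
  if (length(x$diagnostics)) {
    cat(sprintf("  %d unresolved cross-reference(s); see $diagnostics\n",
                length(x$diagnostics)))
  }
  invisible(x)
}

#' @export
summary.pgdb <- function(object, ...) {
  print(object)
  d <- ec_distribution(object$reactions$ec_number)
  cat("  reactions by top-level EC class:\n")
  print(unclass(d))
  invisible(object)
}

# ---- flat-file dialect ------------------------------------------------------

dat_files <- c(genes = "genes.dat", proteins = "proteins.dat",
               reactions = "reactions.dat", compounds = "compounds.dat",
               pathways = "pathways.dat")

known_slots <- list(
  genes = c("UNIQUE-ID", "PRODUCT", "GO-TERMS"),
  proteins = c("UNIQUE-ID", "GENE", "CATALYZES"),
  reactions = c("UNIQUE-ID", "EC-NUMBER", "LEFT", "RIGHT"),
  compounds = c("UNIQUE-ID", "KIND"),
  pathways = c("UNIQUE-ID", "REACTION-LIST")
)

# Parses one attribute-value .dat file into a list of records, each a list of
# slot -> character vector. Dialect: "SLOT - VALUE" lines; records end with a
# line that is exactly "//"; repeated slots accumulate; lines starting with
# "/" (but not "//") continue the previous value; "#" lines are comments.
read_dat_records <- function(path, file_label, slots) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  is_term <- lines == "//"
  is_cont <- startsWith(lines, "/") & !is_term
  # fold continuation lines into the preceding slot line
  if (any(is_cont)) {
    keep <- !is_cont
    tgt <- cumsum(keep)  # index (in kept lines) each line attaches to
    base <- lines[keep]
    for (i in which(is_cont)) {
      if (tgt[i] == 0L || base[tgt[i]] == "//") {
        stop("continuation line without a preceding slot in ", file_label,
             call. = FALSE)
      }
      base[tgt[i]] <- paste0(base[tgt[i]], " ", sub("^/", "", lines[i]))
    }
    lines <- base
    is_term <- lines == "//"
  }
  rec_idx <- cumsum(c(0L, head(is_term, -1L))) + 1L
  if (!is_term[length(lines)]) {
    stop("unterminated record at end of ", file_label,
         " (missing '//')", call. = FALSE)
  }
  slot_lines <- !is_term
  m <- regmatches(lines[slot_lines],
                  regexec("^([A-Za-z0-9?^-]+) - (.*)$", lines[slot_lines]))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed line in ", file_label, ": '",
         lines[slot_lines][bad][1], "'", call. = FALSE)
  }
  slot <- vapply(m, `[[`, character(1), 2L)
  value <- trimws(vapply(m, `[[`, character(1), 3L))
  unknown <- setdiff(unique(slot), slots)
  if (length(unknown)) {
    warning("ignoring unknown slot(s) in ", file_label, ": ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  rec <- rec_idx[slot_lines]
  keep <- slot %in% slots
  n_rec <- max(rec_idx[is_term])
  recs <- vector("list", n_rec)
  split_rec <- split(seq_along(slot)[keep], rec[keep])
  for (r in seq_len(n_rec)) recs[[r]] <- list()
  for (rname in names(split_rec)) {
    i <- split_rec[[rname]]
    recs[[as.integer(rname)]] <- split(value[i], slot[i])
  }
  uid <- vapply(recs, function(r) {
    u <- r[["UNIQUE-ID"]]
    if (is.null(u)) NA_character_ else u[1]
  }, character(1))
  n_uid <- vapply(recs, function(r) length(r[["UNIQUE-ID"]]), integer(1))
  if (anyNA(uid) || any(n_uid != 1L)) {
    bad_rec <- which(is.na(uid) | n_uid != 1L)[1]
    stop(file_label, " record ", bad_rec,
         ": UNIQUE-ID missing or repeated", call. = FALSE)
  }
  if (anyDuplicated(uid)) {
    stop("duplicate UNIQUE-ID in ", file_label, ": ",
         paste(unique(uid[duplicated(uid)]), collapse = ", "),
         call. = FALSE)
  }
  names(recs) <- uid
  recs
}

slot_list <- function(recs, slot) {
  I(lapply(recs, function(r) as_id_set(r[[slot]])))
}
slot_scalar <- function(recs, slot, default = NA_character_) {
  vapply(recs, function(r) {
    v <- r[[slot]]
    if (is.null(v) || !length(v)) default else v[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Read a PGDB from BioCyc-style attribute-value flat files
#'
#' Reads whichever of `genes.dat`, `proteins.dat`, `reactions.dat`,
#' `compounds.dat` and `pathways.dat` exist in `dir`. The dialect is one
#' `SLOT - VALUE` pair per line; records end with a `//` line; repeated
#' slots accumulate into sets; lines starting with `/` continue the previous
#' value; `#` lines are comments. UTF-8, Unix or Windows line endings.
#' Recognized slots per file: genes `UNIQUE-ID, PRODUCT, GO-TERMS`; proteins
#' `UNIQUE-ID, GENE, CATALYZES`; reactions
#' `UNIQUE-ID, EC-NUMBER, LEFT, RIGHT`; compounds `UNIQUE-ID, KIND`;
#' pathways `UNIQUE-ID, REACTION-LIST`. Unknown slots are ignored with a
#' warning. EC numbers are normalized on read.
#'
#' A record without a `UNIQUE-ID`, or a duplicated `UNIQUE-ID` within a
#' file, is an error naming the file and record. Unresolved cross-references
#' are *not* errors: every record is materialized and the dangling
#' references are collected in the returned object's `diagnostics`.
#'
#' @param dir directory containing the `.dat` files.
#' @param name resource name; defaults to the directory basename.
#' @return a [pgdb()] object.
#' @export
parse_pgdb <- function(dir, name = basename(normalizePath(dir, mustWork = FALSE))) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  recs <- lapply(names(dat_files), function(what) {
    path <- file.path(dir, dat_files[[what]])
    if (!file.exists(path)) return(list())
    read_dat_records(path, dat_files[[what]], known_slots[[what]])
  })
  names(recs) <- names(dat_files)
  g <- recs$genes; p <- recs$proteins; r <- recs$reactions
  co <- recs$compounds; pw <- recs$pathways
  pgdb(
    name = name,
    genes = data.frame(gene_id = names(g) %||% character(0),
                       protein_ids = slot_list(g, "PRODUCT"),
                       go_terms = slot_list(g, "GO-TERMS"),
                       stringsAsFactors = FALSE),
    proteins = data.frame(protein_id = names(p) %||% character(0),
                          gene_id = slot_scalar(p, "GENE"),
                          catalyzed_reaction_ids = slot_list(p, "CATALYZES"),
                          stringsAsFactors = FALSE),
    reactions = data.frame(reaction_id = names(r) %||% character(0),
                           ec_number = normalize_ec(slot_scalar(r, "EC-NUMBER")),
                           substrate_ids = slot_list(r, "LEFT"),
                           product_ids = slot_list(r, "RIGHT"),
                           stringsAsFactors = FALSE),
    compounds = data.frame(compound_id = names(co) %||% character(0),
                           kind = slot_scalar(co, "KIND"),
                           stringsAsFactors = FALSE),
    pathways = data.frame(pathway_id = names(pw) %||% character(0),
                          reaction_ids = slot_list(pw, "REACTION-LIST"),
                          stringsAsFactors = FALSE)
  )
}

format_dat_records <- function(ids, slots) {
  # slots: named list of equally-long lists/vectors of values per record
  n <- length(ids)
  out <- character(0)
  chunks <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- sprintf("UNIQUE-ID - %s", ids[i])
    for (s in names(slots)) {
      v <- slots[[s]][[i]]
      v <- v[!is.na(v) & v != ""]
      if (length(v)) rec <- c(rec, sprintf("%s - %s", s, v))
    }
    chunks[[i]] <- c(rec, "//")
  }
  unlist(chunks, use.names = FALSE) %||% character(0)
}

#' Write a PGDB as BioCyc-style flat files
#'
#' Writes the five `.dat` files in the dialect read by [parse_pgdb()].
#' Records are sorted by identifier and set-valued slots are written one
#' value per line in sorted order, so writing is deterministic and
#' `parse_pgdb(write_pgdb(x, d))` reproduces `x` entity-for-entity.
#'
#' @param x a [pgdb()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pgdb <- function(x, dir) {
  stopifnot(inherits(x, "pgdb"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wl <- function(lines, file) {
    con <- file(file.path(dir, file), open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  }
  wl(format_dat_records(x$genes$gene_id,
       list(`PRODUCT` = x$genes$protein_ids,
            `GO-TERMS` = x$genes$go_terms)), "genes.dat")
  wl(format_dat_records(x$proteins$protein_id,
       list(`GENE` = as.list(x$proteins$gene_id),
            `CATALYZES` = x$proteins$catalyzed_reaction_ids)), "proteins.dat")
  wl(format_dat_records(x$reactions$reaction_id,
       list(`EC-NUMBER` = as.list(x$reactions$ec_number),
            `LEFT` = x$reactions$substrate_ids,
            `RIGHT` = x$reactions$product_ids)), "reactions.dat")
  wl(format_dat_records(x$compounds$compound_id,
       list(`KIND` = as.list(x$compounds$kind))), "compounds.dat")
  wl(format_dat_records(x$pathways$pathway_id,
       list(`REACTION-LIST` = x$pathways$reaction_ids)), "pathways.dat")
  invisible(dir)
}

#' Entity-wise equality of two PGDBs
#'
#' Compares the five entity tables (identifiers, scalar slots and set-valued
#' slots) of two [pgdb()] objects; the resource name is ignored.
#'
#' @param a,b [pgdb()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
pgdb_equal <- function(a, b) {
  strip <- function(x) {
    x <- unclass(x)[c("genes", "proteins", "reactions", "compounds", "pathways")]
    rapply(x, function(v) v, how = "replace")
  }
  isTRUE(all.equal(strip(a), strip(b), check.attributes = FALSE))
}
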