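# Ligand-receptor interaction database: genes, heteromeric complexes, and
# interaction records, with referential-integrity validation and manual
# curation support.

#' Construct a ligand-receptor interaction database
#'
#' The database holds three tables: a gene table (identifiers that must match
#' the expression matrix gene names exactly; no symbol aliasing is applied),
#' a complex table mapping each heteromeric complex to its ordered subunits,
#' and an interaction table whose partners are either gene ids ("simple"
#' partners) or complex ids. Interactions are stored unordered; downstream
#' relevance calling evaluates both orientations.
#'
#' @param genes character vector of gene identifiers.
#' @param complexes named list; each element a character vector of >= 2
#'   subunit gene ids, names are complex ids.
#' @param interactions data frame with columns `interaction_id`, `partner_a`,
#'   `partner_b` and optionally `annotation`.
#' @param version version string recorded in run manifests.
#' @return An object of class `lr_database`.
#' @export
lr_database <- function(genes, complexes = list(), interactions = NULL,
                        version = "0") {
  if (is.null(interactions)) {
    interactions <- data.frame(interaction_id = character(),
                               partner_a = character(),
                               partner_b = character(),
                               annotation = character(),
                               stringsAsFactors = FALSE)
  }
  if (!"annotation" %in% names(interactions)) interactions$annotation <- ""
  interactions <- interactions[, c("interaction_id", "partner_a", "partner_b",
                                   "annotation")]
  db <- structure(
    list(genes = as.character(genes),
         complexes = complexes,
         interactions = interactions,
         version = as.character(version)),
    class = "lr_database"
  )
  validate_lr_database(db)
}

#' @method print lr_database
#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf("lr_database (version %s): %d genes, %d complexes, %d interactions\n",
              x$version, length(x$genes), length(x$complexes),
              nrow(x$interactions)))
  invisible(x)
}

validate_lr_database <- function(db) {
  genes <- db$genes
  if (length(genes) == 0L) {
    abort("gene table is empty", "envcci_integrity_error")
  }
  if (anyNA(genes) || any(!nzchar(genes))) {
    abort("gene table contains empty identifiers", "envcci_integrity_error")
  }
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene ids: %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")),
          "envcci_integrity_error")
  }
  cx <- db$complexes
  if (length(cx)) {
    cids <- names(cx)
    if (is.null(cids) || anyNA(cids) || any(!nzchar(cids))) {
      abort("complex table has unnamed entries", "envcci_integrity_error")
    }
    if (anyDuplicated(cids)) {
      abort(sprintf("duplicate complex ids: %s",
                    paste(unique(cids[duplicated(cids)]), collapse = ", ")),
            "envcci_integrity_error")
    }
    clash <- intersect(cids, genes)
    if (length(clash)) {
      abort(sprintf("complex ids collide with gene ids: %s",
                    paste(clash, collapse = ", ")),
            "envcci_integrity_error")
    }
    short <- cids[vapply(cx, length, integer(1)) < 2L]
    if (length(short)) {
      abort(sprintf("complexes with fewer than 2 subunits: %s",
                    paste(short, collapse = ", ")),
            "envcci_integrity_error")
    }
    dup <- cids[vapply(cx, anyDuplicated, integer(1)) > 0L]
    if (length(dup)) {
      abort(sprintf("complexes with duplicated subunits: %s",
                    paste(dup, collapse = ", ")),
            "envcci_integrity_error")
    }
    orphan <- cids[!vapply(cx, function(s) all(s %in% genes), logical(1))]
    if (length(orphan)) {
      bad <- unique(unlist(lapply(cx[orphan], setdiff, y = genes)))
      abort(sprintf("complexes %s reference unknown gene(s): %s",
                    paste(orphan, collapse = ", "),
                    paste(bad, collapse = ", ")),
            "envcci_integrity_error")
    }
  }
  ia <- db$interactions
  require_columns(ia, c("interaction_id", "partner_a", "partner_b"),
                  "interaction table")
  if (nrow(ia)) {
    if (anyDuplicated(ia$interaction_id)) {
      abort(sprintf("duplicate interaction ids: %s",
                    paste(unique(ia$interaction_id[duplicated(ia$interaction_id)]),
                          collapse = ", ")),
            "envcci_integrity_error")
    }
    known <- c(genes, names(cx))
    bad <- setdiff(c(ia$partner_a, ia$partner_b), known)
    if (length(bad)) {
      abort(sprintf("interaction partners not in database: %s",
                    paste(bad, collapse = ", ")),
            "envcci_integrity_error")
    }
    key <- paste(pmin(ia$partner_a, ia$partner_b),
                 pmax(ia$partner_a, ia$partner_b))
    if (anyDuplicated(key)) {
      abort(sprintf("interactions duplicated up to orientation: %s",
                    paste(ia$interaction_id[duplicated(key) |
                                            duplicated(key, fromLast = TRUE)],
                          collapse = ", ")),
            "envcci_integrity_error")
    }
  }
  db
}

#' Load an interaction database from its three CSV tables
#'
#' The gene table has one column `gene_id`; the complex table has
#' `complex_id` plus `subunit_1 .. subunit_N` columns (blank-padded for
#' complexes with fewer subunits); the interaction table has
#' `interaction_id, partner_a, partner_b, annotation`.
#'
#' @param gene_table_path,complex_table_path,interaction_table_path CSV paths.
#' @param version version string stored on the database.
#' @return A validated `lr_database`.
#' @export
load_lr_database <- function(gene_table_path, complex_table_path,
                             interaction_table_path, version = "0") {
  for (p in c(gene_table_path, complex_table_path, interaction_table_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p),
                               "envcci_schema_error")
  }
  gt <- utils::read.csv(gene_table_path, stringsAsFactors = FALSE)
  require_columns(gt, "gene_id", "gene table")
  ct <- utils::read.csv(complex_table_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  complexes <- list()
  if (nrow(ct)) {
    require_columns(ct, c("complex_id", "subunit_1", "subunit_2"),
                    "complex table")
    sub_cols <- grep("^subunit_", names(ct), value = TRUE)
    sub_cols <- sub_cols[order(as.integer(sub("^subunit_", "", sub_cols)))]
    complexes <- lapply(seq_len(nrow(ct)), function(i) {
      s <- as.character(ct[i, sub_cols])
      s[!is.na(s) & nzchar(s)]
    })
    names(complexes) <- ct$complex_id
  }
  it <- utils::read.csv(interaction_table_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  require_columns(it, c("interaction_id", "partner_a", "partner_b"),
                  "interaction table")
  lr_database(gt$gene_id, complexes, it, version = version)
}

#' Write an interaction database back to its three CSV tables
#'
#' Inverse of [load_lr_database()]; loading the written tables reproduces the
#' database field-for-field.
#'
#' @param db an `lr_database`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_lr_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "genes.csv")
  cp <- file.path(dir, "complexes.csv")
  ip <- file.path(dir, "interactions.csv")
  utils::write.csv(data.frame(gene_id = db$genes), gp, row.names = FALSE)
  nsub <- if (length(db$complexes)) max(vapply(db$complexes, length, integer(1))) else 2L
  cx <- data.frame(complex_id = names(db$complexes), stringsAsFactors = FALSE)
  for (j in seq_len(max(nsub, 2L))) {
    cx[[paste0("subunit_", j)]] <- vapply(db$complexes, function(s) {
      if (length(s) >= j) s[j] else ""
    }, character(1), USE.NAMES = FALSE)
  }
  if (!length(db$complexes)) {
    cx <- data.frame(complex_id = character(), subunit_1 = character(),
                     subunit_2 = character())
  }
  utils::write.csv(cx, cp, row.names = FALSE)
  utils::write.csv(db$interactions, ip, row.names = FALSE)
  invisible(c(genes = gp, complexes = cp, interactions = ip))
}

#' Resolve a partner reference to its member genes
#'
#' A simple partner (gene id) resolves to itself; a complex partner resolves
#' to its subunit list in stored order. The member list is never empty for a
#' resolvable partner.
#'
#' @param db an `lr_database`.
#' @param id a gene id or complex id.
#' @return Character vector of member gene ids.
#' @export
members_of <- function(db, id) {
  if (!is_string(id)) abort("partner id must be a single string",
                            "envcci_lookup_error")
  if (id %in% names(db$complexes)) return(db$complexes[[id]])
  if (id %in% db$genes) return(id)
  abort(sprintf("partner '%s' not found in database", id),
        "envcci_lookup_error")
}

#' Partner kind ("simple" or "complex")
#' @inheritParams members_of
#' @return "simple" or "complex".
#' @export
partner_kind <- function(db, id) {
  if (id %in% names(db$complexes)) return("complex")
  if (id %in% db$genes) return("simple")
  abort(sprintf("partner '%s' not found in database", id),
        "envcci_lookup_error")
}

#' Apply a manual curation table to a database
#'
#' Curation records mirror the complex / interaction table schemas with an
#' extra `action` column taking values `add`, `replace` or `remove`. Rows are
#' applied in table order, so later rows win; the result is re-validated.
#' This is how manually curated entries (for example WNT ligand and
#' Frizzled/LRP heteromeric receptor records) are layered onto a base
#' database without editing it in place.
#'
#' @param db an `lr_database`.
#' @param complex_curation optional data frame: complex schema + `action`.
#' @param interaction_curation optional data frame: interaction schema +
#'   `action`.
#' @return A new validated `lr_database`.
#' @export
apply_curation <- function(db, complex_curation = NULL,
                           interaction_curation = NULL) {
  complexes <- db$complexes
  interactions <- db$interactions
  if (!is.null(complex_curation) && nrow(complex_curation)) {
    require_columns(complex_curation, c("complex_id", "action"),
                    "complex curation table")
    sub_cols <- grep("^subunit_", names(complex_curation), value = TRUE)
    sub_cols <- sub_cols[order(as.integer(sub("^subunit_", "", sub_cols)))]
    for (i in seq_len(nrow(complex_curation))) {
      row <- complex_curation[i, ]
      id <- row$complex_id
      action <- row$action
      subs <- as.character(row[sub_cols])
      subs <- subs[!is.na(subs) & nzchar(subs)]
      if (action == "add") {
        if (id %in% names(complexes)) {
          abort(sprintf("cannot add complex '%s': id already present", id),
                "envcci_curation_error")
        }
        complexes[[id]] <- subs
      } else if (action == "replace") {
        if (!id %in% names(complexes)) {
          abort(sprintf("cannot replace unknown complex '%s'", id),
                "envcci_curation_error")
        }
        complexes[[id]] <- subs
      } else if (action == "remove") {
        if (!id %in% names(complexes)) {
          abort(sprintf("cannot remove unknown complex '%s'", id),
                "envcci_curation_error")
        }
        complexes[[id]] <- NULL
      } else {
        abort(sprintf("unknown curation action '%s'", action),
              "envcci_curation_error")
      }
    }
  }
  if (!is.null(interaction_curation) && nrow(interaction_curation)) {
    require_columns(interaction_curation,
                    c("interaction_id", "action"), "interaction curation table")
    for (i in seq_len(nrow(interaction_curation))) {
      row <- interaction_curation[i, ]
      id <- row$interaction_id
      action <- row$action
      hit <- interactions$interaction_id == id
      if (action == "add") {
        if (any(hit)) {
          abort(sprintf("cannot add interaction '%s': id already present", id),
                "envcci_curation_error")
        }
        interactions <- rbind(interactions,
                              data.frame(interaction_id = id,
                                         partner_a = row$partner_a,
                                         partner_b = row$partner_b,
                                         annotation = row$annotation %||% "",
                                         stringsAsFactors = FALSE))
      } else if (action == "replace") {
        if (!any(hit)) {
          abort(sprintf("cannot replace unknown interaction '%s'", id),
                "envcci_curation_error")
        }
        interactions$partner_a[hit] <- row$partner_a
        interactions$partner_b[hit] <- row$partner_b
        if (!is.null(row$annotation)) interactions$annotation[hit] <- row$annotation
      } else if (action == "remove") {
        if (!any(hit)) {
          abort(sprintf("cannot remove unknown interaction '%s'", id),
                "envcci_curation_error")
        }
        interactions <- interactions[!hit, , drop = FALSE]
      } else {
        abort(sprintf("unknown curation action '%s'", action),
              "envcci_curation_error")
      }
    }
  }
  rownames(interactions) <- NULL
  lr_database(db$genes, complexes, interactions,
              version = paste0(db$version, "+curated"))
}

#' Look up one interaction record
#' @param db an `lr_database`.
#' @param interaction_id interaction identifier.
#' @return One-row data frame of the interaction record.
#' @export
get_interaction <- function(db, interaction_id) {
  hit <- db$interactions$interaction_id == interaction_id
  if (!any(hit)) {
    abort(sprintf("interaction '%s' not found in database", interaction_id),
          "envcci_lookup_error")
  }
  db$interactions[hit, , drop = FALSE]
}
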