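# Validated/predicted miRNA-target interaction store: a flat table with
# TSV import/export, deduplicated on (mirna_id, gene_symbol, source,
# db_origin). Gene symbols are upper-cased on import; species context is
# carried by the miRNA id prefix.

#' Create an empty interaction store
#' @return an [InteractionDb-class] with zero records.
#' @export
interactionDb <- function() new("InteractionDb")

#' Number of stored interactions
#' @param db an [InteractionDb-class].
#' @export
nInteractions <- function(db) nrow(db@interactions)

#' Records added by the most recent import
#' @param db an [InteractionDb-class].
#' @export
lastImportCount <- function(db) db@lastImport

.interactionKey <- function(df) {
  paste(df$mirna_id, df$gene_symbol, df$source, df$evidence, df$db_origin,
        sep = "\r")
}

#' Import interactions from a TSV dump
#'
#' Expects a header with columns `mirna_id`, `gene_symbol`, `evidence`,
#' `db_origin` (miRTarBase/TarBase-style dump). Records are deduplicated on
#' (mirna_id, gene_symbol, source, db_origin); re-importing the same file
#' adds nothing. Imported records get `source = "validated-db"`.
#'
#' @param db an [InteractionDb-class].
#' @param path TSV file path.
#' @return the updated store; the number of records actually added is
#'   available via [lastImportCount()].
#' @export
importInteractions <- function(db, path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("mirna_id", "gene_symbol", "evidence", "db_origin")
  if (!all(need %in% colnames(df))) {
    stop(sprintf("interaction TSV is missing column(s): %s",
                 paste(setdiff(need, colnames(df)), collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("empty interaction file: 0 records imported")
    db@lastImport <- 0L
    return(db)
  }
  df <- data.frame(mirna_id = df$mirna_id,
                   gene_symbol = toupper(df$gene_symbol),
                   source = "validated-db",
                   evidence = df$evidence,
                   db_origin = df$db_origin,
                   stringsAsFactors = FALSE)
  addInteractions(db, df)
}

#' Add interaction records
#'
#' @param db an [InteractionDb-class].
#' @param records data.frame with columns `mirna_id`, `gene_symbol`,
#'   `source`, `evidence`, `db_origin`.
#' @return updated store (duplicates of existing records are skipped).
#' @export
addInteractions <- function(db, records) {
  records$gene_symbol <- toupper(records$gene_symbol)
  records <- records[!duplicated(.interactionKey(records)), , drop = FALSE]
  new_keys <- !.interactionKey(records) %in% .interactionKey(db@interactions)
  records <- records[new_keys, , drop = FALSE]
  db@interactions <- rbind(db@interactions,
                           records[, colnames(db@interactions)])
  rownames(db@interactions) <- NULL
  db@lastImport <- nrow(records)
  validObject(db)
  db
}

#' Query all targets of a miRNA
#'
#' @param db an [InteractionDb-class].
#' @param mirna_id miRNA id; unknown ids give an empty result, not an error.
#' @return data.frame of matching records, stable-ordered by gene symbol.
#' @export
queryTargets <- function(db, mirna_id) {
  out <- db@interactions[db@interactions$mirna_id == mirna_id, , drop = FALSE]
  out <- out[order(out$gene_symbol, out$source, out$db_origin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the store as TSV
#' @param db an [InteractionDb-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportInteractions <- function(db, path) {
  utils::write.table(db@interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Verify stored interactions against UTR sequences
#'
#' For every record, scans the matching gene's 3'-UTR with the recorded
#' miRNA and reports whether at least one canonical seed site exists and
#' the best (highest-priority) mode found. Records whose gene has no UTR
#' available are flagged `"no-utr"`, not dropped.
#'
#' @param db an [InteractionDb-class] (or a data.frame of records).
#' @param mirnas a [MiRNASet-class] providing sequences for the recorded
#'   miRNA ids.
#' @param utrs named [Biostrings::DNAStringSet]; names are gene symbols
#'   (matched case-insensitively against the stored uppercase symbols).
#' @return data.frame: record columns + `has_canonical_site`,
#'   `best_site_type` (`"no-utr"` when the UTR is missing, `NA` when no
#'   site).
#' @export
verifyAgainstUTRs <- function(db, mirnas, utrs) {
  recs <- if (is(db, "InteractionDb")) db@interactions else db
  utr_names <- toupper(names(utrs))
  has <- logical(nrow(recs))
  best <- rep(NA_character_, nrow(recs))
  for (i in seq_len(nrow(recs))) {
    gi <- match(recs$gene_symbol[i], utr_names)
    mi <- match(recs$mirna_id[i], mirnaIds(mirnas))
    if (is.na(gi) || is.na(mi)) {
      best[i] <- "no-utr"
      next
    }
    gr <- scanUTR(stats::setNames(as.character(mirnas@seqs[mi]),
                                  recs$mirna_id[i]),
                  stats::setNames(as.character(utrs[gi]), names(utrs)[gi]))
    if (length(gr) > 0L) {
      has[i] <- TRUE
      tys <- S4Vectors::mcols(gr)$site_type
      best[i] <- SITE_TYPES[min(match(tys, SITE_TYPES))]
    }
  }
  cbind(recs, has_canonical_site = has, best_site_type = best,
        stringsAsFactors = FALSE)
}
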