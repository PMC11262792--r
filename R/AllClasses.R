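#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Set of mature miRNA sequences
#'
#' Container for mature miRNA sequences held 5'->3' in the RNA alphabet,
#' with a species tag per record (typically inferred from the id prefix,
#' e.g. \code{hsa-} or \code{mmu-}).
#'
#' @slot seqs an [Biostrings::RNAStringSet] of mature sequences, named by
#'   miRNA id.
#' @slot species character vector parallel to \code{seqs}.
#'
#' @details Validity requires: unique non-empty ids, sequence lengths
#' between 16 and 30 nt, and no residues outside \code{A,C,G,U}.
#'
#' @exportClass MiRNASet
setClass("MiRNASet",
  representation(seqs = "RNAStringSet", species = "character")
)

setValidity("MiRNASet", function(object) {
  ids <- names(object@seqs)
  if (length(object@seqs) == 0L) return(TRUE)
  if (is.null(ids) || any(!nzchar(ids))) {
    return("all miRNA records must have non-empty ids")
  }
  if (anyDuplicated(ids)) {
    return(sprintf("duplicate miRNA id: %s", ids[duplicated(ids)][1L]))
  }
  if (length(object@species) != length(object@seqs)) {
    return("species tag must be parallel to the sequences")
  }
  w <- Biostrings::width(object@seqs)
  if (any(w < 16L | w > 30L)) {
    bad <- ids[which(w < 16L | w > 30L)[1L]]
    return(sprintf("mature miRNA '%s' has length outside 16-30 nt", bad))
  }
  freq <- Biostrings::alphabetFrequency(object@seqs)
  extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "U"), drop = FALSE])
  if (any(extra > 0)) {
    return(sprintf("miRNA '%s' contains residues outside {A,C,G,U}",
                   ids[which(extra > 0)[1L]]))
  }
  TRUE
})

#' Construct a MiRNASet
#'
#' @param seqs named character vector or [Biostrings::RNAStringSet]
#'   (T is accepted and normalised to U, lowercase upcased).
#' @param species species tag per record; by default inferred from the id
#'   prefix before the first "-" (e.g. \code{"hsa"}, \code{"mmu"}).
#' @return a [MiRNASet-class] object.
#' @examples
#' mir182 <- MiRNASet(c("hsa-miR-182-5p" = "UUUGGCAAUGGUAGAACUCACACU"))
#' mirnaIds(mir182)
#' @export
MiRNASet <- function(seqs, species = NULL) {
  if (is.character(seqs)) {
    seqs <- Biostrings::RNAStringSet(normalizeResidues(seqs, "rna"))
  } else {
    seqs <- Biostrings::RNAStringSet(seqs)
  }
  if (is.null(species)) {
    species <- sub("-.*$", "", names(seqs) %||% character(0))
  }
  new("MiRNASet", seqs = seqs, species = as.character(species))
}

#' @describeIn MiRNASet miRNA ids
#' @param x a \code{MiRNASet}
#' @export
mirnaIds <- function(x) names(x@seqs)

#' @describeIn MiRNASet sequences as a character vector named by id
#' @export
mirnaSeqs <- function(x) {
  stats::setNames(as.character(x@seqs), names(x@seqs))
}

#' @describeIn MiRNASet species tag per record
#' @export
mirnaSpecies <- function(x) stats::setNames(x@species, names(x@seqs))

setMethod("show", "MiRNASet", function(object) {
  cat(sprintf("MiRNASet with %d mature miRNA(s), species: %s\n",
              length(object@seqs),
              paste(unique(object@species), collapse = ", ")))
  if (length(object@seqs) > 0) {
    n <- min(5L, length(object@seqs))
    for (i in seq_len(n)) {
      cat(sprintf("  %s  %s\n", names(object@seqs)[i],
                  as.character(object@seqs[[i]])))
    }
    if (length(object@seqs) > n) cat("  ...\n")
  }
})

#' @describeIn MiRNASet number of records
#' @export
setMethod("length", "MiRNASet", function(x) length(x@seqs))

#' Subset a MiRNASet
#' @param x a \code{MiRNASet}
#' @param i index vector (ids, positions or logical)
#' @param j,...,drop ignored
#' @export
setMethod("[", "MiRNASet", function(x, i, j, ..., drop = TRUE) {
  idx <- if (is.character(i)) match(i, names(x@seqs)) else seq_along(x@seqs)[i]
  new("MiRNASet", seqs = x@seqs[idx], species = x@species[idx])
})

#' Cohort expression + phenotype container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' log2 miRNA expression matrix (assay \code{"log2expr"}, rows = miRNAs,
#' columns = samples) and the per-sample phenotype table in \code{colData}
#' (age, sex, BMI, NAS, HbA1c, glucose, insulin, triglycerides, T2D).
#'
#' @details Validity requires finite expression values, NAS within 0-7 and
#' T2D coded 0/1 wherever those columns are present and non-missing.
#'
#' @exportClass CohortExperiment
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
  if (!"log2expr" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'log2expr' is required")
  }
  m <- SummarizedExperiment::assay(object, "log2expr")
  if (any(!is.finite(m))) return("expression values must be finite")
  cd <- SummarizedExperiment::colData(object)
  if ("NAS" %in% colnames(cd)) {
    nas <- cd$NAS[!is.na(cd$NAS)]
    if (any(nas < 0 | nas > 7)) return("NAS must lie in [0, 7]")
  }
  if ("T2D" %in% colnames(cd)) {
    t2d <- cd$T2D[!is.na(cd$T2D)]
    if (!all(t2d %in% c(0, 1))) return("T2D must be coded 0/1")
  }
  TRUE
})

#' Construct a CohortExperiment
#'
#' @param expr numeric matrix of log2 expression, rows = miRNA ids,
#'   columns = sample ids.
#' @param pheno data.frame of phenotypes with rownames (or column
#'   \code{sample}) matching \code{colnames(expr)} exactly.
#' @param detectionP optional list of per-probe detection p-value vectors,
#'   named by probeset/miRNA, stored in \code{metadata} for the DABG rule.
#' @return a [CohortExperiment-class].
#' @export
CohortExperiment <- function(expr, pheno, detectionP = NULL) {
  if (!is.null(pheno$sample)) {
    rownames(pheno) <- pheno$sample
    pheno$sample <- NULL
  }
  if (!setequal(colnames(expr), rownames(pheno)) ||
      is.null(colnames(expr))) {
    stop("sample ids of the expression matrix and phenotype table must match")
  }
  pheno <- pheno[colnames(expr), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = expr),
    colData = S4Vectors::DataFrame(pheno)
  )
  obj <- new("CohortExperiment", se)
  if (!is.null(detectionP)) metadata(obj)$detectionP <- detectionP
  obj
}

#' @describeIn CohortExperiment the log2 expression matrix
#' @param x a \code{CohortExperiment}
#' @export
log2Expr <- function(x) SummarizedExperiment::assay(x, "log2expr")

#' @describeIn CohortExperiment the phenotype table as a data.frame
#' @export
phenoTable <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Validated/predicted miRNA-target interaction store
#'
#' Flat-table store of miRNA-gene interactions in the style of a
#' miRTarBase/TarBase dump, deduplicated on
#' (mirna_id, gene_symbol, source, db_origin).
#'
#' @slot interactions data.frame with columns \code{mirna_id},
#'   \code{gene_symbol} (uppercase), \code{source} (\code{"validated-db"} or
#'   \code{"predicted-seedscan"}), \code{evidence}, \code{db_origin}.
#' @slot lastImport integer, records added by the most recent import.
#'
#' @exportClass InteractionDb
setClass("InteractionDb",
  representation(interactions = "data.frame", lastImport = "integer"),
  prototype(
    interactions = data.frame(
      mirna_id = character(), gene_symbol = character(),
      source = character(), evidence = character(),
      db_origin = character(), stringsAsFactors = FALSE
    ),
    lastImport = 0L
  )
)

setValidity("InteractionDb", function(object) {
  df <- object@interactions
  need <- c("mirna_id", "gene_symbol", "source", "evidence", "db_origin")
  if (!all(need %in% colnames(df))) {
    return(sprintf("missing column(s): %s",
                   paste(setdiff(need, colnames(df)), collapse = ", ")))
  }
  if (nrow(df) == 0L) return(TRUE)
  if (any(!nzchar(df$gene_symbol))) return("gene_symbol must be non-empty")
  if (any(df$gene_symbol != toupper(df$gene_symbol))) {
    return("gene_symbol must be uppercase")
  }
  if (!all(df$source %in% c("validated-db", "predicted-seedscan"))) {
    return("source must be 'validated-db' or 'predicted-seedscan'")
  }
  key <- paste(df$mirna_id, df$gene_symbol, df$source, df$evidence,
               df$db_origin, sep = "\r")
  if (anyDuplicated(key)) return("duplicate interaction record")
  TRUE
})

setMethod("show", "InteractionDb", function(object) {
  df <- object@interactions
  cat(sprintf("InteractionDb: %d record(s), %d miRNA(s), %d gene(s)\n",
              nrow(df), length(unique(df$mirna_id)),
              length(unique(df$gene_symbol))))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
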