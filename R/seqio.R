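# Sequence I/O and alphabet-safe primitives.
#
# Conventions used throughout the package: miRNAs live in the RNA alphabet
# (A,C,G,U), UTRs in the DNA alphabet (A,C,G,T,N); all coordinates are
# 0-based half-open internally and only rendered 1-based in reports.

.RNA_OK <- c("A", "C", "G", "U")
.DNA_OK <- c("A", "C", "G", "T", "N")

#' Normalize a residue string to one alphabet
#'
#' Upcases and maps U<->T so the result is in the requested alphabet.
#' 'N' is accepted (it matches nothing downstream).
#'
#' @param x character vector of sequences.
#' @param moltype `"rna"` or `"dna"`.
#' @return character vector over `{A,C,G,U,N}` or `{A,C,G,T,N}`.
#' @export
normalizeResidues <- function(x, moltype = c("dna", "rna")) {
  moltype <- match.arg(moltype)
  x <- toupper(x)
  x <- if (moltype == "rna") chartr("T", "U", x) else chartr("U", "T", x)
  ok <- if (moltype == "rna") c(.RNA_OK, "N") else .DNA_OK
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]), ok)
  if (length(bad) > 0) {
    stop(sprintf("disallowed residue '%s' for moltype '%s'",
                 bad[1L], moltype), call. = FALSE)
  }
  x
}

.readFastaRaw <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) > 0) {
    empty <- which(Biostrings::width(set) == 0L)
    if (length(empty) > 0) {
      stop(sprintf("FASTA record %d ('%s') has an empty sequence",
                   empty[1L], names(set)[empty[1L]]), call. = FALSE)
    }
    # id = first whitespace-delimited token of the header
    names(set) <- sub("\\s.*$", "", names(set))
    if (any(!nzchar(names(set)))) {
      stop(sprintf("FASTA record %d has an empty header",
                   which(!nzchar(names(set)))[1L]), call. = FALSE)
    }
  }
  set
}

#' Read mature miRNAs from FASTA
#'
#' Reads a (possibly gzipped, wrapped or unwrapped) FASTA file of mature
#' miRNA sequences written 5'->3'. T is normalised to U, lowercase upcased.
#'
#' @param path FASTA file path.
#' @param species optional species tag(s); default inferred from id prefix.
#' @return a [MiRNASet-class]; empty file gives an empty set.
#' @export
readMiRNAFasta <- function(path, species = NULL) {
  set <- .readFastaRaw(path)
  MiRNASet(stats::setNames(normalizeResidues(as.character(set), "rna"),
                           names(set)),
           species = species)
}

#' Read 3'-UTR sequences from FASTA
#'
#' Position 0 of each record is the first base after the stop codon.
#' U is normalised to T; N is permitted.
#'
#' @param path FASTA file path.
#' @return a named [Biostrings::DNAStringSet]; ids must be unique.
#' @export
readUTRFasta <- function(path) {
  set <- .readFastaRaw(path)
  seqs <- normalizeResidues(as.character(set), "dna")
  if (anyDuplicated(names(set))) {
    stop(sprintf("duplicate UTR id: %s",
                 names(set)[duplicated(names(set))][1L]), call. = FALSE)
  }
  Biostrings::DNAStringSet(stats::setNames(seqs, names(set)))
}

#' Write sequences to FASTA
#'
#' @param x a [MiRNASet-class], [Biostrings::XStringSet] or named character
#'   vector.
#' @param path output path (".gz" suffix compresses).
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is(x, "MiRNASet")) x <- x@seqs
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Reverse complement
#'
#' Base-by-base complement, reversed, emitted in the requested alphabet.
#' An involution when input and output alphabets agree. N complements to N.
#'
#' @param seq character vector of sequences (RNA or DNA, mixed case ok).
#' @param out output alphabet, `"dna"` (default) or `"rna"`.
#' @return character vector of reverse complements.
#' @examples
#' revComp("UUGGCAA")           # "TTGCCAA", the miR-182-5p 7mer-m8 motif
#' @export
revComp <- function(seq, out = c("dna", "rna")) {
  out <- match.arg(out)
  seq <- normalizeResidues(seq, "dna")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  rc <- unname(rc)
  if (out == "rna") chartr("T", "U", rc) else rc
}
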