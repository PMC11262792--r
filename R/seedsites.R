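# Canonical seed-match site detection.
#
# With miRNA positions numbered 1..n from the 5' end, the five canonical
# pairing modes map to target-strand motifs (DNA, written 5'->3'):
#   6mer        revcomp(nt 2-7)
#   7mer-m8     revcomp(nt 2-8)
#   7mer-A1     revcomp(nt 2-7) + "A"   (literal A facing miRNA position 1)
#   8mer        revcomp(nt 2-8) + "A"
#   offset-6mer revcomp(nt 3-8)
#
# A "locus" is the seed register: the target coordinate that pairs (or, for
# the offset-6mer, would pair) miRNA position 2. All modes matching at one
# register collapse to one site labeled with the highest-priority mode.

#' Canonical seed-site types, highest priority first
#' @export
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "offset-6mer")

# priority rank, larger = stronger
.SITE_PRIORITY <- stats::setNames(c(5L, 4L, 3L, 2L, 1L), SITE_TYPES)

# offset from a mode's own match start to the seed register, and motif length
.MODE_REG_OFF <- stats::setNames(c(6L, 6L, 5L, 5L, 6L), SITE_TYPES)
.MODE_LEN     <- stats::setNames(c(8L, 7L, 7L, 6L, 6L), SITE_TYPES)

.mirnaSeq1 <- function(mirna) {
  if (is(mirna, "MiRNASet")) {
    if (length(mirna) != 1L) stop("expected a single miRNA", call. = FALSE)
    return(stats::setNames(as.character(mirna@seqs), mirnaIds(mirna)))
  }
  if (length(mirna) != 1L) stop("expected a single miRNA", call. = FALSE)
  stats::setNames(normalizeResidues(as.character(mirna), "rna"),
                  names(mirna) %||% "miRNA")
}

#' Target motifs of the five canonical pairing modes
#'
#' @param mirna a single mature miRNA: character sequence (5'->3') or a
#'   length-1 [MiRNASet-class]. Must be at least 9 nt.
#' @return named character vector of DNA motifs (target strand, 5'->3')
#'   for `8mer`, `7mer-m8`, `7mer-A1`, `6mer`, `offset-6mer`.
#' @examples
#' seedMotifs("UUUGGCAAUGGUAGAACUCACACU")[["7mer-m8"]]  # "TTGCCAA"
#' @export
seedMotifs <- function(mirna) {
  s <- .mirnaSeq1(mirna)
  if (nchar(s) < 9L) {
    stop("miRNA must be at least 9 nt for seed motif construction",
         call. = FALSE)
  }
  nt <- function(a, b) substr(s, a, b)
  core6 <- revComp(nt(2, 7))           # pairs miRNA nt 2-7
  core7 <- revComp(nt(2, 8))           # pairs miRNA nt 2-8
  c("8mer"        = paste0(core7, "A"),
    "7mer-m8"     = core7,
    "7mer-A1"     = paste0(core6, "A"),
    "6mer"        = core6,
    "offset-6mer" = revComp(nt(3, 8)))
}

# per-mode matches of one miRNA across a DNAStringSet of UTRs;
# returns data.frame(utr_id, mode, start0) with 0-based starts
.modeMatches <- function(motifs, utrs) {
  out <- vector("list", length(SITE_TYPES))
  for (k in seq_along(SITE_TYPES)) {
    mode <- SITE_TYPES[k]
    hits <- Biostrings::vmatchPattern(motifs[[mode]], utrs, fixed = TRUE)
    st <- BiocGenerics::start(hits)   # IntegerList, 1-based
    n <- lengths(st)
    if (sum(n) == 0L) next
    out[[k]] <- data.frame(
      utr_id = rep(names(utrs), n),
      mode = mode,
      start0 = unlist(st, use.names = FALSE) - 1L,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

.siteGRanges <- function(df, utrs, mirna_id, collapse) {
  if (is.null(df) || nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths =
            stats::setNames(Biostrings::width(utrs), names(utrs)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      mirna_id = character(), site_type = character(), start0 = integer(),
      end0 = integer(), motif = character(), all_modes = character(),
      register0 = integer()
    )
    return(gr)
  }
  df$register0 <- df$start0 + .MODE_REG_OFF[df$mode]
  if (collapse) {
    key <- paste(df$utr_id, df$register0, sep = "\r")
    pr <- .SITE_PRIORITY[df$mode]
    keep <- integer(0)
    modes_by_key <- split(df$mode, key)
    top_by_key <- vapply(split(seq_len(nrow(df)), key), function(idx) {
      idx[which.max(pr[idx])]
    }, integer(1))
    df_top <- df[top_by_key, , drop = FALSE]
    ord_modes <- vapply(modes_by_key, function(m) {
      paste(m[order(-.SITE_PRIORITY[m])], collapse = ",")
    }, character(1))
    df_top$all_modes <- ord_modes[names(top_by_key)]
    df <- df_top
  } else {
    df$all_modes <- df$mode
  }
  df$len <- .MODE_LEN[df$mode]
  df$end0 <- df$start0 + df$len
  df <- df[order(match(df$utr_id, names(utrs)), df$start0, -.SITE_PRIORITY[df$mode]), ]
  motif <- substr(as.character(utrs[df$utr_id]), df$start0 + 1L, df$end0)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$utr_id, levels = names(utrs)),
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0),
    strand = "+",
    seqlengths = stats::setNames(Biostrings::width(utrs), names(utrs))
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    mirna_id = mirna_id,
    site_type = df$mode,
    start0 = df$start0,
    end0 = df$end0,
    motif = unname(motif),
    all_modes = df$all_modes,
    register0 = df$register0
  )
  names(gr) <- NULL
  gr
}

#' Scan one 3'-UTR for canonical seed sites of one miRNA
#'
#' Every UTR locus whose substring equals a pairing-mode motif is reported.
#' With `collapse = TRUE` (default) all modes matching at one seed register
#' are merged into a single site labeled with the highest-priority mode,
#' the remaining modes retained in `all_modes`. Loci overlapping 'N' are
#' never reported. Output is deterministic and sorted by start.
#'
#' @param mirna single mature miRNA (character 5'->3' or length-1
#'   [MiRNASet-class]); a name supplies the miRNA id.
#' @param utr single UTR: named character or length-1
#'   [Biostrings::DNAStringSet].
#' @param collapse merge modes at one register into one site?
#'   `FALSE` enumerates one row per (mode, start) match.
#' @return a [GenomicRanges::GRanges] (1-based ranges) with metadata
#'   columns `mirna_id`, `site_type`, `start0`, `end0` (0-based half-open),
#'   `motif`, `all_modes`, `register0`.
#' @examples
#' scanUTR(c("hsa-miR-182-5p" = "UUUGGCAAUGGUAGAACUCACACU"),
#'         c(LRP6 = "ACGTACGTTGCCAATACGT"))
#' @export
scanUTR <- function(mirna, utr, collapse = TRUE) {
  s <- .mirnaSeq1(mirna)
  if (is.character(utr)) {
    utr <- Biostrings::DNAStringSet(
      stats::setNames(normalizeResidues(utr, "dna"), names(utr) %||% "UTR"))
  }
  if (length(utr) != 1L) stop("expected a single UTR", call. = FALSE)
  motifs <- seedMotifs(s)
  df <- if (Biostrings::width(utr)[1L] >= 6L) .modeMatches(motifs, utr) else NULL
  .siteGRanges(df, utr, names(s), collapse)
}

#' Scan many miRNAs against many UTRs
#'
#' Concatenation of [scanUTR()] over the Cartesian product, in stable
#' (utr, mirna, start) order.
#'
#' @param mirnas a [MiRNASet-class] (ids must be unique).
#' @param utrs a named [Biostrings::DNAStringSet] (ids must be unique).
#' @param collapse see [scanUTR()].
#' @return a [GenomicRanges::GRanges] of all sites.
#' @export
scanSeedSites <- function(mirnas, utrs, collapse = TRUE) {
  if (!is(mirnas, "MiRNASet")) stop("'mirnas' must be a MiRNASet")
  if (is.character(utrs)) {
    utrs <- Biostrings::DNAStringSet(normalizeResidues(utrs, "dna"))
  }
  if (length(mirnas) == 0L || length(utrs) == 0L) {
    stop("non-empty miRNA and UTR sets required", call. = FALSE)
  }
  if (is.null(names(utrs)) || anyDuplicated(names(utrs))) {
    stop("UTR ids must be present and unique", call. = FALSE)
  }
  scannable <- Biostrings::width(utrs) >= 6L
  per_mirna <- lapply(seq_len(length(mirnas)), function(i) {
    id <- mirnaIds(mirnas)[i]
    motifs <- seedMotifs(as.character(mirnas@seqs[[i]]))
    df <- if (any(scannable)) {
      .modeMatches(motifs, utrs[scannable])
    }
    gr <- .siteGRanges(df, utrs, id, collapse)
    gr
  })
  gr <- do.call(c, per_mirna)
  # stable (utr, mirna, start) order
  ord <- order(as.integer(GenomicRanges::seqnames(gr)),
               match(S4Vectors::mcols(gr)$mirna_id, mirnaIds(mirnas)),
               S4Vectors::mcols(gr)$start0)
  gr[ord]
}

#' Seed-site GRanges as a plain table
#'
#' @param sites GRanges from [scanUTR()]/[scanSeedSites()].
#' @return data.frame with columns utr_id, mirna_id, site_type, start0,
#'   end0, motif, all_modes.
#' @export
siteTable <- function(sites) {
  mc <- as.data.frame(S4Vectors::mcols(sites))
  data.frame(
    utr_id = as.character(GenomicRanges::seqnames(sites)),
    mirna_id = mc$mirna_id,
    site_type = mc$site_type,
    start0 = mc$start0,
    end0 = mc$end0,
    motif = mc$motif,
    all_modes = mc$all_modes,
    stringsAsFactors = FALSE
  )
}

#' Write seed sites as TSV
#' @param sites GRanges of sites.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSitesTSV <- function(sites, path) {
  utils::write.table(siteTable(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write seed sites as BED6
#'
#' chrom = utr id, 0-based half-open coordinates, name = `mirna|type`,
#' score = priority rank, strand "+".
#' @param sites GRanges of sites.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSitesBED <- function(sites, path) {
  tb <- siteTable(sites)
  bed <- data.frame(tb$utr_id, tb$start0, tb$end0,
                    paste0(tb$mirna_id, "|", tb$site_type),
                    unname(.SITE_PRIORITY[tb$site_type]), "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
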