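# Binding-context features for detected seed sites: local AU content,
# 3'-supplementary pairing, position within the UTR, proximity to the stop
# codon, and cooperative neighbouring sites. Features are reported
# independently; no composite score is computed.

.utrChar1 <- function(utr) {
  if (is(utr, "DNAStringSet")) {
    if (length(utr) != 1L) stop("expected a single UTR", call. = FALSE)
    return(as.character(utr)[[1L]])
  }
  if (is(utr, "DNAString")) return(as.character(utr))
  normalizeResidues(as.character(utr)[[1L]], "dna")
}

#' Local AU content around a seed site
#'
#' Fraction of A/T residues among the up-to-`flank` nt immediately 5' and
#' up-to-`flank` nt immediately 3' of the site (site residues excluded;
#' default 30 nt per side, i.e. 60 nt surrounding the seed). Windows are
#' truncated at the UTR boundaries and N residues are excluded from both
#' numerator and denominator.
#'
#' @param utr single UTR sequence (character or DNAString(Set)).
#' @param start0,end0 0-based half-open site coordinates.
#' @param flank flank width per side, nt.
#' @return fraction in `[0, 1]`, or `NA` when no flank residue is available.
#' @export
auContent <- function(utr, start0, end0, flank = 30L) {
  s <- .utrChar1(utr)
  len <- nchar(s)
  if (start0 < 0 || end0 > len || start0 >= end0) {
    stop("site does not lie within the UTR", call. = FALSE)
  }
  left <- substr(s, max(0L, start0 - flank) + 1L, start0)
  right <- substr(s, end0 + 1L, min(len, end0 + flank))
  ch <- strsplit(paste0(left, right), "")[[1L]]
  ch <- ch[ch != "N"]
  if (length(ch) == 0L) return(NA_real_)
  mean(ch %in% c("A", "T"))
}

# Watson-Crick partner of each RNA residue on the DNA target strand
.WC_DNA <- c(A = "T", C = "G", G = "C", U = "A")

#' 3'-supplementary pairing of a seed site
#'
#' Maximum number of contiguous Watson-Crick pairs formed between miRNA
#' positions `window[1]..window[2]` (default 12-17, the canonical
#' supplementary region) and the UTR region 5' of the site, antiparallel
#' and anchored at the seed register, allowing a target offset of up to
#' `offsetTol` nt in either direction. 0 when no pair forms or the UTR
#' truncates the window.
#'
#' @param mirna single mature miRNA (character 5'->3').
#' @param utr single UTR sequence.
#' @param register0 0-based target coordinate pairing miRNA position 2
#'   (column `register0` of [scanUTR()] output).
#' @param window integer length-2, miRNA positions considered.
#' @param offsetTol maximum absolute target offset, nt.
#' @return integer count of contiguous pairs, 0..`diff(window)+1`.
#' @export
threePrimePairing <- function(mirna, utr, register0,
                              window = c(12L, 17L), offsetTol = 2L) {
  m <- .mirnaSeq1(mirna)
  s <- .utrChar1(utr)
  len <- nchar(s)
  ks <- seq.int(window[1L], window[2L])
  ks <- ks[ks <= nchar(m)]
  if (length(ks) == 0L) return(0L)
  mres <- substring(m, ks, ks)
  want <- .WC_DNA[mres]                 # target base required for a pair
  best <- 0L
  for (d in seq.int(-offsetTol, offsetTol)) {
    pos0 <- register0 - (ks - 2L) + d   # antiparallel register
    inb <- pos0 >= 0L & pos0 < len
    tbase <- rep(NA_character_, length(ks))
    if (any(inb)) {
      tbase[inb] <- substring(s, pos0[inb] + 1L, pos0[inb] + 1L)
    }
    hit <- !is.na(tbase) & tbase == want
    run <- 0L; mx <- 0L
    for (h in hit) {
      run <- if (h) run + 1L else 0L
      mx <- max(mx, run)
    }
    best <- max(best, mx)
  }
  best
}

#' Positional features of a seed site
#'
#' @param utr single UTR sequence.
#' @param start0,end0 0-based half-open site coordinates.
#' @return list with `dist_stop` (nt from the stop codon, i.e. UTR 5' end,
#'   to site start), `dist_end` (site end to UTR 3' end), `rel_pos`
#'   (`min(dist_stop, dist_end)/length`, in `[0, 0.5]`) and `near_stop`
#'   (`dist_stop < 15`).
#' @export
positionalFeatures <- function(utr, start0, end0) {
  len <- nchar(.utrChar1(utr))
  if (start0 < 0 || end0 > len || start0 >= end0) {
    stop("site does not lie within the UTR", call. = FALSE)
  }
  dist_stop <- as.integer(start0)
  dist_end <- as.integer(len - end0)
  list(dist_stop = dist_stop,
       dist_end = dist_end,
       rel_pos = min(dist_stop, dist_end) / len,
       near_stop = dist_stop < 15L)
}

#' Cooperative site pairs on one UTR
#'
#' All unordered pairs of sites (same or different miRNA) whose inter-site
#' gap -- end of the upstream site to start of the downstream site -- lies
#' in `[minGap, maxGap]` nt. Overlapping or abutting pairs (gap < minGap)
#' are excluded.
#'
#' @param sites [GenomicRanges::GRanges] of sites, all on the same UTR.
#' @param minGap,maxGap gap bounds, nt (defaults 8 and 40).
#' @return data.frame with columns `idA`, `idB` (site ids of the form
#'   `mirna_id@start0`), `gap`; zero rows when no pair qualifies.
#' @export
cooperativeSites <- function(sites, minGap = 8L, maxGap = 40L) {
  empty <- data.frame(idA = character(), idB = character(), gap = integer(),
                      stringsAsFactors = FALSE)
  if (length(sites) <= 1L) return(empty)
  utr_ids <- unique(as.character(GenomicRanges::seqnames(sites)))
  if (length(utr_ids) > 1L) {
    stop("all sites must lie on the same UTR", call. = FALSE)
  }
  mc <- S4Vectors::mcols(sites)
  id <- paste0(mc$mirna_id, "@", mc$start0)
  n <- length(sites)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # downstream start minus upstream end; overlaps fall below minGap
      if (mc$start0[j] >= mc$end0[i]) gap <- mc$start0[j] - mc$end0[i]
      else if (mc$start0[i] >= mc$end0[j]) gap <- mc$start0[i] - mc$end0[j]
      else gap <- -1L
      if (gap >= minGap && gap <= maxGap) {
        rows[[length(rows) + 1L]] <- data.frame(
          idA = id[i], idB = id[j], gap = gap, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Annotate seed sites with binding-context features
#'
#' Assembles [auContent()], [threePrimePairing()], [positionalFeatures()]
#' and [cooperativeSites()] for every site; fields are reported
#' independently (no combined score).
#'
#' @param sites [GenomicRanges::GRanges] from [scanSeedSites()].
#' @param mirnas the [MiRNASet-class] the sites were scanned with.
#' @param utrs the named [Biostrings::DNAStringSet] scanned.
#' @param flank AU-content flank per side, nt.
#' @param window,offsetTol see [threePrimePairing()].
#' @param minGap,maxGap see [cooperativeSites()].
#' @return the input GRanges with added metadata columns `local_au`,
#'   `tp_pairing`, `dist_stop`, `dist_end`, `rel_pos`, `near_stop`,
#'   `coop_partners` (comma-separated partner site ids).
#' @export
annotateSites <- function(sites, mirnas, utrs, flank = 30L,
                          window = c(12L, 17L), offsetTol = 2L,
                          minGap = 8L, maxGap = 40L) {
  mc <- S4Vectors::mcols(sites)
  n <- length(sites)
  useq <- stats::setNames(as.character(utrs), names(utrs))
  mseq <- mirnaSeqs(mirnas)
  la <- numeric(n); tp <- integer(n)
  ds <- integer(n); de <- integer(n); rp <- numeric(n); ns <- logical(n)
  coop <- character(n)
  utr_of <- as.character(GenomicRanges::seqnames(sites))
  site_id <- paste0(mc$mirna_id, "@", mc$start0)
  for (u in unique(utr_of)) {
    idx <- which(utr_of == u)
    pairs <- cooperativeSites(sites[idx], minGap = minGap, maxGap = maxGap)
    for (ii in idx) {
      s <- useq[[u]]
      la[ii] <- auContent(s, mc$start0[ii], mc$end0[ii], flank = flank)
      tp[ii] <- threePrimePairing(mseq[[mc$mirna_id[ii]]], s,
                                  mc$register0[ii],
                                  window = window, offsetTol = offsetTol)
      pf <- positionalFeatures(s, mc$start0[ii], mc$end0[ii])
      ds[ii] <- pf$dist_stop; de[ii] <- pf$dist_end
      rp[ii] <- pf$rel_pos; ns[ii] <- pf$near_stop
      mine <- site_id[ii]
      partners <- c(pairs$idB[pairs$idA == mine], pairs$idA[pairs$idB == mine])
      coop[ii] <- paste(partners, collapse = ",")
    }
  }
  mc$local_au <- la; mc$tp_pairing <- tp
  mc$dist_stop <- ds; mc$dist_end <- de
  mc$rel_pos <- rp; mc$near_stop <- ns
  mc$coop_partners <- coop
  S4Vectors::mcols(sites) <- mc
  sites
}

#' Write annotated sites as TSV
#' @param sites annotated GRanges from [annotateSites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotatedTSV <- function(sites, path) {
  tb <- cbind(siteTable(sites),
              as.data.frame(S4Vectors::mcols(sites))[
                , c("local_au", "tp_pairing", "dist_stop", "dist_end",
                    "rel_pos", "near_stop", "coop_partners")])
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
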