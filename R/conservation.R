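# Cross-species conservation by 7mer seed identity: two mature miRNAs are
# in the same seed family when nucleotides 2-8 are identical (RNA alphabet),
# irrespective of the rest of the sequence or the arm annotation.

#' Partition miRNAs into 7mer seed families
#'
#' Groups mature miRNAs by exact identity of nucleotides 2-8. Families are
#' returned in deterministic order (sorted by seed string).
#'
#' @param mirnas a [MiRNASet-class]; every sequence must be at least 8 nt
#'   (guaranteed by the class validity).
#' @return data.frame with one row per member: `seed7`, `mirna_id`,
#'   `species`; attribute `"families"` carries the per-family summary
#'   (`seed7`, `n_members`, `n_species`).
#' @export
seedFamilies <- function(mirnas) {
  if (!is(mirnas, "MiRNASet")) stop("'mirnas' must be a MiRNASet")
  if (length(mirnas) == 0L) {
    out <- data.frame(seed7 = character(), mirna_id = character(),
                      species = character(), stringsAsFactors = FALSE)
    attr(out, "families") <- data.frame(seed7 = character(),
                                        n_members = integer(),
                                        n_species = integer())
    return(out)
  }
  seqs <- mirnaSeqs(mirnas)
  seed7 <- substr(seqs, 2L, 8L)
  out <- data.frame(seed7 = unname(seed7),
                    mirna_id = names(seqs),
                    species = unname(mirnaSpecies(mirnas)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$seed7, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  fam <- stats::aggregate(cbind(n_members = mirna_id) ~ seed7, out, length)
  nsp <- stats::aggregate(species ~ seed7, out,
                          function(s) length(unique(s)))
  fam$n_species <- nsp$species[match(fam$seed7, nsp$seed7)]
  attr(out, "families") <- fam
  out
}

#' Seed-level conservation between two miRNA sets
#'
#' Declares a seed family shared when it occurs in both species' sets, and
#' tallies both per-family and per-miRNA (the counting unit of the
#' human-mouse overlap is the expressed mature miRNA of the query species).
#'
#' @param setA,setB [MiRNASet-class] objects, one per species.
#' @return list with `shared_seeds`, `a_only_seeds`, `b_only_seeds`
#'   (character vectors of 7mer seeds), `pairs` (data.frame of id pairs
#'   sharing a seed) and `counts` (per-family and per-miRNA tallies for
#'   both sets).
#' @export
conservedBetween <- function(setA, setB) {
  fa <- seedFamilies(setA)
  fb <- seedFamilies(setB)
  sa <- unique(fa$seed7); sb <- unique(fb$seed7)
  shared <- sort(intersect(sa, sb))
  a_only <- sort(setdiff(sa, sb))
  b_only <- sort(setdiff(sb, sa))
  pa <- fa[fa$seed7 %in% shared, , drop = FALSE]
  pb <- fb[fb$seed7 %in% shared, , drop = FALSE]
  pairs <- merge(pa[, c("seed7", "mirna_id")],
                 pb[, c("seed7", "mirna_id")],
                 by = "seed7", suffixes = c("_A", "_B"))
  pairs <- pairs[order(pairs$seed7, pairs$mirna_id_A, pairs$mirna_id_B), ]
  rownames(pairs) <- NULL
  list(
    shared_seeds = shared,
    a_only_seeds = a_only,
    b_only_seeds = b_only,
    pairs = pairs,
    counts = list(
      families = c(shared = length(shared), a_only = length(a_only),
                   b_only = length(b_only)),
      mirnas_A = c(conserved = sum(fa$seed7 %in% shared),
                   exclusive = sum(!fa$seed7 %in% shared)),
      mirnas_B = c(conserved = sum(fb$seed7 %in% shared),
                   exclusive = sum(!fb$seed7 %in% shared))
    )
  )
}

#' Conserved miRNA ids of a query set
#'
#' Convenience wrapper: ids of `query` whose 7mer seed also occurs in
#' `reference`.
#' @param query,reference [MiRNASet-class] objects.
#' @return character vector of conserved ids of `query`.
#' @export
conservedIds <- function(query, reference) {
  fq <- seedFamilies(query)
  fr <- seedFamilies(reference)
  sort(fq$mirna_id[fq$seed7 %in% fr$seed7])
}
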