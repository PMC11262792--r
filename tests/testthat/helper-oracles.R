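# Shared fixtures and independent brute-force oracles. The oracles use
# only base string operations so they stay independent of the package's
# Biostrings-based implementation.

MIR182 <- "UUUGGCAAUGGUAGAACUCACACU"   # hsa-miR-182-5p, mature, 5'->3'
LRP6_WT  <- "ACGTACGTTGCCAATACGT"      # carries the 7mer-m8 target motif
LRP6_MUT <- "ACGTACGTTGACAATACGT"      # central C -> A seed mutant

ALL_MODES <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "offset-6mer")

# base-by-base complement oracle (RNA or DNA input, DNA output)
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# mode motifs by brute-force antiparallel pairing over positions 1-8
oracle_motifs <- function(mirna) {
  nt <- strsplit(toupper(mirna), "")[[1]]
  sub <- function(a, b) paste(nt[a:b], collapse = "")
  c("8mer"        = paste0(oracle_revcomp(sub(2, 8)), "A"),
    "7mer-m8"     = oracle_revcomp(sub(2, 8)),
    "7mer-A1"     = paste0(oracle_revcomp(sub(2, 7)), "A"),
    "6mer"        = oracle_revcomp(sub(2, 7)),
    "offset-6mer" = oracle_revcomp(sub(3, 8)))
}

# naive sliding-window scan: every window of length 6/7/8 string-compared
# against the mode motifs; returns sorted "mode:start0" keys
oracle_scan <- function(mirna, utr) {
  motifs <- oracle_motifs(mirna)
  utr <- toupper(utr)
  n <- nchar(utr)
  keys <- character(0)
  for (mode in names(motifs)) {
    L <- nchar(motifs[[mode]])
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    hit <- substring(utr, starts, starts + L - 1L) == motifs[[mode]]
    if (any(hit)) keys <- c(keys, paste0(mode, ":", starts[hit] - 1L))
  }
  sort(keys)
}

site_keys <- function(gr) {
  if (length(gr) == 0L) return(character(0))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  sort(paste0(mc$site_type, ":", mc$start0))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# GRanges of synthetic sites on one UTR, for context-module tests
make_sites <- function(starts, lens, utr_len, utr_id = "u",
                       mirna_id = "m") {
  gr <- GenomicRanges::GRanges(
    seqnames = utr_id,
    ranges = IRanges::IRanges(start = starts + 1L, end = starts + lens),
    strand = "+",
    seqlengths = stats::setNames(utr_len, utr_id))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    mirna_id = rep_len(mirna_id, length(starts)),
    site_type = rep_len("6mer", length(starts)),
    start0 = as.integer(starts), end0 = as.integer(starts + lens),
    motif = rep_len("", length(starts)),
    all_modes = rep_len("6mer", length(starts)),
    register0 = as.integer(starts + 5L))
  gr
}

# cohort with the study's planted-effect conditions (see methods vignette)
recovery_cohort <- function(seed, nSamples = 500L, nMirnas = 200L) {
  genCohort(
    nSamples, nMirnas,
    effects = data.frame(
      mirna = rep(1:5, each = 3),
      response = rep(c("T2D", "glucose", "triglycerides"), 5),
      beta = rep(c(1, 6, 15), 5)),
    confounderProxies = 6:8,
    seed = seed)
}

candidate_ids <- sprintf("sim-mir-%04d", 1:5)
proxy_ids <- sprintf("sim-mir-%04d", 6:8)

write_fasta_tmp <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
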