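# Seeded synthetic-data generators. Every generator is a deterministic
# function of its arguments plus `seed` and returns the emitted data
# together with a PlantedTruth record sufficient to score the downstream
# module without re-deriving parameters.
#
# Background sequences are i.i.d. with adjustable GC (no dinucleotide
# structure); cohorts emulate the screening design (covariates age, sex,
# BMI, NAS; continuous traits from a linear model, T2D from a logistic
# model with the intercept centred on a target prevalence).

#' Generate UTRs with planted seed sites
#'
#' Background residues are drawn i.i.d. at the requested GC content;
#' planted motifs are spliced in at exact positions. Background occurrences
#' of motifs are permitted (and discoverable by a scanner).
#'
#' @param n number of UTRs.
#' @param length UTR length, nt (recycled).
#' @param gc background GC fraction.
#' @param plants data.frame with columns `utr` (1-based UTR index),
#'   `mirna_id`, `site_type` (one of [SITE_TYPES]) and `position` (0-based
#'   motif start); may be `NULL`.
#' @param mirnas [MiRNASet-class] supplying sequences for the planted
#'   miRNA ids.
#' @param seed RNG seed.
#' @return list with `utrs` (named [Biostrings::DNAStringSet], ids
#'   `utr0001`...) and `truth` (data.frame `utr_id`, `mirna_id`,
#'   `site_type`, `start0`, plus the seed as an attribute).
#' @export
genUTRs <- function(n, length, gc = 0.5, plants = NULL, mirnas = NULL,
                    seed) {
  set.seed(seed)
  lens <- rep_len(length, n)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(prob), L, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  ids <- sprintf("utr%04d", seq_len(n))
  truth <- data.frame(utr_id = character(), mirna_id = character(),
                      site_type = character(), start0 = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(plants) && nrow(plants) > 0L) {
    if (is.null(mirnas)) stop("'mirnas' required when planting sites")
    for (u in unique(plants$utr)) {
      pu <- plants[plants$utr == u, , drop = FALSE]
      motifs <- lapply(pu$mirna_id, function(id) {
        seedMotifs(mirnaSeqs(mirnas)[[id]])
      })
      w <- vapply(seq_len(nrow(pu)), function(i) {
        nchar(motifs[[i]][[pu$site_type[i]]])
      }, integer(1))
      if (any(pu$position < 0L | pu$position + w > lens[u])) {
        stop("planted site does not fit within the UTR", call. = FALSE)
      }
      iv <- cbind(pu$position, pu$position + w)
      iv <- iv[order(iv[, 1L]), , drop = FALSE]
      if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L])) {
        stop("planted sites overlap", call. = FALSE)
      }
      s <- seqs[u]
      for (i in seq_len(nrow(pu))) {
        motif <- motifs[[i]][[pu$site_type[i]]]
        substr(s, pu$position[i] + 1L, pu$position[i] + w[i]) <- motif
      }
      seqs[u] <- s
      truth <- rbind(truth, data.frame(
        utr_id = ids[u], mirna_id = pu$mirna_id,
        site_type = pu$site_type, start0 = as.integer(pu$position),
        stringsAsFactors = FALSE))
    }
  }
  attr(truth, "seed") <- seed
  list(utrs = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
       truth = truth)
}

# generative coefficients of the continuous traits: intercept and loadings
# on NAS, age, sex, BMI, plus the residual noise SD, in plausible clinical
# units (HbA1c %, glucose mg/dl, insulin mU/l, triglycerides mg/dl)
.TRAIT_GEN <- list(
  HbA1c         = list(b = c(5.6, 0.12, 0.010, 0.05, 0.004), sd = 0.8),
  glucose       = list(b = c(80, 2.0, 0.20, 2.0, 0.15), sd = 12),
  insulin       = list(b = c(6, 1.0, 0.02, 0.5, 0.12), sd = 4),
  triglycerides = list(b = c(90, 6.0, 0.40, 12.0, 0.50), sd = 35)
)

#' Generate a synthetic screening cohort
#'
#' Covariates: age ~ U(20, 70) years, sex ~ Bernoulli(0.5), BMI ~
#' U(32, 85) kg/m2, NAS uniform on the integers 0-7. Continuous traits are
#' linear in (NAS, age, sex, BMI) plus Gaussian noise; T2D follows a
#' logistic model with the linear predictor centred to hit `prevalence`.
#' Expression is Gaussian around a per-miRNA baseline (log2 scale);
#' planted effects add `beta * (expression - baseline)` to the named
#' response (for T2D, on the logit scale); confounder-proxy miRNAs track
#' standardised age instead of carrying trait effects.
#'
#' @param nSamples cohort size (>= 20).
#' @param nMirnas number of simulated miRNAs (ids `sim-mir-0001`...).
#' @param effects data.frame with columns `mirna` (index or id),
#'   `response` (a trait name or `"T2D"`) and `beta`; may be `NULL`.
#' @param confounderProxies indices or ids of miRNAs simulated as pure
#'   age proxies.
#' @param exprSd per-sample SD of log2 expression around the baseline.
#' @param prevalence target T2D prevalence (default 0.5, a matched
#'   case/control design).
#' @param seed RNG seed.
#' @return list with `cohort` (a [CohortExperiment-class]) and `truth`
#'   (list: `effects`, `proxies`, `seed`).
#' @export
genCohort <- function(nSamples, nMirnas, effects = NULL,
                      confounderProxies = character(0), exprSd = 1,
                      prevalence = 0.5, seed) {
  if (nSamples < 20L) stop("nSamples must be at least 20", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("sim-mir-%04d", seq_len(nMirnas))
  .resolve <- function(x) if (is.numeric(x)) ids[x] else as.character(x)
  proxies <- .resolve(confounderProxies)
  if (!is.null(effects)) {
    effects$mirna <- .resolve(effects$mirna)
    bad <- setdiff(effects$mirna, ids)
    if (length(bad) > 0L) {
      stop(sprintf("effect on unknown miRNA '%s'", bad[1L]), call. = FALSE)
    }
    if (!all(effects$response %in% c(names(.TRAIT_GEN), "T2D"))) {
      stop("plantable responses are the continuous traits and T2D",
           call. = FALSE)
    }
  }
  age <- round(stats::runif(nSamples, 20, 70))
  sex <- stats::rbinom(nSamples, 1L, 0.5)
  BMI <- round(stats::runif(nSamples, 32, 85), 1)
  NAS <- sample(0:7, nSamples, replace = TRUE)
  baseline <- stats::runif(nMirnas, 3, 8)
  expr <- matrix(stats::rnorm(nMirnas * nSamples, sd = exprSd),
                 nrow = nMirnas) + baseline
  rownames(expr) <- ids
  colnames(expr) <- sprintf("s%04d", seq_len(nSamples))
  for (p in proxies) {
    i <- match(p, ids)
    expr[i, ] <- baseline[i] + (age - mean(age)) / stats::sd(age) +
      stats::rnorm(nSamples, sd = 0.5)
  }
  centred <- expr - baseline
  plantSum <- function(resp) {
    if (is.null(effects)) return(0)
    e <- effects[effects$response == resp, , drop = FALSE]
    if (nrow(e) == 0L) return(0)
    colSums(centred[e$mirna, , drop = FALSE] * e$beta)
  }
  pheno <- data.frame(age = age, sex = sex, BMI = BMI, NAS = NAS)
  for (tr in names(.TRAIT_GEN)) {
    g <- .TRAIT_GEN[[tr]]
    pheno[[tr]] <- g$b[1] + g$b[2] * NAS + g$b[3] * age + g$b[4] * sex +
      g$b[5] * BMI + plantSum(tr) + stats::rnorm(nSamples, sd = g$sd)
  }
  lp <- 0.25 * NAS + 0.02 * age + 0.2 * sex + 0.02 * BMI + plantSum("T2D")
  lp <- lp - mean(lp) + stats::qlogis(prevalence)
  pheno$T2D <- stats::rbinom(nSamples, 1L, stats::plogis(lp))
  rownames(pheno) <- colnames(expr)
  cohort <- CohortExperiment(expr, pheno)
  list(cohort = cohort,
       truth = list(effects = effects, proxies = proxies, seed = seed))
}

#' Generate a synthetic Ct table
#'
#' For every sample, the housekeeper Ct is drawn from
#' `N(hkMean, hkSd)` and the target Ct is housekeeper + a group-specific
#' dCt draw. Injected outliers have their dCt displaced upward by 8 pooled
#' SDs (at least 6, as required for unambiguous planting).
#'
#' @param groups named list: group -> `c(mean, sd, n)` of the dCt
#'   distribution (each group needs n >= 3).
#' @param hkMean,hkSd housekeeper Ct distribution.
#' @param outliers number of outlier samples to inject (spread over the
#'   groups in order).
#' @param target,housekeeper assay ids used in the emitted table.
#' @param seed RNG seed.
#' @return list with `ct` (long-format Ct table) and `truth` (list:
#'   `ddct` and `fold` per group vs the first group, `outlier_ids`,
#'   `seed`).
#' @export
genCt <- function(groups, hkMean = 20, hkSd = 0.3, outliers = 0L,
                  target = "target", housekeeper = "housekeeper", seed) {
  set.seed(seed)
  gn <- names(groups)
  if (is.null(gn) || length(gn) < 2L) {
    stop("at least two named groups required", call. = FALSE)
  }
  ns <- vapply(groups, function(g) as.integer(g[[3]]), integer(1))
  if (any(ns < 3L)) stop("each group needs n >= 3", call. = FALSE)
  sample_id <- unlist(lapply(seq_along(gn), function(i) {
    sprintf("%s_%02d", gn[i], seq_len(ns[i]))
  }))
  group <- rep(gn, ns)
  dct <- unlist(lapply(groups, function(g) {
    stats::rnorm(as.integer(g[[3]]), mean = g[[1]], sd = g[[2]])
  }), use.names = FALSE)
  outlier_ids <- character(0)
  if (outliers > 0L) {
    idx <- seq_len(min(outliers, length(dct)))
    # displacement relative to the spread of ALL dCt values (the outlier
    # rule pools both groups), well beyond the 6-SD planting minimum
    disp <- 8 * max(stats::sd(dct), .Machine$double.eps)
    dct[idx] <- dct[idx] + disp
    outlier_ids <- sample_id[idx]
  }
  hk <- stats::rnorm(length(dct), hkMean, hkSd)
  ct <- rbind(
    data.frame(sample = sample_id, assay = housekeeper, Ct = hk,
               group = group, stringsAsFactors = FALSE),
    data.frame(sample = sample_id, assay = target, Ct = hk + dct,
               group = group, stringsAsFactors = FALSE)
  )
  rownames(ct) <- NULL
  mu <- vapply(groups, function(g) g[[1]], numeric(1))
  ddct <- mu - mu[[1]]
  list(ct = ct,
       truth = list(ddct = ddct, fold = 2^(-ddct),
                    reference = gn[1L], outlier_ids = outlier_ids,
                    seed = seed))
}
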