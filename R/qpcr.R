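# Delta-delta-Ct quantification: per-sample dCt against a housekeeper
# assay, a pooled 3-SD outlier rule, group fold changes (2^-ddCt) with
# t-test / one-way ANOVA, and confounder-adjusted Pearson correlations.

#' Validate a long-format Ct table
#'
#' @param ct data.frame with columns `sample`, `assay`, `Ct`, `group`.
#' @return the table, invisibly; errors describe the offending record.
#' @export
validateCtTable <- function(ct) {
  need <- c("sample", "assay", "Ct", "group")
  if (!all(need %in% colnames(ct))) {
    stop(sprintf("Ct table is missing column(s): %s",
                 paste(setdiff(need, colnames(ct)), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!is.finite(ct$Ct) | ct$Ct <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("non-finite or non-positive Ct in row %d (sample '%s')",
                 bad[1L], ct$sample[bad[1L]]), call. = FALSE)
  }
  dup <- duplicated(ct[, c("sample", "assay")])
  if (any(dup)) {
    stop(sprintf("duplicate Ct measurement for sample '%s', assay '%s'",
                 ct$sample[dup][1L], ct$assay[dup][1L]), call. = FALSE)
  }
  invisible(ct)
}

#' Per-sample delta-Ct
#'
#' `dCt = Ct(target) - Ct(housekeeper)` per sample. Samples missing either
#' measurement are excluded (recorded in attribute `"excluded"`).
#'
#' @param ct long-format Ct table (see [validateCtTable()]).
#' @param target target assay id.
#' @param housekeeper housekeeper assay id (e.g. hsa-miR-24-3p for miRNA
#'   panels, CASC3/Hprt1 for mRNA panels).
#' @return named numeric vector of dCt values with attributes `"group"`
#'   (group label per retained sample) and `"excluded"`.
#' @export
deltaCt <- function(ct, target, housekeeper) {
  validateCtTable(ct)
  if (!housekeeper %in% ct$assay) {
    stop(sprintf("housekeeper assay '%s' is absent from the table",
                 housekeeper), call. = FALSE)
  }
  if (!target %in% ct$assay) {
    stop(sprintf("target assay '%s' is absent from the table", target),
         call. = FALSE)
  }
  tg <- ct[ct$assay == target, ]
  hk <- ct[ct$assay == housekeeper, ]
  common <- intersect(tg$sample, hk$sample)
  excluded <- setdiff(union(tg$sample, hk$sample), common)
  tg <- tg[match(common, tg$sample), ]
  hk <- hk[match(common, hk$sample), ]
  d <- stats::setNames(tg$Ct - hk$Ct, common)
  attr(d, "group") <- stats::setNames(as.character(tg$group), common)
  attr(d, "excluded") <- excluded
  d
}

#' Pooled 3-SD outlier rule for dCt values
#'
#' A sample is excluded when its dCt lies strictly outside
#' `mean +/- nSD * SD`, with mean and SD computed once over all samples for
#' the gene (both groups pooled, single pass, no re-iteration). A value at
#' exactly the boundary is kept.
#'
#' @param dct named numeric vector of dCt values.
#' @param nSD width of the inclusion interval in standard deviations.
#' @return list with `kept` (named vector, attributes preserved) and
#'   `excluded` (names of removed samples). With fewer than 3 values the
#'   filter is skipped with a warning.
#' @export
outlierFilter <- function(dct, nSD = 3) {
  if (length(dct) < 3L) {
    warning("fewer than 3 samples: outlier filter skipped")
    return(list(kept = dct, excluded = character(0)))
  }
  mu <- mean(dct)
  sdv <- stats::sd(dct)
  out <- abs(dct - mu) > nSD * sdv
  kept <- dct[!out]
  grp <- attr(dct, "group")
  if (!is.null(grp)) attr(kept, "group") <- grp[names(kept)]
  list(kept = kept, excluded = names(dct)[out])
}

#' Group fold changes by the delta-delta-Ct method
#'
#' `ddCt(group) = mean dCt(group) - mean dCt(reference)` and
#' `fold = 2^(-ddCt)`, computed from group means of dCt. Lower dCt in a
#' test group therefore gives a fold change above 1. Two groups are
#' compared by Student's t-test on dCt, more than two by one-way ANOVA.
#'
#' @param dct named numeric dCt vector (e.g. from [deltaCt()]).
#' @param groups group label per sample; defaults to the `"group"`
#'   attribute of `dct`.
#' @param reference reference group label (fold of the reference is 1).
#' @param filterOutliers apply [outlierFilter()] first (pooled rule)?
#' @param nSD see [outlierFilter()].
#' @return object of class `"qpcrFold"`: list with `groups` (data.frame of
#'   per-group n, mean dCt, ddCt, fold), `reference`, `test` ("t-test" or
#'   "anova"), `statistic`, `p.value`, `excluded`.
#' @export
foldChange <- function(dct, groups = NULL, reference,
                       filterOutliers = TRUE, nSD = 3) {
  if (is.null(groups)) groups <- attr(dct, "group")
  if (is.null(groups)) stop("group labels required", call. = FALSE)
  groups <- stats::setNames(as.character(groups), names(dct))
  excluded <- character(0)
  if (filterOutliers && length(dct) >= 3L) {
    fl <- outlierFilter(dct, nSD = nSD)
    excluded <- fl$excluded
    dct <- fl$kept
    groups <- groups[names(dct)]
  }
  if (!reference %in% groups) {
    stop(sprintf("reference group '%s' is empty after filtering", reference),
         call. = FALSE)
  }
  tab <- table(groups)
  if (any(tab == 0L)) {
    stop(sprintf("group '%s' is empty after filtering",
                 names(tab)[tab == 0L][1L]), call. = FALSE)
  }
  if (length(tab) < 2L) {
    stop("at least two groups required", call. = FALSE)
  }
  lev <- c(reference, setdiff(sort(names(tab)), reference))
  mean_dct <- vapply(lev, function(g) mean(dct[groups == g]), numeric(1))
  ddct <- mean_dct - mean_dct[[reference]]
  fold <- 2^(-ddct)
  gf <- factor(groups, levels = lev)
  if (length(lev) == 2L) {
    test <- "t-test"
    ht <- tryCatch(stats::t.test(dct[gf == lev[2L]], dct[gf == lev[1L]],
                                 var.equal = TRUE),
                   error = function(e) NULL)  # zero within-group variance
    statistic <- if (is.null(ht)) NA_real_ else unname(ht$statistic)
    p <- if (is.null(ht)) NA_real_ else ht$p.value
  } else {
    fit <- stats::aov(dct ~ gf)
    sm <- summary(fit)[[1L]]
    test <- "anova"; statistic <- sm[["F value"]][1L]
    p <- sm[["Pr(>F)"]][1L]
  }
  structure(list(
    groups = data.frame(group = lev, n = as.integer(tab[lev]),
                        mean_dct = unname(mean_dct),
                        ddct = unname(ddct), fold = unname(fold),
                        stringsAsFactors = FALSE),
    reference = reference, test = test,
    statistic = statistic, p.value = p, excluded = excluded
  ), class = "qpcrFold")
}

#' @export
print.qpcrFold <- function(x, ...) {
  cat(sprintf("ddCt fold changes (reference: %s)\n", x$reference))
  print(x$groups, row.names = FALSE)
  cat(sprintf("%s: statistic = %.3f, p = %.4g; %d outlier(s) excluded\n",
              x$test, x$statistic, x$p.value, length(x$excluded)))
  invisible(x)
}

#' Confounder-adjusted Pearson correlation
#'
#' Residualises both variables on the adjusters (ordinary least squares)
#' and computes the Pearson correlation of the residuals (partial
#' correlation). With no adjusters this reduces exactly to the plain
#' Pearson correlation.
#'
#' @param x,y numeric vectors (e.g. dCt values and a metabolic trait).
#' @param covars data.frame of adjusters (e.g. age, sex), or `NULL`.
#' @return list with `r`, `p`, `n`; `r` and `p` are `NA` when a variable
#'   has zero variance after residualisation or fewer than
#'   `4 + ncol(covars)` complete cases remain.
#' @export
adjustedCorrelation <- function(x, y, covars = NULL) {
  df <- data.frame(.x = x, .y = y)
  if (!is.null(covars) && ncol(as.data.frame(covars)) > 0L) {
    covars <- as.data.frame(covars)
    df <- cbind(df, covars)
  } else {
    covars <- NULL
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  nadj <- if (is.null(covars)) 0L else ncol(covars)
  if (nrow(df) < 4L + nadj) return(list(r = NA_real_, p = NA_real_,
                                        n = nrow(df)))
  if (!is.null(covars)) {
    adj <- colnames(df)[-(1:2)]
    rx <- stats::residuals(stats::lm(stats::reformulate(adj, ".x"), df))
    ry <- stats::residuals(stats::lm(stats::reformulate(adj, ".y"), df))
  } else {
    rx <- df$.x; ry <- df$.y
  }
  # variance numerically zero after residualisation -> undefined
  tol_x <- 1e-12 * max(stats::var(df$.x), 1)
  tol_y <- 1e-12 * max(stats::var(df$.y), 1)
  if (stats::var(rx) <= tol_x || stats::var(ry) <= tol_y) {
    return(list(r = NA_real_, p = NA_real_, n = nrow(df)))
  }
  ht <- stats::cor.test(rx, ry, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = nrow(df))
}

#' Adjusted-correlation screen with BH-FDR
#'
#' Applies [adjustedCorrelation()] of each variable against a trait and
#' adjusts the p-value family by [bhFdr()].
#'
#' @param xs named list of numeric vectors (dCt or expression).
#' @param trait numeric trait vector (parallel to each `xs` element).
#' @param covars data.frame of adjusters, or `NULL`.
#' @return data.frame with `name`, `r`, `p`, `n`, `q`.
#' @export
correlationScreen <- function(xs, trait, covars = NULL) {
  rows <- lapply(names(xs), function(nm) {
    res <- adjustedCorrelation(xs[[nm]], trait, covars)
    data.frame(name = nm, r = res$r, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  idx <- which(!is.na(out$p))
  if (length(idx) > 0L) out$q[idx] <- bhFdr(out$p[idx])
  out
}
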