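# Cohort screening layer: expression filters, trait/T2D regression models
# with covariates (NAS, age, sex, BMI), confounder exclusion, BH-FDR and
# candidate selection.
#
# Model for a trait response y and one miRNA m:
#   y = b0 + b1*NAS + b2*age + b3*sex + b4*BMI + b5*log2(m)
# linear for continuous traits, logistic (binomial IRLS) for T2D. A
# covariate that is itself the response is removed from the design. The
# reported p-value is the Wald test of b5; effect sizes describe the change
# of the trait per 1 log2 unit of miRNA expression.

.T2D_TRAITS <- c("T2D", "HbA1c", "glucose", "NAS", "insulin", "triglycerides")

.separated <- function(fitted, eps = 1e-10) {
  any(fitted < eps) || any(fitted > 1 - eps)
}

#' Detection-above-background (DABG) filter
#'
#' A probeset is considered expressed when strictly more than half of its
#' probes detect signal above background (per-probe p < `alpha`).
#'
#' @param detectionP named list: probeset -> numeric vector of per-probe
#'   detection p-values.
#' @param alpha per-probe significance level.
#' @return character vector of expressed probeset names.
#' @export
dabgFilter <- function(detectionP, alpha = 0.05) {
  n <- lengths(detectionP)
  if (any(n == 0L)) {
    stop(sprintf("probeset '%s' has no probe p-values",
                 names(detectionP)[which(n == 0L)[1L]]), call. = FALSE)
  }
  frac <- vapply(detectionP, function(p) mean(p < alpha), numeric(1))
  names(detectionP)[frac > 0.5]
}

#' Confident-expression filter
#'
#' A miRNA is retained when the maximum over groups of its group-mean log2
#' value strictly exceeds `threshold` (default 2.3, the minimal group-mean
#' log2 value treated as "is expressed").
#'
#' @param x a [CohortExperiment-class] or log2 expression matrix
#'   (rows = miRNAs).
#' @param groups factor/vector of group labels per sample; defaults to the
#'   T2D column of the phenotype table.
#' @param threshold strict lower bound on the best group mean.
#' @return character vector of retained miRNA ids.
#' @export
expressionFilter <- function(x, groups = NULL, threshold = 2.3) {
  m <- if (is(x, "CohortExperiment")) log2Expr(x) else x
  if (is.null(groups) && is(x, "CohortExperiment")) {
    groups <- phenoTable(x)$T2D
  }
  groups <- as.factor(groups)
  if (length(groups) != ncol(m)) {
    stop("'groups' must have one label per sample", call. = FALSE)
  }
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  gm <- vapply(levels(groups), function(g) {
    rowMeans(m[, groups == g, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = nrow(m))
  keep <- apply(gm, 1L, max) > threshold
  rownames(m)[keep]
}

# assemble the model frame for one miRNA and one response
.modelFrame <- function(x, mirna_id, response,
                        covars = c("NAS", "age", "sex", "BMI")) {
  ph <- phenoTable(x)
  if (!mirna_id %in% rownames(log2Expr(x))) {
    stop(sprintf("unknown miRNA '%s'", mirna_id), call. = FALSE)
  }
  if (!response %in% colnames(ph)) {
    stop(sprintf("unknown response '%s'", response), call. = FALSE)
  }
  covars <- setdiff(covars, response)
  df <- ph[, unique(c(response, covars)), drop = FALSE]
  df$log2mir <- as.numeric(log2Expr(x)[mirna_id, ])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  attr(df, "covars") <- covars
  df
}

.waldFit <- function(df, response, covars, logistic) {
  fml <- stats::reformulate(c(covars, "log2mir"), response = response)
  if (stats::var(df[[response]]) == 0) {
    stop(sprintf("response '%s' is constant: degenerate model", response),
         call. = FALSE)
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    if (logistic) {
      stats::glm(fml, data = df, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100L))
    } else {
      stats::lm(fml, data = df)
    },
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient (singular) design", call. = FALSE)
  }
  converged <- if (logistic) {
    # fitted probabilities numerically 0 or 1 indicate (quasi-)separation,
    # which the IRLS epsilon criterion alone does not catch
    fit$converged && !sep_warn && !.separated(fit$fitted.values)
  } else TRUE
  sm <- summary(fit)$coefficients
  p <- if (converged) sm["log2mir", 4L] else NA_real_
  list(coef = co, p = p, n = nrow(df), converged = converged)
}

#' Fit the trait (or T2D) model for one miRNA
#'
#' @param x a [CohortExperiment-class].
#' @param mirna_id row of the expression matrix to test.
#' @param response a phenotype column; `"T2D"` fits a logistic model, any
#'   other (continuous) response a linear model. When the response is
#'   itself a design covariate (e.g. NAS) it is removed from the design.
#' @return one-row data.frame: `mirna_id`, `response`, `model`, `b0`
#'   (intercept), `b1` (NAS), `b2` (age), `b3` (sex), `b4` (BMI), `b5`
#'   (log2 miRNA), `p` (Wald p of `b5`; `NA` when not converged), `n`,
#'   `converged`. Coefficients of covariates dropped from the design are
#'   `NA`.
#' @export
fitTraitModel <- function(x, mirna_id, response) {
  df <- .modelFrame(x, mirna_id, response)
  covars <- attr(df, "covars")
  logistic <- identical(response, "T2D")
  ft <- .waldFit(df, response, covars, logistic)
  beta <- c(b0 = unname(ft$coef["(Intercept)"]),
            b1 = if ("NAS" %in% covars) unname(ft$coef["NAS"]) else NA_real_,
            b2 = if ("age" %in% covars) unname(ft$coef["age"]) else NA_real_,
            b3 = if ("sex" %in% covars) unname(ft$coef["sex"]) else NA_real_,
            b4 = if ("BMI" %in% covars) unname(ft$coef["BMI"]) else NA_real_,
            b5 = unname(ft$coef["log2mir"]))
  data.frame(mirna_id = mirna_id, response = response,
             model = if (logistic) "logistic" else "linear",
             t(beta), p = ft$p, n = ft$n, converged = ft$converged,
             stringsAsFactors = FALSE)
}

#' Age/BMI confounder check for one miRNA
#'
#' Fits `age = b0 + b1*HbA1c + b3*sex + b4*BMI + b5*log2mir` and
#' `BMI = b0 + b1*HbA1c + b3*sex + b4*age + b5*log2mir`; the miRNA is
#' flagged as confounder-associated when the Wald p of `b5` is below
#' `alpha`.
#'
#' @param x a [CohortExperiment-class].
#' @param mirna_id miRNA to test.
#' @param alpha significance level for the flags.
#' @return list with logical `age_associated`, `bmi_associated` and the
#'   two p-values.
#' @export
confounderCheck <- function(x, mirna_id, alpha = 0.05) {
  p <- c(age = NA_real_, BMI = NA_real_)
  for (resp in c("age", "BMI")) {
    covars <- c("HbA1c", "sex", if (resp == "age") "BMI" else "age")
    df <- .modelFrame(x, mirna_id, resp, covars = covars)
    ft <- .waldFit(df, resp, covars, logistic = FALSE)
    p[[resp]] <- ft$p
  }
  list(age_associated = !is.na(p[["age"]]) && p[["age"]] < alpha,
       bmi_associated = !is.na(p[["BMI"]]) && p[["BMI"]] < alpha,
       p_age = unname(p[["age"]]), p_bmi = unname(p[["BMI"]]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment. The family should be all miRNAs tested for one
#' response.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return q-values in the input order; `q >= p` elementwise.
#' @export
bhFdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Wald fit against a prebuilt design matrix (shared across the miRNAs of
# one response; valid because expression values are finite by class
# validity, so complete cases depend on the phenotypes only). Uses the
# same least-squares / binomial-IRLS machinery as lm()/glm(), via
# stats::lm.fit / stats::glm.fit, without the per-fit formula overhead.
.waldFitMatrix <- function(y, Xbase, m, logistic) {
  X <- cbind(Xbase, log2mir = m)
  p <- ncol(X)
  n <- length(y)
  if (logistic) {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-8,
                                                  maxit = 100L)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (fit$rank < p) stop("rank-deficient (singular) design", call. = FALSE)
    converged <- fit$converged && !sep_warn && !.separated(fit$fitted.values)
    covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    z <- fit$coefficients[p] / sqrt(covmat[p, p])
    pv <- if (converged) 2 * stats::pnorm(-abs(z)) else NA_real_
  } else {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < p) stop("rank-deficient (singular) design", call. = FALSE)
    converged <- TRUE
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - p)
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    covmat <- sigma2 * chol2inv(R)
    tval <- fit$coefficients[p] / sqrt(covmat[p, p])
    pv <- 2 * stats::pt(-abs(tval), df = n - p)
  }
  list(coef = fit$coefficients, p = pv, n = n, converged = converged)
}

# design matrix (intercept + covariates) and response for one model family
.designFor <- function(x, response, covars) {
  ph <- phenoTable(x)
  covars <- setdiff(covars, response)
  df <- ph[, unique(c(response, covars)), drop = FALSE]
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  Xbase <- cbind(`(Intercept)` = 1,
                 as.matrix(df[, covars, drop = FALSE]))
  list(y = df[[response]], Xbase = Xbase, covars = covars, keep = which(cc))
}

#' Run the association screen over many miRNAs and responses
#'
#' Fits the trait model of [fitTraitModel()] for every (miRNA, response)
#' pair -- sharing the design matrix across the miRNAs of one response for
#' speed -- and adds BH q-values within each response family (across the
#' miRNAs tested). Row-by-row the output agrees with [fitTraitModel()].
#'
#' @param x a [CohortExperiment-class].
#' @param mirna_ids miRNAs to screen; default all rows.
#' @param responses phenotype responses; default
#'   `c("T2D", "HbA1c", "glucose", "NAS", "insulin", "triglycerides")`.
#' @return data.frame of [fitTraitModel()] rows plus column `q`.
#' @export
associationScreen <- function(x, mirna_ids = NULL, responses = .T2D_TRAITS) {
  if (is.null(mirna_ids)) mirna_ids <- rownames(log2Expr(x))
  expr <- log2Expr(x)
  rows <- vector("list", length(mirna_ids) * length(responses))
  k <- 0L
  for (resp in responses) {
    logistic <- identical(resp, "T2D")
    d <- .designFor(x, resp, c("NAS", "age", "sex", "BMI"))
    if (stats::var(d$y) == 0) {
      stop(sprintf("response '%s' is constant: degenerate model", resp),
           call. = FALSE)
    }
    for (id in mirna_ids) {
      k <- k + 1L
      ft <- .waldFitMatrix(d$y, d$Xbase, expr[id, d$keep], logistic)
      co <- ft$coef
      beta <- vapply(c("NAS", "age", "sex", "BMI"), function(v) {
        if (v %in% d$covars) unname(co[v]) else NA_real_
      }, numeric(1))
      rows[[k]] <- data.frame(
        mirna_id = id, response = resp,
        model = if (logistic) "logistic" else "linear",
        b0 = unname(co["(Intercept)"]), b1 = beta[["NAS"]],
        b2 = beta[["age"]], b3 = beta[["sex"]], b4 = beta[["BMI"]],
        b5 = unname(co["log2mir"]),
        p = ft$p, n = ft$n, converged = ft$converged,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (resp in responses) {
    idx <- which(out$response == resp & !is.na(out$p))
    if (length(idx) > 0L) out$q[idx] <- bhFdr(out$p[idx])
  }
  out
}

#' Age/BMI confounder flags for many miRNAs
#'
#' Vectorised version of [confounderCheck()] (same models, shared design
#' matrices).
#'
#' @param x a [CohortExperiment-class].
#' @param mirna_ids miRNAs to test; default all rows.
#' @param alpha significance level for the flags.
#' @return data.frame with `mirna_id`, `age_associated`, `bmi_associated`,
#'   `p_age`, `p_bmi`.
#' @export
confounderScreen <- function(x, mirna_ids = NULL, alpha = 0.05) {
  if (is.null(mirna_ids)) mirna_ids <- rownames(log2Expr(x))
  expr <- log2Expr(x)
  pm <- matrix(NA_real_, nrow = length(mirna_ids), ncol = 2L,
               dimnames = list(mirna_ids, c("age", "BMI")))
  for (resp in c("age", "BMI")) {
    covars <- c("HbA1c", "sex", if (resp == "age") "BMI" else "age")
    d <- .designFor(x, resp, covars)
    for (id in mirna_ids) {
      ft <- .waldFitMatrix(d$y, d$Xbase, expr[id, d$keep], logistic = FALSE)
      pm[id, resp] <- ft$p
    }
  }
  data.frame(mirna_id = mirna_ids,
             age_associated = !is.na(pm[, "age"]) & pm[, "age"] < alpha,
             bmi_associated = !is.na(pm[, "BMI"]) & pm[, "BMI"] < alpha,
             p_age = unname(pm[, "age"]), p_bmi = unname(pm[, "BMI"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select candidate miRNAs from screen results
#'
#' A miRNA is a candidate when it (i) passed the expression filter,
#' (ii) is associated (raw Wald p < `alpha`, converged fits only) with at
#' least `minAssoc` distinct responses, (iii) is associated with neither
#' age nor BMI in the confounder models, and (iv) -- when conservation is
#' required -- is seed-conserved in the second species. Raw p-values drive
#' candidacy; q-values are carried along for reporting.
#'
#' @param screen data.frame from [associationScreen()].
#' @param confounders data.frame with columns `mirna_id`,
#'   `age_associated`, `bmi_associated` (e.g. from [confounderCheck()]
#'   applied per miRNA).
#' @param expressed character vector of miRNAs passing
#'   [expressionFilter()].
#' @param conserved character vector of conserved miRNA ids, or `NULL`.
#' @param alpha per-response association level.
#' @param minAssoc minimum number of distinct associated responses
#'   ("multiple associations", default 2).
#' @param requireConserved apply the conservation criterion? Defaults to
#'   `TRUE` when `conserved` is given.
#' @param requireT2D must T2D itself be among the associated responses?
#' @return data.frame per miRNA: `mirna_id`, `passed_expression`,
#'   `n_assoc`, `assoc_traits`, `age_associated`, `bmi_associated`,
#'   `conserved`, `candidate`.
#' @export
selectCandidates <- function(screen, confounders, expressed,
                             conserved = NULL, alpha = 0.05,
                             minAssoc = 2L,
                             requireConserved = !is.null(conserved),
                             requireT2D = FALSE) {
  ids <- unique(screen$mirna_id)
  ok <- !is.na(screen$p) & screen$converged & screen$p < alpha
  rows <- lapply(ids, function(id) {
    hit <- screen$response[ok & screen$mirna_id == id]
    conf <- confounders[confounders$mirna_id == id, , drop = FALSE]
    age_a <- isTRUE(conf$age_associated[1L])
    bmi_a <- isTRUE(conf$bmi_associated[1L])
    cons <- if (is.null(conserved)) NA else id %in% conserved
    cand <- (id %in% expressed) &&
      length(hit) >= minAssoc &&
      (!requireT2D || "T2D" %in% hit) &&
      !age_a && !bmi_a &&
      (!requireConserved || isTRUE(cons))
    data.frame(mirna_id = id,
               passed_expression = id %in% expressed,
               n_assoc = length(hit),
               assoc_traits = paste(hit, collapse = ","),
               age_associated = age_a, bmi_associated = bmi_a,
               conserved = cons, candidate = cand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
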