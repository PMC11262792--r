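test_that("DABG keeps probesets with a strict majority of detected probes", {
  dp <- list(a = c(0.01, 0.02, 0.03, 0.2),   # 3/4 detected
             b = c(0.01, 0.02, 0.9, 0.9),    # exactly half
             c = c(0.5, 0.6, 0.7))           # none
  expect_equal(dabgFilter(dp), "a")
  expect_error(dabgFilter(list(a = c(0.01), bad = numeric(0))), "bad")
})

test_that("expression filter uses a strict threshold on the best group mean", {
  m <- rbind(hi = c(2.4, 2.4, 1.0, 1.0),
             edge = c(2.3, 2.3, 2.3, 2.3),
             big = c(8, 8, 8, 8))
  colnames(m) <- paste0("s", 1:4)
  groups <- c("A", "A", "B", "B")
  expect_equal(expressionFilter(m, groups), c("hi", "big"))
  expect_error(expressionFilter(m, c("A", "A")), "one label per sample")
})

test_that("planted continuous effect is recovered within tolerance", {
  g <- genCohort(500, 10,
                 effects = data.frame(mirna = 1, response = "HbA1c",
                                      beta = 0.8),
                 seed = 202)
  fit <- fitTraitModel(g$cohort, "sim-mir-0001", "HbA1c")
  expect_equal(fit$model, "linear")
  expect_lt(abs(fit$b5 - 0.8), 0.1)
  expect_lt(fit$p, 1e-6)
  expect_true(fit$converged)
  # NAS as response drops NAS from the design
  nasfit <- fitTraitModel(g$cohort, "sim-mir-0001", "NAS")
  expect_true(is.na(nasfit$b1))
  expect_false(is.na(nasfit$b2))
})

test_that("linear coefficients equal the normal-equations solution", {
  set.seed(77)
  g <- genCohort(60, 3, seed = 31)
  x <- g$cohort
  fit <- fitTraitModel(x, "sim-mir-0002", "glucose")
  ph <- phenoTable(x)
  X <- cbind(1, ph$NAS, ph$age, ph$sex, ph$BMI,
             as.numeric(log2Expr(x)["sim-mir-0002", ]))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% ph$glucose)
  expect_equal(unname(unlist(fit[c("b0", "b1", "b2", "b3", "b4", "b5")])),
               as.numeric(beta_oracle), tolerance = 1e-8)
})

test_that("degenerate designs error instead of returning coefficients", {
  g <- genCohort(40, 2, seed = 5)
  x <- g$cohort
  ph <- phenoTable(x)
  ph$glucose <- 100                     # constant response
  xc <- CohortExperiment(log2Expr(x), ph)
  expect_error(fitTraitModel(xc, "sim-mir-0001", "glucose"), "constant")

  expr <- log2Expr(x)
  expr["sim-mir-0001", ] <- 4.2         # constant miRNA, collinear design
  xs <- CohortExperiment(expr, phenoTable(x))
  expect_error(fitTraitModel(xs, "sim-mir-0001", "glucose"), "singular")
})

test_that("perfectly separated logistic fits are flagged, p withheld", {
  g <- genCohort(80, 2, seed = 8)
  x <- g$cohort
  expr <- log2Expr(x)
  ph <- phenoTable(x)
  expr["sim-mir-0001", ] <- ifelse(ph$T2D == 1, 10, 1)  # perfect separation
  xs <- CohortExperiment(expr, ph)
  fit <- fitTraitModel(xs, "sim-mir-0001", "T2D")
  expect_false(fit$converged)
  expect_true(is.na(fit$p))

  # and non-converged fits never count as associations
  scr <- associationScreen(xs, "sim-mir-0001", responses = "T2D")
  conf <- data.frame(mirna_id = "sim-mir-0001", age_associated = FALSE,
                     bmi_associated = FALSE)
  cand <- selectCandidates(scr, conf, expressed = "sim-mir-0001",
                           minAssoc = 1L)
  expect_equal(cand$n_assoc, 0L)
})

test_that("age-proxy miRNAs are flagged, independent ones are not", {
  g <- genCohort(400, 4, confounderProxies = 1, seed = 55)
  proxy <- confounderCheck(g$cohort, "sim-mir-0001")
  expect_true(proxy$age_associated)
  indep <- confounderCheck(g$cohort, "sim-mir-0003")
  expect_false(indep$age_associated)
  expect_false(indep$bmi_associated)
  # vectorised screen agrees with the per-miRNA check
  scr <- confounderScreen(g$cohort)
  expect_equal(scr$p_age[1], proxy$p_age)
  expect_equal(scr$age_associated,
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("BH q-values equal the brute-force step-up computation", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.2), 0.2)
  expect_error(bhFdr(c(0.1, 0)), "0, 1")
  expect_error(bhFdr(c(0.1, 1.2)), "0, 1")

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    qs <- numeric(m)
    for (i in seq_len(m)) qs[i] <- min(1, min(p[o][i:m] * m / (i:m)))
    out <- numeric(m)
    out[o] <- qs
    out
  }
  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bhFdr(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p))
    # order invariance
    perm <- sample(length(p))
    expect_equal(bhFdr(p[perm]), q[perm])
  }
})

test_that("screen rows agree with the reference single fits", {
  g <- genCohort(80, 5, seed = 123)
  x <- g$cohort
  scr <- associationScreen(x)
  for (resp in c("HbA1c", "T2D", "NAS")) {
    ref <- do.call(rbind, lapply(rownames(log2Expr(x)), function(id) {
      fitTraitModel(x, id, resp)
    }))
    sub <- scr[scr$response == resp, ]
    expect_equal(sub$b5, ref$b5, tolerance = 1e-10)
    expect_equal(sub$p, ref$p, tolerance = 1e-10)
    expect_equal(sub$n, ref$n)
  }
  # q-values are the BH adjustment within each response family
  hb <- scr[scr$response == "HbA1c", ]
  expect_equal(hb$q, bhFdr(hb$p))
})

test_that("candidate rules combine expression, traits, confounding, conservation", {
  mk_screen <- function(id, traits_sig) {
    traits <- c("T2D", "HbA1c", "glucose", "NAS", "insulin", "triglycerides")
    data.frame(mirna_id = id, response = traits, model = "linear",
               b0 = 0, b1 = 0, b2 = 0, b3 = 0, b4 = 0, b5 = 1,
               p = ifelse(traits %in% traits_sig, 0.01, 0.5),
               n = 100L, converged = TRUE, q = NA_real_,
               stringsAsFactors = FALSE)
  }
  screen <- rbind(mk_screen("good", c("T2D", "HbA1c", "glucose")),
                  mk_screen("aged", c("T2D", "HbA1c")),
                  mk_screen("single", "T2D"),
                  mk_screen("quiet", character(0)))
  conf <- data.frame(mirna_id = c("good", "aged", "single", "quiet"),
                     age_associated = c(FALSE, TRUE, FALSE, FALSE),
                     bmi_associated = FALSE)
  expressed <- c("good", "aged", "single", "quiet")
  rep1 <- selectCandidates(screen, conf, expressed,
                           conserved = c("good", "aged"))
  expect_equal(rep1$candidate,
               c(TRUE, FALSE, FALSE, FALSE))   # aged excluded by confounder
  expect_equal(rep1$n_assoc, c(3L, 2L, 1L, 0L))
  # conservation requirement can exclude an otherwise valid candidate
  rep2 <- selectCandidates(screen, conf, expressed, conserved = "aged")
  expect_false(rep2$candidate[rep2$mirna_id == "good"])
  # requiring T2D among the associations
  rep3 <- selectCandidates(mk_screen("noT2D", c("HbA1c", "glucose")),
                           data.frame(mirna_id = "noT2D",
                                      age_associated = FALSE,
                                      bmi_associated = FALSE),
                           "noT2D", requireT2D = TRUE)
  expect_false(rep3$candidate)
})
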