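mk_ct <- function(samples, target_ct, hk_ct, groups,
                  target = "miR-182", hk = "miR-24") {
  rbind(data.frame(sample = samples, assay = target, Ct = target_ct,
                   group = groups, stringsAsFactors = FALSE),
        data.frame(sample = samples, assay = hk, Ct = hk_ct,
                   group = groups, stringsAsFactors = FALSE))
}

test_that("delta-Ct is the per-sample difference to the housekeeper", {
  ct <- mk_ct(c("a", "b"), c(25, 26.7), c(20, 21.7), c("ND", "ND"))
  d <- deltaCt(ct, "miR-182", "miR-24")
  expect_equal(as.vector(d), c(5, 5))   # +1.7 shift on both assays cancels
  expect_equal(names(d), c("a", "b"))

  # sample missing the housekeeper is excluded, others intact
  ct2 <- ct[!(ct$sample == "b" & ct$assay == "miR-24"), ]
  d2 <- deltaCt(ct2, "miR-182", "miR-24")
  expect_equal(names(d2), "a")
  expect_equal(attr(d2, "excluded"), "b")

  expect_error(deltaCt(ct, "miR-182", "nope"), "housekeeper")
  bad <- ct; bad$Ct[1] <- -1
  expect_error(validateCtTable(bad), "non-positive")
})

test_that("pooled 3-SD rule excludes exactly the planted outlier", {
  set.seed(4)
  d <- stats::setNames(rnorm(20, 5, 0.5), sprintf("s%02d", 1:20))
  d["s21"] <- 20
  fl <- outlierFilter(d)
  expect_equal(fl$excluded, "s21")
  expect_equal(length(fl$kept), 20L)

  same <- stats::setNames(rep(5, 10), paste0("s", 1:10))
  expect_equal(outlierFilter(same)$excluded, character(0))
  expect_warning(outlierFilter(c(a = 1, b = 2)), "skipped")
})

test_that("the 3-SD boundary is inclusive (strictly outside excludes)", {
  # construct a vector whose extreme value sits at exactly `a` sample SDs
  # from the sample mean: z = c(a, -a/m + t*(+/-1)) with m = n-1 even and
  # t solving sum(z^2) = n - 1, so the sample mean is 0 and sample SD 1
  z_at <- function(a, n = 21L) {
    m <- n - 1L
    t <- sqrt((m - a^2 - a^2 / m) / m)
    c(a, rep(-a / m, m) + t * rep(c(1, -1), m / 2))
  }
  inside <- stats::setNames(z_at(2.95), paste0("s", 1:21))
  expect_equal(stats::sd(inside), 1, tolerance = 1e-12)
  expect_equal(outlierFilter(inside)$excluded, character(0))
  outside <- stats::setNames(z_at(3.05), paste0("s", 1:21))
  expect_equal(outlierFilter(outside)$excluded, "s1")
})

test_that("fold change follows 2^(-ddCt) from group means", {
  samples <- sprintf("s%02d", 1:8)
  dct <- stats::setNames(c(rep(5, 4), rep(3.8, 4)), samples)
  groups <- rep(c("ND", "T2D"), each = 4)
  res <- foldChange(dct, groups, reference = "ND", filterOutliers = FALSE)
  tab <- res$groups
  expect_equal(tab$fold[tab$group == "ND"], 1.0)       # reference fold == 1
  expect_equal(tab$ddct[tab$group == "T2D"], -1.2)
  expect_equal(tab$fold[tab$group == "T2D"], 2^1.2)    # ~2.30
  expect_equal(res$test, "t-test")

  # swapping the reference gives the reciprocal fold
  swap <- foldChange(dct, groups, reference = "T2D", filterOutliers = FALSE)
  expect_equal(swap$groups$fold[swap$groups$group == "ND"],
               1 / tab$fold[tab$group == "T2D"])

  # sign convention: lower dCt in the test group -> fold above 1
  expect_gt(tab$fold[tab$group == "T2D"], 1)

  # three groups are compared by one-way ANOVA
  dct3 <- stats::setNames(c(rep(5, 4), rep(4, 4), rep(3, 4)),
                          sprintf("s%02d", 1:12))
  res3 <- foldChange(dct3, rep(c("chow", "HC", "HFD"), each = 4),
                     reference = "chow", filterOutliers = FALSE)
  expect_equal(res3$test, "anova")
  expect_equal(nrow(res3$groups), 3L)
})

test_that("identical groups give fold 1 and a null test statistic region", {
  set.seed(30)
  d <- stats::setNames(rnorm(40, 5, 0.3), sprintf("s%02d", 1:40))
  res <- foldChange(d, rep(c("A", "B"), 20), reference = "A")
  expect_lt(abs(res$groups$fold[2] - 1), 0.15)
  expect_gt(res$p.value, 0.001)
  expect_error(foldChange(d, rep("A", 40), reference = "A"), "two groups")
})

test_that("adjusted correlation is a partial correlation", {
  set.seed(44)
  n <- 200
  age <- runif(n, 20, 70)
  # identity: x correlated with itself
  expect_equal(adjustedCorrelation(age, age)$r, 1.0)
  # no adjusters == plain Pearson, numerically
  x <- rnorm(n); y <- 0.4 * x + rnorm(n)
  plain <- stats::cor.test(x, y)
  got <- adjustedCorrelation(x, y)
  expect_equal(got$r, unname(plain$estimate))
  expect_equal(got$p, plain$p.value)
  # residualisation removes a shared confounder: both variables track age,
  # adjusting for age leaves only independent noise
  xa <- age + rnorm(n, sd = 2)
  ya <- age + rnorm(n, sd = 1)
  raw_r <- adjustedCorrelation(xa, ya)$r
  adj <- adjustedCorrelation(xa, ya, covars = data.frame(age = age))
  expect_gt(raw_r, 0.8)
  expect_lt(abs(adj$r), 0.1)
  # degenerate: zero variance after residualisation is undefined, not 0
  expect_true(is.na(adjustedCorrelation(age, age,
                                        covars = data.frame(age = age))$r))
})

test_that("correlation screen attaches BH q-values over the family", {
  set.seed(50)
  n <- 80
  trait <- rnorm(n)
  xs <- list(hit = trait + rnorm(n, sd = 0.3),
             null1 = rnorm(n), null2 = rnorm(n))
  scr <- correlationScreen(xs, trait)
  expect_equal(scr$q, bhFdr(scr$p))
  expect_lt(scr$q[scr$name == "hit"], 0.01)
})
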