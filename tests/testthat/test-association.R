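# the three detectors and the genome-wide scan

test_that("linear association matches the regression oracle", {
  # perfect fit: slope recovered, p numerically zero
  d <- rep(0:1, 5)
  res <- linear_association(2 * d, d)
  expect_equal(res$effect, 2, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-12)

  # agreement with lm() on noisy data
  set.seed(1)
  dd <- rbinom(300, 2, 0.3)
  yy <- 0.1 * dd + rnorm(300)
  ours <- linear_association(yy, dd)
  ref <- summary(lm(yy ~ dd))$coefficients[2, ]
  expect_equal(ours$statistic, unname(ref["t value"]), tolerance = 1e-10)
  expect_equal(ours$p_value, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(ours$effect, unname(ref["Estimate"]), tolerance = 1e-10)

  expect_error(linear_association(rnorm(10), rep(1, 10)), "monomorphic")
  expect_error(linear_association(rnorm(2), 0:1), "at least 3")
})

test_that("linear test p-values are uniform under the null", {
  set.seed(2)
  y <- rnorm(1000)
  pvals <- vapply(1:1000, function(i) {
    linear_association(y, rbinom(1000, 1, 0.3))$p_value
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Brown-Forsythe matches an independent Levene implementation", {
  skip_if_not_installed("car")
  set.seed(3)
  for (i in 1:20) {
    d <- rbinom(400, 2, runif(1, 0.1, 0.5))
    if (min(table(d)) < 2) next
    y <- rnorm(400, 0, 1 + 0.3 * d)
    ours <- brown_forsythe(y, d)
    ref <- car::leveneTest(y ~ factor(d), center = median)
    expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(ours$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
    expect_equal(ours$df, ref[1, "Df"])
  }
})

test_that("Brown-Forsythe edge cases and power behave as expected", {
  # identical value multisets in both groups: no spread difference
  y <- c(1, 2, 3, 4, 1, 2, 3, 4)
  d <- rep(0:1, each = 4)
  res <- brown_forsythe(y, d)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  expect_error(brown_forsythe(rnorm(10), rep(0, 10)), "fewer than 2")
  expect_error(brown_forsythe(rnorm(4), c(0, 0, 0, 1)), ">= 2 samples")

  # fourfold variance ratio at n=500/group is essentially always detected
  hits <- vapply(1:20, function(s) {
    y <- withr::with_seed(300 + s,
                          c(rnorm(500, 0, 1), rnorm(500, 0, 2)))
    brown_forsythe(y, rep(0:1, each = 500))$p_value < 1e-10
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # blind to a pure mean shift
  y2 <- withr::with_seed(9, rnorm(2000)) + rep(c(0, 1), each = 1000)
  expect_gt(brown_forsythe(y2, rep(0:1, each = 1000))$p_value, 1e-4)
})

test_that("DGLM nests the linear model on homoscedastic data", {
  set.seed(4)
  consistent <- vapply(1:30, function(s) {
    d <- rbinom(2000, 1, 0.3)
    y <- 0.15 * d + rnorm(2000)
    res <- dglm_association(y, d)
    lin <- linear_association(y, d)
    ratio <- log10(res$p_value[res$test == "dglm_mean"]) -
      log10(lin$p_value)
    abs(ratio) < 1        # within an order of magnitude
  }, logical(1))
  expect_gte(mean(consistent), 0.9)

  # dispersion p roughly uniform when there is no variance effect
  disp_p <- vapply(1:50, function(s) {
    d <- withr::with_seed(500 + s, rbinom(1000, 1, 0.3))
    y <- withr::with_seed(600 + s, 0.15 * d + rnorm(1000))
    dglm_association(y, d)$p_value[2]
  }, numeric(1))
  expect_gt(mean(disp_p), 0.3)
  expect_lt(mean(disp_p), 0.7)
})

test_that("DGLM joint test beats both single tests on combined loci", {
  wins <- vapply(1:50, function(s) {
    g <- generate_hwe(1e4, 0.3, ploidy = 1, seed = 700 + s)
    m <- solve_haploid(0.03, 0.03, q = estimate_maf(g)[1])
    y <- simulate_phenotypes(g$doses[, 1], m, seed = 800 + s)
    d <- g$doses[, 1]
    joint <- dglm_association(y, d)$p_value[3]
    joint < linear_association(y, d)$p_value &&
      joint < brown_forsythe(y, d)$p_value
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("DGLM input validation and convergence reporting", {
  expect_error(dglm_association(rnorm(20), rep(1, 20)), "monomorphic")
  expect_error(dglm_association(rnorm(5), rbinom(5, 1, 0.5)), "at least 10")
  set.seed(5)
  d <- rbinom(200, 1, 0.4)
  y <- rnorm(200, 0, 1 + 0.5 * d)
  expect_warning(res <- dglm_association(y, d, max_iter = 1),
                 "did not converge")
  expect_true(all(is.finite(res$p_value)))
})

test_that("scan produces a tidy table and flags failures without aborting", {
  g <- generate_hwe(300, rep(0.3, 3), ploidy = 1, seed = 6)
  y <- withr::with_seed(7, rnorm(300))
  res <- scan_associations(g, y, tests = c("linear", "brown_forsythe"))
  expect_equal(nrow(res), 6L)
  expect_setequal(unique(res$test), c("linear", "brown_forsythe"))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_equal(res$neg_log10_p, -log10(res$p_value))

  # a monomorphic locus becomes a flagged row, the rest of the scan runs
  g2 <- genotype_matrix(cbind(g$doses[, 1:2], 0L), ploidy = 1)
  res2 <- scan_associations(g2, y, tests = "linear")
  expect_equal(nrow(res2), 3L)
  expect_true(is.na(res2$p_value[3]))
  expect_match(res2$note[3], "monomorphic")

  g3 <- genotype_matrix(matrix(1L, 300, 2), ploidy = 1)
  expect_warning(res3 <- scan_associations(g3, y, tests = "linear"),
                 "monomorphic")
  expect_true(all(is.na(res3$p_value)))

  expect_error(scan_associations(g, rnorm(10)), "does not match")
})
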