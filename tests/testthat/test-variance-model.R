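# solver closed forms, feasibility boundary, decomposition, simulation moments

test_that("single-locus solvers reproduce the closed forms", {
  m <- solve_haploid(c_mu = 0.05, c_v = 0, q = 0.5)
  expect_equal(m$alpha, sqrt(0.05 / 0.25), tolerance = 1e-12)
  expect_equal(m$phi, 0)
  expect_equal(m$sigma, sqrt(0.95), tolerance = 1e-12)

  # no genetic effect: pure N(mu, v_y) noise
  m0 <- solve_haploid(0, 0, q = 0.3)
  expect_equal(c(m0$alpha, m0$phi), c(0, 0))
  expect_equal(m0$sigma, 1)
  m0d <- solve_diploid_codominant(0, 0, q = 0.1, v_y = 2)
  expect_equal(m0d$sigma, sqrt(2), tolerance = 1e-12)

  # co-dominant diploid uses 2pq denominators and 2q*phi in sigma
  m2 <- solve_diploid_codominant(0.05, 0, q = 0.5)
  expect_equal(m2$alpha, sqrt(0.05 / 0.5), tolerance = 1e-12)
  expect_equal(m2$sigma, sqrt(0.95), tolerance = 1e-12)
  m3 <- solve_diploid_codominant(0.03, 0.03, q = 0.2)
  expect_equal(m3$alpha, sqrt(0.03 / 0.32), tolerance = 1e-12)
  expect_equal(m3$phi, sqrt(0.03 / 0.32), tolerance = 1e-12)
  expect_equal(m3$sigma, sqrt(0.94) - 0.4 * sqrt(0.03 / 0.32),
               tolerance = 1e-12)

  # complete dominance collapses to two states at q = q_allele^2
  m4 <- solve_diploid_dominant(0.05, 0, q_allele = 0.5)
  expect_equal(m4$q, 0.25)
  expect_equal(m4$alpha, sqrt(0.05 / 0.1875), tolerance = 1e-12)
  expect_equal(m4$sigma, sqrt(0.95), tolerance = 1e-12)
})

test_that("multi-locus solver matches closed forms and the N=1 limit", {
  m <- solve_phenotype_model(c(0, 0), c(0.07, 0.07), q = c(0.5, 0.5),
                             mode = "haploid")
  expect_equal(m$phi, rep(sqrt(0.07 / 0.25), 2), tolerance = 1e-12)
  expect_equal(m$sigma, sqrt(0.86) - sqrt(0.07 / 0.25), tolerance = 1e-12)

  for (mode in c("haploid", "diploid_codominant", "diploid_dominant")) {
    single <- solve_phenotype_model(0.04, 0.02, q = 0.25, mode = mode)
    multi <- solve_phenotype_model(c(0.04), c(0.02), q = c(0.25),
                                   mode = mode)
    expect_equal(multi[c("alpha", "phi", "sigma")],
                 single[c("alpha", "phi", "sigma")])
  }

  expect_error(solve_phenotype_model(c(0, 0), c(0.1), q = c(0.3, 0.3)),
               "one element per causal locus")
})

test_that("infeasible and invalid configurations fail fast", {
  # q*phi exceeds sqrt(V_Y(1 - C)) -> sigma < 0
  expect_error(solve_haploid(0, 0.3, q = 0.9), "infeasible")
  expect_error(solve_phenotype_model(rep(0, 3), rep(0.3, 3),
                                     q = rep(0.5, 3), mode = "haploid"),
               "infeasible")
  expect_error(solve_haploid(0.6, 0.6, q = 0.3), "exceeds 1")
  expect_error(solve_haploid(0.05, 0, q = 0), "strictly in")
  expect_error(solve_haploid(0.05, 0, q = 1), "strictly in")
  expect_error(solve_haploid(-0.01, 0, q = 0.3), "non-negative")
  # feasibility boundary is exact: error iff analytic sigma < 0
  for (q in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    for (cv in seq(0.02, 0.5, by = 0.04)) {
      sig <- sqrt(1 - cv) - q * sqrt(cv / ((1 - q) * q))
      if (sig < 0) {
        expect_error(solve_haploid(0, cv, q = q), "infeasible")
      } else {
        expect_s3_class(solve_haploid(0, cv, q = q), "phenotype_model")
      }
    }
  }
})

test_that("solver and analytic decomposition round-trip on a (C, q) grid", {
  for (mode in c("haploid", "diploid_codominant", "diploid_dominant")) {
    for (c_mu in seq(0, 0.3, by = 0.05)) {
      for (c_v in seq(0, 0.3, by = 0.05)) {
        for (q in seq(0.05, 0.5, by = 0.15)) {
          m <- tryCatch(
            solve_phenotype_model(c_mu, c_v, q = q, v_y = 2, mode = mode),
            error = function(e) NULL)
          if (is.null(m)) next   # infeasible corner of the grid
          d <- analytic_decomposition(m)
          expect_equal(d$v_m, c_mu * 2, tolerance = 1e-9)
          expect_equal(d$v_v, c_v * 2, tolerance = 1e-9)
          expect_equal(d$v_r, (1 - c_mu - c_v) * 2, tolerance = 1e-9)
          expect_equal(d$v_y, 2, tolerance = 1e-9)
        }
      }
    }
  }
  # zero effects decompose to (0, 0, v_y)
  d0 <- analytic_decomposition(solve_haploid(0, 0, q = 0.3, v_y = 3))
  expect_equal(c(d0$v_m, d0$v_v, d0$v_r), c(0, 0, 3))
})

test_that("negative sign flags flip direction and guard the spread", {
  m <- solve_haploid(0.05, 0.02, q = 0.3, sign_alpha = -1, sign_phi = -1)
  expect_lt(m$alpha, 0)
  expect_lt(m$phi, 0)
  expect_gt(m$sigma + m$phi, 0)          # dose-1 spread stays positive
  d <- analytic_decomposition(m)
  expect_equal(d$v_m, 0.05, tolerance = 1e-9)  # effect sizes sign-invariant
  expect_equal(d$v_v, 0.02, tolerance = 1e-9)
  # a variance-decreasing allele that would zero out the spread is rejected
  expect_error(solve_haploid(0, 0.4, q = 0.1, sign_phi = -1), "infeasible")
})

test_that("simulated phenotypes honor the per-group moment contract", {
  n <- 2e5
  g <- generate_hwe(n, 0.5, ploidy = 1, seed = 11)
  m <- solve_haploid(0.05, 0.05, q = estimate_maf(g)[1])
  y <- simulate_phenotypes(g$doses[, 1], m, seed = 12)
  d <- g$doses[, 1]
  for (dose in 0:1) {
    grp <- y[d == dose]
    mu_th <- m$mu + dose * m$alpha
    sd_th <- m$sigma + dose * m$phi
    expect_lt(abs(mean(grp) - mu_th), 3 * sd_th / sqrt(length(grp)))
    expect_lt(abs(sd(grp) - sd_th), 3 * sd_th / sqrt(2 * (length(grp) - 1)))
  }

  # co-dominant mean-only effect: three equidistant group means
  g2 <- generate_hwe(n, 0.4, ploidy = 2, seed = 13)
  m2 <- solve_diploid_codominant(0.05, 0, q = estimate_maf(g2)[1])
  y2 <- simulate_phenotypes(g2$doses[, 1], m2, seed = 14)
  mg <- tapply(y2, g2$doses[, 1], mean)
  expect_equal(unname(mg[2] - mg[1]), m2$alpha,
               tolerance = 5 / sqrt(n) / m2$alpha)
  expect_equal(unname(mg[3] - mg[2]), m2$alpha,
               tolerance = 5 / sqrt(n) / m2$alpha)
})

test_that("total variance is conserved in all three modes", {
  n <- 5e5
  cfg <- list(
    haploid = list(ploidy = 1, c_mu = c(0.05, 0), c_v = c(0.02, 0.06)),
    diploid_codominant = list(ploidy = 2, c_mu = c(0.05, 0),
                              c_v = c(0.02, 0.06)),
    diploid_dominant = list(ploidy = 2, c_mu = c(0.05, 0),
                            c_v = c(0.02, 0.06)))
  for (mode in names(cfg)) {
    cc <- cfg[[mode]]
    g <- generate_hwe(n, c(0.3, 0.4), ploidy = cc$ploidy, seed = 21)
    q <- if (mode == "diploid_dominant") c(0.3, 0.4) else estimate_maf(g)
    m <- solve_phenotype_model(cc$c_mu, cc$c_v, q = q, v_y = 1.5,
                               mode = mode)
    y <- simulate_phenotypes(g, m, seed = 22)
    expect_equal(var(as.vector(y)), 1.5, tolerance = 0.01)
  }
})

test_that("complete dominance shifts only the recessive homozygote class", {
  n <- 1e5
  g <- generate_hwe(n, 0.3, ploidy = 2, seed = 31)
  # recessive group frequency is the squared allele frequency
  expect_equal(mean(g$doses[, 1] == 2), 0.09, tolerance = 0.01)
  m <- solve_diploid_dominant(0.1, 0, q_allele = 0.3)
  y <- simulate_phenotypes(g$doses[, 1], m, seed = 32)
  mg <- tapply(y, g$doses[, 1], mean)
  expect_lt(abs(mg[["1"]] - mg[["0"]]), 0.02)     # het matches major homo
  expect_equal(unname(mg[["2"]] - mg[["0"]]), m$alpha, tolerance = 0.05)
})

test_that("codominant all-homozygote population mirrors the haploid model", {
  # doses 0/2 only, with alpha halved: mean separation matches haploid alpha
  n <- 2e5
  mh <- solve_haploid(0.08, 0, q = 0.5)
  md <- solve_diploid_codominant(0.08, 0, q = 0.5)   # alpha = alpha_h/sqrt(2)
  doses <- withr::with_seed(41, sample(c(0L, 2L), n, replace = TRUE))
  y <- simulate_phenotypes(matrix(doses), md, seed = 42)
  sep <- mean(y[doses == 2]) - mean(y[doses == 0])
  expect_equal(sep, 2 * md$alpha, tolerance = 0.02)
})

test_that("phenotype draws are bit-identical under a fixed seed", {
  g <- generate_hwe(500, c(0.2, 0.4), ploidy = 2, seed = 51)
  m <- solve_diploid_codominant(c(0.03, 0), c(0, 0.03), q = estimate_maf(g))
  y1 <- simulate_phenotypes(g, m, seed = 52)
  y2 <- simulate_phenotypes(g, m, seed = 52)
  expect_identical(y1, y2)
  expect_false(identical(y1, simulate_phenotypes(g, m, seed = 53)))
  expect_error(simulate_phenotypes(g, m), "seed")
})

test_that("phenotypes are conditionally Gaussian within genotype groups", {
  rejections <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    out <- replicate_shares(900 + 7 * s, n = 2000, c_mu = 0.05, c_v = 0.05)
    pvals <- tapply(out$y, out$doses, function(v) shapiro.test(v)$p.value)
    if (any(pvals < 0.01)) rejections <- rejections + 1L
  }
  expect_gte(n_seeds - rejections, ceiling(0.95 * n_seeds))
})
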