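#' Linear-regression association test (mean effect)
#'
#' Simple linear regression of phenotype on minor-allele dose, the classical
#' single-marker GWAS test (the model behind PLINK's quantitative `assoc`).
#' Reports the slope, its t statistic and the two-sided p-value on
#' `n - 2` degrees of freedom. Detects mean shifts only; a purely
#' variance-shifting locus is invisible to it.
#'
#' @param y numeric phenotype vector.
#' @param doses numeric dose column (0/1 or 0/1/2).
#' @return one-row `data.frame` with columns `test`, `statistic`, `df`,
#'   `p_value`, `effect`.
#' @examples
#' linear_association(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
linear_association <- function(y, doses) {
  n <- length(y)
  if (n != length(doses)) stop("length mismatch", call. = FALSE)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  sxx <- sum((doses - mean(doses))^2)
  if (sxx == 0) {
    stop("dose column is monomorphic; association undefined", call. = FALSE)
  }
  sxy <- sum((doses - mean(doses)) * (y - mean(y)))
  slope <- sxy / sxx
  rss <- sum((y - mean(y))^2) - slope * sxy
  df <- n - 2L
  se <- sqrt(max(rss, 0) / df / sxx)
  tstat <- if (se == 0) Inf * sign(slope) else slope / se
  data.frame(test = "linear", statistic = tstat, df = df,
             p_value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
             effect = slope, stringsAsFactors = FALSE)
}

#' Brown-Forsythe test for variance heterogeneity
#'
#' Levene-type test on absolute deviations from the per-genotype-group
#' median: \eqn{z_{ij} = |y_{ij} - \tilde y_j|} followed by a one-way ANOVA
#' F statistic on the `z` values with `(k - 1, n - k)` degrees of freedom,
#' `k` being the number of genotype groups (2 for haploid or collapsed
#' dominant coding, up to 3 for co-dominant diploid doses). The standard
#' F reference distribution is used. This is the single-pass vGWAS test:
#' it detects spread differences between genotype classes and is blind to
#' pure mean shifts.
#'
#' @inheritParams linear_association
#' @return one-row `data.frame` as in [linear_association()]; `effect` is
#'   the difference in group mean absolute deviation between the highest
#'   and lowest dose groups.
#' @examples
#' set.seed(1)
#' d <- rep(0:1, each = 100)
#' y <- rnorm(200, sd = ifelse(d == 1, 2, 1))
#' brown_forsythe(y, d)
#' @export
brown_forsythe <- function(y, doses) {
  n <- length(y)
  if (n != length(doses)) stop("length mismatch", call. = FALSE)
  grp <- split(y, doses)
  if (length(grp) < 2L) {
    stop("fewer than 2 genotype groups; variance test undefined",
         call. = FALSE)
  }
  sizes <- lengths(grp)
  if (any(sizes < 2L)) {
    stop("every genotype group needs >= 2 samples (smallest has ",
         min(sizes), ")", call. = FALSE)
  }
  z <- lapply(grp, function(v) abs(v - stats::median(v)))
  zbar_g <- vapply(z, mean, numeric(1))
  zbar <- sum(vapply(z, sum, numeric(1))) / n
  k <- length(grp)
  ss_between <- sum(sizes * (zbar_g - zbar)^2)
  ss_within <- sum(vapply(z, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- n - k
  fstat <- if (ss_within == 0) {
    if (ss_between == 0) 0 else Inf
  } else (ss_between / df1) / (ss_within / df2)
  p <- if (ss_within == 0 && ss_between == 0) 1
       else stats::pf(fstat, df1, df2, lower.tail = FALSE)
  data.frame(test = "brown_forsythe", statistic = fstat, df = df1,
             p_value = p, effect = zbar_g[length(zbar_g)] - zbar_g[1L],
             stringsAsFactors = FALSE)
}

#' Double generalized linear model association test
#'
#' Fits paired submodels for the mean and the (log) dispersion of the
#' phenotype as functions of allele dose, by alternating estimation:
#' (i) weighted least squares of `y` on dose with weights equal to inverse
#' fitted variances; (ii) a gamma GLM with log link of leverage-deflated
#' squared residuals \eqn{d_i = r_i^2 / (1 - h_i)} on dose, with prior
#' weights \eqn{(1 - h_i)/2}, whose fitted values update the variances.
#' Iteration stops when the relative change in the heteroscedastic normal
#' log-likelihood falls below `tol`. Three tests are reported: a Wald test
#' of the mean coefficient, a Wald test of the dispersion coefficient
#' (gamma dispersion fixed at 2, as squared normal residuals are
#' \eqn{\sigma^2\chi^2_1}), and a 2-df likelihood-ratio test against the
#' homoscedastic no-effect null, which detects loci whose mean and variance
#' effects are individually modest but jointly strong.
#'
#' @inheritParams linear_association
#' @param max_iter maximum alternating iterations (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return three-row `data.frame` (tests `dglm_mean`, `dglm_disp`,
#'   `dglm_joint`) with columns as in [linear_association()], plus a
#'   `converged` attribute.
#' @examples
#' set.seed(1)
#' d <- rbinom(400, 1, 0.4)
#' y <- 0.4 * d + rnorm(400, sd = 1 + 0.4 * d)
#' dglm_association(y, d)
#' @export
dglm_association <- function(y, doses, max_iter = 100, tol = 1e-8) {
  n <- length(y)
  if (n != length(doses)) stop("length mismatch", call. = FALSE)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  if (stats::var(doses) == 0) {
    stop("dose column is monomorphic; association undefined", call. = FALSE)
  }
  x <- cbind(1, doses)

  loglik <- function(r, v) -0.5 * sum(log(2 * pi * v) + r^2 / v)

  w <- rep(1, n)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mean_fit <- stats::lm.wfit(x, y, w)
    r <- y - x %*% mean_fit$coefficients
    h <- .hat_wls(x, w)
    d <- pmax(as.vector(r)^2 / pmax(1 - h, 1e-8), 1e-300)
    disp_fit <- suppressWarnings(
      stats::glm.fit(x, d, weights = (1 - h) / 2,
                     family = stats::Gamma(link = "log")))
    v <- pmax(exp(as.vector(x %*% disp_fit$coefficients)), 1e-12)
    w <- 1 / v
    ll <- loglik(as.vector(r), v)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warning("DGLM did not converge in ", max_iter,
            " iterations; reporting last iterate", call. = FALSE)
  }

  # Wald tests at the final iterate
  xtwx_inv <- solve(crossprod(x * sqrt(w)))
  se_mean <- sqrt(xtwx_inv[2, 2])
  z_mean <- mean_fit$coefficients[2] / se_mean
  p_mean <- 2 * stats::pnorm(abs(z_mean), lower.tail = FALSE)

  # dispersion submodel Wald: gamma working information with dispersion 2
  wd <- ((1 - h) / 2) / 2                 # prior weight / dispersion
  info_inv <- solve(crossprod(x * sqrt(wd)))
  se_disp <- sqrt(info_inv[2, 2])
  z_disp <- disp_fit$coefficients[2] / se_disp
  p_disp <- 2 * stats::pnorm(abs(z_disp), lower.tail = FALSE)

  # 2-df LRT vs homoscedastic, no-effect null
  r0 <- y - mean(y)
  v0 <- mean(r0^2)
  ll0 <- loglik(r0, rep(v0, n))
  lrt <- 2 * (ll - ll0)
  p_joint <- stats::pchisq(max(lrt, 0), df = 2, lower.tail = FALSE)

  out <- data.frame(
    test = c("dglm_mean", "dglm_disp", "dglm_joint"),
    statistic = c(z_mean, z_disp, max(lrt, 0)),
    df = c(1L, 1L, 2L),
    p_value = c(p_mean, p_disp, p_joint),
    effect = c(mean_fit$coefficients[2], disp_fit$coefficients[2], NA_real_),
    stringsAsFactors = FALSE)
  attr(out, "converged") <- converged
  out
}

.hat_wls <- function(x, w) {
  xw <- x * sqrt(w)
  q <- qr.Q(qr(xw))
  rowSums(q^2)
}

#' Genome-wide association scan
#'
#' Applies the selected tests to every polymorphic locus of a genotype
#' matrix and returns a tidy table (one row per locus and test). Loci where
#' a test fails (monomorphic or degenerate groups) are reported as flagged
#' rows with `NA` statistics rather than aborting the scan.
#'
#' @param g a [genotype_matrix].
#' @param y phenotype vector, one value per sample.
#' @param tests subset of `c("linear", "brown_forsythe", "dglm")`.
#' @param ... passed to [dglm_association()].
#' @return `data.frame` with columns `locus_id`, `position`, `test`,
#'   `statistic`, `df`, `p_value`, `effect`, `note` (and `neg_log10_p` for
#'   Manhattan-style plotting).
#' @examples
#' g <- generate_hwe(300, maf = rep(0.3, 5), ploidy = 1, seed = 1)
#' m <- solve_haploid(0, 0.1, q = 0.3)
#' y <- simulate_phenotypes(g$doses[, 3], m, seed = 2)
#' scan_associations(g, y, tests = c("linear", "brown_forsythe"))
#' @export
scan_associations <- function(g, y,
                              tests = c("linear", "brown_forsythe"), ...) {
  stopifnot(inherits(g, "genotype_matrix"))
  tests <- match.arg(tests, c("linear", "brown_forsythe", "dglm"),
                     several.ok = TRUE)
  if (length(y) != nrow(g$doses)) {
    stop("phenotype length does not match sample count", call. = FALSE)
  }
  m <- ncol(g$doses)
  if (m == 0L) {
    warning("empty genotype matrix; nothing to scan", call. = FALSE)
    return(.empty_scan())
  }
  poly <- apply(g$doses, 2, function(d) length(unique(d)) > 1L)
  if (!any(poly)) warning("all loci are monomorphic", call. = FALSE)

  runner <- list(
    linear = function(yy, dd) linear_association(yy, dd),
    brown_forsythe = function(yy, dd) brown_forsythe(yy, dd),
    dglm = function(yy, dd) dglm_association(yy, dd, ...))

  rows <- vector("list", m * length(tests))
  k <- 0L
  for (j in seq_len(m)) {
    d <- g$doses[, j]
    for (tname in tests) {
      k <- k + 1L
      res <- if (!poly[j]) {
        .flagged_row(tname, "monomorphic")
      } else {
        tryCatch(cbind(runner[[tname]](y, d), note = ""),
                 error = function(e) .flagged_row(tname, conditionMessage(e)))
      }
      res$locus_id <- g$locus_ids[j]
      res$position <- g$positions[j]
      rows[[k]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("locus_id", "position", "test", "statistic", "df",
                 "p_value", "effect", "note")]
  out$neg_log10_p <- -log10(out$p_value)
  rownames(out) <- NULL
  out
}

.flagged_row <- function(test, note) {
  data.frame(test = test, statistic = NA_real_, df = NA_integer_,
             p_value = NA_real_, effect = NA_real_, note = note,
             stringsAsFactors = FALSE)
}

.empty_scan <- function() {
  data.frame(locus_id = character(0), position = numeric(0),
             test = character(0), statistic = numeric(0), df = integer(0),
             p_value = numeric(0), effect = numeric(0), note = character(0),
             neg_log10_p = numeric(0), stringsAsFactors = FALSE)
}
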