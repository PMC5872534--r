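#' Solve the heteroscedastic phenotype model from effect sizes
#'
#' Translates per-locus effect sizes into the parameters of the
#' variance-heterogeneity phenotype model
#' \deqn{y = \mu + g^T\alpha + \epsilon,\qquad
#'       \epsilon \sim N\big(0, (\sigma + g^T\phi)^2\big),}
#' where \eqn{g} is the minor-allele dose vector at the causal loci.
#' The effect sizes are fractions of the total phenotypic variance
#' \eqn{V_Y}: `c_mu` is the share contributed by the mean shift at a locus
#' (\eqn{V_M/V_Y}) and `c_v` the share contributed by the variance
#' (standard-deviation) shift (\eqn{V_V/V_Y}). Under Hardy-Weinberg allele
#' frequencies \eqn{p = 1 - q} the closed forms are, per locus \eqn{i},
#' \deqn{\alpha_i = \sqrt{c_{\mu}^{(i)} V_Y / (k\,p_i q_i)},\qquad
#'       \phi_i  = \sqrt{c_{V}^{(i)} V_Y / (k\,p_i q_i)},}
#' \deqn{\sigma = \sqrt{V_Y\big(1 - \textstyle\sum_i (c_{\mu}^{(i)} +
#'       c_{V}^{(i)})\big)} - k\, q^T\phi,}
#' with \eqn{k = 1} for haploids and \eqn{k = 2} for co-dominant diploids
#' (dose 0/1/2). Under complete dominance the genotype collapses to a
#' two-state 0/1 variable whose "carrier" class is the minor-allele
#' homozygote, so the haploid forms apply with the genotype frequency
#' \eqn{q = q_{allele}^2}.
#'
#' The decomposition of the total variance is
#' \eqn{V_Y = V_M + V_V + V_R} with \eqn{V_M = k p q \alpha^2},
#' \eqn{V_V = k p q \phi^2} and \eqn{V_R = (\sigma + k q \phi)^2}; the solver
#' guarantees this identity, and [analytic_decomposition()] recovers it.
#'
#' Square roots fix only the magnitude of \eqn{\alpha} and \eqn{\phi}; the
#' effect sizes are sign-invariant. The non-negative root is taken by
#' default, with optional per-locus sign flips for effect direction.
#'
#' @param c_mu,c_v numeric vectors (one element per causal locus) of mean and
#'   variance effect sizes, each in `[0, 1]` with
#'   `sum(c_mu) + sum(c_v) <= 1`.
#' @param q minor-allele frequency per causal locus, each in `(0, 1)`. Under
#'   `"diploid_dominant"` this is the *allele* frequency; the model works
#'   with the minor-homozygote genotype frequency `q^2` internally.
#' @param v_y total phenotypic variance (phenotype units squared).
#' @param mu baseline phenotype mean.
#' @param mode inheritance mode: `"haploid"`, `"diploid_codominant"`
#'   (dose 0/1/2), or `"diploid_dominant"` (complete dominance, collapsed
#'   dose 0/1).
#' @param sign_alpha,sign_phi per-locus sign flags (+1/-1, recycled) giving
#'   the direction of the mean and spread shifts. A negative `sign_phi`
#'   (variance-decreasing minor allele) is accepted only while every
#'   attainable dose keeps the group standard deviation positive.
#'
#' @return An object of class `phenotype_model`: a list with elements
#'   `mu`, `v_y`, `alpha`, `phi`, `sigma`, `q` (genotype-scale frequency),
#'   `q_allele`, `c_mu`, `c_v`, `mode`, and `dose_factor` (the constant
#'   \eqn{k} above).
#'
#' @section Infeasibility: Large `q` and/or large `c_v` can demand
#'   \eqn{\sigma < 0}, i.e. the requested configuration has no
#'   representation with a positive baseline spread. The solver fails fast
#'   (no silent clamping, which would distort \eqn{V_Y}) and reports the
#'   largest feasible `c_v` at the given frequency.
#'
#' @examples
#' m <- solve_haploid(c_mu = 0.05, c_v = 0, v_y = 1, q = 0.5)
#' m$alpha  # sqrt(0.05 / 0.25) = 0.447...
#' analytic_decomposition(m)
#'
#' # two variance-only loci, 7% each
#' solve_phenotype_model(c_mu = c(0, 0), c_v = c(0.07, 0.07),
#'                       q = c(0.5, 0.5), mode = "haploid")
#' @seealso [simulate_phenotypes()], [analytic_decomposition()],
#'   [empirical_decomposition()]
#' @export
solve_phenotype_model <- function(c_mu, c_v, q, v_y = 1, mu = 0,
                                  mode = c("haploid", "diploid_codominant",
                                           "diploid_dominant"),
                                  sign_alpha = 1, sign_phi = 1) {
  mode <- match.arg(mode)
  n <- length(q)
  if (length(c_mu) != n || length(c_v) != n) {
    stop("`c_mu`, `c_v` and `q` must have one element per causal locus (",
         "got lengths ", length(c_mu), ", ", length(c_v), ", ", n, ")",
         call. = FALSE)
  }
  stopifnot(is.numeric(c_mu), is.numeric(c_v), is.numeric(q),
            length(v_y) == 1L, length(mu) == 1L)
  if (any(c_mu < 0) || any(c_v < 0)) {
    stop("effect sizes `c_mu` and `c_v` must be non-negative", call. = FALSE)
  }
  tot <- sum(c_mu) + sum(c_v)
  if (tot > 1 + 1e-12) {
    stop("sum of effect sizes exceeds 1 (", format(tot),
         "); residual variance would be negative", call. = FALSE)
  }
  if (any(q <= 0) || any(q >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (v_y <= 0) stop("`v_y` must be positive", call. = FALSE)

  q_allele <- q
  if (mode == "diploid_dominant") q <- q_allele^2   # minor-homozygote freq
  k <- if (mode == "diploid_codominant") 2 else 1
  p <- 1 - q

  sign_alpha <- rep_len(sign(sign_alpha), n)
  sign_phi   <- rep_len(sign(sign_phi), n)
  alpha <- sign_alpha * sqrt(c_mu * v_y / (k * p * q))
  phi   <- sign_phi   * sqrt(c_v  * v_y / (k * p * q))
  sigma <- sqrt(v_y * (1 - tot)) - k * sum(q * phi)

  if (sigma < 0) {
    cv_max <- .max_feasible_cv(c_mu, c_v, q, k)
    stop("infeasible configuration: solved baseline s.d. sigma = ",
         format(sigma, digits = 6), " < 0. At these frequencies the ",
         "largest feasible total variance effect is about ",
         format(cv_max, digits = 4),
         " (reduce `c_v` or pick rarer minor alleles).", call. = FALSE)
  }
  # every attainable dose must keep sigma + g'phi >= 0 (relevant when some
  # phi are negative via sign flags); exact zeros are caught at draw time
  min_shift <- sum(pmin(0, k * phi))
  if (sigma + min_shift < 0) {
    stop("infeasible sign configuration: the most extreme dose vector ",
         "yields a non-positive group standard deviation (",
         format(sigma + min_shift, digits = 6), ")", call. = FALSE)
  }

  structure(
    list(mu = mu, v_y = v_y, alpha = alpha, phi = phi, sigma = sigma,
         q = q, q_allele = q_allele, c_mu = c_mu, c_v = c_v,
         mode = mode, dose_factor = k),
    class = "phenotype_model")
}

# largest total c_v feasible at the same c_mu and frequencies (single-locus
# closed form; multi-locus reported by proportional scaling of c_v)
.max_feasible_cv <- function(c_mu, c_v, q, k) {
  if (length(q) == 1L) {
    p <- 1 - q
    return((1 - c_mu) * p / (p + k * q))
  }
  # scale all c_v by t until sigma(t) = 0: sqrt(1 - S_mu - t S_v) = k q' phi(t)
  f <- function(t) {
    sqrt(max(0, 1 - sum(c_mu) - t * sum(c_v))) -
      k * sum(q * sqrt(t * c_v / (k * (1 - q) * q)))
  }
  t_star <- tryCatch(stats::uniroot(f, c(1e-12, 1))$root, error = function(e) NA)
  if (is.na(t_star)) return(NA_real_)
  t_star * sum(c_v)
}

#' @rdname solve_phenotype_model
#' @export
solve_haploid <- function(c_mu, c_v, q, v_y = 1, mu = 0,
                          sign_alpha = 1, sign_phi = 1) {
  solve_phenotype_model(c_mu, c_v, q, v_y, mu, mode = "haploid",
                        sign_alpha = sign_alpha, sign_phi = sign_phi)
}

#' @rdname solve_phenotype_model
#' @export
solve_diploid_codominant <- function(c_mu, c_v, q, v_y = 1, mu = 0,
                                     sign_alpha = 1, sign_phi = 1) {
  solve_phenotype_model(c_mu, c_v, q, v_y, mu, mode = "diploid_codominant",
                        sign_alpha = sign_alpha, sign_phi = sign_phi)
}

#' @rdname solve_phenotype_model
#' @param q_allele minor-allele frequency (squared internally to the
#'   recessive-homozygote genotype frequency).
#' @export
solve_diploid_dominant <- function(c_mu, c_v, q_allele, v_y = 1, mu = 0,
                                   sign_alpha = 1, sign_phi = 1) {
  solve_phenotype_model(c_mu, c_v, q_allele, v_y, mu,
                        mode = "diploid_dominant",
                        sign_alpha = sign_alpha, sign_phi = sign_phi)
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("<phenotype_model> mode:", x$mode, "\n")
  cat("  mu =", format(x$mu), " V_Y =", format(x$v_y),
      " sigma =", format(x$sigma, digits = 6), "\n")
  cat("  loci:", length(x$alpha), "\n")
  df <- data.frame(q = x$q_allele, c_mu = x$c_mu, c_v = x$c_v,
                   alpha = x$alpha, phi = x$phi)
  print(df, digits = 6, row.names = FALSE)
  invisible(x)
}

#' Simulate phenotypes from a solved model
#'
#' Draws one phenotype per sample from
#' \eqn{y_s = \mu + g_s^T\alpha + \epsilon_s},
#' \eqn{\epsilon_s \sim N(0, (\sigma + g_s^T\phi)^2)}, independently across
#' samples. The dose encoding must match the model's mode: 0/1 for haploid,
#' 0/1/2 for co-dominant diploid; under complete dominance a 0/1/2 diploid
#' dose is collapsed so that only the minor-allele homozygote (dose 2)
#' carries the shift.
#'
#' @param doses a [genotype_matrix] restricted to the causal loci, or a
#'   numeric matrix / vector of per-sample doses (samples in rows, causal
#'   loci in columns).
#' @param model a `phenotype_model` from [solve_phenotype_model()].
#' @param seed integer seed; the draw is bit-reproducible for a fixed seed
#'   and configuration.
#' @return numeric vector of phenotype values, one per sample, with the
#'   per-sample conditional standard deviations in attribute `"sd"`.
#' @examples
#' g <- generate_hwe(500, maf = 0.3, ploidy = 1, seed = 1)
#' m <- solve_haploid(c_mu = 0.05, c_v = 0.05, q = 0.3)
#' y <- simulate_phenotypes(g, m, seed = 2)
#' tapply(y, g$doses[, 1], mean)  # about (mu, mu + alpha)
#' @export
simulate_phenotypes <- function(doses, model, seed) {
  stopifnot(inherits(model, "phenotype_model"))
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is required for a reproducible draw", call. = FALSE)
  }
  g <- .dose_matrix(doses)
  n_loci <- length(model$alpha)
  if (ncol(g) != n_loci) {
    stop("dose matrix has ", ncol(g), " loci but the model was solved for ",
         n_loci, call. = FALSE)
  }
  max_dose <- max(g)
  if (model$mode == "haploid" && max_dose > 1) {
    stop("haploid model given doses above 1; genotypes look diploid",
         call. = FALSE)
  }
  if (model$mode == "diploid_dominant" && max_dose > 1) {
    g <- (g == 2) * 1L                       # recessive homozygote carries
  }
  mean_s <- model$mu + as.vector(g %*% model$alpha)
  sd_s   <- model$sigma + as.vector(g %*% model$phi)
  if (any(sd_s <= 0)) {
    stop("some samples have non-positive group standard deviation (min ",
         format(min(sd_s), digits = 6), "); configuration infeasible for ",
         "the observed doses", call. = FALSE)
  }
  y <- withr::with_seed(as.integer(seed),
                        stats::rnorm(length(mean_s), mean_s, sd_s))
  attr(y, "sd") <- sd_s
  y
}

.dose_matrix <- function(doses) {
  if (inherits(doses, "genotype_matrix")) doses <- doses$doses
  if (is.null(dim(doses))) doses <- matrix(doses, ncol = 1L)
  storage.mode(doses) <- "double"
  doses
}

#' Analytic variance decomposition of a solved model
#'
#' Returns the three variance components implied by the model parameters
#' under Hardy-Weinberg frequencies and independent causal loci:
#' mean-shift variance \eqn{V_M = \sum_i k p_i q_i \alpha_i^2}, spread-shift
#' variance \eqn{V_V = \sum_i k p_i q_i \phi_i^2} and residual
#' \eqn{V_R = (\sigma + k q^T \phi)^2}. For a feasible model these sum to
#' `v_y` exactly; decomposing a solved model recovers the requested
#' `c_mu * v_y` and `c_v * v_y`.
#'
#' @param model a `phenotype_model`.
#' @return list of class `variance_decomposition` with `v_m`, `v_v`, `v_r`,
#'   `v_y`, and the per-locus contributions `v_m_locus`, `v_v_locus`.
#' @export
analytic_decomposition <- function(model) {
  stopifnot(inherits(model, "phenotype_model"))
  k <- model$dose_factor
  p <- 1 - model$q
  v_m_i <- k * p * model$q * model$alpha^2
  v_v_i <- k * p * model$q * model$phi^2
  v_r <- (model$sigma + k * sum(model$q * model$phi))^2
  structure(list(v_m = sum(v_m_i), v_v = sum(v_v_i), v_r = v_r,
                 v_y = sum(v_m_i) + sum(v_v_i) + v_r,
                 v_m_locus = v_m_i, v_v_locus = v_v_i),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("<variance_decomposition>\n")
  cat(sprintf("  V_M = %.6g  V_V = %.6g  V_R = %.6g  (V_Y = %.6g)\n",
              x$v_m, x$v_v, x$v_r, x$v_y))
  invisible(x)
}

#' Moment-based empirical variance decomposition at one locus
#'
#' Estimates the mean-shift and spread-shift variance components at a single
#' locus from simulated (or observed) phenotypes by the method of moments:
#' the per-dose-group sample means and standard deviations are regressed on
#' dose (size-weighted least squares; with two groups this reduces to the
#' plain group difference), giving \eqn{\hat\alpha} and \eqn{\hat\phi},
#' which are plugged into the analytic component formulas with the realized
#' genotype frequency. Serves as an independent check that a simulation
#' realizes its configured effect shares: `v_m / var(y)` estimates `c_mu`
#' and `v_v / var(y)` estimates `c_v`.
#'
#' @param y numeric phenotype vector.
#' @param doses integer dose column for one locus (0/1, or 0/1/2 for
#'   co-dominant diploids).
#' @param ploidy 1 or 2: the maximum attainable dose in `doses` coding.
#'   Collapsed complete-dominance doses are on a 0/1 scale (ploidy 1).
#' @return `variance_decomposition` with additional elements `alpha_hat`,
#'   `phi_hat`, `sigma_hat`, `q_hat`, `v_y_hat` (the overall sample
#'   variance) and the shares `c_mu_hat`, `c_v_hat`.
#' @examples
#' g <- generate_hwe(2000, 0.3, ploidy = 1, seed = 1)
#' m <- solve_haploid(0.05, 0, q = 0.3)
#' y <- simulate_phenotypes(g, m, seed = 2)
#' empirical_decomposition(y, g$doses[, 1], ploidy = 1)$c_mu_hat
#' @export
empirical_decomposition <- function(y, doses, ploidy = max(doses)) {
  if (length(y) != length(doses)) {
    stop("`y` and `doses` must have equal length", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    out <- structure(list(v_m = 0, v_v = 0, v_r = 0, v_y = 0,
                          alpha_hat = 0, phi_hat = 0, sigma_hat = 0,
                          q_hat = mean(doses) / max(1, ploidy), v_y_hat = 0,
                          c_mu_hat = 0, c_v_hat = 0),
                     class = "variance_decomposition")
    return(out)
  }
  lev <- sort(unique(doses))
  if (length(lev) < 2L) {
    stop("dose column is monomorphic; decomposition undefined", call. = FALSE)
  }
  n_g <- tapply(y, doses, length)
  if (any(n_g < 2L)) {
    stop("every genotype group needs at least 2 samples (smallest has ",
         min(n_g), ")", call. = FALSE)
  }
  m_g <- tapply(y, doses, mean)
  s_g <- tapply(y, doses, stats::sd)
  w <- as.numeric(n_g)
  d <- as.numeric(names(m_g))
  alpha_hat <- .wls_slope(d, as.numeric(m_g), w)
  fit_s <- .wls_fit(d, as.numeric(s_g), w)
  phi_hat <- fit_s$slope
  sigma_hat <- fit_s$intercept
  k <- if (ploidy >= 2) 2 else 1
  q_hat <- mean(doses) / k
  p_hat <- 1 - q_hat
  v_m <- k * p_hat * q_hat * alpha_hat^2
  v_v <- k * p_hat * q_hat * phi_hat^2
  v_r <- (sigma_hat + k * q_hat * phi_hat)^2
  v_y_hat <- stats::var(y)
  structure(list(v_m = v_m, v_v = v_v, v_r = v_r, v_y = v_m + v_v + v_r,
                 alpha_hat = alpha_hat, phi_hat = phi_hat,
                 sigma_hat = sigma_hat, q_hat = q_hat, v_y_hat = v_y_hat,
                 c_mu_hat = v_m / v_y_hat, c_v_hat = v_v / v_y_hat),
            class = "variance_decomposition")
}

.wls_fit <- function(x, y, w) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  list(slope = slope, intercept = yb - slope * xb)
}

.wls_slope <- function(x, y, w) .wls_fit(x, y, w)$slope
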