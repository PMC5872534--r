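#' Genotype matrix container
#'
#' A light container for sample-by-locus minor-allele dose matrices, the
#' genotype profile format consumed by the simulator and the association
#' scans. Doses are 0/1 for haploids and 0/1/2 for diploids.
#'
#' @param doses integer matrix, samples in rows, loci in columns; values in
#'   `0:ploidy`.
#' @param positions per-locus coordinate, strictly increasing: either floats
#'   in `[0, 1]` (coalescent-simulator convention) or integer base pairs.
#' @param ploidy 1 or 2.
#' @param locus_ids stable per-locus identifiers (default `"L1"..."Lm"`).
#' @param sample_ids per-sample identifiers (default `"S1"..."Sn"`).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(doses, positions = NULL, ploidy,
                            locus_ids = NULL, sample_ids = NULL) {
  stopifnot(is.matrix(doses), ploidy %in% c(1L, 2L))
  m <- ncol(doses)
  if (is.null(positions)) positions <- seq_len(m)
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(m))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(doses)))
  if (length(positions) != m || length(locus_ids) != m) {
    stop("`positions` and `locus_ids` must have one entry per locus",
         call. = FALSE)
  }
  if (m > 1 && any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  if (any(doses < 0 | doses > ploidy)) {
    stop("doses must lie in 0..ploidy", call. = FALSE)
  }
  storage.mode(doses) <- "integer"
  dimnames(doses) <- list(sample_ids, locus_ids)
  structure(list(doses = doses, positions = positions,
                 ploidy = as.integer(ploidy), locus_ids = locus_ids,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$doses), " samples x ", ncol(x$doses),
      " loci, ploidy ", x$ploidy, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$doses)

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$doses

#' Estimated minor-allele frequencies of a genotype matrix
#'
#' Allele count divided by `ploidy * n_samples`, folded to `<= 0.5`.
#' @param g a [genotype_matrix].
#' @return numeric vector, one folded frequency per locus.
#' @export
estimate_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- unname(colMeans(g$doses)) / g$ploidy
  pmin(f, 1 - f)
}

#' Generate independent Hardy-Weinberg genotypes
#'
#' Draws each locus independently: dose at locus *i* is
#' Binomial(`ploidy`, `maf[i]`). A stand-in for coalescent simulator output
#' when no linkage structure is needed.
#'
#' @param n_samples number of individuals (>= 2).
#' @param maf minor-allele frequency per locus, each in `(0, 0.5]`; recycled
#'   against `n_loci` if scalar.
#' @param ploidy 1 or 2.
#' @param seed integer seed (draw is reproducible).
#' @param n_loci number of loci (defaults to `length(maf)`).
#' @param positions optional per-locus coordinates (default equally spaced
#'   in `(0, 1)`).
#' @return a [genotype_matrix].
#' @examples
#' g <- generate_hwe(1000, maf = 0.5, ploidy = 2, seed = 1)
#' table(g$doses[, 1]) / 1000   # about (0.25, 0.5, 0.25)
#' @export
generate_hwe <- function(n_samples, maf, ploidy = 1, seed,
                         n_loci = length(maf), positions = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_samples < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(maf <= 0) || any(maf > 0.5)) {
    stop("minor-allele frequencies must lie in (0, 0.5]", call. = FALSE)
  }
  maf <- rep_len(maf, n_loci)
  doses <- withr::with_seed(as.integer(seed), {
    matrix(stats::rbinom(n_samples * n_loci, size = ploidy,
                         prob = rep(maf, each = n_samples)),
           nrow = n_samples, ncol = n_loci)
  })
  if (is.null(positions)) positions <- seq_len(n_loci) / (n_loci + 1)
  genotype_matrix(doses, positions, ploidy)
}

#' Generate genotypes with block-wise linkage disequilibrium
#'
#' Haplotype-copying scheme: within a block, the allele at each locus copies
#' the allele at the previous locus with probability
#' `sqrt(within_block_r2)`, otherwise it is a fresh Bernoulli(`maf`) draw.
#' Adjacent within-block loci then have dose correlation about
#' `sqrt(within_block_r2)` (so squared correlation about `within_block_r2`),
#' decaying geometrically with locus distance; loci in different blocks are
#' independent. Diploid doses are sums of two independent haplotypes. This
#' reproduces qualitative "low LD" vs "high LD" regimes without a
#' recombination map.
#'
#' @inheritParams generate_hwe
#' @param n_loci total number of loci.
#' @param block_size loci per LD block (last block may be shorter);
#'   must not exceed `n_loci`.
#' @param within_block_r2 target squared correlation between adjacent
#'   within-block loci, in `[0, 1)`; 0 gives independent loci.
#' @param segment_length segment span used for positions (default 25e6 bp,
#'   loci placed uniformly).
#' @return a [genotype_matrix] with an attribute-free `positions` vector in
#'   base pairs and `block` assignment retained in element `block`.
#' @examples
#' g <- generate_ld_blocks(500, n_loci = 40, block_size = 10,
#'                         within_block_r2 = 0.8, maf = 0.3, seed = 1)
#' cor(g$doses[, 1], g$doses[, 2])^2  # about 0.8
#' @export
generate_ld_blocks <- function(n_samples, n_loci, block_size,
                               within_block_r2, maf = 0.3, ploidy = 1, seed,
                               segment_length = 25e6) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (within_block_r2 < 0 || within_block_r2 >= 1) {
    stop("`within_block_r2` must lie in [0, 1)", call. = FALSE)
  }
  if (block_size > n_loci) {
    stop("`block_size` (", block_size, ") exceeds `n_loci` (", n_loci, ")",
         call. = FALSE)
  }
  maf <- rep_len(maf, n_loci)
  rho <- sqrt(within_block_r2)
  block <- rep(seq_len(ceiling(n_loci / block_size)),
               each = block_size)[seq_len(n_loci)]
  n_hap <- n_samples * ploidy

  hap <- withr::with_seed(as.integer(seed), {
    h <- matrix(0L, nrow = n_hap, ncol = n_loci)
    for (j in seq_len(n_loci)) {
      fresh <- stats::rbinom(n_hap, 1L, maf[j])
      if (j > 1L && block[j] == block[j - 1L] && rho > 0) {
        copy <- stats::runif(n_hap) < rho
        h[, j] <- ifelse(copy, h[, j - 1L], fresh)
      } else {
        h[, j] <- fresh
      }
    }
    h
  })
  doses <- if (ploidy == 2L) {
    hap[seq(1, n_hap, by = 2), , drop = FALSE] +
      hap[seq(2, n_hap, by = 2), , drop = FALSE]
  } else hap

  positions <- withr::with_seed(as.integer(seed) + 1L,
    sort(sample.int(segment_length, n_loci)))
  g <- genotype_matrix(doses, positions, ploidy)
  g$block <- block
  g
}
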