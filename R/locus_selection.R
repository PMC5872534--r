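#' Select causal loci from a genotype matrix
#'
#' Picks the loci whose phenotype effects will be simulated, either by
#' explicit identifier or by searching for loci whose estimated (folded)
#' minor-allele frequency falls inside a window, optionally enforcing a
#' minimum inter-locus spacing. When more loci are eligible than requested,
#' the choice is a uniform random draw under `seed`, so repeated experiments
#' sample different genetic architectures; pass `explicit_ids` to pin the
#' loci instead. Monomorphic loci are never eligible.
#'
#' @param g a [genotype_matrix].
#' @param n_loci number of causal loci to select.
#' @param maf_min,maf_max folded minor-allele frequency window,
#'   `0 <= maf_min < maf_max <= 0.5`.
#' @param explicit_ids optional locus identifiers (or integer indices)
#'   overriding the search; must exist and be polymorphic.
#' @param min_spacing optional minimum distance between selected loci, in
#'   the units of `g$positions`.
#' @param seed integer seed for the random draw (required unless
#'   `explicit_ids` is given).
#' @return integer vector of locus column indices, with the chosen ids and
#'   estimated MAFs in attributes `"locus_ids"` and `"maf"`.
#' @examples
#' g <- generate_hwe(200, maf = runif(50, 0.05, 0.5), ploidy = 1, seed = 1)
#' select_loci(g, n_loci = 3, maf_min = 0.2, maf_max = 0.3, seed = 9)
#' @export
select_loci <- function(g, n_loci = 1, maf_min = 0, maf_max = 0.5,
                        explicit_ids = NULL, min_spacing = NULL, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!(maf_min >= 0 && maf_min < maf_max && maf_max <= 0.5)) {
    stop("require 0 <= maf_min < maf_max <= 0.5", call. = FALSE)
  }
  if (n_loci < 1) stop("`n_loci` must be >= 1", call. = FALSE)
  maf <- estimate_maf(g)

  if (!is.null(explicit_ids)) {
    idx <- if (is.numeric(explicit_ids)) as.integer(explicit_ids)
           else match(explicit_ids, g$locus_ids)
    if (anyNA(idx) || any(idx < 1L) || any(idx > ncol(g$doses))) {
      stop("explicit locus id(s) not found in the genotype matrix",
           call. = FALSE)
    }
    mono <- maf[idx] == 0
    if (any(mono)) {
      stop("explicit locus/loci ", paste(g$locus_ids[idx[mono]],
           collapse = ", "), " are monomorphic", call. = FALSE)
    }
    return(.with_locus_attrs(idx, g, maf))
  }

  if (is.null(seed)) {
    stop("`seed` is required when selecting loci by criteria", call. = FALSE)
  }
  eligible <- which(maf > 0 & maf >= maf_min & maf <= maf_max)
  if (length(eligible) < n_loci) {
    stop("requested ", n_loci, " causal loci but only ", length(eligible),
         " loci have MAF in [", maf_min, ", ", maf_max, "]", call. = FALSE)
  }
  idx <- withr::with_seed(as.integer(seed), {
    if (is.null(min_spacing)) {
      eligible[sample.int(length(eligible), n_loci)]
    } else {
      chosen <- integer(0)
      # random order, then greedy spacing
      pool <- eligible[sample.int(length(eligible))]
      for (cand in pool) {
        if (length(chosen) == n_loci) break
        if (all(abs(g$positions[cand] - g$positions[chosen]) >=
                min_spacing)) {
          chosen <- c(chosen, cand)
        }
      }
      if (length(chosen) < n_loci) {
        stop("could not place ", n_loci, " loci at spacing >= ", min_spacing,
             " (", length(chosen), " placed)", call. = FALSE)
      }
      chosen
    }
  })
  .with_locus_attrs(sort(idx), g, maf)
}

.with_locus_attrs <- function(idx, g, maf) {
  structure(idx, locus_ids = g$locus_ids[idx], maf = maf[idx])
}
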