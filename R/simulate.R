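#' Run a complete vGWAS phenotype simulation
#'
#' End-to-end driver: select (or accept) causal loci in a genotype matrix,
#' estimate their minor-allele frequencies, solve the heteroscedastic
#' phenotype model from the requested effect sizes, and draw one phenotype
#' per sample. Allele frequencies are by default *estimated from the
#' genotypes* (realized frequencies), so the configured effect shares refer
#' to the population actually simulated; theoretical frequencies can be
#' supplied through `q_override`.
#'
#' When causal loci are in linkage disequilibrium the solved baseline
#' standard deviation assumes independent loci, so the realized phenotypic
#' variance can deviate from `v_y`; the realized variance and the pairwise
#' dose correlations of the causal loci are reported in the metadata rather
#' than corrected (no analytic correction exists for the additive model).
#'
#' @param g a [genotype_matrix].
#' @param causal integer indices or locus ids of the causal loci, or the
#'   result of [select_loci()].
#' @param c_mu,c_v per-causal-locus effect sizes (fractions of `v_y`).
#' @param v_y total phenotypic variance; `mu` baseline mean.
#' @param mode inheritance mode; see [solve_phenotype_model()]. Defaults to
#'   haploid/co-dominant according to the matrix ploidy.
#' @param seed integer seed for the phenotype draw (required).
#' @param q_override optional vector of allele frequencies to use instead
#'   of the realized estimates.
#' @param sign_alpha,sign_phi optional per-locus effect directions.
#' @param mu baseline phenotype mean.
#' @return list of class `vgwas_simulation`: `y` (phenotypes), `model`
#'   (solved `phenotype_model`), `causal_idx`, `metadata` (list with
#'   realized frequencies and variance, causal dose correlations, seed).
#' @examples
#' g <- generate_hwe(1000, maf = rep(0.3, 20), ploidy = 2, seed = 1)
#' sim <- run_simulation(g, causal = c(4, 11), c_mu = c(0.05, 0),
#'                       c_v = c(0, 0.05), seed = 7)
#' var(sim$y)
#' @export
run_simulation <- function(g, causal, c_mu, c_v, v_y = 1, mu = 0,
                           mode = NULL, seed, q_override = NULL,
                           sign_alpha = 1, sign_phi = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(mode)) {
    mode <- if (g$ploidy == 1L) "haploid" else "diploid_codominant"
  }
  idx <- if (is.character(causal)) match(causal, g$locus_ids)
         else as.integer(causal)
  if (anyNA(idx)) stop("causal locus id(s) not found", call. = FALSE)

  doses <- g$doses[, idx, drop = FALSE]
  maf <- estimate_maf(g)[idx]
  if (any(maf == 0)) {
    stop("causal locus/loci ", paste(g$locus_ids[idx][maf == 0],
         collapse = ", "), " are monomorphic", call. = FALSE)
  }
  q <- if (is.null(q_override)) maf else q_override

  model <- solve_phenotype_model(c_mu, c_v, q = q, v_y = v_y, mu = mu,
                                 mode = mode, sign_alpha = sign_alpha,
                                 sign_phi = sign_phi)
  y <- simulate_phenotypes(doses, model, seed = seed)

  dose_cor <- if (length(idx) > 1L) stats::cor(doses) else NULL
  structure(list(
    y = as.vector(y), model = model, causal_idx = idx,
    metadata = list(
      causal_ids = g$locus_ids[idx], realized_maf = maf,
      q_used = q, mode = mode, seed = as.integer(seed),
      realized_variance = stats::var(as.vector(y)),
      realized_mean = mean(y),
      causal_dose_correlation = dose_cor,
      alpha = model$alpha, phi = model$phi, sigma = model$sigma)),
    class = "vgwas_simulation")
}

#' @export
print.vgwas_simulation <- function(x, ...) {
  cat("<vgwas_simulation> ", length(x$y), " phenotypes, ",
      length(x$causal_idx), " causal locus/loci (", x$metadata$mode, ")\n",
      sep = "")
  cat("  realized mean ", format(x$metadata$realized_mean, digits = 4),
      ", realized variance ",
      format(x$metadata$realized_variance, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Run a simulation from a YAML/JSON configuration
#'
#' Configuration keys: `seed` (required), `mode`, `mu`, `v_y`, `n_samples`,
#' `genotypes` (either `source: builtin` with `n_loci`/`maf`/`ploidy`, or
#' `source: ms`/`vcf` with `path`), and `loci`: a list of entries each with
#' `c_mu`, `c_v` and either `id` or selection criteria (`maf_min`,
#' `maf_max`). Outputs (written when `out_prefix` is given): a
#' PLINK-compatible `<prefix>.pheno`, a `<prefix>_doses.tsv` of causal dose
#' columns, and a `<prefix>_meta.json` sidecar with solved parameters,
#' realized frequencies and the seed — enough to replay the run exactly.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @param out_prefix optional output path prefix; when `NULL` nothing is
#'   written.
#' @return the `vgwas_simulation` (invisibly when writing files).
#' @export
run_simulation_config <- function(config, out_prefix = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("seed", "loci")) {
    if (is.null(cfg[[key]])) {
      stop("config is missing required key `", key, "`", call. = FALSE)
    }
  }
  gsrc <- cfg$genotypes %||% list(source = "builtin")
  ploidy <- as.integer(gsrc$ploidy %||% 1L)
  g <- switch(gsrc$source %||% "builtin",
    builtin = generate_hwe(
      n_samples = cfg$n_samples %||% 1000L,
      maf = gsrc$maf %||% 0.3,
      ploidy = ploidy,
      n_loci = gsrc$n_loci %||% max(length(gsrc$maf %||% 0.3), 100L),
      seed = as.integer(cfg$seed) + 1L),
    ms = read_ms(gsrc$path, ploidy = ploidy)[[1]],
    vcf = read_vcf(gsrc$path),
    stop("unknown genotype source `", gsrc$source, "`", call. = FALSE))

  loci <- cfg$loci
  c_mu <- vapply(loci, function(l) as.numeric(l$c_mu %||% 0), numeric(1))
  c_v <- vapply(loci, function(l) as.numeric(l$c_v %||% 0), numeric(1))
  ids <- unlist(lapply(loci, function(l) l$id))
  causal <- if (!is.null(ids) && length(ids) == length(loci)) {
    ids
  } else {
    as.integer(select_loci(
      g, n_loci = length(loci),
      maf_min = loci[[1]]$maf_min %||% 0.05,
      maf_max = loci[[1]]$maf_max %||% 0.5,
      seed = as.integer(cfg$seed) + 2L))
  }
  sim <- run_simulation(
    g, causal = causal, c_mu = c_mu, c_v = c_v,
    v_y = cfg$v_y %||% 1, mu = cfg$mu %||% 0,
    mode = cfg$mode, seed = as.integer(cfg$seed),
    sign_alpha = vapply(loci, function(l) as.numeric(l$sign %||% 1),
                        numeric(1)))

  if (!is.null(out_prefix)) {
    write_phenotypes(sim$y, g$sample_ids, paste0(out_prefix, ".pheno"))
    doses <- g$doses[, sim$causal_idx, drop = FALSE]
    utils::write.table(
      data.frame(IID = g$sample_ids, doses, check.names = FALSE),
      paste0(out_prefix, "_doses.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(sim$metadata, paste0(out_prefix, "_meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(sim))
  }
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a
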