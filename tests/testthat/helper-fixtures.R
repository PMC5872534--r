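# shared fixtures for the test suite (all built in code, no binary files)

# tiny ms-style replicate as a character vector
ms_fixture <- function(haplotypes = c("010", "110"),
                       positions = c(0.1, 0.5, 0.9)) {
  c("ms 2 1", "1 2 3", "",
    "//",
    paste0("segsites: ", nchar(haplotypes[1])),
    paste("positions:", paste(positions, collapse = " ")),
    haplotypes)
}

# small plain-text VCF written to a temp file
vcf_fixture <- function(gts) {
  path <- tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("S", seq_len(ncol(gts)))),
                    collapse = "\t"))
  rows <- vapply(seq_len(nrow(gts)), function(i) {
    paste(c("1", i * 100, paste0("rs", i), "A",
            attr(gts, "alt")[i] %||% "T", ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one simulated replicate -> empirical shares at a single causal locus
replicate_shares <- function(seed, n = 2000, maf = 0.3, c_mu = 0, c_v = 0,
                             ploidy = 1,
                             mode = if (ploidy == 1) "haploid"
                                    else "diploid_codominant") {
  g <- generate_hwe(n, maf, ploidy = ploidy, seed = seed)
  q <- estimate_maf(g)[1]
  m <- solve_phenotype_model(c_mu, c_v, q = q, v_y = 1, mu = 0, mode = mode)
  y <- simulate_phenotypes(g$doses[, 1], m, seed = seed + 1L)
  e <- empirical_decomposition(y, g$doses[, 1], ploidy = ploidy)
  list(e = e, y = y, doses = g$doses[, 1], model = m)
}
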