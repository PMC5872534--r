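#' Read ms-style coalescent simulator output
#'
#' Parses the text format emitted by Hudson's `ms` and compatible coalescent
#' simulators: replicates delimited by `//`, a `segsites:` count, a
#' `positions:` line of floats in (0, 1), then one 0/1 haplotype row per
#' chromosome. With `ploidy = 2`, consecutive haplotype pairs (rows 1+2,
#' 3+4, ...) are summed into individual dose rows, following the usual ms
#' convention for forming diploids.
#'
#' @param con a file path, connection, or character vector of lines.
#' @param ploidy 1 (haplotypes as-is) or 2 (pair and sum).
#' @return a list of [genotype_matrix] objects, one per replicate. A
#'   replicate with `segsites: 0` yields a zero-column matrix with a
#'   warning.
#' @examples
#' txt <- c("ms 2 1", "1 2 3", "", "//", "segsites: 3",
#'          "positions: 0.1 0.5 0.9", "010", "110")
#' read_ms(txt)[[1]]$doses
#' @export
read_ms <- function(con, ploidy = 1) {
  stopifnot(ploidy %in% c(1L, 2L))
  lines <- if (is.character(con) && length(con) == 1L && file.exists(con)) {
    readLines(con)
  } else if (is.character(con)) {
    unlist(strsplit(con, "\n", fixed = TRUE))
  } else {
    readLines(con)
  }
  starts <- which(trimws(lines) == "//")
  if (length(starts) == 0L) {
    stop("no replicate delimiter '//' found; not ms-style output",
         call. = FALSE)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(r) {
    .parse_ms_replicate(lines[starts[r]:ends[r]], ploidy, r)
  })
}

.parse_ms_replicate <- function(block, ploidy, rep_idx) {
  seg_line <- grep("^segsites:", trimws(block), value = TRUE)
  if (length(seg_line) != 1L) {
    stop("replicate ", rep_idx, ": expected exactly one 'segsites:' line",
         call. = FALSE)
  }
  segsites <- as.integer(sub("^segsites:\\s*", "", trimws(seg_line)))
  if (is.na(segsites)) {
    stop("replicate ", rep_idx, ": malformed 'segsites:' line", call. = FALSE)
  }
  if (segsites == 0L) {
    warning("replicate ", rep_idx, ": segsites is 0; empty genotype matrix",
            call. = FALSE)
    return(genotype_matrix(matrix(integer(0), nrow = 0, ncol = 0),
                           numeric(0), ploidy,
                           locus_ids = character(0),
                           sample_ids = character(0)))
  }
  pos_line <- grep("^positions:", trimws(block), value = TRUE)
  if (length(pos_line) != 1L) {
    stop("replicate ", rep_idx, ": expected one 'positions:' line",
         call. = FALSE)
  }
  positions <- as.numeric(strsplit(
    sub("^positions:\\s*", "", trimws(pos_line)), "\\s+")[[1]])
  if (length(positions) != segsites) {
    stop("replicate ", rep_idx, ": ", length(positions),
         " positions for ", segsites, " segregating sites", call. = FALSE)
  }
  hap_lines <- trimws(block[grepl("^[01]+$", trimws(block))])
  if (length(hap_lines) == 0L) {
    stop("replicate ", rep_idx, ": no haplotype rows found", call. = FALSE)
  }
  if (any(nchar(hap_lines) != segsites)) {
    stop("replicate ", rep_idx, ": ragged haplotype rows (lengths ",
         paste(unique(nchar(hap_lines)), collapse = ","),
         ", expected ", segsites, ")", call. = FALSE)
  }
  hap <- do.call(rbind, lapply(strsplit(hap_lines, ""),
                               function(x) as.integer(x)))
  if (ploidy == 2L) {
    if (nrow(hap) %% 2L != 0L) {
      stop("replicate ", rep_idx, ": odd haplotype count (", nrow(hap),
           ") cannot form diploid individuals", call. = FALSE)
    }
    hap <- hap[seq(1, nrow(hap), 2), , drop = FALSE] +
           hap[seq(2, nrow(hap), 2), , drop = FALSE]
  }
  # ms positions may tie at printed precision; nudge to strictly increasing
  positions <- .make_increasing(positions)
  genotype_matrix(hap, positions, ploidy)
}

.make_increasing <- function(x) {
  if (length(x) > 1L) for (i in 2:length(x)) {
    if (x[i] <= x[i - 1L]) x[i] <- x[i - 1L] + 1e-9
  }
  x
}

#' Write a genotype matrix as ms-style text
#'
#' Inverse of [read_ms()] for interoperability: doses are emitted as 0/1
#' haplotype rows. Diploid doses are phased deterministically (dose 1
#' becomes haplotypes 1 and 0 in that order), so
#' `read_ms(write_ms(g), ploidy = 2)` round-trips the dose matrix exactly.
#'
#' @param g a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ms <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$doses
  pos <- g$positions
  if (max(pos) > 1) pos <- pos / (max(pos) + 1)   # ms wants (0,1)
  hap <- if (g$ploidy == 2L) {
    h1 <- (d >= 1L) * 1L
    h2 <- (d == 2L) * 1L
    out <- matrix(0L, nrow = 2L * nrow(d), ncol = ncol(d))
    out[seq(1, nrow(out), 2), ] <- h1
    out[seq(2, nrow(out), 2), ] <- h2
    out
  } else d
  lines <- c(paste("ms", nrow(hap), 1), "", "//",
             paste0("segsites: ", ncol(d)),
             paste("positions:", paste(formatC(pos, format = "f",
                                               digits = 8), collapse = " ")),
             apply(hap, 1, paste, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read biallelic genotypes from a VCF file
#'
#' Extracts the ALT-allele dose (count of ALT alleles in the GT field) for
#' biallelic SNP records. Multi-allelic records are skipped with
#' a warning. Missing genotypes (`./.` or `.`) are mean-imputed per locus by
#' default (count reported in a warning), or the affected samples can be
#' dropped.
#'
#' @param path VCF file path (plain text or bgzipped, via vcfR).
#' @param missing `"impute"` (default: per-locus mean dose) or `"drop"`
#'   (remove samples with any missing call).
#' @return a [genotype_matrix] with ploidy inferred from the GT separator.
#' @export
read_vcf <- function(path, missing = c("impute", "drop")) {
  missing <- match.arg(missing)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required to read VCF files", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE) & fix[, "ALT"] != "."
  if (any(!biallelic)) {
    warning(sum(!biallelic), " multi-allelic record(s) skipped",
            call. = FALSE)
  }
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ploidy <- if (any(grepl("[|/]", gt[!is.na(gt)]))) 2L else 1L
  dose_of <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(s, "[|/]")[[1]]) > 0L)
  }
  doses <- t(apply(gt, 1L, function(row) vapply(row, dose_of, integer(1))))
  if (ncol(gt) == 1L) doses <- matrix(as.integer(doses), ncol = 1L)
  doses <- t(doses)  # samples x loci
  samples <- colnames(gt)
  n_miss <- sum(is.na(doses))
  if (n_miss > 0L) {
    if (missing == "drop") {
      keep <- rowSums(is.na(doses)) == 0L
      warning(sum(!keep), " sample(s) with missing genotypes dropped",
              call. = FALSE)
      doses <- doses[keep, , drop = FALSE]
      samples <- samples[keep]
    } else {
      warning(n_miss, " missing genotype call(s) mean-imputed", call. = FALSE)
      for (j in seq_len(ncol(doses))) {
        na <- is.na(doses[, j])
        if (any(na)) {
          doses[na, j] <- as.integer(round(mean(doses[!na, j])))
        }
      }
    }
  }
  pos <- .make_increasing(as.numeric(fix[, "POS"]))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(doses, pos, ploidy, locus_ids = ids,
                  sample_ids = samples)
}

#' Write a genotype matrix as a minimal GT-only VCF
#'
#' Emits a plain-text VCFv4.2 with phased GT as the only FORMAT field.
#' Diploid doses are phased deterministically as in [write_ms()].
#'
#' @param g a [genotype_matrix].
#' @param path output path.
#' @param segment_length scaling for fractional positions (bp).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, segment_length = 1e6) {
  stopifnot(inherits(g, "genotype_matrix"))
  pos <- g$positions
  if (all(pos <= 1)) pos <- pmax(1, round(pos * segment_length))
  pos <- as.integer(.make_increasing(pos))
  gt_string <- function(d) {
    if (g$ploidy == 2L) c("0|0", "1|0", "1|1")[d + 1L] else as.character(d)
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=vgwasim",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  rows <- vapply(seq_len(ncol(g$doses)), function(j) {
    paste(c("1", pos[j], g$locus_ids[j], "A", "T", ".", "PASS", ".", "GT",
            gt_string(g$doses[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write phenotypes in PLINK format
#'
#' One row per sample, whitespace-delimited columns `FID IID PHENO`, values
#' at full floating precision so a read-back is bit-exact.
#'
#' @param y numeric phenotype vector.
#' @param sample_ids sample identifiers (used for both FID and IID).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(y, sample_ids, path) {
  if (length(y) == 0L) stop("empty phenotype vector", call. = FALSE)
  if (length(y) != length(sample_ids)) {
    stop("phenotypes (", length(y), ") and sample ids (",
         length(sample_ids), ") differ in length", call. = FALSE)
  }
  writeLines(paste(sample_ids, sample_ids,
                   formatC(y, format = "g", digits = 17)), path)
  invisible(path)
}

#' Read a PLINK-style phenotype file
#'
#' @param path file written by [write_phenotypes()] (columns FID IID PHENO).
#' @return named numeric vector (names = IID).
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("FID", "IID", "PHENO"),
                           colClasses = c("character", "character",
                                          "numeric"))
  stats::setNames(tab$PHENO, tab$IID)
}
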