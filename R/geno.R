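#' Genotype matrix container
#'
#' A light container for per-sample, per-site allele-dosage calls. Dosages are
#' counts of the alternate allele (0, 1, 2) with `NA` for missing. Sites are
#' rows, samples are columns.
#'
#' @param geno integer matrix, sites x samples, values 0/1/2/NA.
#' @param sites data.frame with at least `chrom`, `pos` (1-based), `ref`,
#'   `alt`; extra per-site columns (outgroup alleles, effect class, constraint
#'   score) are carried along untouched.
#' @param samples data.frame with at least `sample` and `group`
#'   (`wild`, `landrace`, `improved` or `hybrid`).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, sites, samples) {
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == nrow(sites), ncol(geno) == nrow(samples))
  stopifnot(all(geno %in% c(0L, 1L, 2L, NA)))
  storage.mode(geno) <- "integer"
  rownames(geno) <- NULL
  colnames(geno) <- samples$sample
  structure(list(geno = geno, sites = as.data.frame(sites),
                 samples = as.data.frame(samples)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d sites x %d samples\n",
              nrow(x$geno), ncol(x$geno)))
  tab <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  missing rate: %.4f\n", mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param g a [geno_matrix()].
#' @param sites,samples logical or integer index vectors.
#' @return A `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(g, sites = NULL, samples = NULL) {
  if (!is.null(sites)) {
    g$geno <- g$geno[sites, , drop = FALSE]
    g$sites <- g$sites[sites, , drop = FALSE]
    rownames(g$sites) <- NULL
  }
  if (!is.null(samples)) {
    g$geno <- g$geno[, samples, drop = FALSE]
    g$samples <- g$samples[samples, , drop = FALSE]
    rownames(g$samples) <- NULL
  }
  g
}

#' Alternate-allele frequencies per site
#'
#' @param g a [geno_matrix()].
#' @param samples optional sample subset (index or logical).
#' @return Numeric vector of alternate-allele frequencies computed on
#'   non-missing calls; `NaN` where all calls are missing.
#' @export
allele_freq <- function(g, samples = NULL) {
  m <- if (is.null(samples)) g$geno else g$geno[, samples, drop = FALSE]
  rowSums(m, na.rm = TRUE) / (2 * rowSums(!is.na(m)))
}

#' Write genotypes to a VCF 4.2 file
#'
#' Emits a minimal diploid-GT VCF (missing as `./.`). Output is byte-stable
#' for a fixed input, which the simulator relies on for reproducibility
#' checks.
#'
#' @param g a [geno_matrix()].
#' @param path output file path (plain text).
#' @param contig_lengths named integer vector of contig lengths for the
#'   header; defaults to the max position seen per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf_geno <- function(g, path, contig_lengths = NULL) {
  s <- g$sites
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(s$pos, s$chrom, max)
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=domload",
           sprintf("##contig=<ID=%s,length=%d>",
                   names(contig_lengths), as.integer(contig_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples$sample), collapse = "\t"))
  gt <- matrix("./.", nrow(g$geno), ncol(g$geno))
  gt[!is.na(g$geno) & g$geno == 0L] <- "0/0"
  gt[!is.na(g$geno) & g$geno == 1L] <- "0/1"
  gt[!is.na(g$geno) & g$geno == 2L] <- "1/1"
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (via \pkg{vcfR}) into alternate-allele dosages. Only the GT
#' field is used; positions stay 1-based in the site table.
#'
#' @param path VCF file (may be gzipped).
#' @param groups optional data.frame (`sample`, `group`) or path to a
#'   two-column TSV assigning samples to groups; samples absent from it get
#'   group `NA`.
#' @return A [geno_matrix()].
#' @export
read_vcf_geno <- function(path, groups = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  gt2 <- gsub("\\|", "/", gt)
  dos[gt2 == "0/0"] <- 0L
  dos[gt2 %in% c("0/1", "1/0")] <- 1L
  dos[gt2 == "1/1"] <- 2L
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  smp <- data.frame(sample = colnames(gt), group = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    if (is.character(groups)) groups <- read_groups_tsv(groups)
    smp$group <- groups$group[match(smp$sample, groups$sample)]
  }
  geno_matrix(dos, sites, smp)
}

#' Read / write a two-column sample-group TSV
#'
#' @param path file path.
#' @return `read_groups_tsv`: data.frame with `sample` and `group`.
#' @export
read_groups_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @param groups data.frame with `sample` and `group`.
#' @rdname read_groups_tsv
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(groups[, c("sample", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
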