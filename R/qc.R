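#' Per-sample heterozygosity statistics
#'
#' @param g a [geno_matrix()].
#' @return data.frame with per-sample heterozygous call count, homozygous
#'   non-reference count and their ratio (`Inf` when a sample has
#'   heterozygous calls but no homozygous non-reference calls; `NA` when it
#'   has neither).
#' @export
sample_het_stats <- function(g) {
  n_het <- colSums(g$geno == 1L, na.rm = TRUE)
  n_hom_nonref <- colSums(g$geno == 2L, na.rm = TRUE)
  ratio <- ifelse(n_hom_nonref > 0, n_het / n_hom_nonref,
                  ifelse(n_het > 0, Inf, NA_real_))
  data.frame(sample = g$samples$sample, n_het = n_het,
             n_hom_nonref = n_hom_nonref, het_hom_ratio = ratio,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag samples with excess heterozygous-to-homozygous-nonref ratio
#'
#' Flags samples whose heterozygous / homozygous-non-reference call ratio
#' exceeds `ratio_cutoff` *and* whose heterozygous call count exceeds
#' `min_het_count`. At full genome scale the reference count threshold is
#' 0.5 million heterozygous SNPs; the default here scales it as 5% of the
#' number of sites so the rule is meaningful on small matrices.
#'
#' @param g a [geno_matrix()].
#' @param ratio_cutoff flag when the ratio is strictly greater (default 2/3).
#' @param min_het_count minimum heterozygous call count for a sample to be
#'   eligible for flagging; default `0.05 * n_sites`.
#' @return Logical vector (named by sample) of flags.
#' @export
sample_het_ratio_filter <- function(g, ratio_cutoff = 2 / 3,
                                    min_het_count = NULL) {
  if (is.null(min_het_count)) min_het_count <- 0.05 * nrow(g$geno)
  st <- sample_het_stats(g)
  flag <- !is.na(st$het_hom_ratio) & st$het_hom_ratio > ratio_cutoff &
    st$n_het > min_het_count
  stats::setNames(flag, st$sample)
}

#' Per-sample inbreeding coefficient
#'
#' `F = (E - O) / E`, where `O` is the sample's heterozygous call count
#' over sites non-missing in that sample and `E` is the Hardy-Weinberg
#' expected heterozygosity `sum(2 p (1 - p))` over the same sites, with `p`
#' the cohort alternate-allele frequency. Sites monomorphic in the cohort
#' contribute 0 to `E` and are excluded from `O`. When `E = 0` the
#' coefficient is undefined and `NA` is returned for that sample.
#'
#' @param g a [geno_matrix()].
#' @return data.frame with per-sample `O`, `E` and `inbreeding_F`.
#' @export
inbreeding_coefficient <- function(g) {
  p <- allele_freq(g)
  poly <- !is.na(p) & p > 0 & p < 1
  exp_het <- 2 * p * (1 - p)
  exp_het[!poly] <- 0
  nonmiss <- !is.na(g$geno)
  O <- colSums(g$geno == 1L & poly, na.rm = TRUE)
  E <- colSums(nonmiss * exp_het)
  F <- ifelse(E > 0, (E - O) / E, NA_real_)
  data.frame(sample = g$samples$sample, O = O, E = E, inbreeding_F = F,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove samples failing the heterozygosity-ratio or inbreeding filters
#'
#' Removes the union of samples flagged by [sample_het_ratio_filter()] and
#' samples with inbreeding coefficient below `F_cutoff`; samples with
#' undefined F are not filterable on F.
#'
#' @param g a [geno_matrix()].
#' @param F_cutoff exclude samples with `F < F_cutoff` (default 0.8).
#' @param ratio_cutoff,min_het_count passed to [sample_het_ratio_filter()].
#' @return List with `geno` (retained [geno_matrix()]) and `report`
#'   (per-sample flags and reasons).
#' @export
filter_samples <- function(g, F_cutoff = 0.8, ratio_cutoff = 2 / 3,
                           min_het_count = NULL) {
  ratio_flag <- sample_het_ratio_filter(g, ratio_cutoff, min_het_count)
  fstat <- inbreeding_coefficient(g)
  f_flag <- !is.na(fstat$inbreeding_F) & fstat$inbreeding_F < F_cutoff
  removed <- ratio_flag | f_flag
  if (all(removed)) stop("all samples removed by sample filters")
  reason <- ifelse(ratio_flag & f_flag, "ratio+F",
                   ifelse(ratio_flag, "ratio", ifelse(f_flag, "F", "")))
  report <- data.frame(sample = g$samples$sample,
                       inbreeding_F = fstat$inbreeding_F,
                       flag_ratio = unname(ratio_flag), flag_F = f_flag,
                       removed = unname(removed), reason = reason,
                       stringsAsFactors = FALSE)
  list(geno = subset_geno(g, samples = !removed), report = report)
}

#' Site-filter configuration
#'
#' Defaults follow the published filter chain: drop SNPs with more than 20%
#' missing calls, more than 10% heterozygous calls, monomorphic SNPs, and
#' SNPs with minor allele frequency below 1%; per-genotype depth and
#' allele-balance masks precede the site drops.
#'
#' @param max_missing maximum site missing rate.
#' @param max_het maximum site heterozygosity rate (het calls / non-missing
#'   calls).
#' @param min_maf minimum minor allele frequency, computed on non-missing
#'   alleles after masking.
#' @param biallelic_only drop sites with more than one alternate allele.
#' @param depth_mask_multiplier mask genotypes with depth above this
#'   multiple of the sample's mean depth.
#' @param min_allele_balance mask heterozygous genotypes with allele balance
#'   (percent) below this cutoff.
#' @param sv_length_cutoff indel length (bp) separating small indels from
#'   structural variants.
#' @return List of class `site_filter_config`.
#' @export
site_filter_config <- function(max_missing = 0.20, max_het = 0.10,
                               min_maf = 0.01, biallelic_only = TRUE,
                               depth_mask_multiplier = 4,
                               min_allele_balance = 30,
                               sv_length_cutoff = 50) {
  stopifnot(max_missing >= 0, max_missing <= 1, max_het >= 0, max_het <= 1,
            min_maf >= 0, min_maf <= 1, depth_mask_multiplier > 0,
            min_allele_balance >= 0, sv_length_cutoff > 0)
  structure(list(max_missing = max_missing, max_het = max_het,
                 min_maf = min_maf, biallelic_only = biallelic_only,
                 depth_mask_multiplier = depth_mask_multiplier,
                 min_allele_balance = min_allele_balance,
                 sv_length_cutoff = sv_length_cutoff),
            class = "site_filter_config")
}

#' Apply per-genotype masks and site-level filters
#'
#' Masks are applied first (genotype depth above `depth_mask_multiplier`
#' times the sample mean depth, and heterozygous genotypes with allele
#' balance below `min_allele_balance` percent, both set to missing), then
#' sites are dropped in order: non-biallelic, monomorphic (after masking),
#' missing rate above `max_missing`, heterozygosity rate above `max_het`,
#' and minor allele frequency below `min_maf`. Attrition counts are
#' reported per rule in application order. If depth or allele-balance
#' annotations are absent (`depth` / `ab` elements of the object) the
#' corresponding mask is skipped with a warning.
#'
#' @param g a [geno_matrix()]; may carry numeric matrices `g$depth` and
#'   `g$ab` (sites x samples) for the genotype masks.
#' @param config a [site_filter_config()].
#' @return List with `geno` (retained sites), `keep` (logical index into
#'   the input sites) and `attrition` (named counts per rule).
#' @export
filter_sites <- function(g, config = site_filter_config()) {
  geno <- g$geno
  if (!is.null(g$depth)) {
    mean_depth <- colMeans(g$depth, na.rm = TRUE)
    mask <- sweep(g$depth, 2, config$depth_mask_multiplier * mean_depth,
                  ">")
    geno[which(mask)] <- NA_integer_
  } else {
    warning("depth annotation absent; depth mask skipped")
  }
  if (!is.null(g$ab)) {
    mask <- !is.na(geno) & geno == 1L & g$ab < config$min_allele_balance
    geno[mask] <- NA_integer_
  } else {
    warning("allele-balance annotation absent; AB mask skipped")
  }
  n_nonmiss <- rowSums(!is.na(geno))
  ac <- rowSums(geno, na.rm = TRUE)
  an <- 2 * n_nonmiss
  p <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(p, 1 - p)
  het_rate <- ifelse(n_nonmiss > 0,
                     rowSums(geno == 1L, na.rm = TRUE) / n_nonmiss, 0)
  miss_rate <- rowMeans(is.na(geno))

  keep <- rep(TRUE, nrow(geno))
  attrition <- c(non_biallelic = 0L, monomorphic = 0L, missing = 0L,
                 het = 0L, maf = 0L)
  if (config$biallelic_only && !is.null(g$sites$alt)) {
    drop <- keep & grepl(",", g$sites$alt)
    attrition["non_biallelic"] <- sum(drop); keep <- keep & !drop
  }
  drop <- keep & (is.na(p) | p == 0 | p == 1)
  attrition["monomorphic"] <- sum(drop); keep <- keep & !drop
  drop <- keep & miss_rate > config$max_missing
  attrition["missing"] <- sum(drop); keep <- keep & !drop
  drop <- keep & het_rate > config$max_het
  attrition["het"] <- sum(drop); keep <- keep & !drop
  drop <- keep & maf < config$min_maf
  attrition["maf"] <- sum(drop); keep <- keep & !drop

  out <- g
  out$geno <- geno
  out <- subset_geno(out, sites = keep)
  if (!is.null(g$depth)) out$depth <- g$depth[keep, , drop = FALSE]
  if (!is.null(g$ab)) out$ab <- g$ab[keep, , drop = FALSE]
  list(geno = out, keep = keep, attrition = attrition)
}

#' Split indel lengths into small indels and structural variants
#'
#' @param lengths integer vector of indel lengths (bp).
#' @param sv_cutoff structural variants are those with length strictly
#'   greater than this cutoff (default 50 bp).
#' @return Named list with `n_total`, `n_small` and `n_sv`.
#' @export
split_indel_lengths <- function(lengths, sv_cutoff = 50) {
  n_sv <- sum(lengths > sv_cutoff)
  list(n_total = length(lengths), n_small = length(lengths) - n_sv,
       n_sv = n_sv)
}
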