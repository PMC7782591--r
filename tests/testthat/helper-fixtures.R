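# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

# genotype matrix from an explicit dosage matrix (sites x samples)
toy_geno <- function(dos, pos = seq_len(nrow(dos)) * 10L, chrom = "chr1",
                     groups = rep("wild", ncol(dos)),
                     ref = rep("A", nrow(dos)), alt = rep("G", nrow(dos))) {
  geno_matrix(dos,
              data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE),
              data.frame(sample = sprintf("s%02d", seq_len(ncol(dos))),
                         group = groups, stringsAsFactors = FALSE))
}

# random dosage matrix with given allele frequencies and inbreeding
random_dosages <- function(p, n_samples, F = 0, missing_rate = 0) {
  hom <- p^2 + F * p * (1 - p)
  het <- 2 * p * (1 - p) * (1 - F)
  u <- matrix(runif(length(p) * n_samples), length(p), n_samples)
  m <- matrix(0L, length(p), n_samples)
  m[u < hom] <- 2L
  m[u >= hom & u < hom + het] <- 1L
  if (missing_rate > 0)
    m[matrix(runif(length(m)) < missing_rate, nrow(m))] <- NA_integer_
  m
}

# brute-force per-site pairwise diversity: average mismatch over all
# unordered allele pairs, treating a genotype as an unordered allele pair
brute_pi_site <- function(dosages) {
  alleles <- unlist(lapply(dosages[!is.na(dosages)], function(d)
    c(rep(1L, d), rep(0L, 2L - d))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    diff <- diff + (alleles[a] != alleles[b])
  diff / choose(n, 2)
}

# independent textbook implementation of Tajima's D from S, pi-hat, n
brute_tajima_d <- function(S, pihat, n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# a 12-species neutral tree of realistic span (~1 substitution/site) with
# the reference as one leaf; fixed topology via seed
fixture_tree <- function(n_tip = 12, scale = 0.6, seed = 7) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tr <- ape::rtree(n_tip, br = function(n) runif(n, 0.02, 0.12) * scale)
  tr$tip.label <- c("Gmax", paste0("sp", seq_len(n_tip - 1)))
  tr
}

# quick small simulation for pipeline-level tests; `...` overrides defaults
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_wild = 30, n_landrace = 30, n_improved = 8,
               n_sites = 1500, n_deleterious = 150, chrom_length = 1e6,
               sweep_regions = data.frame(start = 3e5, end = 4.5e5,
                                          escape_scale = 0.02),
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# the full polarize -> classify -> burden recovery of the planted landrace
# burden reduction, as a percent
burden_reduction_percent <- function(seed) {
  cfg <- sim_config(n_wild = 100, n_landrace = 100, n_improved = 25,
                    n_sites = 6000, n_deleterious = 5000, seed = seed)
  sim <- simulate_populations(cfg)
  g <- sim$geno
  p <- allele_freq(g)
  psites <- data.frame(
    major = ifelse(p > 0.5, g$sites$alt, g$sites$ref),
    minor = ifelse(p > 0.5, g$sites$ref, g$sites$alt),
    out1 = g$sites$out1, out2 = g$sites$out2, maf = pmin(p, 1 - p),
    stringsAsFactors = FALSE)
  pol <- polarize_sites(fit_polarizer(psites), psites)
  delset <- build_deleterious_set(g$sites$effect, g$sites$rs_score)
  bt <- mutation_burden(g, pol, delset, NULL, sim$cds)
  pw <- compare_burden(bt)$pairwise
  pw$percent_difference[pw$focal == "landrace" & pw$reference == "wild"]
}
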