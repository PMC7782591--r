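# Synthetic cohort generator, alignment simulator, pseudodiploids.

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(burden_ratio_landrace = 1.2), "burden ratios")
  expect_error(sim_config(sweep_regions = data.frame(
    start = 9.9e6, end = 10.5e6, escape_scale = 0.02)), "outside")
  expect_error(sim_config(sweep_regions = data.frame(
    start = c(1e6, 1.2e6), end = c(1.5e6, 1.6e6), escape_scale = 0.02)),
    "overlap")
  expect_error(sim_config(selfing_F = 1.4), "fractions")
})

test_that("no drift and no sweeps leave the populations identical", {
  cfg <- small_sim_config(seed = 5, drift_omega = 0,
                          sweep_regions = data.frame(start = numeric(0),
                                                     end = numeric(0),
                                                     escape_scale = numeric(0)),
                          burden_ratio_landrace = 1,
                          burden_ratio_improved = 1)
  sim <- simulate_populations(cfg)
  f <- sim$truth$freqs
  expect_equal(f[, "wild"], f[, "landrace"])
  g <- sim$geno
  wild <- g$samples$group == "wild"
  dom <- g$samples$group %in% c("landrace", "improved")
  pw <- sum(nucleotide_diversity(subset_geno(g, samples = wild), 1e6,
                                 1e6)$pi)
  pd <- sum(nucleotide_diversity(subset_geno(g, samples = dom), 1e6,
                                 1e6)$pi)
  expect_lt(abs(pd / pw - 1), 0.1)
})

test_that("complete selfing yields only homozygous genotypes with realized F near 1", {
  cfg <- small_sim_config(seed = 6, selfing_F = 1, missing_rate = 0)
  sim <- simulate_populations(cfg)
  expect_true(all(sim$geno$geno %in% c(0L, 2L)))
  fc <- inbreeding_coefficient(sim$geno)
  expect_true(all(fc$inbreeding_F >= 0.99, na.rm = TRUE))
})

test_that("realized wild frequencies track the truth within binomial error", {
  cfg <- small_sim_config(seed = 7, missing_rate = 0)
  sim <- simulate_populations(cfg)
  g <- sim$geno
  wild <- g$samples$group == "wild"
  p_real <- allele_freq(g, wild)
  # convert alt-frequency back to derived-frequency
  p_real_der <- ifelse(sim$truth$ref_is_derived, 1 - p_real, p_real)
  p_true <- sim$truth$freqs[, "wild"]
  n_al <- 2 * sum(wild)
  z <- abs(p_real_der - p_true) /
    sqrt(pmax(p_true * (1 - p_true), 1e-4) / n_al)
  # rare sites are Poisson-discrete, so slightly more than the Gaussian
  # 6e-5 land beyond 4 standard errors
  expect_gt(mean(z < 4), 0.97)
})

test_that("planted sweep regions show elevated frequency differentiation", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_populations(cfg)
  f <- sim$truth$freqs
  d <- abs(f[, "wild"] - f[, "landrace"])
  pos <- sim$geno$sites$pos
  sw <- sim$truth$sweep_regions
  in_sweep <- vapply(pos, function(p)
    any(p >= sw$start & p <= sw$end), logical(1))
  wt <- wilcox.test(d[in_sweep], d[!in_sweep], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("planted burden ratios hold for the expected group burdens", {
  cfg <- small_sim_config(seed = 9)
  sim <- simulate_populations(cfg)
  eb <- sim$truth$expected_burden
  expect_equal(unname(eb["landrace"] / eb["wild"]), 0.929,
               tolerance = 1e-6)
  expect_equal(unname(eb["improved"] / eb["wild"]), 0.929 * 0.986,
               tolerance = 1e-6)
  # deleterious sites are CDS-confined and nonsynonymous
  del <- sim$truth$deleterious
  expect_true(all(sim$geno$sites$effect[del] == "nonsynonymous"))
  cds <- sim$cds
  in_cds <- vapply(sim$geno$sites$pos[del], function(p)
    any(p >= cds$start & p <= cds$end), logical(1))
  expect_true(all(in_cds))
})

test_that("identical seeds give byte-identical VCF output", {
  cfg <- small_sim_config(seed = 10)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_sim_outputs(simulate_populations(cfg), d1)
  write_sim_outputs(simulate_populations(cfg), d2)
  f1 <- file.path(d1, "genotypes.vcf"); f2 <- file.path(d2, "genotypes.vcf")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed differs
  write_sim_outputs(simulate_populations(small_sim_config(seed = 11)), d2)
  expect_false(identical(unname(tools::md5sum(f1)),
                         unname(tools::md5sum(f2))))
})

test_that("VCF round-trips through the reader", {
  cfg <- small_sim_config(seed = 12)
  sim <- simulate_populations(cfg)
  d <- file.path(tempdir(), "sim_rt")
  f <- write_sim_outputs(sim, d)
  g2 <- read_vcf_geno(f[["vcf"]], f[["groups"]])
  expect_equal(unname(g2$geno), unname(sim$geno$geno))
  expect_equal(g2$sites$pos, sim$geno$sites$pos)
  expect_equal(g2$samples$group, sim$geno$samples$group)
})

test_that("simulated alignment columns behave at the rate extremes", {
  tr <- fixture_tree(n_tip = 8)
  msa <- simulate_msa(tr, 200, constrained_fraction = 1, seed = 13,
                      constrained_rate = 0)
  expect_true(all(apply(msa$columns, 1,
                        function(r) length(unique(r)) == 1)))
  # seeded reproducibility
  msa2 <- simulate_msa(tr, 200, constrained_fraction = 1, seed = 13,
                       constrained_rate = 0)
  expect_identical(msa$columns, msa2$columns)
  # unconstrained columns vary (tree span ~0.5 subs/site)
  msa3 <- simulate_msa(tr, 200, constrained_fraction = 0, seed = 14)
  expect_gt(mean(apply(msa3$columns, 1,
                       function(r) length(unique(r)) > 1)), 0.3)
})

test_that("pseudodiploid merging follows the IUPAC rules", {
  expect_equal(build_pseudodiploid("A", "A"), "A")
  expect_equal(build_pseudodiploid("A", "G"), "R")
  expect_equal(build_pseudodiploid("A", "N"), "N")
  expect_equal(build_pseudodiploid("ACGT", "ACGA"), "ACGW")
  expect_error(build_pseudodiploid("AC", "A"), "length")

  # ambiguity codes resolve to a concrete base before merging
  out <- build_pseudodiploid("R", "A", seed = 3)
  expect_true(out %in% c("A", "R"))  # resolved R is A or G

  # symmetric up to seeded ambiguity resolution
  set.seed(15)
  h1 <- paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE),
              collapse = "")
  h2 <- paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE),
              collapse = "")
  expect_identical(build_pseudodiploid(h1, h2, seed = 1),
                   build_pseudodiploid(h2, h1, seed = 1))
})

test_that("pair enumeration is complete, ordered and rejects duplicates", {
  p8 <- enumerate_pseudodiploid_pairs(sprintf("acc%02d", 1:8))
  expect_equal(nrow(p8), 28)
  expect_equal(nrow(enumerate_pseudodiploid_pairs(c("a", "b"))), 1)
  acc5 <- c("e", "b", "a", "d", "c")
  p5 <- enumerate_pseudodiploid_pairs(acc5)
  brute <- t(combn(sort(acc5), 2))
  expect_equal(nrow(p5), 10)
  expect_equal(as.matrix(p5), brute, ignore_attr = TRUE)
  expect_error(enumerate_pseudodiploid_pairs(c("a", "a", "b")),
               "duplicate")
})
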