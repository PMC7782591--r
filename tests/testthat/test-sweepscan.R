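# Composite-likelihood sweep scan: drift estimation, per-SNP likelihood
# ratios, windowed scanning, threshold and region calling.

test_that("omega estimation is exact on undrifted data and matches a direct formula", {
  p1 <- runif(2000, 0.25, 0.75)
  expect_equal(estimate_omega(p1, p1), 0)

  # 5-SNP toy with no trimming: plain calibrated moment
  p <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  q <- c(0.35, 0.38, 0.55, 0.52, 0.75)
  z2 <- (q - p)^2 / (p * (1 - p))
  expect_equal(estimate_omega(p, q, trim = 0, p1_band = c(0, 1),
                              min_snps = 5),
               mean(z2), tolerance = 1e-12)
  expect_error(estimate_omega(0.5, 0.5), "too few")
})

test_that("omega recovery on simulated drift is within 15%", {
  set.seed(101)
  p1 <- rbeta(1e4, 0.2, 0.2)
  p1 <- pmin(pmax(p1, 0.01), 0.99)
  p2 <- pmin(1, pmax(0, rnorm(1e4, p1, sqrt(0.05 * p1 * (1 - p1)))))
  est <- estimate_omega(p1, p2)
  expect_lt(abs(est - 0.05) / 0.05, 0.15)
})

test_that("per-SNP log-likelihood ratio matches adaptive quadrature and limits", {
  p1 <- 0.5; k <- 20; n <- 20; d <- 1e-4; omega <- 0.02; s <- 0.01
  v <- snp_loglik_ratio(p1, k, n, d, omega, s)
  sd0 <- sqrt(omega * p1 * (1 - p1))
  m0 <- pnorm(0, p1, sd0); m1 <- 1 - pnorm(1, p1, sd0)
  l_neu <- m0 * dbinom(k, n, 0) + m1 * dbinom(k, n, 1) +
    integrate(function(x) dnorm(x, p1, sd0) * dbinom(k, n, x), 0, 1,
              rel.tol = 1e-10)$value
  cc <- 1 - exp(-d / s)
  mix <- function(x) p1 * dbinom(k, n, cc * x + 1 - cc) +
    (1 - p1) * dbinom(k, n, cc * x)
  l_sw <- m0 * mix(0) + m1 * mix(1) +
    integrate(function(x) dnorm(x, p1, sd0) * mix(x), 0, 1,
              rel.tol = 1e-10)$value
  expect_equal(v, log(l_sw) - log(l_neu), tolerance = 1e-6)
  expect_gt(v, 0)  # full fixation right at the grid point favors a sweep

  # far from the sweep (c -> 1) the models coincide
  expect_equal(snp_loglik_ratio(p1, k, n, d = 10, omega, s), 0,
               tolerance = 1e-12)
  # vanishing selection scale at positive distance likewise
  expect_equal(snp_loglik_ratio(p1, k, n, d = 0.01, omega, 1e-9), 0,
               tolerance = 1e-10)
  expect_error(snp_loglik_ratio(p1, k, n, d, omega, 0), "s_scale")

  # allele-label flip invariance: p -> 1 - p in both populations
  v1 <- snp_loglik_ratio(0.3, 5, 18, 2e-4, 0.05, 0.01)
  v2 <- snp_loglik_ratio(0.7, 13, 18, 2e-4, 0.05, 0.01)
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("a duplicated SNP is down-weighted to match the deduplicated scan", {
  set.seed(102)
  n_sites <- 30
  p <- runif(n_sites, 0.2, 0.8)
  dos <- random_dosages(p, 40, F = 0.9)
  pos <- sort(sample.int(2e5, n_sites))
  groups <- rep(c("wild", "landrace"), each = 20)
  map <- data.frame(chrom = "chr1", bp = c(1, 2e5), cM = c(0, 0.5))
  cfg <- sweep_scan_config(grid_bp = 5e4, omega = 0.05,
                           window_morgans = 0.005)
  g1 <- toy_geno(dos, pos = pos, groups = groups)
  # duplicate site 10 at the same position
  dup <- c(seq_len(n_sites), 10L)
  o <- order(pos[dup])
  g2 <- toy_geno(dos[dup, ][o, ], pos = pos[dup][o], groups = groups)
  s1 <- sweep_scan(g1, map, cfg)
  s2 <- sweep_scan(g2, map, cfg)
  expect_equal(s1$clr, s2$clr, tolerance = 1e-8)
})

test_that("a single-SNP window reduces to the per-SNP statistic at its optimum", {
  dos <- random_dosages(c(0.5, 0.4), 30, F = 1)
  g <- toy_geno(dos, pos = c(1000L, 90000L),
                groups = rep(c("wild", "landrace"), 15))
  map <- data.frame(chrom = "chr1", bp = c(1, 1e5), cM = c(0, 0.25))
  cfg <- sweep_scan_config(grid_bp = 1000, max_snps = 1, omega = 0.05)
  sc <- sweep_scan(g, map, cfg)
  row <- sc[sc$pos == 1000, ]
  obj <- g$samples$group == "landrace"
  wildidx <- g$samples$group == "wild"
  p1 <- sum(g$geno[1, wildidx]) / (2 * sum(wildidx))
  k <- sum(g$geno[1, obj]); n <- 2 * sum(obj)
  # the first grid point coincides with the SNP, so d = 0
  lrs <- vapply(cfg$s_grid, function(s)
    snp_loglik_ratio(p1, k, n, 0, 0.05, s), numeric(1))
  expect_equal(row$clr, max(0, 2 * max(lrs)), tolerance = 1e-8)
})

test_that("region calling reproduces the documented merge rules", {
  # windows laid out so each aggregation window holds one grid point
  mk_scores <- function(clr) data.frame(chrom = "chr1",
                                        pos = seq_along(clr) * 100 - 50,
                                        gpos = 0, n_snps = 1, clr = clr)
  # flags TTFT merge into one region (single sub-threshold gap tolerated)
  calls <- call_regions(mk_scores(c(10, 10, 1, 10)), genome_length = 400,
                        genome_fraction = 0.8, window = 100, slide = 100)
  expect_equal(nrow(calls$regions), 1)
  expect_equal(calls$regions$start, 0)
  expect_equal(calls$regions$end, 400)

  # flags TFFT split into two regions
  calls2 <- call_regions(mk_scores(c(10, 1, 1, 10)), genome_length = 400,
                         genome_fraction = 0.6, window = 100, slide = 100)
  expect_equal(nrow(calls2$regions), 2)

  # empty input
  empty <- call_regions(data.frame(), genome_length = 100)
  expect_equal(nrow(empty$regions), 0)
})

test_that("threshold and regions match an exhaustive oracle on a 20-window toy", {
  set.seed(103)
  clr <- round(runif(20, 0, 100), 1)
  scores <- data.frame(chrom = "chr1", pos = seq_len(20) * 100 - 50,
                       gpos = 0, n_snps = 1, clr = clr)
  calls <- call_regions(scores, genome_length = 2000,
                        genome_fraction = 0.25, window = 100, slide = 100)
  # oracle: try every candidate threshold, flag, measure span
  cand <- sort(unique(clr))
  spans <- vapply(cand, function(t) 100 * sum(clr > t), numeric(1))
  thr_oracle <- min(cand[spans <= 0.25 * 2000])
  expect_equal(calls$threshold, thr_oracle)
  flags <- clr > thr_oracle
  # oracle merge: runs tolerating one FALSE
  regions <- 0; inside <- FALSE; gap <- 0
  for (f in flags) {
    if (f) { if (!inside) { regions <- regions + 1; inside <- TRUE }
      gap <- 0 }
    else if (inside) { gap <- gap + 1
      if (gap > 1) { inside <- FALSE; gap <- 0 } }
  }
  expect_equal(nrow(calls$regions), regions)
})

test_that("smaller genome fractions give non-decreasing thresholds and nested regions", {
  set.seed(104)
  clr <- runif(50, 0, 50)
  scores <- data.frame(chrom = "chr1", pos = seq_len(50) * 100 - 50,
                       gpos = 0, n_snps = 1, clr = clr)
  fr <- c(0.4, 0.2, 0.1)
  out <- lapply(fr, function(f)
    call_regions(scores, 5000, f, window = 100, slide = 100))
  expect_true(out[[2]]$threshold >= out[[1]]$threshold)
  expect_true(out[[3]]$threshold >= out[[2]]$threshold)
  # flagged windows nest
  f1 <- out[[1]]$windows$flagged; f2 <- out[[2]]$windows$flagged
  f3 <- out[[3]]$windows$flagged
  expect_true(all(!f2 | f1))
  expect_true(all(!f3 | f2))
})

test_that("planted sweeps are recovered from the default simulation", {
  sim <- simulate_populations(sim_config(seed = 1))
  sc <- sweep_scan(sim$geno, sim$map, sweep_scan_config(grid_bp = 1e4))
  calls <- call_regions(sc, sim$config$chrom_length, 0.05,
                        genes = data.frame(gene = sim$cds$gene,
                                           chrom = sim$cds$chrom,
                                           start = sim$cds$start,
                                           end = sim$cds$end))
  truth <- sim$truth$sweep_regions
  reg <- calls$regions
  overlaps <- vapply(seq_len(nrow(truth)), function(i)
    any(reg$end > truth$start[i] & reg$start < truth$end[i]), logical(1))
  expect_true(all(overlaps))
  false_regions <- sum(vapply(seq_len(nrow(reg)), function(i)
    !any(truth$end > reg$start[i] & truth$start < reg$end[i]),
    logical(1)))
  expect_lte(false_regions, 1)
  expect_false(any(is.na(reg$candidate_gene)))
})
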