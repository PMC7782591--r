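# Effect annotation, deleterious sets, burden counting and comparisons.

test_that("codon effects classify against the standard genetic code", {
  #            123456789012
  genome <- "GGATGGGATGGC"   # CDS 3..11 (+): ATG GGA TGG
  cds <- data.frame(gene = "g1", start = 3L, end = 11L, strand = "+",
                    phase = 0L, stringsAsFactors = FALSE)
  sites <- data.frame(pos = c(5L, 8L, 11L),
                      ref = c("G", "A", "G"),
                      alt = c("A", "G", "A"), stringsAsFactors = FALSE)
  eff <- annotate_effect(sites, cds, genome)
  expect_equal(eff[1], "nonsynonymous")  # ATG -> ATA (M -> I)
  expect_equal(eff[2], "synonymous")     # GGA -> GGG (G -> G)
  expect_equal(eff[3], "stop_gained")    # TGG -> TGA (W -> *)

  # reverse strand: CDS 1..9 on minus is the reverse complement
  genome2 <- "CATTCCCAT"     # revcomp = ATG GGA ATG
  cds2 <- data.frame(gene = "g2", start = 1L, end = 9L, strand = "-",
                     phase = 0L, stringsAsFactors = FALSE)
  sites2 <- data.frame(pos = 5L, ref = "C", alt = "T",
                       stringsAsFactors = FALSE)
  # plus-strand C at pos 5 is G on minus (codon GGA -> GAA, G -> E)
  eff2 <- annotate_effect(sites2, cds2, genome2)
  expect_equal(eff2[1], "nonsynonymous")

  # site outside any CDS is noncoding
  sites3 <- data.frame(pos = 2L, ref = "G", alt = "C")
  expect_equal(annotate_effect(sites3, cds, genome)[1], "noncoding")

  # frame-inconsistent terminal codon -> noncoding with warning
  cds4 <- data.frame(gene = "g4", start = 3L, end = 12L, strand = "+",
                     phase = 0L, stringsAsFactors = FALSE)
  expect_warning(
    eff4 <- annotate_effect(data.frame(pos = 12L, ref = "C", alt = "T"),
                            cds4, genome),
    "frame")
  expect_equal(eff4[1], "noncoding")
})

test_that("deleterious-set criteria partition effects by constraint strata", {
  eff <- c("nonsynonymous", "synonymous", "stop_gained", "noncoding")
  rs <- c(2.5, 5, 4.5, 6)
  expect_equal(build_deleterious_set(eff, rs, criterion = "GERP2_nonsyn"),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(build_deleterious_set(eff, rs, criterion = "GERP2_4_nonsyn"),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(build_deleterious_set(eff, rs, criterion = "GERP4_nonsyn"),
               c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(build_deleterious_set(eff, rs, criterion = "GERP4_syn"),
               c(FALSE, TRUE, FALSE, FALSE))
  expect_error(build_deleterious_set(eff, rs, criterion = "SIFT05_nonsyn"),
               "sift")

  # 20-site random toy equals a hand partition
  set.seed(91)
  eff20 <- sample(c("nonsynonymous", "synonymous", "stop_gained",
                    "noncoding"), 20, replace = TRUE)
  rs20 <- runif(20, -1, 6)
  got <- build_deleterious_set(eff20, rs20, criterion = "GERP2_4_syn")
  hand <- vapply(1:20, function(i)
    eff20[i] == "synonymous" && rs20[i] > 2 && rs20[i] <= 4, logical(1))
  expect_equal(got, hand)
})

test_that("reference-bias weights are the stratified class-rate ratio", {
  # single bin with P(del | ref anc) = 0.30 and P(del | ref der) = 0.15
  freq <- rep(0.25, 300)
  refder <- c(rep(FALSE, 200), rep(TRUE, 100))
  del <- c(rep(TRUE, 60), rep(FALSE, 140),    # 60/200 = 0.30
           rep(TRUE, 15), rep(FALSE, 85))     # 15/100 = 0.15
  w <- reference_bias_correction(freq, refder, del, n_bins = 1)
  expect_equal(unique(w$weight[refder & del]), 2.0)
  expect_true(all(w$weight[!refder] == 1))
  expect_true(all(w$weight[!del] == 1))

  # null case: equal rates in both strata give weights 1
  del_null <- rep(c(TRUE, FALSE), 150)
  w0 <- reference_bias_correction(freq, refder, del_null, n_bins = 1)
  expect_true(all(w0$weight == 1))

  # empty stratum falls back to weight 1 with a warning
  expect_warning(
    w1 <- reference_bias_correction(freq, rep(FALSE, 300), del,
                                    n_bins = 1),
    "empty")
  expect_true(all(w1$weight == 1))
})

test_that("burden counts derived copies and normalizes per 100-kb CDS", {
  # 3 deleterious sites: hom-derived, het, hom-ancestral in one accession
  g <- toy_geno(matrix(c(2L, 1L, 0L), 3, 1), pos = c(10L, 20L, 30L))
  pol <- data.frame(p_major_ancestral = rep(0.9, 3),
                    ancestral = "A", derived = "G",
                    usable = TRUE, stringsAsFactors = FALSE)
  cds <- data.frame(start = 1L, end = 150000L)
  bt <- mutation_burden(g, pol, rep(TRUE, 3), NULL, cds)
  expect_equal(bt$raw, 3)
  expect_equal(bt$per_100kb, 2.0)

  # all-missing accession carries zero burden and is flagged via n_missing
  g2 <- toy_geno(matrix(NA_integer_, 3, 1), pos = c(10L, 20L, 30L))
  bt2 <- mutation_burden(g2, pol, rep(TRUE, 3), NULL, cds)
  expect_equal(bt2$raw, 0)
  expect_equal(bt2$n_missing, 3L)
})

test_that("burden matches a hand count and is additive over sweep/control", {
  set.seed(92)
  n_sites <- 40; n_acc <- 5
  dos <- random_dosages(runif(n_sites, 0.1, 0.8), n_acc, F = 0.9,
                        missing_rate = 0.05)
  pos <- sort(sample.int(1e5, n_sites))
  g <- toy_geno(dos, pos = pos,
                groups = c("wild", "wild", "wild", "landrace", "landrace"))
  derived <- sample(c("A", "G"), n_sites, replace = TRUE)  # G = alt
  pol <- data.frame(p_major_ancestral = runif(n_sites),
                    ancestral = ifelse(derived == "G", "A", "G"),
                    derived = derived,
                    usable = runif(n_sites) > 0.1, stringsAsFactors = FALSE)
  del <- runif(n_sites) > 0.3
  w <- runif(n_sites, 1, 2)
  cds <- data.frame(start = c(1L, 60001L), end = c(50000L, 100000L))
  sweeps <- data.frame(start = 1L, end = 50000L)
  # min_certainty 0 keeps every usable site so the hand count is direct
  bt <- mutation_burden(g, pol, del, w, cds, sweeps, min_certainty = 0)

  hand <- matrix(0, n_acc, 3,
                 dimnames = list(NULL, c("genome", "sweep", "control")))
  for (i in seq_len(n_sites)) {
    if (!del[i] || !pol$usable[i]) next
    for (a in seq_len(n_acc)) {
      d <- dos[i, a]
      if (is.na(d)) next
      copies <- if (derived[i] == "G") d else 2L - d
      cls <- if (pos[i] <= 50000) "sweep" else "control"
      hand[a, "genome"] <- hand[a, "genome"] + w[i] * copies
      hand[a, cls] <- hand[a, cls] + w[i] * copies
    }
  }
  for (cls in colnames(hand))
    expect_equal(bt$raw[bt$region == cls], unname(hand[, cls]),
                 tolerance = 1e-12)
  # additivity: sweep + control = genome, per accession
  expect_equal(bt$raw[bt$region == "sweep"] +
                 bt$raw[bt$region == "control"],
               bt$raw[bt$region == "genome"], tolerance = 1e-12)
})

test_that("flipping a site's polarity changes burden by the allele complement", {
  set.seed(93)
  dos <- random_dosages(runif(10, 0.2, 0.8), 4, F = 1)
  g <- toy_geno(dos)
  pol <- data.frame(p_major_ancestral = 0.9, ancestral = "A",
                    derived = "G", usable = TRUE,
                    stringsAsFactors = FALSE)[rep(1, 10), ]
  cds <- data.frame(start = 1L, end = 1000L)
  b1 <- mutation_burden(g, pol, rep(TRUE, 10), NULL, cds)
  pol2 <- pol
  pol2$ancestral[3] <- "G"; pol2$derived[3] <- "A"
  b2 <- mutation_burden(g, pol2, rep(TRUE, 10), NULL, cds)
  expect_equal(b2$raw - b1$raw, 2 - 2 * dos[3, ], ignore_attr = TRUE)
})

test_that("group comparison percent difference and Welch t match closed forms", {
  mk <- function(vals, grp) data.frame(sample = paste0(grp, seq_along(vals)),
                                       group = grp, region = "genome",
                                       raw = vals, cds_length = 1e5,
                                       per_100kb = vals, n_missing = 0L,
                                       stringsAsFactors = FALSE)
  bt <- rbind(mk(c(10, 12, 11), "a"), mk(c(8, 9, 10), "b"))
  cmp <- compare_burden(bt, reference_group = "a")
  expect_equal(cmp$pairwise$percent_difference, 100 * (1 - 9 / 11),
               tolerance = 1e-12)
  s1 <- stats::var(c(8, 9, 10)); s2 <- stats::var(c(10, 12, 11))
  t_hand <- (9 - 11) / sqrt(s1 / 3 + s2 / 3)
  expect_equal(cmp$pairwise$t_statistic, t_hand, tolerance = 1e-12)

  # identical groups: zero percent difference, p near 1
  bt0 <- rbind(mk(c(10, 12, 11), "a"), mk(c(10, 12, 11), "b"))
  cmp0 <- compare_burden(bt0, reference_group = "a")
  expect_equal(cmp0$pairwise$percent_difference, 0)
  expect_equal(cmp0$pairwise$p_value, 1, tolerance = 1e-9)

  # three groups adds a Tukey table
  bt3 <- rbind(bt, mk(c(7, 7.5, 8), "c"))
  cmp3 <- compare_burden(bt3, reference_group = "a")
  expect_equal(nrow(cmp3$tukey), 3)
})
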