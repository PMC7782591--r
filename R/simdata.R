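#' Configuration for the synthetic wild/domesticated cohort simulator
#'
#' Captures the study conditions the simulator emulates: a predominantly
#' selfing species (inbreeding coefficient near 1), a domestication
#' bottleneck that removes roughly half of the wild diversity, planted
#' selective-sweep regions with elevated allele-frequency differentiation,
#' a planted reduction of derived-deleterious burden in the domesticated
#' groups, and two outgroups that mismatch the true ancestral allele at
#' lineage-specific rates.
#'
#' @param n_wild,n_landrace,n_improved sample counts per group.
#' @param n_sites total segregating sites simulated.
#' @param n_deleterious number of sites flagged deleterious; these are
#'   placed inside CDS and annotated nonsynonymous (default 3% of sites,
#'   the approximate share of deleterious SNPs among all segregating SNPs
#'   in large crop resequencing panels).
#' @param chrom_length chromosome length in bp.
#' @param cds_fraction fraction of the chromosome annotated as CDS
#'   (soybean-like default 0.115).
#' @param selfing_F target inbreeding coefficient in `[0,1]` used for the
#'   genotype draw (hom-derived with probability `p^2 + F p (1-p)`).
#' @param drift_omega variance scale of the bottleneck drift kernel: the
#'   domesticated frequency is `TruncNormal(p1, drift_omega * p1 (1-p1))`
#'   with the out-of-range mass absorbed at 0/1 -- the same kernel the
#'   sweep scan assumes under neutrality. The default (0.1) keeps the
#'   neutral background in the regime where planted sweeps show elevated
#'   differentiation; see [bottleneck_omega()] for the much larger value
#'   that reproduces the full ~48% domestication diversity loss (the
#'   one-step kernel cannot produce both conditions at once).
#' @param burden_ratio_landrace,burden_ratio_improved planted ratios of the
#'   expected per-accession derived-deleterious burden relative to wild
#'   (defaults: 0.929 and 0.929 * 0.986, i.e. a 7.1% reduction plus a
#'   further 1.4%).
#' @param sweep_regions data.frame with columns `start`, `end` (bp, 1-based
#'   inclusive) and `escape_scale` (Morgans); non-overlapping and inside
#'   the chromosome.
#' @param outgroup_mismatch length-2 numeric: probabilities that each
#'   outgroup allele differs from the true ancestral allele.
#' @param missing_rate per-call missing-genotype probability.
#' @param cm_per_mb constant genetic-map rate (centimorgans per megabase).
#' @param mu_per_year mutation rate per nucleotide per year.
#' @param generation_years generation time in years.
#' @param seed integer master seed; every random stream derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_wild = 100, n_landrace = 100, n_improved = 25,
                       n_sites = 20000, n_deleterious = 600,
                       chrom_length = 10e6, cds_fraction = 0.115,
                       selfing_F = 0.98, drift_omega = 0.1,
                       burden_ratio_landrace = 0.929,
                       burden_ratio_improved = 0.929 * 0.986,
                       sweep_regions = default_sweep_regions(),
                       outgroup_mismatch = c(0.05, 0.10),
                       missing_rate = 0.01, cm_per_mb = 2.5,
                       mu_per_year = 1.5e-8, generation_years = 1,
                       seed = 1L) {
  cfg <- list(n_wild = n_wild, n_landrace = n_landrace,
              n_improved = n_improved, n_sites = n_sites,
              n_deleterious = n_deleterious, chrom_length = chrom_length,
              cds_fraction = cds_fraction, selfing_F = selfing_F,
              drift_omega = drift_omega,
              burden_ratio_landrace = burden_ratio_landrace,
              burden_ratio_improved = burden_ratio_improved,
              sweep_regions = as.data.frame(sweep_regions),
              outgroup_mismatch = outgroup_mismatch,
              missing_rate = missing_rate, cm_per_mb = cm_per_mb,
              mu_per_year = mu_per_year,
              generation_years = generation_years, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Drift scale calibrated to the domestication diversity loss
#'
#' The one-step absorbed-normal drift kernel couples diversity loss and
#' allele-frequency differentiation: at the variance scale that removes
#' roughly half of the wild diversity (the published wild-to-domesticated
#' ratio 0.0012/0.0023), neutral background differentiation is near its
#' maximum and planted sweeps no longer stand out. The simulator therefore
#' defaults to a moderate scale and this constant, calibrated once by
#' simulation against the realized diversity ratio, reproduces the
#' bottleneck condition when the diversity reduction itself is the object
#' of study: `simulate_populations(sim_config(drift_omega =
#' bottleneck_omega()))` yields a domesticated/wild diversity ratio of
#' about 0.52.
#'
#' @return The calibrated variance scale (dimensionless).
#' @export
bottleneck_omega <- function() 80

#' @rdname sim_config
#' @export
default_sweep_regions <- function() {
  data.frame(start = c(1.0e6, 4.5e6, 8.0e6),
             end   = c(1.06e6, 4.56e6, 8.06e6),
             escape_scale = 0.02)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_wild >= 2, cfg$n_landrace >= 2, cfg$n_improved >= 0)
  stopifnot(cfg$n_sites >= cfg$n_deleterious, cfg$n_deleterious >= 0)
  frac <- c(cfg$cds_fraction, cfg$selfing_F, cfg$missing_rate,
            cfg$outgroup_mismatch)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0,1]")
  if (cfg$burden_ratio_landrace <= 0 || cfg$burden_ratio_landrace > 1 ||
      cfg$burden_ratio_improved <= 0 || cfg$burden_ratio_improved > 1)
    stop("burden ratios must lie in (0,1]")
  if (cfg$drift_omega < 0) stop("drift_omega must be >= 0")
  sw <- cfg$sweep_regions
  if (nrow(sw)) {
    if (any(sw$start < 1) || any(sw$end > cfg$chrom_length) ||
        any(sw$end <= sw$start))
      stop("sweep region outside chromosome")
    o <- order(sw$start)
    if (any(sw$start[o][-1] <= sw$end[o][-nrow(sw)]))
      stop("sweep regions overlap")
    if (any(sw$escape_scale <= 0)) stop("escape_scale must be > 0")
  }
  invisible(cfg)
}

# Regularly spaced single-CDS genes filling cds_fraction of the chromosome.
make_cds_annotation <- function(chrom_length, cds_fraction,
                                gene_len = 1200L) {
  total <- floor(chrom_length * cds_fraction)
  n_genes <- max(1L, floor(total / gene_len))
  pitch <- floor(chrom_length / n_genes)
  start <- (seq_len(n_genes) - 1L) * pitch + 1L
  data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
             chrom = "chr1", start = start,
             end = pmin(start + gene_len - 1L, chrom_length),
             strand = rep_len(c("+", "-"), n_genes), phase = 0L,
             stringsAsFactors = FALSE)
}

# Hitchhiking transform shared with the sweep-scan model: a linked neutral
# lineage escapes the sweeping haplotype with probability
# c = 1 - exp(-d / s); with probability (1 - c) it carries the swept
# haplotype's allele B.
hitchhike_freq <- function(p_neutral, p1, d, escape_scale) {
  cc <- 1 - exp(-d / escape_scale)
  b <- stats::rbinom(length(p1), 1L, p1)
  cc * p_neutral + (1 - cc) * b
}

# Multiplicatively rescale frequencies so they sum to `target`, keeping
# every value in [0,1]. Values clamped at 1 are frozen and the deficit is
# redistributed over the rest, so the planted expected burden ratio is
# exact even when individual frequencies saturate.
rescale_to_sum <- function(p, target) {
  if (sum(p) <= 0) return(p)
  free <- rep(TRUE, length(p))
  for (i in 1:20) {
    room <- target - sum(p[!free])
    s <- sum(p[free])
    if (s <= 0 || room <= 0) break
    p[free] <- p[free] * room / s
    over <- free & p >= 1
    if (!any(over)) break
    p[over] <- 1
    free <- free & !over
  }
  p
}

draw_drift <- function(p, omega, scale = 1) {
  if (omega <= 0) return(p)
  clamp01(stats::rnorm(length(p), p, sqrt(scale * omega * p * (1 - p))))
}

draw_dosage <- function(p, n_samples, F) {
  n <- length(p)
  hom <- p^2 + F * p * (1 - p)
  het <- 2 * p * (1 - p) * (1 - F)
  u <- matrix(stats::runif(n * n_samples), n, n_samples)
  m <- matrix(0L, n, n_samples)
  m[u < hom] <- 2L
  m[u >= hom & u < hom + het] <- 1L
  m
}

#' Simulate wild and domesticated cohorts with known ground truth
#'
#' Wild derived-allele frequencies are drawn from a neutral-SFS prior
#' (density proportional to `1/i` on derived-allele counts). Domesticated
#' frequencies pass through the absorbed truncated-normal drift kernel that
#' the sweep scan assumes under neutrality; sites inside planted sweep
#' regions are additionally transformed by the hitchhiking mixture with the
#' configured escape scale. Genotypes are drawn with the inbreeding-adjusted
#' Hardy-Weinberg probabilities. Deleterious sites are confined to CDS,
#' flagged nonsynonymous, and the domesticated deleterious frequencies are
#' rescaled multiplicatively so the expected per-accession burden ratio
#' equals the configured planted ratio. Outgroup alleles equal the ancestral
#' allele flipped (to the derived allele) independently with the configured
#' mismatch probabilities.
#'
#' @param config a [sim_config()].
#' @return A list with components `geno` (a [geno_matrix()] whose site table
#'   carries outgroup alleles, effect class and a constraint score), `cds`
#'   (the CDS annotation), `map` (genetic map: `chrom`, `bp`, `cM`) and
#'   `truth` (ancestral alleles, deleterious flags, true group frequencies,
#'   sweep intervals and expected group burden means).
#' @export
simulate_populations <- function(config) {
  cfg <- validate_sim_config(config)
  seed <- cfg$seed
  L <- as.integer(cfg$chrom_length)
  cds <- make_cds_annotation(L, cfg$cds_fraction)

  # -- site positions: deleterious sites inside CDS, the rest anywhere
  cds_bp <- unlist(mapply(seq.int, cds$start, cds$end, SIMPLIFY = FALSE))
  pos <- with_stream(seed, "positions", {
    del_pos <- sort(sample(cds_bp, cfg$n_deleterious))
    bg_pos <- sample.int(L, cfg$n_sites - cfg$n_deleterious)
    while (anyDuplicated(c(del_pos, bg_pos))) {
      bad <- bg_pos %in% del_pos | duplicated(bg_pos)
      bg_pos[bad] <- sample.int(L, sum(bad))
    }
    c(del_pos, bg_pos)
  })
  deleterious <- c(rep(TRUE, cfg$n_deleterious),
                   rep(FALSE, cfg$n_sites - cfg$n_deleterious))
  o <- order(pos)
  pos <- pos[o]; deleterious <- deleterious[o]
  n <- cfg$n_sites

  in_cds <- vapply(pos, function(p)
    any(p >= cds$start & p <= cds$end), logical(1))

  # -- wild frequencies from the 1/i neutral SFS prior
  p1 <- with_stream(seed, "sfs", {
    i <- sample.int(2 * cfg$n_wild - 1, n, replace = TRUE,
                    prob = 1 / seq_len(2 * cfg$n_wild - 1))
    i / (2 * cfg$n_wild)
  })

  # -- bottleneck drift, then hitchhiking inside planted sweeps
  p2 <- with_stream(seed, "drift", draw_drift(p1, cfg$drift_omega))
  sw <- cfg$sweep_regions
  gpos <- pos * cfg$cm_per_mb / 1e6 / 100  # Morgans, linear map
  p2s <- p2
  if (nrow(sw)) {
    p2s <- with_stream(seed, "sweep", {
      out <- p2
      for (r in seq_len(nrow(sw))) {
        idx <- which(pos >= sw$start[r] & pos <= sw$end[r])
        if (!length(idx)) next
        center <- (sw$start[r] + sw$end[r]) / 2
        d <- abs(gpos[idx] - center * cfg$cm_per_mb / 1e6 / 100)
        out[idx] <- hitchhike_freq(p2[idx], p1[idx], d, sw$escape_scale[r])
      }
      out
    })
  }
  p3 <- with_stream(seed, "drift_improved",
                    draw_drift(p2s, cfg$drift_omega, scale = 0.05))

  # -- plant the burden ratios: multiplicative rescale of domesticated
  #    deleterious frequencies so the expected per-accession burden ratio
  #    (sum of 2p over deleterious sites) is exactly the configured ratio
  del <- which(deleterious)
  if (length(del) && sum(p2s[del]) > 0) {
    p2s[del] <- rescale_to_sum(p2s[del],
                               cfg$burden_ratio_landrace * sum(p1[del]))
    p3[del] <- rescale_to_sum(p3[del],
                              cfg$burden_ratio_improved * sum(p1[del]))
  }

  # -- alleles: ancestral base, derived base, reference orientation
  bases <- c("A", "C", "G", "T")
  anc <- with_stream(seed, "alleles_anc", sample(bases, n, replace = TRUE))
  der <- with_stream(seed, "alleles_der", {
    shift <- sample.int(3L, n, replace = TRUE)
    bases[(match(anc, bases) - 1L + shift) %% 4L + 1L]
  })
  # reference genome behaves like a domesticated line: carries the derived
  # allele with probability equal to the landrace frequency
  ref_is_derived <- with_stream(seed, "refallele",
                                stats::runif(n) < p2s)
  ref <- ifelse(ref_is_derived, der, anc)
  alt <- ifelse(ref_is_derived, anc, der)

  # outgroup alleles: the ancestral base, flipped with probability e_k to
  # one of the three other bases chosen uniformly (divergence mutations do
  # not know about the ingroup's derived allele; flips to a third base are
  # later treated as missing by the polarizer)
  e <- cfg$outgroup_mismatch
  flip_base <- function(x) {
    shift <- sample.int(3L, length(x), replace = TRUE)
    bases[(match(x, bases) - 1L + shift) %% 4L + 1L]
  }
  out1 <- with_stream(seed, "outgroup1",
                      ifelse(stats::runif(n) < e[1], flip_base(anc), anc))
  out2 <- with_stream(seed, "outgroup2",
                      ifelse(stats::runif(n) < e[2], flip_base(anc), anc))

  # -- effect classes and a constraint-score track consistent with truth
  effect <- rep("noncoding", n)
  effect[in_cds] <- with_stream(seed, "effect",
    sample(c("nonsynonymous", "synonymous"), sum(in_cds), replace = TRUE,
           prob = c(0.62, 0.38)))
  effect[deleterious] <- "nonsynonymous"
  rs <- with_stream(seed, "scores", {
    x <- stats::runif(n, -2, 2)
    x[deleterious] <- stats::runif(sum(deleterious), 2.05, 6)
    x
  })

  # -- genotypes (derived dosage), then reorient to alt dosage
  groups <- c(rep("wild", cfg$n_wild), rep("landrace", cfg$n_landrace),
              rep("improved", cfg$n_improved))
  freqs <- cbind(wild = p1, landrace = p2s, improved = p3)
  dmat <- with_stream(seed, "genotypes", {
    cbind(draw_dosage(p1, cfg$n_wild, cfg$selfing_F),
          draw_dosage(p2s, cfg$n_landrace, cfg$selfing_F),
          draw_dosage(p3, cfg$n_improved, cfg$selfing_F))
  })
  amat <- dmat
  amat[ref_is_derived, ] <- 2L - dmat[ref_is_derived, , drop = FALSE]
  if (cfg$missing_rate > 0) {
    amat <- with_stream(seed, "missing", {
      amat[matrix(stats::runif(length(amat)) < cfg$missing_rate,
                  nrow(amat))] <- NA_integer_
      amat
    })
  }

  sites <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                      out1 = out1, out2 = out2, effect = effect,
                      rs_score = rs, stringsAsFactors = FALSE)
  samples <- data.frame(sample = sprintf("%s%03d", groups,
                                         unlist(lapply(table(factor(groups,
                                           levels = unique(groups))),
                                           seq_len))),
                        group = groups, stringsAsFactors = FALSE)
  g <- geno_matrix(amat, sites, samples)

  truth <- list(ancestral = anc, derived = der,
                ref_is_derived = ref_is_derived,
                deleterious = deleterious, freqs = freqs,
                sweep_regions = sw,
                expected_burden = c(
                  wild = 2 * sum(p1[del]),
                  landrace = 2 * sum(p2s[del]),
                  improved = 2 * sum(p3[del])))
  map <- data.frame(chrom = "chr1",
                    bp = seq(1L, L, length.out = 51),
                    cM = seq(1L, L, length.out = 51) * cfg$cm_per_mb / 1e6)
  list(geno = g, cds = cds, map = map, truth = truth, config = cfg)
}

#' Write simulator outputs to disk
#'
#' Emits VCF 4.2 genotypes, 0-based half-open BED files for the CDS
#' annotation and true sweep intervals, a sample-group TSV, the genetic map
#' and a truth JSON.
#'
#' @param sim result of [simulate_populations()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_sim_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(vcf = file.path(dir, "genotypes.vcf"),
         cds = file.path(dir, "cds.bed"),
         sweeps = file.path(dir, "sweeps_truth.bed"),
         groups = file.path(dir, "groups.tsv"),
         map = file.path(dir, "map.tsv"),
         truth = file.path(dir, "truth.json"))
  write_vcf_geno(sim$geno, f["vcf"],
                 contig_lengths = c(chr1 = sim$config$chrom_length))
  write_bed(data.frame(chrom = sim$cds$chrom, start = sim$cds$start - 1L,
                       end = sim$cds$end, name = sim$cds$gene), f["cds"])
  sw <- sim$truth$sweep_regions
  write_bed(data.frame(chrom = "chr1", start = as.integer(sw$start) - 1L,
                       end = as.integer(sw$end),
                       name = sprintf("sweep%d", seq_len(nrow(sw)))),
            f["sweeps"])
  write_groups_tsv(sim$geno$samples, f["groups"])
  utils::write.table(sim$map, f["map"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(deleterious_pos = sim$geno$sites$pos[sim$truth$deleterious],
         expected_burden = as.list(sim$truth$expected_burden),
         seed = sim$config$seed),
    f["truth"], auto_unbox = TRUE, digits = NA)
  f
}

write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate multi-species alignment columns on a neutral tree
#'
#' Columns evolve under Jukes-Cantor along the supplied tree; constrained
#' columns use rate multiplier `constrained_rate` (near 0), unconstrained
#' columns rate 1. Used to calibrate and test the constraint scorer.
#'
#' @param tree an \pkg{ape} `phylo` tree with branch lengths in
#'   substitutions/site.
#' @param n_columns number of columns to simulate.
#' @param constrained_fraction fraction of columns drawn as constrained.
#' @param seed integer seed.
#' @param constrained_rate rate multiplier for constrained columns.
#' @return List with `columns` (character matrix, columns x species) and
#'   `constrained` (logical truth labels).
#' @export
simulate_msa <- function(tree, n_columns, constrained_fraction, seed,
                         constrained_rate = 0.02) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 3,
            all(tree$edge.length >= 0))
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  with_stream(seed, "msa", {
    constrained <- stats::runif(n_columns) < constrained_fraction
    rate <- ifelse(constrained, constrained_rate, 1)
    ed <- ape::reorder.phylo(tree, "postorder")$edge
    elen <- ape::reorder.phylo(tree, "postorder")$edge.length
    root <- setdiff(ed[, 1], ed[, 2])[1]
    state <- matrix(0L, n_columns, n_node)
    state[, root] <- sample.int(4L, n_columns, replace = TRUE)
    # preorder: walk edges parent-before-child
    for (i in rev(seq_len(nrow(ed)))) {
      p_same <- 0.25 + 0.75 * exp(-4 / 3 * elen[i] * rate)
      same <- stats::runif(n_columns) < p_same
      shift <- sample.int(3L, n_columns, replace = TRUE)
      child <- ifelse(same, state[, ed[i, 1]],
                      (state[, ed[i, 1]] - 1L + shift) %% 4L + 1L)
      state[, ed[i, 2]] <- child
    }
    cols <- matrix(bases[state[, seq_len(n_tip)]], n_columns, n_tip)
    colnames(cols) <- tree$tip.label
    list(columns = cols, constrained = constrained)
  })
}

# IUPAC helpers ---------------------------------------------------------

iupac_pair_code <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "")
    code <- names(map)[vapply(map, function(s)
      paste(sort(strsplit(s, "")[[1]]), collapse = "") == key, logical(1))]
    if (!length(code)) "N" else code[1]
  }
})

resolve_iupac <- function(x) {
  map <- Biostrings::IUPAC_CODE_MAP
  amb <- !(x %in% c("A", "C", "G", "T", "N"))
  if (any(amb)) {
    x[amb] <- vapply(x[amb], function(code) {
      opts <- strsplit(map[[code]] %||% "N", "")[[1]]
      opts[sample.int(length(opts), 1L)]
    }, character(1))
  }
  x
}

#' Merge two haploid sequences into a pseudodiploid
#'
#' Within each haploid, IUPAC ambiguity codes are first resolved to one
#' concrete base chosen uniformly among the code's bases (seeded). Positions
#' where the haploids then agree emit that base; disagreeing positions emit
#' the IUPAC code for the pair; `N` in either haploid yields `N`. This is
#' the standard construction for running diploid coalescent inference on
#' pairs of inbred genomes.
#'
#' @param hap1,hap2 equal-length character strings (or character vectors of
#'   single bases) over A,C,G,T,N and IUPAC codes.
#' @param seed integer seed for ambiguity resolution.
#' @return The merged sequence, in the same form as the input (string in,
#'   string out).
#' @export
build_pseudodiploid <- function(hap1, hap2, seed = 1L) {
  as_vec <- function(x) if (length(x) == 1L && nchar(x[1]) > 1L)
    strsplit(x, "")[[1]] else x
  string_in <- length(hap1) == 1L && nchar(hap1[1]) > 1L
  h1 <- toupper(as_vec(hap1)); h2 <- toupper(as_vec(hap2))
  if (length(h1) != length(h2)) stop("haploid sequences differ in length")
  with_stream(seed, "pseudodiploid", {
    h1 <- resolve_iupac(h1)
    h2 <- resolve_iupac(h2)
    out <- character(length(h1))
    nn <- h1 == "N" | h2 == "N"
    same <- !nn & h1 == h2
    out[same] <- h1[same]
    out[nn] <- "N"
    diff <- which(!same & !nn)
    if (length(diff))
      out[diff] <- unlist(Map(iupac_pair_code, h1[diff], h2[diff]),
                          use.names = FALSE)
    if (string_in) paste(out, collapse = "") else out
  })
}

#' Enumerate unordered accession pairs for pseudodiploid construction
#'
#' @param accessions character vector of distinct accession names.
#' @return data.frame with columns `a` and `b`, all `choose(n, 2)` unordered
#'   pairs in lexicographic order.
#' @export
enumerate_pseudodiploid_pairs <- function(accessions) {
  if (length(accessions) < 2) stop("need at least 2 accessions")
  if (anyDuplicated(accessions)) stop("duplicate accession names")
  acc <- sort(accessions)
  cmb <- utils::combn(acc, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}
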