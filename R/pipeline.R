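# End-to-end orchestration: simulate (optional) -> qc -> window stats ->
# polarize -> constraint scores -> sweep scan -> burden, with a manifest
# of every intermediate so any stage can be re-run in isolation.

#' Pipeline configuration
#'
#' @param simulate a [sim_config()] to generate inputs, or `NULL` to read
#'   them from files.
#' @param vcf,groups,map,cds paths to input files when not simulating
#'   (VCF, sample-group TSV, genetic-map TSV, CDS BED).
#' @param alignment optional list with `columns` (character matrix),
#'   `tree` (`phylo`) and `reference` for constraint scoring; when absent
#'   the per-site score track from the VCF/simulation is used instead.
#' @param qc named list of [filter_samples()] / [site_filter_config()]
#'   overrides.
#' @param stats named list: `window` (bp), `run_ld` (logical; LD decay is
#'   quadratic in sites and off by default).
#' @param sweep named list of [sweep_scan_config()] overrides.
#' @param burden named list: `criterion`, `reference_bias` (logical).
#' @param seed integer seed.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, vcf = NULL, groups = NULL,
                       map = NULL, cds = NULL, alignment = NULL,
                       qc = list(), stats = list(), sweep = list(),
                       burden = list(), seed = 1L) {
  allowed <- list(qc = c("F_cutoff", "ratio_cutoff", "min_het_count",
                         "max_missing", "max_het", "min_maf"),
                  stats = c("window", "run_ld"),
                  sweep = c("window_morgans", "max_snps", "grid_bp",
                            "corr_cutoff", "omega", "genome_fraction"),
                  burden = c("criterion", "reference_bias"))
  for (blk in names(allowed)) {
    bad <- setdiff(names(get(blk)), allowed[[blk]])
    if (length(bad)) stop("unknown ", blk, " config keys: ",
                          paste(bad, collapse = ", "))
  }
  if (is.null(simulate) && is.null(vcf))
    stop("either a simulation config or a VCF path is required")
  structure(list(simulate = simulate, vcf = vcf, groups = groups,
                 map = map, cds = cds, alignment = alignment, qc = qc,
                 stats = stats, sweep = sweep, burden = burden,
                 seed = as.integer(seed)),
            class = "run_config")
}

read_bed_cds <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- df$start + 1L  # BED is 0-based half-open
  df$gene <- if (ncol(df) >= 4) df[[4]] else sprintf("g%d", seq_len(nrow(df)))
  df$strand <- if (ncol(df) >= 6) df[[6]] else "+"
  df$phase <- 0L
  df
}

log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  msg)
  message(line)
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), sample/site QC, windowed diversity
#' statistics, polarization, constraint scoring (from an alignment when
#' given, otherwise the supplied per-site score track), the sweep scan
#' with region calling, and the burden comparison. Every tabular
#' intermediate is written as TSV under `out_dir` and recorded, with an
#' md5, in the returned manifest. Stage outputs are pure functions of
#' (inputs, config, seed); a rerun with the same seed reproduces every
#' hash.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return The manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out_dir, "run.log")
  if (file.exists(log)) unlink(log)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("domload")),
                   seed = config$seed, stages = list(), files = list())
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$files[[name]] <<- list(path = path,
                                    md5 = unname(tools::md5sum(path)),
                                    rows = nrow(df))
    path
  }

  # ---- inputs
  if (!is.null(config$simulate)) {
    log_stage(log, "simulate", "generating synthetic cohorts")
    sim <- simulate_populations(config$simulate)
    write_sim_outputs(sim, file.path(out_dir, "sim"))
    g <- sim$geno; cds <- sim$cds; map <- sim$map
    genome_length <- config$simulate$chrom_length
    manifest$stages$simulate <- list(n_sites = nrow(g$sites),
                                     n_samples = ncol(g$geno))
  } else {
    log_stage(log, "input", paste("reading", config$vcf))
    g <- read_vcf_geno(config$vcf, config$groups)
    cds <- read_bed_cds(config$cds)
    map <- utils::read.table(config$map, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    genome_length <- max(g$sites$pos)
    sim <- NULL
  }

  # ---- qc
  qc_args <- config$qc
  fs <- filter_samples(g,
                       F_cutoff = qc_args$F_cutoff %||% 0.8,
                       ratio_cutoff = qc_args$ratio_cutoff %||% 2 / 3,
                       min_het_count = qc_args$min_het_count)
  sfc <- site_filter_config(max_missing = qc_args$max_missing %||% 0.20,
                            max_het = qc_args$max_het %||% 0.10,
                            min_maf = qc_args$min_maf %||% 0.01)
  fsite <- withCallingHandlers(
    filter_sites(fs$geno, sfc),
    warning = function(w) {
      log_stage(log, "qc", paste("WARN:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  g2 <- fsite$geno
  emit("qc_samples", fs$report)
  manifest$stages$qc <- list(samples_removed = sum(fs$report$removed),
                             site_attrition = as.list(fsite$attrition),
                             sites_retained = nrow(g2$sites))
  log_stage(log, "qc", sprintf("%d samples, %d sites retained",
                               ncol(g2$geno), nrow(g2$sites)))

  # ---- windowed statistics per population
  window <- config$stats$window %||% 1e5
  wild <- g2$samples$group == "wild"
  dom <- g2$samples$group %in% c("landrace", "improved")
  ws_wild <- window_stats(subset_geno(g2, samples = wild), window,
                          genome_length)
  ws_dom <- window_stats(subset_geno(g2, samples = dom), window,
                         genome_length)
  ws_wild$population <- "wild"; ws_dom$population <- "domesticated"
  emit("window_stats", rbind(ws_wild, ws_dom))
  pi_wild <- sum(ws_wild$pi * (ws_wild$end - ws_wild$start)) / genome_length
  pi_dom <- sum(ws_dom$pi * (ws_dom$end - ws_dom$start)) / genome_length
  manifest$stages$popstats <- list(
    pi_wild = pi_wild, pi_dom = pi_dom,
    diversity_reduction_percent = diversity_reduction(pi_dom, pi_wild))
  if (isTRUE(config$stats$run_ld)) {
    ld <- ld_decay(subset_geno(g2, samples = wild))
    manifest$stages$popstats$half_decay_bp <- ld$half_decay_distance
  }
  log_stage(log, "popstats",
            sprintf("pi wild %.5f, dom %.5f", pi_wild, pi_dom))

  # ---- polarization
  psites <- polarity_input(g2)
  model <- fit_polarizer(psites)
  pol <- polarize_sites(model, psites)
  emit("polarity", cbind(g2$sites[, c("chrom", "pos")], pol))
  manifest$stages$polarize <- list(e1 = model$e[1], e2 = model$e[2],
                                   prior = model$prior_major_ancestral,
                                   n_usable = model$n_usable)
  log_stage(log, "polarize",
            sprintf("e = (%.3f, %.3f)", model$e[1], model$e[2]))

  # ---- constraint scores
  if (!is.null(config$alignment)) {
    al <- config$alignment
    gs <- gerp_score(al$columns, al$tree, al$reference)
    emit("constraint_scores", gs)
    rs <- g2$sites$rs_score  # site track still drives the SNP sets
    manifest$stages$gerp <- list(n_columns = nrow(gs),
                                 mean_RS = mean(gs$RS))
  } else if (!is.null(g2$sites$rs_score)) {
    rs <- g2$sites$rs_score
    log_stage(log, "gerp",
              "WARN: no alignment given; using supplied score track")
    manifest$stages$gerp <- list(skipped = TRUE)
  } else stop("gerp: neither an alignment nor a score track is available")

  # ---- sweep scan
  sw_args <- config$sweep
  scfg <- sweep_scan_config(
    window_morgans = sw_args$window_morgans %||% 0.0005,
    max_snps = sw_args$max_snps %||% 200,
    grid_bp = sw_args$grid_bp %||% 100,
    corr_cutoff = sw_args$corr_cutoff %||% 0.7,
    omega = sw_args$omega,
    genome_fraction = sw_args$genome_fraction %||% 0.05)
  sc <- sweep_scan(g2, map, scfg)
  calls <- call_regions(sc, genome_length, scfg$genome_fraction,
                        genes = cds[, c("gene", "chrom", "start", "end")])
  emit("sweep_scores", sc)
  if (nrow(calls$regions)) emit("sweep_regions", calls$regions)
  manifest$stages$sweep <- list(threshold = calls$threshold,
                                n_regions = nrow(calls$regions))
  log_stage(log, "sweep", sprintf("threshold %.2f, %d regions",
                                  calls$threshold, nrow(calls$regions)))

  # ---- burden
  b_args <- config$burden
  delset <- build_deleterious_set(g2$sites$effect, rs,
                                  criterion = b_args$criterion %||%
                                    "GERP2_nonsyn")
  weights <- NULL
  if (isTRUE(b_args$reference_bias)) {
    p <- allele_freq(g2)
    der_freq <- ifelse(pol$derived == g2$sites$alt, p, 1 - p)
    ref_der <- pol$derived == g2$sites$ref
    rbw <- reference_bias_correction(der_freq, ref_der, delset)
    weights <- rbw$weight
  }
  regions <- if (nrow(calls$regions))
    data.frame(start = calls$regions$start + 1, end = calls$regions$end)
  else NULL
  bt <- mutation_burden(g2, pol, delset, weights, cds, regions)
  emit("burden", bt)
  cmp <- compare_burden(bt)
  manifest$stages$burden <- list(
    n_deleterious = sum(delset),
    comparisons = stats::setNames(
      as.list(cmp$pairwise$percent_difference),
      paste(cmp$pairwise$focal, "vs", cmp$pairwise$reference)))
  log_stage(log, "burden", paste(
    sprintf("%s vs %s: %.2f%%", cmp$pairwise$focal,
            cmp$pairwise$reference, cmp$pairwise$percent_difference),
    collapse = "; "))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# major/minor + outgroup table for the polarizer, from a genotype matrix
# whose site table carries outgroup alleles
polarity_input <- function(g) {
  p <- allele_freq(g)
  alt_major <- !is.na(p) & p > 0.5
  data.frame(major = ifelse(alt_major, g$sites$alt, g$sites$ref),
             minor = ifelse(alt_major, g$sites$ref, g$sites$alt),
             out1 = g$sites$out1, out2 = g$sites$out2,
             maf = pmin(p, 1 - p),
             stringsAsFactors = FALSE)
}
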