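# Windowed diversity statistics and LD decay.
#
# Windows are 0-based half-open internally; VCF positions are 1-based and
# converted on windowing. Per-site pairwise diversity uses the unbiased
# genotype-based estimator 2 j (n - j) / (n (n - 1)) with j the alternate
# allele count and n the number of non-missing alleles.

site_pairwise_diversity <- function(geno) {
  j <- rowSums(geno, na.rm = TRUE)
  n <- 2 * rowSums(!is.na(geno))
  ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
}

make_windows <- function(pos, window, chrom_length = NULL) {
  top <- if (is.null(chrom_length)) max(pos) else chrom_length
  n_win <- max(1L, ceiling(top / window))
  data.frame(start = (seq_len(n_win) - 1) * window,
             end = pmin(seq_len(n_win) * window, top))
}

#' Windowed nucleotide diversity
#'
#' Per-window pi, per bp: the sum of per-site pairwise diversities divided
#' by the window length. Sites with fewer than two non-missing alleles are
#' skipped.
#'
#' @param g a [geno_matrix()] (one chromosome at a time is assumed; sites
#'   on other chromosomes are windowed independently).
#' @param window window size in bp (default 100 kb).
#' @param chrom_length optional chromosome length; defaults to the largest
#'   position observed.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `n_sites` and `pi`.
#' @export
nucleotide_diversity <- function(g, window = 1e5, chrom_length = NULL) {
  pi_s <- site_pairwise_diversity(g$geno)
  out <- lapply(split(seq_len(nrow(g$sites)), g$sites$chrom), function(idx) {
    w <- make_windows(g$sites$pos[idx], window, chrom_length)
    wi <- window_index(g$sites$pos[idx], window) + 1L
    ok <- !is.na(pi_s[idx])
    agg <- tapply(pi_s[idx][ok], factor(wi[ok], levels = seq_len(nrow(w))),
                  sum)
    cnt <- tapply(rep(1L, sum(ok)), factor(wi[ok],
                                           levels = seq_len(nrow(w))), sum)
    data.frame(chrom = g$sites$chrom[idx][1], start = w$start, end = w$end,
               n_sites = ifelse(is.na(cnt), 0L, cnt),
               pi = ifelse(is.na(agg), 0, agg) / (w$end - w$start))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Standard normalized difference between the mean-pairwise-difference and
#' segregating-sites estimators of the population mutation rate. The
#' chromosome sample size `n` for the constants is the maximum non-missing
#' allele count over sites in the window (per-site variation in n is
#' ignored, matching common windowed implementations). Windows without
#' segregating sites return `NA`.
#'
#' @inheritParams nucleotide_diversity
#' @return data.frame with `chrom`, `start`, `end`, `n_sites` (segregating)
#'   and `tajimas_D`.
#' @export
tajimas_d <- function(g, window = 1e5, chrom_length = NULL) {
  j <- rowSums(g$geno, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(g$geno))
  seg <- an >= 2 & j > 0 & j < an
  pi_s <- site_pairwise_diversity(g$geno)
  out <- lapply(split(seq_len(nrow(g$sites)), g$sites$chrom), function(idx) {
    w <- make_windows(g$sites$pos[idx], window, chrom_length)
    wi <- window_index(g$sites$pos[idx], window) + 1L
    d <- vapply(seq_len(nrow(w)), function(k) {
      ii <- idx[wi == k & seg[idx]]
      S <- length(ii)
      if (S == 0) return(c(0, NA_real_))
      n <- max(an[ii])
      if (n < 2) return(c(S, NA_real_))
      cst <- tajima_constants(n)
      pihat <- sum(pi_s[ii])
      denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
      c(S, (pihat - S / cst$a1) / denom)
    }, numeric(2))
    data.frame(chrom = g$sites$chrom[idx][1], start = w$start, end = w$end,
               n_sites = as.integer(d[1, ]), tajimas_D = d[2, ])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-window SNP/indel densities
#'
#' Counts sorted sites per half-open window; the last partial window is
#' included.
#'
#' @param pos integer vector of 1-based positions (single chromosome).
#' @param window window size in bp.
#' @param chrom_length optional chromosome length.
#' @return data.frame with `start`, `end` and `count`.
#' @export
window_densities <- function(pos, window = 1e5, chrom_length = NULL) {
  if (!length(pos)) {
    if (is.null(chrom_length)) {
      return(data.frame(start = numeric(0), end = numeric(0),
                        count = integer(0)))
    }
    w <- make_windows(1, window, chrom_length)
    return(data.frame(start = w$start, end = w$end,
                      count = rep(0L, nrow(w))))
  }
  w <- make_windows(pos, window, chrom_length)
  wi <- window_index(pos, window) + 1L
  cnt <- tabulate(wi, nbins = nrow(w))
  data.frame(start = w$start, end = w$end, count = cnt)
}

#' Combined per-window summary table
#'
#' @inheritParams nucleotide_diversity
#' @return data.frame with pi, Tajima's D and SNP density per window.
#' @export
window_stats <- function(g, window = 1e5, chrom_length = NULL) {
  pi <- nucleotide_diversity(g, window, chrom_length)
  d <- tajimas_d(g, window, chrom_length)
  pi$tajimas_D <- d$tajimas_D
  pi$snp_density <- pi$n_sites
  pi
}

ld_bin_breaks <- function(max_dist, fine_width = 100, coarse_width = 1000,
                          fine_limit = 5000) {
  c(seq(0, min(fine_limit, max_dist), by = fine_width),
    if (max_dist > fine_limit)
      seq(fine_limit + coarse_width, max_dist, by = coarse_width))
}

#' Half-decay distance of an LD curve
#'
#' Smallest distance at which the binned curve drops to half its maximum,
#' with linear interpolation between bin midpoints.
#'
#' @param midpoints bin midpoints (bp), increasing.
#' @param r2 mean r-squared per bin.
#' @return Half-decay distance in bp, or `NA` if the curve never falls to
#'   half its maximum.
#' @export
half_decay_distance <- function(midpoints, r2) {
  ok <- !is.na(r2)
  midpoints <- midpoints[ok]; r2 <- r2[ok]
  if (!length(r2)) return(NA_real_)
  target <- max(r2) / 2
  below <- which(r2 <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(midpoints[1])
  x0 <- midpoints[i - 1]; y0 <- r2[i - 1]
  x1 <- midpoints[i]; y1 <- r2[i]
  if (y0 == y1) return(x1)
  x0 + (y0 - target) / (y0 - y1) * (x1 - x0)
}

#' Linkage-disequilibrium decay curve
#'
#' Pairwise genotype (dosage) correlation r-squared for site pairs within
#' `max_dist`, averaged in distance bins (100-bp bins below 5 kb, 1-kb bins
#' above). Genotype-based r-squared is appropriate for a highly inbred
#' cohort where genotypes are effectively haploid.
#'
#' @param g a [geno_matrix()].
#' @param max_dist maximum pair distance in bp (default 1 Mb).
#' @param min_maf minimum minor allele frequency for a site to qualify.
#' @param max_missing maximum missing rate for a site to qualify.
#' @return List of class `ld_curve`: `bins` (midpoint, mean r2, n pairs),
#'   `max_r2` and `half_decay_distance`.
#' @export
ld_decay <- function(g, max_dist = 1e6, min_maf = 0.05,
                     max_missing = 0.1) {
  p <- allele_freq(g)
  ok <- !is.na(p) & pmin(p, 1 - p) >= min_maf &
    rowMeans(is.na(g$geno)) <= max_missing
  breaks <- ld_bin_breaks(max_dist)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  sums <- numeric(length(mids)); cnts <- integer(length(mids))
  for (chrom in unique(g$sites$chrom)) {
    idx <- which(ok & g$sites$chrom == chrom)
    if (length(idx) < 2) next
    pos <- g$sites$pos[idx]
    o <- order(pos); idx <- idx[o]; pos <- pos[o]
    m <- g$geno[idx, , drop = FALSE]
    for (a in seq_len(length(idx) - 1)) {
      b <- which(pos > pos[a] & pos - pos[a] <= max_dist)
      b <- b[b > a]
      if (!length(b)) next
      r <- suppressWarnings(
        stats::cor(m[a, ], t(m[b, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      bin <- findInterval(pos[b] - pos[a], breaks, left.open = TRUE)
      keep <- !is.na(r2) & bin >= 1 & bin <= length(mids)
      if (any(keep)) {
        add <- tapply(r2[keep], bin[keep], sum)
        cadd <- tapply(rep(1L, sum(keep)), bin[keep], length)
        ib <- as.integer(names(add))
        sums[ib] <- sums[ib] + add
        cnts[ib] <- cnts[ib] + cadd
      }
    }
  }
  mean_r2 <- ifelse(cnts > 0, sums / cnts, NA_real_)
  bins <- data.frame(midpoint = mids, mean_r2 = mean_r2, n_pairs = cnts)
  used <- bins[!is.na(bins$mean_r2), ]
  structure(list(bins = bins,
                 max_r2 = if (nrow(used)) max(used$mean_r2) else NA_real_,
                 half_decay_distance =
                   half_decay_distance(used$midpoint, used$mean_r2)),
            class = "ld_curve")
}

#' @export
print.ld_curve <- function(x, ...) {
  cat(sprintf("ld_curve: %d non-empty bins, max r2 = %.3f, half-decay = %s bp\n",
              sum(!is.na(x$bins$mean_r2)), x$max_r2,
              format(x$half_decay_distance)))
  invisible(x)
}

#' Plot an LD decay curve
#'
#' @param x an `ld_curve`.
#' @param ... passed to [plot()].
#' @export
plot.ld_curve <- function(x, ...) {
  b <- x$bins[!is.na(x$bins$mean_r2), ]
  plot(b$midpoint / 1000, b$mean_r2, type = "l", xlab = "distance (kb)",
       ylab = expression(mean ~ r^2), ...)
  if (!is.na(x$half_decay_distance))
    graphics::abline(v = x$half_decay_distance / 1000, lty = 2)
  invisible(x)
}

#' Percent diversity reduction between two cohorts
#'
#' `100 * (1 - pi_focal / pi_reference)`; the domestication-bottleneck
#' summary when the focal cohort is domesticated and the reference wild.
#'
#' @param pi_focal,pi_reference per-bp diversity estimates.
#' @return Percent reduction.
#' @export
diversity_reduction <- function(pi_focal, pi_reference) {
  100 * (1 - pi_focal / pi_reference)
}
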