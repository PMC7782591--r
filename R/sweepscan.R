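# Cross-population composite-likelihood sweep scan.
#
# Neutral model: the object-population (domesticated) allele frequency is a
# Brownian perturbation of the reference-population (wild) frequency,
# latent p2 ~ Normal(p1, omega * p1 * (1 - p1)) truncated to (0,1) with the
# out-of-range mass absorbed at the 0/1 boundaries. Sweep model: a linked
# neutral lineage escapes the sweeping haplotype with probability
# c = 1 - exp(-d / s), d the genetic distance to the putatively selected
# grid point and s an effective selection scale (Morgans); with probability
# 1 - c it carries the swept haplotype's allele B (P(B = 1) = p1), giving
# post-sweep latent frequency q = c * p + (1 - c) * B. Observed derived
# counts are binomial in the latent frequency; the latent variable is
# integrated by 64-point Gauss-Legendre quadrature plus the boundary
# masses.

#' Sweep-scan configuration
#'
#' @param window_morgans genetic window half-width in Morgans (default
#'   0.0005, i.e. 0.05 cM).
#' @param max_snps maximum SNPs per window (default 200, nearest first).
#' @param grid_bp spacing of scan grid points in bp (default 100; coarser
#'   values trade resolution for speed on large regions).
#' @param corr_cutoff genotype-correlation cutoff above which SNPs in a
#'   window are clustered and down-weighted (default 0.7, on r).
#' @param s_grid selection-scale grid in Morgans (default 15 points,
#'   logarithmic from 1e-5 to 1e-1).
#' @param omega drift variance scale; `NULL` to estimate from the data.
#' @param genome_fraction fraction of the genome allowed above the sweep
#'   threshold (default 0.05).
#' @param obs_error small genotype-error probability absorbed into the
#'   emission: the binomial success probability `q` becomes
#'   `obs_error + (1 - 2 obs_error) q` in both models. Without it the
#'   sweep emission is degenerate for SNPs at vanishing genetic distance
#'   (the model then predicts exact fixation, and a single imperfectly
#'   fixed SNP drives the window's composite likelihood to minus
#'   infinity). Default 0.005.
#' @param n_quad Gauss-Legendre node count.
#' @return List of class `sweep_scan_config`.
#' @export
sweep_scan_config <- function(window_morgans = 0.0005, max_snps = 200,
                              grid_bp = 100, corr_cutoff = 0.7,
                              s_grid = exp(seq(log(1e-5), log(1e-1),
                                               length.out = 15)),
                              omega = NULL, genome_fraction = 0.05,
                              obs_error = 0.005, n_quad = 64) {
  stopifnot(window_morgans > 0, max_snps >= 1, grid_bp > 0,
            corr_cutoff > 0, all(s_grid > 0), !is.unsorted(s_grid),
            genome_fraction > 0, genome_fraction <= 1,
            obs_error >= 0, obs_error < 0.5)
  structure(list(window_morgans = window_morgans, max_snps = max_snps,
                 grid_bp = grid_bp, corr_cutoff = corr_cutoff,
                 s_grid = s_grid, omega = omega,
                 genome_fraction = genome_fraction,
                 obs_error = obs_error, n_quad = n_quad),
            class = "sweep_scan_config")
}

# central trimmed mean of a chi-square(1), for calibrating the trimmed
# moment estimator of omega
chisq1_trimmed_mean <- function(trim) {
  if (trim <= 0) return(1)
  lo <- stats::qchisq(trim, 1); hi <- stats::qchisq(1 - trim, 1)
  stats::integrate(function(x) x * stats::dchisq(x, 1), lo, hi)$value /
    (1 - 2 * trim)
}

#' Estimate the drift variance scale from genome-wide frequencies
#'
#' Moment estimator of the Brownian drift scale: the central trimmed mean
#' of `(p2 - p1)^2 / (p1 (1 - p1))` over putatively neutral SNPs, divided
#' by the matching trimmed mean of a chi-square(1) so the estimator is
#' unbiased for the kernel's variance scale (squared normal deviates are
#' chi-square; trimming alone would lose the heavy right tail).
#'
#' @param p1,p2 reference- and object-population derived (or alternate)
#'   allele frequencies.
#' @param exclude optional logical vector of SNPs to exclude (e.g.
#'   candidate sweep regions).
#' @param trim fraction trimmed from each tail (default 0.05: central
#'   90%).
#' @param p1_band only SNPs with reference frequency inside this band are
#'   used (default `c(0.2, 0.8)`): for mid-frequency SNPs the 0/1 boundary
#'   lies beyond the trimmed tail of the squared deviate, so boundary
#'   absorption cannot bias the trimmed moment.
#' @param min_snps minimum usable SNPs (default 1000).
#' @return The estimated variance scale omega.
#' @export
estimate_omega <- function(p1, p2, exclude = NULL, trim = 0.05,
                           p1_band = c(0.2, 0.8), min_snps = 1000) {
  ok <- !is.na(p1) & !is.na(p2) & p1 > 0 & p1 < 1
  if (!is.null(exclude)) ok <- ok & !exclude
  if (sum(ok) < min_snps) stop("too few polymorphic SNPs to estimate omega")
  band <- ok & p1 >= p1_band[1] & p1 <= p1_band[2]
  # fall back to all polymorphic SNPs if the band is too sparse
  if (sum(band) >= min(min_snps, 200)) ok <- band
  z2 <- (p2[ok] - p1[ok])^2 / (p1[ok] * (1 - p1[ok]))
  q <- stats::quantile(z2, c(trim, 1 - trim))
  mean(z2[z2 >= q[1] & z2 <= q[2]]) / chisq1_trimmed_mean(trim)
}

gauss_legendre_01 <- function(n) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  list(x = gl$x, w = gl$w)
}

#' Per-SNP composite log-likelihood ratio (sweep vs neutral)
#'
#' @param p1 reference-population frequency in (0,1).
#' @param k,n derived-allele count and total allele count in the object
#'   population.
#' @param d genetic distance (Morgans) from the SNP to the grid point.
#' @param omega drift variance scale.
#' @param s_scale effective selection scale in Morgans (> 0).
#' @param obs_error genotype-error probability absorbed into the emission
#'   (see [sweep_scan_config()]); 0 gives the pure model.
#' @param quad optional precomputed quadrature nodes from
#'   `pracma::gaussLegendre`.
#' @return `log L_sweep - log L_neutral` (may be negative).
#' @export
snp_loglik_ratio <- function(p1, k, n, d, omega, s_scale, obs_error = 0,
                             quad = NULL) {
  if (s_scale <= 0) stop("s_scale must be > 0")
  stopifnot(p1 > 0, p1 < 1, n > 0, d >= 0)
  if (is.null(quad)) quad <- gauss_legendre_01(64)
  adj <- function(q) obs_error + (1 - 2 * obs_error) * q
  sd <- sqrt(omega * p1 * (1 - p1))
  m0 <- stats::pnorm(0, p1, sd)
  m1 <- stats::pnorm(1, p1, sd, lower.tail = FALSE)
  dens <- stats::dnorm(quad$x, p1, sd) * quad$w
  lik_neu <- m0 * stats::dbinom(k, n, adj(0)) +
    m1 * stats::dbinom(k, n, adj(1)) +
    sum(dens * stats::dbinom(k, n, adj(quad$x)))
  cc <- 1 - exp(-d / s_scale)
  mix <- function(p) p1 * stats::dbinom(k, n, adj(cc * p + (1 - cc))) +
    (1 - p1) * stats::dbinom(k, n, adj(cc * p))
  lik_sw <- m0 * mix(0) + m1 * mix(1) + sum(dens * mix(quad$x))
  log(lik_sw) - log(lik_neu)
}

# vectorized over SNPs for a fixed escape probability per SNP
snp_loglik_ratio_vec <- function(p1, k, n, cc, omega, quad,
                                 obs_error = 0) {
  adj <- function(q) obs_error + (1 - 2 * obs_error) * q
  sd <- sqrt(omega * p1 * (1 - p1))
  m0 <- stats::pnorm(0, p1, sd)
  m1 <- stats::pnorm(1, p1, sd, lower.tail = FALSE)
  nq <- length(quad$x); m <- length(p1)
  X <- matrix(quad$x, nq, m)
  D <- stats::dnorm(X, rep(p1, each = nq), rep(sd, each = nq)) * quad$w
  K <- rep(k, each = nq); N <- rep(n, each = nq)
  lik_neu <- m0 * stats::dbinom(k, n, adj(0)) +
    m1 * stats::dbinom(k, n, adj(1)) +
    colSums(matrix(stats::dbinom(K, N, adj(as.vector(X))), nq, m) * D)
  CC <- rep(cc, each = nq)
  mixmat <- rep(p1, each = nq) *
    stats::dbinom(K, N, adj(pmin(CC * as.vector(X) + (1 - CC), 1))) +
    rep(1 - p1, each = nq) * stats::dbinom(K, N, adj(CC * as.vector(X)))
  mix0 <- p1 * stats::dbinom(k, n, adj(1 - cc)) +
    (1 - p1) * stats::dbinom(k, n, adj(0))
  mix1 <- p1 * stats::dbinom(k, n, adj(1)) +
    (1 - p1) * stats::dbinom(k, n, adj(cc))
  lik_sw <- m0 * mix0 + m1 * mix1 + colSums(matrix(mixmat, nq, m) * D)
  log(pmax(lik_sw, 1e-300)) - log(pmax(lik_neu, 1e-300))
}

# single-linkage clusters of SNPs whose |genotype correlation| exceeds the
# cutoff; returns per-SNP weights 1 / cluster size
corr_weights <- function(geno, cutoff) {
  m <- nrow(geno)
  if (m == 1) return(1)
  r <- suppressWarnings(stats::cor(t(geno), use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    if (r[a, b] > cutoff) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(m), find, integer(1))
  size <- table(root)
  1 / as.numeric(size[as.character(root)])
}

interp_genetic <- function(bp, map) {
  # linear interpolation; outside the map range extrapolate with the
  # terminal slope
  o <- order(map$bp)
  x <- map$bp[o]; y <- map$cM[o]
  g <- stats::approx(x, y, xout = bp, rule = 2)$y
  lo <- bp < x[1]; hi <- bp > x[length(x)]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    g[lo] <- y[1] + (bp[lo] - x[1]) * s
  }
  if (any(hi)) {
    nn <- length(x)
    s <- (y[nn] - y[nn - 1]) / (x[nn] - x[nn - 1])
    g[hi] <- y[nn] + (bp[hi] - x[nn]) * s
  }
  g / 100  # cM -> Morgans
}

#' Composite-likelihood sweep scan
#'
#' For each grid point along the chromosome: select up to `max_snps` SNPs
#' within the genetic window (nearest first), down-weight correlated SNPs
#' (single-linkage clusters at genotype correlation above the cutoff get
#' weight 1/cluster-size), and maximize the summed per-SNP log-likelihood
#' ratio over the selection-scale grid. The score is `2 x` the maximized
#' weighted sum, clipped at 0.
#'
#' @param g a [geno_matrix()] with groups assigning samples to the
#'   reference (wild) and object (domesticated) populations.
#' @param map genetic map data.frame (`chrom`, `bp`, `cM`), monotone in
#'   position.
#' @param config a [sweep_scan_config()].
#' @param ref_groups,obj_groups group labels of the reference and object
#'   populations.
#' @return data.frame of class `sweep_scan`: `chrom`, `pos` (grid point,
#'   bp), `gpos` (Morgans), `n_snps`, `clr`, `s_hat`; grid points with no
#'   usable SNP are absent.
#' @export
sweep_scan <- function(g, map, config = sweep_scan_config(),
                       ref_groups = "wild",
                       obj_groups = c("landrace", "improved")) {
  ref <- g$samples$group %in% ref_groups
  obj <- g$samples$group %in% obj_groups
  stopifnot(any(ref), any(obj))
  quad <- gauss_legendre_01(config$n_quad)
  res <- lapply(unique(g$sites$chrom), function(chrom) {
    idx <- which(g$sites$chrom == chrom)
    pos <- g$sites$pos[idx]
    p1 <- allele_freq(subset_geno(g, sites = idx), samples = ref)
    kobj <- rowSums(g$geno[idx, obj, drop = FALSE], na.rm = TRUE)
    nobj <- 2 * rowSums(!is.na(g$geno[idx, obj, drop = FALSE]))
    usable <- !is.na(p1) & p1 > 0 & p1 < 1 & nobj > 0
    if (!any(usable)) return(NULL)
    omega <- config$omega %||%
      estimate_omega(p1[usable],
                     kobj[usable] / nobj[usable],
                     min_snps = min(1000, sum(usable)))
    gpos <- interp_genetic(pos, map[map$chrom == chrom, ])
    grid <- seq(min(pos), max(pos), by = config$grid_bp)
    ggrid <- interp_genetic(grid, map[map$chrom == chrom, ])
    su <- which(usable)
    rows <- lapply(seq_along(grid), function(gi) {
      dd <- abs(gpos[su] - ggrid[gi])
      inw <- which(dd <= config$window_morgans)
      if (!length(inw)) return(NULL)
      inw <- inw[order(dd[inw])][seq_len(min(length(inw),
                                             config$max_snps))]
      sel <- su[inw]
      w <- corr_weights(g$geno[idx[sel], c(which(ref), which(obj)),
                               drop = FALSE], config$corr_cutoff)
      d <- abs(gpos[sel] - ggrid[gi])
      best <- -Inf; s_hat <- NA_real_
      for (s in config$s_grid) {
        cc <- 1 - exp(-d / s)
        val <- sum(w * snp_loglik_ratio_vec(p1[sel], kobj[sel], nobj[sel],
                                            cc, omega, quad,
                                            config$obs_error))
        if (val > best) { best <- val; s_hat <- s }
      }
      data.frame(chrom = chrom, pos = grid[gi], gpos = ggrid[gi],
                 n_snps = length(sel), clr = max(0, 2 * best),
                 s_hat = s_hat, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  attr(out, "omega") <- config$omega
  class(out) <- c("sweep_scan", class(out))
  out
}

aggregate_windows <- function(scores, window, slide, chrom_length = NULL) {
  do.call(rbind, lapply(split(scores, scores$chrom), function(sc) {
    top <- chrom_length %||% max(sc$pos)
    starts <- seq(0, max(0, top - 1), by = slide)
    starts <- starts[starts < top]
    ends <- pmin(starts + window, top)
    mu <- vapply(seq_along(starts), function(i) {
      v <- sc$clr[sc$pos > starts[i] & sc$pos <= ends[i]]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
    data.frame(chrom = sc$chrom[1], start = starts, end = ends,
               score = mu, stringsAsFactors = FALSE)
  }))
}

flagged_span <- function(win, thr) {
  f <- !is.na(win$score) & win$score > thr
  if (!any(f)) return(0)
  total <- 0
  for (chrom in unique(win$chrom[f])) {
    sel <- f & win$chrom == chrom
    ir <- IRanges::reduce(IRanges::IRanges(win$start[sel] + 1,
                                           win$end[sel]))
    total <- total + sum(IRanges::width(ir))
  }
  total
}

#' Threshold sweep-window scores and call merged sweep regions
#'
#' Grid scores are aggregated to sliding windows (mean of grid scores per
#' window). The threshold is the smallest windowed score such that flagged
#' windows (score strictly above it) span at most `genome_fraction` of the
#' genome. Regions are maximal runs of flagged windows tolerating at most
#' one sub-threshold window inside each run; two or more consecutive
#' sub-threshold windows split regions. Each region's candidate gene is
#' the gene closest to its maximum-score window.
#'
#' @param scores a `sweep_scan` result (or data.frame with `chrom`, `pos`,
#'   `clr`).
#' @param genome_length total genome length in bp.
#' @param genome_fraction allowed flagged fraction (default 0.05).
#' @param window,slide aggregation window and step in bp (defaults 100 kb
#'   and 10 kb).
#' @param genes optional gene annotation (`gene`, `chrom`, `start`, `end`)
#'   for candidate assignment.
#' @return List with `threshold`, `windows` (with `flagged`), and
#'   `regions` (data.frame: `chrom`, `start`, `end` 0-based half-open,
#'   `max_score`, `max_window_start`, `mean_score`, `candidate_gene`).
#' @export
call_regions <- function(scores, genome_length, genome_fraction = 0.05,
                         window = 1e5, slide = 1e4, genes = NULL) {
  if (is.null(scores) || !nrow(scores)) {
    return(list(threshold = NA_real_, windows = NULL,
                regions = data.frame()))
  }
  win <- aggregate_windows(scores, window, slide, genome_length)
  vals <- sort(unique(win$score[!is.na(win$score)]))
  budget <- genome_fraction * genome_length
  # smallest threshold whose flagged span fits the budget (span is
  # monotone non-increasing in the threshold)
  lo <- 1L; hi <- length(vals); thr <- vals[hi]
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    if (flagged_span(win, vals[mid]) <= budget) {
      thr <- vals[mid]; hi <- mid - 1L
    } else lo <- mid + 1L
  }
  win$flagged <- !is.na(win$score) & win$score > thr
  regions <- do.call(rbind, lapply(split(win, win$chrom), function(w) {
    w <- w[order(w$start), ]
    scored <- which(!is.na(w$score))
    if (!length(scored)) return(NULL)
    w <- w[scored, ]
    runs <- list(); cur <- NULL; gap <- 0L
    for (i in seq_len(nrow(w))) {
      if (w$flagged[i]) {
        if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
        gap <- 0L
      } else if (!is.null(cur)) {
        gap <- gap + 1L
        if (gap > 1L) { runs[[length(runs) + 1L]] <- cur
          cur <- NULL; gap <- 0L }
      }
    }
    if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
    do.call(rbind, lapply(runs, function(r) {
      ww <- w[r[1]:r[2], ]
      mx <- which.max(ww$score)
      data.frame(chrom = w$chrom[1], start = ww$start[1],
                 end = ww$end[nrow(ww)], max_score = ww$score[mx],
                 max_window_start = ww$start[mx],
                 mean_score = mean(ww$score, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(regions) && nrow(regions)) {
    rownames(regions) <- NULL
    regions$candidate_gene <- NA_character_
    if (!is.null(genes) && nrow(genes)) {
      for (i in seq_len(nrow(regions))) {
        gsel <- genes[genes$chrom == regions$chrom[i], ]
        if (!nrow(gsel)) next
        mid <- regions$max_window_start[i] + window / 2
        dist <- pmax(0, pmax(gsel$start - mid, mid - gsel$end))
        regions$candidate_gene[i] <- gsel$gene[which.min(dist)]
      }
    }
  } else regions <- data.frame()
  list(threshold = thr, windows = win, regions = regions)
}

#' Plot a sweep scan with its called regions
#'
#' @param x a `sweep_scan` result.
#' @param calls optional output of [call_regions()].
#' @param ... passed to [plot()].
#' @export
plot.sweep_scan <- function(x, calls = NULL, ...) {
  plot(x$pos / 1e6, x$clr, pch = 16, cex = 0.4, xlab = "position (Mb)",
       ylab = "composite likelihood ratio", ...)
  if (!is.null(calls)) {
    graphics::abline(h = calls$threshold, lty = 2)
    if (nrow(calls$regions))
      graphics::rect(calls$regions$start / 1e6, 0,
                     calls$regions$end / 1e6,
                     max(x$clr) * 0.02, col = "red", border = NA)
  }
  invisible(x)
}
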