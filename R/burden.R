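# Effect annotation, deleterious-set construction, per-accession derived
# deleterious burden with reference-bias correction, and group comparisons.

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Annotate coding effect of SNPs
#'
#' Translates the reference and alternate codon with the standard nuclear
#' code and classifies each site as synonymous, nonsynonymous, stop_gained,
#' stop_lost or noncoding. Reverse-strand CDS are complemented. Stop
#' classes are folded into nonsynonymous by the deleterious-set builder.
#' Sites in frame-inconsistent CDS (a truncated terminal codon) are
#' classified noncoding with a warning.
#'
#' @param sites data.frame with `pos`, `ref`, `alt` (single chromosome).
#' @param cds data.frame with `gene`, `start`, `end`, `strand`, `phase`
#'   (1-based inclusive intervals; multi-interval genes are concatenated in
#'   coding order).
#' @param genome character string: the chromosome's reference sequence.
#' @return Character vector of effect classes, plus attribute `gene`.
#' @export
annotate_effect <- function(sites, cds, genome) {
  seqv <- strsplit(toupper(genome), "")[[1]]
  code <- Biostrings::GENETIC_CODE
  effect <- rep("noncoding", nrow(sites))
  gene <- rep(NA_character_, nrow(sites))
  warned <- FALSE
  for (gn in unique(cds$gene)) {
    iv <- cds[cds$gene == gn, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    strand <- iv$strand[1]
    coding_pos <- unlist(mapply(seq.int, iv$start, iv$end,
                                SIMPLIFY = FALSE))
    if (strand == "-") coding_pos <- rev(coding_pos)
    phase <- iv$phase[1] %||% 0L
    coding_pos <- coding_pos[(phase + 1L):length(coding_pos)]
    cds_seq <- seqv[coding_pos]
    if (strand == "-") cds_seq <- comp_base(cds_seq)
    usable_len <- (length(coding_pos) %/% 3L) * 3L
    hit <- which(sites$pos %in% coding_pos)
    for (si in hit) {
      ci <- match(sites$pos[si], coding_pos)
      if (ci > usable_len) {
        if (!warned) {
          warning("site in frame-inconsistent codon treated as noncoding")
          warned <- TRUE
        }
        next
      }
      codon_i <- (ci - 1L) %/% 3L
      idx <- codon_i * 3L + 1:3
      ref_codon <- cds_seq[idx]
      within <- ci - codon_i * 3L
      ref_b <- sites$ref[si]; alt_b <- sites$alt[si]
      if (strand == "-") { ref_b <- comp_base(ref_b)
        alt_b <- comp_base(alt_b) }
      if (!identical(ref_codon[within], ref_b)) next  # allele mismatch
      alt_codon <- ref_codon
      alt_codon[within] <- alt_b
      aa_ref <- code[[paste(ref_codon, collapse = "")]]
      aa_alt <- code[[paste(alt_codon, collapse = "")]]
      effect[si] <- if (aa_ref == aa_alt) "synonymous"
        else if (aa_alt == "*") "stop_gained"
        else if (aa_ref == "*") "stop_lost"
        else "nonsynonymous"
      gene[si] <- gn
    }
  }
  attr(effect, "gene") <- gene
  effect
}

#' Build a deleterious site set
#'
#' Criteria partition nonsynonymous/synonymous effects (stop classes count
#' as nonsynonymous) by constraint-score strata, or use a per-site
#' SIFT-style deleterious flag. The default, nonsynonymous with RS > 2, is
#' the conventional working definition of a deleterious mutation set.
#'
#' @param effect character vector of effect classes.
#' @param rs numeric vector of per-site constraint scores.
#' @param sift optional logical vector: SIFT score < 0.05 flags.
#' @param criterion one of `GERP2_nonsyn` (default: nonsyn and RS > 2),
#'   `GERP2_4_nonsyn`, `GERP4_nonsyn`, `GERP2_4_syn`, `GERP4_syn`,
#'   `SIFT05_nonsyn`.
#' @return Logical membership vector.
#' @export
build_deleterious_set <- function(effect, rs, sift = NULL,
                                  criterion = "GERP2_nonsyn") {
  nonsyn <- effect %in% c("nonsynonymous", "stop_gained", "stop_lost")
  syn <- effect == "synonymous"
  switch(criterion,
    GERP2_nonsyn = nonsyn & rs > 2,
    GERP2_4_nonsyn = nonsyn & rs > 2 & rs <= 4,
    GERP4_nonsyn = nonsyn & rs > 4,
    GERP2_4_syn = syn & rs > 2 & rs <= 4,
    GERP4_syn = syn & rs > 4,
    SIFT05_nonsyn = {
      if (is.null(sift)) stop("SIFT05_nonsyn criterion requires sift flags")
      nonsyn & sift
    },
    stop("unknown criterion: ", criterion))
}

#' Reference-bias correction weights
#'
#' Annotation pipelines trained on the reference genome under-call
#' deleterious alleles at sites where the reference carries the derived
#' allele. Within each derived-allele-frequency bin, the correction factor
#' is `f = P(deleterious | reference ancestral) / P(deleterious |
#' reference derived)`; deleterious sites with a derived reference allele
#' get weight `f`, all other sites weight 1. Bins where either stratum is
#' empty fall back to weight 1 with a warning.
#'
#' @param derived_freq per-site derived-allele frequency.
#' @param ref_is_derived logical: reference allele is the derived one.
#' @param deleterious logical deleterious flags.
#' @param n_bins number of equal-width frequency bins (default 10).
#' @return List with `weight` (per site) and `bins` (diagnostics).
#' @export
reference_bias_correction <- function(derived_freq, ref_is_derived,
                                      deleterious, n_bins = 10) {
  bin <- pmin(pmax(ceiling(derived_freq * n_bins), 1L), n_bins)
  weight <- rep(1, length(derived_freq))
  diag <- data.frame(bin = seq_len(n_bins), p_del_ref_anc = NA_real_,
                     p_del_ref_der = NA_real_, f = 1)
  warned <- FALSE
  for (b in seq_len(n_bins)) {
    anc <- bin == b & !ref_is_derived
    der <- bin == b & ref_is_derived
    if (!any(anc) || !any(der)) {
      if (any(bin == b) && !warned) {
        warning("empty reference stratum in a frequency bin; weight 1 used")
        warned <- TRUE
      }
      next
    }
    pa <- mean(deleterious[anc]); pd <- mean(deleterious[der])
    diag$p_del_ref_anc[b] <- pa; diag$p_del_ref_der[b] <- pd
    if (pd > 0) {
      f <- pa / pd
      diag$f[b] <- f
      weight[der & deleterious] <- f
    }
  }
  list(weight = weight, bins = diag)
}

cds_length_in <- function(cds, regions = NULL, invert = FALSE) {
  cds_r <- IRanges::reduce(IRanges::IRanges(cds$start, cds$end))
  if (is.null(regions)) return(sum(IRanges::width(cds_r)))
  reg <- IRanges::reduce(IRanges::IRanges(regions$start, regions$end))
  inter <- IRanges::intersect(cds_r, reg)
  inside <- sum(IRanges::width(inter))
  if (invert) sum(IRanges::width(cds_r)) - inside else inside
}

burden_counts <- function(g, polarity, member, weight,
                          min_certainty = 0.8) {
  certain <- !is.na(polarity$p_major_ancestral) &
    pmax(polarity$p_major_ancestral, 1 - polarity$p_major_ancestral) >=
      min_certainty
  idx <- which(member & polarity$usable & certain)
  if (!length(idx)) {
    return(list(raw = stats::setNames(rep(0, ncol(g$geno)),
                                      g$samples$sample),
                n_missing = stats::setNames(rep(0L, ncol(g$geno)),
                                            g$samples$sample)))
  }
  dos <- g$geno[idx, , drop = FALSE]
  # derived copies: alt dosage when derived == alt, else complement
  der_is_alt <- polarity$derived[idx] == g$sites$alt[idx]
  dcop <- dos
  dcop[!der_is_alt, ] <- 2L - dos[!der_is_alt, , drop = FALSE]
  w <- weight[idx]
  n_missing <- colSums(is.na(dcop))
  dcop[is.na(dcop)] <- 0L
  list(raw = colSums(dcop * w), n_missing = n_missing)
}

#' Per-accession derived-deleterious mutation burden
#'
#' Raw burden is the weighted count of derived allele copies over the
#' deleterious set (hom-derived = 2, het = 1, hom-ancestral = 0; missing
#' genotypes contribute 0 and are reported). Normalized burden is raw x
#' 1e5 / CDS length (alleles per 100 kb of CDS). When sweep regions are
#' supplied, burden is computed separately for deleterious sites inside
#' (sweep) and outside (control) the regions, each normalized by its own
#' CDS length.
#'
#' @param g a [geno_matrix()].
#' @param polarity output of [polarize_sites()] (row-aligned with the
#'   sites of `g`). Unusable sites are excluded.
#' @param deleterious logical membership vector from
#'   [build_deleterious_set()].
#' @param weights optional per-site weights (default 1; see
#'   [reference_bias_correction()]).
#' @param cds CDS annotation data.frame (`start`, `end`), used for CDS
#'   lengths.
#' @param regions optional sweep-region data.frame (`start`, `end`,
#'   1-based inclusive).
#' @param min_certainty minimum posterior certainty
#'   `max(p, 1 - p)` of the ancestral state for a site to enter the
#'   burden (default 0.8). Ambiguously polarized sites carry no
#'   directional information and only dilute group contrasts; 0.5 keeps
#'   every usable site.
#' @return data.frame with one row per accession and region class
#'   (`genome`, plus `sweep`/`control` when regions are given): group, raw
#'   burden, CDS length, normalized burden per 100-kb CDS, missing-call
#'   count.
#' @export
mutation_burden <- function(g, polarity, deleterious, weights = NULL,
                            cds, regions = NULL, min_certainty = 0.8) {
  if (is.null(weights)) weights <- rep(1, nrow(g$sites))
  one <- function(member, cds_len, class) {
    if (cds_len <= 0) stop("zero CDS length for region class ", class)
    b <- burden_counts(g, polarity, member, weights, min_certainty)
    data.frame(sample = g$samples$sample, group = g$samples$group,
               region = class, raw = unname(b$raw),
               cds_length = cds_len,
               per_100kb = unname(b$raw) * 1e5 / cds_len,
               n_missing = unname(b$n_missing),
               stringsAsFactors = FALSE)
  }
  out <- one(deleterious, cds_length_in(cds), "genome")
  if (!is.null(regions) && nrow(regions)) {
    in_sweep <- vapply(g$sites$pos, function(p)
      any(p >= regions$start & p <= regions$end), logical(1))
    out <- rbind(out,
                 one(deleterious & in_sweep,
                     cds_length_in(cds, regions), "sweep"),
                 one(deleterious & !in_sweep,
                     cds_length_in(cds, regions, invert = TRUE), "control"))
  }
  out
}

#' Compare mutation burden between groups and region classes
#'
#' For each pair of groups: the percent difference of group means,
#' `100 * (1 - mean_focal / mean_reference)`, and a two-sided Welch
#' t-test. With three or more groups a Tukey HSD on the one-way layout is
#' added. When the burden table carries sweep/control classes, a paired
#' within-group sweep-vs-control comparison (per-100-kb normalized burden)
#' is included.
#'
#' @param burden output of [mutation_burden()].
#' @param reference_group group used as the denominator of percent
#'   differences (default `"wild"`).
#' @param value which column to compare (default `per_100kb`).
#' @return List of class `burden_comparison`: `pairwise`, optional
#'   `tukey`, optional `sweep_vs_control`.
#' @export
compare_burden <- function(burden, reference_group = "wild",
                           value = "per_100kb") {
  gen <- burden[burden$region == "genome", ]
  grp <- split(gen[[value]], gen$group)
  grp <- grp[vapply(grp, length, 1L) >= 2]
  if (length(grp) < 2) stop("need >= 2 groups with >= 2 accessions")
  nm <- names(grp)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  # denominator preference: the wild reference first, then the less-derived
  # domesticated group, so differences read "focal reduced relative to ref"
  pref <- unique(c(reference_group, "landrace", "improved", "hybrid", nm))
  pw <- do.call(rbind, lapply(pairs, function(p) {
    b <- p[which.min(match(p, pref))]  # reference (denominator)
    a <- setdiff(p, b)                 # focal
    tt <- stats::t.test(grp[[a]], grp[[b]])
    data.frame(focal = a, reference = b,
               percent_difference = 100 * (1 - mean(grp[[a]]) /
                                             mean(grp[[b]])),
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  out <- list(pairwise = pw)
  if (length(grp) >= 3) {
    df <- data.frame(y = unlist(grp, use.names = FALSE),
                     g = factor(rep(nm, vapply(grp, length, 1L))))
    out$tukey <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
  }
  if (any(burden$region == "sweep")) {
    sw <- burden[burden$region == "sweep", ]
    ct <- burden[burden$region == "control", ]
    key <- match(sw$sample, ct$sample)
    svc <- do.call(rbind, lapply(split(seq_len(nrow(sw)), sw$group),
      function(i) {
        if (length(i) < 2) return(NULL)
        tt <- stats::t.test(sw[[value]][i], ct[[value]][key[i]],
                            paired = TRUE)
        data.frame(group = sw$group[i][1],
                   mean_sweep = mean(sw[[value]][i]),
                   mean_control = mean(ct[[value]][key[i]]),
                   percent_difference =
                     100 * (1 - mean(sw[[value]][i]) /
                              mean(ct[[value]][key[i]])),
                   p_value = tt$p.value, stringsAsFactors = FALSE)
      }))
    rownames(svc) <- NULL
    out$sweep_vs_control <- svc
  }
  structure(out, class = "burden_comparison")
}

#' @export
print.burden_comparison <- function(x, ...) {
  cat("Mutation-burden comparison\n")
  print(x$pairwise, row.names = FALSE)
  if (!is.null(x$sweep_vs_control)) {
    cat("sweep vs control (paired, within group):\n")
    print(x$sweep_vs_control, row.names = FALSE)
  }
  invisible(x)
}
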