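# Rejected-substitution (RS) constraint scoring from multi-species
# alignment columns. The expected number of substitutions at a column is
# the span (sum of branch lengths, substitutions/site) of the neutral tree
# restricted to the species actually aligned, with the reference sequence
# projected out to avoid reference bias; the estimated number is the span
# times the maximum-likelihood rate multiplier under Jukes-Cantor.
# RS = expected - estimated; positions that cannot be scored are filled
# with 0.

#' Project the neutral tree onto the aligned species
#'
#' Removes the reference leaf, restricts the tree to the species aligned at
#' a column, suppresses the resulting degree-2 internal nodes (their branch
#' lengths are summed), and reports the span of the result.
#'
#' @param tree an \pkg{ape} `phylo` with branch lengths in
#'   substitutions/site.
#' @param aligned_species character vector of species with non-gap
#'   characters at the column (subset of the tree's leaves).
#' @param reference_name reference species to project out (may be absent
#'   from the tree).
#' @return List with `subtree` (a `phylo`, or `NULL` when unscorable) and
#'   `T_proj` (its span; 0 when unscorable).
#' @export
project_tree <- function(tree, aligned_species, reference_name) {
  keep <- setdiff(intersect(aligned_species, tree$tip.label),
                  reference_name)
  if (length(keep) < 2) return(list(subtree = NULL, T_proj = 0))
  sub <- ape::keep.tip(tree, keep)
  list(subtree = sub, T_proj = sum(sub$edge.length))
}

# Felsenstein pruning log-likelihood of one column under JC69 with branch
# lengths scaled by `r`. `column` is a named character vector of bases for
# (at least) the subtree's tips.
jc_column_loglik <- function(column, tree, r) {
  bases <- c("A", "C", "G", "T")
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- max(tr$edge)
  L <- matrix(0, n_node, 4)
  obs <- match(toupper(column[tr$tip.label]), bases)
  for (i in seq_len(n_tip)) {
    if (is.na(obs[i])) L[i, ] <- 1 else L[i, obs[i]] <- 1
  }
  L[(n_tip + 1):n_node, ] <- 1
  scale_log <- 0
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    t <- tr$edge.length[k] * r
    ps <- 0.25 + 0.75 * exp(-4 / 3 * t)
    pd <- 0.25 - 0.25 * exp(-4 / 3 * t)
    lc <- L[child, ]
    msg <- pd * sum(lc) + (ps - pd) * lc
    L[par, ] <- L[par, ] * msg
    m <- max(L[par, ])
    if (m > 0 && m < 1e-200) { L[par, ] <- L[par, ] / m
      scale_log <- scale_log + log(m) }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  log(sum(0.25 * L[root, ])) + scale_log
}

#' Maximum-likelihood substitution-rate multiplier of a column
#'
#' Maximizes the Jukes-Cantor pruning likelihood of the column on the
#' subtree over a rate multiplier `r` in `[0, r_max]`, by golden-section
#' search to `|dr| < tol`, with the interval endpoints checked explicitly
#' so boundary maxima (fully conserved or saturated columns) are exact.
#'
#' @param column named character vector of bases (names = species).
#' @param subtree projected `phylo` tree.
#' @param r_max upper bound of the rate scale (default 3).
#' @param tol search tolerance (default 1e-4).
#' @return The estimated rate multiplier.
#' @export
estimate_column_rate <- function(column, subtree, r_max = 3, tol = 1e-4) {
  f <- function(r) jc_column_loglik(column, subtree, r)
  opt <- stats::optimize(f, c(0, r_max), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, r_max)
  ll <- c(f(0), opt$objective, f(r_max))
  cand[which.max(ll)]
}

#' Score alignment columns for evolutionary constraint
#'
#' For each column: the tree is projected onto the aligned species with the
#' reference removed; `RS = T_proj * (1 - r_hat)` where `r_hat` is the
#' column's ML rate multiplier. Columns with fewer than two non-reference
#' species aligned (including reference-N positions) are unscorable and
#' filled with `RS = 0`, class `unscored`. Classes follow the conventional
#' 0 / 2 / 4 cutoffs.
#'
#' @param columns character matrix (rows = positions, columns = species;
#'   colnames are species names). Gaps (`-`) and `N` both denote absence.
#' @param tree the neutral `phylo` tree.
#' @param reference_name reference species name.
#' @param positions optional position labels (default row index).
#' @param r_max,tol passed to [estimate_column_rate()].
#' @return data.frame with `position`, `n_species`, `T_proj`, `r_hat`,
#'   `est_subs`, `RS` and `class`.
#' @export
gerp_score <- function(columns, tree, reference_name,
                       positions = seq_len(nrow(columns)), r_max = 3,
                       tol = 1e-4) {
  species <- colnames(columns)
  cache <- new.env(parent = emptyenv())
  n <- nrow(columns)
  out <- data.frame(position = positions, n_species = 0L, T_proj = 0,
                    r_hat = NA_real_, est_subs = 0, RS = 0,
                    class = "unscored", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    col <- toupper(columns[i, ])
    present <- species[col %in% c("A", "C", "G", "T")]
    keep <- setdiff(present, reference_name)
    out$n_species[i] <- length(keep)
    # reference positions that are N (or gap) are never scored: zero-fill
    if (reference_name %in% species &&
        !(col[[reference_name]] %in% c("A", "C", "G", "T"))) next
    if (length(keep) < 2) next
    key <- paste(sort(keep), collapse = "|")
    proj <- get0(key, envir = cache)
    if (is.null(proj)) {
      proj <- project_tree(tree, present, reference_name)
      assign(key, proj, envir = cache)
    }
    if (is.null(proj$subtree)) next
    cvec <- stats::setNames(col, species)[keep]
    r_hat <- estimate_column_rate(cvec, proj$subtree, r_max, tol)
    out$T_proj[i] <- proj$T_proj
    out$r_hat[i] <- r_hat
    out$est_subs[i] <- r_hat * proj$T_proj
    out$RS[i] <- proj$T_proj - out$est_subs[i]
    out$class[i] <- rs_class(out$RS[i])
  }
  out
}

rs_class <- function(rs) {
  if (rs <= 0) "<=0" else if (rs <= 2) "(0,2]" else if (rs <= 4) "(2,4]"
  else ">4"
}

#' Genome-wide constraint summary
#'
#' Fractions of the genome under constraint at the conventional RS
#' cutoffs.
#'
#' @param rs numeric vector of per-position RS scores (unscored positions
#'   as 0).
#' @param genome_length total genome length in bp (defaults to
#'   `length(rs)` when scores cover every position).
#' @return data.frame with cutoffs 0/2/4, bp counts and percentages
#'   (1 decimal).
#' @export
genome_constraint_summary <- function(rs, genome_length = length(rs)) {
  cut <- c(0, 2, 4)
  bp <- vapply(cut, function(k) sum(rs > k), numeric(1))
  data.frame(cutoff = cut, bp = bp,
             percent = round(100 * bp / genome_length, 1))
}
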