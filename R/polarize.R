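# Ancestral-allele polarization against two outgroups.
#
# Two-state per-site model: the ancestral allele is one of the two ingroup
# alleles (major or minor). Each outgroup allele matches the ancestral
# allele unless a lineage-specific mismatch occurred (probability e_k);
# outgroup states outside {major, minor} are treated as missing. The prior
# probability that the major allele is ancestral is a mixture weight,
# stratified by minor-allele frequency when the site table provides a
# `maf` column (rare minor alleles are much more often derived than
# alleles near frequency one-half, so a single global weight misleads the
# hard calls at intermediate frequencies); with no `maf` column a single
# weight is fitted.

# per-outgroup match indicators: 1 = matches major, 0 = matches minor,
# NA = missing/other state
outgroup_match <- function(sites) {
  enc <- function(o) ifelse(is.na(o), NA_real_,
                            ifelse(o == sites$major, 1,
                                   ifelse(o == sites$minor, 0, NA_real_)))
  cbind(enc(sites$out1), enc(sites$out2))
}

site_likelihoods <- function(match, e) {
  # L(a): product over non-missing outgroups of (1 - e_k) if o_k == a else e_k
  l_major <- rep(1, nrow(match)); l_minor <- rep(1, nrow(match))
  for (k in 1:2) {
    mk <- match[, k]
    ok <- !is.na(mk)
    l_major[ok] <- l_major[ok] * ifelse(mk[ok] == 1, 1 - e[k], e[k])
    l_minor[ok] <- l_minor[ok] * ifelse(mk[ok] == 0, 1 - e[k], e[k])
  }
  cbind(major = l_major, minor = l_minor)
}

prior_bin_index <- function(sites, freq_bins) {
  if (is.null(sites$maf) || freq_bins <= 1)
    return(rep(1L, nrow(sites)))
  pmin(pmax(ceiling(sites$maf * 2 * freq_bins), 1L), freq_bins)
}

#' Fit the two-outgroup polarization model by EM
#'
#' Estimates the per-outgroup mismatch probabilities and the prior
#' probability that the major allele is ancestral, by
#' expectation-maximization over the latent per-site ancestral state. The
#' reported mismatch rate is conditional on the outgroup carrying one of
#' the two ingroup alleles (outgroup states outside that pair carry no
#' directional information and are treated as missing). When `sites`
#' carries a `maf` column (minor-allele frequency in `[0, 0.5]`) the prior
#' is fitted per frequency bin.
#'
#' @param sites data.frame with columns `major`, `minor`, `out1`, `out2`
#'   (allele characters; `NA` or third-state outgroup alleles are treated
#'   as missing), optionally `maf`. Sites with both outgroups missing are
#'   unusable and are excluded from the fit.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param e_init,prior_init starting values.
#' @param freq_bins number of minor-allele-frequency bins for the prior
#'   (used only when `sites$maf` is present; default 5).
#' @return Object of class `polarizer_fit` with elements `e` (length 2),
#'   `prior_major_ancestral` (posterior-mean weight), `prior_bins`
#'   (per-bin weights), `loglik` (trace), `n_usable`, and `boundary`
#'   (TRUE when a mismatch rate hit its lower bound).
#' @export
fit_polarizer <- function(sites, tol = 1e-8, max_iter = 500,
                          e_init = c(0.05, 0.05), prior_init = 0.7,
                          freq_bins = 5) {
  match <- outgroup_match(sites)
  usable <- rowSums(!is.na(match)) > 0
  if (sum(usable) < 2) stop("too few usable sites to fit the polarizer")
  bin_all <- prior_bin_index(sites, freq_bins)
  m <- match[usable, , drop = FALSE]
  bin <- bin_all[usable]
  n_bins <- max(bin)
  e <- pmin(pmax(e_init, 1e-6), 0.5 - 1e-6)
  prior <- rep(min(max(prior_init, 1e-6), 1 - 1e-6), n_bins)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lik <- site_likelihoods(m, e)
    pb <- prior[bin]
    num <- pb * lik[, "major"]
    den <- num + (1 - pb) * lik[, "minor"]
    w <- num / den
    ll <- sum(log(den))
    trace <- c(trace, ll)
    # M-step
    prior <- vapply(seq_len(n_bins), function(b) {
      wb <- w[bin == b]
      if (!length(wb)) return(prior[b])
      min(max(mean(wb), 1e-6), 1 - 1e-6)
    }, numeric(1))
    for (k in 1:2) {
      ok <- !is.na(m[, k])
      # mismatch when the outgroup allele differs from the ancestral state
      mis <- sum(w[ok] * (m[ok, k] == 0) + (1 - w[ok]) * (m[ok, k] == 1))
      e[k] <- min(max(mis / sum(ok), 1e-6), 0.5 - 1e-6)
    }
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) break
  }
  structure(list(e = e, prior_major_ancestral = mean(prior[bin]),
                 prior_bins = prior, freq_bins = freq_bins,
                 loglik = trace, n_usable = sum(usable),
                 boundary = any(e <= 1e-6)),
            class = "polarizer_fit")
}

#' @export
print.polarizer_fit <- function(x, ...) {
  cat("Two-outgroup polarization model (EM)\n")
  cat(sprintf("  mismatch rates: e1 = %.4f, e2 = %.4f%s\n", x$e[1], x$e[2],
              if (x$boundary) " (boundary)" else ""))
  if (length(x$prior_bins %||% 1) > 1) {
    cat("  P(major ancestral) by minor-frequency bin:",
        paste(sprintf("%.3f", x$prior_bins), collapse = " "), "\n")
  } else {
    cat(sprintf("  P(major ancestral) prior = %.4f\n",
                x$prior_major_ancestral))
  }
  cat(sprintf("  log-likelihood %.4f after %d iterations (%d sites)\n",
              utils::tail(x$loglik, 1), length(x$loglik), x$n_usable))
  invisible(x)
}

#' @export
coef.polarizer_fit <- function(object, ...) {
  c(e1 = object$e[1], e2 = object$e[2],
    prior_major_ancestral = object$prior_major_ancestral)
}

#' @export
logLik.polarizer_fit <- function(object, ...) {
  structure(utils::tail(object$loglik, 1), df = 3, class = "logLik")
}

model_prior_for <- function(model, sites) {
  bins <- model$prior_bins %||% model$prior_major_ancestral
  if (length(bins) == 1) return(rep(bins, nrow(sites)))
  bin <- prior_bin_index(sites, model$freq_bins %||% length(bins))
  bins[pmin(bin, length(bins))]
}

#' Polarize sites with a fitted (or fixed) model
#'
#' Computes the posterior probability that the major allele is ancestral at
#' each site and hard-calls the derived allele as the one opposite the more
#' probable ancestral state. At a posterior of exactly 0.5 the major allele
#' is deemed ancestral (deterministic, conservative tie-break). Sites with
#' both outgroups missing are marked unusable.
#'
#' @param model a `polarizer_fit` (or a list with `e` and
#'   `prior_major_ancestral` for a fixed model).
#' @param sites data.frame as in [fit_polarizer()].
#' @param min_posterior posterior cutoff below which the hard call is also
#'   reported; kept at 0.5 (hard calls) by default.
#' @return data.frame with `p_major_ancestral`, `ancestral`, `derived` and
#'   `usable`.
#' @export
polarize_sites <- function(model, sites, min_posterior = 0.5) {
  match <- outgroup_match(sites)
  usable <- rowSums(!is.na(match)) > 0
  lik <- site_likelihoods(match, model$e)
  prior <- model_prior_for(model, sites)
  num <- prior * lik[, "major"]
  p <- num / (num + (1 - prior) * lik[, "minor"])
  p[!usable] <- NA_real_
  major_anc <- !is.na(p) & p >= min_posterior
  data.frame(p_major_ancestral = p,
             ancestral = ifelse(usable,
                                ifelse(major_anc, sites$major, sites$minor),
                                NA_character_),
             derived = ifelse(usable,
                              ifelse(major_anc, sites$minor, sites$major),
                              NA_character_),
             usable = usable, stringsAsFactors = FALSE)
}
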