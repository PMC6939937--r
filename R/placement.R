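# Stimulus placement rules: ZEST (posterior mean) and Psi / Psi-marginal
# (expected posterior entropy minimization).

# Snap values to the nearest candidate; exact midpoints go to the lower one.
snap_to_candidates <- function(x, candidates) {
  i <- findInterval(x, candidates, all.inside = TRUE)
  lo <- candidates[i]; hi <- candidates[i + 1]
  ifelse(x - lo <= hi - x, lo, hi)
}

#' ZEST placement: posterior mean of the threshold, snapped to a candidate
#'
#' Multi-axis posteriors are marginalized over nuisance axes first. The
#' mean is snapped to the nearest stimulus candidate (midpoint ties go to
#' the lower candidate).
#'
#' @param posterior A `psy_posterior`.
#' @param candidates Stimulus candidates; defaults to the grid's.
#' @return A stimulus intensity, log10 arcsec.
#' @export
zest_place <- function(posterior, candidates = posterior$grid$stimuli) {
  snap_to_candidates(posterior_mean(posterior, "threshold"), candidates)
}

xlog2x <- function(v) {
  out <- v * log2(v)
  out[v <= 0] <- 0
  out
}

# Grouping of hypothesis points by their joint value on the interest axes.
interest_groups <- function(posterior, interest) {
  pts <- posterior$points
  key <- 0L
  mult <- 1L
  for (ax in interest) {
    idx <- match(pts[[ax]], posterior$grid[[ax]])
    key <- key + (idx - 1L) * mult
    mult <- mult * length(posterior$grid[[ax]])
  }
  key + 1L
}

#' Expected posterior entropy after one trial at each candidate intensity
#'
#' For each candidate `x` the two possible responses are weighted by their
#' predictive probability under the current posterior, and the Shannon
#' entropy (bits) of the updated posterior, marginalized onto the interest
#' axes, is averaged:
#' \deqn{E[H] = p(r{=}1\mid x) H(p_{+}) + p(r{=}0\mid x) H(p_{-}).}
#' Psi uses all axes as interest axes; Psi-marginal variants use the
#' threshold (and optionally the spread), treating the rest as nuisance.
#'
#' @param posterior A `psy_posterior`.
#' @param candidates Candidate intensities (default: the grid's stimuli).
#' @param interest Character vector of interest axes (default: all axes).
#' @param lik Optional precomputed likelihood table (internal use).
#'
#' @return Numeric vector of expected entropies, one per candidate.
#' @export
expected_posterior_entropy <- function(posterior,
                                       candidates = posterior$grid$stimuli,
                                       interest = grid_axes(posterior$grid),
                                       lik = NULL) {
  stopifnot(inherits(posterior, "psy_posterior"))
  if (!all(interest %in% grid_axes(posterior$grid))) {
    rlang::abort("unknown interest axis", class = "zestsim_invalid_request")
  }
  p <- posterior$mass
  if (is.null(lik)) {
    L <- vapply(candidates, function(x) point_likelihood(posterior, x, 1L),
                numeric(posterior$points$n))
    L <- matrix(L, nrow = posterior$points$n)
  } else {
    L <- lik$L
  }
  full <- setequal(interest, grid_axes(posterior$grid))
  if (full && !is.null(lik)) {
    # log-decomposition: sum w log w = sum p L (log p + log L), with the
    # log-likelihood tables precomputed (no per-call logs over the grid)
    lp <- log2(clip_probability(p))
    pr1 <- as.numeric(crossprod(L, p))
    cl <- as.numeric(crossprod(L, p * lp))
    a1 <- cl + as.numeric(crossprod(lik$Llog2L, p))
    a0 <- (sum(p * lp) - cl) + as.numeric(crossprod(lik$Mlog2M, p))
    pr0 <- 1 - pr1
    return(-(a1 + a0) + xlog2x(pr1) + xlog2x(pr0))
  }
  grp <- interest_groups(posterior, interest)
  W <- L * p                      # joint mass if correct, per candidate col
  m1 <- rowsum(W, grp)            # marginal over interest axes
  m0 <- as.numeric(rowsum(p, grp)) - m1
  pr1 <- colSums(m1)
  pr0 <- 1 - pr1
  -(colSums(xlog2x(m1)) + colSums(xlog2x(m0))) + xlog2x(pr1) + xlog2x(pr0)
}

#' Psi placement: candidate minimizing the expected posterior entropy
#'
#' Ties are broken toward the smaller intensity.
#'
#' @inheritParams expected_posterior_entropy
#' @return A stimulus intensity, log10 arcsec.
#' @export
psi_place <- function(posterior, candidates = posterior$grid$stimuli,
                      interest = grid_axes(posterior$grid), lik = NULL) {
  eh <- expected_posterior_entropy(posterior, candidates, interest, lik)
  candidates[which.min(eh)]   # which.min returns the first (smallest) tie
}
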