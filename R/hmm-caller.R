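# Distance-aware HMM segmentation of (corrected) LRR into copy-number states.
#
# States are copy numbers 0..4. Transitions depend on the physical distance d
# to the previous marker: with probability rho(d) = exp(-d / decay_distance)
# the state persists, otherwise it is redrawn from the stationary prior:
#   a(s -> t | d) = rho(d) * 1[s == t] + (1 - rho(d)) * prior[t].
# Chromosome boundaries reset to the prior. Emissions are Gaussian in LRR per
# state, optionally multiplied by a genotype-mixture BAF density whose
# component weights are binomial in the marker's population B-allele
# frequency.

#' HMM parameter set
#'
#' @param lrr_mean,lrr_sd Per-state emission mean/SD for copy numbers
#'   0,1,2,3,4. Defaults are canonical SNP-array values from the CNV-calling
#'   literature: means (-3.0, -0.66, 0, 0.40, 0.68), SDs
#'   (1.0, 0.28, 0.16, 0.21, 0.19).
#' @param prior Stationary state prior; defaults to 0.995 on CN2 with the
#'   remainder split evenly.
#' @param decay_distance Transition memory in bp (default 1e5): the distance
#'   at which state persistence has decayed to 1/e.
#' @param use_baf Include the BAF genotype-mixture emission term
#'   (default `FALSE`).
#' @param baf_sd SD of each BAF mixture component (default 0.05).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(lrr_mean = c(-3.0, -0.66, 0.0, 0.40, 0.68),
                       lrr_sd = c(1.0, 0.28, 0.16, 0.21, 0.19),
                       prior = c(0.00125, 0.00125, 0.995, 0.00125, 0.00125),
                       decay_distance = 1e5, use_baf = FALSE, baf_sd = 0.05) {
  stopifnot(length(lrr_mean) == 5L, length(lrr_sd) == 5L, length(prior) == 5L)
  if (any(lrr_sd <= 0)) stop_format("hmm_params: lrr_sd must be positive")
  if (abs(sum(prior) - 1) > 1e-12) stop_format("hmm_params: prior must sum to 1")
  if (decay_distance <= 0) stop_format("hmm_params: decay_distance must be positive")
  structure(list(states = 0:4, lrr_mean = lrr_mean, lrr_sd = lrr_sd,
                 prior = prior, decay_distance = decay_distance,
                 use_baf = use_baf, baf_sd = baf_sd),
            class = "hmm_params")
}

# BAF mixture component centers per copy-number state (CN0 handled as uniform)
baf_centers <- list(`0` = numeric(), `1` = c(0, 1), `2` = c(0, 0.5, 1),
                    `3` = c(0, 1/3, 2/3, 1), `4` = c(0, 0.25, 0.5, 0.75, 1))

#' Emission log-likelihood of one observation under one state
#'
#' Gaussian log-density of the (corrected) LRR at the state's mean/SD; when
#' `use_baf` is on and BAF is observed, adds the log of a genotype-mixture
#' density (components at the state's allelic fractions, binomial weights in
#' `pfb`, truncated-normal components on \[0,1\]; CN0 is uniform). Missing
#' observations contribute 0, so a fully missing marker is uninformative.
#'
#' @param mlrr_value,baf_value Observations (may be `NA`).
#' @param pfb_value Population B-allele frequency at the marker.
#' @param state Copy number in 0..4.
#' @param params An `hmm_params`.
#' @return Log-likelihood (scalar).
#' @export
emission_loglik <- function(mlrr_value, baf_value, pfb_value, state, params) {
  if (!state %in% params$states) stop_format("unknown state %s", state)
  si <- state + 1L
  ll <- 0
  if (!is.na(mlrr_value)) {
    ll <- dnorm(mlrr_value, params$lrr_mean[si], params$lrr_sd[si], log = TRUE)
  }
  if (isTRUE(params$use_baf) && !is.na(baf_value)) {
    ll <- ll + log(baf_mixture_density(baf_value, pfb_value, state, params$baf_sd))
  }
  ll
}

baf_mixture_density <- function(baf, pfb, state, baf_sd) {
  if (state == 0L) return(1)  # uniform on [0,1]
  centers <- baf_centers[[as.character(state)]]
  nalleles <- state
  w <- dbinom(seq_along(centers) - 1L, nalleles, pfb)
  dens <- vapply(centers, function(c0) {
    dnorm(baf, c0, baf_sd) / (pnorm(1, c0, baf_sd) - pnorm(0, c0, baf_sd))
  }, numeric(1L))
  max(sum(w * dens), 1e-300)
}

# markers x 5 matrix of emission log-likelihoods, vectorized over markers
emission_matrix <- function(lrr, baf, pfb, params) {
  n <- length(lrr)
  em <- matrix(0, n, 5L)
  for (si in 1:5) {
    ok <- !is.na(lrr)
    em[ok, si] <- dnorm(lrr[ok], params$lrr_mean[si], params$lrr_sd[si], log = TRUE)
  }
  if (isTRUE(params$use_baf)) {
    ok <- which(!is.na(baf))
    if (is.null(pfb)) pfb <- rep(0.5, n)
    for (i in ok) {
      for (s in 1:4) {
        em[i, s + 1L] <- em[i, s + 1L] +
          log(baf_mixture_density(baf[i], pfb[i], s, params$baf_sd))
      }
    }
  }
  em
}

log_transition <- function(d, params) {
  rho <- exp(-d / params$decay_distance)
  log(rho * diag(5L) + (1 - rho) * matrix(params$prior, 5L, 5L, byrow = TRUE))
}

# state preference for tie-breaks: CN2 first, then smaller copy number
.state_pref <- c(3L, 1L, 2L, 4L, 5L)

#' Viterbi copy-number path
#'
#' Maximum-a-posteriori state path per chromosome under the distance-decayed
#' transition kernel; the first marker of each chromosome starts from the
#' prior. Ties break toward CN2, then the smaller copy number.
#'
#' @param lrr Numeric (corrected) LRR vector.
#' @param markers Marker map aligned to `lrr`.
#' @param params An `hmm_params`.
#' @param baf Optional BAF vector (used when `params$use_baf`).
#' @param pfb Optional PFB vector.
#' @param emissions Optional precomputed markers x 5 emission log-likelihood
#'   matrix (recomputed from `lrr`/`baf` when `NULL`).
#' @return List with `path` (integer copy numbers per marker) and `loglik`
#'   (log-probability of the path, emissions included).
#' @export
viterbi_path <- function(lrr, markers, params = hmm_params(), baf = NULL, pfb = NULL,
                         emissions = NULL) {
  n <- nrow(markers)
  if (length(lrr) != n) stop_format("viterbi_path: lrr not aligned to markers")
  em <- if (is.null(emissions)) emission_matrix(lrr, baf, pfb, params) else emissions
  path <- integer(n)
  total_ll <- 0
  log_prior <- log(params$prior)
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    if (length(idx) == 0L) stop_format("viterbi_path: empty chromosome %s", ch)
    m <- length(idx)
    pos <- markers$position[idx]
    delta <- log_prior + em[idx[1L], ]
    back <- matrix(NA_integer_, m, 5L)
    if (m > 1L) {
      for (j in 2:m) {
        la <- log_transition(pos[j] - pos[j - 1L], params)
        cand <- la + delta              # cand[s, t], delta recycled by column
        candP <- cand[.state_pref, , drop = FALSE]
        bi <- max.col(t(candP), ties.method = "first")
        back[j, ] <- .state_pref[bi]
        delta <- candP[cbind(bi, 1:5)] + em[idx[j], ]
      }
    }
    lastP <- delta[.state_pref]
    best <- .state_pref[which.max(lastP)]
    total_ll <- total_ll + delta[best]
    states <- integer(m)
    states[m] <- best
    if (m > 1L) for (j in m:2) states[j - 1L] <- back[j, states[j]]
    path[idx] <- states - 1L
  }
  list(path = path, loglik = total_ll)
}

#' Segment a state path into CNV calls
#'
#' Maximal runs of a common non-diploid state become calls spanning the first
#' to last marker of the run. Confidence is the summed per-marker emission
#' log-likelihood advantage of the called state over CN2 (natural log), the
#' usual log-likelihood-ratio confidence for array CNV calls.
#'
#' @param path Integer copy-number vector per marker.
#' @param markers Marker map aligned to `path`.
#' @param emissions Markers x 5 emission log-likelihood matrix (as produced
#'   internally; exposed via [call_cnvs()]).
#' @param sample_id Sample id stamped on calls.
#' @param caller Caller tag (default `"wavecnv-hmm"`).
#' @return CNV call `data.frame`.
#' @export
segment_calls <- function(path, markers, emissions, sample_id, caller = "wavecnv-hmm") {
  n <- nrow(markers)
  if (length(path) != n) stop_format("segment_calls: path not aligned to markers")
  runs <- rle(paste(markers$chrom, path, sep = ":"))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(path[starts] != 2L)
  if (length(keep) == 0L) return(cnv_calls_frame())
  rows <- lapply(keep, function(r) {
    i <- starts[r]:ends[r]
    st <- path[starts[r]]
    conf <- sum(emissions[i, st + 1L] - emissions[i, 3L])
    list(chrom = markers$chrom[starts[r]], start = markers$position[starts[r]],
         end = markers$position[ends[r]], cn = st, n_snps = length(i), conf = conf)
  })
  cnv_calls_frame(sample_id = sample_id,
                  chrom = vapply(rows, `[[`, "", "chrom"),
                  start = vapply(rows, `[[`, 0, "start"),
                  end = vapply(rows, `[[`, 0, "end"),
                  cn = vapply(rows, `[[`, 0L, "cn"),
                  n_snps = vapply(rows, `[[`, 0L, "n_snps"),
                  confidence = vapply(rows, `[[`, 0, "conf"),
                  caller = caller)
}

#' Call CNVs from a (corrected) signal
#'
#' Convenience wrapper: emission matrix + Viterbi + segmentation.
#'
#' @param x A `corrected_signal`, `signal_sample`, or bare numeric LRR
#'   vector.
#' @param markers Marker map.
#' @param params An `hmm_params`.
#' @param pfb Optional PFB vector (BAF emission term).
#' @param sample_id Overrides the sample id carried by `x`.
#' @return CNV call `data.frame`.
#' @export
call_cnvs <- function(x, markers, params = hmm_params(), pfb = NULL,
                      sample_id = NULL) {
  if (inherits(x, "corrected_signal")) {
    lrr <- x$mlrr; baf <- x$baf
    if (is.null(sample_id)) sample_id <- x$sample_id
  } else if (inherits(x, "signal_sample")) {
    lrr <- x$lrr; baf <- x$baf
    if (is.null(sample_id)) sample_id <- x$sample_id
  } else {
    lrr <- as.numeric(x); baf <- NULL
    if (is.null(sample_id)) sample_id <- "sample"
  }
  em <- emission_matrix(lrr, baf, pfb, params)
  vit <- viterbi_path(lrr, markers, params, baf = baf, pfb = pfb, emissions = em)
  segment_calls(vit$path, markers, em, sample_id)
}
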