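# Sample quality control and population B-allele frequency (PFB).
#
# QC is applied per sample: a sample enters reference building or screening
# only if its genotype call rate is >= 0.98 and the standard deviation of its
# autosomal LRR is <= 0.2 (both bounds inclusive). SD uses the n-1 divisor,
# the one convention used throughout the package.

#' Per-sample quality control
#'
#' @param sample A `signal_sample`.
#' @param markers Marker map aligned to `sample` (used to restrict the LRR SD
#'   to autosomes).
#' @param min_call_rate Minimum genotype call rate, inclusive (default 0.98).
#' @param max_lrr_sd Maximum autosomal LRR standard deviation, inclusive
#'   (default 0.2).
#' @return A one-row `data.frame`: `sample_id`, `call_rate`, `lrr_sd`,
#'   `passed`. The call rate is the fraction of markers with a non-missing
#'   BAF and, when a genotype column is present, genotype other than `"NC"`.
#' @export
sample_qc <- function(sample, markers, min_call_rate = 0.98, max_lrr_sd = 0.2) {
  called <- !is.na(sample$baf)
  if (!is.null(sample$genotype)) called <- called & sample$genotype != "NC"
  call_rate <- mean(called)
  auto <- is_autosome(markers$chrom)
  lrr <- sample$lrr[auto]
  lrr <- lrr[!is.na(lrr)]
  if (length(lrr) == 0L) stop_format("sample_qc: no non-missing autosomal LRR values")
  lrr_sd <- if (length(lrr) > 1L) sd(lrr) else 0
  data.frame(sample_id = sample$sample_id, call_rate = call_rate,
             lrr_sd = lrr_sd,
             passed = call_rate >= min_call_rate && lrr_sd <= max_lrr_sd,
             stringsAsFactors = FALSE)
}

#' Marker-level call-rate filter
#'
#' Across-sample call rate per marker, for optional marker pruning when
#' building a reference.
#'
#' @param samples List of `signal_sample`s on a common marker map.
#' @param min_call_rate Minimum across-sample call rate (default 0.98).
#' @return Logical vector, `TRUE` for markers passing.
#' @export
marker_call_rate_filter <- function(samples, min_call_rate = 0.98) {
  if (length(samples) == 0L) stop_format("no samples")
  called <- vapply(samples, function(s) {
    ok <- !is.na(s$baf)
    if (!is.null(s$genotype)) ok <- ok & s$genotype != "NC"
    ok
  }, logical(length(samples[[1L]]$baf)))
  rowMeans(called) >= min_call_rate
}

#' Population B-allele frequency from a cohort
#'
#' Per-marker mean of non-missing BAF across samples, clamped into
#' \[0.01, 0.99\] (the clamp keeps exported tables usable as genotype-mixture
#' priors). Markers observed in no sample get 0.5.
#'
#' @param samples Non-empty list of `signal_sample`s on a common marker map.
#' @return Numeric PFB vector, one value per marker.
#' @export
compute_pfb <- function(samples) {
  if (length(samples) == 0L) stop_format("compute_pfb: need at least one sample")
  n <- length(samples[[1L]]$baf)
  bafs <- vapply(samples, function(s) {
    if (length(s$baf) != n) stop_format("compute_pfb: samples on different marker maps")
    s$baf
  }, numeric(n))
  bafs <- matrix(bafs, nrow = n)
  m <- rowMeans(bafs, na.rm = TRUE)
  m[is.nan(m)] <- 0.5
  pmin(pmax(m, 0.01), 0.99)
}
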