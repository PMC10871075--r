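# Wave correction of test samples.
#
# A test sample is first assigned to the wave cluster it resembles (k-NN over
# the reference cohort's bin features), then its LRR is Z-scored against that
# cluster's frozen per-marker mean and SD, and finally rescaled so the
# corrected signal (mLRR) keeps the sample's original LRR mean and SD. The
# wave — shared by the cluster — cancels in the Z-score; copy-number
# deviations, absent from the cluster reference, survive.

#' Assign a sample to its wave cluster by k-NN
#'
#' Bin features are computed on the model's informative bins (missing bins
#' imputed with the reference cohort's bin means); the label is the majority
#' vote among the `knn_k` nearest reference samples (Euclidean). Vote ties
#' break to the tied label whose centroid is nearest the query, then to the
#' smaller cluster index.
#'
#' @param sample A `signal_sample` aligned to the model's marker map.
#' @param model A `wave_reference`.
#' @param knn_k Number of neighbours (default 5).
#' @return Integer cluster id in `1..model$k`.
#' @export
assign_cluster <- function(sample, model, knn_k = 5L) {
  f <- query_features(sample, model)
  d <- sqrt(rowSums(sweep(model$ref_features, 2L, f)^2))
  nn <- order(d)[seq_len(min(knn_k, length(d)))]
  votes <- tabulate(model$labels[nn], nbins = model$k)
  top <- which(votes == max(votes))
  if (length(top) == 1L) return(top)
  dc <- sqrt(rowSums(sweep(model$centroids[top, , drop = FALSE], 2L, f)^2))
  top[order(dc, top)][1L]
}

query_features <- function(sample, model) {
  if (length(sample$lrr) != nrow(model$markers)) {
    stop_format("sample %s not aligned to the model's marker map", sample$sample_id)
  }
  f <- extract_bin_features(sample, model$markers, model$scheme)[model$scheme$informative]
  miss <- is.na(f)
  f[miss] <- model$feature_means[miss]
  f
}

#' Z-score a sample's LRR against a wave cluster
#'
#' Per marker i, `z_i = (x_i - mean_i) / sd_i` with the cluster's frozen
#' per-marker statistics; missing LRR stays missing. The stored SD floor
#' guarantees finite output.
#'
#' @inheritParams assign_cluster
#' @param cluster_id Cluster index in `1..model$k`.
#' @return Numeric Z-score vector, one value per marker.
#' @export
zscore_normalize <- function(sample, model, cluster_id) {
  if (cluster_id < 1L || cluster_id > model$k) stop_format("invalid cluster_id %s", cluster_id)
  (sample$lrr - model$marker_mean[cluster_id, ]) / model$marker_sd[cluster_id, ]
}

#' Rescale Z-scores to the sample's original LRR moments
#'
#' Over markers where both vectors are present (restricted to `subset` when
#' given): `mlrr = (z - mean(z)) * sd(raw)/sd(z) + mean(raw)`, making the
#' corrected signal's mean and SD equal the raw signal's exactly. If the
#' Z-scores are (numerically) constant the rescale is degenerate: every mlrr
#' is set to `mean(raw)` and the scale is recorded as 0.
#'
#' @param z Z-score vector.
#' @param raw_lrr Raw LRR vector, aligned to `z`.
#' @param subset Optional logical vector of markers eligible for the moment
#'   computation (e.g. autosomes only); the affine map is still applied to
#'   all markers.
#' @return List with `mlrr`, `scale`, `center` (`center = mean(raw)`).
#' @export
rescale_to_mlrr <- function(z, raw_lrr, subset = NULL) {
  if (length(z) != length(raw_lrr)) stop_format("rescale_to_mlrr: length mismatch")
  ok <- !is.na(z) & !is.na(raw_lrr)
  if (!is.null(subset)) ok <- ok & subset
  if (sum(ok) < 2L) stop_format("rescale_to_mlrr: need >= 2 non-missing pairs")
  mz <- mean(z[ok]); sz <- sd(z[ok])
  mr <- mean(raw_lrr[ok]); sr <- sd(raw_lrr[ok])
  if (sz < 1e-12) {
    mlrr <- ifelse(is.na(raw_lrr), NA_real_, mr)
    return(list(mlrr = mlrr, scale = 0, center = mr))
  }
  scale <- sr / sz
  mlrr <- (z - mz) * scale + mr
  mlrr[is.na(raw_lrr)] <- NA_real_
  list(mlrr = mlrr, scale = scale, center = mr)
}

#' Wave-correct a sample end to end
#'
#' Composition of [assign_cluster()], [zscore_normalize()] and
#' [rescale_to_mlrr()]. BAF passes through untouched. Moment matching uses
#' autosomal markers (the clusters are fitted on autosomes); the affine map
#' is applied genome-wide.
#'
#' @inheritParams assign_cluster
#' @param cluster_id Optional fixed cluster id, skipping the k-NN step.
#' @return An object of class `corrected_signal`: `sample_id`, `cluster_id`,
#'   `z`, `mlrr`, `scale`, `center`, `baf`, `genotype`.
#' @export
correct_sample <- function(sample, model, knn_k = 5L, cluster_id = NULL) {
  if (is.null(cluster_id)) cluster_id <- assign_cluster(sample, model, knn_k = knn_k)
  z <- zscore_normalize(sample, model, cluster_id)
  auto <- is_autosome(model$markers$chrom)
  rs <- rescale_to_mlrr(z, sample$lrr, subset = auto)
  structure(list(sample_id = sample$sample_id, cluster_id = cluster_id,
                 z = z, mlrr = rs$mlrr, scale = rs$scale, center = rs$center,
                 baf = sample$baf, genotype = sample$genotype),
            class = "corrected_signal")
}

#' @export
print.corrected_signal <- function(x, ...) {
  cat(sprintf("<corrected_signal> %s: cluster %d, %d markers, scale %.4g, center %.4g\n",
              x$sample_id, x$cluster_id, length(x$mlrr), x$scale, x$center))
  invisible(x)
}

#' Corrected signal as a `signal_sample`
#'
#' Repackages the mLRR as the LRR slot so the corrected sample can be written
#' with [write_signal_table()] and fed to any downstream caller as a drop-in
#' signal file.
#'
#' @param corrected A `corrected_signal`.
#' @return A `signal_sample` whose `lrr` holds the mLRR.
#' @export
as_signal_sample <- function(corrected) {
  signal_sample(corrected$sample_id, lrr = corrected$mlrr, baf = corrected$baf,
                genotype = corrected$genotype)
}
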