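# The wave-pattern reference model.
#
# Genomic waves are chromosome-scale baseline drifts in LRR that recur across
# samples in a handful of shared patterns. The reference is fitted on a
# cohort: autosomes are tiled into 1 Mb bins, each sample is summarized by
# its per-bin mean LRR, uninformative bins are dropped, the number of wave
# patterns k is chosen by the elbow of the within-cluster distance curve over
# k = 2..20, samples are k-means clustered, and per-cluster per-marker LRR
# means and SDs are frozen for later Z-scoring of test samples.

#' Tile autosomes into fixed-size bins
#'
#' Each autosome present in the marker map is tiled from position 1 to the
#' bin containing its last marker; the final partial bin is kept at full
#' nominal width. Sex chromosomes are excluded (wave features are autosomal).
#'
#' @param markers Marker map.
#' @param bin_size Bin width in base pairs (default 1e6).
#' @return An object of class `bin_scheme`: list with `bin_size`, `bins`
#'   (data.frame chrom/start/end) and `informative` (logical mask, `NULL`
#'   until [select_informative_bins()] has run).
#' @export
bin_genome <- function(markers, bin_size = 1e6) {
  if (bin_size < 1) stop_format("bin_size must be >= 1")
  auto <- markers[is_autosome(markers$chrom), , drop = FALSE]
  chroms <- unique(auto$chrom)
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    last <- max(auto$position[auto$chrom == ch])
    n <- ceiling(last / bin_size)
    data.frame(chrom = ch, start = (seq_len(n) - 1) * bin_size + 1,
               end = seq_len(n) * bin_size, stringsAsFactors = FALSE)
  }))
  if (is.null(bins)) bins <- data.frame(chrom = character(), start = numeric(), end = numeric())
  structure(list(bin_size = bin_size, bins = bins, informative = NULL),
            class = "bin_scheme")
}

# Bin row index for every marker (NA for markers outside the scheme).
bin_index <- function(markers, scheme) {
  idx <- rep(NA_integer_, nrow(markers))
  for (ch in unique(scheme$bins$chrom)) {
    rows <- which(scheme$bins$chrom == ch)
    sel <- markers$chrom == ch
    j <- ceiling(markers$position[sel] / scheme$bin_size)
    j[j > length(rows)] <- NA_integer_
    idx[sel] <- rows[j]
  }
  idx
}

#' Per-bin mean LRR features for one sample
#'
#' @param sample A `signal_sample`.
#' @param markers Marker map the sample is aligned to.
#' @param scheme A `bin_scheme` from [bin_genome()].
#' @return Numeric vector, one value per bin (all bins, not only informative
#'   ones); bins with no non-missing LRR are `NA`.
#' @export
extract_bin_features <- function(sample, markers, scheme) {
  idx <- bin_index(markers, scheme)
  ok <- !is.na(idx) & !is.na(sample$lrr)
  out <- rep(NA_real_, nrow(scheme$bins))
  if (any(ok)) {
    sums <- rowsum(sample$lrr[ok], idx[ok])
    cnts <- rowsum(rep(1, sum(ok)), idx[ok])
    out[as.integer(rownames(sums))] <- sums / cnts
  }
  out
}

#' Bin-feature matrix for a cohort
#'
#' @param samples List of `signal_sample`s on one marker map.
#' @inheritParams extract_bin_features
#' @return Matrix, samples in rows, bins in columns.
#' @export
bin_feature_matrix <- function(samples, markers, scheme) {
  f <- t(vapply(samples, extract_bin_features, numeric(nrow(scheme$bins)),
                markers = markers, scheme = scheme))
  rownames(f) <- vapply(samples, `[[`, "", "sample_id")
  f
}

#' Select informative bins
#'
#' A bin is informative when it has markers in every sample and its
#' across-sample SD of per-bin mean LRR exceeds `sd_cutoff`; bins at or below
#' the cutoff carry no wave signal (flat everywhere) and are dropped.
#'
#' @param features Bin-feature matrix (samples x bins), >= 2 samples.
#' @param sd_cutoff Exclusive lower bound on the across-sample SD
#'   (default 0.05; a bin with SD exactly 0.05 is excluded).
#' @return Logical mask over bins.
#' @export
select_informative_bins <- function(features, sd_cutoff = 0.05) {
  if (nrow(features) < 2L) stop_format("select_informative_bins: need >= 2 samples")
  has_all <- colSums(is.na(features)) == 0L
  sds <- apply(features, 2L, sd, na.rm = TRUE)
  has_all & !is.na(sds) & sds > sd_cutoff
}

# column-mean imputation for residual missing values
impute_col_means <- function(x, means = colMeans(x, na.rm = TRUE)) {
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- means[nas[, 2L]]
  x
}

# kmeans++ seeding: first centre uniform, subsequent centres drawn with
# probability proportional to squared distance from the nearest chosen
# centre. Makes restarts far less likely to merge two distant clusters.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - x[rep(idx[1L], n), , drop = FALSE])^2)
  if (k > 1L) for (j in 2:k) {
    if (all(d2 <= 0)) {
      idx[j] <- sample.int(n, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - x[rep(idx[j], n), , drop = FALSE])^2))
  }
  x[idx, , drop = FALSE]
}

#' k-means with unsquared-distance scoring
#'
#' Lloyd's algorithm (via [stats::kmeans()]) with `nstart` kmeans++-seeded
#' restarts; the restart kept is the one minimizing the sum of plain
#' (unsquared) Euclidean point-to-centroid distances, which is also the
#' score reported — the quantity the elbow curve is built from.
#'
#' @param features Numeric matrix (samples x features), no missing values
#'   (residual `NA`s are mean-imputed).
#' @param k Number of clusters, `1 <= k <= nrow(features)`.
#' @param seed Integer seed controlling all restarts.
#' @param nstart Number of random restarts (default 10).
#' @param warm_centers Optional k x ncol matrix of starting centres; when
#'   given, the assignment it induces and the Lloyd run it seeds join the
#'   candidate pool ([select_k_elbow()] chains fits this way so the
#'   selection curve is non-increasing in k).
#' @return List with `labels` (integer vector in 1..k), `centroids`
#'   (k x ncol matrix) and `score`.
#' @export
fit_kmeans <- function(features, k, seed = 1L, nstart = 10L, warm_centers = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k > n) stop_format("fit_kmeans: k (%d) exceeds sample count (%d)", k, n)
  features <- impute_col_means(features)
  if (k == n) {
    return(list(labels = seq_len(n), centroids = features, score = 0))
  }
  nearest_assignment <- function(centroids) {
    d2 <- vapply(seq_len(nrow(centroids)), function(c0) {
      rowSums((features - centroids[rep(c0, n), , drop = FALSE])^2)
    }, numeric(n))
    d2 <- matrix(d2, nrow = n)
    labels <- max.col(-d2, ties.method = "first")
    list(labels = labels, centroids = centroids,
         score = sum(sqrt(d2[cbind(seq_len(n), labels)])))
  }
  score_of <- function(labels, centroids) {
    sum(sqrt(rowSums((features - centroids[labels, , drop = FALSE])^2)))
  }
  if (k == 1L) {
    ctr <- matrix(colMeans(features), 1L)
    return(list(labels = rep(1L, n), centroids = ctr,
                score = score_of(rep(1L, n), ctr)))
  }
  take <- function(best, cand) {
    if (is.null(best) || cand$score < best$score) cand else best
  }
  set.seed(seed)
  best <- NULL
  if (!is.null(warm_centers)) {
    best <- take(best, nearest_assignment(warm_centers))
    km <- tryCatch(
      suppressWarnings(kmeans(features, centers = warm_centers,
                              iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km)) {
      best <- take(best, list(labels = as.integer(km$cluster),
                              centroids = unname(km$centers),
                              score = score_of(km$cluster, km$centers)))
    }
  }
  attempts <- 0L
  done <- 0L
  while (done < nstart && attempts < 10L * nstart) {
    attempts <- attempts + 1L
    km <- tryCatch(
      suppressWarnings(kmeans(features, centers = kmeanspp_centers(features, k),
                              iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL)  # empty cluster / duplicate centres: redraw
    if (is.null(km)) next
    done <- done + 1L
    best <- take(best, list(labels = as.integer(km$cluster),
                            centroids = unname(km$centers),
                            score = score_of(km$cluster, km$centers)))
  }
  if (is.null(best)) stop_format("fit_kmeans: no restart produced a valid clustering")
  best
}

#' Choose k by the elbow of the within-cluster distance curve
#'
#' Fits k-means for every k in `k_min..k_max` (and k = 1, used to pad the
#' curve's left edge), then picks the k maximizing the discrete second
#' difference `score(k-1) - 2*score(k) + score(k+1)` over interior k — the
#' point where the curve's improvement collapses. Ties break to the smallest
#' k.
#'
#' @inheritParams fit_kmeans
#' @param k_min,k_max Search range (defaults 2 and 20).
#' @return List with `k` (selected) and `curve` (data.frame `k`, `score`;
#'   includes the k = 1 padding row).
#' @export
select_k_elbow <- function(features, k_min = 2L, k_max = 20L, seed = 1L, nstart = 10L) {
  if (k_max < k_min) stop_format("select_k_elbow: k_max < k_min")
  if (k_max > nrow(features)) stop_format("select_k_elbow: k_max exceeds sample count")
  if (k_min == k_max) {
    fit <- fit_kmeans(features, k_min, seed = seed, nstart = nstart)
    return(list(k = k_min, curve = data.frame(k = k_min, score = fit$score)))
  }
  features <- impute_col_means(as.matrix(features))
  ks <- unique(c(1L, seq.int(k_min, k_max)))
  scores <- numeric(length(ks))
  prev <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    warm <- if (is.null(prev)) NULL else grow_centers(features, prev$centroids, k)
    fit <- fit_kmeans(features, k, seed = seed + k, nstart = nstart,
                      warm_centers = warm)
    scores[i] <- fit$score
    prev <- fit
  }
  curve <- data.frame(k = ks, score = scores)
  list(k = elbow_pick(curve, k_min, k_max), curve = curve)
}

# Grow a centre matrix to k rows by repeatedly adding the point farthest
# from its nearest centre. The assignment induced by the grown centres can
# only improve on the smaller fit, which keeps the elbow curve monotone.
grow_centers <- function(features, centroids, k) {
  while (nrow(centroids) < k) {
    d2 <- vapply(seq_len(nrow(centroids)), function(c0) {
      rowSums((features - centroids[rep(c0, nrow(features)), , drop = FALSE])^2)
    }, numeric(nrow(features)))
    nearest <- apply(matrix(d2, nrow = nrow(features)), 1L, min)
    centroids <- rbind(centroids, features[which.max(nearest), , drop = FALSE])
  }
  centroids[seq_len(k), , drop = FALSE]
}

# Elbow rule on a fitted curve: maximal second difference
# score(k-1) - 2 score(k) + score(k+1) over interior k, the left edge padded
# with the k = 1 score; ties break to the smallest k.
elbow_pick <- function(curve, k_min, k_max) {
  sc_at <- function(k) {
    if (k < k_min) curve$score[curve$k == 1L] else curve$score[curve$k == k]
  }
  interior <- seq.int(k_min, k_max - 1L)
  d2 <- vapply(interior, function(k) sc_at(k - 1L) - 2 * sc_at(k) + sc_at(k + 1L),
               numeric(1L))
  interior[which.max(d2)]
}

#' Fit a genomic-wave reference model
#'
#' The central fit of the package. Builds the 1 Mb bin scheme on autosomes,
#' summarizes every cohort sample by its per-bin mean LRR, drops
#' uninformative bins, chooses the number of wave patterns by the elbow
#' method (unless `k` is given), runs k-means, and freezes per-cluster
#' per-marker LRR means and SDs — the statistics later used to Z-score and
#' wave-correct test samples. The model never updates after fitting.
#'
#' @param samples List of QC-passing `signal_sample`s sharing `markers`.
#' @param markers Marker map for the cohort.
#' @param bin_size Bin width in bp (default 1e6).
#' @param k Number of clusters; `NULL` (default) selects it by
#'   [select_k_elbow()] over `k_min..k_max`.
#' @param k_min,k_max Elbow search range (defaults 2, 20).
#' @param sd_floor Lower bound applied to every stored per-marker SD so
#'   Z-scores stay finite (default 1e-4).
#' @param nstart k-means restarts (default 10).
#' @param seed Integer seed; the fit is bit-for-bit reproducible given
#'   (inputs, seed).
#' @return An object of class `wave_reference` with components `k`,
#'   `scheme`, `centroids`, `labels`, `cluster_sizes`, `ref_features`
#'   (informative-bin features of the cohort, imputed), `marker_mean` /
#'   `marker_sd` (k x n_marker matrices), `curve` (elbow curve when k was
#'   selected), `markers`, `sd_floor`, `seed`.
#' @seealso [predict.wave_reference()], [correct_sample()],
#'   [write_reference()]
#' @export
wave_reference <- function(samples, markers, bin_size = 1e6, k = NULL,
                           k_min = 2L, k_max = 20L, sd_floor = 1e-4,
                           nstart = 10L, seed = 1L) {
  n <- length(samples)
  if (n < 2L) stop_format("wave_reference: need >= 2 samples")
  nm <- nrow(markers)
  for (s in samples) {
    if (length(s$lrr) != nm) stop_format("wave_reference: sample %s not aligned to marker map", s$sample_id)
  }
  scheme <- bin_genome(markers, bin_size)
  feats_all <- bin_feature_matrix(samples, markers, scheme)
  mask <- select_informative_bins(feats_all)
  if (!any(mask)) stop_format("wave_reference: no informative bins")
  scheme$informative <- mask
  feats <- impute_col_means(feats_all[, mask, drop = FALSE])
  curve <- NULL
  if (is.null(k)) {
    sel <- select_k_elbow(feats, k_min = k_min, k_max = min(k_max, n),
                          seed = seed, nstart = nstart)
    k <- sel$k
    curve <- sel$curve
  }
  km <- fit_kmeans(feats, k, seed = seed, nstart = nstart)
  sizes <- tabulate(km$labels, nbins = k)
  if (any(sizes < 2L)) {
    stop_format("wave_reference: cluster with < 2 members (sizes: %s)",
                paste(sizes, collapse = ", "))
  }
  lrr_mat <- vapply(samples, `[[`, numeric(nm), "lrr")  # markers x samples
  marker_mean <- matrix(NA_real_, k, nm)
  marker_sd <- matrix(NA_real_, k, nm)
  for (cl in seq_len(k)) {
    sub <- lrr_mat[, km$labels == cl, drop = FALSE]
    cnt <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[cnt == 0L] <- 0
    ss <- rowSums(sub^2, na.rm = TRUE) - cnt * mu^2
    sdv <- sqrt(pmax(ss, 0) / pmax(cnt - 1L, 1L))
    sdv[cnt < 2L] <- 0
    marker_mean[cl, ] <- mu
    marker_sd[cl, ] <- pmax(sdv, sd_floor)
  }
  structure(list(k = k, scheme = scheme, centroids = km$centroids,
                 labels = km$labels, cluster_sizes = sizes,
                 ref_features = feats,
                 feature_means = colMeans(feats),
                 marker_mean = marker_mean, marker_sd = marker_sd,
                 markers = markers, sd_floor = sd_floor, seed = seed,
                 curve = curve, n_samples = n,
                 version = as.character(utils::packageVersion("wavecnv"))),
            class = "wave_reference")
}

#' @export
print.wave_reference <- function(x, ...) {
  cat(sprintf("Genomic-wave reference model (wavecnv %s)\n", x$version))
  cat(sprintf("  cohort: %d samples on %d markers\n", x$n_samples, nrow(x$markers)))
  cat(sprintf("  bins: %d of %d informative (%.0f kb bins)\n",
              sum(x$scheme$informative), nrow(x$scheme$bins),
              x$scheme$bin_size / 1e3))
  cat(sprintf("  wave clusters: k = %d%s; sizes %s\n", x$k,
              if (is.null(x$curve)) " (fixed)" else " (elbow-selected)",
              paste(x$cluster_sizes, collapse = ", ")))
  invisible(x)
}

#' @export
summary.wave_reference <- function(object, ...) {
  amp <- apply(object$centroids, 1L, function(v) max(abs(v)))
  out <- list(model = object,
              cluster = data.frame(cluster = seq_len(object$k),
                                   size = object$cluster_sizes,
                                   centroid_peak_lrr = amp),
              curve = object$curve)
  class(out) <- "summary.wave_reference"
  out
}

#' @export
print.summary.wave_reference <- function(x, ...) {
  print(x$model)
  cat("\nPer-cluster summary:\n")
  print(x$cluster, row.names = FALSE)
  if (!is.null(x$curve)) {
    cat("\nElbow curve (within-cluster distance score by k):\n")
    print(x$curve, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.wave_reference <- function(object, ...) object$centroids

#' Plot wave-cluster centroids
#'
#' One line per cluster across informative bins, in genome order: the shape
#' of each wave pattern the reference captured.
#'
#' @param x A `wave_reference`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.wave_reference <- function(x, ...) {
  graphics::matplot(t(x$centroids), type = "l", lty = 1L,
                    xlab = "informative bin (genome order)",
                    ylab = "mean LRR", main = sprintf("%d wave patterns", x$k), ...)
  invisible(x)
}

#' Predict method: cluster assignment or wave correction
#'
#' @param object A `wave_reference`.
#' @param newdata A `signal_sample` (or list of them) aligned to the model's
#'   marker map.
#' @param type `"cluster"` for the k-NN wave-cluster assignment, `"mlrr"`
#'   for the full corrected signal (a `corrected_signal` object).
#' @param knn_k Neighbours used for classification (default 5).
#' @param ... Unused.
#' @return For `"cluster"`, an integer (vector); for `"mlrr"`, a
#'   `corrected_signal` or list of them.
#' @export
predict.wave_reference <- function(object, newdata, type = c("cluster", "mlrr"),
                                   knn_k = 5L, ...) {
  type <- match.arg(type)
  one <- function(s) {
    if (type == "cluster") assign_cluster(s, object, knn_k = knn_k)
    else correct_sample(s, object, knn_k = knn_k)
  }
  if (inherits(newdata, "signal_sample")) return(one(newdata))
  res <- lapply(newdata, one)
  if (type == "cluster") unlist(res) else res
}
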