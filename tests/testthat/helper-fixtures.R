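# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; heavier cohorts are cached per test run.

# small deterministic marker map: n_chrom autosomes, m markers each, evenly
# spaced over len bp
tiny_map <- function(n_chrom = 2L, m = 10L, len = 1e6) {
  pos <- round(seq(1, len, length.out = m))
  marker_map(marker = paste0("m", rep(seq_len(n_chrom), each = m), "_", seq_len(m)),
             chrom = rep(as.character(seq_len(n_chrom)), each = m),
             position = rep(pos, n_chrom))
}

# quick CNV-call table builder
mk_calls <- function(chrom, start, end, cn, n_snps = 20L, confidence = 100,
                     sample_id = "s1", caller = "test") {
  wavecnv:::cnv_calls_frame(sample_id = sample_id, chrom = chrom, start = start,
                            end = end, cn = cn, n_snps = n_snps,
                            confidence = confidence, caller = caller)
}

# hand-built one-bin wave_reference: features are scalars (one informative
# bin), markers = bin_width-worth of positions on chromosome 1
scalar_model <- function(features, labels, sd_floor = 1e-4) {
  k <- max(labels)
  markers <- marker_map(c("a", "b"), c("1", "1"), c(1L, 2L))
  scheme <- structure(list(bin_size = 1e6,
                           bins = data.frame(chrom = "1", start = 1, end = 1e6),
                           informative = TRUE), class = "bin_scheme")
  feats <- matrix(features, ncol = 1L)
  rownames(feats) <- paste0("r", seq_along(features))
  centroids <- matrix(vapply(seq_len(k), function(c) mean(features[labels == c]),
                             numeric(1L)), ncol = 1L)
  structure(list(k = k, scheme = scheme, centroids = centroids,
                 labels = as.integer(labels),
                 cluster_sizes = tabulate(labels, k),
                 ref_features = feats, feature_means = colMeans(feats),
                 marker_mean = matrix(0, k, 2L),
                 marker_sd = matrix(1, k, 2L),
                 markers = markers, sd_floor = sd_floor, seed = 1L,
                 curve = NULL, n_samples = length(features), version = "test"),
            class = "wave_reference")
}

# signal_sample whose single informative bin mean equals x
scalar_query <- function(x) signal_sample("q", lrr = c(x, x), baf = c(0.5, 0.5))

# independent Viterbi oracle: exhaustive enumeration over all 5^n paths,
# with emissions and transitions computed from their definitions
viterbi_brute <- function(lrr, pos, params) {
  n <- length(lrr)
  em <- sapply(1:5, function(si) {
    ifelse(is.na(lrr), 0, dnorm(lrr, params$lrr_mean[si], params$lrr_sd[si], log = TRUE))
  })
  em <- matrix(em, nrow = n)
  paths <- as.matrix(expand.grid(rep(list(1:5), n)))
  lp <- log(params$prior)[paths[, 1L]] + em[cbind(1L, paths[, 1L])]
  if (n > 1L) for (j in 2:n) {
    rho <- exp(-(pos[j] - pos[j - 1L]) / params$decay_distance)
    same <- paths[, j] == paths[, j - 1L]
    lp <- lp + log(rho * same + (1 - rho) * params$prior[paths[, j]]) +
      em[cbind(j, paths[, j])]
  }
  best <- which.max(lp)
  list(path = unname(paths[best, ]) - 1L, loglik = max(lp))
}

# independent interval-union oracle on small coordinates: mark base pairs
union_len_brute <- function(start, end, limit) {
  covered <- logical(limit)
  for (i in seq_along(start)) covered[start[i]:end[i]] <- TRUE
  sum(covered)
}

# cached cohorts so expensive simulations run once per suite
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# compact study-scale cohort + fitted reference shared by correction tests:
# 6 archetypes x 30 samples on a 8-chromosome genome
small_reference <- function() {
  cached("small_reference", {
    cfg <- sim_config(n_chromosomes = 8L, markers_per_chromosome = 300L,
                      lrr_noise_sd = 0.1, seed = 301L)
    co <- simulate_cohort(cfg, per_archetype_n = 30L)
    model <- wave_reference(co$samples, co$markers, seed = 302L)
    list(cfg = cfg, cohort = co, model = model)
  })
}
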