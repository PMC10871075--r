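# Synthetic SNP-array cohorts with planted wave patterns and injected CNVs.
#
# The generator emulates the structure the wave-correction method exploits:
# a small number of genome-wide smooth wave archetypes shared within
# clusters, a sample-specific wave amplitude, marker-level Gaussian LRR
# noise, genotype-mixture BAF per copy-number state, and CNV segments with
# recorded ground truth. The genome is scaled down (22 chromosomes of 10 Mb,
# 500 markers each by default) so the full pipeline runs in seconds; real
# dimensions are configuration options.

#' Simulation configuration
#'
#' @param n_chromosomes Number of autosomes (default 22).
#' @param chromosome_length Length of each chromosome in bp (default 1e7).
#' @param markers_per_chromosome Markers per chromosome (default 500).
#' @param n_archetypes Number of planted wave patterns (default 6, the
#'   typical count of distinct wave patterns in a clinical reference
#'   cohort).
#' @param wave_amplitude Peak absolute wave LRR value A (default 0.2).
#' @param amplitude_jitter SD of the per-sample wave amplitude factor around
#'   1 (default 0.1).
#' @param lrr_noise_sd Marker-level Gaussian LRR noise SD (default 0.15).
#' @param baf_noise_sd BAF noise SD around genotype fractions (default 0.03).
#' @param harmonics Sinusoid components per chromosome per archetype
#'   (default 3; periods 3-20 Mb).
#' @param seed Integer seed; everything drawn from the config is
#'   reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 22L, chromosome_length = 1e7,
                       markers_per_chromosome = 500L, n_archetypes = 6L,
                       wave_amplitude = 0.2, amplitude_jitter = 0.1,
                       lrr_noise_sd = 0.15, baf_noise_sd = 0.03,
                       harmonics = 3L, seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              markers_per_chromosome = as.integer(markers_per_chromosome),
              n_archetypes = as.integer(n_archetypes),
              wave_amplitude = wave_amplitude,
              amplitude_jitter = amplitude_jitter,
              lrr_noise_sd = lrr_noise_sd, baf_noise_sd = baf_noise_sd,
              harmonics = as.integer(harmonics), seed = as.integer(seed))
  if (any(unlist(cfg[c("n_chromosomes", "chromosome_length", "markers_per_chromosome",
                       "n_archetypes", "harmonics")]) < 1)) {
    stop_format("sim_config: counts and lengths must be >= 1")
  }
  if (cfg$markers_per_chromosome > cfg$chromosome_length) {
    stop_format("sim_config: more markers than positions on a chromosome")
  }
  structure(cfg, class = "sim_config")
}

# per-state LRR shift used when injecting CNVs; CN2 sits at 0
.state_shift <- c(`0` = -3.0, `1` = -0.66, `2` = 0, `3` = 0.40, `4` = 0.68)

#' Generate a synthetic marker map
#'
#' Marker positions are drawn uniformly without replacement per chromosome
#' and sorted; deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A marker map `data.frame`.
#' @export
make_marker_map <- function(config) {
  set.seed(config$seed)
  chroms <- as.character(seq_len(config$n_chromosomes))
  pieces <- lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chromosome_length, config$markers_per_chromosome))
    data.frame(marker = sprintf("snp%s_%05d", ch, seq_along(pos)),
               chrom = ch, position = pos, stringsAsFactors = FALSE)
  })
  mm <- do.call(rbind, pieces)
  marker_map(mm$marker, mm$chrom, mm$position)
}

#' Generate wave archetypes
#'
#' Each archetype is, per chromosome, a sum of `harmonics` sinusoids with
#' periods drawn from 3-20 Mb, then rescaled so the maximum absolute value
#' over all markers equals `wave_amplitude`. Archetypes are redrawn until
#' every pairwise Pearson correlation is below 0.5, so the planted patterns
#' are genuinely distinct.
#'
#' @param markers Marker map (typically from [make_marker_map()]).
#' @param config A `sim_config`.
#' @return Matrix, one row per archetype, one column per marker.
#' @export
make_wave_archetypes <- function(markers, config) {
  set.seed(config$seed + 1L)
  draw_one <- function() {
    w <- numeric(nrow(markers))
    for (ch in unique(markers$chrom)) {
      sel <- markers$chrom == ch
      p <- markers$position[sel]
      v <- 0
      for (h in seq_len(config$harmonics)) {
        period <- runif(1L, 3e6, 2e7)
        amp <- runif(1L, 0.5, 1)
        phase <- runif(1L, 0, 2 * pi)
        v <- v + amp * sin(2 * pi * p / period + phase)
      }
      w[sel] <- v
    }
    w * (config$wave_amplitude / max(abs(w)))
  }
  arch <- matrix(NA_real_, config$n_archetypes, nrow(markers))
  arch[1L, ] <- draw_one()
  if (config$n_archetypes > 1L) {
    for (a in 2:config$n_archetypes) {
      ok <- FALSE
      for (try in seq_len(100L)) {
        cand <- draw_one()
        cc <- suppressWarnings(cor(cand, t(arch[seq_len(a - 1L), , drop = FALSE])))
        cc[is.na(cc)] <- 0  # flat (zero-amplitude) archetypes are uncorrelated
        if (all(cc < 0.5)) {
          arch[a, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop_format("make_wave_archetypes: could not decorrelate archetype %d in 100 attempts", a)
    }
  }
  arch
}

# cohort-level population B-allele frequencies, one per marker
make_pop_freq <- function(n_markers, seed) {
  set.seed(seed + 2L)
  runif(n_markers, 0.05, 0.95)
}

#' Simulate one sample
#'
#' `lrr_i = shift(state_i) + s * w_i + eps_i` with amplitude factor
#' `s ~ N(1, amplitude_jitter)` and `eps ~ N(0, lrr_noise_sd)`; state shifts
#' are the canonical per-copy-number LRR means (0 at CN2). Genotypes are
#' drawn per marker as Binomial(copy number, population B frequency); BAF is
#' the B-allele fraction plus noise, clipped to \[0, 1\] (CN0: uniform).
#'
#' @param markers Marker map.
#' @param archetype Wave vector for the sample's cluster (one row of
#'   [make_wave_archetypes()]).
#' @param config A `sim_config`.
#' @param cnvs Optional data.frame (chrom, start, end, cn) of CNVs to
#'   inject; must lie within chromosome bounds and not overlap.
#' @param sample_id Sample identifier.
#' @param pop_freq Per-marker population B-allele frequencies; defaults to
#'   the cohort-level frequencies derived from `config$seed`.
#' @param seed Optional seed; when `NULL` the ambient RNG stream is used
#'   (as [simulate_cohort()] does).
#' @return List with `sample` (a `signal_sample`) and `truth` (list:
#'   `sample_id`, `archetype_id` (`NA` here), `amplitude_factor`, `cnvs`).
#' @export
simulate_sample <- function(markers, archetype, config, cnvs = NULL,
                            sample_id = "sim", pop_freq = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(markers)
  if (length(archetype) != n) stop_format("archetype not aligned to markers")
  if (is.null(pop_freq)) pop_freq <- make_pop_freq(n, config$seed)
  state <- rep(2L, n)
  if (!is.null(cnvs) && nrow(cnvs)) {
    cnvs$chrom <- norm_chrom(cnvs$chrom)
    for (i in seq_len(nrow(cnvs))) {
      if (cnvs$start[i] < 1 || cnvs$end[i] > config$chromosome_length) {
        stop_format("injected CNV outside chromosome bounds")
      }
      sel <- markers$chrom == cnvs$chrom[i] &
        markers$position >= cnvs$start[i] & markers$position <= cnvs$end[i]
      state[sel] <- as.integer(cnvs$cn[i])
    }
  }
  s_amp <- rnorm(1L, 1, config$amplitude_jitter)
  lrr <- .state_shift[as.character(state)] + s_amp * archetype +
    rnorm(n, 0, config$lrr_noise_sd)
  b_count <- rbinom(n, state, pop_freq)
  frac <- ifelse(state == 0L, runif(n), b_count / pmax(state, 1L))
  baf <- pmin(pmax(frac + rnorm(n, 0, config$baf_noise_sd), 0), 1)
  geno <- ifelse(state == 2L, c("AA", "AB", "BB")[b_count + 1L], "NC")
  truth <- list(sample_id = sample_id, archetype_id = NA_integer_,
                amplitude_factor = s_amp,
                cnvs = if (is.null(cnvs)) cnvs_empty() else
                  data.frame(chrom = cnvs$chrom, start = cnvs$start,
                             end = cnvs$end, cn = as.integer(cnvs$cn)))
  list(sample = signal_sample(sample_id, lrr = unname(lrr), baf = baf, genotype = geno),
       truth = truth)
}

cnvs_empty <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             cn = integer(), stringsAsFactors = FALSE)
}

#' Simulate a cohort
#'
#' `per_archetype_n` samples per planted wave pattern, byte-reproducible
#' from `config$seed`. CNVs are injected per `cnv_spec`, a data.frame with
#' columns `sample` (index into the cohort), `chrom`, `start`, `end`, `cn`.
#'
#' @param config A `sim_config`.
#' @param per_archetype_n Samples per archetype.
#' @param cnv_spec Optional CNV injection table (see above).
#' @return List with `markers`, `samples` (list of `signal_sample`),
#'   `truths` (list, one per sample), `archetypes`, `pop_freq`, `config`.
#' @export
simulate_cohort <- function(config, per_archetype_n, cnv_spec = NULL) {
  markers <- make_marker_map(config)
  arch <- make_wave_archetypes(markers, config)
  pop_freq <- make_pop_freq(nrow(markers), config$seed)
  set.seed(config$seed + 3L)
  n_total <- config$n_archetypes * per_archetype_n
  samples <- vector("list", n_total)
  truths <- vector("list", n_total)
  i <- 0L
  for (a in seq_len(config$n_archetypes)) {
    for (j in seq_len(per_archetype_n)) {
      i <- i + 1L
      sid <- sprintf("S%04d_A%d", i, a)
      cnvs <- NULL
      if (!is.null(cnv_spec) && nrow(cnv_spec)) {
        rows <- cnv_spec[cnv_spec$sample == i, c("chrom", "start", "end", "cn"), drop = FALSE]
        if (nrow(rows)) cnvs <- rows
      }
      sim <- simulate_sample(markers, arch[a, ], config, cnvs = cnvs,
                             sample_id = sid, pop_freq = pop_freq, seed = NULL)
      sim$truth$archetype_id <- a
      samples[[i]] <- sim$sample
      truths[[i]] <- sim$truth
    }
  }
  list(markers = markers, samples = samples, truths = truths,
       archetypes = arch, pop_freq = pop_freq, config = config)
}
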