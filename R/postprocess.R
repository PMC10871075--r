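# Post-processing of CNV calls and screening against the disorder database:
# gap merging (< 200 kb), threshold filtering (> 10 SNPs, > 50 kb,
# confidence > 50; all strict), two-caller union, overlap with known
# disorder regions, and the per-sample detected/normal verdict.

call_direction <- function(cn) ifelse(cn < 2L, "del", "dup")

#' Merge adjacent same-direction calls
#'
#' Calls on the same chromosome with the same direction (deletion: cn < 2;
#' duplication: cn > 2) are merged when the intervening gap
#' (`next.start - prev.end - 1`) is strictly smaller than `max_gap`. The
#' merged call spans the union, sums marker counts and confidences, and
#' takes the copy number of the longer constituent. Iterated to fixpoint;
#' merging is idempotent.
#'
#' @param calls CNV call data.frame for a single sample.
#' @param max_gap Merge threshold in bp (default 200000; a gap of exactly
#'   200000 is not merged).
#' @return Merged call data.frame.
#' @export
merge_adjacent_calls <- function(calls, max_gap = 200000) {
  validate_calls(calls)
  if (nrow(calls) <= 1L) return(calls)
  if (length(unique(calls$sample_id)) > 1L) {
    stop_format("merge_adjacent_calls: calls from more than one sample")
  }
  dir <- call_direction(calls$cn)
  out <- list()
  for (grp in split(seq_len(nrow(calls)), paste(calls$chrom, dir))) {
    g <- calls[grp, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    cur <- g[1L, , drop = FALSE]
    for (i in seq_len(nrow(g))[-1L]) {
      nxt <- g[i, , drop = FALSE]
      gap <- nxt$start - cur$end - 1
      if (gap < max_gap) {
        # cn of the longer constituent, span union, additive evidence
        len_cur <- cur$end - cur$start + 1
        len_nxt <- nxt$end - nxt$start + 1
        cur$cn <- if (len_nxt > len_cur) nxt$cn else cur$cn
        cur$end <- max(cur$end, nxt$end)
        cur$n_snps <- cur$n_snps + nxt$n_snps
        cur$confidence <- cur$confidence + nxt$confidence
        if (!identical(cur$caller, nxt$caller)) cur$caller <- "merged"
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[marker_order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter calls on marker count, length and confidence
#'
#' All three thresholds are strict, as in routine array screening practice:
#' a call with exactly 10 SNPs, exactly 50 kb, or confidence exactly 50 is
#' removed.
#'
#' @param calls CNV call data.frame.
#' @param min_snps,min_length,min_conf Strict lower bounds
#'   (defaults 10, 50000, 50).
#' @return Filtered call data.frame (subset of the input).
#' @export
filter_calls <- function(calls, min_snps = 10, min_length = 50000, min_conf = 50) {
  validate_calls(calls)
  keep <- calls$n_snps > min_snps &
    (calls$end - calls$start + 1) > min_length &
    calls$confidence > min_conf
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of two callsets
#'
#' Union semantics chosen to reduce false negatives: every call from either
#' set survives. Overlapping same-direction calls collapse to their span
#' union with confidence = max (the two callers' confidence scales are not
#' commensurable, so they are not summed) and caller tag `"both"` when the
#' constituents come from different callers; opposite-direction overlaps are
#' kept separately. Commutative and associative up to caller tags.
#'
#' @param calls_a,calls_b CNV call data.frames for the same sample.
#' @return Combined call data.frame.
#' @export
combine_callsets <- function(calls_a, calls_b) {
  validate_calls(calls_a); validate_calls(calls_b)
  pool <- rbind(calls_a, calls_b)
  if (nrow(pool) <= 1L) { rownames(pool) <- NULL; return(pool) }
  dir <- call_direction(pool$cn)
  out <- list()
  for (grp in split(seq_len(nrow(pool)), paste(pool$chrom, dir))) {
    g <- pool[grp, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    cur <- g[1L, , drop = FALSE]
    for (i in seq_len(nrow(g))[-1L]) {
      nxt <- g[i, , drop = FALSE]
      if (nxt$start <= cur$end) {  # >= 1 bp shared
        len_cur <- cur$end - cur$start + 1
        len_nxt <- nxt$end - nxt$start + 1
        cur$cn <- if (len_nxt > len_cur) nxt$cn else cur$cn
        cur$end <- max(cur$end, nxt$end)
        cur$n_snps <- max(cur$n_snps, nxt$n_snps)
        cur$confidence <- max(cur$confidence, nxt$confidence)
        cur$caller <- if (identical(cur$caller, nxt$caller)) cur$caller else "both"
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[marker_order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fraction of a disorder region covered by matching calls
#'
#' The union of the intersections of direction-matching calls with the
#' region, divided by the region's length (1-based inclusive lengths) — the
#' detected-length over known-length ratio used to judge whether a known CNV
#' was recovered.
#'
#' @param calls CNV call data.frame.
#' @param region One-row disorder region (data.frame with chrom, start, end,
#'   direction, optionally expected_cn).
#' @return Fraction in \[0, 1\].
#' @export
detected_fraction <- function(calls, region) {
  validate_calls(calls)
  if (nrow(calls) == 0L) return(0)
  sel <- calls$chrom == region$chrom &
    call_direction(calls$cn) == region$direction &
    calls$end >= region$start & calls$start <= region$end
  if (!is.null(region$expected_cn) && !is.na(region$expected_cn)) {
    sel <- sel & calls$cn == region$expected_cn
  }
  if (!any(sel)) return(0)
  s <- pmax(calls$start[sel], region$start)
  e <- pmin(calls$end[sel], region$end)
  interval_union_length(s, e) / (region$end - region$start + 1)
}

#' Screen calls against a disorder database
#'
#' One verdict per disorder region: `detected` when the detected fraction
#' reaches `min_fraction`, else `normal`. Direction must match; when the
#' database row carries an `expected_cn` the call's copy number must equal
#' it.
#'
#' @param calls Filtered CNV call data.frame for one sample.
#' @param db Disorder database (see [read_disorder_db()]).
#' @param sample_id Sample id for the report (default: from `calls`, or
#'   `"sample"` when there are none).
#' @param min_fraction Detection threshold on the detected fraction;
#'   the default (1e-9) means any positive overlap counts as detected.
#' @return A `data.frame` of screen results: `sample_id`, `disorder`,
#'   `detected_fraction`, `n_matched_calls`, `status`; the matching calls
#'   per disorder are attached as the list column `matched_calls`.
#' @export
match_disorders <- function(calls, db, sample_id = NULL, min_fraction = 1e-9) {
  validate_calls(calls)
  if (min_fraction <= 0) stop_format("min_fraction must be > 0")
  if (is.null(sample_id)) {
    sample_id <- if (nrow(calls)) calls$sample_id[1L] else "sample"
  }
  res <- lapply(seq_len(nrow(db)), function(i) {
    region <- db[i, , drop = FALSE]
    frac <- detected_fraction(calls, region)
    sel <- logical(nrow(calls))
    if (nrow(calls)) {
      sel <- calls$chrom == region$chrom &
        call_direction(calls$cn) == region$direction &
        calls$end >= region$start & calls$start <= region$end
      if (!is.na(region$expected_cn)) sel <- sel & calls$cn == region$expected_cn
    }
    list(frac = frac, matched = calls[sel, , drop = FALSE])
  })
  out <- data.frame(sample_id = sample_id, disorder = db$name,
                    detected_fraction = vapply(res, `[[`, 0, "frac"),
                    n_matched_calls = vapply(res, function(r) nrow(r$matched), 0L),
                    stringsAsFactors = FALSE)
  out$status <- ifelse(out$detected_fraction >= min_fraction, "detected", "normal")
  out$matched_calls <- I(lapply(res, `[[`, "matched"))
  out
}
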