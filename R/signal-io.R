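# Readers and writers for the on-disk formats the pipeline touches:
# per-sample signal tables (GenomeStudio/PennCNV export dialect), PFB tables,
# rawcnv-style CNV call files, BED export, the disorder-region database, and
# the serialized wave-reference model archive.
#
# Coordinates are 1-based inclusive everywhere in memory; BED is the only
# 0-based half-open surface. Missing values serialize as "NaN"; any
# unparseable numeric field parses back as missing rather than an error.

#' Construct a marker map
#'
#' A marker map is the spatial backbone of the package: an ordered table of
#' SNP marker identifiers and genomic coordinates. All per-sample signal
#' vectors are positionally aligned to it.
#'
#' @param marker Character vector of unique marker identifiers.
#' @param chrom Chromosome labels ("1".."22", "X", "Y"; a leading "chr" is
#'   stripped). Sex chromosomes are carried along but excluded from wave
#'   features, which are autosomal.
#' @param position 1-based base-pair positions.
#' @return A `data.frame` with columns `marker`, `chrom`, `position`, sorted
#'   by (chromosome, position).
#' @export
marker_map <- function(marker, chrom, position) {
  marker <- as.character(marker)
  chrom <- norm_chrom(chrom)
  position <- as.integer(position)
  if (anyDuplicated(marker)) stop_format("duplicate marker_id in marker map")
  if (any(is.na(position)) || any(position < 1L)) {
    stop_format("marker positions must be integers >= 1")
  }
  o <- marker_order(chrom, position)
  data.frame(marker = marker[o], chrom = chrom[o], position = position[o],
             stringsAsFactors = FALSE)
}

#' Construct a per-sample signal object
#'
#' Holds one sample's per-marker log R ratio (LRR) and B allele frequency
#' (BAF), plus an optional genotype vector, aligned to a marker map.
#'
#' @param sample_id Sample identifier.
#' @param lrr Numeric LRR vector (log2-ratio units), `NA` for missing.
#' @param baf Numeric BAF vector in \[0, 1\], `NA` for missing.
#' @param genotype Optional character vector in `{"AA","AB","BB","NC"}`.
#' @return An object of class `signal_sample`.
#' @export
signal_sample <- function(sample_id, lrr, baf, genotype = NULL) {
  if (length(lrr) != length(baf)) stop_format("lrr and baf lengths differ")
  if (!is.null(genotype) && length(genotype) != length(lrr)) {
    stop_format("genotype length differs from lrr")
  }
  bad <- !is.na(baf) & (baf < 0 | baf > 1)
  if (any(bad)) stop_format("BAF outside [0, 1] at %d marker(s)", sum(bad))
  structure(list(sample_id = as.character(sample_id),
                 lrr = as.numeric(lrr), baf = as.numeric(baf),
                 genotype = if (is.null(genotype)) NULL else as.character(genotype)),
            class = "signal_sample")
}

#' @export
print.signal_sample <- function(x, ...) {
  cat(sprintf("<signal_sample> %s: %d markers, %.1f%% LRR present, %.1f%% BAF present%s\n",
              x$sample_id, length(x$lrr),
              100 * mean(!is.na(x$lrr)), 100 * mean(!is.na(x$baf)),
              if (is.null(x$genotype)) "" else ", genotypes attached"))
  invisible(x)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a per-sample signal table
#'
#' Parses the tab-delimited one-sample-per-file export dialect: columns
#' `Name`, `Chr`, `Position`, `<sample>.Log R Ratio`, `<sample>.B Allele Freq`
#' and optionally `<sample>.GType`. Rows are sorted to marker-map order;
#' unparseable LRR/BAF fields become missing values.
#'
#' @param path Path to the tab-delimited file.
#' @return A list with elements `markers` (marker map) and `sample`
#'   (`signal_sample`).
#' @export
read_signal_table <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  want <- function(pat, what) {
    i <- grep(pat, hdr)
    if (length(i) != 1L) stop_format("signal table: missing or ambiguous %s column", what)
    i
  }
  i_name <- want("^Name$", "Name")
  i_chr <- want("^Chr$", "Chr")
  i_pos <- want("^Position$", "Position")
  i_lrr <- want("\\.Log R Ratio$", "Log R Ratio")
  i_baf <- want("\\.B Allele Freq$", "B Allele Freq")
  i_gt <- grep("\\.GType$", hdr)
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE)
  pos_raw <- tab[[i_pos]]
  pos <- suppressWarnings(as.numeric(pos_raw))
  if (any(is.na(pos)) || any(pos != floor(pos))) {
    stop_format("signal table: non-integer Position value")
  }
  sample_id <- sub("\\.Log R Ratio$", "", hdr[i_lrr])
  m <- marker_map(tab[[i_name]], tab[[i_chr]], pos)
  # permute the signal columns to the sorted marker order
  perm <- match(m$marker, tab[[i_name]])
  gt <- if (length(i_gt) == 1L) tab[[i_gt]][perm] else NULL
  s <- signal_sample(sample_id,
                     lrr = num_or_na(tab[[i_lrr]][perm]),
                     baf = pmin(pmax(num_or_na(tab[[i_baf]][perm]), 0), 1),
                     genotype = gt)
  list(markers = m, sample = s)
}

#' Write a per-sample signal table
#'
#' Inverse of [read_signal_table()]; missing values are written as `"NaN"`,
#' numerics at 4 decimal places.
#'
#' @param markers Marker map.
#' @param sample `signal_sample` aligned to `markers`.
#' @param path Output path.
#' @export
write_signal_table <- function(markers, sample, path) {
  if (length(sample$lrr) != nrow(markers)) {
    stop_format("signal length (%d) does not match marker map (%d rows)",
                length(sample$lrr), nrow(markers))
  }
  id <- sample$sample_id
  cols <- c("Name", "Chr", "Position",
            paste0(id, ".Log R Ratio"), paste0(id, ".B Allele Freq"))
  lines <- paste(markers$marker, markers$chrom, markers$position,
                 fmt_num(sample$lrr), fmt_num(sample$baf), sep = "\t")
  if (!is.null(sample$genotype)) {
    cols <- c(cols, paste0(id, ".GType"))
    lines <- paste(lines, sample$genotype, sep = "\t")
  }
  writeLines(c(paste(cols, collapse = "\t"), if (nrow(markers)) lines), path)
  invisible(path)
}

#' Read a PFB (population B-allele frequency) table
#'
#' @param path TSV with columns Name, Chr, Position, PFB.
#' @return Named numeric vector of PFB values (names = marker ids).
#' @export
read_pfb_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("Name", "PFB") %in% names(tab))) stop_format("PFB table: need Name and PFB columns")
  setNames(num_or_na(tab$PFB), tab$Name)
}

#' Write a PFB table
#' @param markers Marker map.
#' @param pfb Numeric vector aligned to `markers`.
#' @param path Output path.
#' @export
write_pfb_table <- function(markers, pfb, path) {
  if (length(pfb) != nrow(markers)) stop_format("PFB length mismatch")
  writeLines(c("Name\tChr\tPosition\tPFB",
               paste(markers$marker, markers$chrom, markers$position,
                     fmt_num(pfb), sep = "\t")), path)
  invisible(path)
}

cnv_calls_frame <- function(sample_id = character(), chrom = character(),
                            start = integer(), end = integer(), cn = integer(),
                            n_snps = integer(), confidence = numeric(),
                            caller = character()) {
  df <- data.frame(sample_id = as.character(sample_id), chrom = norm_chrom(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   cn = as.integer(cn), n_snps = as.integer(n_snps),
                   confidence = as.numeric(confidence), caller = as.character(caller),
                   stringsAsFactors = FALSE)
  validate_calls(df)
}

validate_calls <- function(df) {
  if (nrow(df) == 0L) return(df)
  if (any(df$end < df$start)) stop_format("CNV call with end < start")
  if (any(df$cn == 2L)) stop_format("CNV call with cn = 2 (diploid) is invalid")
  if (any(df$n_snps < 1L)) stop_format("CNV call with n_snps < 1")
  df
}

# cn <-> PennCNV-style state tag
cn_to_state <- function(cn) c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)[as.character(cn)]

#' Read CNV calls in the rawcnv dialect
#'
#' One call per line:
#' `chr2:110852875-110983320 numsnp=66 length=130,446 state2,cn=1 <sample>
#' startsnp=rs1 endsnp=rs2 conf=123.4`. Thousands separators in `length` are
#' ignored; a missing `conf` field yields confidence 0.
#'
#' @param path Input file.
#' @param sample_id Sample id to assign; defaults to the file's sample field.
#' @param caller Caller tag recorded on each call (default `"external"`).
#' @return A CNV call `data.frame` (columns sample_id, chrom, start, end, cn,
#'   n_snps, confidence, caller).
#' @export
read_cnv_calls <- function(path, sample_id = NULL, caller = "external") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(cnv_calls_frame())
  parse_one <- function(ln) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    rg <- regmatches(f[1L], regexec("^chr([^:]+):([0-9]+)-([0-9]+)$", f[1L]))[[1L]]
    if (length(rg) != 4L) stop_format("rawcnv: malformed region '%s'", f[1L])
    kv <- function(key, default = NA_character_) {
      hit <- grep(paste0("^", key, "="), f, value = TRUE)
      if (length(hit) == 0L) return(default)
      sub(paste0("^", key, "="), "", hit[1L])
    }
    cnf <- grep("^state[0-9]+,cn=[0-9]+$", f, value = TRUE)
    if (length(cnf) != 1L) stop_format("rawcnv: missing state/cn field in '%s'", ln)
    cn <- as.integer(sub(".*,cn=", "", cnf))
    if (cn == 2L) stop_format("rawcnv: call with cn=2 violates the call invariant")
    sid <- if (!is.null(sample_id)) sample_id else if (length(f) >= 5L) f[5L] else "unknown"
    conf <- num_or_na(kv("conf"))
    list(sample_id = sid, chrom = norm_chrom(rg[2L]),
         start = as.numeric(rg[3L]), end = as.numeric(rg[4L]), cn = cn,
         n_snps = as.integer(kv("numsnp")),
         confidence = if (is.na(conf)) 0 else conf)
  }
  rows <- lapply(lines, parse_one)
  cnv_calls_frame(sample_id = vapply(rows, `[[`, "", "sample_id"),
                  chrom = vapply(rows, `[[`, "", "chrom"),
                  start = vapply(rows, `[[`, 0, "start"),
                  end = vapply(rows, `[[`, 0, "end"),
                  cn = vapply(rows, `[[`, 0L, "cn"),
                  n_snps = vapply(rows, `[[`, 0L, "n_snps"),
                  confidence = vapply(rows, `[[`, 0, "confidence"),
                  caller = caller)
}

#' Write CNV calls in the rawcnv dialect
#'
#' @param calls CNV call data.frame.
#' @param path Output file.
#' @param markers Optional marker map used to fill `startsnp=`/`endsnp=`
#'   fields; omitted markers are written as `-`.
#' @export
write_cnv_calls <- function(calls, path, markers = NULL) {
  validate_calls(calls)
  snp_at <- function(chrom, pos) {
    if (is.null(markers)) return(rep("-", length(pos)))
    key <- paste(markers$chrom, markers$position)
    markers$marker[match(paste(chrom, pos), key)]
  }
  lines <- sprintf("chr%s:%d-%d numsnp=%d length=%s state%d,cn=%d %s startsnp=%s endsnp=%s conf=%.4g",
                   calls$chrom, as.integer(calls$start), as.integer(calls$end),
                   calls$n_snps,
                   formatC(calls$end - calls$start + 1, format = "d", big.mark = ","),
                   cn_to_state(calls$cn), calls$cn, calls$sample_id,
                   snp_at(calls$chrom, calls$start), snp_at(calls$chrom, calls$end),
                   calls$confidence)
  writeLines(lines, path)
  invisible(path)
}

#' Export CNV calls as BED
#'
#' The only 0-based half-open surface in the package: BED start = start - 1,
#' BED end = end. The name column carries `cn=<cn>`, the score the confidence
#' clipped into \[0, 1000\].
#'
#' @param calls CNV call data.frame.
#' @param path Output file.
#' @export
write_calls_bed <- function(calls, path) {
  validate_calls(calls)
  lines <- if (nrow(calls)) {
    sprintf("%s\t%d\t%d\tcn=%d\t%d", calls$chrom,
            as.integer(calls$start) - 1L, as.integer(calls$end), calls$cn,
            as.integer(round(pmin(pmax(calls$confidence, 0), 1000))))
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosomal-disorder region database
#'
#' TSV with header `name, chrom, start, end, direction[, expected_cn]`;
#' `direction` is `del` or `dup`. Overlapping regions are permitted.
#'
#' @param path Input TSV.
#' @return A `data.frame` of disorder regions.
#' @export
read_disorder_db <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("name", "chrom", "start", "end", "direction")
  if (!all(need %in% names(tab))) {
    stop_format("disorder db: missing column(s) %s",
                paste(setdiff(need, names(tab)), collapse = ", "))
  }
  db <- data.frame(name = tab$name, chrom = norm_chrom(tab$chrom),
                   start = as.numeric(tab$start), end = as.numeric(tab$end),
                   direction = tab$direction,
                   expected_cn = if ("expected_cn" %in% names(tab))
                     suppressWarnings(as.integer(tab$expected_cn)) else NA_integer_,
                   stringsAsFactors = FALSE)
  if (any(is.na(db$start)) || any(is.na(db$end)) || any(db$end < db$start)) {
    stop_format("disorder db: invalid region coordinates (end < start?)")
  }
  if (!all(db$direction %in% c("del", "dup"))) {
    stop_format("disorder db: direction must be 'del' or 'dup'")
  }
  bad <- !is.na(db$expected_cn) &
    ((db$direction == "del" & db$expected_cn >= 2L) |
       (db$direction == "dup" & db$expected_cn <= 2L))
  if (any(bad)) stop_format("disorder db: expected_cn inconsistent with direction")
  db
}
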