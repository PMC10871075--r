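# Internal helpers shared across modules.

#' @importFrom stats sd cor rnorm runif rbinom dbinom dnorm pnorm kmeans setNames
#' @importFrom utils read.delim write.table
NULL

# Normalize chromosome labels: strip a leading "chr", keep "X"/"Y" as is.
norm_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  toupper(x)
}

is_autosome <- function(chrom) {
  suppressWarnings(!is.na(as.integer(chrom)))
}

# Sort key: autosomes numerically, then X, then Y, then anything else.
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.integer(chrom))
  r <- ifelse(!is.na(n), n, ifelse(chrom == "X", 100L, ifelse(chrom == "Y", 101L, 102L)))
  r
}

marker_order <- function(chrom, position) {
  order(chrom_rank(chrom), position)
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

# Union length of a set of 1-based inclusive intervals (sorted sweep).
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= cur_e + 1) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1)
}

# Format doubles for on-disk tables; digits = 4 matches array-export practice,
# digits = 17 is exact round-trip for the model archive.
fmt_num <- function(x, digits = 4L) {
  out <- if (digits >= 17L) sprintf("%.17g", x) else
    sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- "NaN"
  out
}
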