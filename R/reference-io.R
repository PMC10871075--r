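# Serialization of the wave-reference model: a directory archive with one
# JSON metadata document and plain TSV matrices, all text. Numerics are
# written at 17 significant digits so a read-back model is exactly the model
# written.

write_matrix_tsv <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(fmt_num(r, 17L), collapse = "\t"))
  writeLines(as.character(lines), path)
}

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(matrix(numeric(), 0L, 0L))
  do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
}

#' Write a wave-reference model archive
#'
#' @param model A `wave_reference`.
#' @param path Directory to create (overwritten if it exists).
#' @export
write_reference <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "wavecnv-reference", version = model$version,
               k = model$k, bin_size = model$scheme$bin_size,
               sd_floor = model$sd_floor, seed = model$seed,
               n_samples = model$n_samples,
               cluster_sizes = model$cluster_sizes, labels = model$labels,
               informative = model$scheme$informative,
               sample_ids = rownames(model$ref_features),
               curve = model$curve)
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write.table(model$scheme$bins, file.path(path, "bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(model$markers, file.path(path, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(model$centroids, file.path(path, "centroids.tsv"))
  write_matrix_tsv(model$marker_mean, file.path(path, "marker_mean.tsv"))
  write_matrix_tsv(model$marker_sd, file.path(path, "marker_sd.tsv"))
  write_matrix_tsv(model$ref_features, file.path(path, "ref_features.tsv"))
  invisible(path)
}

#' Read a wave-reference model archive
#'
#' @param path Directory written by [write_reference()].
#' @return A `wave_reference`.
#' @export
read_reference <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "wavecnv-reference")) {
    stop_format("%s is not a wavecnv reference archive", path)
  }
  bins <- read.delim(file.path(path, "bins.tsv"), colClasses = c("character", "numeric", "numeric"))
  mk <- read.delim(file.path(path, "markers.tsv"),
                   colClasses = c("character", "character", "integer"))
  scheme <- structure(list(bin_size = meta$bin_size, bins = bins,
                           informative = as.logical(meta$informative)),
                      class = "bin_scheme")
  feats <- read_matrix_tsv(file.path(path, "ref_features.tsv"))
  rownames(feats) <- meta$sample_ids
  curve <- meta$curve
  if (!is.null(curve)) curve <- as.data.frame(curve)
  structure(list(k = as.integer(meta$k), scheme = scheme,
                 centroids = read_matrix_tsv(file.path(path, "centroids.tsv")),
                 labels = as.integer(meta$labels),
                 cluster_sizes = as.integer(meta$cluster_sizes),
                 ref_features = feats, feature_means = colMeans(feats),
                 marker_mean = read_matrix_tsv(file.path(path, "marker_mean.tsv")),
                 marker_sd = read_matrix_tsv(file.path(path, "marker_sd.tsv")),
                 markers = mk, sd_floor = meta$sd_floor, seed = meta$seed,
                 curve = curve, n_samples = as.integer(meta$n_samples),
                 version = meta$version),
            class = "wave_reference")
}
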