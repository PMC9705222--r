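# Delimited-text persistence with JSON sidecar metadata.
#
# Arrays are written as tab-separated text (one column per A-line) with
# full-precision "%.17g" formatting, so a write/read cycle reproduces every
# double bit-exactly and reruns with the same seed produce byte-identical
# files. Every artifact embeds the resolved run configuration and the package
# version in its meta.json.

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  txt <- apply(m, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(txt, path)
}

read_matrix_tsv <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "numeric")))
}

qc_meta <- function(extra = list()) {
  c(list(package = "quadcal",
         version = as.character(utils::packageVersion("quadcal"))),
    extra)
}

write_meta <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

read_meta <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write / read a raw two-channel batch
#'
#' A batch is stored as a directory holding `ch_I.tsv` and `ch_II.tsv` (one
#' column per A-line, full precision) and a `meta.json` with the grid, the
#' reflector ground truth when available, and any extra metadata supplied.
#'
#' @param batch a `raw_batch`.
#' @param dir target directory (created if needed).
#' @param extra_meta named list merged into the sidecar metadata.
#' @return `dir`, invisibly (`write`); a `raw_batch` (`read`).
#' @export
write_raw_batch <- function(batch, dir, extra_meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(batch$ch_I, file.path(dir, "ch_I.tsv"))
  write_matrix_tsv(batch$ch_II, file.path(dir, "ch_II.tsv"))
  truth <- NULL
  if (!is.null(batch$truth) && !is.null(batch$truth$reflectors)) {
    truth <- list(depths = batch$truth$reflectors$depths,
                  amplitudes = batch$truth$reflectors$amplitudes)
  }
  meta <- qc_meta(c(list(
    N = batch$grid$N, M = ncol(batch$ch_I),
    k_min = batch$grid$k[1], k_max = batch$grid$k[batch$grid$N],
    truth = truth), extra_meta))
  write_meta(meta, file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_raw_batch
#' @export
read_raw_batch <- function(dir) {
  meta <- read_meta(file.path(dir, "meta.json"))
  grid <- make_kgrid(meta$N, meta$k_min, meta$k_max)
  truth <- NULL
  if (!is.null(meta$truth) && length(meta$truth$depths) > 0) {
    truth <- list(reflectors = reflector_set(meta$truth$depths,
                                             meta$truth$amplitudes))
  }
  new_raw_batch(read_matrix_tsv(file.path(dir, "ch_I.tsv")),
                read_matrix_tsv(file.path(dir, "ch_II.tsv")),
                grid, truth)
}

#' Write / read a correction set
#'
#' The calibration product is stored as `chromatic.tsv` (columns `beta_k`,
#' `dphi_k` over the wavenumber axis), `spatial.tsv` (columns `zbar`,
#' `beta_z`, `dphi_z`) and a `meta.json` carrying the grid, fit metadata and
#' package version. The round trip is exact: `read_correction_set()` returns
#' vectors bit-identical to those written.
#'
#' @param cs a `correction_set`.
#' @param dir target directory.
#' @param extra_meta named list merged into the metadata.
#' @return `dir`, invisibly (`write`); a `correction_set` (`read`).
#' @export
write_correction_set <- function(cs, dir, extra_meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("beta_k\tdphi_k",
               paste(fmt_num(cs$beta_k), fmt_num(cs$dphi_k), sep = "\t")),
             file.path(dir, "chromatic.tsv"))
  writeLines(c("zbar\tbeta_z\tdphi_z",
               paste(fmt_num(cs$grid$zbar), fmt_num(cs$beta_z),
                     fmt_num(cs$dphi_z), sep = "\t")),
             file.path(dir, "spatial.tsv"))
  meta <- qc_meta(c(list(
    N = cs$grid$N, k_min = cs$grid$k[1], k_max = cs$grid$k[cs$grid$N],
    fit_meta = cs$fit_meta), extra_meta))
  write_meta(meta, file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_correction_set
#' @export
read_correction_set <- function(dir) {
  meta <- read_meta(file.path(dir, "meta.json"))
  grid <- make_kgrid(meta$N, meta$k_min, meta$k_max)
  ch <- utils::read.table(file.path(dir, "chromatic.tsv"), sep = "\t",
                          header = TRUE, colClasses = "numeric")
  sp <- utils::read.table(file.path(dir, "spatial.tsv"), sep = "\t",
                          header = TRUE, colClasses = "numeric")
  correction_set(ch$beta_k, ch$dphi_k, sp$beta_z, sp$dphi_z, grid,
                 fit_meta = meta$fit_meta)
}

#' Write a dB image as plain-text PGM
#'
#' Renders a matrix of dB magnitudes (rows = depth, columns = lateral
#' position) into an ASCII (`P2`) portable graymap, clipping to
#' `range` and quantizing to 255 gray levels. A text raster keeps the
#' deliverable binary-free while remaining viewable in any image tool.
#'
#' @param db numeric matrix of dB values.
#' @param path output file.
#' @param range two-element dB display range (values outside are clipped).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(db, path, range = c(30, 90)) {
  q <- pmin(pmax((db - range[1]) / diff(range), 0), 1)
  g <- round(q * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(g), nrow(g)), "255"), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
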