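# Minimal multi-page TIFF I/O for image volumes. Volumes are stored as
# 32-bit float pages (one page per z-slice) normalized to [0, 1]; the
# intensity scale travels in a small JSON sidecar so arbitrary ADU ranges
# round-trip exactly.

#' Write / read a (z, y, x) volume as a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` on write and restored on read via
#' a `<path>.json` sidecar recording the scale and offset.
#'
#' @param volume numeric or integer 3-D array (`z, y, x`); 2-D arrays are
#'   written as a single page.
#' @param path TIFF path.
#' @return `read_volume_tiff` returns a numeric `(z, y, x)` array.
#' @export
write_volume_tiff <- function(volume, path) {
  if (length(dim(volume)) == 2L) volume <- array(volume, c(1L, dim(volume)))
  offset <- min(volume)
  scale <- max(volume) - offset
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(volume)[1]),
                  function(z) (volume[z, , ] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(offset = offset, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  if (!file.exists(path)) nf_format_error(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(offset = 0, scale = 1)
  }
  out <- array(0, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]] * meta$scale + meta$offset
  out
}
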