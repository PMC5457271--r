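# FLIM image stack I/O: multi-page TIFF (one 16-bit page per time bin)
# with a JSON sidecar carrying the acquisition settings.

#' Write / read a FLIM image stack
#'
#' The stack is stored as a multi-page 16-bit TIFF, one page per time
#' bin, with the acquisition settings in `<path>.json`. Counts above
#' 65535 per bin do not occur at realistic per-pixel photon budgets and
#' are rejected.
#'
#' @param image A [flim_image()].
#' @param path TIFF file path (the sidecar is written next to it).
#' @return `write_flim_image()` returns `path` invisibly;
#'   `read_flim_image()` returns a [flim_image()].
#' @export
write_flim_image <- function(image, path) {
  stopifnot(inherits(image, "flim_image"))
  if (max(image$counts) > 65535)
    stop("per-bin counts exceed the 16-bit TIFF range")
  d <- dim(image$counts)
  pages <- lapply(seq_len(d[3]), function(b) image$counts[, , b] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  s <- image$settings
  sidecar <- list(rep_rate_mhz = s$rep_rate_mhz, n_bins = s$n_bins,
                  irf_fwhm_ps = s$irf_fwhm_ps, counts_target = s$counts_target)
  if (!is.null(image$mask)) sidecar$mask <- image$mask
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_flim_image
#' @export
read_flim_image <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing acquisition-settings sidecar: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  counts <- array(0, dim = d)
  for (b in seq_along(pages)) counts[, , b] <- pages[[b]]
  settings <- acquisition_settings(meta$rep_rate_mhz, meta$n_bins,
                                   meta$irf_fwhm_ps, meta$counts_target)
  mask <- if (!is.null(meta$mask)) as.matrix(meta$mask) else NULL
  flim_image(counts, settings, mask = mask)
}
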