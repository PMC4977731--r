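# Volume + sidecar I/O. The sidecar is a JSON file:
#   {"times_ms": [...], "convention": "magnitude"|"signed",
#    "anchor_index": n (optional, 1-based), "model_hint": "..." (optional),
#    "units": "ms" (optional; anything else is rejected)}
# Times are stored in ms everywhere; seconds are rejected, never converted
# silently.

#' Read an image series from a volume plus timing sidecar
#'
#' @param volume_path Path to a NIfTI volume (`height x width x n_frames`).
#' @param sidecar_path Path to the JSON timing sidecar.
#' @return An [image_series()].
#' @export
read_volume_with_sidecar <- function(volume_path, sidecar_path) {
  vol <- RNifti::readNifti(volume_path)
  arr <- as.array(vol)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) == 4L && dim(arr)[3] == 1L) {
    arr <- array(arr, dim = dim(arr)[c(1, 2, 4)])
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sc$times_ms)) stop("sidecar lacks times_ms", call. = FALSE)
  if (!is.null(sc$units) && !identical(tolower(sc$units), "ms")) {
    stop("sidecar times must be in ms (got units '", sc$units, "')",
         call. = FALSE)
  }
  times <- as.numeric(sc$times_ms)
  if (length(times) != dim(arr)[3]) {
    stop(sprintf("sidecar lists %d times for %d frames", length(times),
                 dim(arr)[3]), call. = FALSE)
  }
  image_series(arr, times,
               convention = if (is.null(sc$convention)) "magnitude" else sc$convention,
               model_hint = sc$model_hint,
               anchor_index = sc$anchor_index)
}

#' Write an image series as a volume plus timing sidecar
#'
#' @param series An [image_series()].
#' @param volume_path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param sidecar_path Output JSON path.
#' @return Invisibly, the two paths.
#' @export
write_volume_with_sidecar <- function(series, volume_path, sidecar_path) {
  stopifnot(inherits(series, "image_series"))
  RNifti::writeNifti(RNifti::asNifti(series$frames, datatype = "double"),
                     volume_path)
  sc <- list(times_ms = series$times, convention = series$convention,
             units = "ms")
  if (!is.null(series$model_hint)) sc$model_hint <- series$model_hint
  if (!is.null(series$anchor_index)) sc$anchor_index <- series$anchor_index
  jsonlite::write_json(sc, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(volume_path, sidecar_path))
}

#' Write a relaxation map to disk
#'
#' The primary format is lossless 64-bit floating-point NIfTI: `tau.nii.gz`,
#' `residual.nii.gz`, `refined_mask.nii.gz`, `excluded_mask.nii.gz` plus a
#' `provenance.json` with the model, variant, settings digest and pixel
#' counts. `format = "png"` additionally writes a 16-bit preview of the tau
#' map scaled to a fixed window (0 to `png_window` ms), with the scale factor
#' documented in the provenance record.
#'
#' @param map A [fit_map()] result.
#' @param path Output directory (created if needed).
#' @param format `"nifti"` (default) or `"png"` (preview in addition).
#' @param png_window Upper display window for the PNG preview, ms.
#' @return Invisibly, the output directory.
#' @export
write_map <- function(map, path, format = c("nifti", "png"),
                      png_window = 2000) {
  stopifnot(inherits(map, "relaxation_map"))
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wn <- function(x, f) {
    RNifti::writeNifti(RNifti::asNifti(x, datatype = "double"),
                       file.path(path, f))
  }
  wn(map$tau_map, "tau.nii.gz")
  res <- map$residual_map
  res[!is.finite(res)] <- -1  # sentinel for undefined residual on disk
  wn(res, "residual.nii.gz")
  wn(map$refined_mask * 1, "refined_mask.nii.gz")
  wn(map$excluded_mask * 1, "excluded_mask.nii.gz")
  prov <- c(map$provenance, list(n_pixels = map$n_pixels,
                                 times_ms = map$times,
                                 convention = map$convention,
                                 residual_sentinel = -1))
  if (format == "png") {
    scaled <- pmin(pmax(map$tau_map / png_window, 0), 1)
    png::writePNG(scaled, file.path(path, "tau_preview.png"))
    prov$png_window_ms <- png_window
    prov$png_scale <- sprintf("pixel_value = tau_ms / %g (clamped to [0,1])",
                              png_window)
  }
  jsonlite::write_json(prov, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a relaxation map written by [write_map()]
#'
#' @param path Directory written by [write_map()].
#' @return A `relaxation_map` (parameter maps `A_map`/`B_map` are not
#'   serialized and come back as `NULL`).
#' @export
read_map <- function(path) {
  rn <- function(f) {
    arr <- as.array(RNifti::readNifti(file.path(path, f)))
    matrix(arr, nrow = dim(arr)[1])
  }
  tau <- rn("tau.nii.gz")
  res <- rn("residual.nii.gz")
  prov <- jsonlite::read_json(file.path(path, "provenance.json"),
                              simplifyVector = TRUE)
  res[res == prov$residual_sentinel] <- NA_real_
  refined <- rn("refined_mask.nii.gz") > 0
  excluded <- rn("excluded_mask.nii.gz") > 0
  structure(list(
    tau_map = tau, residual_map = res, A_map = NULL, B_map = NULL,
    refined_mask = refined, excluded_mask = excluded,
    active_mask = NULL, monotone = NA,
    n_pixels = as.list(prov$n_pixels),
    times = prov$times_ms, convention = prov$convention,
    anchor_index = NULL,
    provenance = prov[setdiff(names(prov),
                              c("n_pixels", "times_ms", "convention",
                                "residual_sentinel"))]
  ), class = "relaxation_map")
}

#' Read or write ROI masks
#'
#' Masks travel either as binary PNG images or as a run-length encoded
#' plain-text format (`height width` on the first line, then alternating
#' run lengths of FALSE/TRUE in column-major order).
#'
#' @param path File path; `.png` selects PNG, anything else the text format.
#' @return [roi_mask()] for the reader; invisibly the path for the writer.
#' @export
read_roi <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    roi_mask(img > 0.5)
  } else {
    ln <- readLines(path)
    hd <- as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]])
    runs <- as.integer(strsplit(paste(ln[-1], collapse = " "), "\\s+")[[1]])
    vals <- rep(rep(c(FALSE, TRUE), length.out = length(runs)), runs)
    roi_mask(matrix(vals, nrow = hd[1], ncol = hd[2]))
  }
}

#' @rdname read_roi
#' @param roi An [roi_mask()].
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(roi$mask * 1, path)
  } else {
    r <- rle(as.vector(roi$mask))
    # force the FALSE/TRUE alternation to start at FALSE
    lengths <- r$lengths
    if (length(r$values) && r$values[1]) lengths <- c(0L, lengths)
    writeLines(c(paste(nrow(roi$mask), ncol(roi$mask)),
                 paste(lengths, collapse = " ")), path)
  }
  invisible(path)
}
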