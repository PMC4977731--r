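# Minimal DICOM reading for relaxometry series: standard tags only
# (inversion time, echo time, trigger time, rows/columns, pixel data),
# uncompressed little-endian transfer syntaxes, explicit or implicit VR.
# Vendor private headers are out of scope. A matching minimal writer
# generates single-frame fixtures (used by the simulator's DICOM emission
# and the test-suite); it is not a general-purpose DICOM exporter.

.TAGS <- c(
  inversion_time = "0018,0082", echo_time = "0018,0081",
  trigger_time = "0018,1060", rows = "0028,0010", columns = "0028,0011",
  bits_allocated = "0028,0100", pixel_representation = "0028,0103",
  rescale_intercept = "0028,1052", rescale_slope = "0028,1053",
  pixel_data = "7fe0,0010", transfer_syntax = "0002,0010"
)

.u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# parse one DICOM file into a list of raw element values keyed "gggg,eeee"
.parse_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elements <- list()
  explicit <- TRUE   # file meta group is always explicit; re-check after it

  while (pos + 7L <= length(raw)) {
    group <- .u16(raw, pos)
    elem <- .u16(raw, pos + 2L)
    key <- sprintf("%04x,%04x", group, elem)
    if (group != 2L) {
      ts <- elements[["0002,0010"]]
      if (!is.null(ts)) {
        uid <- trimws(rawToChar(ts))
        if (uid == "1.2.840.10008.1.2") explicit <- FALSE
        else if (!uid %in% c("1.2.840.10008.1.2.1", "")) {
          stop("unsupported DICOM transfer syntax '", uid, "' in ", path,
               call. = FALSE)
        }
        elements[["0002,0010"]] <- NULL  # consume once
      }
    }
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- .u32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- .u16(raw, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, pos + 4L)
      hdr <- 8L
    }
    if (len == 4294967295) {  # undefined length (sequences): skip to delimiter
      p <- pos + hdr
      repeat {
        if (p + 7L > length(raw)) stop("unterminated sequence in ", path,
                                       call. = FALSE)
        if (.u16(raw, p) == 0xFFFE && .u16(raw, p + 2L) == 0xE0DD) {
          p <- p + 8L
          break
        }
        p <- p + 2L
      }
      pos <- p
      next
    }
    val_start <- pos + hdr
    if (val_start + len - 1L > length(raw)) {
      stop("truncated DICOM element in ", path, call. = FALSE)
    }
    if (len > 0) elements[[key]] <- raw[val_start:(val_start + len - 1L)]
    else elements[key] <- list(raw(0))
    pos <- val_start + len
  }
  elements
}

.dcm_ds <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(trimws(rawToChar(el)), "\\\\")[[1]])[1]
}
.dcm_us <- function(el) if (is.null(el)) NULL else .u16(el, 1L)

.read_dicom_frame <- function(path) {
  el <- .parse_dicom(path)
  rows <- .dcm_us(el[["0028,0010"]])
  cols <- .dcm_us(el[["0028,0011"]])
  bits <- .dcm_us(el[["0028,0100"]])
  if (is.null(rows) || is.null(cols) || is.null(el[["7fe0,0010"]])) {
    stop("missing image data in ", path, call. = FALSE)
  }
  if (!is.null(bits) && bits != 16L) {
    stop("only 16-bit pixel data is supported (", path, ")", call. = FALSE)
  }
  signed <- identical(.dcm_us(el[["0028,0103"]]), 1L)
  px <- readBin(el[["7fe0,0010"]], "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
  if (!signed) px[px < 0] <- px[px < 0] + 65536L
  slope <- .dcm_ds(el[["0028,1053"]]); intercept <- .dcm_ds(el[["0028,1052"]])
  vals <- px * (if (is.null(slope)) 1 else slope) +
    (if (is.null(intercept)) 0 else intercept)
  ti <- .dcm_ds(el[["0018,0082"]])
  te <- .dcm_ds(el[["0018,0081"]])
  trig <- .dcm_ds(el[["0018,1060"]])
  time <- NA_real_; origin <- NA_character_
  if (!is.null(ti)) { time <- ti; origin <- "InversionTime (0018,0082)" }
  else if (!is.null(te)) { time <- te; origin <- "EchoTime (0018,0081)" }
  else if (!is.null(trig)) { time <- trig; origin <- "TriggerTime (0018,1060)" }
  list(pixels = matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
       rows = rows, cols = cols, time = time, origin = origin)
}

#' Read a DICOM series into an image series
#'
#' Per-frame preparation times are resolved from standard tags: Inversion
#' Time (0018,0082), else Echo Time (0018,0081), else Trigger Time
#' (0018,1060) as a MOLLI fallback. Frames are sorted by time. Frames whose
#' time cannot be resolved trigger a metadata error naming the files.
#'
#' @param paths Character vector of DICOM file paths, or a single directory
#'   (its `*.dcm` files are read in lexical order).
#' @param convention Signal convention of the pixel data.
#' @return A list with `series` (an [image_series()]) and `manifest` (a
#'   tibble with `file`, `time_ms`, `origin`, `rows`, `columns`).
#' @export
read_dicom_series <- function(paths, convention = c("magnitude", "signed")) {
  convention <- match.arg(convention)
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.dcm$", ignore.case = TRUE,
                             full.names = TRUE))
  }
  if (length(paths) == 0L) stop("no DICOM files to read", call. = FALSE)
  frames <- lapply(paths, .read_dicom_frame)
  geo <- vapply(frames, function(f) paste(f$rows, f$cols), character(1))
  if (length(unique(geo)) != 1L) {
    stop("mixed image geometries across the series", call. = FALSE)
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (any(is.na(times))) {
    stop("no resolvable preparation time (TI/TE/TriggerTime) in: ",
         paste(basename(paths[is.na(times)]), collapse = ", "), call. = FALSE)
  }
  origins <- vapply(frames, `[[`, character(1), "origin")
  model_hint <- if (all(grepl("EchoTime", origins))) "se_t2" else NULL
  arr <- array(0, dim = c(frames[[1]]$rows, frames[[1]]$cols, length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]$pixels
  list(
    series = image_series(arr, times, convention, model_hint = model_hint),
    manifest = tibble(file = paths, time_ms = times, origin = origins,
                      rows = frames[[1]]$rows, columns = frames[[1]]$cols)
  )
}

# ---- minimal writer (fixture generation) -----------------------------------

.w_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

.w_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  hdr <- c(.w_u16(group), .w_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    hdr <- c(hdr, as.raw(c(0L, 0L)),
             writeBin(length(value_raw), raw(), size = 4L, endian = "little"))
  } else {
    hdr <- c(hdr, .w_u16(length(value_raw)))
  }
  c(hdr, value_raw)
}

#' Write an image series as single-frame DICOM files
#'
#' Emits one explicit-VR little-endian file per frame with the preparation
#' time in the chosen standard tag. Pixel values are stored as unsigned
#' 16-bit integers with a rescale slope chosen to cover the data range, so
#' non-integer data round-trips approximately; integer data in 0–65535
#' round-trips exactly (slope 1).
#'
#' @param series An [image_series()] (anchor frames are not representable).
#' @param dir Output directory.
#' @param time_tag Which tag carries the time: `"TI"`, `"TE"` or
#'   `"TriggerTime"`.
#' @return Invisibly, the written file paths.
#' @export
write_dicom_series <- function(series, dir,
                               time_tag = c("TI", "TE", "TriggerTime")) {
  stopifnot(inherits(series, "image_series"))
  if (!is.null(series$anchor_index)) {
    stop("anchor frames cannot be written to DICOM fixtures", call. = FALSE)
  }
  time_tag <- match.arg(time_tag)
  tag <- switch(time_tag, TI = c(0x0018, 0x0082), TE = c(0x0018, 0x0081),
                TriggerTime = c(0x0018, 0x1060))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$frames)
  lo <- min(series$frames); hi <- max(series$frames)
  intercept <- min(lo, 0)
  slope <- if (hi - intercept <= 65535 &&
               all(series$frames == round(series$frames)) &&
               intercept == 0) 1 else max((hi - intercept) / 65535, 1e-12)
  out <- character(d[3])
  for (k in seq_len(d[3])) {
    px <- round((t(series$frames[, , k]) - intercept) / slope)  # row-major
    px <- pmin(pmax(px, 0), 65535)
    px[px > 32767] <- px[px > 32767] - 65536   # writeBin needs signed range
    ds <- function(x) charToRaw(format(x, scientific = FALSE))
    body <- c(
      .w_element(0x0008, 0x0060, "CS", charToRaw("MR")),
      .w_element(tag[1], tag[2], "DS", ds(series$times[k])),
      .w_element(0x0028, 0x0010, "US", .w_u16(d[1])),
      .w_element(0x0028, 0x0011, "US", .w_u16(d[2])),
      .w_element(0x0028, 0x0100, "US", .w_u16(16L)),
      .w_element(0x0028, 0x0103, "US", .w_u16(0L)),
      .w_element(0x0028, 0x1052, "DS", ds(intercept)),
      .w_element(0x0028, 0x1053, "DS", ds(slope)),
      .w_element(0x7FE0, 0x0010, "OW",
                 writeBin(as.integer(px), raw(), size = 2L, endian = "little"))
    )
    meta <- .w_element(0x0002, 0x0010, "UI",
                       charToRaw("1.2.840.10008.1.2.1"))
    out[k] <- file.path(dir, sprintf("frame_%03d.dcm", k))
    con <- file(out[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(out)
}
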