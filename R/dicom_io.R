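## DICOM ingestion: a minimal Part-10 reader/writer covering the tag subset
## mammographic asymmetry analysis needs (pixel data, bit depth, windowing,
## laterality/view, patient id). Explicit and implicit little-endian
## transfer syntaxes are supported; pixel data must be single-frame,
## single-sample grayscale.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(x) as.integer(x[1]) + 256L * as.integer(x[2])
.u32 <- function(x) {
  as.numeric(x[1]) + 256 * as.numeric(x[2]) +
    65536 * as.numeric(x[3]) + 16777216 * as.numeric(x[4])
}

.raw_u16 <- function(v) as.raw(c(v %% 256L, v %/% 256L))
.raw_u32 <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

.pad_even <- function(b, pad = as.raw(0L)) {
  if (length(b) %% 2L == 1L) c(b, pad) else b
}

.str_bytes <- function(s, pad = as.raw(0x20)) {
  .pad_even(charToRaw(s), pad)
}

## One explicit-VR little-endian data element as a raw vector.
.element <- function(group, elem, vr, value) {
  head <- c(.raw_u16(group), .raw_u16(elem), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(head, as.raw(c(0L, 0L)), .raw_u32(length(value)), value)
  } else {
    c(head, .raw_u16(length(value)), value)
  }
}

#' Write a minimal grayscale DICOM Part-10 file
#'
#' Writes a single-frame MONOCHROME2 image with explicit little-endian
#' transfer syntax. Intended for phantom generation and fixtures; clinical
#' DICOM writing is out of scope.
#'
#' @param raw integer matrix of stored pixel values (rows x cols),
#'   non-negative, must fit in \code{bitsStored} bits.
#' @param path output file path.
#' @param bitsStored stored bits per pixel (<= 16); bits allocated is 16.
#' @param laterality optional "L" or "R" for the ImageLaterality tag.
#' @param viewPosition optional e.g. "CC"/"MLO" for the ViewPosition tag.
#' @param patientID optional patient identifier string.
#' @param windowCenter,windowWidth optional VOI window (both or neither).
#' @return \code{path}, invisibly.
#' @export
writeDicom <- function(raw, path, bitsStored = 12L, laterality = NULL,
                       viewPosition = NULL, patientID = "",
                       windowCenter = NULL, windowWidth = NULL) {
  stopifnot(is.matrix(raw), bitsStored >= 8L, bitsStored <= 16L)
  if (any(raw < 0) || any(raw > 2^bitsStored - 1)) {
    stop("pixel values must fit in bitsStored bits")
  }
  rows <- nrow(raw)
  cols <- ncol(raw)
  sop_class <- "1.2.840.10008.5.1.4.1.1.1.2" # digital mammography X-ray
  sop_inst <- paste0("1.2.826.0.1.3680043.9.7434.", rows, ".", cols, ".",
                     sum(as.numeric(raw)) %% 1e6)

  meta <- c(
    .element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .element(0x0002, 0x0002, "UI", .str_bytes(sop_class, as.raw(0L))),
    .element(0x0002, 0x0003, "UI", .str_bytes(sop_inst, as.raw(0L))),
    .element(0x0002, 0x0010, "UI", .str_bytes(.TS_EXPLICIT_LE, as.raw(0L))),
    .element(0x0002, 0x0012, "UI",
             .str_bytes("1.2.826.0.1.3680043.9.7434.1", as.raw(0L)))
  )

  ds <- c(
    .element(0x0008, 0x0016, "UI", .str_bytes(sop_class, as.raw(0L))),
    .element(0x0008, 0x0018, "UI", .str_bytes(sop_inst, as.raw(0L)))
  )
  if (nzchar(patientID)) {
    ds <- c(ds, .element(0x0010, 0x0020, "LO", .str_bytes(patientID)))
  }
  if (!is.null(viewPosition)) {
    ds <- c(ds, .element(0x0018, 0x5101, "CS", .str_bytes(viewPosition)))
  }
  if (!is.null(laterality)) {
    ds <- c(ds, .element(0x0020, 0x0062, "CS", .str_bytes(laterality)))
  }
  ds <- c(
    ds,
    .element(0x0028, 0x0002, "US", .raw_u16(1L)),
    .element(0x0028, 0x0004, "CS", .str_bytes("MONOCHROME2")),
    .element(0x0028, 0x0010, "US", .raw_u16(rows)),
    .element(0x0028, 0x0011, "US", .raw_u16(cols)),
    .element(0x0028, 0x0100, "US", .raw_u16(16L)),
    .element(0x0028, 0x0101, "US", .raw_u16(as.integer(bitsStored))),
    .element(0x0028, 0x0102, "US", .raw_u16(as.integer(bitsStored) - 1L)),
    .element(0x0028, 0x0103, "US", .raw_u16(0L))
  )
  if (!is.null(windowCenter) && !is.null(windowWidth)) {
    ds <- c(
      ds,
      .element(0x0028, 0x1050, "DS", .str_bytes(format(windowCenter))),
      .element(0x0028, 0x1051, "DS", .str_bytes(format(windowWidth)))
    )
  }
  ## pixel data, row-major, 16-bit little endian
  vals <- as.integer(t(raw))
  pix <- raw(2L * length(vals))
  pix[seq(1L, length(pix), 2L)] <- as.raw(vals %% 256L)
  pix[seq(2L, length(pix), 2L)] <- as.raw(vals %/% 256L)
  ds <- c(ds, .element(0x7FE0, 0x0010, "OW", pix))

  out <- c(
    raw(128L), charToRaw("DICM"),
    .element(0x0002, 0x0000, "UL", .raw_u32(length(meta))),
    meta, ds
  )
  writeBin(out, path)
  invisible(path)
}

## Parse one element header at pos; returns list(group, elem, vr, len,
## data_pos, next_pos). For implicit syntax vr is NA.
.parse_header <- function(bytes, pos, explicit) {
  group <- .u16(bytes[pos:(pos + 1L)])
  elem <- .u16(bytes[(pos + 2L):(pos + 3L)])
  if (group == 0xFFFE) { # item / delimiter: always implicit-style
    len <- .u32(bytes[(pos + 4L):(pos + 7L)])
    return(list(group = group, elem = elem, vr = NA_character_, len = len,
                data_pos = pos + 8L))
  }
  if (explicit) {
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .long_vrs) {
      len <- .u32(bytes[(pos + 8L):(pos + 11L)])
      list(group = group, elem = elem, vr = vr, len = len,
           data_pos = pos + 12L)
    } else {
      len <- .u16(bytes[(pos + 6L):(pos + 7L)])
      list(group = group, elem = elem, vr = vr, len = len,
           data_pos = pos + 8L)
    }
  } else {
    len <- .u32(bytes[(pos + 4L):(pos + 7L)])
    list(group = group, elem = elem, vr = NA_character_, len = len,
         data_pos = pos + 8L)
  }
}

.UNDEF <- 4294967295

## Skip an undefined-length sequence body; returns position after the
## sequence delimiter.
.skip_sq <- function(bytes, pos, explicit) {
  repeat {
    if (pos + 7L > length(bytes)) stop("truncated DICOM sequence")
    h <- .parse_header(bytes, pos, explicit)
    if (h$group == 0xFFFE && h$elem == 0xE0DD) return(h$data_pos)
    if (h$group == 0xFFFE && h$elem == 0xE000) { # item
      if (h$len == .UNDEF) {
        pos <- h$data_pos
        repeat {
          ih <- .parse_header(bytes, pos, explicit)
          if (ih$group == 0xFFFE && ih$elem == 0xE00D) {
            pos <- ih$data_pos
            break
          }
          pos <- if (ih$len == .UNDEF) {
            .skip_sq(bytes, ih$data_pos, explicit)
          } else {
            ih$data_pos + ih$len
          }
        }
      } else {
        pos <- h$data_pos + h$len
      }
    } else {
      stop("unexpected element inside sequence")
    }
  }
}

.ascii_value <- function(bytes, h) {
  if (h$len == 0) return("")
  val <- bytes[h$data_pos:(h$data_pos + h$len - 1L)]
  trimws(rawToChar(val[val != as.raw(0L)]))
}

.us_value <- function(bytes, h) .u16(bytes[h$data_pos:(h$data_pos + 1L)])

.ds_first <- function(s) {
  as.numeric(strsplit(s, "\\\\")[[1]][1])
}

## Read the raw tag set of a DICOM file; internal.
.read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140L ||
      !identical(rawToChar(bytes[129:132]), "DICM")) {
    stop("not a DICOM Part-10 file: ", path)
  }
  pos <- 133L
  ts <- .TS_EXPLICIT_LE
  ## file meta group is always explicit little endian
  while (pos + 7L <= length(bytes)) {
    h <- .parse_header(bytes, pos, explicit = TRUE)
    if (h$group != 0x0002) break
    if (h$elem == 0x0010) ts <- .ascii_value(bytes, h)
    pos <- h$data_pos + h$len
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    stop("unsupported transfer syntax: ", ts)
  )
  tags <- list()
  while (pos + 7L <= length(bytes)) {
    h <- .parse_header(bytes, pos, explicit)
    key <- sprintf("%04X%04X", h$group, h$elem)
    if (h$len == .UNDEF) {
      ## undefined length: a sequence body (e.g. a VOI LUT Sequence)
      tags[[key]] <- "SQ"
      pos <- .skip_sq(bytes, h$data_pos, explicit)
      next
    }
    take <- switch(key,
      "00100020" = , "00185101" = , "00200062" = , "00280004" = ,
      "00281050" = , "00281051" = "ascii",
      "00280002" = , "00280010" = , "00280011" = , "00280008" = ,
      "00280100" = , "00280101" = , "00280103" = "us",
      "7FE00010" = "pixels",
      NA_character_
    )
    if (!is.na(take)) {
      tags[[key]] <- switch(take,
        ascii = .ascii_value(bytes, h),
        us = .us_value(bytes, h),
        pixels = bytes[h$data_pos:(h$data_pos + h$len - 1L)]
      )
    } else if (key == "00283010") {
      tags[[key]] <- "SQ" # defined-length VOI LUT Sequence: noted, skipped
    }
    pos <- h$data_pos + h$len
  }
  tags
}

#' Read a DICOM mammogram
#'
#' Reads a grayscale DICOM file, optionally applies linear VOI LUT
#' windowing (when WindowCenter/WindowWidth are present), and normalizes
#' intensities to \[0, 1\]. Without a window, normalization divides by
#' \code{2^bits - 1} where \code{bits} is BitsStored when present and is
#' otherwise inferred from the maximum stored value
#' (see \code{\link{normalizeIntensity}}).
#'
#' @param path path to a .dcm file.
#' @param applyVoi apply the VOI window if the file carries one.
#' @return a \linkS4class{Mammogram}.
#' @details Only single-frame, single-sample (grayscale) images are
#'   supported; a tabulated VOI LUT Sequence is not applied (only the
#'   linear WindowCenter/WindowWidth form is implemented) and the DICOM
#'   sigmoid VOI LUT function is unsupported.
#' @export
readMammogram <- function(path, applyVoi = TRUE) {
  if (!file.exists(path)) stop("cannot read DICOM file: ", path)
  tags <- .read_dicom(path)
  if (is.null(tags[["7FE00010"]])) stop("DICOM file has no pixel data")
  spp <- tags[["00280002"]]
  if (!is.null(spp) && spp != 1L) {
    stop("unsupported format: color pixel data (SamplesPerPixel != 1)")
  }
  frames <- tags[["00280008"]]
  if (!is.null(frames) && frames > 1L) {
    stop("unsupported format: multi-frame pixel data")
  }
  rows <- tags[["00280010"]]
  cols <- tags[["00280011"]]
  if (is.null(rows) || is.null(cols)) stop("DICOM file lacks Rows/Columns")
  ba <- tags[["00280100"]]
  if (is.null(ba)) ba <- 16L
  pix <- tags[["7FE00010"]]
  if (ba == 16L) {
    vals <- readBin(pix, "integer", n = length(pix) / 2L, size = 2L,
                    signed = FALSE, endian = "little")
  } else if (ba == 8L) {
    vals <- as.integer(pix)
  } else {
    stop("unsupported format: BitsAllocated ", ba)
  }
  if (length(vals) != rows * cols) {
    stop("unsupported format: pixel data is not a single 2-D frame")
  }
  raw_mat <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  bits <- tags[["00280101"]]
  if (is.null(bits)) {
    bits <- normalizeIntensity(raw_mat)$bitDepth
  }
  wc <- tags[["00281050"]]
  ww <- tags[["00281051"]]
  if (applyVoi && !is.null(wc) && !is.null(ww)) {
    pixels <- applyVoiLut(raw_mat, .ds_first(wc), .ds_first(ww))
  } else {
    pixels <- raw_mat / (2^bits - 1)
    pixels[pixels > 1] <- 1
  }
  lat <- switch(tags[["00200062"]] %||% "",
                L = "LEFT", R = "RIGHT", "UNKNOWN")
  proj <- tags[["00185101"]] %||% ""
  proj <- if (proj %in% c("CC", "MLO")) proj else "UNKNOWN"
  new("Mammogram",
      pixels = pixels, laterality = lat, projection = proj,
      sourceBitDepth = as.integer(bits),
      originalShape = c(as.integer(rows), as.integer(cols)),
      patientID = tags[["00100020"]] %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear VOI LUT windowing
#'
#' Maps stored pixel values to display intensities in \[0, 1\] with the
#' linear window transform: values at or below
#' \code{center - width/2} map to 0, values at or above
#' \code{center + width/2} map to 1, linear in between.
#'
#' @param raw numeric matrix (or vector) of stored values.
#' @param windowCenter window center in stored-value units.
#' @param windowWidth window width (> 0) in stored-value units.
#' @return numeric array of the same shape with values in \[0, 1\].
#' @export
applyVoiLut <- function(raw, windowCenter, windowWidth) {
  if (!is.numeric(windowWidth) || windowWidth <= 0) {
    stop("windowWidth must be > 0")
  }
  out <- (raw - (windowCenter - windowWidth / 2)) / windowWidth
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Normalize stored intensities by inferred bit depth
#'
#' Infers the acquisition bit depth from the maximum stored value as the
#' smallest depth in \{8, 10, 12, 14, 16\} (the depths used by digital
#' mammography) that can represent it, then divides by \code{2^bits - 1}.
#'
#' @param raw integer matrix with at least one nonzero pixel.
#' @return list with \code{pixels} (matrix in \[0, 1\]) and \code{bitDepth}.
#' @export
normalizeIntensity <- function(raw) {
  mx <- max(raw)
  if (mx <= 0) stop("degenerate input: all-zero image")
  depths <- c(8L, 10L, 12L, 14L, 16L)
  ok <- depths[mx <= 2^depths - 1]
  if (length(ok) == 0L) stop("intensities exceed 16-bit range")
  b <- ok[1]
  list(pixels = raw / (2^b - 1), bitDepth = b)
}

#' Resize an image (or Mammogram) to the standard analysis resolution
#'
#' Bilinear resize to a square \code{target} x \code{target} frame (no
#' aspect-ratio preservation; the original shape is retained on the
#' \linkS4class{Mammogram} for reporting). An image already at the target
#' size is returned unchanged, bit for bit.
#'
#' @param x numeric matrix in \[0, 1\], or a \linkS4class{Mammogram}.
#' @param target side length in pixels.
#' @return object of the same kind as \code{x}, resized.
#' @export
setGeneric("resizeToStandard",
           function(x, target = 512L) standardGeneric("resizeToStandard"))

#' @rdname resizeToStandard
#' @export
setMethod("resizeToStandard", "matrix", function(x, target = 512L) {
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
  if (nrow(x) == target && ncol(x) == target) return(x)
  out <- EBImage::resize(x, w = target, h = target, filter = "bilinear")
  out <- matrix(as.numeric(out), nrow = target, ncol = target)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
})

#' @rdname resizeToStandard
#' @export
setMethod("resizeToStandard", "Mammogram", function(x, target = 512L) {
  x@pixels <- resizeToStandard(x@pixels, target)
  validObject(x)
  x
})

#' Dump an intensity image or mask to 8-bit PNG for inspection
#'
#' Intensities are scaled by 255 and rounded half-up; logical masks are
#' written as 0/255.
#'
#' @param x numeric matrix in \[0, 1\] or logical matrix.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writePng <- function(x, path) {
  if (is.logical(x)) {
    img <- matrix(as.numeric(x), nrow(x), ncol(x))
  } else {
    img <- floor(x * 255 + 0.5) / 255
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read a binary mask from a PNG file
#'
#' Grayscale (or first-channel) values above 0.5 are foreground.
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
readMaskPng <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}
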