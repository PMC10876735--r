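# Minimal DICOM support: single-frame, explicit-VR little-endian files, one
# slice per file.  Only the handful of tags the pipeline needs are written
# and read (rows/cols, pixel spacing, slice spacing, instance number, pixel
# data with a linear rescale).  This is deliberately not a general DICOM
# implementation: orientation matrices, sequences and compressed transfer
# syntaxes are out of scope.

dcmU16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
dcmU32 <- function(raw4) sum(as.numeric(raw4) * 256^(0:3))

rawU16 <- function(x) as.raw(c(x %% 256L, x %/% 256L %% 256L))
rawU32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256,
                               x %/% 256^2 %% 256, x %/% 256^3 %% 256))

dcmElement <- function(group, elem, vr, value) {
  if (vr %in% c("DS", "IS", "CS", "UI", "LO")) {
    v <- charToRaw(as.character(value))
    if (length(v) %% 2L == 1L)
      v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  } else if (vr == "US") {
    v <- rawU16(as.integer(value))
  } else if (vr == "UL") {
    v <- rawU32(value)
  } else if (vr == "OW") {
    v <- value  # already raw
  } else stop("unsupported VR")
  hdr <- c(rawU16(group), rawU16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UT", "UN"))
    c(hdr, as.raw(c(0L, 0L)), rawU32(length(v)), v)
  else
    c(hdr, rawU16(length(v)), v)
}

# Write one slice; intensities are linearly mapped to uint16 with the
# mapping stored as RescaleSlope/RescaleIntercept.
writeDicomSlice <- function(slice, path, instance, inPlaneSpacing,
                            sliceSpacing, lo, hi) {
  nr <- nrow(slice); nc <- ncol(slice)
  slope <- if (hi > lo) (hi - lo) / 65535 else 1
  stored <- as.integer(round((t(slice) - lo) / slope))  # row-major pixels
  pix <- writeBin(stored, raw(), size = 2L, endian = "little")
  meta <- c(
    dcmElement(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  body <- c(
    dcmElement(0x0008, 0x0060, "CS", "MR"),
    dcmElement(0x0018, 0x0050, "DS", format(sliceSpacing)),
    dcmElement(0x0018, 0x0088, "DS", format(sliceSpacing)),
    dcmElement(0x0020, 0x0013, "IS", format(instance)),
    dcmElement(0x0028, 0x0010, "US", nr),
    dcmElement(0x0028, 0x0011, "US", nc),
    dcmElement(0x0028, 0x0030, "DS",
               paste0(format(inPlaneSpacing[1]), "\\",
                      format(inPlaneSpacing[2]))),
    dcmElement(0x0028, 0x0100, "US", 16L),
    dcmElement(0x0028, 0x0103, "US", 0L),
    dcmElement(0x0028, 0x1052, "DS", format(lo)),
    dcmElement(0x0028, 0x1053, "DS", format(slope)),
    dcmElement(0x7FE0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(dcmElement(0x0002, 0x0000, "UL", length(meta)), meta, body), con)
  invisible(path)
}

#' Write an image stack as a DICOM series
#'
#' One explicit-VR little-endian single-frame file per slice, carrying pixel
#' spacing, slice spacing, instance number and linearly rescaled uint16
#' pixel data.  Intended for phantom export and round-trip testing, not as a
#' clinical-grade DICOM implementation.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
writeDicomSeries <- function(stack, dir) {
  stopifnot(is(stack, "ImageStack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- stack@values
  lo <- min(v); hi <- max(v)
  g <- stack@geometry
  paths <- vapply(seq_len(dim(v)[1]), function(z) {
    p <- file.path(dir, sprintf("slice_%03d.dcm", z))
    writeDicomSlice(v[z, , ], p, instance = z,
                    inPlaneSpacing = g@inPlaneSpacing,
                    sliceSpacing = g@sliceSpacing, lo = lo, hi = hi)
    p
  }, character(1))
  invisible(paths)
}

parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    lmnError(sprintf("'%s' is not a DICOM file", path),
             "landmarknetFormatError")
  p <- 133L
  out <- list()
  n <- length(raw)
  while (p + 7L <= n) {
    group <- dcmU16(raw[p:(p + 1L)])
    elem <- dcmU16(raw[(p + 2L):(p + 3L)])
    vr <- rawToChar(raw[(p + 4L):(p + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- dcmU32(raw[(p + 8L):(p + 11L)])
      vp <- p + 12L
    } else {
      len <- dcmU16(raw[(p + 6L):(p + 7L)])
      vp <- p + 8L
    }
    if (vp + len - 1L > n)
      lmnError(sprintf("truncated DICOM element in '%s'", path),
               "landmarknetFormatError")
    key <- sprintf("%04x%04x", group, elem)
    val <- raw[vp:(vp + len - 1L)]
    out[[key]] <- list(vr = vr, value = val)
    p <- vp + len
  }
  out
}

dcmString <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

readDicomSeries <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L)
    lmnError(sprintf("no DICOM slices found in '%s'", dir),
             "landmarknetFormatError")
  slices <- lapply(files, parseDicomFile)
  inst <- vapply(slices, function(s) {
    v <- dcmString(s[["00200013"]])
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  ord <- order(inst)
  slices <- slices[ord]
  first <- slices[[1]]
  spacingStr <- dcmString(first[["00280030"]])
  sliceStr <- dcmString(first[["00180088"]]) %||% dcmString(first[["00180050"]])
  if (is.null(spacingStr) || is.null(sliceStr))
    lmnError("DICOM series lacks pixel/slice spacing metadata",
             "landmarknetMetadataError")
  ips <- as.numeric(strsplit(spacingStr, "\\\\")[[1]])
  nr <- dcmU16(first[["00280010"]]$value)
  nc <- dcmU16(first[["00280011"]]$value)
  vals <- array(0, c(length(slices), nr, nc))
  for (z in seq_along(slices)) {
    s <- slices[[z]]
    pix <- s[["7fe00010"]]
    if (is.null(pix))
      lmnError("DICOM slice without pixel data", "landmarknetFormatError")
    stored <- readBin(pix$value, "integer", n = nr * nc, size = 2L,
                      signed = FALSE, endian = "little")
    slope <- as.numeric(dcmString(s[["00281053"]]) %||% "1")
    inter <- as.numeric(dcmString(s[["00281052"]]) %||% "0")
    vals[z, , ] <- t(matrix(stored * slope + inter, nc, nr))
  }
  geom <- voxelGeometry(inPlaneSpacing = ips,
                        sliceSpacing = as.numeric(sliceStr))
  imageStack(vals, geom, subjectId = basename(dir))
}
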