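## Minimal single-frame grayscale DICOM input/output.
##
## Scope: uncompressed little-endian transfer syntaxes only (explicit VR
## written; explicit and implicit VR read), MONOCHROME2, 16-bit signed
## pixels, single frame. Enough to round-trip the pipeline's images and
## masks and to interoperate with standard DICOM toolkits on such files.

.DCM_TS_EXPLICIT <- "1.2.840.10008.1.2.1"
.DCM_TS_IMPLICIT <- "1.2.840.10008.1.2"
.DCM_UID_ROOT <- "1.2.826.0.1.3680043.10.999"

.dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")
.dcm_uint32 <- function(x) {
  ## writeBin has no unsigned 32-bit; lengths here are far below 2^31
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

.dcm_pad <- function(bytes, padByte) {
  if (length(bytes) %% 2L == 1L) c(bytes, padByte) else bytes
}

## Encode one data element, explicit VR little endian.
.dcm_element <- function(group, element, vr, value) {
  body <- switch(vr,
    US = .dcm_uint16(value),
    UL = .dcm_uint32(value),
    OW = value,                       # raw vector already
    OB = value,
    UI = .dcm_pad(charToRaw(value), as.raw(0L)),
    DS = ,
    IS = ,
    CS = ,
    LO = ,
    SH = .dcm_pad(charToRaw(value), charToRaw(" ")),
    stop("unsupported VR ", vr))
  head <- c(.dcm_uint16(group), .dcm_uint16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    c(head, as.raw(c(0L, 0L)), .dcm_uint32(length(body)), body)
  } else {
    c(head, .dcm_uint16(length(body)), body)
  }
}

.dcm_format_ds <- function(x) {
  s <- formatC(x, format = "fg", digits = 10)
  gsub(" ", "", s)
}

## Write a 2D numeric matrix as a single-frame DICOM file.
## NA pixels are stored as the minimum representable raw value.
.dcm_write <- function(path, values, spacingMm, slope = 1, intercept = 0,
                       modality = "OT") {
  stopifnot(is.matrix(values), slope != 0)
  raw16 <- round((values - intercept) / slope)
  raw16[!is.finite(raw16)] <- -32768
  raw16 <- pmax(pmin(raw16, 32767), -32768)
  ## PixelData is row-major (row by row); R matrices are column-major
  pix <- writeBin(as.integer(t(raw16)), raw(), size = 2, endian = "little")

  sopInstance <- sprintf("%s.1.%d.%d.%d", .DCM_UID_ROOT, nrow(values),
                         ncol(values),
                         abs(sum(as.numeric(raw16))) %% 999999937)
  sopClass <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture

  ds <- c(
    .dcm_element(0x0008, 0x0016, "UI", sopClass),
    .dcm_element(0x0008, 0x0018, "UI", sopInstance),
    .dcm_element(0x0008, 0x0060, "CS", modality),
    .dcm_element(0x0028, 0x0002, "US", 1L),
    .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_element(0x0028, 0x0010, "US", nrow(values)),
    .dcm_element(0x0028, 0x0011, "US", ncol(values)),
    .dcm_element(0x0028, 0x0030, "DS",
                 paste(.dcm_format_ds(spacingMm), .dcm_format_ds(spacingMm),
                       sep = "\\")),
    .dcm_element(0x0028, 0x0100, "US", 16L),
    .dcm_element(0x0028, 0x0101, "US", 16L),
    .dcm_element(0x0028, 0x0102, "US", 15L),
    .dcm_element(0x0028, 0x0103, "US", 1L),
    .dcm_element(0x0028, 0x1052, "DS", .dcm_format_ds(intercept)),
    .dcm_element(0x0028, 0x1053, "DS", .dcm_format_ds(slope)),
    .dcm_element(0x7FE0, 0x0010, "OW", pix))

  meta <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .dcm_element(0x0002, 0x0002, "UI", sopClass),
    .dcm_element(0x0002, 0x0003, "UI", sopInstance),
    .dcm_element(0x0002, 0x0010, "UI", .DCM_TS_EXPLICIT),
    .dcm_element(0x0002, 0x0012, "UI", paste0(.DCM_UID_ROOT, ".0.1")))
  metaLen <- .dcm_element(0x0002, 0x0000, "UL", length(meta))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(metaLen, meta, ds), con)
  invisible(path)
}

## VRs with the 4-byte length form in explicit encoding
.DCM_LONG_VR <- c("OB", "OW", "OF", "SQ", "UT", "UN")

## Tag-keyed dictionary for the elements the reader interprets.
.DCM_KEYS <- c("0008,0060" = "modality",
               "0028,0008" = "frames",
               "0028,0010" = "rows",
               "0028,0011" = "cols",
               "0028,0030" = "spacing",
               "0028,0100" = "bits",
               "0028,0103" = "pixrep",
               "0028,1052" = "intercept",
               "0028,1053" = "slope",
               "7fe0,0010" = "pixeldata")

## Parse a single-frame grayscale DICOM file into a list:
## values (rescaled matrix), spacingMm, slope, intercept, modality.
.dcm_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 ||
      rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)

  u16 <- function(at) sum(as.integer(bytes[at + 0:1]) * c(1, 256))
  u32 <- function(at) sum(as.integer(bytes[at + 0:3]) * c(1, 256, 65536,
                                                          16777216))
  pos <- 133L
  ts <- .DCM_TS_EXPLICIT
  fields <- list()
  explicit <- TRUE
  metaEnd <- Inf

  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); element <- u16(pos + 2L)
    inMeta <- group == 2L
    useExplicit <- inMeta || explicit
    if (useExplicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% .DCM_LONG_VR) {
        len <- u32(pos + 8L); valAt <- pos + 12L
      } else {
        len <- u16(pos + 6L); valAt <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4L); valAt <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length elements unsupported")
    val <- if (len > 0) bytes[valAt:(valAt + len - 1L)] else raw(0)
    tag <- sprintf("%04x,%04x", group, element)

    if (tag == "0002,0010") {
      ts <- sub("\\s+$", "", rawToChar(val[val != as.raw(0)]))
      if (!ts %in% c(.DCM_TS_EXPLICIT, .DCM_TS_IMPLICIT))
        stop("unsupported transfer syntax: ", ts)
      explicit <- ts == .DCM_TS_EXPLICIT
    }
    key <- .DCM_KEYS[tag]
    if (!is.na(key)) {
      fields[[key]] <- if (tag == "7fe0,0010") {
        val
      } else if (tag %in% c("0028,0010", "0028,0011", "0028,0100",
                            "0028,0103")) {
        u16(valAt)
      } else {
        sub("\\s+$", "", rawToChar(val[val != as.raw(0)]))
      }
    }
    pos <- valAt + len
    if (!is.na(key) && key == "pixeldata") break
  }

  if (!is.null(fields$frames) && as.integer(fields$frames) > 1L)
    stop("multi-frame DICOM input is unsupported")
  if (is.null(fields$rows) || is.null(fields$cols) ||
      is.null(fields$pixeldata))
    stop("DICOM header error: missing Rows/Columns/PixelData")
  if (is.null(fields$spacing))
    stop("DICOM header error: missing PixelSpacing (0028,0030)")

  sp <- as.numeric(strsplit(fields$spacing, "\\\\")[[1]])
  if (any(!is.finite(sp)) || length(sp) < 1L || sp[1] <= 0)
    stop("DICOM header error: unparsable PixelSpacing")
  if (length(sp) == 2L && abs(sp[1] - sp[2]) > 1e-9)
    stop("non-square pixels are unsupported")

  bits <- if (is.null(fields$bits)) 16L else fields$bits
  if (bits != 16L) stop("only 16-bit pixel data is supported")
  signed <- !is.null(fields$pixrep) && fields$pixrep == 1L
  n <- fields$rows * fields$cols
  raw16 <- readBin(fields$pixeldata, "integer", n = n, size = 2,
                   signed = signed, endian = "little")
  values <- matrix(raw16, nrow = fields$rows, ncol = fields$cols,
                   byrow = TRUE)

  list(values = values, spacingMm = sp[1],
       slope = if (is.null(fields$slope)) NA_real_
               else as.numeric(fields$slope),
       intercept = if (is.null(fields$intercept)) NA_real_
                   else as.numeric(fields$intercept),
       modality = if (is.null(fields$modality)) "OT" else fields$modality)
}
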