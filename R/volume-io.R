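#' Read a volumetric image
#'
#' Supported inputs: NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mha`, `.mhd`),
#' or a directory containing a single-frame DICOM series (explicit VR,
#' little endian, uncompressed).  Grey values are preserved bit-exactly for
#' integer inputs.  DICOM slices are ordered by their image position along
#' the slice normal, never by file name; non-uniform slice spacing beyond 1%
#' is a geometry error.
#'
#' Anatomical axis labels are recovered from the metadata written by
#' [write_volume()] (NIfTI `descrip` / MetaImage `Comment`); files from
#' other sources default to `c("ML", "AP", "PD")` with a log note.
#'
#' @param path file path or DICOM directory.
#' @return a [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) rf_stop("volio", "no such file or directory: %s", path)
  if (dir.exists(path)) return(read_dicom_series(path))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_nifti_volume(path))
  if (grepl("\\.(mha|mhd)$", lp)) return(read_metaimage(path))
  rf_stop("volio", "unrecognized volume format: %s", basename(path))
}

#' Write a volumetric image
#'
#' Inverse of [read_volume()] for NIfTI and MetaImage; round-trips are exact
#' for integer grey values and within machine precision for doubles.  DICOM
#' writing is intentionally not supported.
#'
#' @param vol a [volume_image()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image") || inherits(vol, "binary_mask"))
  if (inherits(vol, "binary_mask"))
    vol <- volume_image(array(as.integer(vol$data), dim(vol$data)),
                        vol$spacing, vol$origin, vol$axes)
  lp <- tolower(path)
  ok <- tryCatch({
    if (grepl("\\.nii(\\.gz)?$", lp)) write_nifti_volume(vol, path)
    else if (grepl("\\.mha$", lp)) write_metaimage(vol, path)
    else rf_stop("volio", "unsupported output format: %s", basename(path))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) rf_stop("volio", "cannot write %s: %s", path,
                           conditionMessage(ok))
  invisible(path)
}

## ---- NIfTI -----------------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  data <- as.array(img)
  if (length(dim(data)) != 3L)
    rf_stop("volio", "NIfTI volume is not 3D: %s", basename(path))
  spacing <- abs(RNifti::pixdim(img))[1:3]
  origin <- RNifti::xform(img)[1:3, 4]
  axes <- parse_axes_tag(hdr$descrip)
  volume_image(data, spacing, origin, axes)
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data,
                         list(descrip = paste0("axes:", paste(vol$axes, collapse = ","))))
  m <- diag(4)
  m[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::`pixdim<-`(img, vol$spacing) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

parse_axes_tag <- function(txt) {
  m <- regmatches(txt, regexpr("axes:[A-Z,]+", txt))
  if (length(m) == 1 && nzchar(m)) {
    ax <- strsplit(sub("axes:", "", m), ",")[[1]]
    if (setequal(ax, c("ML", "AP", "PD"))) return(ax)
  }
  rf_log("info", "no axis labels in file metadata; assuming ML,AP,PD")
  c("ML", "AP", "PD")
}

## ---- MetaImage -------------------------------------------------------------

.met_types <- list(
  MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
  MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
  MET_INT = list(what = "integer", size = 4, signed = TRUE),
  MET_UINT = list(what = "integer", size = 4, signed = FALSE),
  MET_FLOAT = list(what = "double", size = 4, signed = TRUE),
  MET_DOUBLE = list(what = "double", size = 8, signed = TRUE)
)

read_metaimage <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # header is the text up to and including the ElementDataFile line
  nl <- which(raw == as.raw(10))
  hdr_lines <- character()
  data_off <- NA_integer_
  start <- 1L
  for (pos in nl) {
    line <- rawToChar(raw[start:(pos - 1L)])
    line <- sub("\r$", "", line)
    hdr_lines <- c(hdr_lines, line)
    start <- pos + 1L
    if (grepl("^\\s*ElementDataFile", line)) { data_off <- pos; break }
  }
  if (is.na(data_off)) rf_stop("volio", "corrupt MetaImage header (no ElementDataFile): %s",
                               basename(path))
  kv <- strsplit(hdr_lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  names(vals) <- trimws(keys)
  need <- function(k) {
    if (!k %in% names(vals)) rf_stop("volio", "MetaImage header missing %s", k)
    vals[[k]]
  }
  if (as.integer(need("NDims")) != 3L) rf_stop("volio", "only 3D MetaImage supported")
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  etype <- need("ElementType")
  tp <- .met_types[[etype]]
  if (is.null(tp)) rf_stop("volio", "unsupported ElementType %s", etype)
  if (isTRUE(toupper(vals["CompressedData"]) == "TRUE"))
    rf_stop("volio", "compressed MetaImage not supported")
  spacing <- if ("ElementSpacing" %in% names(vals))
    as.numeric(strsplit(vals[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if ("Offset" %in% names(vals))
    as.numeric(strsplit(vals[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  axes <- parse_axes_tag(if ("Comment" %in% names(vals)) vals[["Comment"]] else "")
  datafile <- trimws(need("ElementDataFile"))
  n <- prod(dims)
  if (toupper(datafile) == "LOCAL") {
    bytes <- raw[(data_off + 1L):length(raw)]
  } else {
    dpath <- file.path(dirname(path), datafile)
    if (!file.exists(dpath)) rf_stop("volio", "MetaImage data file missing: %s", datafile)
    bytes <- readBin(dpath, "raw", file.size(dpath))
  }
  if (length(bytes) < n * tp$size)
    rf_stop("volio", "MetaImage data truncated (%d bytes, need %d)",
            length(bytes), n * tp$size)
  vals_num <- readBin(bytes, tp$what, n = n, size = tp$size,
                      signed = if (tp$size < 4) tp$signed else TRUE,
                      endian = "little")
  volume_image(array(vals_num, dims), spacing, origin, axes)
}

write_metaimage <- function(vol, path) {
  data <- vol$data
  integral <- is.integer(data) ||
    (is.numeric(data) && all(data == round(data)) && max(abs(data)) < 2^31 - 1)
  etype <- if (integral) "MET_INT" else "MET_DOUBLE"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(data), collapse = " ")),
    paste("ElementSpacing =", paste(sprintf("%.17g", vol$spacing), collapse = " ")),
    paste("Offset =", paste(sprintf("%.17g", vol$origin), collapse = " ")),
    paste0("Comment = axes:", paste(vol$axes, collapse = ",")),
    paste("ElementType =", etype),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (integral)
    writeBin(as.integer(data), con, size = 4, endian = "little")
  else
    writeBin(as.double(data), con, size = 8, endian = "little")
  invisible(path)
}

## ---- DICOM (read-only, explicit VR little endian) --------------------------

# VRs carrying a 4-byte length after 2 reserved bytes
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    rf_stop("volio", "not a DICOM file (missing DICM magic): %s", basename(path))
  pos <- 133L
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) as.integer(raw[p]) + 256 * as.integer(raw[p + 1L]) +
    65536 * as.integer(raw[p + 2L]) + 16777216 * as.integer(raw[p + 3L])
  tags <- list()
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      rf_stop("volio", "unsupported DICOM encoding (implicit VR?): %s", basename(path))
    if (vr %in% .long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1L > length(raw))
      rf_stop("volio", "truncated DICOM element in %s", basename(path))
    key <- sprintf("%04x,%04x", group, elem)
    val <- raw[vstart:(vstart + len - 1L)]
    tags[[key]] <- list(vr = vr, bytes = val)
    pos <- vstart + len
    if (key == "7fe0,0010") break
  }
  tags
}

dicom_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  trimws(rawToChar(t$bytes))
}
dicom_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$bytes, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
}

read_dicom_series <- function(dirpath) {
  files <- list.files(dirpath, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) rf_stop("volio", "empty DICOM directory: %s", dirpath)
  slices <- lapply(files, function(f) {
    tags <- parse_dicom_file(f)
    rows <- dicom_us(tags, "0028,0010")
    cols <- dicom_us(tags, "0028,0011")
    if (is.null(rows) || is.null(cols))
      rf_stop("volio", "DICOM file lacks Rows/Columns: %s", basename(f))
    psp <- as.numeric(strsplit(dicom_str(tags, "0028,0030"), "\\\\")[[1]])
    ipp <- as.numeric(strsplit(dicom_str(tags, "0020,0032"), "\\\\")[[1]])
    bits <- dicom_us(tags, "0028,0100")
    rep_ <- dicom_us(tags, "0028,0103")
    if (is.null(bits)) bits <- 16L
    if (is.null(rep_)) rep_ <- 0L
    px <- tags[["7fe0,0010"]]
    if (is.null(px)) rf_stop("volio", "DICOM file lacks PixelData: %s", basename(f))
    vals <- readBin(px$bytes, "integer", n = as.integer(rows) * cols,
                    size = bits / 8, signed = (rep_ == 1L) || bits >= 32,
                    endian = "little")
    # PixelData is row-major: cols vary fastest within a row
    m <- t(matrix(vals, nrow = cols, ncol = rows))
    list(rows = rows, cols = cols, psp = psp, z = ipp[3], ipp = ipp, data = m)
  })
  ord <- order(vapply(slices, `[[`, 0, "z"))
  slices <- slices[ord]
  nz <- length(slices)
  rows <- slices[[1]]$rows; cols <- slices[[1]]$cols
  if (!all(vapply(slices, function(s) s$rows == rows && s$cols == cols, TRUE)))
    rf_stop("volio", "DICOM slices have inconsistent dimensions")
  if (nz >= 2) {
    dz <- diff(vapply(slices, `[[`, 0, "z"))
    if (any(dz <= 0)) rf_stop("volio", "duplicate or unordered DICOM slice positions")
    if ((max(dz) - min(dz)) / mean(dz) > 0.01)
      rf_stop("volio", "non-uniform DICOM slice spacing beyond 1%%")
    zsp <- mean(dz)
  } else zsp <- 1
  psp <- slices[[1]]$psp # [row spacing, column spacing]
  arr <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) arr[, , k] <- t(slices[[k]]$data)
  if (all(arr == round(arr))) storage.mode(arr) <- "integer"
  origin <- c(slices[[1]]$ipp[1], slices[[1]]$ipp[2], slices[[1]]$z)
  rf_log("info", "DICOM series: %d slices, spacing %.4g x %.4g x %.4g mm",
         nz, psp[2], psp[1], zsp)
  volume_image(arr, c(psp[2], psp[1], zsp), origin, c("ML", "AP", "PD"))
}

# Minimal single-frame DICOM writer (explicit VR LE, uncompressed).  Used to
# build synthetic series in tests; DICOM *writing* is not part of the public
# surface.
write_dicom_series <- function(vol, dirpath) {
  dir.create(dirpath, showWarnings = FALSE, recursive = TRUE)
  data <- vol$data
  if (min(data) < 0 || max(data) > 65535 || any(data != round(data)))
    rf_stop("volio", "DICOM test writer needs integer grey values in [0, 65535]")
  nz <- dim(data)[3]
  elem <- function(group, el, vr, bytes) {
    if (length(bytes) %% 2 == 1) bytes <- c(bytes, as.raw(if (vr == "UI") 0 else 32))
    hdr <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
             writeBin(as.integer(el), raw(), size = 2, endian = "little"),
             charToRaw(vr))
    if (vr %in% .long_vrs)
      c(hdr, as.raw(c(0, 0)),
        writeBin(length(bytes), raw(), size = 4, endian = "little"), bytes)
    else
      c(hdr, writeBin(length(bytes), raw(), size = 2, endian = "little"), bytes)
  }
  ds <- function(...) charToRaw(paste(sprintf("%.10g", c(...)), collapse = "\\"))
  us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  for (k in seq_len(nz)) {
    slice <- data[, , k] # [i = ML/cols, j = AP/rows]
    # stream order: rows outer, columns fastest == column-major of [i, j]
    px <- writeBin(as.integer(as.vector(slice)), raw(), size = 2,
                   endian = "little")
    z <- vol$origin[3] + (k - 1) * vol$spacing[3]
    body <- c(
      elem(0x0008, 0x0060, "CS", charToRaw("CT")),
      elem(0x0020, 0x0013, "IS", charToRaw(as.character(k))),
      elem(0x0020, 0x0032, "DS", ds(vol$origin[1], vol$origin[2], z)),
      elem(0x0020, 0x0037, "DS", ds(1, 0, 0, 0, 1, 0)),
      elem(0x0028, 0x0002, "US", us(1)),
      elem(0x0028, 0x0010, "US", us(dim(data)[2])),  # Rows = AP extent
      elem(0x0028, 0x0011, "US", us(dim(data)[1])),  # Columns = ML extent
      elem(0x0028, 0x0030, "DS", ds(vol$spacing[2], vol$spacing[1])),
      elem(0x0028, 0x0100, "US", us(16)),
      elem(0x0028, 0x0101, "US", us(16)),
      elem(0x0028, 0x0102, "US", us(15)),
      elem(0x0028, 0x0103, "US", us(0)),
      elem(0x7FE0, 0x0010, "OW", px)
    )
    out <- c(raw(128), charToRaw("DICM"), body)
    writeBin(out, file.path(dirpath, sprintf("slice_%03d.dcm", k)))
  }
  invisible(dirpath)
}
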