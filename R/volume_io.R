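#' Read or write a scalar volume as NRRD
#'
#' Minimal NRRD (raw encoding, little endian) support sufficient for exact
#' round-trips of [voxel_volume()] objects: `data`, `spacing` and `origin`
#' are preserved bitwise. Axis-aligned `space directions` only.
#'
#' @param path file path ending in `.nrrd`.
#' @return [read_volume()] returns a [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!grepl("\\.nrrd$", path, ignore.case = TRUE))
    stop("unknown volume format (expected .nrrd): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header: ", path)
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    fields[[trimws(kv[1])]] <- trimws(kv[2])
  }
  need <- c("type", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss) > 0)
    stop("NRRD header missing required field(s): ", paste(miss, collapse = ", "))
  if (fields$encoding != "raw") stop("only raw NRRD encoding is supported")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  if (is.null(fields$`space directions`))
    stop("NRRD header missing spacing ('space directions' field)")
  dirs <- parse_nrrd_vectors(fields$`space directions`)
  if (nrow(dirs) != 3L) stop("expected 3 space direction vectors")
  offdiag <- dirs; diag(offdiag) <- 0
  if (any(offdiag != 0))
    stop("oblique NRRD volumes are not supported (non-axis-aligned space directions)")
  spacing <- diag(dirs)
  origin <- if (!is.null(fields$`space origin`))
    as.numeric(parse_nrrd_vectors(fields$`space origin`)) else c(0, 0, 0)
  n <- prod(sizes)
  what <- switch(fields$type,
                 "double" = "double", "float" = "double",
                 "short" = "integer", "int16" = "integer",
                 "int" = "integer", "int32" = "integer",
                 "uchar" = "integer", "uint8" = "integer",
                 stop("unsupported NRRD type: ", fields$type))
  size <- switch(fields$type,
                 "double" = 8L, "float" = 4L, "short" = 2L, "int16" = 2L,
                 "int" = 4L, "int32" = 4L, "uchar" = 1L, "uint8" = 1L)
  signed <- !fields$type %in% c("uchar", "uint8")
  raw <- readBin(con, what = what, n = n, size = size, signed = signed,
                 endian = "little")
  if (length(raw) != n) stop("NRRD data shorter than 'sizes' promise")
  voxel_volume(array(as.numeric(raw), dim = sizes), spacing, origin)
}

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  do.call(rbind, lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])))
}

#' @rdname read_volume
#' @param volume a [voxel_volume()] to write.
#' @export
write_volume <- function(volume, path) {
  if (!grepl("\\.nrrd$", path, ignore.case = TRUE))
    stop("unknown volume format (expected .nrrd): ", path)
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(volume$data)
  sp <- volume$spacing
  hdr <- c(
    "NRRD0004",
    "# written by guidefit",
    "type: double",
    "dimension: 3",
    "space dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            sp[1], sp[2], sp[3]),
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    "")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.numeric(volume$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a CT volume from a DICOM series directory
#'
#' Reads every single-frame CT slice in `directory` (uncompressed implicit
#' or explicit VR little endian), sorts slices by position along the slice
#' axis, rescales intensities by slope/intercept and assembles an
#' axis-aligned [voxel_volume()]. Mixed series UIDs, oblique orientations
#' and non-uniform slice gaps (beyond 1% of the gap) are rejected; a series
#' with fewer than two slices is an error. Missing rescale tags fall back to
#' slope 1 / intercept 0 with a warning.
#'
#' @param directory path holding the slice files.
#' @param pattern filename regexp for slice files (default `\\.dcm$`,
#'   case-insensitive).
#' @return A [voxel_volume()] with intensities in rescaled CT units.
#' @export
read_dicom_series <- function(directory, pattern = "\\.dcm$") {
  files <- list.files(directory, pattern = pattern, full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) < 2L)
    stop("DICOM series needs at least 2 slices, found ", length(files))
  slices <- lapply(files, read_dicom_slice)

  uids <- vapply(slices, function(s) s$series_uid %||% "", "")
  if (length(unique(uids)) > 1L)
    stop("mixed SeriesInstanceUID values in directory: not a single series")

  for (s in slices) {
    ori <- s$orientation
    if (!is.null(ori) && max(abs(ori - c(1, 0, 0, 0, 1, 0))) > 1e-6)
      stop("oblique DICOM orientations are not supported (ImageOrientationPatient must be 1\\0\\0\\0\\1\\0)")
  }

  z <- vapply(slices, function(s) s$position[3], 0)
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  gaps <- diff(z)
  if (any(gaps <= 0)) stop("duplicate or non-increasing slice positions")
  if ((max(gaps) - min(gaps)) > 0.01 * mean(gaps))
    stop(sprintf("non-uniform slice gap: min %.6g mm, max %.6g mm", min(gaps),
                 max(gaps)))

  ps <- slices[[1]]$pixel_spacing
  for (s in slices)
    if (max(abs(s$pixel_spacing - ps)) > 1e-9)
      stop("in-plane pixel spacing differs between slices")

  no_rescale <- vapply(slices, function(s) is.null(s$slope), TRUE)
  if (any(no_rescale))
    warning("missing rescale tags in ", sum(no_rescale),
            " slice(s); assuming slope 1, intercept 0")

  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows
  data <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    if (s$cols != nx || s$rows != ny) stop("slice matrix sizes differ")
    slope <- s$slope %||% 1
    intercept <- s$intercept %||% 0
    # pixel data is row-major (rows of the image = y)
    data[, , k] <- matrix(s$pixels, nrow = nx, ncol = ny) * slope + intercept
  }
  # PixelSpacing is (row spacing, column spacing) = (dy, dx)
  spacing <- c(ps[2], ps[1], mean(gaps))
  origin <- c(slices[[1]]$position[1], slices[[1]]$position[2], z[1])
  voxel_volume(data, spacing, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- minimal DICOM single-frame parser (uncompressed little endian) ---

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L) stop("not a DICOM file (too short): ", path)
  if (rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  n <- length(raw)
  out <- list()
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) as.numeric(u16(p)) + 65536 * u16(p + 2L)
  explicit_vrs <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO",
                    "LT","OB","OF","OW","PN","SH","SL","SQ","SS","ST","TM",
                    "UI","UL","UN","US","UT")
  while (pos + 8L <= n + 1L) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vb <- raw[(pos + 4L):(pos + 5L)]
    is_alpha <- all(as.integer(vb) >= 65L & as.integer(vb) <= 90L)
    vr <- if (is_alpha) rawToChar(vb) else ""
    explicit <- vr %in% explicit_vrs
    if (explicit) {
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- u32(pos + 8L)
        hdr <- 12L
      } else {
        len <- u16(pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4L)
      hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements not supported")
    val_start <- pos + hdr
    val_end <- val_start + len - 1L
    if (val_end > n) stop("truncated DICOM element at byte ", pos)
    bytes <- raw[seq.int(val_start, length.out = len)]
    tag <- sprintf("%04x,%04x", group, elem)
    txt <- function() trimws(rawToChar(bytes[bytes != as.raw(0)]))
    ds <- function() as.numeric(strsplit(txt(), "\\\\")[[1]])
    switch(tag,
      "0020,000e" = out$series_uid <- txt(),
      "0020,0032" = out$position <- ds(),
      "0020,0037" = out$orientation <- ds(),
      "0028,0010" = out$rows <- if (!is.na(vr) && vr == "US") u16(val_start) else u16(val_start),
      "0028,0011" = out$cols <- u16(val_start),
      "0028,0030" = out$pixel_spacing <- ds(),
      "0028,0100" = out$bits <- u16(val_start),
      "0028,0103" = out$pixel_rep <- u16(val_start),
      "0028,1052" = out$intercept <- ds()[1],
      "0028,1053" = out$slope <- ds()[1],
      "7fe0,0010" = out$pixel_bytes <- bytes,
      NULL)
    pos <- val_start + len
    if (!is.null(out$pixel_bytes)) break
  }
  if (is.null(out$pixel_bytes)) stop("no PixelData element found in ", path)
  if (is.null(out$rows) || is.null(out$cols))
    stop("missing Rows/Columns in ", path)
  if (is.null(out$position)) stop("missing ImagePositionPatient in ", path)
  if (is.null(out$pixel_spacing)) stop("missing PixelSpacing in ", path)
  bits <- out$bits %||% 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data supported")
  signed <- (out$pixel_rep %||% 1L) == 1L
  out$pixels <- readBin(out$pixel_bytes, "integer",
                        n = out$rows * out$cols, size = 2L,
                        signed = signed, endian = "little")
  out
}
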