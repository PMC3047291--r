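# Minimal writer of single-frame CT DICOM slices (explicit VR little
# endian), used only to build read_dicom_series fixtures in code.

write_dicom_slice <- function(path, pixels, position, pixel_spacing = c(0.4, 0.4),
                              series_uid = "1.2.3.4.5", slope = 1,
                              intercept = 0, with_rescale = TRUE,
                              orientation = c(1, 0, 0, 0, 1, 0)) {
  con <- file(path, "wb")
  on.exit(close(con))

  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  elem_str <- function(group, elem, vr, value, pad = as.raw(0x20)) {
    bytes <- charToRaw(value)
    if (length(bytes) %% 2 == 1) bytes <- c(bytes, pad)  # even-length rule
    u16(group); u16(elem)
    writeChar(vr, con, eos = NULL)
    u16(length(bytes))
    writeBin(bytes, con)
  }
  elem_us <- function(group, elem, value) {
    u16(group); u16(elem)
    writeChar("US", con, eos = NULL)
    u16(2L)
    u16(value)
  }

  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  # file meta (group 0002): transfer syntax = explicit VR little endian
  elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1", pad = as.raw(0))

  elem_str(0x0008, 0x0060, "CS", "CT")
  elem_str(0x0020, 0x000E, "UI", series_uid, pad = as.raw(0))
  elem_str(0x0020, 0x0032, "DS",
           paste(sprintf("%g", position), collapse = "\\"))
  elem_str(0x0020, 0x0037, "DS",
           paste(sprintf("%g", orientation), collapse = "\\"))
  elem_us(0x0028, 0x0010, nrow(t(pixels)))          # Rows (y)
  elem_us(0x0028, 0x0011, nrow(pixels))             # Columns (x)
  elem_str(0x0028, 0x0030, "DS",
           paste(sprintf("%g", rev(pixel_spacing[1:2])), collapse = "\\"))
  elem_us(0x0028, 0x0100, 16L)                      # BitsAllocated
  elem_us(0x0028, 0x0103, 1L)                       # PixelRepresentation
  if (with_rescale) {
    elem_str(0x0028, 0x1052, "DS", sprintf("%g", intercept))
    elem_str(0x0028, 0x1053, "DS", sprintf("%g", slope))
  }
  # PixelData (OW, 12-byte header)
  npix <- length(pixels)
  u16(0x7FE0); u16(0x0010)
  writeChar("OW", con, eos = NULL)
  u16(0L)
  u32(2L * npix)
  # row-major raster: x fastest within each row -> column-major of [x, y]
  writeBin(as.integer(pixels), con, size = 2L, endian = "little")
  invisible(path)
}

# Write a small synthetic series; pixels[i, j, k] indexed (x, y, slice).
write_dicom_series_fixture <- function(dir, data, spacing = c(0.4, 0.4, 0.5),
                                       origin = c(0, 0, 0), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(data)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    paths[k] <- file.path(dir, sprintf("slice%03d.dcm", k))
    write_dicom_slice(paths[k], data[, , k],
                      position = c(origin[1], origin[2],
                                   origin[3] + (k - 1) * spacing[3]),
                      pixel_spacing = spacing[1:2], ...)
  }
  paths
}
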