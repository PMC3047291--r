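#' Read or write a triangle mesh (binary STL or ascii PLY)
#'
#' Format is chosen by extension. STL stores each facet's corners
#' independently, so reading merges coincident vertices (tolerance
#' `1e-6` mm); both loaders drop degenerate/duplicated faces and record the
#' number removed in `attr(mesh, "n_dropped_faces")`.
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @return [read_mesh()] returns a [tri_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (file.info(path)$size == 0L) stop("empty mesh file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl_binary(path),
         ply = read_ply_ascii(path),
         stop("unknown mesh format '.", ext, "' (expected .stl or .ply)"))
}

#' @rdname read_mesh
#' @param mesh a [tri_mesh()] to write.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl_binary(mesh, path),
         ply = write_ply_ascii(mesh, path),
         stop("unknown mesh format '.", ext, "' (expected .stl or .ply)"))
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "guidefit binary STL"))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  fn <- face_normals(mesh)
  V <- mesh$vertices
  # per-facet record: normal, 3 vertices (float32), attribute count (uint16)
  rec <- matrix(0, 12, nf)
  for (k in 1:3) rec[k, ] <- fn[, k]
  for (v in 1:3)
    for (k in 1:3)
      rec[3 * v + k, ] <- V[mesh$faces[, v], k]
  for (f in seq_len(nf)) {
    writeBin(as.numeric(rec[, f]), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf <= 0L) stop("empty or corrupt STL file: ", path)
  body <- readBin(con, "raw", n = nf * 50L)
  if (length(body) < nf * 50L) stop("truncated STL file: ", path)
  # each 50-byte record: 12 float32 then uint16
  m <- matrix(body, nrow = 50L)
  floats <- readBin(as.raw(m[1:48, ]), "numeric", n = 12L * nf, size = 4L,
                    endian = "little")
  rec <- matrix(floats, nrow = 12L)
  V <- matrix(0, 3L * nf, 3L)
  for (v in 1:3)
    for (k in 1:3)
      V[seq.int(v, by = 3L, length.out = nf), k] <- rec[3 * v + k, ]
  F <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  raw_mesh <- tri_mesh(V, F)
  merged <- merge_vertices(raw_mesh, tol = 1e-6)
  merged <- drop_duplicate_faces(merged,
                                 already_dropped = attr(raw_mesh, "n_dropped_faces") +
                                   attr(merged, "n_dropped_faces"))
  merged
}

write_ply_ascii <- function(mesh, path, quality = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0", "comment written by guidefit",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(quality)) {
    stopifnot(length(quality) == nv)
    hdr <- c(hdr, "property float quality")
  }
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  vm <- if (is.null(quality)) mesh$vertices else cbind(mesh$vertices, quality)
  vlines <- apply(vm, 1, function(r) paste(sprintf("%.9g", r), collapse = " "))
  flines <- paste("3", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1] != "ply") stop("not a PLY file: ", path)
  if (!grepl("ascii", lines[2])) stop("only ascii PLY is supported")
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("PLY header not terminated")
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (length(nv) != 1L || length(nf) != 1L) stop("PLY missing vertex/face elements")
  # vertex property count (x y z [quality ...])
  elems <- grep("^element ", hdr)
  vstart <- grep("^element vertex ", hdr)
  vend <- min(c(elems[elems > vstart], endh))
  nprop <- sum(grepl("^property ", hdr[vstart:vend]))
  vlines <- lines[endh + seq_len(nv)]
  vm <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
               ncol = nprop, byrow = TRUE)
  flines <- lines[endh + nv + seq_len(nf)]
  fm <- matrix(as.numeric(unlist(strsplit(trimws(flines), "\\s+"))),
               ncol = 4L, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("only triangle PLY faces are supported")
  mesh <- tri_mesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L)
  if (nprop >= 4L) attr(mesh, "quality") <- vm[, 4]
  drop_duplicate_faces(mesh, already_dropped = attr(mesh, "n_dropped_faces"))
}

# remove repeated faces (same vertex set); count them into n_dropped_faces
drop_duplicate_faces <- function(mesh, already_dropped = 0L) {
  if (nrow(mesh$faces) == 0L) return(mesh)
  key <- apply(mesh$faces, 1, function(f) paste(sort(f), collapse = ","))
  dup <- duplicated(key)
  out <- mesh
  out$faces <- mesh$faces[!dup, , drop = FALSE]
  attr(out, "n_dropped_faces") <- as.integer(already_dropped + sum(dup))
  out
}

#' Export a deviation field as a colour-mappable PLY
#'
#' Writes the sampled test-surface points of a [compare_surfaces()] result
#' as PLY vertices with the signed deviation (mm) in a per-vertex `quality`
#' property, the standard hand-off for heat-map rendering in mesh viewers.
#'
#' @param field a `deviation_field` from [compare_surfaces()].
#' @param path output `.ply` path.
#' @export
write_deviation_ply <- function(field, path) {
  nv <- nrow(field$sample_points)
  mesh <- list(vertices = field$sample_points,
               faces = matrix(integer(0), 0, 3))
  class(mesh) <- "tri_mesh"
  write_ply_ascii(mesh, path, quality = field$distances)
  invisible(path)
}
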