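#' Triangle surface mesh
#'
#' A triangle mesh in millimetre world coordinates: the container for optical
#' scans, extracted isosurfaces and synthetic phantoms. Faces are 1-based
#' vertex-index triples; outward orientation is implied by counter-clockwise
#' winding seen from outside. Degenerate faces (repeated vertex indices or
#' zero area) are dropped at construction; the number removed is kept in
#' `attr(mesh, "n_dropped_faces")`.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh` with elements `vertices`, `faces`.
#' @export
tri_mesh <- function(vertices, faces) {
  V <- as.matrix(vertices)
  storage.mode(V) <- "double"
  F <- as.matrix(faces)
  storage.mode(F) <- "integer"
  if (ncol(V) != 3L) stop("vertices must be n x 3")
  if (nrow(F) > 0 && (ncol(F) != 3L)) stop("faces must be m x 3")
  if (nrow(F) > 0 && (min(F) < 1L || max(F) > nrow(V)))
    stop("face indices out of vertex range")
  dropped <- 0L
  if (nrow(F) > 0) {
    dup <- F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 1] == F[, 3]
    a2 <- face_areas_internal(V, F)
    bad <- dup | a2 <= 0
    dropped <- sum(bad)
    F <- F[!bad, , drop = FALSE]
  }
  structure(list(vertices = V, faces = F), class = "tri_mesh",
            n_dropped_faces = dropped)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces, area %.3f mm^2%s\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

face_areas_internal <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Face areas of a mesh
#' @param mesh a [tri_mesh()].
#' @return numeric vector of per-face areas (mm^2).
#' @export
face_areas <- function(mesh) face_areas_internal(mesh$vertices, mesh$faces)

#' Total surface area of a mesh
#' @param mesh a [tri_mesh()].
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed (signed) volume of a closed mesh
#'
#' Divergence-theorem volume; positive for outward-oriented closed surfaces.
#' @param mesh a [tri_mesh()].
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) cpp_signed_volume(mesh$vertices, mesh$faces)

#' Unit per-face normals
#' @param mesh a [tri_mesh()].
#' @return m x 3 matrix of unit normals (winding convention).
#' @export
face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' Area-weighted unit vertex normals
#' @param mesh a [tri_mesh()].
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], mesh$faces[, k], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      vn[idx, d] <- vn[idx, d] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Manifoldness / orientation audit of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return list with edge counts: `n_edges`, `n_boundary`, `n_nonmanifold`,
#'   `n_inconsistent` (interior edges whose two faces disagree in winding).
#' @export
edge_audit <- function(mesh) cpp_edge_audit(mesh$faces, nrow(mesh$vertices))

#' Is a mesh watertight and consistently oriented?
#'
#' True when every edge is shared by exactly two faces with opposite
#' traversal directions.
#' @param mesh a [tri_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  a <- edge_audit(mesh)
  a$n_boundary == 0L && a$n_nonmanifold == 0L && a$n_inconsistent == 0L
}

#' Merge coincident vertices
#'
#' Vertices closer than `tol` on every axis collapse to one; needed after
#' reading STL, which stores each facet's corners independently.
#'
#' @param mesh a [tri_mesh()].
#' @param tol merge tolerance in mm.
#' @return A [tri_mesh()] with shared vertices.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  key <- apply(round(mesh$vertices / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  V <- mesh$vertices[first, , drop = FALSE]
  F <- matrix(map[mesh$faces], ncol = 3)
  tri_mesh(V, F)
}

#' Connected components of a mesh
#'
#' Faces are connected when they share a vertex.
#' @param mesh a [tri_mesh()].
#' @return integer vector, 1-based component label per face.
#' @export
mesh_components <- function(mesh)
  cpp_face_components(mesh$faces, nrow(mesh$vertices))

#' Keep the largest connected surface component
#' @param mesh a [tri_mesh()].
#' @return submesh (a [tri_mesh()]) of the component with the most faces;
#'   ties broken by the lowest component label (first-encountered face).
#' @export
largest_mesh_component <- function(mesh) {
  comp <- mesh_components(mesh)
  tab <- tabulate(comp)
  keep <- which(comp == which.max(tab))
  submesh_by_faces(mesh, keep)
}

submesh_by_faces <- function(mesh, face_idx) {
  F <- mesh$faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  out <- tri_mesh(mesh$vertices[used, , drop = FALSE],
                  matrix(remap[F], ncol = 3))
  attr(out, "vertex_map") <- used
  attr(out, "face_map") <- face_idx
  out
}

#' Sample points on a mesh surface
#'
#' Two seeded, area-weighted schemes:
#' * `"vertex"` (default): vertices drawn with probability proportional to
#'   one third of their incident face area. Sampled points coincide with mesh
#'   vertices, so per-vertex measurement noise (e.g. the simulated optical
#'   scanner) is preserved undiluted in downstream statistics.
#' * `"face"`: faces drawn proportional to area, points placed uniformly in
#'   the face by barycentric coordinates. Smooth coverage, but it averages
#'   per-vertex noise (variance shrinks by about one half).
#'
#' @param mesh a [tri_mesh()].
#' @param n number of points.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param method `"vertex"` or `"face"`.
#' @return n x 3 matrix of points on the surface.
#' @export
sample_surface <- function(mesh, n, seed = 1L, method = c("vertex", "face")) {
  method <- match.arg(method)
  stopifnot(n >= 1, nrow(mesh$faces) >= 1)
  withr::with_seed(seed, {
    ar <- face_areas(mesh)
    if (method == "vertex") {
      w <- numeric(nrow(mesh$vertices))
      for (k in 1:3) {
        acc <- rowsum(ar, mesh$faces[, k], reorder = FALSE)
        idx <- as.integer(rownames(acc))
        w[idx] <- w[idx] + acc[, 1] / 3
      }
      vi <- sample.int(nrow(mesh$vertices), n, replace = TRUE, prob = w)
      mesh$vertices[vi, , drop = FALSE]
    } else {
      fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = ar)
      r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
      w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
      F <- mesh$faces[fi, , drop = FALSE]
      mesh$vertices[F[, 1], , drop = FALSE] * w1 +
        mesh$vertices[F[, 2], , drop = FALSE] * w2 +
        mesh$vertices[F[, 3], , drop = FALSE] * w3
    }
  })
}
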