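#' Rigid transform (proper rotation + translation)
#'
#' Constructs a rigid-body transform mapping a point `p` to `R p + t`, in
#' millimetre world coordinates. The rotation must be a proper orthonormal
#' matrix (`R'R = I`, `det(R) = +1`, both within `1e-9`).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric translation vector (mm).
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' tf <- rigid_transform(rotation_about_z(pi / 2), c(1, 0, 0))
#' apply_transform(c(1, 0, 0), tf)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper: det(R) = +1 within 1e-9")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang * 180 / pi, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix about a coordinate axis
#'
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula.
#'
#' @param axis length-3 axis (normalised internally).
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  # atan2 form: resolves angles near 0 and pi far better than acos of the
  # trace (whose resolution floor is ~sqrt(machine eps))
  co <- (sum(diag(R)) - 1) / 2
  si <- sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
             (R[2, 1] - R[1, 2])^2) / 2
  atan2(si, co)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param a a `rigid_transform`.
#' @return The inverse `rigid_transform`, satisfying
#'   `compose_transform(a, invert_transform(a))` = identity.
#' @export
invert_transform <- function(a) {
  Rt <- t(a$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% a$translation))
}

#' Apply a rigid transform to points or a mesh
#'
#' Every point `p` maps to `R p + t`. Mesh connectivity is untouched.
#'
#' @param x an n x 3 point matrix, a length-3 point, or a [tri_mesh()].
#' @param transform a `rigid_transform`.
#' @return Same kind of object as `x`.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "tri_mesh")) {
    x$vertices <- apply_transform(x$vertices, transform)
    return(x)
  }
  pts <- if (is.null(dim(x))) matrix(x, ncol = 3) else x
  out <- pts %*% t(transform$rotation) +
    matrix(transform$translation, nrow(pts), 3, byrow = TRUE)
  if (is.null(dim(x))) as.numeric(out) else out
}

#' Paired landmark set for point-based registration
#'
#' Index-paired corresponding points manually (or synthetically) picked on a
#' source and a target model.
#'
#' @param source_points,target_points n x 3 matrices (mm), n >= 3, same n.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(source_points, target_points) {
  s <- as.matrix(source_points); t <- as.matrix(target_points)
  if (ncol(s) != 3L || ncol(t) != 3L) stop("landmark points must be n x 3")
  if (nrow(s) != nrow(t)) stop("source and target landmark counts differ")
  if (nrow(s) < 3L) stop("degenerate configuration: need at least 3 landmark pairs")
  sc <- sweep(s, 2, colMeans(s))
  d <- svd(sc, nu = 0, nv = 0)$d
  if (d[2] <= 1e-9)
    stop("degenerate configuration: source landmarks are collinear")
  structure(list(source_points = s, target_points = t), class = "landmark_set")
}

#' Least-squares rigid alignment of paired landmarks (SVD method)
#'
#' Kabsch/Arun solution: both point sets are centred on their centroids, the
#' 3x3 cross-covariance is decomposed by singular values, and a possible
#' reflection is corrected so that `det(R) = +1`. The result minimises the
#' sum of squared pair distances over proper rigid motions; it is the coarse
#' alignment step before surface-based refinement with [icp_refine()].
#'
#' @param landmarks a [landmark_set()].
#' @return A `rigid_transform` mapping source points onto target points.
#' @export
landmark_register <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set"))
    landmarks <- landmark_set(landmarks$source_points, landmarks$target_points)
  X <- landmarks$source_points
  Y <- landmarks$target_points
  xm <- colMeans(X); ym <- colMeans(Y)
  H <- crossprod(sweep(X, 2, xm), sweep(Y, 2, ym))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ym - as.numeric(R %*% xm))
}

#' Read/write a plain-text landmark file
#'
#' One pair per line, six whitespace-separated mm floats
#' (`xs ys zs xt yt zt`); `#` starts a comment.
#'
#' @param path file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("landmark file is empty: ", path)
  vals <- lapply(lines, function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
  if (any(vapply(vals, length, 1L) != 6L))
    stop("each landmark line must hold 6 numbers (xs ys zs xt yt zt)")
  m <- do.call(rbind, vals)
  landmark_set(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()] to write.
#' @export
write_landmarks <- function(landmarks, path) {
  m <- cbind(landmarks$source_points, landmarks$target_points)
  writeLines(c("# xs ys zs xt yt zt",
               apply(m, 1, function(r) paste(sprintf("%.9g", r), collapse = " "))),
             path)
  invisible(path)
}
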