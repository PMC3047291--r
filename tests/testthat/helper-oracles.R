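# Independent oracles used to freeze expected values: brute-force geometry
# in plain R, deliberately ignorant of the package's BVH/pseudonormal path.

# Exact closest point on one triangle by direct region classification
# (project onto plane, clamp to edges/vertices via all candidates).
oracle_point_triangle <- function(p, a, b, c) {
  candidates <- list()
  n <- pracma::cross(b - a, c - a)
  nn <- sum(n^2)
  if (nn > 0) {
    # projection onto the triangle plane, inside test via barycentrics
    q <- p - n * sum((p - a) * n) / nn
    v0 <- b - a; v1 <- c - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) candidates <- c(candidates, list(q))
  }
  seg <- function(p, u, v) {
    t <- sum((p - u) * (v - u)) / sum((v - u)^2)
    u + (v - u) * max(0, min(1, t))
  }
  candidates <- c(candidates, list(seg(p, a, b), seg(p, b, c), seg(p, c, a)))
  d2 <- vapply(candidates, function(q) sum((p - q)^2), 0)
  candidates[[which.min(d2)]]
}

# Unsigned brute-force distance: loop over all triangles.
oracle_unsigned_distance <- function(p, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  best <- Inf
  for (f in seq_len(nrow(F))) {
    q <- oracle_point_triangle(p, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

# Generalized winding number (van Oosterom & Strackee solid angles);
# ~1 inside a closed outward-oriented mesh, ~0 outside.
oracle_winding_number <- function(p, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  total <- 0
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ] - p; b <- V[F[f, 2], ] - p; c <- V[F[f, 3], ] - p
    la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(c^2))
    num <- sum(a * pracma::cross(b, c))
    den <- la * lb * lc + sum(a * b) * lc + sum(b * c) * la + sum(a * c) * lb
    total <- total + 2 * atan2(num, den)
  }
  total / (4 * pi)
}

oracle_signed_distance <- function(p, mesh) {
  d <- oracle_unsigned_distance(p, mesh)
  if (oracle_winding_number(p, mesh) > 0.5) -d else d
}

# Random unit quaternion -> rotation matrix.
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

random_rigid_transform <- function(max_angle = pi, max_trans = 10) {
  q <- stats::rnorm(4)
  ang <- stats::runif(1, 0, max_angle)
  ax <- stats::rnorm(3)
  rigid_transform(rotation_about_axis(ax, ang),
                  stats::runif(3, -max_trans, max_trans))
}

# Direct minimisation of the rigid least-squares objective over unit
# quaternions: multistart Nelder-Mead. Independent check that the closed-form
# SVD solution is the optimum.
oracle_rigid_objective <- function(X, Y) {
  obj <- function(q) {
    R <- quat_to_rot(q)
    t <- colMeans(Y) - as.numeric(R %*% colMeans(X))
    sum((X %*% t(R) + rep(1, nrow(X)) %o% t - Y)^2)
  }
  best <- Inf
  for (s in 1:12) {
    q0 <- stats::rnorm(4)
    r <- stats::optim(q0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

kabsch_objective <- function(tf, X, Y) {
  sum((apply_transform(X, tf) - Y)^2)
}

# random watertight star-shaped mesh: icosphere with radial perturbation
random_star_mesh <- function(subdiv = 1, radius = 1, wobble = 0.3) {
  m <- make_sphere_mesh(radius, subdiv)
  r <- 1 + stats::runif(nrow(m$vertices), -wobble, wobble)
  m$vertices <- m$vertices * r
  m
}

# random triangle soup (magnitude-only oracle checks)
random_soup_mesh <- function(n_tri = 50, scale = 2) {
  V <- matrix(stats::runif(9 * n_tri, -scale, scale), ncol = 3)
  tri_mesh(V, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE))
}
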