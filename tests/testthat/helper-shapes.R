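# Analytic fixture meshes and contour stacks built in code.

# axis-aligned unit cube as 12 outward-oriented triangles
unit_cube_mesh <- function(origin = c(0, 0, 0), side = 1) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * side
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = 0 (down)
             c(5, 6, 8), c(5, 8, 7),   # z = 1 (up)
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 7, 8), c(3, 8, 4),   # y = 1
             c(1, 5, 7), c(1, 7, 3),   # x = 0
             c(2, 4, 8), c(2, 8, 6))   # x = 1
  triangle_mesh(v, f)
}

# icosphere: subdivided icosahedron projected to radius r
icosphere <- function(r = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  v <- sweep(v, 2, center, "+")
  triangle_mesh(v, f)
}

# circular contour of n points at height z (slicing axis 3)
circle_contour <- function(r = 1, z = 0, n = 100, slice_index = round(z),
                           center = c(0, 0), role = "known") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  planar_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th), z),
                 slice_index = slice_index, plane_coord = z, role = role,
                 axis = 3)
}

# stack of coaxial circular rings
ring_stack <- function(radii, zs, n = 100, n_intermediate = 3L) {
  contours <- mapply(function(r, z, i) circle_contour(r, z, n, i),
                     radii, zs, seq_along(zs) - 1, SIMPLIFY = FALSE)
  contour_stack(contours, axis = 3, points_per_contour = as.integer(n),
                n_intermediate = as.integer(n_intermediate))
}

# independent dense Laplacian oracle built directly from the definition:
# diagonal 1, -1/N_neighbours at adjacency, over the ring vertices of the
# scaffold tube (cap fans and apices sit outside the fairing graph)
dense_laplacian_oracle <- function(scaffold) {
  n <- scaffold$n_rings * scaffold$n_points_per_ring
  f <- scaffold$mesh$faces
  f <- f[f[, 1] <= n & f[, 2] <= n & f[, 3] <= n, , drop = FALSE]
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(f))) {
    tri <- f[i, ]
    adj[tri[1], tri[2]] <- adj[tri[2], tri[1]] <- TRUE
    adj[tri[2], tri[3]] <- adj[tri[3], tri[2]] <- TRUE
    adj[tri[3], tri[1]] <- adj[tri[1], tri[3]] <- TRUE
  }
  L <- diag(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    if (length(nb) > 0) L[i, nb] <- -1 / length(nb)
  }
  L
}

# dense direct fairing solve (base solve(), independent of the package path)
dense_fair_oracle <- function(scaffold, order) {
  L <- dense_laplacian_oracle(scaffold)
  S <- if (order == 2) L %*% L else L
  n <- nrow(L)
  u <- which(!scaffold$known_mask[seq_len(n)])
  k <- which(scaffold$known_mask[seq_len(n)])
  x <- scaffold$mesh$vertices
  for (d in 1:3)
    x[u, d] <- solve(S[u, u], -S[u, k, drop = FALSE] %*% x[k, d])
  x
}
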