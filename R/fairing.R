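# Surface fairing: the uniform (umbrella) graph Laplacian over the scaffold
# and the sparse Laplacian / bi-Laplacian solves for the unknown vertex
# positions.
#
# The discrete Laplacian over the scaffold graph is
#   L[n, n] = 1,
#   L[n, m] = -1 / N_neighbours(n)   when m is adjacent to n,
#   L[n, m] = 0                      otherwise,
# so every row sums to zero. Setting L x = L y = L z = 0 at the unknown
# vertices is the force balance of a uniform spring network (a discrete
# minimal surface); setting L^2 x = 0 penalizes curvature instead and yields
# a thin-plate surface. The full L -- including rows at known vertices -- is
# assembled before squaring, so the bi-Laplacian penalizes curvature across
# the known rings too; rows and columns are restricted to the unknowns only
# at solve time.

#' Assemble the fairing system for a scaffold
#'
#' @param scaffold a [scaffold_mesh].
#' @param order 1 for the Laplacian (minimal-surface, spring) system, 2 for
#'   the bi-Laplacian (thin-plate) system; the system matrix for order 2 is
#'   the sparse product `L %*% L`.
#' @return An object of class `fairing_system` with elements `L` (the
#'   order-1 Laplacian), `S` (the system matrix actually solved), `order`,
#'   `known_idx` and `unknown_idx`.
#' @export
build_laplacian <- function(scaffold, order = 2) {
  order <- as.integer(order)
  fs_stopifnot(order %in% c(1L, 2L), "order must be 1 or 2",
               "fastsurf_invalid_input")
  mesh <- scaffold$mesh
  n <- scaffold$n_rings * scaffold$n_points_per_ring
  f <- mesh$faces
  # The fairing energy lives on the contour tube: cap fans only close the
  # output surface, and the fixed apices are not part of the system, so
  # faces touching an apex stay out of the graph. (Apices are never
  # adjacent to an unknown ring, so the order-1 equations are unaffected;
  # for order 2 this keeps the artificial rim curvature of the caps from
  # entering the thin-plate energy.)
  tube <- f[f[, 1] <= n & f[, 2] <= n & f[, 3] <= n, , drop = FALSE]
  from <- c(tube[, 1], tube[, 2], tube[, 3])
  to <- c(tube[, 2], tube[, 3], tube[, 1])
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  keep <- !duplicated(lo + (hi - 1) * as.double(n))
  ei <- lo[keep]
  ej <- hi[keep]
  deg <- tabulate(c(ei, ej), nbins = n)
  if (any(deg == 0L))
    fs_abort("scaffold contains an isolated vertex", "fastsurf_graph_error")
  ii <- c(seq_len(n), ei, ej)
  jj <- c(seq_len(n), ej, ei)
  xx <- c(rep(1, n), -1 / deg[ei], -1 / deg[ej])
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  S <- if (order == 2L) L %*% L else L
  structure(list(L = L, S = S, order = order,
                 known_idx = which(scaffold$known_mask[seq_len(n)]),
                 unknown_idx = which(!scaffold$known_mask[seq_len(n)])),
            class = "fairing_system")
}

# unpreconditioned bi-conjugate gradient (Fletcher) for a sparse
# non-symmetric system A x = b
bicg_solve <- function(A, b, x0, tol = 1e-8, maxiter = NULL) {
  if (is.null(maxiter)) maxiter <- 10L * length(b)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = rep(0, length(b)), converged = TRUE))
  At <- Matrix::t(A)
  x <- x0
  r <- b - as.numeric(A %*% x)
  rt <- r
  p <- r
  pt <- rt
  rho <- sum(rt * r)
  for (it in seq_len(maxiter)) {
    if (sqrt(sum(r^2)) / bnorm <= tol)
      return(list(x = x, converged = TRUE))
    Ap <- as.numeric(A %*% p)
    denom <- sum(pt * Ap)
    if (denom == 0 || rho == 0) break
    alpha <- rho / denom
    x <- x + alpha * p
    r <- r - alpha * Ap
    rt <- rt - alpha * as.numeric(At %*% pt)
    rho_new <- sum(rt * r)
    beta <- rho_new / rho
    rho <- rho_new
    p <- r + beta * p
    pt <- rt + beta * pt
  }
  list(x = x, converged = sqrt(sum(r^2)) / bnorm <= tol)
}

#' Solve the fairing system for the unknown vertex positions
#'
#' For each coordinate independently, the system matrix is restricted to the
#' unknown rows and columns, the known columns are moved to the right-hand
#' side, and the sparse system is solved with the bi-conjugate gradient
#' method (relative residual 1e-8), starting from the scaffold's
#' linear-interpolation positions. On non-convergence a direct sparse
#' factorization is used as fallback below 20000 unknowns. Known vertices
#' are returned bit-identical to their input positions.
#'
#' @param system a [build_laplacian] result.
#' @param scaffold the [scaffold_mesh] the system was assembled from.
#' @param method `"bicg"` (default, with direct fallback) or `"direct"`.
#' @return A closed [triangle_mesh] with the unknown vertices moved to their
#'   faired positions.
#' @export
solve_fairing <- function(system, scaffold, method = c("bicg", "direct")) {
  method <- match.arg(method)
  mesh <- scaffold$mesh
  u <- system$unknown_idx
  k <- system$known_idx
  fs_stopifnot(length(k) > 0, "the system has no known vertices",
               "fastsurf_invalid_input")
  if (length(u) == 0L) return(mesh)
  S <- system$S
  A <- S[u, u, drop = FALSE]
  B <- S[u, k, drop = FALSE]
  xyz <- mesh$vertices
  rhs <- -as.matrix(B %*% xyz[k, , drop = FALSE])
  out <- xyz
  for (d in 1:3) {
    if (method == "bicg") {
      res <- bicg_solve(A, rhs[, d], x0 = xyz[u, d])
      if (!res$converged) {
        if (length(u) < 20000L) {
          res$x <- as.numeric(Matrix::solve(A, rhs[, d]))
        } else {
          fs_abort("fairing solver did not converge",
                   "fastsurf_solver_error")
        }
      }
      out[u, d] <- res$x
    } else {
      out[u, d] <- as.numeric(Matrix::solve(A, rhs[, d]))
    }
    resid <- sqrt(sum((as.numeric(A %*% out[u, d]) - rhs[, d])^2))
    scale <- max(sqrt(sum(rhs[, d]^2)), 1e-300)
    if (resid / scale > 1e-6)
      fs_abort("fairing solution failed the residual check",
               "fastsurf_solver_error")
  }
  triangle_mesh(out, mesh$faces, check = FALSE)
}

#' Reconstruct a closed surface from a sparse contour stack
#'
#' The full pipeline: resample all contours to the stack's point count,
#' build the triangulated scaffold with intermediate rings, assemble the
#' Laplacian (order 1) or bi-Laplacian (order 2, the default) system, and
#' solve for the intermediate vertex positions. Known contour points are
#' interpolated exactly.
#'
#' @param stack a [contour_stack] of known contours.
#' @param order 2 (thin-plate, default) or 1 (minimal surface).
#' @param n_intermediate intermediate rings per gap; defaults to the
#'   stack's setting.
#' @param points_per_contour ring point count; defaults to the stack's
#'   setting.
#' @return A closed [triangle_mesh].
#' @export
reconstruct <- function(stack, order = 2,
                        n_intermediate = stack$n_intermediate,
                        points_per_contour = stack$points_per_contour) {
  counts <- vapply(stack$contours, function(ct) nrow(ct$points), 0L)
  if (length(unique(counts)) != 1L || counts[1] != points_per_contour)
    stack <- resample_stack(stack, points_per_contour)
  scaffold <- build_scaffold(stack, n_intermediate = n_intermediate)
  system <- build_laplacian(scaffold, order = order)
  solve_fairing(system, scaffold)
}
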