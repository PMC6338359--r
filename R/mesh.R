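#' Triangle mesh in world coordinates
#'
#' @param vertices V x 3 numeric matrix of world-mm coordinates.
#' @param faces F x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (outward normals for a closed surface).
#' @param check validate indices and drop exactly degenerate (zero-area)
#'   faces (default `TRUE`).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, check = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (check) {
    if (nrow(faces) > 0) {
      if (min(faces) < 1L || max(faces) > nrow(vertices))
        fs_abort("face indices out of range", "fastsurf_invalid_input")
      a <- vertices[faces[, 1], , drop = FALSE]
      ab <- vertices[faces[, 2], , drop = FALSE] - a
      ac <- vertices[faces[, 3], , drop = FALSE] - a
      cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                  ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                  ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
      area2 <- sqrt(rowSums(cr^2))
      if (any(area2 == 0)) faces <- faces[area2 > 0, , drop = FALSE]
    }
  }
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @exportS3Method print triangle_mesh
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) ", closed" else ", open"))
  invisible(x)
}

#' Test whether a mesh is closed and consistently oriented
#'
#' Watertight here means every undirected edge is shared by exactly two
#' faces and every directed half-edge occurs exactly once (consistent
#' orientation).
#'
#' @param mesh a [triangle_mesh].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  nv <- nrow(mesh$vertices)
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  directed <- (from - 1) * nv + to
  if (anyDuplicated(directed) > 0) return(FALSE)
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  undirected <- (lo - 1) * nv + hi
  tab <- table(undirected)
  all(tab == 2L)
}

check_closed <- function(mesh) {
  fs_stopifnot(inherits(mesh, "triangle_mesh"), "not a triangle_mesh",
               "fastsurf_invalid_input")
  if (!is_watertight(mesh))
    fs_abort("mesh is not closed (watertight, consistently oriented)",
             "fastsurf_open_surface")
  invisible(mesh)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem: the sum of signed tetrahedron
#' volumes spanned by the origin and each face. Positive for outward-oriented
#' surfaces, and invariant under translation.
#'
#' @param mesh a closed [triangle_mesh].
#' @return Volume in mm^3 (signed; positive when normals point outward).
#' @export
mesh_volume <- function(mesh) {
  check_closed(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Point containment test for a closed mesh
#'
#' Vertical ray-crossing parity; points lying on the surface (within a
#' relative tolerance of the mesh extent) are deterministically counted as
#' inside.
#'
#' @param mesh a closed [triangle_mesh].
#' @param points P x 3 matrix of query points in mm.
#' @return Logical vector of length P.
#' @export
contains_points <- function(mesh, points) {
  check_closed(mesh)
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_points_in_mesh(mesh$vertices, mesh$faces, points)
}

#' Affine transform of world coordinates
#'
#' @param matrix 4x4 homogeneous matrix; last row `(0,0,0,1)`.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  m <- base::matrix(as.numeric(matrix), 4, 4)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    fs_abort("last row of an affine must be (0,0,0,1)",
             "fastsurf_invalid_transform")
  if (abs(det(m[1:3, 1:3])) < 1e-12)
    fs_abort("affine has a singular linear part",
             "fastsurf_invalid_transform")
  structure(list(matrix = m), class = "affine_transform")
}

#' Apply an affine transform to a mesh
#'
#' Vertices are mapped through the transform; when the linear part has a
#' negative determinant the face orientation is flipped so normals stay
#' outward.
#'
#' @param mesh a [triangle_mesh].
#' @param transform an [affine_transform] (or 4x4 matrix).
#' @return The transformed [triangle_mesh].
#' @export
apply_affine <- function(mesh, transform) {
  if (!inherits(transform, "affine_transform"))
    transform <- affine_transform(transform)
  m <- transform$matrix
  v <- cbind(mesh$vertices, 1) %*% t(m)
  f <- mesh$faces
  if (det(m[1:3, 1:3]) < 0) f <- f[, c(1, 3, 2), drop = FALSE]
  triangle_mesh(v[, 1:3, drop = FALSE], f, check = FALSE)
}

#' Read a 4x4 affine from FLIRT-style text or JSON
#'
#' Accepts a plain-text file of 4 whitespace-delimited rows (as written by
#' FSL-FLIRT) or a JSON file holding a 4x4 array.
#'
#' @param path input file path.
#' @return An [affine_transform].
#' @export
read_affine <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (grepl("^\\s*\\[", paste(txt, collapse = ""))) {
    m <- jsonlite::fromJSON(paste(txt, collapse = "\n"))
    return(affine_transform(m))
  }
  nums <- scan(text = paste(txt, collapse = "\n"), quiet = TRUE)
  if (length(nums) != 16)
    fs_abort("expected 16 numbers in a 4x4 affine file",
             "fastsurf_invalid_transform")
  affine_transform(matrix(nums, 4, 4, byrow = TRUE))
}
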