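# Triangulated surface patches: the stand-in for a reconstructed luminal
# surface. Lengths in mm, areas in mm^2.

#' Construct a surface mesh object
#'
#' Bundles vertex positions, triangle connectivity, outward unit normals and
#' per-vertex area weights, with validity checks. Most users will build
#' meshes with [build_patch_mesh()] rather than call this directly.
#'
#' @param vertices numeric n x 3 matrix of positions (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param normals numeric n x 3 matrix of unit normals.
#' @param vertex_areas optional numeric vector of per-vertex areas (mm^2);
#'   computed as one third of the incident triangle areas when omitted.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, normals, vertex_areas = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  normals <- as.matrix(normals)
  n <- nrow(vertices)
  if (ncol(vertices) != 3L || ncol(normals) != 3L) {
    stop_invalid("vertices and normals must have 3 columns")
  }
  if (nrow(normals) != n) stop_invalid("one normal per vertex required")
  if (any(triangles < 1L) || any(triangles > n)) {
    stop_invalid("triangle indices out of range")
  }
  nl <- row_norms(normals)
  if (any(abs(nl - 1) > 1e-9)) stop_invalid("normals must have unit length")
  if (is.null(vertex_areas)) {
    vertex_areas <- vertex_area_weights(vertices, triangles)
  }
  if (length(vertex_areas) != n || any(vertex_areas <= 0)) {
    stop_invalid("all vertex areas must be positive")
  }
  structure(
    list(vertices = vertices, triangles = triangles, normals = normals,
         vertex_areas = as.numeric(vertex_areas)),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, total area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$vertex_areas)))
  invisible(x)
}

# triangle areas (mm^2) from vertex positions
triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  0.5 * row_norms(cross3(b - a, c_ - a))
}

# barycentric lumping: each triangle contributes a third of its area to
# each of its vertices
vertex_area_weights <- function(vertices, triangles) {
  ta <- triangle_areas(vertices, triangles)
  w <- numeric(nrow(vertices))
  for (k in 1:3) {
    acc <- tapply(ta, triangles[, k], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + acc
  }
  w / 3
}

#' Build an open cylindrical surface patch
#'
#' Generates a tube of `n_axial` vertex rings by `n_circ` vertices around the
#' circumference (open at both ends, closed circumferentially), triangulated
#' into quads split along one diagonal, with outward radial unit normals.
#' The patch plays the role of a luminal vessel surface for synthetic fields.
#'
#' @param n_axial number of axial vertex rings (>= 2).
#' @param n_circ number of circumferential vertices per ring (>= 3).
#' @param radius cylinder radius (mm).
#' @param length axial extent (mm).
#' @return A [surface_mesh] with `n_axial * n_circ` vertices. The axial
#'   coordinate is `z`.
#' @examples
#' m <- build_patch_mesh(10, 16, radius = 3, length = 20)
#' sum(m$vertex_areas)  # close to 2*pi*3*20
#' @export
build_patch_mesh <- function(n_axial, n_circ, radius, length) {
  if (n_axial < 2L) stop_invalid("n_axial must be >= 2")
  if (n_circ < 3L) stop_invalid("n_circ must be >= 3")
  if (radius <= 0 || length <= 0) {
    stop_invalid("radius and length must be positive")
  }
  z <- seq(0, length, length.out = n_axial)
  th <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  # vertex (i, j): ring i, circumferential slot j; index (i-1)*n_circ + j
  grid <- expand.grid(j = seq_len(n_circ), i = seq_len(n_axial))
  theta <- th[grid$j]
  vertices <- cbind(radius * cos(theta), radius * sin(theta), z[grid$i])
  normals <- cbind(cos(theta), sin(theta), 0)

  tri <- vector("list", (n_axial - 1L) * n_circ)
  k <- 0L
  for (i in seq_len(n_axial - 1L)) {
    for (j in seq_len(n_circ)) {
      jn <- if (j == n_circ) 1L else j + 1L
      v00 <- (i - 1L) * n_circ + j
      v01 <- (i - 1L) * n_circ + jn
      v10 <- i * n_circ + j
      v11 <- i * n_circ + jn
      k <- k + 1L
      tri[[k]] <- rbind(c(v00, v01, v11), c(v00, v11, v10))
    }
  }
  triangles <- do.call(rbind, tri)
  surface_mesh(vertices, triangles, normals)
}

#' Normalized axial coordinate of mesh vertices
#'
#' Maps the axial (`z`) coordinate to `[0, 1]`; used to lay smooth phenotype
#' gradients along a vessel patch.
#'
#' @param mesh a [surface_mesh].
#' @return numeric vector in `[0, 1]`, one value per vertex.
#' @export
axial_coordinate <- function(mesh) {
  z <- mesh$vertices[, 3]
  rng <- range(z)
  if (diff(rng) == 0) return(rep(0, length(z)))
  (z - rng[1]) / diff(rng)
}

#' Logistic phenotype ramp along the axial coordinate
#'
#' Smooth blend map from the athero-protective phenotype (0) at one end of
#' the patch to the athero-prone phenotype (1) at the other, via a logistic
#' transition centred at `center` with slope `steepness`.
#'
#' @param mesh a [surface_mesh].
#' @param center transition midpoint on the normalized axial axis.
#' @param steepness logistic steepness (larger = sharper transition).
#' @return per-vertex blend values in `[0, 1]`.
#' @export
phenotype_ramp <- function(mesh, center = 0.5, steepness = 12) {
  s <- axial_coordinate(mesh)
  1 / (1 + exp(-steepness * (s - center)))
}
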