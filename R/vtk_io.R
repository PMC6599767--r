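# Minimal VTK legacy ASCII polydata reader/writer, scoped to what the
# pipeline emits: POINTS + POLYGONS (triangles) + POINT_DATA with NORMALS
# and named SCALARS arrays. Values are written at full double precision so
# round-trips are lossless to ~1e-16 relative.

fmt_nums <- function(x, per_line = 1L) {
  s <- sprintf("%.17g", x)
  m <- matrix(s, ncol = per_line, byrow = TRUE)
  apply(m, 1, paste, collapse = " ")
}

#' Write a surface mesh (and optional per-vertex scalars) as VTK polydata
#'
#' Emits a legacy ASCII VTK file with points, triangle polygons, per-vertex
#' normals and one `SCALARS` array per column of `point_scalars`.
#'
#' @param mesh a [surface_mesh].
#' @param path output file path.
#' @param point_scalars optional data frame / named list of per-vertex
#'   numeric vectors to attach as point data.
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(mesh, path, point_scalars = NULL) {
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "gcxmech surface",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(fmt_nums(t(mesh$vertices), per_line = 3L), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(paste("3", mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines("NORMALS normals double", con)
  writeLines(fmt_nums(t(mesh$normals), per_line = 3L), con)
  writeLines("SCALARS vertex_area double 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(fmt_nums(mesh$vertex_areas), con)
  if (!is.null(point_scalars)) {
    for (nm in names(point_scalars)) {
      v <- as.numeric(point_scalars[[nm]])
      if (length(v) != n) stop_invalid("scalar '%s' has wrong length", nm)
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(fmt_nums(v), con)
    }
  }
  invisible(path)
}

#' Read a VTK legacy ASCII polydata file written by [write_vtk_polydata()]
#'
#' @param path file path.
#' @return A list with elements `mesh` (a [surface_mesh]) and `point_scalars`
#'   (named list of per-vertex numeric vectors, possibly empty).
#' @export
read_vtk_polydata <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  i <- grep("^POINTS", lines)[1]
  if (is.na(i)) stop_invalid("no POINTS section in %s", path)
  n <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  read_block <- function(start, count, per_line) {
    vals <- as.numeric(unlist(strsplit(trimws(
      lines[start:(start + count - 1L)]), "\\s+")))
    matrix(vals, ncol = per_line, byrow = TRUE)
  }
  vertices <- read_block(i + 1L, n, 3L)
  j <- grep("^POLYGONS", lines)[1]
  m <- as.integer(strsplit(lines[j], "\\s+")[[1]][2])
  tri <- read_block(j + 1L, m, 4L)
  if (any(tri[, 1] != 3)) stop_invalid("only triangle polygons supported")
  triangles <- matrix(as.integer(tri[, 2:4]), ncol = 3L) + 1L

  normals <- NULL
  areas <- NULL
  scalars <- list()
  k <- grep("^POINT_DATA", lines)[1]
  pos <- k + 1L
  while (!is.na(pos) && pos <= length(lines)) {
    hdr <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (identical(hdr[1], "NORMALS")) {
      normals <- read_block(pos + 1L, n, 3L)
      pos <- pos + 1L + n
    } else if (identical(hdr[1], "SCALARS")) {
      vals <- as.numeric(unlist(strsplit(trimws(
        lines[(pos + 2L):(pos + 1L + n)]), "\\s+")))
      if (identical(hdr[2], "vertex_area")) {
        areas <- vals
      } else {
        scalars[[hdr[2]]] <- vals
      }
      pos <- pos + 2L + n
    } else {
      break
    }
  }
  if (is.null(normals)) stop_invalid("no NORMALS point data in %s", path)
  mesh <- surface_mesh(vertices, triangles, normals, vertex_areas = areas)
  list(mesh = mesh, point_scalars = scalars)
}
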