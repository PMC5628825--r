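#' Correspondence-tagged triangle mesh
#'
#' A `corr_shape` is a surface as `n` ordered vertices (world mm) with an
#' optional triangle list. Shapes sharing a `family_id` are in vertex
#' correspondence: vertex `j` denotes the same anatomical location on every
#' member, which is what lets shapes be stacked as dictionary atoms.
#'
#' @param vertices n x 3 numeric matrix, world mm.
#' @param faces optional F x 3 integer matrix of 1-based vertex indices.
#' @param family_id optional correspondence tag (character).
#' @return object of class `corr_shape`.
#' @export
corr_shape <- function(vertices, faces = NULL, family_id = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L) stopf("vertices must be n x 3")
  if (any(!is.finite(vertices))) stopf("vertices must be finite")
  if (!is.null(faces)) {
    faces <- matrix(as.integer(faces), ncol = 3L)
    if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
      stopf("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces,
                 family_id = family_id),
            class = "corr_shape")
}

#' @export
print.corr_shape <- function(x, ...) {
  cat(sprintf("<corr_shape> %d vertices, %s faces%s\n", nrow(x$vertices),
              if (is.null(x$faces)) "no" else nrow(x$faces),
              if (is.null(x$family_id)) "" else paste0(" [", x$family_id, "]")))
  invisible(x)
}

face_normals_raw <- function(shape) {
  v <- shape$vertices; f <- shape$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Outward area-weighted vertex normals
#' @param shape a [corr_shape()] with faces oriented outward.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(shape) {
  if (is.null(shape$faces)) stopf("vertex normals need faces")
  fn <- face_normals_raw(shape) # length = 2*area, so this is area weighting
  n <- nrow(shape$vertices)
  vn <- matrix(0, n, 3)
  for (c in 1:3) {
    for (a in 1:3) {
      acc <- rowsum(fn[, a], shape$faces[, c], reorder = FALSE)
      vn[as.integer(rownames(acc)), a] <- vn[as.integer(rownames(acc)), a] + acc
    }
  }
  len <- row_norms(vn)
  len[len == 0] <- 1
  vn / len
}

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Positive when faces are oriented outward (divergence-theorem tetrahedra).
#' @param shape a [corr_shape()] with faces.
#' @export
mesh_volume <- function(shape) {
  v <- shape$vertices; f <- shape$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
      a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

# Flip face orientation if the signed volume is negative.
orient_outward <- function(shape) {
  if (!is.null(shape$faces) && nrow(shape$faces) >= 4 && mesh_volume(shape) < 0)
    shape$faces <- shape$faces[, c(1L, 3L, 2L)]
  shape
}

# Undirected edge list (E x 2, sorted pairs) of a face matrix.
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Is the mesh closed (watertight)?
#'
#' TRUE iff every undirected edge is shared by exactly two faces.
#' @param shape a [corr_shape()] with faces.
#' @export
is_closed_mesh <- function(shape) {
  if (is.null(shape$faces) || nrow(shape$faces) < 4L) return(FALSE)
  e <- mesh_edges(shape$faces)
  tab <- table(paste(e[, 1], e[, 2]))
  all(tab == 2L)
}

# 1-ring neighbour list (list of integer vectors, one per vertex).
vertex_neighbors <- function(shape) {
  n <- nrow(shape$vertices)
  e <- mesh_edges(shape$faces)
  e <- unique(e)
  nb <- vector("list", n)
  sp1 <- split(e[, 2], e[, 1])
  sp2 <- split(e[, 1], e[, 2])
  for (k in names(sp1)) nb[[as.integer(k)]] <- c(nb[[as.integer(k)]], sp1[[k]])
  for (k in names(sp2)) nb[[as.integer(k)]] <- c(nb[[as.integer(k)]], sp2[[k]])
  lapply(nb, unique)
}

# ---------------------------------------------------------------------------
# Mesh file I/O: ASCII PLY (default), OBJ, ASCII STL.
# ---------------------------------------------------------------------------

#' Read a triangle mesh (PLY, OBJ or STL)
#'
#' Vertices are taken to be world mm. Faces are re-oriented outward when the
#' signed enclosed volume is negative. STL facets (which carry no shared
#' vertices) are merged by exact coordinate identity.
#'
#' @param path file path.
#' @param format one of "ply", "obj", "stl"; default inferred from extension.
#' @param family_id optional correspondence tag to attach.
#' @return a [corr_shape()].
#' @export
read_mesh <- function(path, format = NULL, family_id = NULL) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  format <- tolower(format %||% tools::file_ext(path))
  shape <- switch(format,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    stopf("unsupported mesh format '%s' (use ply/obj/stl)", format))
  shape$family_id <- family_id
  orient_outward(shape)
}

#' Write a triangle mesh (PLY, OBJ or STL)
#' @param shape a [corr_shape()].
#' @param path output path.
#' @param format one of "ply", "obj", "stl"; default inferred from extension.
#' @export
write_mesh <- function(shape, path, format = NULL) {
  stopifnot(inherits(shape, "corr_shape"))
  if (nrow(shape$vertices) == 0L) stopf("refusing to write an empty mesh")
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    ply = write_ply(shape, path),
    obj = write_obj(shape, path),
    stl = write_stl(shape, path),
    stopf("unsupported mesh format '%s' (use ply/obj/stl)", format))
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply")
    stopf("PLY parse failure: missing 'ply' magic in %s", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stopf("PLY parse failure: no end_header in %s", path)
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stopf("PLY parse failure: only ASCII PLY supported (%s)", path)
  nv <- suppressWarnings(as.integer(sub("^element\\s+vertex\\s+", "",
                                        grep("^element\\s+vertex\\s", hdr, value = TRUE))))
  nf <- suppressWarnings(as.integer(sub("^element\\s+face\\s+", "",
                                        grep("^element\\s+face\\s", hdr, value = TRUE))))
  if (length(nv) != 1L || is.na(nv))
    stopf("PLY parse failure: element vertex count missing in %s", path)
  nf <- if (length(nf) == 1L && !is.na(nf)) nf else 0L
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stopf("PLY parse failure: body shorter than header promises")
  vts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
  if (any(is.na(vts))) stopf("PLY parse failure: non-numeric vertex line")
  faces <- NULL
  if (nf > 0L) {
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(fl, function(x) {
      x <- as.integer(x)
      if (is.na(x[1]) || x[1] != 3L)
        stopf("PLY parse failure: non-triangular face (count %s)", x[1])
      x[2:4] + 1L
    }))
  }
  corr_shape(vts, faces)
}

write_ply <- function(shape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- if (is.null(shape$faces)) 0L else nrow(shape$faces)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(shape$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(shape$vertices, 1, function(v)
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")), con)
  if (nf > 0L)
    writeLines(apply(shape$faces - 1L, 1, function(f)
      paste(c(3L, f), collapse = " ")), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L) stopf("OBJ parse failure: no vertex lines in %s", path)
  vts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
  if (any(is.na(vts))) stopf("OBJ parse failure: non-numeric vertex line")
  faces <- NULL
  if (length(fl)) {
    faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
      idx <- as.integer(sub("/.*$", "", x[-1]))
      if (length(idx) != 3L || any(is.na(idx)))
        stopf("OBJ parse failure: faces must be triangles with numeric indices")
      idx
    }))
  }
  corr_shape(vts, faces)
}

write_obj <- function(shape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(shape$vertices, 1, function(v)
    paste(c("v", format(v, digits = 17, scientific = FALSE, trim = TRUE)),
          collapse = " ")), con)
  if (!is.null(shape$faces))
    writeLines(apply(shape$faces, 1, function(f)
      paste(c("f", f), collapse = " ")), con)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE, skipNul = TRUE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1]))
    stopf("STL parse failure: only ASCII STL supported (%s)", path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L || length(vl) == 0L)
    stopf("STL parse failure: vertex count not a multiple of 3")
  raw <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
  if (any(is.na(raw))) stopf("STL parse failure: non-numeric vertex")
  # merge duplicated facet corners by exact coordinate identity
  key <- apply(raw, 1, function(v) paste(sprintf("%.17g", v), collapse = ","))
  uk <- !duplicated(key)
  verts <- raw[uk, , drop = FALSE]
  id <- match(key, key[uk])
  faces <- matrix(id, ncol = 3L, byrow = TRUE)
  corr_shape(verts, faces)
}

write_stl <- function(shape, path) {
  if (is.null(shape$faces)) stopf("STL needs faces")
  con <- file(path, "w")
  on.exit(close(con))
  fn <- face_normals_raw(shape)
  len <- row_norms(fn); len[len == 0] <- 1
  fn <- fn / len
  writeLines("solid spssm", con)
  v <- shape$vertices
  for (i in seq_len(nrow(shape$faces))) {
    f <- shape$faces[i, ]
    writeLines(c(
      paste(c("facet normal", sprintf("%.9g", fn[i, ])), collapse = " "),
      "  outer loop",
      paste("    vertex", paste(sprintf("%.17g", v[f[1], ]), collapse = " ")),
      paste("    vertex", paste(sprintf("%.17g", v[f[2], ]), collapse = " ")),
      paste("    vertex", paste(sprintf("%.17g", v[f[3], ]), collapse = " ")),
      "  endloop", "endfacet"), con)
  }
  writeLines("endsolid spssm", con)
}
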