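#' Canonical anatomical mark-point group names
#'
#' The seven named surface landmark groups used to anchor the sparse shape fit:
#' high-curvature or tissue-adjacent locations that a PCA shape model tends to
#' smooth away.
#' @export
LANDMARK_GROUPS <- c(
  "Hepatic Dome",
  "Right Lobe Anterior Segment",
  "Right Lobe Tip",
  "Right Lobe Posterior Segment",
  "Morrison Pouch",
  "Porta Hepatis",
  "Left Lobe Lateral Segment")

#' Landmark set
#'
#' An ordered set of named mark points, each either a vertex index into a
#' correspondence family (mode `"index"`) or a world point in mm (mode
#' `"world"`). In files, vertex indices are 0-based; in R they are held
#' 1-based.
#'
#' @param names character vector of group names (unique).
#' @param mode "index" or "world" (single mode for the whole set).
#' @param values for "index": integer vector (1-based); for "world": n x 3
#'   matrix of mm coordinates.
#' @export
landmark_set <- function(names, mode = c("world", "index"), values) {
  mode <- match.arg(mode)
  names <- as.character(names)
  if (anyDuplicated(names)) stopf("duplicate landmark group name")
  if (length(names) == 0L) stopf("empty landmark set")
  extra <- setdiff(names, LANDMARK_GROUPS)
  if (length(extra))
    warnf("non-canonical landmark group name(s): %s", paste(extra, collapse = ", "))
  if (mode == "index") {
    values <- as.integer(values)
    if (length(values) != length(names) || any(values < 1L))
      stopf("index-mode landmarks need one positive index per group")
  } else {
    values <- as.matrix(values)
    if (nrow(values) != length(names) || ncol(values) != 3L)
      stopf("world-mode landmarks need one (x,y,z) mm row per group")
  }
  structure(list(names = names, mode = mode, values = values),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d groups (%s mode): %s\n", length(x$names),
              x$mode, paste(x$names, collapse = "; ")))
  invisible(x)
}

#' Resolve a landmark set to world points
#' @param lm a [landmark_set()].
#' @param shape a [corr_shape()]; required for index-mode sets.
#' @return n x 3 matrix of world mm points, rownames = group names.
#' @export
landmark_points <- function(lm, shape = NULL) {
  pts <- if (lm$mode == "world") lm$values else {
    if (is.null(shape)) stopf("index-mode landmarks need a shape to resolve")
    if (max(lm$values) > nrow(shape$vertices))
      stopf("landmark index %d exceeds shape vertex count %d",
            max(lm$values), nrow(shape$vertices))
    shape$vertices[lm$values, , drop = FALSE]
  }
  rownames(pts) <- lm$names
  pts
}

#' Read landmarks from JSON
#'
#' Expected form: a JSON array of objects with fields `name`,
#' `mode` ("index" or "world") and `value` (0-based vertex index, or [x,y,z]
#' mm). All entries must share one mode.
#' @param path JSON file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  js <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (length(js) == 0L) stopf("empty landmark file: %s", path)
  nms <- vapply(js, function(e) as.character(e$name %||% NA_character_), "")
  modes <- vapply(js, function(e) as.character(e$mode %||% NA_character_), "")
  if (any(is.na(nms)) || any(is.na(modes)))
    stopf("landmark entries need 'name' and 'mode' fields")
  if (length(unique(modes)) != 1L) stopf("mixed landmark modes are not supported")
  mode <- modes[1]
  if (mode == "index") {
    vals <- vapply(js, function(e) as.integer(e$value), 1L) + 1L # 0-based in file
    landmark_set(nms, "index", vals)
  } else if (mode == "world") {
    vals <- do.call(rbind, lapply(js, function(e) as.numeric(unlist(e$value))))
    landmark_set(nms, "world", vals)
  } else stopf("landmark mode must be 'index' or 'world', got '%s'", mode)
}

#' Write landmarks to JSON (inverse of [read_landmarks()])
#' @param lm a [landmark_set()].
#' @param path output path.
#' @export
write_landmarks <- function(lm, path) {
  entries <- lapply(seq_along(lm$names), function(i) {
    list(name = lm$names[i], mode = lm$mode,
         value = if (lm$mode == "index") lm$values[i] - 1L
                 else as.numeric(lm$values[i, ]))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
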