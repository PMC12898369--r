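# Canal centerline and implant-apex landmarks.

#' Construct a centerline
#'
#' An ordered polyline of world-mm points tracing the nerve/canal axis.
#' Arc length is the cumulative Euclidean distance along the polyline and
#' parameterizes every downstream per-station quantity.
#'
#' @param points numeric matrix (n x 3), n >= 2, consecutive points distinct.
#' @return An object of class `centerline` with fields `points` and
#'   `arc_length` (mm, `arc_length[1] == 0`, strictly increasing).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop_geometry("centerline points must be an n x 3 numeric matrix")
  if (nrow(points) < 2L)
    stop_geometry("a centerline needs at least 2 points")
  if (any(!is.finite(points)))
    stop_geometry("centerline points must be finite")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    stop_geometry("centerline contains repeated consecutive points")
  dimnames(points) <- NULL
  structure(list(points = points, arc_length = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("Centerline:", nrow(x$points), "points,",
      format(total_arc_length(x), digits = 6), "mm arc length\n")
  invisible(x)
}

total_arc_length <- function(cl) cl$arc_length[length(cl$arc_length)]

# Interpolated position(s) on the polyline at arc-length coordinate(s) s.
point_at_arc <- function(cl, s) {
  s <- pmin(pmax(s, 0), total_arc_length(cl))
  i <- findInterval(s, cl$arc_length, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(cl$points) - 1L)
  t <- (s - cl$arc_length[i]) / (cl$arc_length[i + 1L] - cl$arc_length[i])
  cl$points[i, , drop = FALSE] * (1 - t) +
    cl$points[i + 1L, , drop = FALSE] * t
}

parse_point_table <- function(path, what) {
  if (!file.exists(path))
    stop_format(sprintf("%s file does not exist: '%s'", what, path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^[A-Za-z]", lines[1]) &&
      !grepl("^[-+0-9.]", lines[1]))
    lines <- lines[-1L]  # tolerate an x,y,z header row
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "[,;[:space:]]+")[[1]]))
    v <- v[!is.na(v)]
    if (length(v) != 3L)
      stop_format(sprintf("%s '%s': expected 3 numbers per line, got '%s'",
                          what, path, l))
    v
  })
  do.call(rbind, rows)
}

#' Read a centerline from a plain-text point table
#'
#' One world-mm point per line, comma- or whitespace-separated x, y, z;
#' lines beginning with `#` are ignored.
#'
#' @param path text file path.
#' @return A [centerline()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("# canal axis", "0,0,0", "0,0,10"), f)
#' read_centerline(f)$arc_length
#' @export
read_centerline <- function(path) {
  pts <- parse_point_table(path, "centerline")
  if (is.null(pts) || nrow(pts) < 2L)
    stop_geometry(sprintf("centerline '%s' needs at least 2 points", path))
  centerline(pts)
}

#' Construct an implant-apex landmark pair
#'
#' The mesial apex of the mesial implant and the distal apex of the distal
#' implant bound the surgically disrupted canal segment; their straight-line
#' distance is the defect length, the denominator of the regeneration
#' percentage.
#'
#' @param mesial_apex,distal_apex world-mm points (length-3), distinct.
#' @return An object of class `landmark_pair` with the two apices and the
#'   `defect_length` in mm.
#' @export
landmark_pair <- function(mesial_apex, distal_apex) {
  mesial_apex <- as_point3(mesial_apex, "mesial_apex")
  distal_apex <- as_point3(distal_apex, "distal_apex")
  d <- vdist(mesial_apex, distal_apex)
  if (d == 0)
    stop_geometry("landmark apices must be distinct")
  structure(list(mesial_apex = mesial_apex, distal_apex = distal_apex,
                 defect_length = d),
            class = "landmark_pair")
}

#' Read an apex landmark pair from a plain-text table
#'
#' Expects exactly two x,y,z rows: the mesial apex first, the distal apex
#' second (same comment and separator rules as [read_centerline()]).
#'
#' @param path text file path.
#' @return A [landmark_pair()].
#' @export
read_landmarks <- function(path) {
  pts <- parse_point_table(path, "landmarks")
  if (is.null(pts) || nrow(pts) != 2L)
    stop_format(sprintf("landmark file '%s' must contain exactly 2 points", path))
  landmark_pair(pts[1L, ], pts[2L, ])
}
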