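#' @title Planar geometry helpers
#' @name pialnet-geometry
#' @description Millimetre-scale planar geometry used throughout: shoelace
#'   areas, point-in-polygon tests, convex clipping and uniform sampling.
#'   Polygons are open rings (n x 2 matrices, last vertex not repeated).
NULL

# orient ring counter-clockwise and drop a repeated closing vertex
ccwRing <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (n > 1 && all(abs(m[1, ] - m[n, ]) < 1e-12)) m <- m[-n, , drop = FALSE]
  if (nrow(m) >= 3 && cppPolygonSignedArea(m) < 0)
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' @describeIn pialnet-geometry unsigned polygon area (mm^2)
#' @param poly,subject,clipper open-ring polygon matrices.
#' @export
polygonArea <- function(poly) cppPolygonArea(ccwRing(poly))

#' @describeIn pialnet-geometry logical: is each point inside (or on) the
#'   polygon
#' @param pts two-column point matrix.
#' @param eps boundary tolerance (mm).
#' @export
pointInPolygon <- function(pts, poly, eps = 1e-9) {
  pts <- rbind(pts)
  cppPointsInPolygon(pts, ccwRing(poly), eps)
}

#' @describeIn pialnet-geometry intersection of a simple polygon with a
#'   convex polygon (Sutherland--Hodgman)
#' @export
clipToConvex <- function(subject, clipper)
  cppClipToConvex(ccwRing(subject), ccwRing(clipper))

#' @describeIn pialnet-geometry minimum distance from points to a polygon
#'   boundary (mm)
#' @export
distanceToBoundary <- function(pts, poly)
  cppDistToBoundary(rbind(pts), ccwRing(poly))

# uniform points in a polygon by bounding-box rejection
samplePointsInPolygon <- function(n, poly) {
  poly <- ccwRing(poly)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  lo <- apply(poly, 2, min); hi <- apply(poly, 2, max)
  out <- matrix(NA_real_, n, 2)
  got <- 0
  while (got < n) {
    m <- max(2 * (n - got), 16)
    cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]))
    keep <- cand[cppPointsInPolygon(cand, poly, 0), , drop = FALSE]
    take <- min(nrow(keep), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- keep[seq_len(take), ]
      got <- got + take
    }
  }
  out
}

# regular n-gon of the requested area
regularPolygon <- function(area, n = 24, center = c(0, 0), rotation = 0) {
  r <- sqrt(2 * area / (n * sin(2 * pi / n)))
  th <- rotation + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# polyline string <-> matrix ("x,y;x,y;...")
polylineFormat <- function(m) {
  if (is.null(m) || !nrow(m)) return(NA_character_)
  paste(sprintf("%.9g,%.9g", m[, 1], m[, 2]), collapse = ";")
}

polylineParse <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p)))
  if (any(!is.finite(m))) stop("malformed polyline string: ", s)
  m
}

# arc-length midpoint of a polyline matrix
polylineMidpoint <- function(m) {
  if (nrow(m) == 1) return(m[1, ])
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  half <- cum[length(cum)] / 2
  i <- findInterval(half, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1), nrow(m) - 1)
  t <- if (seg[i] > 0) (half - cum[i]) / seg[i] else 0
  m[i, ] + t * (m[i + 1, ] - m[i, ])
}
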