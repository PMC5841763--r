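## Planar computational geometry used by the range-size module: shoelace
## areas, boundary-inclusive point-in-polygon, Bowyer-Watson Delaunay
## triangulation, Delaunay alpha-shapes and convex-polygon clipping.
## Coordinates are planar kilometres throughout.

EARTH_RADIUS_KM <- 6371.0088

#' Signed and absolute polygon area
#'
#' Shoelace area of a simple polygon given as a two-column coordinate matrix
#' (vertices in order, ring not repeated).
#'
#' @param poly numeric matrix with columns x, y.
#' @return Area in squared coordinate units (non-negative).
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' Boundary-inclusive point-in-polygon test
#'
#' Ray-casting test; points lying on an edge (within a small relative
#' tolerance) count as inside.
#'
#' @param pts two-column matrix of query points.
#' @param poly two-column matrix of polygon vertices.
#' @param tol absolute snapping tolerance for the on-boundary test.
#' @return Logical vector, one entry per query point.
#' @export
point_in_polygon <- function(pts, poly, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  poly <- as.matrix(poly)
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- poly[j, 1L]; y2 <- poly[j, 2L]
  out <- logical(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    px <- pts[k, 1L]; py <- pts[k, 2L]
    ## on-segment check
    dx <- x2 - x1; dy <- y2 - y1
    cross <- dx * (py - y1) - dy * (px - x1)
    dot <- (px - x1) * dx + (py - y1) * dy
    len2 <- dx * dx + dy * dy
    on_edge <- abs(cross) <= tol * pmax(1, sqrt(len2)) &
      dot >= -tol & dot <= len2 + tol
    if (any(on_edge)) { out[k] <- TRUE; next }
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    out[k] <- (sum(crosses) %% 2L) == 1L
  }
  out
}

## Circumcentre and squared circumradius of triangles given by index rows of
## `tri` into point matrix `P`.  Degenerate (collinear) triangles get an
## infinite radius.
circumcircles <- function(P, tri) {
  ax <- P[tri[, 1L], 1L]; ay <- P[tri[, 1L], 2L]
  bx <- P[tri[, 2L], 1L]; by <- P[tri[, 2L], 2L]
  cx <- P[tri[, 3L], 1L]; cy <- P[tri[, 3L], 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  bad <- !is.finite(d) | abs(d) < 1e-12
  ux[bad] <- Inf; uy[bad] <- Inf; r2[bad] <- Inf
  cbind(ux, uy, r2)
}

#' Delaunay triangulation (Bowyer-Watson)
#'
#' Incremental Delaunay triangulation of a planar point set.  Cocircular
#' point groups (e.g. grid data) are triangulated with an arbitrary but
#' deterministic diagonal choice; this does not affect alpha-shape areas.
#'
#' @param pts two-column matrix of unique, non-collinear points (>= 3).
#' @return Integer matrix, one row per triangle, columns indexing `pts`.
#' @export
delaunay_triangulation <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) abort_validation("need at least 3 points for a triangulation")
  rng_x <- range(pts[, 1L]); rng_y <- range(pts[, 2L])
  cx <- mean(rng_x); cy <- mean(rng_y)
  span <- max(rng_x[2L] - rng_x[1L], rng_y[2L] - rng_y[1L], 1)
  M <- 50 * span
  P <- rbind(pts, c(cx - 2 * M, cy - M), c(cx + 2 * M, cy - M), c(cx, cy + 2 * M))
  cap <- 4L * n + 16L
  tri <- matrix(0L, nrow = cap, ncol = 3L)
  cc <- matrix(0, nrow = cap, ncol = 3L)
  active <- logical(cap)
  tri[1L, ] <- c(n + 1L, n + 2L, n + 3L)
  cc[1L, ] <- circumcircles(P, tri[1L, , drop = FALSE])
  active[1L] <- TRUE
  ntri <- 1L
  ord <- order(pts[, 1L], pts[, 2L])
  for (i in ord) {
    px <- P[i, 1L]; py <- P[i, 2L]
    idx <- which(active[seq_len(ntri)])
    d2 <- (cc[idx, 1L] - px)^2 + (cc[idx, 2L] - py)^2
    ## cocircular points (d2 == r2) are treated as inside, so cocircular
    ## groups are re-fanned deterministically from the inserted point
    bad <- idx[d2 <= cc[idx, 3L] * (1 + 1e-10)]
    if (!length(bad)) {
      ## numerically outside every circumcircle: fall back to the triangle
      ## that contains the point
      bad <- idx[triangle_contains(P, tri[idx, , drop = FALSE], px, py)]
      bad <- bad[seq_len(min(1L, length(bad)))]
    }
    ## boundary of the cavity: edges used by exactly one bad triangle
    e <- rbind(tri[bad, c(1L, 2L), drop = FALSE],
               tri[bad, c(2L, 3L), drop = FALSE],
               tri[bad, c(3L, 1L), drop = FALSE])
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    keep_edge <- !(key %in% key[duplicated(key)])
    e <- e[keep_edge, , drop = FALSE]
    active[bad] <- FALSE
    if (nrow(e)) {
      newt <- cbind(e, i)
      newcc <- circumcircles(P, newt)
      ni <- nrow(newt)
      if (ntri + ni > cap) {
        grow <- max(cap, ni) * 2L
        tri <- rbind(tri, matrix(0L, grow, 3L))
        cc <- rbind(cc, matrix(0, grow, 3L))
        active <- c(active, logical(grow))
        cap <- cap + grow
      }
      rows <- ntri + seq_len(ni)
      tri[rows, ] <- newt
      cc[rows, ] <- newcc
      active[rows] <- TRUE
      ntri <- ntri + ni
    }
  }
  res <- tri[seq_len(ntri), , drop = FALSE][active[seq_len(ntri)], , drop = FALSE]
  res <- res[res[, 1L] <= n & res[, 2L] <= n & res[, 3L] <= n, , drop = FALSE]
  storage.mode(res) <- "integer"
  res
}

## Barycentric containment test for index-triangle rows over points P.
triangle_contains <- function(P, tri, px, py, tol = 1e-9) {
  ax <- P[tri[, 1L], 1L]; ay <- P[tri[, 1L], 2L]
  bx <- P[tri[, 2L], 1L]; by <- P[tri[, 2L], 2L]
  cx <- P[tri[, 3L], 1L]; cy <- P[tri[, 3L], 2L]
  d1 <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  d2 <- (cx - bx) * (py - by) - (cy - by) * (px - bx)
  d3 <- (ax - cx) * (py - cy) - (ay - cy) * (px - cx)
  (d1 >= -tol & d2 >= -tol & d3 >= -tol) |
    (d1 <= tol & d2 <= tol & d3 <= tol)
}

all_collinear <- function(pts) {
  if (nrow(pts) < 3L) return(TRUE)
  p0 <- pts[1L, ]
  v <- sweep(pts[-1L, , drop = FALSE], 2L, p0)
  span <- max(abs(v), 1e-12)
  cr <- v[1L, 1L] * v[, 2L] - v[1L, 2L] * v[, 1L]
  ## first direction vector may be degenerate; test all pairs against longest
  i_long <- which.max(rowSums(v^2))
  cr <- v[i_long, 1L] * v[, 2L] - v[i_long, 2L] * v[, 1L]
  all(abs(cr) <= 1e-9 * span^2)
}

#' Delaunay alpha-shape of a planar point set
#'
#' Union of the Delaunay triangles whose circumradius is at most `alpha`; the
#' polygonal counterpart of the alpha-hull.  As `alpha` grows the shape grows
#' monotonically towards the convex hull; small `alpha` can give a
#' disconnected (multi)polygon or an empty set.
#'
#' @param pts two-column matrix of planar points (km).
#' @param alpha radius threshold in the same units as `pts`.
#' @return An object of class `alpha_shape`: list with `points`, kept
#'   `triangles` (index matrix), `alpha`, `area` (sum of kept triangle
#'   areas), and `rings` (list of boundary-ring coordinate matrices; outer
#'   rings counter-clockwise, holes clockwise).
#' @export
alpha_shape <- function(pts, alpha) {
  pts <- unique(as.matrix(pts))
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    abort_validation("'alpha' must be a single positive value (Inf allowed)")
  if (nrow(pts) < 3L || all_collinear(pts))
    abort_validation("alpha_shape needs >= 3 non-collinear points")
  tri <- delaunay_triangulation(pts)
  cc <- circumcircles(pts, tri)
  keep <- sqrt(cc[, 3L]) <= alpha
  kept <- tri[keep, , drop = FALSE]
  area <- if (nrow(kept)) {
    sum(vapply(seq_len(nrow(kept)), function(i)
      polygon_area(pts[kept[i, ], , drop = FALSE]), numeric(1)))
  } else 0
  structure(list(points = pts, triangles = kept, alpha = alpha,
                 area = area, rings = alpha_shape_rings(pts, kept)),
            class = "alpha_shape")
}

## Assemble boundary rings from the kept triangles: orient every triangle
## counter-clockwise, collect directed edges whose reverse is absent, then
## chain them.  Outer rings come out CCW, holes CW.
alpha_shape_rings <- function(pts, kept) {
  if (!nrow(kept)) return(list())
  for (i in seq_len(nrow(kept))) {
    if (polygon_signed_area(pts[kept[i, ], , drop = FALSE]) < 0)
      kept[i, ] <- kept[i, c(1L, 3L, 2L)]
  }
  ed <- rbind(kept[, c(1L, 2L), drop = FALSE],
              kept[, c(2L, 3L), drop = FALSE],
              kept[, c(3L, 1L), drop = FALSE])
  fwd <- paste(ed[, 1L], ed[, 2L])
  rev <- paste(ed[, 2L], ed[, 1L])
  boundary <- ed[!(fwd %in% rev), , drop = FALSE]
  rings <- list()
  used <- logical(nrow(boundary))
  from <- split(seq_len(nrow(boundary)), boundary[, 1L])
  while (any(!used)) {
    start <- which(!used)[1L]
    ring <- boundary[start, 1L]
    cur <- start
    repeat {
      used[cur] <- TRUE
      nxt_v <- boundary[cur, 2L]
      ring <- c(ring, nxt_v)
      cand <- from[[as.character(nxt_v)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1L]
    }
    if (length(ring) >= 4L && ring[1L] == ring[length(ring)])
      rings[[length(rings) + 1L]] <- pts[ring[-length(ring)], , drop = FALSE]
  }
  rings
}

is_convex_polygon <- function(poly, tol = 1e-9) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1L], 1L)
  nx2 <- nxt[nxt]
  cr <- (poly[nxt, 1L] - poly[, 1L]) * (poly[nx2, 2L] - poly[nxt, 2L]) -
    (poly[nxt, 2L] - poly[, 2L]) * (poly[nx2, 1L] - poly[nxt, 1L])
  scale <- max(abs(cr), tol)
  all(cr >= -tol * scale) || all(cr <= tol * scale)
}

## Sutherland-Hodgman clipping of an arbitrary subject polygon against a
## CONVEX clip polygon.  Returns a coordinate matrix (possibly with 0 rows).
clip_polygon_convex <- function(subject, clip) {
  clip <- as.matrix(clip)
  if (polygon_signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- as.matrix(subject)
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (!nrow(out)) break
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    dx <- b[1L] - a[1L]; dy <- b[2L] - a[2L]
    inside <- function(p) dx * (p[2L] - a[2L]) - dy * (p[1L] - a[1L]) >= -1e-12
    inp <- out
    out <- matrix(numeric(0), ncol = 2L)
    n <- nrow(inp)
    for (j in seq_len(n)) {
      cur <- inp[j, ]; prv <- inp[if (j == 1L) n else j - 1L, ]
      ci <- inside(cur); pi <- inside(prv)
      if (ci) {
        if (!pi) out <- rbind(out, seg_line_intersect(prv, cur, a, b))
        out <- rbind(out, cur)
      } else if (pi) {
        out <- rbind(out, seg_line_intersect(prv, cur, a, b))
      }
    }
  }
  out
}

seg_line_intersect <- function(p1, p2, a, b) {
  ## intersection of segment p1-p2 with the infinite line a-b
  d1 <- (b[1L] - a[1L]) * (p1[2L] - a[2L]) - (b[2L] - a[2L]) * (p1[1L] - a[1L])
  d2 <- (b[1L] - a[1L]) * (p2[2L] - a[2L]) - (b[2L] - a[2L]) * (p2[1L] - a[1L])
  t <- d1 / (d1 - d2)
  p1 + t * (p2 - p1)
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf("alpha-shape: alpha = %g, %d triangles, %d boundary ring(s), area = %.4g\n",
              x$alpha, nrow(x$triangles), length(x$rings), x$area))
  invisible(x)
}

#' @export
plot.alpha_shape <- function(x, ...) {
  plot(x$points, asp = 1, pch = 16, cex = 0.4, col = "grey40",
       xlab = "x (km)", ylab = "y (km)", ...)
  for (r in x$rings) {
    graphics::polygon(r[, 1L], r[, 2L], border = "firebrick", lwd = 1.5)
  }
  invisible(x)
}
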