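#' @include AllClasses.R
NULL

# Planar geometry helpers for score-space domains. Hull vertices are kept
# counter-clockwise; all polygons handled here are convex.

#' @importFrom grDevices chull
NULL

# convex hull as a CCW-ordered two-column matrix (may be a point or segment)
convexHullCCW <- function(xy) {
  xy <- as.matrix(xy)
  idx <- chull(xy[, 1], xy[, 2])      # chull returns clockwise order
  v <- xy[rev(idx), , drop = FALSE]
  dimnames(v) <- list(NULL, c("PC1", "PC2"))
  v
}

# signed shoelace area; positive for CCW rings
polygonArea <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# point-in-convex-polygon (boundary counts as inside)
pointInConvex <- function(p, v, tol = 1e-12) {
  n <- nrow(v)
  if (n == 0L) return(FALSE)
  if (n == 1L) return(all(abs(p - v[1, ]) <= tol))
  if (n == 2L) {
    d <- v[2, ] - v[1, ]
    cr <- d[1] * (p[2] - v[1, 2]) - d[2] * (p[1] - v[1, 1])
    if (abs(cr) > tol * (1 + sum(abs(d)))) return(FALSE)
    t <- sum((p - v[1, ]) * d) / sum(d * d)
    return(t >= -tol && t <= 1 + tol)
  }
  j <- c(2:n, 1L)
  cr <- (v[j, 1] - v[, 1]) * (p[2] - v[, 2]) - (v[j, 2] - v[, 2]) * (p[1] - v[, 1])
  all(cr >= -tol * (1 + max(abs(v))))
}

# Sutherland-Hodgman clip of convex subject polygon by convex clip polygon
clipConvex <- function(subject, clip) {
  if (nrow(subject) < 3L || nrow(clip) < 3L) return(subject[0, , drop = FALSE])
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]; b <- clip[if (i == n) 1L else i + 1L, ]
    inside <- function(p) {
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    }
    intersect_ab <- function(p, q) {
      d1 <- q - p; d2 <- b - a
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
      p + t * d1
    }
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    for (k in seq_len(m)) {
      cur <- inp[k, ]; nxt <- inp[if (k == m) 1L else k + 1L, ]
      ci <- inside(cur); ni <- inside(nxt)
      if (ci) out <- rbind(out, cur)
      if (ci != ni) out <- rbind(out, intersect_ab(cur, nxt))
    }
  }
  dimnames(out) <- list(NULL, c("PC1", "PC2"))
  out
}

# area of intersection of two convex polygons
convexOverlapArea <- function(a, b) {
  inter <- clipConvex(a, b)
  if (nrow(inter) < 3L) return(0)
  abs(polygonArea(inter))
}

# 32-bit FNV-1a hash of a character scalar, as hex (config fingerprinting)
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256                      # xor touches the low byte only
    h <- h - low + bitwXor(low, b %% 256)
    # 32-bit modular multiply in two 16-bit halves (doubles lose precision)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
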