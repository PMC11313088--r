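# Shared low-level helpers: interpolation, cyclic vectors, polygon geometry.

# Bilinear sample of a matrix at fractional (row, col) positions (1-based).
# Positions outside [1, nrow] x [1, ncol] return `fill`.
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1L) * nr + r0
  v <- img[i00]       * (1 - fr) * (1 - fc) +
       img[i00 + 1L]  * fr       * (1 - fc) +
       img[i00 + nr]  * (1 - fr) * fc +
       img[i00 + nr + 1L] * fr   * fc
  out[ok] <- v
  out
}

# Linear interpolation along a 1-D profile at fractional positions (1-based),
# clamped to the ends.
linear_sample <- function(v, x) {
  n <- length(v)
  x <- pmin(pmax(x, 1), n)
  x0 <- pmin(floor(x), n - 1L)
  f <- x - x0
  v[x0] * (1 - f) + v[x0 + 1L] * f
}

# Fill NA entries of a cyclic vector by linear interpolation between the
# nearest non-NA neighbours around the circle.
fill_cyclic_na <- function(x) {
  n <- length(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0L) stop("all values missing; nothing to interpolate")
  if (length(idx) == n) return(x)
  # unroll three periods so stats::approx handles the wrap
  xi <- c(idx - n, idx, idx + n)
  yi <- rep(x[idx], 3L)
  miss <- which(is.na(x))
  x[miss] <- approx(xi, yi, xout = miss)$y
  x
}

# Cyclic running median with odd window.
cyclic_median_filter <- function(x, window = 5L) {
  n <- length(x)
  if (n == 0L) return(x)
  h <- (window - 1L) %/% 2L
  xp <- c(tail(x, h), x, head(x, h))
  vapply(seq_len(n), function(i) median(xp[i:(i + 2L * h)]), numeric(1))
}

# Shoelace area of a polygon given as an n x 2 matrix of (x, y) vertices.
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# 31-bit polynomial rolling hash of a character scalar (configuration
# fingerprinting; stable across platforms, no external dependency).
string_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Minimal covering cyclic arc of a set of distinct 1-based row indices on a
# circle of n rows. Returns list(lo, hi, width) where the arc runs lo..hi
# cyclically (1-based) and width is its length in rows.
cyclic_span <- function(rows, n) {
  rows <- sort(unique(rows))
  if (length(rows) == 1L) return(list(lo = rows, hi = rows, width = 1L))
  gaps <- diff(c(rows, rows[1] + n))
  g <- which.max(gaps)
  lo <- rows[if (g == length(rows)) 1L else g + 1L]
  hi <- rows[g]
  width <- n - max(gaps) + 1L
  list(lo = lo, hi = hi, width = as.integer(width))
}

# Indices (1-based) of the cyclic interval lo..hi on a circle of n rows.
cyclic_seq <- function(lo, hi, n) {
  if (hi >= lo) lo:hi else c(lo:n, 1:hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
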