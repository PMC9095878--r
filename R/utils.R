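# Internal helpers: seeded sub-streams, small geometry, image resampling.

# Derive an independent sub-stream seed from a master seed and a stream
# counter. Kept below 2^31-1 so it is always a valid integer seed.
split_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) + 99991 * as.numeric(stream)
  as.integer(s %% 2147483647)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

# Rotation matrices acting on column vectors (x, y, z).
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

# Rodrigues rotation about an arbitrary unit axis.
rot_axis <- function(axis, deg) {
  u <- unit_vec(axis)
  a <- deg2rad(deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Unsigned angle between two vectors, degrees in [0, 180].
vec_angle <- function(u, v) {
  cu <- unit_vec(u); cv <- unit_vec(v)
  rad2deg(acos(max(-1, min(1, sum(cu * cv)))))
}

# Signed angle (degrees, (-180, 180]) from `from` to `to` measured about
# the normal `n`; both vectors are projected into the plane perpendicular
# to `n` first.
signed_angle_about <- function(n, from, to) {
  n <- unit_vec(n)
  f <- from - sum(from * n) * n
  t <- to - sum(to * n) * n
  if (sqrt(sum(f^2)) < 1e-8 || sqrt(sum(t^2)) < 1e-8)
    stop("projection into the rotation plane vanishes; angle undefined")
  f <- unit_vec(f); t <- unit_vec(t)
  a <- rad2deg(atan2(sum(cross3(f, t) * n), sum(f * t)))
  if (a <= -180) a <- a + 360
  a
}

# Least-squares rigid superposition (Kabsch). Returns the rotation that
# maps centered P onto centered Q plus both centroids.
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  cp <- colMeans(p); cq <- colMeans(q)
  p0 <- sweep(p, 2, cp); q0 <- sweep(q, 2, cq)
  s <- svd(crossprod(p0, q0))
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = r, center_p = cp, center_q = cq)
}

coords_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(x)
  }
  as.matrix(x[, c("x", "y", "z")])
}

# Bilinear sampling of matrix `m` at fractional (row, col) positions.
# Positions outside [1, nrow] x [1, ncol] yield NA.
bilinear_sample <- function(m, rr, cc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(rr))
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  if (!any(ok)) return(out)
  r <- rr[ok]; c <- cc[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v <- m[i00] * (1 - fr) * (1 - fc) +
    m[i00 + 1] * fr * (1 - fc) +
    m[i00 + nr] * (1 - fr) * fc +
    m[i00 + nr + 1] * fr * fc
  out[ok] <- v
  out
}

# Catmull-Rom bicubic sampling at fractional (row, col) positions;
# outside the grid -> NA, edge taps clamped.
bicubic_sample <- function(m, rr, cc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(rr))
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  if (!any(ok)) return(out)
  r <- rr[ok]; c <- cc[ok]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  cub <- function(x) {
    ax <- abs(x)
    ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
           ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
  }
  acc <- numeric(length(r))
  for (i in -1:2) {
    wi <- cub(fr - i)
    ri <- pmin(pmax(r0 + i, 1), nr)
    for (j in -1:2) {
      wj <- cub(fc - j)
      cj <- pmin(pmax(c0 + j, 1), nc)
      acc <- acc + wi * wj * m[(cj - 1) * nr + ri]
    }
  }
  out[ok] <- acc
  out
}

# Rotate an image (matrix) by `deg` counter-clockwise in (row, col)
# coordinates about `center` (row, col); outside -> fill.
rotate_image <- function(m, deg, center = NULL, fill = NA_real_,
                         interp = c("bilinear", "bicubic")) {
  interp <- match.arg(interp)
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  a <- deg2rad(deg)
  gr <- matrix(seq_len(nr), nr, nc) - center[1]
  gc <- matrix(rep(seq_len(nc), each = nr), nr, nc) - center[2]
  sr <- center[1] + cos(a) * gr + sin(a) * gc
  sc <- center[2] - sin(a) * gr + cos(a) * gc
  v <- if (interp == "bicubic")
    bicubic_sample(m, as.vector(sr), as.vector(sc))
  else bilinear_sample(m, as.vector(sr), as.vector(sc))
  v[is.na(v)] <- fill
  matrix(v, nr, nc)
}

# Translate an image by a (possibly fractional) (row, col) shift.
translate_image <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- matrix(seq_len(nr), nr, nc) - dr
  sc <- matrix(rep(seq_len(nc), each = nr), nr, nc) - dc
  v <- bilinear_sample(m, as.vector(sr), as.vector(sc))
  v[is.na(v)] <- fill
  matrix(v, nr, nc)
}

# Integer shift of a matrix with constant fill (used by grayscale dilation).
shift_matrix <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) < 1 || length(cs) < 1) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Connected components (4-connectivity) of a logical mask; returns an
# integer matrix of labels (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx_all <- which(mask)
  cur <- 0L
  for (seed in idx_all) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier) > 0) {
      r <- ((frontier - 1L) %% nr) + 1L
      up <- frontier[r > 1L] - 1L
      dn <- frontier[r < nr] + 1L
      lf <- frontier[frontier > nr] - nr
      rt <- frontier[frontier <= nr * (nc - 1L)] + nr
      nb <- unique(c(up, dn, lf, rt))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}
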