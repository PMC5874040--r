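`%||%` <- function(x, y) if (is.null(x)) y else x

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# geometric median (Weiszfeld): the L1 ("linear cost") analogue of the
# mean; rotation-equivariant and robust to a minority of displaced points
geometric_median <- function(X, max_iter = 200L, tol = 1e-12) {
  m <- colMeans(X)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(X, 2, m)^2))
    d[d < 1e-12] <- 1e-12
    m_new <- colSums(X / d) / sum(1 / d)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# signed angle (deg) about unit axis `n` rotating a onto b, both perp to n
signed_angle_about <- function(a, b, n) {
  rad2deg(atan2(sum(n * cross3(a, b)), sum(a * b)))
}
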