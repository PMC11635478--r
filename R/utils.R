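#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm rnorm rpois runif qpois qlnorm sd mad median
#'   quantile var cor ppois nls coef t.test complete.cases setNames approx
#' @importFrom utils write.csv read.csv head
NULL

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state. All randomness in the package flows through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Shift a matrix by (dr, dc), filling exposed entries with `fill`.
shift_matrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Integral of a unit 2-D Gaussian PSF over whole pixels.
# Pixel (col c, row r), 0-based, covers [c-0.5, c+0.5) x [r-0.5, r+0.5);
# continuous coordinates (x, y) = (column, row) with pixel centres at
# integers. Returns the rendered patch and its top-left pixel (0-based).
gaussian_patch <- function(x, y, sigma, intensity, nrow_img, ncol_img,
                           extent = 5) {
  h <- ceiling(extent * sigma)
  c0 <- max(0L, floor(x) - h); c1 <- min(ncol_img - 1L, floor(x) + h)
  r0 <- max(0L, floor(y) - h); r1 <- min(nrow_img - 1L, floor(y) + h)
  if (c0 > c1 || r0 > r1) return(NULL)
  cols <- c0:c1; rows <- r0:r1
  px <- pnorm((cols + 0.5 - x) / sigma) - pnorm((cols - 0.5 - x) / sigma)
  py <- pnorm((rows + 0.5 - y) / sigma) - pnorm((rows - 0.5 - y) / sigma)
  list(patch = intensity * outer(py, px), r0 = r0, c0 = c0)
}

# Add a rendered patch into an image matrix in place-ish fashion.
add_patch <- function(img, p) {
  if (is.null(p)) return(img)
  rows <- (p$r0 + 1L):(p$r0 + nrow(p$patch))
  cols <- (p$c0 + 1L):(p$c0 + ncol(p$patch))
  img[rows, cols] <- img[rows, cols] + p$patch
  img
}

# Draws from N(mu, sigma^2) truncated at zero (left truncation).
rtruncnorm0 <- function(n, mu, sigma) {
  if (n == 0L) return(numeric(0))
  if (sigma <= 0) return(rep(mu, n))
  p0 <- pnorm(0, mu, sigma)
  u <- runif(n, p0, 1)
  qnorm(u, mu, sigma)
}

fmt_num <- function(x) format(x, trim = TRUE, digits = 6)

# Group sums over integer groups 1..n, with zeros for empty groups.
sum_by <- function(x, g, n) {
  s <- rowsum(as.numeric(x), as.integer(g))
  out <- numeric(n)
  out[as.integer(rownames(s))] <- as.numeric(s)
  out
}
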