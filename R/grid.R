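# Periodic torus grids and fields: the shared numerical substrate.
#
# Fourier conventions (non-unitary, matching the kernel symbols):
#   forward   u_hat(k) = h^d * fft(u)          ~ int u(x) exp(-i k.x) dx
#   inverse   u(x)     = Re(fft(u_hat, inverse)) / L^d
# so that convolution is u_hat * symbol and Parseval reads
#   ||u||_L2^2 = h^d sum u^2 = (1/L^d) sum |u_hat|^2.

#' Periodic torus grid
#'
#' A node-centered lattice of `n^d` points on the box `[-L/2, L/2)^d` with
#' the wavenumber lattice `k = (2 pi / L) * j`, `j` in the usual FFT order.
#'
#' @param n points per dimension (a power of two).
#' @param d spatial dimension.
#' @param L box edge length (default 10).
#' @return an object of class `"torus_grid"` with fields `n`, `d`, `L`, `h`
#'   (cell size), `x` (node coordinates per axis), `kv` (wavenumbers per
#'   axis), `karr` (list of `d` wavenumber-component arrays), `k2`, `kmag`,
#'   `dealias` (2/3-rule mask array).
#' @export
torus_grid <- function(n = 32, d = 3, L = 10) {
  if (n < 4 || bitwAnd(n, n - 1L) != 0) stop("n must be a power of two >= 4")
  if (d < 1) stop("d must be positive")
  if (d * log2(n) > 26) stop("grid too large: d*log2(n) > 26")
  h <- L / n
  kv <- (2 * pi / L) * c(0:(n / 2 - 1), -(n / 2):-1)
  dims <- rep(n, d)
  karr <- vector("list", d)
  for (j in seq_len(d)) {
    perm <- seq_len(d)
    perm[c(1, j)] <- perm[c(j, 1)]
    base <- array(rep(kv, times = n^(d - 1)), dims)
    karr[[j]] <- if (j == 1) base else aperm(base, perm)
  }
  k2 <- Reduce(`+`, lapply(karr, function(a) a^2))
  kcut <- (2 / 3) * (2 * pi / L) * (n / 2)
  dealias <- Reduce(`&`, lapply(karr, function(a) abs(a) <= kcut)) * 1
  structure(list(n = as.integer(n), d = as.integer(d), L = L, h = h,
                 x = seq(-L / 2, L / 2 - h, by = h), kv = kv, karr = karr,
                 k2 = k2, kmag = sqrt(k2), dealias = dealias),
            class = "torus_grid")
}

#' @export
print.torus_grid <- function(x, ...) {
  cat(sprintf("torus grid: %d^%d nodes on [-%g, %g)^%d, h = %g\n",
              x$n, x$d, x$L / 2, x$L / 2, x$d, x$h))
  invisible(x)
}

#' Scalar field on a torus grid
#'
#' @param values numeric array with `d` dimensions of extent `n` (or a
#'   vector of length `n^d`, reshaped).
#' @param grid a [torus_grid()].
#' @param time simulation-time tag (optional).
#' @return an object of class `"grid_field"`.
#' @export
grid_field <- function(values, grid, time = NA_real_) {
  dims <- rep(grid$n, grid$d)
  if (is.null(dim(values))) dim(values) <- dims
  if (!all(dim(values) == dims)) stop("field values do not match the grid")
  if (!all(is.finite(values))) stop("non-finite field values")
  structure(list(values = values, grid = grid, time = time),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  n <- x$grid
  cat(sprintf("grid field on %d^%d torus (t = %s): range [%.4g, %.4g], mass %.6g\n",
              n$n, n$d, format(x$time), min(x$values), max(x$values),
              field_mass(x)))
  invisible(x)
}

# forward / inverse transforms for plain arrays
fft_fwd <- function(values, grid) stats::fft(values) * grid$h^grid$d
fft_inv <- function(vhat, grid) Re(stats::fft(vhat, inverse = TRUE)) / grid$L^grid$d

#' Integral of a field over the box
#' @param field a [grid_field()].
#' @return `h^d` times the sum of nodal values.
#' @export
field_mass <- function(field) sum(field$values) * field$grid$h^field$grid$d

#' Spectral convolution with a kernel symbol
#'
#' Multiplies the field transform pointwise by the symbol and transforms
#' back. The kernel's zero-mode convention is inherited from the symbol
#' (mollified Riesz symbols carry zero mode 0).
#'
#' @param field a [grid_field()].
#' @param symbol numeric array of symbol values on the grid wavenumber
#'   lattice (same dimensions as the field).
#' @return a [grid_field()] of the convolution.
#' @export
spectral_convolve <- function(field, symbol) {
  g <- field$grid
  if (!all(dim(symbol) == dim(field$values))) {
    stop("symbol dimensions do not match the field grid")
  }
  grid_field(fft_inv(fft_fwd(field$values, g) * symbol, g), g, field$time)
}

#' Deposit particles as a density field
#'
#' Spreads unit total weight over the grid with nearest-grid-point or
#' cloud-in-cell weights and divides by `N h^d`, so the result integrates to
#' exactly 1. With `deconvolve = TRUE` the cloud-in-cell transfer function
#' `prod_j sinc^2(k_j h / 2)` is divided out in Fourier space, restoring (up
#' to aliasing) the spectrum of the atomic empirical measure; use this when
#' the deposit is subsequently smoothed by a kernel that decays before the
#' Nyquist scale.
#'
#' @param positions `N x d` matrix of positions inside the box.
#' @param grid a [torus_grid()].
#' @param scheme `"cic"` (default) or `"ngp"`.
#' @param deconvolve logical; divide out the CIC transfer function.
#' @return a [grid_field()] with unit mass.
#' @export
deposit_particles <- function(positions, grid, scheme = c("cic", "ngp"),
                              deconvolve = FALSE) {
  scheme <- match.arg(scheme)
  if (!all(is.finite(positions))) stop("non-finite particle positions")
  w <- if (scheme == "cic") cic_deposit_cpp(positions, grid$n, grid$L)
       else ngp_deposit_cpp(positions, grid$n, grid$L)
  vals <- array(w / grid$h^grid$d, rep(grid$n, grid$d))
  if (deconvolve) {
    if (scheme != "cic") stop("deconvolution applies to the CIC scheme")
    vals <- fft_inv(fft_fwd(vals, grid) / cic_transfer(grid), grid)
  }
  grid_field(vals, grid)
}

# CIC Fourier transfer function, cached on the grid object environment
cic_transfer <- function(grid) {
  w1 <- ifelse(grid$kv == 0, 1,
               (sin(grid$kv * grid$h / 2) / (grid$kv * grid$h / 2))^2)
  tr <- Reduce(`*`, lapply(seq_len(grid$d), function(j) {
    perm <- seq_len(grid$d)
    perm[c(1, j)] <- perm[c(j, 1)]
    base <- array(rep(w1, times = grid$n^(grid$d - 1)), rep(grid$n, grid$d))
    if (j == 1) base else aperm(base, perm)
  }))
  tr
}

#' Interpolate a field at particle positions
#'
#' Multilinear (cloud-in-cell) gather; exact for fields that are multilinear
#' within a cell, and adjoint to [deposit_particles()] with the CIC scheme.
#'
#' @param field a [grid_field()].
#' @param positions `N x d` matrix of positions inside the box.
#' @return numeric vector of length `N`.
#' @export
interpolate_field <- function(field, positions) {
  if (!all(is.finite(positions))) stop("non-finite particle positions")
  g <- field$grid
  cic_gather_cpp(as.vector(field$values), positions, g$n, g$L)
}

#' Norms of a grid field
#'
#' `l2` and `l1` by the quadrature weight `h^d`, `linf` as the max nodal
#' magnitude, and the `H^1` seminorm by exact spectral differentiation.
#'
#' @param field a [grid_field()].
#' @return a list with `l2`, `h1_semi`, `l1`, `linf`.
#' @export
field_norms <- function(field) {
  g <- field$grid
  hd <- g$h^g$d
  vh <- fft_fwd(field$values, g)
  l2_spec <- sqrt(sum(Mod(vh)^2) / g$L^g$d)
  h1 <- sqrt(sum(g$k2 * Mod(vh)^2) / g$L^g$d)
  list(l2 = sqrt(sum(field$values^2) * hd), h1_semi = h1,
       l1 = sum(abs(field$values)) * hd, linf = max(abs(field$values)),
       l2_spectral = l2_spec)
}

#' Wrapped (periodized) isotropic Gaussian density on the grid
#'
#' The heat kernel on the torus: an isotropic Gaussian of width `s0`
#' periodized over `[-L/2, L/2)^d` by summing lattice images. Serves as the
#' default initial density `u0` and as the closed-form reference for heat
#' flow tests.
#'
#' @param grid a [torus_grid()].
#' @param s0 Gaussian width (standard deviation per coordinate).
#' @param center center of the Gaussian (length `d`).
#' @param images number of periodic images summed per side.
#' @return a [grid_field()] with unit mass up to image truncation.
#' @export
gaussian_field <- function(grid, s0, center = rep(0, grid$d), images = 3) {
  marg <- lapply(seq_len(grid$d), function(j) {
    v <- 0
    for (m in -images:images) v <- v + stats::dnorm(grid$x + m * grid$L,
                                                    center[j], s0)
    v
  })
  vals <- Reduce(function(a, b) outer(a, b), marg)
  dim(vals) <- rep(grid$n, grid$d)
  grid_field(vals, grid)
}

# wrap coordinates into [-L/2, L/2)
wrap_box <- function(x, L) x - L * floor((x + L / 2) / L)
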