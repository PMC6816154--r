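`%||%` <- function(a, b) if (is.null(a)) b else a

# gather indices for a circular shift: fftshift uses split = n - n %/% 2,
# ifftshift uses split = n %/% 2 (they coincide for even n)
shift_indices <- function(n, split) {
  if (n <= 1L) return(1L)
  c((split + 1L):n, 1L:split)
}

apply_shift <- function(x, split_fun) {
  d <- dim(x)
  if (is.null(d)) {
    return(x[shift_indices(length(x), split_fun(length(x)))])
  }
  idx <- lapply(d, function(n) shift_indices(n, split_fun(n)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Centre / uncentre the zero-frequency component of an array
#'
#' `fftshift()` moves the zero-frequency (DC) element of an array of Fourier
#' coefficients to the centre of each dimension; `ifftshift()` is its exact
#' inverse (they differ only for odd-length dimensions).
#'
#' @param x numeric or complex vector, matrix, or array.
#' @return An array of the same shape.
#' @export
fftshift <- function(x) apply_shift(x, function(n) n - n %/% 2L)

#' @rdname fftshift
#' @export
ifftshift <- function(x) apply_shift(x, function(n) n %/% 2L)

#' Centred unitary discrete Fourier transform
#'
#' `fftc()` maps an image-domain array to k-space with the DC coefficient at
#' the matrix centre and with unitary scaling (`1/sqrt(N)`), so Parseval's
#' identity holds exactly and the adjoint of the transform equals its
#' inverse. `ifftc()` is the inverse map.
#'
#' @param x complex (or numeric) array in the image domain.
#' @param k complex array in centred k-space.
#' @return A complex array of the same shape.
#' @export
fftc <- function(x) fftshift(stats::fft(x)) / sqrt(length(x))

#' @rdname fftc
#' @export
ifftc <- function(k) stats::fft(ifftshift(k), inverse = TRUE) / sqrt(length(k))

#' Normalised root-mean-square error
#'
#' RMSE between two real arrays, normalised by the intensity range of the
#' reference.
#'
#' @param estimate,reference real arrays of identical shape.
#' @return A single number (dimensionless).
#' @export
nrmse <- function(estimate, reference) {
  stopifnot(length(estimate) == length(reference))
  rng <- max(reference) - min(reference)
  if (rng <= 0) stop("reference has zero intensity range")
  sqrt(mean((as.numeric(estimate) - as.numeric(reference))^2)) / rng
}

# deterministic child seeds below 2^31 from one master seed
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(2147483646L, n)
}

# i.i.d. complex Gaussian draws; `sd` is the per-component (real and
# imaginary) standard deviation
complex_noise <- function(n, sd) {
  complex(real = rnorm(n, 0, sd), imaginary = rnorm(n, 0, sd))
}

# replicate a (ny x nz) phase-encode mask along the readout dimension
broadcast_mask <- function(grid, nx) {
  array(rep(as.logical(grid), each = nx), c(nx, dim(grid)))
}

# separable Gaussian blur of a matrix with replicate padding; sigma in pixels
gauss_blur2 <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_rows <- function(m) {
    n <- nrow(m)
    pad <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

# Fourier-domain smoothing + zero-padded upsampling of a matrix. MR
# magnitude images are band-limited, so sinc (Fourier) interpolation is the
# natural sub-pixel interpolant; an optional Gaussian low-pass (sigma in
# input pixels) is applied in the same pass. Returns a (factor*ny) x
# (factor*nz) matrix whose pixel (1,1) is co-located with input pixel (1,1)
# and whose spacing is 1/factor input pixels.
fourier_upsample2 <- function(img, factor = 4L, sigma = 0) {
  ny <- nrow(img); nz <- ncol(img)
  K <- fftshift(fft(img))
  ky <- seq_len(ny) - (ny %/% 2 + 1)
  kz <- seq_len(nz) - (nz %/% 2 + 1)
  if (sigma > 0) {
    wy <- exp(-2 * pi^2 * sigma^2 * (ky / ny)^2)
    wz <- exp(-2 * pi^2 * sigma^2 * (kz / nz)^2)
    K <- K * outer(wy, wz)
  }
  if (factor == 1L) {
    return(Re(fft(ifftshift(K), inverse = TRUE)) / (ny * nz))
  }
  NY <- factor * ny; NZ <- factor * nz
  Kp <- matrix(0i, NY, NZ)
  Kp[(NY %/% 2 + 1) + ky, (NZ %/% 2 + 1) + kz] <- K
  Re(fft(ifftshift(Kp), inverse = TRUE)) / (ny * nz)
}

# vectorised bilinear interpolation; y, z in 1-based pixel index units
bilinear <- function(img, y, z) {
  ny <- nrow(img); nz <- ncol(img)
  y <- pmin(pmax(y, 1), ny)
  z <- pmin(pmax(z, 1), nz)
  y0 <- pmin(floor(y), ny - 1L); z0 <- pmin(floor(z), nz - 1L)
  dy <- y - y0; dz <- z - z0
  img[cbind(y0, z0)] * (1 - dy) * (1 - dz) +
    img[cbind(y0 + 1L, z0)] * dy * (1 - dz) +
    img[cbind(y0, z0 + 1L)] * (1 - dy) * dz +
    img[cbind(y0 + 1L, z0 + 1L)] * dy * dz
}
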