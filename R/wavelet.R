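# Orthogonal Daubechies-4 (8-tap) discrete wavelet transform with periodic
# boundary handling. The multi-level analysis operator along one axis is
# materialised as an orthogonal matrix (small axis lengths make this cheap)
# and cached, so the synthesis operator is exactly the transpose and the
# l1 proximal step is exact.

# orthonormal scaling filter, sum = sqrt(2)
.db4_h <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)

.wavelet_cache <- new.env(parent = emptyenv())

# number of decomposition levels actually usable for an axis of length n
dwt_levels <- function(n, max_levels = 3L) {
  k <- 0L
  while (k < max_levels && n %% 2L == 0L && n / 2L >= 4L) {
    n <- n / 2L
    k <- k + 1L
  }
  k
}

# one analysis step as an L x L orthogonal matrix (rows: approx then detail)
wavelet_step_matrix <- function(L) {
  h <- .db4_h
  g <- rev(h) * (-1)^(0:7)              # quadrature mirror filter
  M <- matrix(0, L, L)
  half <- L %/% 2L
  for (k in seq_len(half)) {
    for (j in seq_along(h)) {
      col <- (2L * (k - 1L) + (j - 1L)) %% L + 1L
      M[k, col] <- M[k, col] + h[j]
      M[half + k, col] <- M[half + k, col] + g[j]
    }
  }
  M
}

# full multi-level analysis matrix for an axis of length n (cached)
wavelet_matrix <- function(n, levels) {
  levels <- dwt_levels(n, levels)
  key <- paste0(n, "_", levels)
  if (!is.null(.wavelet_cache[[key]])) return(.wavelet_cache[[key]])
  W <- diag(n)
  cur <- n
  for (l in seq_len(levels)) {
    Tm <- wavelet_step_matrix(cur)
    B <- diag(n)
    B[seq_len(cur), seq_len(cur)] <- Tm
    W <- B %*% W
    cur <- cur %/% 2L
  }
  .wavelet_cache[[key]] <- W
  W
}

# multiply an n x n matrix along dimension d of an array
mat_along <- function(x, M, d) {
  dm <- dim(x)
  perm <- c(d, setdiff(seq_along(dm), d))
  y <- aperm(x, perm)
  dim(y) <- c(dm[d], prod(dm[-d]))
  y <- M %*% y
  dim(y) <- dm[perm]
  aperm(y, order(perm))
}

#' Separable orthogonal wavelet transform of an array
#'
#' Applies a periodised orthogonal Daubechies-4 (8-tap) multi-level wavelet
#' decomposition independently along every dimension of the input. Axes whose
#' length does not allow a halving step (odd length, or shorter than 8 after
#' splitting) receive fewer levels, down to none (identity). The transform is
#' orthogonal, so [wavelet_reconstruct()] (its transpose) inverts it exactly
#' and energy is preserved.
#'
#' @param x real or complex vector, matrix, or array.
#' @param levels maximum number of decomposition levels per axis (default 3).
#' @return Array of wavelet coefficients, same shape as `x`.
#' @export
wavelet_transform <- function(x, levels = 3L) {
  dm <- dim(x) %||% length(x)
  if (is.null(dim(x))) dim(x) <- dm
  for (d in seq_along(dm)) {
    if (dm[d] > 1L) x <- mat_along(x, wavelet_matrix(dm[d], levels), d)
  }
  x
}

#' @rdname wavelet_transform
#' @param w coefficient array produced by [wavelet_transform()].
#' @export
wavelet_reconstruct <- function(w, levels = 3L) {
  dm <- dim(w) %||% length(w)
  if (is.null(dim(w))) dim(w) <- dm
  for (d in seq_along(dm)) {
    if (dm[d] > 1L) w <- mat_along(w, t(wavelet_matrix(dm[d], levels)), d)
  }
  w
}

#' Complex soft-thresholding
#'
#' Proximal operator of `t * |z|`: shrinks the magnitude of every element by
#' `t`, clipping at zero, and preserves the phase. Real input stays real.
#'
#' @param z numeric or complex array.
#' @param t threshold, a single non-negative number.
#' @return Array of the same shape and mode as `z`.
#' @export
soft_threshold <- function(z, t) {
  if (length(t) != 1L || is.na(t) || t < 0) {
    stop("threshold `t` must be a single non-negative number")
  }
  if (t == 0) return(z)
  m <- Mod(z)
  scale <- ifelse(m > t, (m - t) / m, 0)
  z * scale
}
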