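#' Wavelet specification for the row-wise decomposition
#'
#' Bundles the Daubechies filter order, the decomposition depth `J`, and the
#' boundary rule used by [modwt_forward()] and [modwt_mra()].
#'
#' @param order Daubechies order (number of vanishing moments), 1 to 10.
#'   `order = 1` is the Haar wavelet; the default `order = 4` ("db4") is the
#'   common default for terrain profiles.
#' @param J Decomposition depth (number of detail levels), at least 1. A
#'   signal must contain at least `2^J` samples to be decomposed.
#' @param boundary Either `"periodic"` (circular extension, the standard
#'   MODWT definition and the default) or `"reflection"` (the signal is
#'   mirrored to length 2N before a periodic transform and the first N values
#'   of every output are kept).
#' @return An object of class `wavelet_spec`.
#' @export
#' @examples
#' wavelet_spec(order = 1, J = 1)
wavelet_spec <- function(order = 4L, J = 4L, boundary = c("periodic", "reflection")) {
  boundary <- match.arg(boundary)
  order <- as.integer(order)
  J <- as.integer(J)
  if (is.na(order) || order < 1L || order > 10L)
    stop("Daubechies order must be an integer in 1..10, got ", order)
  if (is.na(J) || J < 1L)
    stop("decomposition depth J must be a positive integer")
  structure(list(family = "daubechies", order = order, J = J, boundary = boundary),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> db%d, J = %d, %s boundary\n",
              x$order, x$J, x$boundary))
  invisible(x)
}

# Daubechies DWT scaling filter by spectral factorization of the Daubechies
# polynomial P(y) = sum_k C(p-1+k, k) y^k; minimum-phase root selection
# (|z| < 1), oriented so the large taps lead (the textbook tabulation).
.daub_scaling_dwt <- function(p) {
  if (p == 1L) return(c(1, 1) / sqrt(2))
  ck <- choose(p - 1 + 0:(p - 1), 0:(p - 1))
  yroots <- polyroot(ck)
  coef <- 1 + 0i
  for (i in seq_len(p)) coef <- .polymul(coef, c(1, 1 + 0i))        # (1+z)^p
  for (y in yroots) {
    b <- 2 - 4 * y
    disc <- sqrt(b^2 - 4 + 0i)
    z1 <- (b + disc) / 2
    z2 <- (b - disc) / 2
    z0 <- if (Mod(z1) < 1) z1 else z2
    coef <- .polymul(coef, c(-z0, 1) / (1 - z0))
  }
  g <- Re(coef)
  g <- g * sqrt(2) / sum(g)
  rev(g)
}

# polynomial product, coefficients in increasing powers
.polymul <- function(a, b) {
  out <- vector(mode = typeof(c(a[0], b[0])), length = length(a) + length(b) - 1L)
  out[] <- 0
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' MODWT Daubechies filter pair
#'
#' Returns the Daubechies scaling (low-pass) and wavelet (high-pass) filters
#' in the MODWT convention, i.e. the orthonormal DWT filters rescaled by
#' `1/sqrt(2)`, so that the scaling filter sums to 1 and the wavelet filter
#' sums to 0. The wavelet filter is the quadrature mirror of the scaling
#' filter: `h[l] = (-1)^l g[L-1-l]`.
#'
#' @param order Daubechies order, 1 to 10 (`order = 1` gives the Haar pair
#'   `(0.5, 0.5)` / `(0.5, -0.5)`).
#' @return A list with numeric vectors `scaling` and `wavelet`, each of
#'   length `2 * order`.
#' @export
#' @examples
#' daubechies_filters(1)
daubechies_filters <- function(order) {
  order <- as.integer(order)
  if (is.na(order) || order < 1L || order > 10L)
    stop("Daubechies order must be an integer in 1..10")
  g <- .daub_scaling_dwt(order) / sqrt(2)
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * g[L:1]
  list(scaling = g, wavelet = h)
}

# y[t] = sum_l f[l] x[(t - step*(l-1)) mod n]   (circular filtering)
.circ_filter <- function(x, f, step) {
  n <- length(x)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    y <- y + f[l] * x[((t0 - step * (l - 1L)) %% n) + 1L]
  }
  y
}

# adjoint: y[t] = sum_l f[l] x[(t + step*(l-1)) mod n]
.circ_filter_adj <- function(x, f, step) {
  n <- length(x)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    y <- y + f[l] * x[((t0 + step * (l - 1L)) %% n) + 1L]
  }
  y
}

.check_signal <- function(signal, spec) {
  if (!is.numeric(signal) || length(signal) < 2L)
    stop("signal must be a numeric vector of length >= 2")
  if (any(!is.finite(signal)))
    stop("signal contains non-finite entries")
  if (length(signal) < 2^spec$J)
    stop(sprintf("level too deep: J = %d needs at least %d samples, signal has %d",
                 spec$J, 2^spec$J, length(signal)))
}

#' Forward maximal overlap discrete wavelet transform
#'
#' Pyramid MODWT of a 1-D signal: at level `j` the signal is circularly
#' filtered with the level-`j` filters (the base filters upsampled by
#' inserting `2^(j-1) - 1` zeros between taps). All coefficient series have
#' the length of the input; the transform is defined for any signal length
#' `N >= 2^J`.
#'
#' @param signal Numeric vector, all entries finite.
#' @param spec A [wavelet_spec()].
#' @return A list with `W`, a list of `J` wavelet-coefficient vectors
#'   (finest first), and `V`, the level-`J` scaling-coefficient vector.
#' @export
#' @examples
#' modwt_forward(c(1, 2, 3, 4), wavelet_spec(order = 1, J = 1))
modwt_forward <- function(signal, spec = wavelet_spec()) {
  .check_signal(signal, spec)
  if (spec$boundary == "reflection") {
    ext <- modwt_forward(c(signal, rev(signal)),
                         wavelet_spec(spec$order, spec$J, "periodic"))
    n <- length(signal)
    return(list(W = lapply(ext$W, function(w) w[seq_len(n)]),
                V = ext$V[seq_len(n)]))
  }
  f <- daubechies_filters(spec$order)
  V <- signal
  W <- vector("list", spec$J)
  for (j in seq_len(spec$J)) {
    step <- 2L^(j - 1L)
    W[[j]] <- .circ_filter(V, f$wavelet, step)
    V <- .circ_filter(V, f$scaling, step)
  }
  list(W = W, V = V)
}

#' Multiresolution analysis (additive decomposition) via the MODWT
#'
#' Computes the additive detail series `D1..DJ` and the smooth `SJ` such that
#' `signal = SJ + D1 + ... + DJ` exactly (to floating-point precision). Each
#' component is obtained by running the inverse MODWT on one coefficient band
#' in isolation. The MRA inherits the MODWT's shift invariance: the MRA of a
#' circularly shifted signal is the shifted MRA.
#'
#' @inheritParams modwt_forward
#' @return An object of class `wavelet_mra`: a list with `details` (list of
#'   `J` numeric vectors, finest scale first), `smooth` (numeric vector) and
#'   `spec`.
#' @export
#' @examples
#' m <- modwt_mra(c(1, 2, 3, 4), wavelet_spec(order = 1, J = 1))
#' m$smooth + m$details[[1]]  # reproduces the input
modwt_mra <- function(signal, spec = wavelet_spec()) {
  .check_signal(signal, spec)
  if (spec$boundary == "reflection") {
    ext <- modwt_mra(c(signal, rev(signal)),
                     wavelet_spec(spec$order, spec$J, "periodic"))
    n <- length(signal)
    out <- list(details = lapply(ext$details, function(d) d[seq_len(n)]),
                smooth = ext$smooth[seq_len(n)], spec = spec)
    return(structure(out, class = "wavelet_mra"))
  }
  f <- daubechies_filters(spec$order)
  fwd <- modwt_forward(signal, spec)
  details <- vector("list", spec$J)
  for (j in seq_len(spec$J)) {
    d <- .circ_filter_adj(fwd$W[[j]], f$wavelet, 2L^(j - 1L))
    for (k in rev(seq_len(j - 1L))) {
      d <- .circ_filter_adj(d, f$scaling, 2L^(k - 1L))
    }
    details[[j]] <- d
  }
  s <- fwd$V
  for (k in rev(seq_len(spec$J))) {
    s <- .circ_filter_adj(s, f$scaling, 2L^(k - 1L))
  }
  structure(list(details = details, smooth = s, spec = spec),
            class = "wavelet_mra")
}

#' @export
print.wavelet_mra <- function(x, ...) {
  cat(sprintf("<wavelet_mra> db%d, J = %d, n = %d\n",
              x$spec$order, x$spec$J, length(x$smooth)))
  invisible(x)
}
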