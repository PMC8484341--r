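#' Wavelet filter coefficients
#'
#' Unit-norm scaling (`g`) and wavelet (`h`) filters of the supported mother
#' wavelets. The MODWT uses these rescaled by `1/sqrt(2)` at every level.
#'
#' @param name "haar" or "d4" (Daubechies extremal-phase, 4 taps).
#' @return List with `g`, `h` and the filter length `L`.
#' @export
wavelet_filters <- function(name = c("haar", "d4")) {
  name <- match.arg(name)
  g <- switch(name,
    haar = c(1, 1) / sqrt(2),
    d4 = c(0.4829629131445341, 0.8365163037378079,
           0.2241438680420134, -0.1294095225512604))
  L <- length(g)
  # quadrature mirror: h_l = (-1)^l g_{L-1-l}
  h <- rev(g) * (-1)^(seq_len(L) - 1)
  list(g = g, h = h, L = L)
}

# circularly shift the rows of a matrix down by s (s may be negative)
.row_shift <- function(m, s) {
  n <- nrow(m)
  m[((seq_len(n) - 1 - s) %% n) + 1, , drop = FALSE]
}

# MODWT pyramid on an N x m matrix of signals (one signal per column).
# Returns W: list over levels of N x m matrices, V: N x m smooth at level J.
.modwt_mat <- function(x, filt, J) {
  n <- nrow(x)
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  W <- vector("list", J)
  V <- x
  for (j in seq_len(J)) {
    step <- 2^(j - 1)
    Wj <- matrix(0, n, ncol(x))
    Vj <- matrix(0, n, ncol(x))
    for (l in seq_along(ht)) {
      shifted <- .row_shift(V, (l - 1) * step)
      Wj <- Wj + ht[l] * shifted
      Vj <- Vj + gt[l] * shifted
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V)
}

# inverse MODWT pyramid (circular); W may contain NULL entries meaning zero
.imodwt_mat <- function(W, V, filt, J, n, m) {
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  for (j in rev(seq_len(J))) {
    step <- 2^(j - 1)
    Vprev <- matrix(0, n, m)
    for (l in seq_along(ht)) {
      if (!is.null(W[[j]]))
        Vprev <- Vprev + ht[l] * .row_shift(W[[j]], -(l - 1) * step)
      Vprev <- Vprev + gt[l] * .row_shift(V, -(l - 1) * step)
    }
    V <- Vprev
  }
  V
}

.reflect <- function(x) rbind(x, x[rev(seq_len(nrow(x))), , drop = FALSE])

#' Maximum overlap discrete wavelet transform
#'
#' Undecimated (shift-equivariant) wavelet transform with level-j filters
#' rescaled by `2^(-j/2)`: every level carries exactly `length(signal)`
#' coefficients. Under the circular boundary the transform conserves energy
#' (`sum_j ||W_j||^2 + ||V_J||^2 = ||x||^2`) and the multiresolution
#' components sum back to the signal exactly.
#'
#' @param signal numeric vector (a pulse), finite values.
#' @param config a [wavelet_config()].
#' @return Object of class `modwt_decomposition`: list with `W` (list of
#'   detail coefficient vectors, levels 1..J), `V` (level-J smooth
#'   coefficients), `config` and `n`.
#' @export
modwt <- function(signal, config = wavelet_config()) {
  if (!all(is.finite(signal)))
    stop("signal must be finite")
  n <- length(signal)
  J <- config$max_level
  if (2^J > n)
    stop(sprintf("2^max_level = %d exceeds signal length %d", 2^J, n))
  filt <- wavelet_filters(config$mother_wavelet)
  x <- matrix(signal, ncol = 1)
  if (config$boundary == "reflection") x <- .reflect(x)
  dec <- .modwt_mat(x, filt, J)
  W <- lapply(dec$W, function(m) m[seq_len(n), 1])
  V <- dec$V[seq_len(n), 1]
  structure(list(W = W, V = V, config = config, n = n),
            class = "modwt_decomposition")
}

#' @export
print.modwt_decomposition <- function(x, ...) {
  cat(sprintf("<modwt_decomposition> %s wavelet, %d levels, n = %d (%s boundary)\n",
              x$config$mother_wavelet, x$config$max_level, x$n,
              x$config$boundary))
  invisible(x)
}

#' Inverse MODWT
#'
#' @param decomposition a `modwt_decomposition` from [modwt()].
#' @return The reconstructed signal.
#' @export
imodwt <- function(decomposition) {
  d <- decomposition
  filt <- wavelet_filters(d$config$mother_wavelet)
  n_work <- if (d$config$boundary == "reflection") 2 * d$n else d$n
  # reflection boundary: coefficients beyond n were discarded; re-derive
  # them by transforming the reflected input is not possible here, so the
  # inverse is exact only for circular decompositions
  if (d$config$boundary == "reflection")
    stop("imodwt supports the circular boundary; use modwt_mra for reflection")
  W <- lapply(d$W, function(w) matrix(w, ncol = 1))
  V <- matrix(d$V, ncol = 1)
  .imodwt_mat(W, V, filt, d$config$max_level, n_work, 1)[seq_len(d$n), 1]
}

# full MRA on a matrix of signals (columns = events): for each level return
# the detail component D_j (N x m), plus the smooth S_J
.modwt_mra_mat <- function(x, filt, J, boundary) {
  n <- nrow(x); m <- ncol(x)
  xw <- if (boundary == "reflection") .reflect(x) else x
  nw <- nrow(xw)
  dec <- .modwt_mat(xw, filt, J)
  zeroW <- vector("list", J)
  details <- vector("list", J)
  for (j in seq_len(J)) {
    Wonly <- zeroW
    Wonly[[j]] <- dec$W[[j]]
    details[[j]] <- .imodwt_mat(Wonly, matrix(0, nw, m), filt, J, nw, m)[seq_len(n), , drop = FALSE]
  }
  smooth <- .imodwt_mat(zeroW, dec$V, filt, J, nw, m)[seq_len(n), , drop = FALSE]
  list(details = details, smooth = smooth)
}

#' Multiresolution analysis of a signal
#'
#' Splits a signal additively into per-level detail components plus the
#' level-J smooth: `signal = sum_j details[[j]] + smooth` (exact under the
#' circular boundary).
#'
#' @param signal numeric vector.
#' @param config a [wavelet_config()].
#' @return List with `details` (list of length-J vectors) and `smooth`.
#' @export
modwt_mra <- function(signal, config = wavelet_config()) {
  if (!all(is.finite(signal))) stop("signal must be finite")
  n <- length(signal)
  if (2^config$max_level > n)
    stop(sprintf("2^max_level = %d exceeds signal length %d",
                 2^config$max_level, n))
  filt <- wavelet_filters(config$mother_wavelet)
  r <- .modwt_mra_mat(matrix(signal, ncol = 1), filt, config$max_level,
                      config$boundary)
  list(details = lapply(r$details, function(m) m[, 1]),
       smooth = r$smooth[, 1])
}
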