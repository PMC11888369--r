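#' Kronecker power of a matrix
#'
#' `kron_power(A, d)` is the d-fold Kronecker product of `A` with itself,
#' the building block that lifts polynomial readout dynamics into the
#' neuron space of a multiplicative SCN.
#'
#' @param A numeric matrix (or vector, treated as a column).
#' @param d integer power, `d >= 1`.
#' @return the `d`-fold Kronecker product.
#' @export
kron_power <- function(A, d) {
  if (d < 1 || d != round(d)) stop("d must be an integer >= 1")
  Reduce(kronecker, rep(list(A), d))
}

#' Stacked vector of Kronecker powers
#'
#' Concatenates `r, r^{(x)2}, ..., r^{(x)g}`: the set of multiplicative
#' interaction terms available to the slow connectivity.
#'
#' @param r numeric vector.
#' @param g maximum power, `g >= 1`.
#' @return vector of length `sum(length(r)^d, d = 1..g)`.
#' @export
g_vector <- function(r, g) {
  if (g < 1 || g != round(g)) stop("g must be an integer >= 1")
  unlist(lapply(seq_len(g), function(d) kron_power(r, d)))
}

#' Multivariate polynomial energy
#'
#' Represents `U(z) = sum_k coeff_k * prod_m z_m^{e_km}` for an
#' M-dimensional variable; the un-normalized density the network samples
#' from is `P(z) = exp(-U(z))`.
#'
#' @param exponents integer matrix, one row per term, `M` columns of
#'   non-negative exponents.  A vector is taken as a single-column matrix
#'   (M = 1) when `M` is not given.
#' @param coeffs numeric coefficients, one per term.
#' @param M variable dimension (inferred from `exponents` by default).
#' @return an object of class `energy_poly`.
#' @examples
#' # the bimodal test energy U(z) = z^4 - 2 z^2, modes at +/-1
#' U <- energy_poly(c(4, 2), c(1, -2))
#' @export
energy_poly <- function(exponents, coeffs, M = NULL) {
  if (is.null(dim(exponents))) exponents <- matrix(exponents, ncol = M %||% 1)
  exponents <- as.matrix(exponents)
  dimnames(exponents) <- NULL
  storage.mode(exponents) <- "integer"
  if (any(exponents < 0)) stop("exponents must be non-negative")
  if (nrow(exponents) != length(coeffs))
    stop("one coefficient per exponent row required")
  structure(list(M = ncol(exponents), exponents = exponents,
                 coeffs = as.numeric(coeffs),
                 degree = max(rowSums(exponents))),
            class = "energy_poly")
}

#' @export
print.energy_poly <- function(x, ...) {
  terms <- vapply(seq_along(x$coeffs), function(k) {
    e <- x$exponents[k, ]
    mono <- paste0("z", seq_len(x$M), "^", e)[e > 0]
    paste0(format(x$coeffs[k]), if (length(mono)) " " else "",
           paste(mono, collapse = " "))
  }, character(1))
  cat("U(z) =", paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' Gaussian energy
#' @param mean,sd target mean and standard deviation (M = 1).
#' @return `energy_poly` for `U(z) = (z - mean)^2 / (2 sd^2)`.
#' @export
gaussian_energy <- function(mean = 0, sd = 1) {
  # (z - m)^2/(2 s^2) = z^2/(2 s^2) - m z/s^2 + m^2/(2 s^2)
  energy_poly(matrix(c(2L, 1L, 0L), ncol = 1),
              c(1 / (2 * sd^2), -mean / sd^2, mean^2 / (2 * sd^2)))
}

#' Bimodal double-well energy `U(z) = z^4 - 2 z^2`
#' @return `energy_poly` with modes at +/- 1.
#' @export
bimodal_energy <- function() energy_poly(c(4L, 2L), c(1, -2))

#' Two-dimensional soft-ring energy
#'
#' `U(x, y) = s (s - 2 rho^2)` with `s = x^2 + y^2`: a quartic annulus
#' prior whose density concentrates on a ring.
#'
#' @param rho ring radius parameter.
#' @return `energy_poly` in two variables.
#' @export
ring_energy <- function(rho = 1) {
  # s^2 - 2 rho^2 s = x^4 + 2 x^2 y^2 + y^4 - 2 rho^2 x^2 - 2 rho^2 y^2
  energy_poly(rbind(c(4L, 0L), c(2L, 2L), c(0L, 4L), c(2L, 0L), c(0L, 2L)),
              c(1, 2, 1, -2 * rho^2, -2 * rho^2))
}

#' Evaluate a polynomial energy
#'
#' @param U an `energy_poly`.
#' @param z point (length M) or matrix of points (n x M).
#' @return energy value(s).
#' @export
eval_energy <- function(U, z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = U$M)
  if (ncol(z) != U$M) stop("z must have ", U$M, " columns")
  out <- numeric(nrow(z))
  for (k in seq_along(U$coeffs)) {
    e <- U$exponents[k, ]
    term <- rep(U$coeffs[k], nrow(z))
    for (m in which(e > 0)) term <- term * z[, m]^e[m]
    out <- out + term
  }
  out
}

# map a monomial exponent vector (sum = d) to its canonical column in the
# row-major Kronecker power z^{(x)d}: indices sorted ascending
kron_index <- function(e, M) {
  d <- sum(e)
  if (d == 0) return(1L)
  idx <- rep(seq_len(M), e) # ascending variable indices, one per factor
  col <- 0L
  for (k in seq_len(d)) col <- col * M + (idx[k] - 1L)
  col + 1L
}

#' Per-degree polynomial drift coefficients
#'
#' Container for a polynomial vector field `F(z) = sum_d A_d z^{(x)d}`,
#' with `A_d` an `M x M^d` matrix.
#'
#' @param coeffs list of matrices `A_0 .. A_g` (`A_0` is `M x 1`).
#' @param M variable dimension.
#' @return object of class `poly_drift`.
#' @export
poly_drift <- function(coeffs, M) {
  for (d in seq_along(coeffs) - 1L) {
    A <- as.matrix(coeffs[[d + 1L]])
    if (nrow(A) != M || ncol(A) != M^d)
      stop(sprintf("A_%d must be %d x %d", d, M, M^d))
    coeffs[[d + 1L]] <- A
  }
  structure(list(M = M, degree = length(coeffs) - 1L, coeffs = coeffs),
            class = "poly_drift")
}

#' Gradient of a polynomial energy as per-degree coefficients
#'
#' Differentiates `U` term-wise and assembles the gradient into the
#' Kronecker form `grad U(z) = sum_d A_d z^{(x)d}`, the shape consumed by
#' the multiplicative-synapse construction and by the samplers.
#'
#' @param U an `energy_poly` of degree >= 1.
#' @return a `poly_drift` with degree `degree(U) - 1`.
#' @export
grad_energy <- function(U) {
  if (U$degree < 1) stop("constant energy has a degenerate gradient")
  M <- U$M
  g <- U$degree - 1L
  coeffs <- lapply(0:g, function(d) matrix(0, M, M^d))
  for (k in seq_along(U$coeffs)) {
    e <- U$exponents[k, ]
    for (m in which(e > 0)) {
      enew <- e
      enew[m] <- enew[m] - 1L
      d <- sum(enew)
      col <- kron_index(enew, M)
      coeffs[[d + 1L]][m, col] <- coeffs[[d + 1L]][m, col] +
        U$coeffs[k] * e[m]
    }
  }
  poly_drift(coeffs, M)
}

#' Evaluate a polynomial drift
#'
#' @param drift a `poly_drift`.
#' @param z point of length M.
#' @return `sum_d A_d z^{(x)d}`, length M.
#' @export
eval_drift <- function(drift, z) {
  if (length(z) != drift$M) stop("z must have length ", drift$M)
  out <- numeric(drift$M)
  for (d in seq_along(drift$coeffs) - 1L) {
    zd <- if (d == 0) 1 else kron_power(z, d)
    out <- out + drop(drift$coeffs[[d + 1L]] %*% zd)
  }
  out
}

#' Slow multiplicative connectivity
#'
#' Materializes the per-degree slow weights that implement the neuron-space
#' drift `D^T(-(1/tau_s) grad U(D r) + lambda D r)`: the degree-d matrix is
#' `-(1/tau_s) D^T A_d D^{(x)d}`, with the leak compensation
#' `+lambda D^T D` folded into the linear term.  At simulation time the
#' drift is computed unfactored in readout space; these matrices are for
#' inspection and testing.
#'
#' @param D decoding matrix (M x N).
#' @param drift `poly_drift` for `grad U` (dimension M).
#' @param lambda leak.
#' @param tau_s sampling timescale.
#' @return list of matrices `omega_s_0 .. omega_s_g`; degree-d entry has
#'   shape `N x N^d`.
#' @export
build_slow_weights <- function(D, drift, lambda, tau_s) {
  D <- validate_readout(D)
  if (nrow(D) != drift$M)
    stop("drift dimension must equal the readout dimension of D")
  lapply(seq_along(drift$coeffs) - 1L, function(d) {
    A <- drift$coeffs[[d + 1L]]
    W <- -crossprod(D, A) / tau_s
    if (d == 0) return(W)
    Dd <- kron_power(D, d)
    W <- W %*% Dd
    if (d == 1) W <- W + lambda * crossprod(D)
    W
  })
}

#' Check that `exp(-U)` is normalizable
#'
#' For M = 1 the check is exact: the maximum total degree must be even
#' with a positive leading coefficient.  For M > 1 the tail decay is
#' checked numerically: `exp(-U)` is integrated on expanding grids and
#' the energy is probed on expanding shells of random directions; both
#' must indicate a decaying tail.
#'
#' @param U an `energy_poly`.
#' @return `TRUE` or `FALSE` (never raises).
#' @export
check_normalizable <- function(U) {
  deg <- rowSums(U$exponents)
  gmax <- max(deg)
  if (gmax == 0) return(FALSE)
  if (U$M == 1) {
    lead <- sum(U$coeffs[deg == gmax])
    return(gmax %% 2 == 0 && lead > 0)
  }
  if (U$M > 3) return(FALSE) # numerical check unsupported beyond 3-D
  # shell probe: U must grow along every probed direction (deterministic set)
  nd <- 64L
  if (U$M == 2) {
    ang <- 2 * pi * (seq_len(nd) - 1) / nd
    dirs <- cbind(cos(ang), sin(ang))
  } else {
    # Fibonacci sphere
    k <- seq_len(nd) - 0.5
    phi <- acos(1 - 2 * k / nd)
    th <- pi * (1 + sqrt(5)) * k
    dirs <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  }
  radii <- c(5, 10, 20)
  shell <- sapply(radii, function(R) min(eval_energy(U, dirs * R)))
  if (!(all(is.finite(shell)) && all(diff(shell) > 0) && shell[3] > 50))
    return(FALSE)
  # expanding-grid integral must stabilize
  ints <- sapply(c(6, 10), function(L) {
    n <- 61
    gr <- seq(-L, L, length.out = n)
    pts <- as.matrix(expand.grid(rep(list(gr), U$M)))
    w <- Reduce(kronecker, rep(list(trapz_weights(n, gr[2] - gr[1])), U$M))
    sum(w * exp(-pmin(eval_energy(U, pts), 700)))
  })
  is.finite(ints[2]) && abs(ints[2] - ints[1]) <= 1e-3 * abs(ints[1])
}

#' Serialize / deserialize a polynomial energy as JSON
#'
#' The on-disk format is a list of `{exponents: [...], coeff: x}` records.
#'
#' @param U an `energy_poly`.
#' @param path file path.
#' @return `read_energy` returns an `energy_poly`; `write_energy` its
#'   path, invisibly.
#' @export
write_energy <- function(U, path) {
  recs <- lapply(seq_along(U$coeffs), function(k)
    list(exponents = as.integer(U$exponents[k, ]), coeff = U$coeffs[k]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_energy
#' @export
read_energy <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  expo <- do.call(rbind, lapply(recs, function(r) as.integer(unlist(r$exponents))))
  energy_poly(expo, vapply(recs, function(r) as.numeric(r$coeff), numeric(1)))
}
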