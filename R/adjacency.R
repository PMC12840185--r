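#' Electrode adjacency from 3-D sensor positions
#'
#' Builds the spatial graph used by the graph-convolution path: a k-nearest
#' neighbour graph on Euclidean distances between electrode positions,
#' symmetrized by union, with self-loops added and symmetric degree
#' normalization applied (`D^{-1/2} (A + I) D^{-1/2}`). The result is
#' symmetric, nonnegative and deterministic given the coordinates.
#'
#' @param coords numeric matrix `[C, 3]` of electrode positions.
#' @param k neighbour count, `1 <= k < C`.
#' @return An object of class `dstage_adjacency`: the normalized `C x C`
#'   matrix with attributes `normalization = "sym_degree"` and `k`.
#' @examples
#' coords <- cbind(cos(seq(0, pi, length.out = 8)),
#'                 sin(seq(0, pi, length.out = 8)), 0)
#' A <- build_adjacency(coords, k = 2)
#' all.equal(A, t(A))
#' @export
build_adjacency <- function(coords, k) {
  coords <- as.matrix(coords)
  C <- nrow(coords)
  if (C < 2L) stop("need at least 2 electrodes")
  if (!all(is.finite(coords))) stop("electrode coordinates must be finite")
  if (k < 1L || k >= C) stop("k must satisfy 1 <= k < C (got k=", k, ", C=", C, ")")
  d <- as.matrix(stats::dist(coords))
  dup <- which(d < 1e-12 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0L)
    stop("duplicate coordinates for distinct electrodes ", dup[1, 1], " and ",
         dup[1, 2])
  A <- matrix(0, C, C)
  for (i in seq_len(C)) {
    nb <- order(d[i, ])[-1L][seq_len(k)]  # drop self, take k nearest
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))                      # union symmetrization
  A <- A + diag(C)                        # self-loops
  dg <- rowSums(A)
  A <- A * tcrossprod(1 / sqrt(dg))       # D^{-1/2} A D^{-1/2}
  structure(A, normalization = "sym_degree", k = as.integer(k),
            class = c("dstage_adjacency", "matrix", "array"))
}

check_adjacency <- function(A, C) {
  if (!is.matrix(A) || nrow(A) != C || ncol(A) != C)
    stop("adjacency must be ", C, " x ", C)
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (any(A < -1e-12)) stop("adjacency must be nonnegative")
  invisible(A)
}

#' Deterministic spherical-cap electrode layout
#'
#' Places `C` sensors quasi-uniformly on the upper unit hemisphere (Fibonacci
#' lattice), a stand-in montage for simulations when no measured positions are
#' available.
#'
#' @param C number of electrodes.
#' @return `C x 3` coordinate matrix.
#' @export
electrode_coords <- function(C) {
  i <- seq_len(C) - 0.5
  z <- i / C                       # upper hemisphere only
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
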