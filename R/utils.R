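#' @keywords internal
#' @useDynLib neuroattrib, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
"_PACKAGE"

## FWHM (voxels) -> Gaussian sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically maps a master seed and a character tag to a 31-bit
#' integer seed, so that pipeline stages (and ensemble runs) can be re-run
#' in isolation with independent but reproducible random streams.
#'
#' @param master integer master seed.
#' @param tag character tag naming the consumer (e.g. "train", "attrib").
#' @return A single integer in [0, 2^31).
#' @export
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(master)) * 48271 + h * 16807) %% 2147483647)
}

## 1D smoothing matrix: rows normalised truncated-Gaussian weights
smoothing_matrix_1d <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  w <- exp(-d^2 / (2 * sigma^2))
  w / rowSums(w)
}

#' Smooth a 3D volume with a separable Gaussian kernel
#'
#' Smoothing is applied axis-by-axis with a truncated, row-renormalised
#' Gaussian, so edge voxels are not darkened by the volume boundary.
#'
#' @param vol 3D numeric array.
#' @param fwhm full width at half maximum of the kernel, in voxels; 0 is the
#'   identity.
#' @return Smoothed array of the same dimension.
#' @export
gaussian_smooth <- function(vol, fwhm) {
  if (fwhm <= 0) return(vol)
  dm <- dim(vol)
  stop_if_not(length(dm) == 3L, "gaussian_smooth expects a 3D array")
  sg <- fwhm_to_sigma(fwhm)
  s1 <- smoothing_matrix_1d(dm[1], sg)
  s2 <- smoothing_matrix_1d(dm[2], sg)
  s3 <- smoothing_matrix_1d(dm[3], sg)
  ## axis 1
  x <- s1 %*% matrix(vol, dm[1], dm[2] * dm[3])
  dim(x) <- dm
  ## axis 2
  x <- aperm(x, c(2, 1, 3))
  x <- s2 %*% matrix(x, dm[2], dm[1] * dm[3])
  dim(x) <- dm[c(2, 1, 3)]
  x <- aperm(x, c(2, 1, 3))
  ## axis 3
  x <- aperm(x, c(3, 1, 2))
  x <- s3 %*% matrix(x, dm[3], dm[1] * dm[2])
  dim(x) <- dm[c(3, 1, 2)]
  aperm(x, c(2, 3, 1))
}

## Trilinear upsampling of a coarse 3D array onto a target grid.
## Coarse cell centres are mapped onto the fine grid by aligned scaling
## (centre-to-centre), values outside the coarse hull are clamped.
upsample_trilinear <- function(vol, target_dim) {
  dm <- dim(vol)
  out <- array(0, target_dim)
  ## coordinates of fine voxel centres in coarse index space
  coords <- lapply(1:3, function(a) {
    if (dm[a] == 1L) rep(1, target_dim[a])
    else {
      x <- (seq_len(target_dim[a]) - 0.5) / target_dim[a] * dm[a] + 0.5
      pmin(pmax(x, 1), dm[a])
    }
  })
  lo <- lapply(seq_len(3), function(a) pmax(pmin(floor(coords[[a]]), dm[a] - (dm[a] > 1L)), 1))
  fr <- lapply(seq_len(3), function(a) coords[[a]] - lo[[a]])
  i1 <- lo[[1]]; i2 <- lo[[2]]; i3 <- lo[[3]]
  f1 <- fr[[1]]; f2 <- fr[[2]]; f3 <- fr[[3]]
  g1 <- rep(i1, times = target_dim[2] * target_dim[3])
  g2 <- rep(rep(i2, each = target_dim[1]), times = target_dim[3])
  g3 <- rep(i3, each = target_dim[1] * target_dim[2])
  h1 <- rep(f1, times = target_dim[2] * target_dim[3])
  h2 <- rep(rep(f2, each = target_dim[1]), times = target_dim[3])
  h3 <- rep(f3, each = target_dim[1] * target_dim[2])
  up1 <- pmin(g1 + 1L, dm[1]); up2 <- pmin(g2 + 1L, dm[2]); up3 <- pmin(g3 + 1L, dm[3])
  lin <- function(a, b, c) a + (b - 1L) * dm[1] + (c - 1L) * dm[1] * dm[2]
  v <- as.vector(vol)
  res <- v[lin(g1, g2, g3)] * (1 - h1) * (1 - h2) * (1 - h3) +
    v[lin(up1, g2, g3)] * h1 * (1 - h2) * (1 - h3) +
    v[lin(g1, up2, g3)] * (1 - h1) * h2 * (1 - h3) +
    v[lin(g1, g2, up3)] * (1 - h1) * (1 - h2) * h3 +
    v[lin(up1, up2, g3)] * h1 * h2 * (1 - h3) +
    v[lin(up1, g2, up3)] * h1 * (1 - h2) * h3 +
    v[lin(g1, up2, up3)] * (1 - h1) * h2 * h3 +
    v[lin(up1, up2, up3)] * h1 * h2 * h3
  array(res, target_dim)
}
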