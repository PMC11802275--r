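# Binary 3D morphology used by the mask generator and V-SHARP erosion.
# Dilation/erosion use FFT convolution with a spherical structuring
# element; connected components use vectorized 6-neighbour flood fill.

# Origin-centred ball indicator with wrap-around distances, ready for
# spectral convolution.  Radius in voxel units (index space).
.ball_kernel <- function(dim, radius) {
  dist_axis <- function(n) pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L))
  dx <- array(dist_axis(dim[1L]), dim = dim)
  dy <- array(rep(dist_axis(dim[2L]), each = dim[1L]), dim = dim)
  dz <- array(rep(dist_axis(dim[3L]), each = dim[1L] * dim[2L]), dim = dim)
  (dx^2 + dy^2 + dz^2) <= radius^2
}

#' Binary dilation / erosion / closing with a spherical element
#'
#' @param x logical 3D array.
#' @param radius structuring-element radius in voxels.
#' @return logical 3D array.
#' @export
binary_dilate <- function(x, radius) {
  k <- .ball_kernel(dim(x), radius)
  ifft3_real(fft3(array(as.numeric(x), dim(x))) * fft3(array(as.numeric(k), dim(k)))) > 0.5
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(x, radius) {
  !binary_dilate(!x, radius)
}

#' @rdname binary_dilate
#' @export
binary_close <- function(x, radius) {
  binary_erode(binary_dilate(x, radius), radius)
}

# One 6-neighbour dilation step (no wrap-around), vectorized with shifts.
.dilate6 <- function(x) {
  d <- dim(x)
  out <- x
  out[-1, , ] <- out[-1, , ] | x[-d[1L], , ]
  out[-d[1L], , ] <- out[-d[1L], , ] | x[-1, , ]
  out[, -1, ] <- out[, -1, ] | x[, -d[2L], ]
  out[, -d[2L], ] <- out[, -d[2L], ] | x[, -1, ]
  out[, , -1] <- out[, , -1] | x[, , -d[3L]]
  out[, , -d[3L]] <- out[, , -d[3L]] | x[, , -1]
  out
}

#' Largest 6-connected component of a binary volume
#'
#' @param x logical 3D array with at least one `TRUE` voxel.
#' @return logical array keeping only the largest component (ties broken
#'   by first-encountered seed in array order).
#' @export
largest_component <- function(x) {
  stopifnot(any(x))
  remaining <- x
  best <- NULL
  best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1L]
    region <- array(FALSE, dim = dim(x))
    region[seed] <- TRUE
    repeat {
      grown <- .dilate6(region) & remaining
      if (sum(grown) == sum(region)) break
      region <- grown
    }
    n <- sum(region)
    if (n > best_n) {
      best <- region
      best_n <- n
    }
    remaining <- remaining & !region
  }
  best
}
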