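# Delay-and-sum back-projection of per-position A-scans into a 2-D
# B-scan image, with the transducer sensitivity approximated as a conic
# section along the scan direction.

#' Delay-and-sum B-scan reconstruction
#'
#' Each image pixel accumulates, over every scan position whose
#' sensitivity cone contains it, the A-scan amplitude at the two-way-free
#' delay \eqn{\sqrt{(x - x_p)^2 + z^2} / v_s} (linear interpolation
#' between time samples; delays outside the A-scan contribute zero).  The
#' sum is normalized by the number of contributing positions.
#'
#' @param ascans List of \code{averaged_ascan}s, one per scan position.
#' @param positions Strictly increasing lateral detector positions in
#'   metres.
#' @param medium A \code{\link{medium}}.
#' @param transducer A \code{\link{transducer_model}} (provides the
#'   acceptance cone half-angle).
#' @param lateral_spacing,axial_spacing Pixel pitches in metres.  Defaults:
#'   the scan step and \code{v_s / fs}.
#' @param depth_range Two-element axial extent in metres (default: 0 to
#'   the depth covered by one period).
#' @return An object of class \code{"bscan_image"}: list with
#'   \code{pixels} (rows = depth, columns = lateral), \code{lateral},
#'   \code{depth} axis vectors and the spacings.
#' @export
backproject <- function(ascans, positions, medium = fwmot::medium(),
                        transducer = transducer_model(),
                        lateral_spacing = NULL, axial_spacing = NULL,
                        depth_range = NULL) {
  if (length(ascans) == 0L || length(ascans) != length(positions))
    stop("need one A-scan per scan position", call. = FALSE)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing", call. = FALSE)
  vs <- medium$speed_of_sound
  fs <- ascans[[1L]]$sampling_rate
  period <- ascans[[1L]]$period
  if (is.null(lateral_spacing))
    lateral_spacing <- if (length(positions) > 1L)
      positions[2L] - positions[1L] else 1e-5
  if (is.null(axial_spacing)) axial_spacing <- vs / fs
  if (is.null(depth_range)) depth_range <- c(0, vs * period)
  lat <- seq(positions[1L], positions[length(positions)],
             by = lateral_spacing)
  dep <- seq(depth_range[1L], depth_range[2L], by = axial_spacing)
  img <- matrix(0, length(dep), length(lat))
  hits <- matrix(0L, length(dep), length(lat))
  tan_a <- tan(transducer$acceptance_half_angle)
  ts <- (seq_along(ascans[[1L]]$samples) - 1) / fs
  for (p in seq_along(positions)) {
    a <- ascans[[p]]$samples
    dx <- outer(rep(1, length(dep)), lat - positions[p])
    zz <- outer(dep, rep(1, length(lat)))
    inside <- abs(dx) <= zz * tan_a
    delay <- sqrt(dx^2 + zz^2) / vs
    vals <- stats::approx(ts, a, xout = delay[inside], rule = 1)$y
    vals[is.na(vals)] <- 0
    img[inside] <- img[inside] + vals
    hits[inside] <- hits[inside] + 1L
  }
  img <- ifelse(hits > 0L, img / pmax(hits, 1L), 0)
  structure(
    list(pixels = img, lateral = lat, depth = dep,
         lateral_spacing = lateral_spacing, axial_spacing = axial_spacing,
         wavelength_id = ascans[[1L]]$wavelength_id),
    class = "bscan_image"
  )
}

#' @export
print.bscan_image <- function(x, ...) {
  cat(sprintf(
    "B-scan image: %d x %d pixels (%.4g x %.4g mm), wavelength %d\n",
    nrow(x$pixels), ncol(x$pixels),
    diff(range(x$depth)) * 1e3, diff(range(x$lateral)) * 1e3,
    x$wavelength_id))
  invisible(x)
}

#' @export
plot.bscan_image <- function(x, ...) {
  graphics::image(x$lateral * 1e3, x$depth * 1e3, t(x$pixels),
                  xlab = "lateral (mm)", ylab = "depth (mm)",
                  ylim = rev(range(x$depth * 1e3)),
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}

# analytic-signal magnitude of a real vector via the frequency-domain
# Hilbert construction
.envelope <- function(v) {
  n <- length(v)
  if (n < 2L) return(abs(v))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(v) * h, inverse = TRUE) / n)
}

#' Envelope image for display
#'
#' Replaces each image column (depth profile) by the magnitude of its
#' analytic signal — collapsing the bipolar wavelet into a single-lobed
#' envelope — and normalizes the image to [0, 1].
#'
#' @param image A \code{\link{backproject} bscan_image}.
#' @return A \code{bscan_image} with non-negative pixels in [0, 1].
#' @export
envelope_image <- function(image) {
  stopifnot(inherits(image, "bscan_image"))
  env <- apply(image$pixels, 2L, .envelope)
  mx <- max(env)
  if (mx > 0) env <- env / mx
  out <- image
  out$pixels <- env
  out
}

#' Locate the brightest pixel of a B-scan image
#'
#' @param image A \code{bscan_image}.
#' @return List with \code{lateral}, \code{depth} (metres) and the row /
#'   column indices of the maximum-amplitude pixel.
#' @export
image_peak <- function(image) {
  idx <- which(abs(image$pixels) == max(abs(image$pixels)),
               arr.ind = TRUE)[1, ]
  list(lateral = image$lateral[idx[2L]], depth = image$depth[idx[1L]],
       row = unname(idx[1L]), col = unname(idx[2L]))
}
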