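# Analytic Sholl phantom: a filled soma disc with straight 1-pixel arms at
# distinct angles.  Every ring between the soma edge and the arm tips must
# intersect exactly n_arms processes, which makes the phantom an exact
# oracle for the ring-intersection counter.

#' Generate a k-arm star phantom for Sholl analysis
#'
#' A binary 2D image: a filled disc of radius `soma_radius` at the field
#' centre with `n_arms` straight rays extending radially from the centre to
#' radius `arm_length`, at evenly spaced angles.  The truth states that a
#' Sholl ring at any radius strictly between `soma_radius` and `arm_length`
#' crosses exactly `n_arms` processes.
#'
#' @param n_arms Number of arms (>= 1).
#' @param arm_length Arm tip radius from the soma centre (um).
#' @param pixel_size Pixel size (um); pixels are square.
#' @param soma_radius Soma disc radius (um).
#' @param margin Border margin (um).
#' @return List with `image` (a one-channel binary [volume_image()], grey
#'   levels 0/255) and `truth` (class `sholl_truth`).
#' @export
generate_sholl_phantom <- function(n_arms, arm_length, pixel_size = 0.5,
                                   soma_radius = 5, margin = 3) {
  if (n_arms < 1L) stop("n_arms must be >= 1")
  if (arm_length <= soma_radius) stop("arm_length must exceed soma_radius")
  side_um <- 2 * (arm_length + margin)
  n_px <- as.integer(ceiling(side_um / pixel_size)) + 1L
  ext <- (n_px - 1L) * pixel_size
  if (arm_length > ext / 2 - pixel_size)
    stop("arms exceed the field: increase margin or field size")
  center <- c(ext / 2, ext / 2)
  img <- matrix(FALSE, n_px, n_px)

  # soma disc
  yy <- index_to_um(seq_len(n_px), pixel_size)
  d2 <- outer((yy - center[1])^2, (yy - center[2])^2, "+")
  img[d2 <= soma_radius^2] <- TRUE

  angles <- 2 * pi * (seq_len(n_arms) - 1L) / n_arms + 0.13
  c_px <- um_to_index(center, pixel_size)
  for (a in angles) {
    tip <- um_to_index(center + arm_length * c(sin(a), cos(a)), pixel_size)
    pts <- bresenham_line(c_px[1], c_px[2], tip[1], tip[2])
    keep <- pts[, 1] >= 1L & pts[, 1] <= n_px & pts[, 2] >= 1L & pts[, 2] <= n_px
    img[pts[keep, , drop = FALSE]] <- TRUE
  }

  data <- array(0, c(1L, 1L, n_px, n_px))
  data[1, 1, , ] <- img * 255
  truth <- structure(list(
    n_arms = as.integer(n_arms),
    soma_radius = soma_radius,
    arm_length = arm_length,
    center_um = center,
    angles = angles,
    pixel_size = pixel_size
  ), class = "sholl_truth")
  list(image = volume_image(data, c(1, pixel_size, pixel_size), "Iba1"),
       truth = truth)
}
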