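#' Gaussian bead model of an electron density
#'
#' The electron density is represented as a sum of \code{m} isotropic Gaussian
#' beads with common height \code{h} (electrons) and common width parameter
#' \code{w} (1/Angstrom, a *precision*: the bead profile is
#' \code{h (w/sqrt(2 pi))^3 exp(-w^2 |r - y_i|^2 / 2)}, so larger \code{w}
#' means narrower beads and each bead integrates to exactly \code{h}).
#'
#' @param positions numeric matrix \code{m x 3} of bead centers (Angstrom).
#' @param height common bead height \code{h} in electrons. The default, 7, is
#'   roughly the mean electron count per protein heavy atom including its
#'   bonded hydrogens.
#' @param width common precision \code{w} in 1/Angstrom. The default gives a
#'   bead FWHM of 2 Angstrom (\code{w = 2 sqrt(2 log 2) / 2}).
#' @return object of class \code{bead_model}.
#' @seealso [evaluate_density()], [structure_factor()], [intensity()],
#'   [smooth_model()]
#' @export
bead_model <- function(positions, height = 7.0, width = fwhm_to_width(2.0)) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3L)
    stop("positions must be an m x 3 matrix")
  storage.mode(positions) <- "double"
  if (nrow(positions) < 1L) stop("need at least one bead")
  if (!all(is.finite(positions))) stop("bead positions must be finite")
  if (!is.finite(height) || height < 0)
    stop("invalid model: height must be a finite nonnegative scalar")
  if (!is.finite(width) || width <= 0)
    stop("invalid model: width must be a finite positive scalar")
  dimnames(positions) <- NULL
  structure(list(positions = positions, height = as.numeric(height),
                 width = as.numeric(width)),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> m = %d beads, h = %g e-, w = %g 1/A (FWHM %.2f A)\n",
              nrow(x$positions), x$height, x$width, width_to_fwhm(x$width)))
  invisible(x)
}

#' Convert a real-space FWHM (Angstrom) to the bead precision w (1/Angstrom)
#' @param fwhm full width at half maximum of the bead profile, Angstrom.
#' @export
fwhm_to_width <- function(fwhm) 2 * sqrt(2 * log(2)) / fwhm

#' @rdname fwhm_to_width
#' @param width bead precision, 1/Angstrom.
#' @export
width_to_fwhm <- function(width) 2 * sqrt(2 * log(2)) / width

n_beads <- function(model) nrow(model$positions)

#' Gaussian smoothing kernel
#'
#' @param sigma standard deviation of the real-space Gaussian convolution
#'   kernel, in Angstrom; \code{sigma = 0} is the identity.
#' @export
smoothing_kernel <- function(sigma) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(sigma = as.numeric(sigma)), class = "smoothing_kernel")
}

# h = 0 (the zero density) is a permitted edge case; negative h or
# non-positive w is not.
stop_if_invalid <- function(model) {
  if (model$height < 0 || model$width <= 0)
    stop("invalid model: height must be >= 0 and width > 0")
  invisible(model)
}

#' Evaluate the bead density at points in real space
#'
#' @param model a [bead_model()].
#' @param points numeric matrix \code{P x 3} (Angstrom), or a length-3 vector.
#' @return numeric vector of densities, electrons per cubic Angstrom.
#' @export
evaluate_density <- function(model, points) {
  stop_if_invalid(model)
  points <- as_points(points)
  as.numeric(cpp_density(points, model$positions, model$height, model$width))
}

#' Structure factor (Fourier transform) of a bead model
#'
#' Closed form for Gaussian beads:
#' \code{rho_hat(k) = h exp(-|k|^2/(2 w^2)) sum_i exp(+i k . y_i)}.
#' The sign convention is \code{exp(+i k . y)}; intensities are unaffected.
#'
#' @param model a [bead_model()].
#' @param kpoints numeric matrix \code{P x 3} of scattering vectors
#'   (1/Angstrom), or a length-3 vector.
#' @return complex vector of amplitudes.
#' @export
structure_factor <- function(model, kpoints) {
  stop_if_invalid(model)
  kpoints <- as_points(kpoints)
  as.complex(cpp_structure_factor(kpoints, model$positions,
                                  model$height, model$width))
}

#' Scattering intensity |rho_hat(k)|^2 of a bead model
#'
#' Translation invariant and Friedel symmetric (I(k) = I(-k)).
#'
#' @inheritParams structure_factor
#' @return numeric vector of nonnegative intensities.
#' @export
intensity <- function(model, kpoints) {
  stop_if_invalid(model)
  kpoints <- as_points(kpoints)
  as.numeric(cpp_intensity(kpoints, model$positions, model$height, model$width))
}

#' Gaussian smoothing of a bead model
#'
#' Convolution with an isotropic Gaussian of standard deviation \code{sigma}
#' keeps positions and heights and widens every bead:
#' \code{1/w'^2 = 1/w^2 + sigma^2}. Equivalently the structure factor is
#' multiplied by \code{exp(-sigma^2 k^2 / 2)} (Fourier convolution theorem).
#'
#' @param model a [bead_model()].
#' @param kernel a [smoothing_kernel()] or a nonnegative sigma in Angstrom.
#' @return the smoothed [bead_model()].
#' @export
smooth_model <- function(model, kernel) {
  if (!inherits(kernel, "smoothing_kernel")) kernel <- smoothing_kernel(kernel)
  sigma <- kernel$sigma
  if (sigma == 0) return(model)
  w_new <- 1 / sqrt(1 / model$width^2 + sigma^2)
  bead_model(model$positions, height = model$height, width = w_new)
}

as_points <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) stop("points must be P x 3")
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("points must be P x 3")
  if (!all(is.finite(x))) stop("points must be finite")
  storage.mode(x) <- "double"
  x
}
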