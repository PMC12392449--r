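#' Tabulated intensity maps I_{l,r,s}
#'
#' Evaluates the model intensity at every rotated grid center
#' \code{R_l q_{r,s}}. Stored as an array of dimension
#' \code{(n_r, n_s, n_R)} (column-major match with the compiled kernels);
#' index as \code{maps$values[r, s, l]}.
#'
#' @param model a [bead_model()].
#' @param quad a [build_orientation_quadrature()].
#' @param grid a [build_polar_grid()].
#' @return object of class \code{intensity_maps}.
#' @export
compute_intensity_maps <- function(model, quad, grid) {
  stop_if_invalid(model)
  K <- rotated_grid_points(quad, grid)
  I <- cpp_intensity(K, model$positions, model$height, model$width)
  values <- array(I, dim = c(grid$n_r, grid$n_s, quad$n_nodes))
  structure(list(values = values, quad = quad, grid = grid, kpoints = K),
            class = "intensity_maps")
}

#' Expected-count integrals lambda_l per orientation
#'
#' \code{lambda_l = sum_{r,s} a_{r,s} I_{l,r,s}}: the quadrature estimate of
#' the intensity integral over the Ewald cap in orientation \code{l};
#' \code{i0_eff * lambda_l} is the expected photon count.
#'
#' @param maps an [compute_intensity_maps()] result.
#' @return numeric vector of length \code{n_R}.
#' @export
estimate_lambdas <- function(maps) {
  a <- as.numeric(maps$grid$areas)
  apply(maps$values, 3L, function(M) sum(a * as.numeric(M)))
}

bin_imageset <- function(images, grid) {
  # flatten photon cell indices (0-based) with image offsets for the kernel
  if (inherits(images, "image_set")) images <- images$images
  if (inherits(images, "scattering_image")) images <- list(images)
  n <- vapply(images, function(im) nrow(im$photons), integer(1))
  ptr <- c(0L, cumsum(n))
  if (sum(n) == 0L)
    return(list(pr = integer(0), ps = integer(0), ptr = ptr))
  all_k <- do.call(rbind, lapply(images, `[[`, "photons"))
  b <- bin_photon(all_k, grid)
  list(pr = b$r - 1L, ps = b$s - 1L, ptr = ptr)
}

#' Log-likelihood of a single image on precomputed maps
#'
#' Grid approximation of the orientation-marginalized single-image
#' likelihood: a weighted sum over Ewald orientations \code{l} and angular
#' shifts \code{s'} (beam-axis rotations realized as cyclic index shifts),
#' evaluated with log-sum-exp. Constant per-photon factors of the beam
#' intensity are dropped, so values are comparable only within one
#' beam/grid configuration. Returns \code{-Inf} (with a warning) if every
#' \code{(l, s')} term hits a zero intensity cell.
#'
#' @param image a \code{scattering_image}.
#' @param maps an [compute_intensity_maps()] result.
#' @param beam a [beam_params()].
#' @return log-likelihood in nats.
#' @export
log_likelihood_image <- function(image, maps, beam) {
  res <- loglik_core(list(image), maps, beam, want_grad = FALSE)
  if (!is.finite(res$total))
    warning("image likelihood is zero on this grid (-Inf log-likelihood)")
  res$total
}

loglik_core <- function(images, maps, beam, want_grad) {
  b <- bin_imageset(images, maps$grid)
  lam <- estimate_lambdas(maps)
  cpp_batch_loglik(maps$values, log(maps$quad$weights), lam, beam$i0_eff,
                   maps$grid$areas, b$pr, b$ps, b$ptr, want_grad)
}

#' Log-likelihood of an image batch
#'
#' Computes the intensity maps once and sums the per-image
#' orientation-marginalized log-likelihoods.
#'
#' @param images an \code{image_set} or list of \code{scattering_image}.
#' @param model a [bead_model()].
#' @param quad,grid geometry (see [build_orientation_quadrature()],
#'   [build_polar_grid()]).
#' @param beam a [beam_params()]; defaults to the image set's beam.
#' @return list with \code{total}, \code{per_image}, \code{lambdas}.
#' @export
log_likelihood_batch <- function(images, model, quad, grid, beam = NULL) {
  if (is.null(beam) && inherits(images, "image_set")) beam <- images$beam
  if (is.null(beam)) stop("beam required")
  maps <- compute_intensity_maps(model, quad, grid)
  res <- loglik_core(images, maps, beam, want_grad = FALSE)
  list(total = res$total, per_image = as.numeric(res$per_image),
       lambdas = estimate_lambdas(maps))
}

#' Gradient of the batch log-likelihood with respect to bead positions
#'
#' Backpropagation: per-image posterior responsibilities over orientation and
#' angular shift (softmax of the log terms) give the adjoint \code{dL/dI} on
#' the maps -- photons contribute \code{1/I} at their cells, the expected-count
#' term contributes \code{-i0_eff a_{r,s}} -- and the chain rule through the
#' closed-form Gaussian-mixture intensity yields per-bead 3-vectors.
#'
#' @inheritParams log_likelihood_batch
#' @return list with \code{gradient} (\code{m x 3}, 1/Angstrom), \code{total},
#'   \code{per_image}, \code{lambdas}.
#' @export
grad_log_likelihood <- function(images, model, quad, grid, beam = NULL) {
  if (is.null(beam) && inherits(images, "image_set")) beam <- images$beam
  if (is.null(beam)) stop("beam required")
  maps <- compute_intensity_maps(model, quad, grid)
  res <- loglik_core(images, maps, beam, want_grad = TRUE)
  if (!isTRUE(res$grad_ok))
    stop("gradient undefined: at least one image has -Inf log-likelihood")
  K <- maps$kpoints
  g <- as.numeric(res$G)  # same (r, s, l) ordering as K rows
  grad <- cpp_grad_intensity_adjoint(K, model$positions, model$height,
                                     model$width, g)
  list(gradient = grad, total = res$total,
       per_image = as.numeric(res$per_image),
       lambdas = estimate_lambdas(maps))
}
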