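#' Simulate one sparse scattering image
#'
#' Forward model: a molecular orientation \code{R} is drawn uniformly from
#' SO(3) (uniform unit quaternion); the photon count is Poisson with rate
#' \code{i0_eff * lambda(R)}, where \code{lambda(R)} is the integral of
#' \code{I(R k)} over the recorded Ewald cap; photon positions are i.i.d. on
#' the cap with density proportional to \code{I(R k)}. The cap integral and
#' the position density are tabulated on a fine polar grid (cells sampled
#' proportional to intensity times area, then uniformly in \code{(q^2, phi)}
#' within the cell, which is uniform with respect to the exact area element
#' \code{q dq dphi}).
#'
#' @param model a [bead_model()].
#' @param beam a [beam_params()].
#' @param sim_grid optional [build_polar_grid()] used for tabulation; default
#'   a 96 x 64 grid (refine to check convergence).
#' @return object of class \code{scattering_image}: a list with \code{photons}
#'   (\code{n x 2} matrix of transverse components, 1/Angstrom) and
#'   \code{rotation} (the true orientation, kept for diagnostics only).
#' @export
simulate_image <- function(model, beam, sim_grid = NULL) {
  stop_if_invalid(model)
  if (is.null(sim_grid)) sim_grid <- build_polar_grid(96L, 64L, beam)
  R <- random_rotation()
  if (model$height == 0)
    return(scattering_image(matrix(numeric(0), 0L, 2L), rotation = R))
  Krot <- sim_grid$centers %*% t(R)
  I <- cpp_intensity(Krot, model$positions, model$height, model$width)
  wcell <- I * as.numeric(sim_grid$areas)  # areas are constant across s per r
  lam <- sum(wcell)
  n <- stats::rpois(1L, beam$i0_eff * lam)
  if (n == 0L || lam <= 0) {
    return(scattering_image(matrix(numeric(0), 0L, 2L), rotation = R))
  }
  cell <- sample.int(length(wcell), n, replace = TRUE, prob = wcell)
  r <- ((cell - 1L) %% sim_grid$n_r) + 1L
  s <- ((cell - 1L) %/% sim_grid$n_r) + 1L
  q2 <- stats::runif(n, sim_grid$q_edges[r]^2, sim_grid$q_edges[r + 1L]^2)
  phi <- stats::runif(n, sim_grid$phi_edges[s], sim_grid$phi_edges[s + 1L])
  tz <- transverse_from_q3d(sqrt(q2), sim_grid$k_in)
  scattering_image(cbind(tz$kt * cos(phi), tz$kt * sin(phi)), rotation = R)
}

scattering_image <- function(photons, rotation = NULL) {
  photons <- as.matrix(photons)
  if (ncol(photons) != 2L && nrow(photons) > 0L)
    stop("photons must be n x 2")
  if (nrow(photons) == 0L) photons <- matrix(numeric(0), 0L, 2L)
  structure(list(photons = photons, rotation = rotation),
            class = "scattering_image")
}

#' @export
print.scattering_image <- function(x, ...) {
  cat(sprintf("<scattering_image> %d photons\n", nrow(x$photons)))
  invisible(x)
}

random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4L)
    n2 <- sum(q^2)
    if (n2 > 1e-12) { q <- q / sqrt(n2); break }
  }
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Simulate a set of scattering images
#'
#' @inheritParams simulate_image
#' @param n_images number of independent images (>= 1).
#' @param seed integer seed; given the seed the photon lists are
#'   bit-reproducible.
#' @return object of class \code{image_set}: list with \code{images} (list of
#'   \code{scattering_image}), \code{beam}, and \code{provenance}.
#' @export
simulate_imageset <- function(model, beam, n_images, seed = NULL,
                              sim_grid = NULL) {
  n_images <- as.integer(n_images)
  if (n_images < 1L) stop("n_images must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sim_grid)) sim_grid <- build_polar_grid(96L, 64L, beam)
  images <- vector("list", n_images)
  for (j in seq_len(n_images))
    images[[j]] <- simulate_image(model, beam, sim_grid)
  image_set(images, beam,
            provenance = list(generator = "rasta::simulate_imageset",
                              seed = seed, n_images = n_images,
                              sim_grid = c(n_r = sim_grid$n_r, n_s = sim_grid$n_s),
                              version = as.character(utils::packageVersion("rasta"))))
}

image_set <- function(images, beam, provenance = list()) {
  if (length(images) < 1L) stop("an image set needs at least one image")
  structure(list(images = images, beam = beam, provenance = provenance),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  n <- vapply(x$images, function(im) nrow(im$photons), integer(1))
  cat(sprintf("<image_set> N = %d images, mean %.2f photons/image\n",
              length(x$images), mean(n)))
  invisible(x)
}

#' Photon counts per image
#' @param imageset an \code{image_set}.
#' @export
photon_counts <- function(imageset) {
  vapply(imageset$images, function(im) nrow(im$photons), integer(1))
}

#' Choose i0_eff to hit a target mean photon count
#'
#' Computes the orientation-averaged Ewald-cap intensity integral by
#' quadrature and returns \code{i0_eff = target / mean_l lambda_l}; see
#' [physical_i0_eff()] for the physical route.
#'
#' @param model a [bead_model()].
#' @param beam a [beam_params()] (its i0_eff is ignored).
#' @param target_photons desired expected photons per image.
#' @param n_quad orientation-quadrature size for the average.
#' @param n_r,n_s tabulation grid.
#' @return i0_eff scalar.
#' @export
calibrate_i0_eff <- function(model, beam, target_photons, n_quad = 32L,
                             n_r = 64L, n_s = 32L) {
  quad <- build_orientation_quadrature(n_quad)
  grid <- build_polar_grid(n_r, n_s, beam)
  lam <- estimate_lambdas(compute_intensity_maps(model, quad, grid))
  target_photons / sum(quad$weights * lam)
}
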