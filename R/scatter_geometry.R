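#' Beam and recording parameters
#'
#' Conventions: angular scattering vectors, \code{|k_in| = 2 pi / wavelength},
#' resolution \code{d = 2 pi / |k|}; the beam travels along +z and the Ewald
#' sphere through the origin is \code{|q + k_in| = |k_in|}.
#'
#' @param wavelength X-ray wavelength, Angstrom.
#' @param i0_eff effective incident intensity scale: \code{i0_eff * lambda_l}
#'   is the expected photon count for Ewald orientation \code{l}, where
#'   \code{lambda_l} is the intensity integral over the recorded cap.
#' @param kmax cutoff on the (3D) scattering-vector norm, 1/Angstrom; must not
#'   exceed the backscattering bound \code{2 |k_in|}.
#' @export
beam_params <- function(wavelength = 2.5, i0_eff = 1e-6, kmax = 3.0) {
  if (!is.finite(wavelength) || wavelength <= 0) stop("wavelength must be > 0")
  if (!is.finite(i0_eff) || i0_eff <= 0) stop("i0_eff must be > 0")
  k_in <- 2 * pi / wavelength
  if (!is.finite(kmax) || kmax <= 0 || kmax > 2 * k_in)
    stop(sprintf("kmax must lie in (0, %g] (backscattering bound 2*2pi/wavelength)",
                 2 * k_in))
  structure(list(wavelength = wavelength, i0_eff = i0_eff, kmax = kmax,
                 k_in = k_in),
            class = "beam_params")
}

#' Effective intensity scale from a physical beam description
#'
#' Converts photon fluence and the Thomson cross-section into the
#' \code{i0_eff} scale used by the forward model: a surface patch \code{dA} of
#' the Ewald sphere (radius \code{K = 2 pi / wavelength}) subtends solid angle
#' \code{dA / K^2}, so \code{i0_eff = fluence * r_e^2 / K^2} with
#' \code{r_e = 2.818e-5} Angstrom the classical electron radius. This
#' reproduces published per-image photon rates only to order of magnitude;
#' treat it as a starting point and set \code{i0_eff} directly to hit a target
#' photon rate.
#'
#' @param photons_per_pulse photons in one pulse (e.g. 1e12).
#' @param beam_diameter focal spot diameter, Angstrom (1 micron = 1e4).
#' @param wavelength Angstrom.
#' @return i0_eff (Angstrom^2).
#' @export
physical_i0_eff <- function(photons_per_pulse = 1e12, beam_diameter = 1e4,
                            wavelength = 2.5) {
  r_e <- 2.8179403e-5
  fluence <- photons_per_pulse / (pi * (beam_diameter / 2)^2)
  fluence * r_e^2 / (2 * pi / wavelength)^2
}

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch.
gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(x = e$values[idx], w = 2 * e$vectors[1L, idx]^2)
}

# Minimal rotation carrying the +z axis onto unit vector u (Rodrigues).
rotation_z_to <- function(u) {
  u <- u / sqrt(sum(u^2))
  c_ <- u[3L]
  axis <- c(-u[2L], u[1L], 0)
  s_ <- sqrt(sum(axis^2))
  if (s_ < 1e-14) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # u = -z: rotate pi about x
  }
  axis <- axis / s_
  Kx <- matrix(c(0, axis[3L], -axis[2L],
                 -axis[3L], 0, axis[1L],
                 axis[2L], -axis[1L], 0), 3, 3)
  diag(3) + s_ * Kx + (1 - c_) * (Kx %*% Kx)
}

#' Orientation quadrature over beam-axis directions
#'
#' Builds \code{n_nodes} rotations \code{R_l} with positive weights \code{w_l}
#' summing to 1. The nodes are a Gauss-Legendre (polar angle) x uniform
#' (azimuth) product rule on the sphere: \code{n_nodes = 2 t^2} uses \code{t}
#' Gauss-Legendre nodes in \code{cos(theta)} and \code{2 t} uniform azimuths,
#' and integrates spherical harmonics exactly up to degree \code{2 t - 1}.
#' Each node (a beam-axis direction in the molecular frame) is mapped to the
#' minimal rotation carrying +z onto it; the residual rotation about the beam
#' axis is handled exactly downstream by the angular-shift sum of the
#' likelihood.
#'
#' @param n_nodes 1 (identity rotation) or \code{2 t^2} for integer t.
#' @return object of class \code{orientation_quadrature} with fields
#'   \code{rotations} (list of 3x3 matrices), \code{weights}, \code{n_nodes},
#'   \code{rule}.
#' @export
build_orientation_quadrature <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes == 1L) {
    return(structure(list(rotations = list(diag(3)), weights = 1,
                          n_nodes = 1L, rule = "identity"),
                     class = "orientation_quadrature"))
  }
  t_ <- sqrt(n_nodes / 2)
  if (n_nodes < 2L || abs(t_ - round(t_)) > 1e-9) {
    valid <- c(1L, 2L * seq_len(12L)^2)
    stop(sprintf("unsupported quadrature size %d; valid sizes are 1 or 2*t^2: %s, ...",
                 n_nodes, paste(valid, collapse = ", ")))
  }
  t_ <- as.integer(round(t_))
  gl <- gauss_legendre(t_)
  n_phi <- 2L * t_
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  rot <- vector("list", n_nodes)
  wts <- numeric(n_nodes)
  idx <- 0L
  for (a in seq_len(t_)) {
    ct <- gl$x[a]
    st <- sqrt(max(0, 1 - ct^2))
    for (b in seq_len(n_phi)) {
      idx <- idx + 1L
      u <- c(st * cos(phi[b]), st * sin(phi[b]), ct)
      rot[[idx]] <- rotation_z_to(u)
      wts[idx] <- gl$w[a] / 2 / n_phi
    }
  }
  wts <- wts / sum(wts)
  structure(list(rotations = rot, weights = wts, n_nodes = n_nodes,
                 rule = sprintf("gauss_legendre_product_t%d", t_)),
            class = "orientation_quadrature")
}

#' @export
print.orientation_quadrature <- function(x, ...) {
  cat(sprintf("<orientation_quadrature> n_R = %d (%s)\n", x$n_nodes, x$rule))
  invisible(x)
}

# 3D scattering-vector norm q from transverse norm kt on the Ewald sphere.
q3d_from_transverse <- function(kt, k_in) {
  kt2 <- pmin(kt^2, k_in^2)
  sqrt(2 * k_in * (k_in - sqrt(k_in^2 - kt2)))
}

# Transverse norm kt and z-component from 3D norm q (q <= 2 k_in).
transverse_from_q3d <- function(q, k_in) {
  kt2 <- pmax(0, q^2 - q^4 / (4 * k_in^2))
  list(kt = sqrt(kt2), kz = -q^2 / (2 * k_in))
}

#' Polar grid on the Ewald sphere
#'
#' Cells are uniform in the 3D scattering-vector norm \code{q} on
#' \code{[0, kmax]} (n_r bins) and uniform in azimuth (n_s bins). On a sphere
#' through the origin the area element in \code{(q, phi)} coordinates is
#' exactly \code{q dq dphi}, so the cell area is
#' \code{a_{r,s} = dphi (q_+^2 - q_-^2)/2} and the total is \code{pi kmax^2}
#' (the spherical cap area). The strict angular uniformity is what lets
#' beam-axis rotations act as cyclic index shifts in the likelihood.
#'
#' @param n_r radial cell count (>= 1).
#' @param n_s angular cell count (>= 2).
#' @param beam a [beam_params()].
#' @return object of class \code{polar_grid} with cell centers (3D points on
#'   the reference Ewald sphere, ordered r fastest then s) and areas
#'   (\code{n_r x n_s}).
#' @export
build_polar_grid <- function(n_r, n_s, beam) {
  n_r <- as.integer(n_r); n_s <- as.integer(n_s)
  if (n_r < 1L || n_s < 2L) stop("need n_r >= 1 and n_s >= 2")
  k_in <- beam$k_in
  kmax <- beam$kmax
  q_edges <- seq(0, kmax, length.out = n_r + 1L)
  phi_edges <- seq(0, 2 * pi, length.out = n_s + 1L)
  dphi <- 2 * pi / n_s
  q_mid <- (q_edges[-1L] + q_edges[-(n_r + 1L)]) / 2
  phi_mid <- (phi_edges[-1L] + phi_edges[-(n_s + 1L)]) / 2
  areas <- matrix(dphi * diff(q_edges^2) / 2, n_r, n_s)
  tz <- transverse_from_q3d(q_mid, k_in)
  # centers ordered r fastest, then s -> row index r + n_r*(s-1)
  kt <- rep(tz$kt, times = n_s)
  kz <- rep(tz$kz, times = n_s)
  ph <- rep(phi_mid, each = n_r)
  centers <- cbind(kt * cos(ph), kt * sin(ph), kz)
  structure(list(n_r = n_r, n_s = n_s, kmax = kmax, wavelength = beam$wavelength,
                 k_in = k_in, q_edges = q_edges, phi_edges = phi_edges,
                 q_mid = q_mid, phi_mid = phi_mid,
                 centers = centers, areas = areas),
            class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("<polar_grid> %d x %d cells, kmax = %g 1/A, lambda = %g A\n",
              x$n_r, x$n_s, x$kmax, x$wavelength))
  invisible(x)
}

#' Bin photons into polar-grid cells
#'
#' Photons are given by their transverse components \code{(k_x, k_y)}; the
#' radial coordinate is the 3D scattering-vector norm recovered from the Ewald
#' condition. Bins are right-open \code{[low, high)} with the top bin closed.
#'
#' @param k numeric vector \code{c(kx, ky)} or an \code{n x 2} matrix.
#' @param grid a [build_polar_grid()] result.
#' @return list with integer vectors \code{r}, \code{s} (1-based).
#' @export
bin_photon <- function(k, grid) {
  if (is.null(dim(k))) k <- matrix(k, ncol = 2L, byrow = TRUE)
  k <- as.matrix(k)
  if (ncol(k) != 2L) stop("photons must be n x 2 (k_x, k_y)")
  kt <- sqrt(k[, 1L]^2 + k[, 2L]^2)
  q <- q3d_from_transverse(kt, grid$k_in)
  if (any(q > grid$kmax * (1 + 1e-12)))
    stop("photon beyond kmax (out of recorded range)")
  r <- pmin(grid$n_r, 1L + floor(q / (grid$kmax / grid$n_r)))
  phi <- atan2(k[, 2L], k[, 1L]) %% (2 * pi)
  s <- pmin(grid$n_s, 1L + floor(phi / (2 * pi / grid$n_s)))
  list(r = as.integer(r), s = as.integer(s))
}

# All rotated grid centers R_l q_{r,s}, ordered (r, s, l) with r fastest:
# row p = r + n_r*(s-1) + n_r*n_s*(l-1); matches the (n_r, n_s, n_R) map cube.
rotated_grid_points <- function(quad, grid) {
  do.call(rbind, lapply(quad$rotations, function(R) grid$centers %*% t(R)))
}
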