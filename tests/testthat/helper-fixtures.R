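# Shared fixtures: everything is generated in code, no binary data.

toy_beam <- function(i0_eff = 1e-6) beam_params(2.5, i0_eff, 3.0)

# beam calibrated so `model` yields ~rate photons/image
calibrated_beam <- function(model, rate = 30) {
  beam_params(2.5, calibrate_i0_eff(model, toy_beam(), rate), 3.0)
}

toy_quad <- function(n = 32L) build_orientation_quadrature(n)
toy_grid <- function(beam, n_r = 32L, n_s = 32L) build_polar_grid(n_r, n_s, beam)

random_model <- function(m, seed = 1, spread = 3, height = 7,
                         width = fwhm_to_width(2)) {
  set.seed(seed)
  bead_model(matrix(stats::rnorm(3 * m, sd = spread), m, 3),
             height = height, width = width)
}

# central finite differences of a scalar function of bead positions
fd_gradient <- function(f, model, h = 1e-4) {
  m <- nrow(model$positions)
  g <- matrix(0, m, 3)
  for (i in seq_len(m)) for (d in 1:3) {
    mp <- model; mp$positions[i, d] <- mp$positions[i, d] + h
    mm <- model; mm$positions[i, d] <- mm$positions[i, d] - h
    g[i, d] <- (f(mp) - f(mm)) / (2 * h)
  }
  g
}

# z-axis rotation matrix
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# radial (3D |k|) values of an image's photons
photon_q <- function(image, beam) {
  if (nrow(image$photons) == 0) return(numeric(0))
  kt <- sqrt(rowSums(image$photons^2))
  sqrt(2 * beam$k_in * (beam$k_in - sqrt(pmax(0, beam$k_in^2 - kt^2))))
}

# tiny synthetic PDB content (3 heavy atoms + H + water + altlocs)
synthetic_pdb_lines <- function() {
  c("HEADER    SYNTHETIC TEST MOLECULE",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00 10.00           C",
    "ATOM      3  HA  ALA A   1       2.700   2.900   3.100  1.00 10.00           H",
    "ATOM      4  CB AALA A   1       3.500   1.000   2.000  0.40 10.00           C",
    "ATOM      5  CB BALA A   1       3.600   1.100   2.100  0.60 10.00           C",
    "HETATM    6  O   HOH A 101       8.000   8.000   8.000  1.00 10.00           O",
    "END")
}

# all permutations of 1:n (n small), for exhaustive assignment oracles
rasta_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in rasta_perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
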