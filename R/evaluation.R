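#' Earth-mover's distance between bead sets
#'
#' Exact optimal transport with uniform weights and Euclidean ground cost.
#' For equal-size sets this is a linear assignment problem (solved exactly by
#' shortest augmenting paths); the EMD is the mean matched distance in
#' Angstrom. Unequal sizes are handled exactly by replicating each side to
#' \code{lcm(n_a, n_b)} points (capped at 4096; larger unequal problems
#' error out).
#'
#' @param positions_a,positions_b \code{n x 3} matrices or [bead_model()]s.
#' @return list with \code{emd} (Angstrom), \code{plan} (integer vector:
#'   matched index in b for each point of a, equal-size case only),
#'   \code{transform} (NULL; see [align_models()] for aligned EMD).
#' @export
emd <- function(positions_a, positions_b) {
  A <- as_positions(positions_a)
  B <- as_positions(positions_b)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty point set")
  na <- nrow(A); nb <- nrow(B)
  if (na != nb) {
    g <- lcm_int(na, nb)
    if (g > 4096L)
      stop("unequal sizes need lcm(n_a, n_b) <= 4096 for the exact formulation")
    A <- A[rep(seq_len(na), each = g / na), , drop = FALSE]
    B <- B[rep(seq_len(nb), each = g / nb), , drop = FALSE]
  }
  Dm <- cross_dist(A, B)
  sol <- cpp_lap(Dm)
  plan <- if (na == nb) as.integer(sol$assignment) else NULL
  list(emd = sol$cost / nrow(A), plan = plan, transform = NULL)
}

lcm_int <- function(a, b) {
  gcd <- function(x, y) if (y == 0L) x else gcd(y, x %% y)
  as.integer(a / gcd(a, b) * b)
}

as_positions <- function(x) {
  if (inherits(x, "bead_model")) x$positions else as_points(x)
}

cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  D2 <- outer(a2, b2, `+`) - 2 * A %*% t(B)
  sqrt(pmax(D2, 0))
}

# Kabsch: proper rotation R minimizing ||R A^T - B^T|| for paired rows.
kabsch_rotation <- function(A, B) {
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Rigid (+ optional inversion) alignment minimizing EMD
#'
#' The scattering intensity is invariant under global rotation, translation
#' and point inversion, so reconstructions land in an arbitrary frame and
#' hand. This searches \code{{rotation + translation} x {identity,
#' inversion}} by multi-start iteration of exact matching (assignment) and
#' least-squares superposition (Kabsch) on the matched pairs. Deterministic
#' given \code{seed}.
#'
#' @param moving,reference [bead_model()]s or \code{n x 3} matrices.
#' @param n_starts random-rotation restarts per hand (principal-axis starts
#'   are always added).
#' @param max_iter matching/superposition iterations per start.
#' @param seed integer seed for the random starts.
#' @return list of class \code{rigid_transform}: \code{rotation} (3x3),
#'   \code{translation} (length 3), \code{inverted} (logical), \code{emd}
#'   (post-alignment, Angstrom). Apply with [apply_transform()]; the moving
#'   positions are first inverted (if flagged), then rotated, then shifted.
#' @export
align_models <- function(moving, reference, n_starts = 12L, max_iter = 60L,
                         seed = 1L) {
  X <- as_positions(moving)
  Yr <- as_positions(reference)
  if (nrow(X) == 0L || nrow(Yr) == 0L) stop("empty model")
  set.seed(seed)
  cx <- colMeans(X); cy <- colMeans(Yr)
  X0 <- sweep(X, 2L, cx)
  Y0 <- sweep(Yr, 2L, cy)
  starts <- c(list(diag(3)), pca_starts(X0, Y0),
              replicate(n_starts, random_rotation(), simplify = FALSE))
  best <- list(emd = Inf)
  eq <- equalize_sizes(X0, Y0)
  for (hand in c(1, -1)) {
    Xh <- hand * eq$A
    for (R0 in starts) {
      R <- R0
      prev_asg <- NULL
      for (it in seq_len(max_iter)) {
        asg <- as.integer(cpp_lap(cross_dist(Xh %*% t(R), eq$B))$assignment)
        if (!is.null(prev_asg) && identical(asg, prev_asg)) break
        prev_asg <- asg
        # total rotation refit against the unrotated source points
        R <- kabsch_rotation(Xh, eq$B[asg, , drop = FALSE])
      }
      e <- emd(Xh %*% t(R), eq$B)$emd
      if (e < best$emd)
        best <- list(emd = e, rotation = R, inverted = hand < 0)
    }
  }
  # y = R (s (x - cx)) + cy  =  R s x + (cy - R s cx)
  s <- if (best$inverted) -1 else 1
  translation <- as.numeric(cy - best$rotation %*% (s * cx))
  structure(list(rotation = best$rotation, translation = translation,
                 inverted = best$inverted, emd = best$emd),
            class = "rigid_transform")
}

# replicate both sides to lcm size so assignment is square
equalize_sizes <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  if (na != nb) {
    g <- lcm_int(na, nb)
    A <- A[rep(seq_len(na), each = g / na), , drop = FALSE]
    B <- B[rep(seq_len(nb), each = g / nb), , drop = FALSE]
  }
  list(A = A, B = B)
}

pca_starts <- function(X0, Y0) {
  # align principal axes; all 4 proper sign combinations
  ex <- eigen(stats::cov(X0), symmetric = TRUE)$vectors
  ey <- eigen(stats::cov(Y0), symmetric = TRUE)$vectors
  if (det(ex) < 0) ex[, 3L] <- -ex[, 3L]
  if (det(ey) < 0) ey[, 3L] <- -ey[, 3L]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  lapply(signs, function(s) ey %*% diag(s) %*% t(ex))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> emd = %.4g A, hand: %s\n", x$emd,
              if (x$inverted) "inverted" else "identity"))
  invisible(x)
}

#' Apply a rigid transform (with optional inversion) to positions
#' @param transform an [align_models()] result.
#' @param x positions (\code{n x 3}) or a [bead_model()].
#' @export
apply_transform <- function(transform, x) {
  model <- NULL
  if (inherits(x, "bead_model")) { model <- x; x <- x$positions }
  s <- if (transform$inverted) -1 else 1
  out <- sweep((s * x) %*% t(transform$rotation), 2L, transform$translation, `+`)
  if (!is.null(model)) bead_model(out, model$height, model$width) else out
}

#' Fourier shell correlation between two bead models
#'
#' Both densities are rasterized analytically on a common cubic grid, Fourier
#' transformed, and correlated per spherical shell in \code{|k|}
#' (angular convention; the reported resolution is \code{d = 2 pi / k*} at
#' the first shell whose correlation drops below \code{cutoff}, linearly
#' interpolated). Models should be pre-aligned (see [align_models()]).
#'
#' @param model_a,model_b [bead_model()]s.
#' @param voxel voxel edge, Angstrom.
#' @param padding box padding beyond the joint bounding box, Angstrom; an
#'   error is raised if any bead sits too close to the box edge (density
#'   truncation).
#' @param shell_width shell width in 1/Angstrom (default: one frequency step).
#' @param cutoff correlation cutoff for the resolution estimate.
#' @return object of class \code{fsc_curve}: data.frame \code{shells}
#'   (k center, correlation, n coefficients), \code{resolution} (Angstrom, NA
#'   if the curve never crosses the cutoff), \code{cutoff}, \code{voxel}.
#' @export
fsc <- function(model_a, model_b, voxel = 0.5, padding = 10, shell_width = NULL,
                cutoff = 0.5) {
  stop_if_invalid(model_a); stop_if_invalid(model_b)
  P <- rbind(model_a$positions, model_b$positions)
  lo <- apply(P, 2L, min) - padding
  hi <- apply(P, 2L, max) + padding
  L <- max(hi - lo)
  n <- 2L * ceiling(L / voxel / 2)
  L <- n * voxel
  guard <- 4 / min(model_a$width, model_b$width)  # ~4 sd of the widest bead
  if (padding < guard)
    stop(sprintf("box too small: padding %.2f A < %.2f A needed to avoid density truncation",
                 padding, guard))
  ctr <- (lo + hi) / 2
  ax <- ctr[1L] + (seq_len(n) - (n + 1) / 2) * voxel
  ay <- ctr[2L] + (seq_len(n) - (n + 1) / 2) * voxel
  az <- ctr[3L] + (seq_len(n) - (n + 1) / 2) * voxel
  pts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  Fa <- stats::fft(array(evaluate_density(model_a, pts), dim = c(n, n, n)))
  Fb <- stats::fft(array(evaluate_density(model_b, pts), dim = c(n, n, n)))
  fr <- 2 * pi * fft_freq(n) / L  # angular spatial frequencies
  k2 <- outer(outer(fr^2, fr^2, `+`), fr^2, `+`)
  kk <- sqrt(as.numeric(k2))
  dk <- if (is.null(shell_width)) 2 * pi / L else shell_width
  shell <- pmin(floor(kk / dk), ceiling(pi / voxel / dk))
  num <- as.numeric(Re(tapply(as.complex(Fa * Conj(Fb)), shell, sum)))
  da <- as.numeric(tapply(abs(as.complex(Fa))^2, shell, sum))
  db <- as.numeric(tapply(abs(as.complex(Fb))^2, shell, sum))
  cnt <- as.numeric(tapply(kk, shell, length))
  corr <- num / sqrt(da * db)
  kc <- (as.numeric(names(table(shell))) + 0.5) * dk
  keep <- kc <= pi / voxel  # up to the grid Nyquist
  shells <- data.frame(k = kc[keep], correlation = corr[keep], n = cnt[keep])
  structure(list(shells = shells,
                 resolution = fsc_resolution(shells, cutoff),
                 cutoff = cutoff, voxel = voxel),
            class = "fsc_curve")
}

fft_freq <- function(n) {
  # DFT frequencies in cycles per box: 0, 1, ..., n/2-1, -n/2, ..., -1
  f <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  f
}

fsc_resolution <- function(shells, cutoff) {
  co <- shells$correlation
  k <- shells$k
  below <- which(co < cutoff)
  below <- below[below > 1L]
  if (length(below) == 0L) return(2 * pi / max(k))
  i <- below[1L]
  # linear interpolation between shells i-1 and i
  k_star <- k[i - 1L] + (k[i] - k[i - 1L]) * (co[i - 1L] - cutoff) /
    (co[i - 1L] - co[i])
  2 * pi / k_star
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells, resolution %.3g A at FSC = %g\n",
              nrow(x$shells), x$resolution, x$cutoff))
  invisible(x)
}
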