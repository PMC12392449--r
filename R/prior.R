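#' Parameters of the bead-position prior
#'
#' The negative log-prior is a sum of a short-range repulsive pair term and a
#' smooth connectivity term:
#' \deqn{-\log P = \sum_{i \ne j} f_1(d_{ij}) + \sum_i f_3\big(\sum_{j \ne i}
#'   f_2(d_{ij})\big)}
#' with \code{f1(d) = c1 max(0, 1 - d/d_rep)^2} (compactly supported, C^1
#' repulsion below \code{d_rep}), \code{f2(d) = 1/(1 + exp((d - r_nb)/s_nb))}
#' (smooth neighbor indicator within radius \code{r_nb}), and
#' \code{f3(x) = c3 max(0, n_min - x)^2} (one-sided penalty when the smooth
#' neighbor count falls below \code{n_min}). Self terms (i = j) are excluded.
#'
#' @param d_rep repulsion distance, Angstrom.
#' @param c1 repulsion strength.
#' @param r_nb neighbor radius, Angstrom.
#' @param s_nb neighbor indicator smoothness, Angstrom.
#' @param n_min minimum smooth neighbor count (0 disables connectivity).
#' @param c3 connectivity strength.
#' @export
prior_params <- function(d_rep = 1.0, c1 = 10.0, r_nb = 4.5, s_nb = 0.5,
                         n_min = 2.0, c3 = 1.0) {
  stopifnot(d_rep > 0, r_nb > 0, s_nb > 0, c1 >= 0, c3 >= 0, n_min >= 0)
  structure(list(d_rep = d_rep, c1 = c1, r_nb = r_nb, s_nb = s_nb,
                 n_min = n_min, c3 = c3),
            class = "prior_params")
}

pair_dists <- function(Y) {
  D <- as.matrix(stats::dist(Y))
  diag(D) <- Inf  # excludes self terms from f1/f2
  D
}

#' Log-prior of bead positions
#'
#' Invariant under rigid motion and bead permutation. Returns \code{log P}
#' (so well-separated, well-connected configurations score 0 and violations
#' are negative).
#'
#' @param model a [bead_model()].
#' @param params a [prior_params()].
#' @return log-prior in nats (<= 0).
#' @export
log_prior <- function(model, params) {
  Y <- model$positions
  if (nrow(Y) == 1L) return(0)
  D <- pair_dists(Y)
  f1 <- params$c1 * pmax(0, 1 - D / params$d_rep)^2
  f2 <- 1 / (1 + exp((D - params$r_nb) / params$s_nb))
  counts <- rowSums(f2)
  f3 <- params$c3 * pmax(0, params$n_min - counts)^2
  -(sum(f1) + sum(f3))
}

#' Analytic gradient of the log-prior
#'
#' Per-bead 3-vectors; the rows sum exactly to zero (rigid-translation
#' invariance) and match central finite differences.
#'
#' @inheritParams log_prior
#' @return numeric matrix \code{m x 3}.
#' @export
grad_log_prior <- function(model, params) {
  Y <- model$positions
  m <- nrow(Y)
  if (m == 1L) return(matrix(0, 1L, 3L))
  D <- pair_dists(Y)
  # d(-logP)/dy_i = sum_j 2 f1'(d_ij) u_ij + sum over connectivity chain
  f1p <- -2 * params$c1 / params$d_rep * pmax(0, 1 - D / params$d_rep)
  f2 <- 1 / (1 + exp((D - params$r_nb) / params$s_nb))
  f2p <- -f2 * (1 - f2) / params$s_nb
  counts <- rowSums(f2)
  f3p <- -2 * params$c3 * pmax(0, params$n_min - counts)
  # chain: d/dy_i sum_a f3(c_a), c_a = sum_b f2(d_ab);
  # pair (i,j) contributes (f3'(c_i) + f3'(c_j)) f2'(d_ij) u_ij to bead i.
  W <- 2 * f1p + outer(f3p, f3p, `+`) * f2p  # symmetric pair weights
  W[!is.finite(D)] <- 0
  grad <- matrix(0, m, 3L)
  invD <- ifelse(is.finite(D) & D > 0, 1 / D, 0)
  for (d in 1:3) {
    diffd <- outer(Y[, d], Y[, d], `-`)  # y_i - y_j
    grad[, d] <- rowSums(W * diffd * invD)
  }
  -grad  # gradient of logP = -(gradient of -logP)
}
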