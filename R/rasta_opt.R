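#' Annealing schedule for resolution-annealed gradient ascent
#'
#' The smoothing scale decays linearly to zero,
#' \code{sigma(t) = sigma0 * max(0, 1 - t/t_anneal)}, so the final
#' \code{T - t_anneal} steps run at full resolution; the step size decays
#' geometrically from \code{eta0} to \code{eta1}; the momentum parameter is
#' constant. All profiles are evaluated at 0-based step index \code{t}.
#'
#' @param total_steps number of optimization steps T.
#' @param sigma0 initial smoothing scale, Angstrom.
#' @param t_anneal step at which sigma reaches 0 (default \code{0.8 * T}).
#' @param sigma_power exponent p of the decay profile
#'   \code{sigma(t) = sigma0 (1 - t/t_anneal)^p}; p > 1 dwells longer at
#'   small sigma, where fine structure assembles.
#' @param eta0,eta1 initial/final step size (Angstrom^2; gradients are in
#'   1/Angstrom).
#' @param beta momentum parameter in [0, 1).
#' @param batch_size images drawn (uniformly, with replacement) per step.
#' @param clip_norm cap on the Frobenius norm of the stochastic gradient
#'   before the momentum update (Inf = plain update). Stochastic photon
#'   batches occasionally produce gradient spikes that can destabilize
#'   momentum; clipping preserves the ascent direction.
#' @param seed integer seed for batch sampling and photon thinning.
#' @export
anneal_schedule <- function(total_steps, sigma0 = 3.0,
                            t_anneal = ceiling(0.8 * total_steps),
                            sigma_power = 1, eta0 = 1e-4, eta1 = 1e-5,
                            beta = 0.9, batch_size = 1000L, clip_norm = Inf,
                            seed = 1L) {
  stopifnot(total_steps >= 0, sigma0 >= 0, eta0 > 0, eta1 > 0, sigma_power > 0,
            beta >= 0, beta < 1, batch_size >= 1, clip_norm > 0)
  structure(list(total_steps = as.integer(total_steps), sigma0 = sigma0,
                 t_anneal = max(1L, as.integer(t_anneal)),
                 sigma_power = sigma_power,
                 eta0 = eta0, eta1 = eta1, beta = beta,
                 batch_size = as.integer(batch_size), clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

#' @rdname anneal_schedule
#' @param schedule an \code{anneal_schedule}.
#' @param t 0-based step index.
#' @export
sigma_at <- function(schedule, t)
  schedule$sigma0 * max(0, 1 - t / schedule$t_anneal)^(schedule$sigma_power %||% 1)

#' @rdname anneal_schedule
#' @export
eta_at <- function(schedule, t) {
  T_ <- max(1L, schedule$total_steps - 1L)
  schedule$eta0 * (schedule$eta1 / schedule$eta0)^(min(t, T_) / T_)
}

#' @rdname anneal_schedule
#' @export
beta_at <- function(schedule, t) schedule$beta

#' Thin an image by resolution-dependent photon rejection
#'
#' Keeps each photon independently with probability
#' \code{exp(-sigma^2 |k|^2)} (\code{|k|} the 3D scattering-vector norm),
#' which makes the thinned images distributionally identical to images of the
#' Gaussian-smoothed density \code{smooth_model(model, sigma)}.
#'
#' @param image a \code{scattering_image}.
#' @param sigma smoothing scale, Angstrom (>= 0).
#' @param k_in Ewald radius \code{2 pi / wavelength} used to recover the 3D
#'   norm from the stored transverse components.
#' @return thinned \code{scattering_image} (photon order preserved).
#' @export
thin_image <- function(image, sigma, k_in) {
  if (sigma < 0) stop("sigma must be >= 0")
  n <- nrow(image$photons)
  if (sigma == 0 || n == 0L) return(image)
  kt <- sqrt(image$photons[, 1L]^2 + image$photons[, 2L]^2)
  q2 <- q3d_from_transverse(kt, k_in)^2
  keep <- stats::runif(n) < exp(-sigma^2 * q2)
  scattering_image(image$photons[keep, , drop = FALSE], rotation = image$rotation)
}

#' Optimizer state
#'
#' @param model current [bead_model()].
#' @param velocity \code{m x 3} momentum buffer (defaults to zero).
#' @param t 0-based step counter.
#' @export
optimizer_state <- function(model, velocity = NULL, t = 0L) {
  if (is.null(velocity)) velocity <- matrix(0, n_beads(model), 3L)
  stopifnot(all(dim(velocity) == dim(model$positions)))
  structure(list(model = model, velocity = velocity, t = as.integer(t)),
            class = "optimizer_state")
}

#' One RASTA update step
#'
#' Thin the batch at \code{sigma}, evaluate the gradient of the batch
#' log-likelihood under the sigma-smoothed model (scaled by
#' \code{n_total / batch size} for an unbiased full-set estimate) plus the
#' log-prior gradient on the raw positions, then apply the momentum update
#' \code{v <- beta v + g; y <- y + eta v}.
#'
#' @param state an [optimizer_state()].
#' @param batch list of \code{scattering_image} (nonempty).
#' @param sigma,eta,beta current schedule values.
#' @param quad,grid,beam geometry.
#' @param prior a [prior_params()] or NULL for a flat prior.
#' @param n_total total number of images in the full set (for gradient
#'   scaling); defaults to the batch size.
#' @param clip_norm gradient-norm cap (see [anneal_schedule()]).
#' @return updated [optimizer_state()].
#' @export
rasta_step <- function(state, batch, sigma, eta, beta, quad, grid, beam,
                       prior = NULL, n_total = length(batch),
                       clip_norm = Inf) {
  if (length(batch) == 0L) stop("batch must be nonempty")
  thinned <- lapply(batch, thin_image, sigma = sigma, k_in = beam$k_in)
  sm <- smooth_model(state$model, sigma)
  gl <- grad_log_likelihood(thinned, sm, quad, grid, beam)
  g <- (n_total / length(batch)) * gl$gradient
  if (!is.null(prior)) g <- g + grad_log_prior(state$model, prior)
  if (!all(is.finite(g))) stop("step rejected: gradient is not finite")
  gn <- sqrt(sum(g^2))
  if (gn > clip_norm) g <- g * (clip_norm / gn)
  v <- beta * state$velocity + g
  y <- state$model$positions + eta * v
  model <- bead_model(y, height = state$model$height, width = state$model$width)
  out <- optimizer_state(model, velocity = v, t = state$t + 1L)
  out$last_loglik <- gl$total
  out$last_grad_norm <- sqrt(sum(g^2))
  out
}

#' Run resolution-annealed stochastic gradient ascent
#'
#' Draws a random batch per step, thins it at \code{sigma(t)}, and ascends the
#' stochastic log-posterior gradient with momentum for
#' \code{schedule$total_steps} steps (fixed step count; no adaptive stopping).
#' Bit-reproducible given \code{schedule$seed}.
#'
#' @param imageset an \code{image_set}.
#' @param init_model initial [bead_model()]; see [random_init_model()].
#' @param schedule an [anneal_schedule()].
#' @param quad,grid geometry.
#' @param prior a [prior_params()] or NULL.
#' @param checkpoint_sigmas decreasing sigma thresholds at which model
#'   snapshots are stored.
#' @param average_last if > 0, the returned model's positions are the average
#'   over the final \code{average_last} steps (Polyak-Ruppert averaging;
#'   suppresses the stationary jitter of constant-step-size SGD). The raw
#'   final state remains available as \code{state}.
#' @param verbose print progress every \code{verbose} steps (0 = quiet).
#' @return list with \code{model} (final), \code{state}, \code{metrics}
#'   (per-step data.frame: step, sigma, eta, loglik proxy of the thinned
#'   batch, gradient-norm surrogate |velocity|), \code{checkpoints},
#'   \code{provenance}.
#' @export
run_rasta <- function(imageset, init_model, schedule, quad, grid,
                      prior = prior_params(), checkpoint_sigmas = numeric(0),
                      average_last = 0L, verbose = 0L) {
  beam <- imageset$beam
  N <- length(imageset$images)
  state <- optimizer_state(init_model)
  T_ <- schedule$total_steps
  met_step <- integer(T_)
  met_sigma <- met_eta <- met_ll <- met_gn <- numeric(T_)
  checkpoints <- list()
  cp_pending <- sort(checkpoint_sigmas, decreasing = TRUE)
  avg_from <- T_ - min(average_last, T_)
  pos_acc <- 0 * init_model$positions
  n_acc <- 0L
  set.seed(schedule$seed)
  for (t in seq_len(T_) - 1L) {
    sigma <- sigma_at(schedule, t)
    eta <- eta_at(schedule, t)
    beta <- beta_at(schedule, t)
    idx <- sample.int(N, min(schedule$batch_size, N), replace = TRUE)
    batch <- imageset$images[idx]
    prev <- state$model
    state <- rasta_step(state, batch, sigma, eta, beta, quad, grid, beam,
                        prior = prior, n_total = N,
                        clip_norm = schedule$clip_norm %||% Inf)
    met_step[t + 1L] <- t
    met_sigma[t + 1L] <- sigma
    met_eta[t + 1L] <- eta
    met_ll[t + 1L] <- state$last_loglik %||% NA_real_
    met_gn[t + 1L] <- state$last_grad_norm %||% NA_real_
    if (t >= avg_from && average_last > 0L) {
      pos_acc <- pos_acc + state$model$positions
      n_acc <- n_acc + 1L
    }
    while (length(cp_pending) && sigma <= cp_pending[1L]) {
      checkpoints[[sprintf("sigma_%.3g", cp_pending[1L])]] <- prev
      cp_pending <- cp_pending[-1L]
    }
    if (verbose > 0L && (t %% verbose == 0L))
      message(sprintf("step %d  sigma=%.3f  eta=%.3g  |grad|=%.3g",
                      t, sigma, eta, met_gn[t + 1L]))
  }
  metrics <- data.frame(step = met_step, sigma = met_sigma, eta = met_eta,
                        loglik = met_ll, grad_norm = met_gn)
  final_model <- if (n_acc > 0L) {
    bead_model(pos_acc / n_acc, init_model$height, init_model$width)
  } else state$model
  list(model = final_model, state = state, metrics = metrics,
       checkpoints = checkpoints,
       provenance = list(schedule = unclass(schedule), n_images = N,
                         quad = quad$rule,
                         grid = c(n_r = grid$n_r, n_s = grid$n_s),
                         average_last = average_last,
                         init = attr(init_model, "init_provenance")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random initial bead cloud
#'
#' Gaussian cloud scaled to a target radius of gyration (the optimizer's
#' likelihood is invariant to the global frame, so only the size scale
#' matters for initialization).
#'
#' @param m number of beads.
#' @param rg target radius of gyration, Angstrom.
#' @param height,width bead parameters (see [bead_model()]).
#' @param seed integer seed.
#' @export
random_init_model <- function(m, rg = 5.0, height = 7.0,
                              width = fwhm_to_width(2.0), seed = 1L) {
  set.seed(seed)
  Y <- matrix(stats::rnorm(3L * m), m, 3L)
  Y <- sweep(Y, 2L, colMeans(Y))
  cur <- sqrt(mean(rowSums(Y^2)))
  if (cur > 0) Y <- Y * rg / cur
  out <- bead_model(Y, height = height, width = width)
  attr(out, "init_provenance") <- list(kind = "gaussian_cloud", m = m,
                                       rg = rg, seed = seed)
  out
}
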