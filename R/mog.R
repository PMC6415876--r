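#' Mixture-of-Gaussians background model parameters
#'
#' Per-pixel intensity is modelled as a mixture of `K` Gaussians
#' (Stauffer--Grimson style). Components that carry most of the weight at
#' low variance explain the static background; intensities not explained by
#' them belong to moving objects (motile sperm).
#'
#' @param K Gaussians per pixel (integer >= 1).
#' @param alpha learning rate in (0, 1); 0 freezes the model.
#' @param match_sigmas matching distance in standard deviations (> 0).
#' @param bg_weight_fraction cumulative-weight cutoff T in (0, 1): the
#'   smallest set of components (ordered by weight/SD) whose summed weight
#'   reaches T is declared background.
#' @param initial_variance variance assigned to newly created components
#'   (intensity-squared units).
#' @param burn_in frames excluded from counting while the model settles.
#' @return object of class `bg_model_params`.
#' @export
bg_model_params <- function(K = 3L, alpha = 0.05, match_sigmas = 2.5,
                            bg_weight_fraction = 0.7, initial_variance = 225,
                            burn_in = 5L) {
  if (K < 1L) stop_spermfx("K must be >= 1", "parameter_error")
  if (alpha < 0 || alpha >= 1) stop_spermfx("alpha must be in [0, 1)", "parameter_error")
  if (match_sigmas <= 0) stop_spermfx("match_sigmas must be > 0", "parameter_error")
  if (bg_weight_fraction <= 0 || bg_weight_fraction >= 1)
    stop_spermfx("bg_weight_fraction must be in (0, 1)", "parameter_error")
  if (initial_variance <= 0) stop_spermfx("initial_variance must be > 0", "parameter_error")
  if (burn_in < 0L) stop_spermfx("burn_in must be >= 0", "parameter_error")
  structure(list(K = as.integer(K), alpha = alpha, match_sigmas = match_sigmas,
                 bg_weight_fraction = bg_weight_fraction,
                 initial_variance = initial_variance, burn_in = as.integer(burn_in)),
            class = "bg_model_params")
}

VAR_FLOOR <- 9  # intensity^2; keeps the match gate from collapsing below ~3 levels

#' Initialize a pixel-mixture background model from one frame
#'
#' Each pixel gets one component centred at the observed intensity with
#' weight 1 and `initial_variance`; the remaining `K - 1` component slots
#' are parked far outside the 0--255 range so they can never match before
#' being recycled.
#'
#' @param frame numeric matrix, intensities 0--255.
#' @param params [bg_model_params()].
#' @return object of class `pixel_mixture` (per-pixel weights, means,
#'   variances and the frame count seen).
#' @export
mog_init <- function(frame, params = bg_model_params()) {
  stopifnot(is.matrix(frame))
  n <- length(frame); K <- params$K
  w  <- matrix(0, K, n); w[1, ] <- 1
  mu <- matrix(-1e6, K, n); mu[1, ] <- as.numeric(frame)
  s2 <- matrix(params$initial_variance, K, n)
  structure(list(w = w, mu = mu, s2 = s2, dim = dim(frame), n_seen = 1L),
            class = "pixel_mixture")
}

#' Update a pixel-mixture background model with a frame
#'
#' For each pixel the matching component (within `match_sigmas` standard
#' deviations, the best-fitting one by weight/SD when several match) has its
#' weight, mean and variance moved toward the observation by `alpha`; when
#' nothing matches, the lowest-weight component is replaced by a fresh
#' component centred at the observation with `initial_variance`. Weights are
#' renormalized to sum to 1 per pixel. With `alpha = 0` the model is
#' returned unchanged. While the model is young the effective rate is
#' raised to `1/t` (t = frames seen) so component weights track empirical
#' frequencies during initialization.
#'
#' @param model a `pixel_mixture` from [mog_init()].
#' @param frame numeric matrix with the model's dimensions.
#' @param params [bg_model_params()].
#' @return the updated `pixel_mixture`.
#' @export
mog_update <- function(model, frame, params = bg_model_params()) {
  stopifnot(inherits(model, "pixel_mixture"))
  if (!identical(dim(frame), model$dim))
    stop_spermfx("frame dimensions do not match the model", "shape_error")
  if (params$alpha == 0) { model$n_seen <- model$n_seen + 1L; return(model) }
  x <- as.numeric(frame)
  n <- length(x); K <- params$K
  # adaptive rate while the model is young: weights then track empirical
  # frequencies and the burn-in transient clears in a few frames
  a <- max(params$alpha, 1 / (model$n_seen + 1))
  w <- model$w; mu <- model$mu; s2 <- model$s2
  sd_ <- sqrt(s2)
  dev <- abs(sweep(mu, 2, x))                 # K x n
  match <- dev <= params$match_sigmas * sd_
  fit <- w / sd_
  score <- ifelse(match, fit, -1)
  best <- max.col(t(score), ties.method = "first")      # component index per pixel
  matched <- score[cbind(best, seq_len(n))] >= 0

  mi <- which(matched)
  if (length(mi)) {
    idx <- cbind(best[mi], mi)
    w[, mi] <- (1 - a) * w[, mi]
    w[idx] <- w[idx] + a
    d <- x[mi] - mu[idx]
    mu[idx] <- mu[idx] + a * d
    s2[idx] <- pmax(s2[idx] + a * (d * d - s2[idx]), VAR_FLOOR)
  }
  ui <- which(!matched)
  if (length(ui)) {
    kmin <- max.col(t(-w[, ui, drop = FALSE]), ties.method = "first")
    idx <- cbind(kmin, ui)
    mu[idx] <- x[ui]
    s2[idx] <- params$initial_variance
    w[idx] <- a
    cs <- colSums(w[, ui, drop = FALSE])
    w[, ui] <- sweep(w[, ui, drop = FALSE], 2, cs, "/")
  }
  model$w <- w; model$mu <- mu; model$s2 <- s2
  model$n_seen <- model$n_seen + 1L
  model
}

#' Extract the foreground (motile) mask for a frame
#'
#' Components are ordered by weight/SD; the smallest prefix whose cumulative
#' weight reaches `bg_weight_fraction` forms the background. A pixel is
#' foreground iff its intensity matches no background component.
#'
#' @param model a trained `pixel_mixture`.
#' @param frame numeric matrix with the model's dimensions.
#' @param params [bg_model_params()].
#' @return binary (0/1) integer matrix, 1 = foreground.
#' @export
mog_foreground <- function(model, frame, params = bg_model_params()) {
  stopifnot(inherits(model, "pixel_mixture"))
  if (is.null(model$n_seen) || model$n_seen < 1L)
    stop_spermfx("background model has not seen any frame", "state_error")
  if (!identical(dim(frame), model$dim))
    stop_spermfx("frame dimensions do not match the model", "shape_error")
  x <- as.numeric(frame)
  w <- model$w; mu <- model$mu; s2 <- model$s2
  K <- nrow(w); n <- length(x)
  sd_ <- sqrt(s2)
  fit <- w / sd_
  # rank components per pixel by fitness (descending, ties by index)
  rank_ <- matrix(1L, K, n)
  if (K > 1L) {
    for (k in seq_len(K)) {
      r <- rep(1L, n)
      for (j in seq_len(K)) {
        if (j == k) next
        r <- r + (fit[j, ] > fit[k, ] | (fit[j, ] == fit[k, ] & j < k))
      }
      rank_[k, ] <- r
    }
  }
  # cumulative weight of components ranked strictly before k
  cum_before <- matrix(0, K, n)
  if (K > 1L) {
    for (k in seq_len(K)) {
      cb <- rep(0, n)
      for (j in seq_len(K)) {
        if (j == k) next
        cb <- cb + w[j, ] * (rank_[j, ] < rank_[k, ])
      }
      cum_before[k, ] <- cb
    }
  }
  is_bg <- cum_before < params$bg_weight_fraction
  dev <- abs(sweep(mu, 2, x))
  match <- dev <= params$match_sigmas * sd_
  fg <- colSums(is_bg & match) == 0
  matrix(as.integer(fg), model$dim[1], model$dim[2])
}
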