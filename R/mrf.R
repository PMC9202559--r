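# Ising-MRF mask polishing: bipolarization of probability maps, Gaussian
# noise injection on the bipolar states, the total energy
#   E(x, y) = -sum_pairs x_p x_q  -  eta * sum_ij x_ij y_ij
# (pairs = ((i,j),(i+1,j+1)) for the diagonal neighborhood, 4-adjacency
# for n4, no wraparound), and ICM coordinate-descent minimization with an
# exhaustive brute-force minimizer for validation on tiny grids.
#
# Defaults eta = 15 and sigma = 1.5 follow the source method.  Note that
# with bipolar states, additive N(0, 1.5^2) noise followed by sign() flips
# a pixel with probability Phi(-1/1.5) ~ 0.2525 -- slightly above the
# nominal "20% noise".

#' MRF configuration
#'
#' @param eta data-term weight (> 0, default 15).
#' @param sigma Gaussian noise standard deviation (> 0, default 1.5).
#' @param neighborhood `"diag"` (the literal (i+1, j+1) coupling; default)
#'   or `"n4"` (standard 4-adjacency).
#' @param max_sweeps maximum ICM sweeps (default 50).
#' @param seed RNG seed for noise injection.
#' @return object of class `mrf_config`.
#' @export
mrf_config <- function(eta = 15, sigma = 1.5, neighborhood = c("diag", "n4"),
                       max_sweeps = 50L, seed = 1L) {
  stopifnot_scalar_number(eta, "eta", positive = TRUE)
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  neighborhood <- match.arg(neighborhood)
  if (max_sweeps < 1L) validation_error("max_sweeps must be >= 1")
  structure(list(eta = eta, sigma = sigma, neighborhood = neighborhood,
                 max_sweeps = as.integer(max_sweeps), seed = as.integer(seed)),
            class = "mrf_config")
}

.check_bipolar <- function(x, name = "mask") {
  if (!is.matrix(x) || nrow(x) < 1L || ncol(x) < 1L)
    validation_error(sprintf("%s must be a matrix of at least 1x1", name))
  if (!all(x == 1L | x == -1L))
    validation_error(sprintf("%s values must all be in {-1, +1}", name))
  invisible(x)
}

#' Threshold a probability map to a bipolar mask
#'
#' `+1` where `p >= threshold` (boundary inclusive), `-1` otherwise.
#'
#' @param prob_map numeric matrix of per-pixel probabilities in \[0, 1\].
#' @param threshold scalar in \[0, 1\] (default 0.5).
#' @return integer matrix over \{-1, +1\}.
#' @export
to_bipolar <- function(prob_map, threshold = 0.5) {
  if (any(prob_map < 0 | prob_map > 1))
    validation_error("probabilities must be in [0, 1]")
  if (threshold < 0 || threshold > 1)
    validation_error("threshold must be in [0, 1]")
  out <- matrix(ifelse(prob_map >= threshold, 1L, -1L),
                nrow(prob_map), ncol(prob_map))
  out
}

#' Convert a 0/1 mask to bipolar and back
#'
#' @param mask 0/1 matrix (binary) or bipolar matrix.
#' @return the other representation.
#' @export
binary_to_bipolar <- function(mask) {
  if (!all(mask %in% c(0, 1))) validation_error("mask values must be 0/1")
  matrix(ifelse(mask > 0, 1L, -1L), nrow(mask), ncol(mask))
}

#' @rdname binary_to_bipolar
#' @export
bipolar_to_binary <- function(mask) {
  .check_bipolar(mask)
  matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
}

#' Inject Gaussian noise onto a bipolar mask
#'
#' `y_ij = sign(x_ij + g_ij)` with `g ~ N(0, sigma^2)` i.i.d. (sign(0) is
#' +1).  The expected flip rate is `pnorm(-1/sigma)`; at the default
#' sigma = 1.5 that is ~0.2525.
#'
#' @param x bipolar matrix over \{-1, +1\}.
#' @param sigma noise standard deviation (> 0).
#' @param seed RNG seed.
#' @return bipolar matrix.
#' @export
inject_noise <- function(x, sigma = 1.5, seed = 1L) {
  .check_bipolar(x)
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  set.seed(as.integer(seed))
  g <- matrix(rnorm(length(x), 0, sigma), nrow(x), ncol(x))
  matrix(ifelse(x + g >= 0, 1L, -1L), nrow(x), ncol(x))
}

#' Total Ising energy of a configuration
#'
#' @param x candidate bipolar mask.
#' @param y observed bipolar mask.
#' @param config an [mrf_config()].
#' @return scalar energy (lower = better agreement with both the coupling
#'   prior and the observation).
#' @export
total_energy <- function(x, y, config = mrf_config()) {
  .check_bipolar(x, "x"); .check_bipolar(y, "y")
  if (!identical(dim(x), dim(y))) contract_error("x and y must share a shape")
  H <- nrow(x); W <- ncol(x)
  coupling <- 0
  if (config$neighborhood == "diag") {
    if (H > 1L && W > 1L)
      coupling <- sum(x[-H, -W] * x[-1, -1])
  } else {
    if (H > 1L) coupling <- coupling + sum(x[-H, ] * x[-1, ])
    if (W > 1L) coupling <- coupling + sum(x[, -W] * x[, -1])
  }
  -coupling - config$eta * sum(x * y)
}

#' Denoise a bipolar mask by iterated conditional modes
#'
#' Raster-order sweeps; each pixel takes the sign of its local field
#' (coupling neighbors plus `eta * y`), keeping its current value on ties;
#' terminates when a full sweep changes nothing or after `max_sweeps`.
#' Every accepted single-pixel update strictly decreases the energy, so
#' `E(out, y) <= E(y, y)` when started from `y`.
#'
#' @param y observed bipolar mask (the ICM starting point).
#' @param config an [mrf_config()].
#' @param init optional alternative starting mask (defaults to `y`).
#' @param trace if TRUE, attach attributes `sweeps` and `deltas` (energy
#'   change of every accepted update).
#' @return bipolar matrix at an ICM fixed point (or after `max_sweeps`).
#' @export
icm_denoise <- function(y, config = mrf_config(), init = NULL, trace = FALSE) {
  .check_bipolar(y, "y")
  x0 <- if (is.null(init)) y else .check_bipolar(init, "init")
  if (!identical(dim(x0), dim(y))) contract_error("init and y must share a shape")
  r <- icm_sweeps(matrix(as.integer(x0), nrow(y), ncol(y)),
                  matrix(as.integer(y), nrow(y), ncol(y)),
                  config$eta, as.integer(config$neighborhood == "diag"),
                  config$max_sweeps)
  out <- r$x
  if (trace) {
    attr(out, "sweeps") <- r$sweeps
    attr(out, "deltas") <- r$deltas
  }
  out
}

#' Exhaustive global Ising minimizer (validation oracle)
#'
#' Enumerates all `2^(H*W)` candidate masks; only sensible for tiny grids
#' (H*W <= 16).
#'
#' @param y observed bipolar mask.
#' @param config an [mrf_config()].
#' @return list with `x` (a global minimizer) and `energy`.
#' @export
brute_force_minimum <- function(y, config = mrf_config()) {
  .check_bipolar(y, "y")
  n <- length(y)
  if (n > 16L) validation_error("brute force is limited to grids of <= 16 pixels")
  best <- NULL; best_e <- Inf
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(n)]
    x <- matrix(ifelse(bits == 1L, 1L, -1L), nrow(y), ncol(y))
    e <- total_energy(x, y, config)
    if (e < best_e) { best_e <- e; best <- x }
  }
  list(x = best, energy = best_e)
}
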