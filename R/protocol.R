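#' Generate a random center-out-and-back perturbation protocol
#'
#' Builds the platform displacement trajectory used to perturb the perched
#' body: `n_moves` center-out-and-back excursions, each along a direction
#' drawn uniformly on the unit sphere, reaching the surface of a sphere of
#' radius `radius_m` and returning to the origin. Each event is preceded by a
#' dwell of `dwell_s` seconds at the origin; the displacement profile within a
#' move is a raised-cosine pulse (half-cosine out, half-cosine back), so the
#' commanded position, velocity and acceleration are all smooth and known in
#' closed form.
#'
#' @param n_moves Number of displacements (>= 0).
#' @param radius_m Sphere radius in meters (> 0).
#' @param move_duration_s Duration of one out-and-back move in seconds
#'   (default 0.4: 0.2 s out, 0.2 s back).
#' @param dwell_s Dwell at the origin before each move, seconds (default 0.1).
#' @param rate_hz Sampling rate in Hz (default 1000).
#' @param seed Integer seed for the random directions.
#' @param max_samples Capacity guard: error if the trajectory would exceed
#'   this many samples (default 5e7).
#'
#' @return An object of class `perch_protocol` with fields `rate_hz`,
#'   `radius_m`, `n_moves`, `events` (data frame of `start_index` and unit
#'   direction components), `platform_pos`, `platform_vel`, `platform_acc`
#'   (N x 3 matrices, SI units, axes x = lateral, y = fore-aft, z = vertical).
#'
#' @examples
#' pr <- generate_protocol(n_moves = 5, radius_m = 0.02, seed = 1)
#' max(sqrt(rowSums(pr$platform_pos^2)))  # 0.02
#' @export
generate_protocol <- function(n_moves, radius_m, move_duration_s = 0.4,
                              dwell_s = 0.1, rate_hz = 1000, seed = 1L,
                              max_samples = 5e7) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0)
    stop("rate_hz must be a positive number")
  if (!is.numeric(move_duration_s) || move_duration_s <= 0)
    stop("move_duration_s must be positive")
  if (!is.numeric(dwell_s) || dwell_s < 0)
    stop("dwell_s must be non-negative")
  if (!is.numeric(radius_m) || radius_m <= 0)
    stop("radius_m must be positive")
  if (!is.numeric(n_moves) || n_moves < 0 || n_moves != round(n_moves))
    stop("n_moves must be a non-negative integer")
  n_moves <- as.integer(n_moves)

  # even sample count per move so the excursion peak lands exactly on a sample
  n_move <- 2L * max(1L, as.integer(round(move_duration_s * rate_hz / 2)))
  n_dwell <- as.integer(round(dwell_s * rate_hz))
  n_per <- n_move + n_dwell
  N <- as.double(n_moves) * n_per
  if (N > max_samples)
    stop("protocol would need ", N, " samples, exceeding max_samples = ",
         max_samples, " (capacity)")
  N <- as.integer(N)

  axes <- c("x", "y", "z")
  pos <- vel <- acc <- matrix(0, N, 3, dimnames = list(NULL, axes))

  if (n_moves > 0) {
    set.seed(seed)
    g <- matrix(rnorm(3L * n_moves), ncol = 3)
    nrm <- sqrt(rowSums(g^2))
    nrm[nrm == 0] <- 1
    dirs <- g / nrm

    # raised-cosine pulse: s(t) = (1 - cos(2 pi t / T)) / 2, peak 1 at T/2
    t_move <- n_move / rate_hz
    j <- seq_len(n_move)
    ph <- 2 * pi * j / n_move
    prof_p <- (1 - cos(ph)) / 2
    prof_v <- (pi / t_move) * sin(ph)
    prof_a <- (2 * pi^2 / t_move^2) * cos(ph)

    starts <- (seq_len(n_moves) - 1L) * n_per + n_dwell + 1L
    for (k in seq_len(n_moves)) {
      idx <- starts[k] + 0:(n_move - 1L)
      d <- dirs[k, ]
      pos[idx, ] <- radius_m * (prof_p %o% d)
      vel[idx, ] <- radius_m * (prof_v %o% d)
      acc[idx, ] <- radius_m * (prof_a %o% d)
    }
    events <- data.frame(start_index = starts,
                         dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
  } else {
    events <- data.frame(start_index = integer(0), dx = numeric(0),
                         dy = numeric(0), dz = numeric(0))
  }

  structure(list(rate_hz = rate_hz, radius_m = radius_m, n_moves = n_moves,
                 move_duration_s = n_move / rate_hz, dwell_s = n_dwell / rate_hz,
                 seed = seed, events = events,
                 platform_pos = pos, platform_vel = vel, platform_acc = acc),
            class = "perch_protocol")
}

#' @export
print.perch_protocol <- function(x, ...) {
  cat("Perturbation protocol:", x$n_moves, "center-out-and-back moves,",
      sprintf("radius %.1f mm,", 1000 * x$radius_m),
      sprintf("%g Hz sampling\n", x$rate_hz))
  cat(sprintf("  move %.3f s + dwell %.3f s -> %.1f s total (%d samples)\n",
              x$move_duration_s, x$dwell_s,
              nrow(x$platform_pos) / x$rate_hz, nrow(x$platform_pos)))
  invisible(x)
}
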