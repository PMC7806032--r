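new_recording <- function(rate_hz, foot, hip, head, meta = list()) {
  N <- nrow(foot)
  structure(list(rate_hz = rate_hz, t = (seq_len(N) - 1) / rate_hz,
                 foot = foot, hip = hip, head = head, meta = meta),
            class = "perch_recording")
}

#' Simulate the compliant two-stage chain response to a platform protocol
#'
#' Integrates, per axis, the serial linear chain
#' \deqn{m_b \ddot{x}_h = -k_l (x_h - p) - c_l (\dot{x}_h - \dot{p})
#'       - k_n (x_h - x_d) - c_n (\dot{x}_h - \dot{x}_d)}
#' \deqn{m_d \ddot{x}_d = -k_n (x_d - x_h) - c_n (\dot{x}_d - \dot{x}_h)}
#' where \eqn{p} is the platform position, \eqn{x_h} the hip and \eqn{x_d}
#' the head coordinate. The feet are rigidly attached to the platform, so the
#' foot accelerometer reads the platform acceleration \eqn{\ddot{p}} itself.
#' The chain is linear, so it is integrated by exact first-order-hold
#' discretization of the continuous state-space at the protocol's sampling
#' rate (the commanded platform input is interpolated linearly across each
#' sample interval; bit-reproducible, no step-size error control needed);
#' hip and head accelerations are read out algebraically from the states and
#' instantaneous inputs.
#' Accelerometers report perturbation-induced linear acceleration only
#' (gravity / DC removed).
#'
#' @param protocol A [generate_protocol()] object.
#' @param params A [mechanical_params()] object.
#' @return A noiseless `perch_recording`: fields `rate_hz`, `t`, and N x 3
#'   matrices `foot`, `hip`, `head` (m/s^2, axes x/y/z), plus `meta`.
#' @examples
#' pr <- generate_protocol(5, 0.01, seed = 2)
#' rec <- simulate_chain(pr, mechanical_params("low"))
#' @export
simulate_chain <- function(protocol, params) {
  if (!inherits(protocol, "perch_protocol")) stop("protocol must be a perch_protocol")
  if (!inherits(params, "perch_params")) stop("params must be a perch_params")
  validate_params(params)
  rate <- protocol$rate_hz
  dt <- 1 / rate
  N <- nrow(protocol$platform_pos)
  axes <- c("x", "y", "z")
  hip <- head_ <- matrix(0, N, 3, dimnames = list(NULL, axes))
  unstable <- FALSE

  mb <- params$m_body; mh <- params$m_head
  kn <- params$k_neck; cn <- params$c_neck
  for (a in 1:3) {
    kl <- params$k_leg[a]; cl <- params$c_leg[a]
    # states: x_h, v_h, x_d, v_d; inputs: p, pdot
    Ac <- matrix(c(0, 1, 0, 0,
                   -(kl + kn) / mb, -(cl + cn) / mb, kn / mb, cn / mb,
                   0, 0, 0, 1,
                   kn / mh, cn / mh, -kn / mh, -cn / mh),
                 4, 4, byrow = TRUE)
    Bc <- matrix(c(0, 0,
                   kl / mb, cl / mb,
                   0, 0,
                   0, 0), 4, 2, byrow = TRUE)
    # exact first-order hold: augment with the input and its (held) slope so
    # the matrix exponential yields x(k+1) = Ad x(k) + Bm u(k) + Bp u(k+1)
    Maug <- rbind(cbind(Ac, Bc, matrix(0, 4, 2)),
                  cbind(matrix(0, 2, 6), diag(2)),
                  matrix(0, 2, 8))
    Ed <- as.matrix(Matrix::expm(Matrix::Matrix(Maug * dt)))
    Ad <- Ed[1:4, 1:4, drop = FALSE]
    G1 <- Ed[1:4, 5:6, drop = FALSE]
    G2 <- Ed[1:4, 7:8, drop = FALSE]
    Bm <- G1 - G2 / dt
    Bp <- G2 / dt
    if (any(Mod(eigen(Ad, only.values = TRUE)$values) >= 1 - 1e-12)) {
      unstable <- TRUE
      warning("discrete chain has eigenvalue magnitude >= 1 on axis ", axes[a],
              "; response may not decay")
    }
    if (N > 0) {
      Cacc <- Ac[c(2, 4), , drop = FALSE]
      Dacc <- Bc[c(2, 4), , drop = FALSE]
      u <- cbind(protocol$platform_pos[, a], protocol$platform_vel[, a])
      u_next <- rbind(u[-1, , drop = FALSE], 0 * u[1, , drop = FALSE])
      y <- ss_output_cpp(Ad, cbind(Bm, Bp), Cacc,
                         cbind(Dacc, matrix(0, 2, 2)),
                         cbind(u, u_next), numeric(4))
      hip[, a] <- y[, 1]
      head_[, a] <- y[, 2]
    }
  }

  foot <- protocol$platform_acc
  meta <- list(radius_m = protocol$radius_m, n_moves = protocol$n_moves,
               neck_preset = params$neck_preset, params = params,
               protocol_seed = protocol$seed, unstable = unstable,
               noise_sd = 0)
  new_recording(rate, foot, hip, head_, meta)
}

#' Add independent Gaussian measurement noise to every channel
#'
#' @param recording A `perch_recording`.
#' @param noise_sd Noise standard deviation, m/s^2 (>= 0). Zero returns the
#'   input unchanged.
#' @param seed Integer seed for the noise stream.
#' @return A `perch_recording` with noisy traces; the noiseless originals are
#'   retained in `meta$noiseless`.
#' @export
add_sensor_noise <- function(recording, noise_sd, seed = 1L) {
  if (!inherits(recording, "perch_recording")) stop("recording must be a perch_recording")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop("noise_sd must be a non-negative number")
  if (noise_sd == 0) return(recording)
  set.seed(seed)
  out <- recording
  out$meta$noiseless <- recording[c("foot", "hip", "head")]
  for (ch in c("foot", "hip", "head")) {
    x <- recording[[ch]]
    out[[ch]] <- x + matrix(rnorm(length(x), sd = noise_sd), nrow(x), ncol(x),
                            dimnames = dimnames(x))
  }
  out$meta$noise_sd <- noise_sd
  out$meta$noise_seed <- seed
  out
}

#' The eight-trial grid: four sphere radii by two neck stiffnesses
#'
#' @return Data frame with columns `trial_label`, `radius_mm`, `neck_preset`.
#' @examples
#' trial_grid()
#' @export
trial_grid <- function() {
  g <- expand.grid(radius_mm = c(2, 5, 10, 20),
                   neck_preset = c("low", "high"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$trial_label <- sprintf("Trial_%s_%d",
                           ifelse(g$neck_preset == "low", "LS", "HS"),
                           g$radius_mm)
  g[, c("trial_label", "radius_mm", "neck_preset")]
}

parse_trial_label <- function(trial_label) {
  m <- regmatches(trial_label,
                  regexec("^Trial_(LS|HS)_([0-9]+)$", trial_label))[[1]]
  if (length(m) != 3)
    stop("trial_label must follow the Trial_{LS|HS}_{radius mm} scheme, got '",
         trial_label, "'")
  list(neck_preset = if (m[2] == "HS") "high" else "low",
       radius_m = as.numeric(m[3]) / 1000)
}

#' Simulate one full perturbation trial
#'
#' Composes [generate_protocol()], [simulate_chain()] and
#' [add_sensor_noise()]. A trial is identified either by a label following
#' the `Trial_{LS|HS}_{radius mm}` scheme (e.g. `"Trial_HS_20"`) or by
#' `radius_m` and `neck_preset` directly. One master `seed` is split
#' deterministically into independent protocol-direction and noise streams,
#' so identical arguments reproduce the recording bit for bit.
#'
#' @param trial_label Optional trial label; overrides `radius_m`/`neck_preset`.
#' @param radius_m Sphere radius, m.
#' @param neck_preset "low" or "high".
#' @param n_moves Number of displacements (default 3000, the full trial).
#' @param seed Master seed.
#' @param noise_sd Sensor noise SD, m/s^2.
#' @param move_duration_s,dwell_s,rate_hz Protocol timing, see
#'   [generate_protocol()].
#' @param params Optional [mechanical_params()]; defaults to the preset.
#' @return A `perch_recording` whose `meta` records everything needed to
#'   regenerate it.
#' @examples
#' rec <- run_trial("Trial_LS_2", n_moves = 10, seed = 7)
#' @export
run_trial <- function(trial_label = NULL, radius_m = NULL, neck_preset = NULL,
                      n_moves = 3000, seed = 1L, noise_sd = 0.05,
                      move_duration_s = 0.4, dwell_s = 0.1, rate_hz = 1000,
                      params = NULL) {
  if (!is.null(trial_label)) {
    parsed <- parse_trial_label(trial_label)
    radius_m <- parsed$radius_m
    neck_preset <- parsed$neck_preset
  }
  if (is.null(radius_m) || is.null(neck_preset))
    stop("either trial_label or both radius_m and neck_preset are required")
  if (!neck_preset %in% c("low", "high"))
    stop("unknown neck preset '", neck_preset, "' (expected 'low' or 'high')")
  if (is.null(params)) params <- mechanical_params(neck_preset)
  if (is.null(trial_label))
    trial_label <- sprintf("Trial_%s_%g",
                           if (neck_preset == "high") "HS" else "LS",
                           1000 * radius_m)

  set.seed(seed)
  streams <- sample.int(2147483646L, 2)
  pr <- generate_protocol(n_moves, radius_m, move_duration_s, dwell_s,
                          rate_hz, seed = streams[1])
  rec <- simulate_chain(pr, params)
  rec <- add_sensor_noise(rec, noise_sd, seed = streams[2])
  rec$meta$trial_label <- trial_label
  rec$meta$seed <- seed
  rec$meta$noise_sd <- noise_sd
  rec
}

#' @export
print.perch_recording <- function(x, ...) {
  N <- nrow(x$foot)
  cat(sprintf("Sensor recording%s: %d samples at %g Hz (%.1f s)\n",
              if (!is.null(x$meta$trial_label))
                paste0(" [", x$meta$trial_label, "]") else "",
              N, x$rate_hz, N / x$rate_hz))
  cat(sprintf("  channels: foot, hip, head (3-axis, m/s^2); noise sd %g\n",
              if (is.null(x$meta$noise_sd)) 0 else x$meta$noise_sd))
  invisible(x)
}

#' Extract a contiguous window of a recording
#'
#' @param recording A `perch_recording`.
#' @param start First sample index (1-based).
#' @param n Number of samples.
#' @return A `perch_recording` covering the window (time axis restarted at 0).
#' @export
window_recording <- function(recording, start, n) {
  N <- nrow(recording$foot)
  if (start < 1 || n < 1 || start + n - 1 > N)
    stop("window [", start, ", ", start + n - 1, "] outside recording of ", N,
         " samples")
  idx <- start + 0:(n - 1L)
  out <- recording
  for (ch in c("foot", "hip", "head"))
    out[[ch]] <- recording[[ch]][idx, , drop = FALSE]
  out$t <- (seq_len(n) - 1) / recording$rate_hz
  out$meta$window_start <- start
  out$meta$noiseless <- NULL
  out
}

#' Write / read a recording as CSV plus JSON sidecar metadata
#'
#' The CSV has the header
#' `time_s,foot_x,foot_y,foot_z,hip_x,hip_y,hip_z,head_x,head_y,head_z`
#' (SI units); `<path>.json` stores the trial metadata.
#'
#' @param recording A `perch_recording`.
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `perch_recording`.
#' @export
write_recording <- function(recording, path) {
  df <- data.frame(time_s = recording$t,
                   foot_x = recording$foot[, 1], foot_y = recording$foot[, 2],
                   foot_z = recording$foot[, 3],
                   hip_x = recording$hip[, 1], hip_y = recording$hip[, 2],
                   hip_z = recording$hip[, 3],
                   head_x = recording$head[, 1], head_y = recording$head[, 2],
                   head_z = recording$head[, 3])
  data.table::fwrite(df, path)
  meta <- recording$meta
  meta$noiseless <- NULL
  meta$params <- unclass(meta$params)
  jsonlite::write_json(c(list(rate_hz = recording$rate_hz), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("time_s", "foot_x", "foot_y", "foot_z", "hip_x", "hip_y", "hip_z",
            "head_x", "head_y", "head_z")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns: ", paste(need, collapse = ", "))
  side <- paste0(path, ".json")
  meta <- list()
  rate <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    rate <- meta$rate_hz
    meta$rate_hz <- NULL
  }
  if (is.null(rate)) {
    dtv <- diff(df$time_s)
    rate <- 1 / median(dtv)
  }
  axes <- c("x", "y", "z")
  grab <- function(pre) {
    m <- as.matrix(df[, paste0(pre, "_", axes)])
    dimnames(m) <- list(NULL, axes)
    m
  }
  new_recording(rate, grab("foot"), grab("hip"), grab("head"), as.list(meta))
}
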