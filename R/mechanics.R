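#' Lumped mechanical parameters of the perched body
#'
#' The body is modeled per axis as a serial two-mass chain: the platform
#' drives a leg stage (spring `k_leg`, damper `c_leg`) carrying the hip/torso
#' mass `m_body`, which drives a neck stage (`k_neck`, `c_neck`) carrying the
#' head mass `m_head`. Two named neck presets ("low", "high") mimic swapping
#' neck materials of different stiffness; the "high" preset is strictly
#' stiffer. Leg stiffness carries a per-axis asymmetry (the physical body is
#' only symmetric in the sagittal plane), so the lateral (x), fore-aft (y) and
#' vertical (z) axes respond slightly differently.
#'
#' Default magnitudes place the leg-stage body resonance near 6 Hz and the
#' neck-stage head resonance near 2.5 Hz (low preset) / 3.5 Hz (high preset),
#' with light neck damping so the head spectrum is dominated by the neck mode.
#'
#' @param neck_preset "low" or "high".
#' @param m_body Hip/torso lumped mass, kg.
#' @param m_head Head lumped mass, kg.
#' @param k_leg,c_leg Optional per-axis (length-3) leg stiffness (N/m) and
#'   damping (N s/m); derived from `k_leg_base`, `leg_axis_scale`, `zeta_leg`
#'   when NULL.
#' @param k_neck,c_neck Optional scalar neck stiffness (N/m) and damping
#'   (N s/m); derived from the preset when NULL.
#' @param k_leg_base Base leg stiffness before per-axis scaling, N/m.
#' @param zeta_leg,zeta_neck Damping ratios used to derive default dampers.
#' @param leg_axis_scale Per-axis multipliers on `k_leg_base` (x, y, z).
#' @param k_neck_low,k_neck_high Neck stiffness of the two presets, N/m.
#'
#' @return Object of class `perch_params`.
#' @examples
#' mechanical_params("high")$k_neck > mechanical_params("low")$k_neck
#' @export
mechanical_params <- function(neck_preset = c("low", "high"),
                              m_body = 1.3, m_head = 0.12,
                              k_leg = NULL, c_leg = NULL,
                              k_neck = NULL, c_neck = NULL,
                              k_leg_base = 1850, zeta_leg = 0.15,
                              leg_axis_scale = c(x = 0.8, y = 1.2, z = 1.0),
                              k_neck_low = 30, k_neck_high = 57,
                              zeta_neck = 0.15) {
  neck_preset <- match.arg(neck_preset)
  if (is.null(k_leg)) k_leg <- k_leg_base * leg_axis_scale
  k_leg <- rep_len(as.numeric(k_leg), 3)
  if (is.null(c_leg)) c_leg <- 2 * zeta_leg * sqrt(k_leg * m_body)
  c_leg <- rep_len(as.numeric(c_leg), 3)
  if (is.null(k_neck))
    k_neck <- if (neck_preset == "high") k_neck_high else k_neck_low
  if (is.null(c_neck)) c_neck <- 2 * zeta_neck * sqrt(k_neck * m_head)

  p <- structure(list(m_body = m_body, m_head = m_head,
                      k_leg = setNames(k_leg, c("x", "y", "z")),
                      c_leg = setNames(c_leg, c("x", "y", "z")),
                      k_neck = k_neck, c_neck = c_neck,
                      neck_preset = neck_preset),
                 class = "perch_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (!(p$m_body > 0) || !(p$m_head > 0))
    stop("masses must be positive")
  if (any(p$k_leg <= 0) || !(p$k_neck > 0))
    stop("stiffnesses must be positive")
  if (any(p$c_leg < 0) || p$c_neck < 0)
    stop("dampings must be non-negative")
  invisible(p)
}

#' @export
print.perch_params <- function(x, ...) {
  cat(sprintf("Perch mechanics (neck preset: %s)\n", x$neck_preset))
  cat(sprintf("  m_body %.3g kg, m_head %.3g kg\n", x$m_body, x$m_head))
  cat(sprintf("  k_leg [%s] N/m, c_leg [%s] N s/m\n",
              paste(signif(x$k_leg, 3), collapse = ", "),
              paste(signif(x$c_leg, 3), collapse = ", ")))
  cat(sprintf("  k_neck %.3g N/m, c_neck %.3g N s/m\n", x$k_neck, x$c_neck))
  invisible(x)
}
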