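#' Specification of a simulated nanoindentation force curve
#'
#' Bundles the ground-truth parameters of a Sneddon-type elastic indentation
#' curve for a sharp conical/pyramidal AFM tip: sample modulus and Poisson
#' ratio, tip half-angle, cantilever spring constant, contact point along the
#' piezo axis, maximum indentation depth, and the noise model (additive white
#' Gaussian force noise plus optional linear baseline drift).
#'
#' @param modulus_true True sample elastic modulus, Pa. Must be positive.
#' @param poisson_sample Sample Poisson ratio, in `[0, 0.5]`.
#' @param tip_half_angle Tip half-opening angle, degrees.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param contact_point Piezo position at which tip-sample contact begins, nm.
#' @param max_indentation Maximum indentation depth reached, nm (0 gives a
#'   flat, contact-free curve).
#' @param noise_sd Standard deviation of additive force noise, nN.
#' @param drift_slope Linear baseline drift on the force channel, nN per nm
#'   of piezo travel.
#' @param points_per_segment Samples per segment (approach and retract),
#'   at least 16.
#' @param seed Optional integer seed making the generated curve reproducible.
#' @return An object of class `curve_sim_spec`.
#' @seealso [generate_force_curve()]
#' @export
curve_sim_spec <- function(modulus_true,
                           poisson_sample = 0.5,
                           tip_half_angle = 35,
                           spring_constant = 0.24,
                           contact_point = 200,
                           max_indentation = 50,
                           noise_sd = 0,
                           drift_slope = 0,
                           points_per_segment = 512,
                           seed = NULL) {
  .assert_scalar(modulus_true, "modulus_true", lower = 0, allow_lower = FALSE)
  .assert_scalar(poisson_sample, "poisson_sample", lower = 0, upper = 0.5)
  .assert_scalar(tip_half_angle, "tip_half_angle", lower = 0, upper = 90,
                 allow_lower = FALSE, allow_upper = FALSE)
  .assert_scalar(spring_constant, "spring_constant", lower = 0,
                 allow_lower = FALSE)
  .assert_scalar(contact_point, "contact_point", lower = 0,
                 allow_lower = FALSE)
  .assert_scalar(max_indentation, "max_indentation", lower = 0)
  .assert_scalar(noise_sd, "noise_sd", lower = 0)
  .assert_scalar(drift_slope, "drift_slope")
  .assert_scalar(points_per_segment, "points_per_segment", lower = 16)
  if (!is.null(seed)) .assert_scalar(seed, "seed")
  structure(list(modulus_true = modulus_true,
                 poisson_sample = poisson_sample,
                 tip_half_angle = tip_half_angle,
                 spring_constant = spring_constant,
                 contact_point = contact_point,
                 max_indentation = max_indentation,
                 noise_sd = noise_sd,
                 drift_slope = drift_slope,
                 points_per_segment = as.integer(points_per_segment),
                 seed = seed),
            class = "curve_sim_spec")
}

# Sneddon cone force-law coefficient, nN/nm^2:
#   F = (2/pi) * tan(theta) * E/(1 - nu^2) * delta^2
# with E in Pa and delta in nm (1 Pa nm^2 = 1e-9 nN). The same geometric
# constant is assumed by the analyzer's ideal area function, so the forward
# model and the Oliver-Pharr chain form an exact round trip for epsilon =
# 2(pi-2)/pi.
.sneddon_coefficient <- function(modulus_true, poisson_sample,
                                 tip_half_angle) {
  (2 / pi) * tan(.deg2rad(tip_half_angle)) *
    modulus_true / (1 - poisson_sample^2) * 1e-9
}

#' Generate a synthetic AFM force-displacement curve
#'
#' Simulates the approach and retract segments of a cantilever-based
#' nanoindentation experiment on an elastic half-space indented by a sharp
#' cone. In contact, force follows the Sneddon law
#' \deqn{F = \frac{2}{\pi} \tan\theta \, \frac{E}{1-\nu^2}\, \delta^2,}
#' and the recorded deflection is obtained by solving the cantilever-sample
#' force balance \eqn{F(\delta) = k d} with \eqn{\delta = (z - z_0) - d},
#' so the piezo and deflection channels are mutually consistent with the
#' stated spring constant. Pre-contact force is zero-mean Gaussian noise plus
#' optional linear drift.
#'
#' @param spec A [curve_sim_spec()].
#' @return A [force_curve()] whose `truth` attribute records the generating
#'   parameters.
#' @examples
#' crv <- generate_force_curve(curve_sim_spec(1e9, seed = 1))
#' head(as.data.frame(crv))
#' @export
generate_force_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  k <- spec$spring_constant
  C <- .sneddon_coefficient(spec$modulus_true, spec$poisson_sample,
                            spec$tip_half_angle)
  z0 <- spec$contact_point
  dmax <- spec$max_indentation
  # deflection at full indentation; z range sized so delta_max is reached
  d_at_max <- C * dmax^2 / k
  z_max <- z0 + dmax + d_at_max
  n <- spec$points_per_segment
  z_app <- seq(0, z_max, length.out = n)
  deflect <- function(z) {
    u <- pmax(z - z0, 0)
    if (dmax == 0 || C == 0) return(rep(0, length(z)))
    # solve C (u - d)^2 = k d for the indentation delta = u - d
    delta <- (-k + sqrt(k^2 + 4 * C * k * u)) / (2 * C)
    u - delta
  }
  d_app <- deflect(z_app)
  z_ret <- rev(z_app)
  d_ret <- deflect(z_ret)
  z <- c(z_app, z_ret)
  d <- c(d_app, d_ret)
  if (spec$noise_sd > 0) {
    d <- d + stats::rnorm(length(d), sd = spec$noise_sd / k)
  }
  if (spec$drift_slope != 0) {
    d <- d + spec$drift_slope * z / k
  }
  segment <- rep(c("approach", "retract"), each = n)
  crv <- force_curve(z = z, deflection = d, segment = segment,
                     spring_constant = k)
  attr(crv, "truth") <- spec
  crv
}
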