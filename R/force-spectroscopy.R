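#' AFM force curve container
#'
#' Holds a raw force-displacement record: piezo displacement `z` (nm),
#' cantilever deflection (nm, or V with an `invOLS` to resolve), per-sample
#' segment labels and the attached calibration.
#'
#' @param z Piezo displacement series, nm.
#' @param deflection Deflection series, nm (or V if `deflection_unit = "V"`,
#'   resolved through `invOLS`).
#' @param segment Character vector of `"approach"`/`"retract"` labels, one
#'   per sample.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param medium Medium tag, e.g. `"air"`, `"PBS"`, `"EtOH25"`.
#' @param deflection_unit `"nm"` or `"V"`.
#' @param invOLS Inverse optical lever sensitivity, nm/V; required when
#'   `deflection_unit = "V"`.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, deflection, segment, spring_constant,
                        medium = "air", deflection_unit = c("nm", "V"),
                        invOLS = NULL) {
  deflection_unit <- match.arg(deflection_unit)
  if (length(z) != length(deflection) || length(z) != length(segment)) {
    stop("z, deflection and segment must have equal length", call. = FALSE)
  }
  if (!all(segment %in% c("approach", "retract"))) {
    stop("segment labels must be 'approach' or 'retract'", call. = FALSE)
  }
  .assert_scalar(spring_constant, "spring_constant", lower = 0,
                 allow_lower = FALSE)
  if (deflection_unit == "V") {
    if (is.null(invOLS)) stop("invOLS required for deflection in V",
                              call. = FALSE)
    deflection <- deflection * invOLS
    deflection_unit <- "nm"
  }
  for (seg in unique(segment)) {
    zz <- z[segment == seg]
    dz <- diff(zz)
    if (length(dz) && !(all(dz > 0) || all(dz < 0))) {
      stop("z must be strictly monotone within segment '", seg, "'",
           call. = FALSE)
    }
  }
  structure(list(z = as.numeric(z), deflection = as.numeric(deflection),
                 segment = as.character(segment),
                 spring_constant = spring_constant, medium = medium),
            class = "force_curve")
}

#' @export
as.data.frame.force_curve <- function(x, ...) {
  data.frame(z_nm = x$z, deflection_nm = x$deflection, segment = x$segment)
}

#' @export
print.force_curve <- function(x, ...) {
  cat("<force_curve> ", length(x$z), " samples (",
      sum(x$segment == "approach"), " approach), k = ",
      x$spring_constant, " N/m, medium = ", x$medium, "\n", sep = "")
  invisible(x)
}

#' Cantilever calibration record
#'
#' @param spring_constant Spring constant k, N/m.
#' @param invOLS Optional inverse optical lever sensitivity, nm/V.
#' @param temperature Temperature, K.
#' @param thermal_correction Dimensionless correction applied by the thermal
#'   method (default 0.971, first flexural mode of a rectangular lever).
#' @return An object of class `cantilever_calibration`.
#' @export
cantilever_calibration <- function(spring_constant, invOLS = NULL,
                                   temperature = 294,
                                   thermal_correction = 0.971) {
  .assert_scalar(spring_constant, "spring_constant", lower = 0,
                 allow_lower = FALSE)
  .assert_scalar(temperature, "temperature", lower = 0, allow_lower = FALSE)
  structure(list(spring_constant = spring_constant, invOLS = invOLS,
                 temperature = temperature,
                 thermal_correction = thermal_correction),
            class = "cantilever_calibration")
}

#' Thermal-noise spring constant calibration
#'
#' Equipartition estimate of the cantilever spring constant from the thermal
#' deflection noise: \eqn{k = \chi \, k_B T / \langle d^2 \rangle}, with
#' \eqn{\langle d^2 \rangle} the variance of the detrended deflection signal
#' and \eqn{\chi} a mode-shape correction (0.971 for the first flexural mode
#' of a rectangular lever).
#'
#' @param deflection_nm Detrended thermal deflection series, nm.
#' @param temperature Temperature, K.
#' @param correction Dimensionless correction factor.
#' @return Spring constant, N/m.
#' @examples
#' thermal_spring_constant(rnorm(1e4, sd = sqrt(1.69e-2)), 294, 1)
#' @export
thermal_spring_constant <- function(deflection_nm, temperature = 294,
                                    correction = 0.971) {
  .assert_scalar(temperature, "temperature", lower = 0, allow_lower = FALSE)
  v <- stats::var(deflection_nm)
  if (!is.finite(v) || v <= 0) {
    stop("deflection series has zero variance; cannot calibrate",
         call. = FALSE)
  }
  # var in nm^2 -> m^2
  correction * .kB * temperature / (v * 1e-18)
}

#' Locate the tip-sample contact point of a force curve
#'
#' Two-regime detection on the approach segment. The force record is split
#' at the index minimizing the combined residual sum of squares of a
#' straight baseline (pre-contact, captures offset and linear drift) and a
#' quadratic contact branch; the split is searched globally, so the method
#' does not assume any particular balance between free travel and contact
#' travel. The curve is declared contact-free when the baseline-corrected
#' force never sustains `threshold_sd` baseline residual SDs above zero.
#' The split estimate is refined by regressing \eqn{\sqrt{F}} on the tip
#' position \eqn{s = z - d} over the in-contact samples (linear for a
#' quadratic contact law) and extrapolating to zero force.
#'
#' @param curve A [force_curve()].
#' @param threshold_sd Contact/no-contact threshold in multiples of the
#'   baseline residual SD.
#' @param min_run Consecutive above-threshold samples required to call
#'   contact.
#' @return A list of class `contact_point` with elements `z0` (nm),
#'   `no_contact` flag, `baseline` (force-vs-z intercept/slope, nN and
#'   nN/nm) and `baseline_rms` (nN).
#' @export
find_contact_point <- function(curve, threshold_sd = 5, min_run = 3) {
  stopifnot(inherits(curve, "force_curve"))
  app <- curve$segment == "approach"
  z <- curve$z[app]; d <- curve$deflection[app]
  n <- length(z)
  if (n < 16) stop("approach segment too short", call. = FALSE)
  if (z[1] > z[n]) { z <- rev(z); d <- rev(d) }
  F <- curve$spring_constant * d
  # tip position: in contact the Sneddon force is exactly quadratic in s
  # with its vertex at the contact point, whatever the lever/sample
  # stiffness balance; pre-contact force is a line in z (offset + drift)
  s <- z - d
  # baseline drift is always small against the lever constant; bounding the
  # baseline slope keeps the line from absorbing the (nearly linear in z)
  # contact branch when the contact is much stiffer than the lever
  slope_max <- 0.05 * curve$spring_constant
  fit_model <- function(s0) {
    pre <- s < s0
    npre <- sum(pre)
    if (npre >= 2) {
      lf <- stats::lsfit(z[pre], F[pre])
      bl <- lf$coefficients
      if (abs(bl[2]) > slope_max) {
        bl[2] <- sign(bl[2]) * slope_max
        bl[1] <- mean(F[pre] - bl[2] * z[pre])
      }
      rss1 <- sum((F[pre] - bl[1] - bl[2] * z[pre])^2)
    } else {
      bl <- c(0, 0)
      rss1 <- 0
    }
    con <- which(!pre)
    rss2 <- 0
    C <- 0
    if (length(con) >= 3) {
      w <- (s[con] - s0)^2
      Fc <- F[con] - (bl[1] + bl[2] * z[con])
      denom <- sum(w^2)
      C <- if (denom > 0) max(sum(Fc * w) / denom, 0) else 0
      rss2 <- sum((Fc - C * w)^2)
    }
    list(rss = rss1 + rss2, baseline = as.numeric(bl), npre = npre,
         C = C)
  }
  # coarse grid over the interior of the tip-position range, then
  # golden-section refinement of the split
  srt <- sort(s)
  cand <- unique(stats::quantile(srt[4:(n - 3)],
                                 probs = seq(0, 1, length.out = 64),
                                 names = FALSE, type = 7))
  rss <- vapply(cand, function(s0) fit_model(s0)$rss, numeric(1))
  gr <- (sqrt(5) - 1) / 2
  golden <- function(lo, hi) {
    a1 <- hi - gr * (hi - lo); b1 <- lo + gr * (hi - lo)
    f1 <- fit_model(a1)$rss; f2 <- fit_model(b1)$rss
    for (it in 1:60) {
      if (hi - lo < 1e-6 * max(1, abs(hi))) break
      if (f1 <= f2) {
        hi <- b1; b1 <- a1; f2 <- f1
        a1 <- hi - gr * (hi - lo); f1 <- fit_model(a1)$rss
      } else {
        lo <- a1; a1 <- b1; f1 <- f2
        b1 <- lo + gr * (hi - lo); f2 <- fit_model(b1)$rss
      }
    }
    (lo + hi) / 2
  }
  # the objective can be multi-modal (a soft lever makes the contact
  # branch almost linear in z); refine the best few separated candidates
  # and keep the global winner
  ord <- order(rss)
  picks <- integer(0)
  for (j in ord) {
    if (all(abs(j - picks) > 1)) picks <- c(picks, j)
    if (length(picks) >= 4) break
  }
  s0 <- NA_real_; best_rss <- Inf
  for (i in picks) {
    lo <- cand[max(1, i - 1)]; hi <- cand[min(length(cand), i + 1)]
    cand_s0 <- golden(lo, hi)
    r <- fit_model(cand_s0)$rss
    if (r < best_rss) { best_rss <- r; s0 <- cand_s0 }
  }
  best <- fit_model(s0)
  bl <- best$baseline
  pre <- which(s < s0)
  Fc <- F - (bl[1] + bl[2] * z)
  rms <- if (length(pre) >= 2) sqrt(mean(Fc[pre]^2)) else 0
  # absolute floor keeps a zero-noise baseline from tripping on round-off
  thr <- max(threshold_sd * rms, 1e-9 * max(abs(F), 1))
  runs <- rle(Fc > thr)
  if (!any(runs$values & runs$lengths >= min_run)) {
    return(structure(list(z0 = NA_real_, no_contact = TRUE,
                          baseline = as.numeric(bl), baseline_rms = rms),
                     class = "contact_point"))
  }
  # at contact the deflection equals its baseline value, so the piezo
  # position equals the tip position there. The split fit works in tip
  # position (deflection-corrected, hence noisy); refine on the noise-free
  # piezo axis with the exact lever-contact model when possible.
  if (best$C > 0) {
    ref <- tryCatch(.sneddon_fit_z(z, F, curve$spring_constant, s0,
                                   best$C, bl),
                    error = function(e) NULL)
    if (!is.null(ref) && is.finite(ref$z0) &&
        abs(ref$z0 - s0) < 0.25 * diff(range(z))) {
      s0 <- ref$z0
    }
  }
  structure(list(z0 = as.numeric(s0), no_contact = FALSE,
                 baseline = as.numeric(bl), baseline_rms = rms),
            class = "contact_point")
}

#' Convert a force curve to force vs. tip-sample separation
#'
#' Applies the calibration and contact point: force \eqn{F = k (d -
#' d_{baseline})} and indentation \eqn{\delta = (z - z_0) - (d -
#' d_{baseline})}, the piezo travel corrected for cantilever bending.
#'
#' @param curve A [force_curve()].
#' @param z0 Contact point, nm (within the curve's z range).
#' @param baseline Optional numeric `c(intercept, slope)` of a force-vs-z
#'   baseline (nN, nN/nm) to subtract, e.g. from [find_contact_point()].
#' @param segment Which segment to convert.
#' @return A data frame with columns `delta_nm` and `force_nN`.
#' @export
to_force_and_separation <- function(curve, z0, baseline = c(0, 0),
                                    segment = "approach") {
  stopifnot(inherits(curve, "force_curve"))
  sel <- curve$segment == segment
  z <- curve$z[sel]; d <- curve$deflection[sel]
  if (z0 < min(z) || z0 > max(z)) {
    stop("z0 outside the curve's z range", call. = FALSE)
  }
  k <- curve$spring_constant
  F <- k * d - (baseline[1] + baseline[2] * z)
  d_corr <- F / k
  data.frame(delta_nm = (z - z0) - d_corr, force_nN = F)
}

# Stiffness fit on the piezo axis. The deflection noise enters the
# indentation as -noise/k, perfectly anticorrelated with the force noise;
# regressing force on that noisy indentation attenuates the slope
# (errors-in-variables), badly so for soft levers. Instead: fit F against
# the noise-free piezo position z, rebuild a smooth indentation
# delta = (z - z0) - (F_fit - baseline)/k from the fitted force, and run
# the quadratic force-indentation fit on that. For noiseless curves the
# rebuilt indentation equals the true one and the chain stays exact.
.stiffness_fit_z <- function(z, F, k, z0, baseline = c(0, 0),
                             fit_fraction = 1) {
  if (fit_fraction <= 0 || fit_fraction > 1) {
    stop("fit_fraction must be in (0, 1]", call. = FALSE)
  }
  Fc <- F - (baseline[1] + baseline[2] * z)
  delta_raw <- (z - z0) - Fc / k
  contact <- delta_raw > 0 & z > z0
  if (sum(contact) < 8) {
    stop("need at least 8 in-contact points", call. = FALSE)
  }
  zz <- z[contact]; ff <- Fc[contact]
  o <- order(zz); zz <- zz[o]; ff <- ff[o]
  sm <- stats::runmed(ff, k = min(7L, 2L * (length(ff) %/% 2L) - 1L))
  if (stats::cor(sm, zz) < 0.5) {
    stop("contact segment is not monotone after smoothing", call. = FALSE)
  }
  # initial smooth indentation from a cubic force-piezo fit
  Xg <- outer(zz - mean(zz), 1:3, `^`)
  d_hat <- (zz - z0) - stats::fitted(stats::lm(ff ~ Xg)) / k
  # self-consistent refinement: fit the quadratic force-indentation law,
  # then re-solve the lever equation k d = F(delta), delta = (z - z0) - d
  # for delta under the fitted law (closed form); exact at convergence for
  # a noiseless quadratic contact law
  cf <- NULL
  for (it in 1:4) {
    fit <- stats::lm(ff ~ d_hat + I(d_hat^2))
    cf <- stats::coef(fit)
    if (any(!is.finite(cf)) || cf[3] <= 0) break
    disc <- (cf[2] + k)^2 - 4 * cf[3] * (cf[1] - k * (zz - z0))
    if (any(disc < 0)) break
    d_new <- (-(cf[2] + k) + sqrt(disc)) / (2 * cf[3])
    if (max(abs(d_new - d_hat)) < 1e-10 * max(abs(d_hat))) {
      d_hat <- d_new
      break
    }
    d_hat <- d_new
  }
  dmax_all <- max(d_hat)
  lo <- dmax_all - fit_fraction * (dmax_all - min(d_hat))
  win <- d_hat >= lo
  if (sum(win) < 5) win <- seq_along(d_hat) > length(d_hat) - 8
  fit <- stats::lm(ff[win] ~ d_hat[win] + I(d_hat[win]^2))
  cf <- stats::coef(fit)
  dmax <- max(d_hat[win])
  S <- cf[2] + 2 * cf[3] * dmax
  if (!is.finite(S) || S <= 0) {
    stop("non-positive contact stiffness from fit", call. = FALSE)
  }
  P_max <- as.numeric(cf[1] + cf[2] * dmax + cf[3] * dmax^2)
  # residual contact-point offset: the fitted law's zero-force root; a
  # slightly early contact point shifts the whole indentation axis, which
  # this removes from the reported depth (slope and load are unaffected
  # by an axis shift)
  if (is.finite(cf[3]) && cf[3] > 0) {
    disc <- cf[2]^2 - 4 * cf[3] * cf[1]
    if (disc >= 0) {
      roots <- (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
      b <- roots[which.min(abs(roots))]
      if (is.finite(b) && abs(b) < 0.3 * dmax) dmax <- dmax - b
    }
  }
  res <- stats::residuals(fit)
  ss_tot <- sum((ff[win] - mean(ff[win]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  list(S_c = as.numeric(S), delta_max = dmax, P_max = P_max,
       r_squared = r2, residual_sd = stats::sd(res))
}

# Joint refinement of the contact point and the quadratic (sharp-cone)
# force law on the piezo axis: minimize RSS of the exact lever-contact
# model F(z) with F = C_f delta^2 and k d = F, delta = (z - s0) - d, over
# (C_f, s0). The abscissa is noise-free, the model exact, so the
# estimates are unbiased and minimum-variance for the Sneddon law; the
# Oliver-Pharr chain then consumes S_c = 2 C_f delta_max as usual.
.sneddon_fit_z <- function(z, F, k, z0_init, C_init, baseline = c(0, 0)) {
  Fc <- F - (baseline[1] + baseline[2] * z)
  spacing <- stats::median(abs(diff(z)))
  model_rss <- function(s0, Cc) {
    u <- pmax(z - s0, 0)
    delta <- (-k + sqrt(k^2 + 4 * Cc * k * u)) / (2 * Cc)
    sum((Fc - Cc * delta^2)^2)
  }
  prof_C <- function(s0) {
    stats::optimize(function(Cc) model_rss(s0, Cc),
                    interval = c(C_init / 10, C_init * 10),
                    tol = .Machine$double.eps^0.5)
  }
  s0_opt <- stats::optimize(function(s0) prof_C(s0)$objective,
                            interval = c(z0_init - 30 * spacing,
                                         z0_init + 30 * spacing),
                            tol = 1e-8 * max(1, abs(z0_init)))
  s0 <- s0_opt$minimum
  Cf <- prof_C(s0)$minimum
  u <- pmax(z - s0, 0)
  delta <- (-k + sqrt(k^2 + 4 * Cf * k * u)) / (2 * Cf)
  dmax <- max(delta)
  if (!is.finite(Cf) || Cf <= 0 || dmax <= 0) return(NULL)
  res <- Fc - Cf * delta^2
  con <- u > 0
  ss_tot <- sum((Fc[con] - mean(Fc[con]))^2)
  list(S_c = 2 * Cf * dmax, delta_max = dmax, P_max = Cf * dmax^2,
       z0 = s0,
       r_squared = if (ss_tot > 0) 1 - sum(res[con]^2) / ss_tot else 1,
       residual_sd = stats::sd(res[con]))
}

# Full stiffness fit diagnostics; exported wrapper below returns S_c.
.stiffness_fit <- function(delta, force, fit_fraction = 0.3) {
  if (fit_fraction <= 0 || fit_fraction > 1) {
    stop("fit_fraction must be in (0, 1]", call. = FALSE)
  }
  contact <- delta > 0
  if (sum(contact) < 8) {
    stop("need at least 8 in-contact points", call. = FALSE)
  }
  dl <- delta[contact]; fr <- force[contact]
  o <- order(dl); dl <- dl[o]; fr <- fr[o]
  # monotonicity after smoothing (running median) guards against
  # adhesive snap-ins and retract artefacts
  sm <- stats::runmed(fr, k = min(7L, 2L * (length(fr) %/% 2L) - 1L))
  if (stats::cor(sm, dl) < 0.5) {
    stop("contact segment is not monotone after smoothing", call. = FALSE)
  }
  dmax <- dl[length(dl)]
  lo <- dmax - fit_fraction * (dmax - dl[1])
  win <- dl >= lo
  if (sum(win) < 5) win <- seq_along(dl) > length(dl) - 8
  x <- dl[win]; y <- fr[win]
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  S <- cf[2] + 2 * cf[3] * dmax
  if (!is.finite(S) || S <= 0) {
    stop("non-positive contact stiffness from fit", call. = FALSE)
  }
  P_max <- as.numeric(cf[1] + cf[2] * dmax + cf[3] * dmax^2)
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  res_sd <- stats::sd(res)
  list(S_c = as.numeric(S), delta_max = dmax, P_max = P_max,
       r_squared = r2, residual_sd = res_sd)
}

#' Contact stiffness at maximum load
#'
#' Slope \eqn{S_c = dF/d\delta} at maximum load, from a quadratic polynomial
#' fitted over the top `fit_fraction` of the in-contact indentation range of
#' the loading segment.
#'
#' @param delta Indentation series, nm (in-contact where `delta > 0`).
#' @param force Force series, nN.
#' @param fit_fraction Fraction of the contact depth range (from maximum
#'   load downward) used in the fit.
#' @return Contact stiffness, N/m, with fit diagnostics (`delta_max`,
#'   `P_max`, `r_squared`, `residual_sd`) as attributes.
#' @examples
#' d <- seq(0, 100, length.out = 64); f <- 1e-3 * d^2
#' contact_stiffness(d, f)  # 2 * 1e-3 * 100 = 0.2 N/m
#' @export
contact_stiffness <- function(delta, force, fit_fraction = 0.3) {
  fit <- .stiffness_fit(delta, force, fit_fraction)
  structure(fit$S_c, delta_max = fit$delta_max, P_max = fit$P_max,
            r_squared = fit$r_squared, residual_sd = fit$residual_sd)
}

#' Oliver-Pharr contact depth
#'
#' \eqn{h_c = h_{max} - \epsilon P_{max} / S_c}. The geometry factor
#' \eqn{\epsilon} is 2(pi-2)/pi (~0.727) for a conical indenter; 0.75 is the
#' common paraboloid value.
#'
#' @param h_max Indentation depth at maximum load, nm.
#' @param P_max Maximum load, nN.
#' @param S_c Contact stiffness, N/m.
#' @param epsilon Geometry factor.
#' @return Contact depth, nm (clipped at 0 with a warning if negative).
#' @export
contact_depth <- function(h_max, P_max, S_c, epsilon = 2 * (pi - 2) / pi) {
  .assert_scalar(S_c, "S_c", lower = 0, allow_lower = FALSE)
  h_c <- h_max - epsilon * P_max / S_c
  if (h_c < 0) {
    warning("negative contact depth clipped to 0")
    h_c <- 0
  }
  h_c
}

#' Indenter projected area function
#'
#' Either the ideal sharp-cone geometry \eqn{A_c = \pi \tan^2\theta \,
#' h_c^2}, or a calibrated polynomial \eqn{A_c = C_0 h_c^2 + C_1 h_c + C_2
#' h_c^{1/2} + C_3 h_c^{1/4} + \dots} (Oliver-Pharr series).
#'
#' @param theta_deg Half-opening angle of the ideal tip, degrees.
#' @param coefficients Optional numeric vector `C0, C1, ...` switching to
#'   calibrated mode.
#' @return An object of class `tip_area_function`.
#' @export
tip_area_function <- function(theta_deg = 35, coefficients = NULL) {
  .assert_scalar(theta_deg, "theta_deg", lower = 0, upper = 90,
                 allow_lower = FALSE, allow_upper = FALSE)
  source <- if (is.null(coefficients)) "ideal-geometry" else "calibrated"
  structure(list(theta_deg = theta_deg, coefficients = coefficients,
                 source = source),
            class = "tip_area_function")
}

#' Projected contact area at a contact depth
#'
#' @param area_fn A [tip_area_function()].
#' @param h_c Contact depth, nm (non-negative).
#' @return Projected area, nm^2.
#' @examples
#' area_at_depth(tip_area_function(35), 20)  # pi tan(35 deg)^2 * 400
#' @export
area_at_depth <- function(area_fn, h_c) {
  stopifnot(inherits(area_fn, "tip_area_function"))
  if (any(h_c < 0)) stop("h_c must be non-negative", call. = FALSE)
  if (area_fn$source == "ideal-geometry") {
    return(pi * tan(.deg2rad(area_fn$theta_deg))^2 * h_c^2)
  }
  co <- area_fn$coefficients
  expo <- c(2, 1, 1 / 2, 1 / 4, 1 / 8, 1 / 16, 1 / 32, 1 / 64)
  if (length(co) > length(expo)) stop("too many area coefficients",
                                      call. = FALSE)
  A <- rowSums(outer(h_c, expo[seq_along(co)], `^`) *
                 rep(co, each = length(h_c)))
  if (any(A[h_c > 0] <= 0)) stop("area function non-positive at h_c > 0",
                                 call. = FALSE)
  A
}

#' Reduced modulus from stiffness and contact area
#'
#' \deqn{E_r = \frac{\sqrt{\pi}}{2\beta} \frac{S_c}{\sqrt{A_c}},}
#' with \eqn{\beta} a shape parameter close to unity (admissible range
#' 1.0226-1.085, or exactly 1 by the convention adopted here).
#'
#' @param S_c Contact stiffness, N/m.
#' @param A_c Projected contact area, nm^2.
#' @param beta Indenter shape parameter.
#' @return Reduced modulus, Pa.
#' @examples
#' reduced_modulus(0.2, 2450)  # ~3.58e6 Pa
#' @export
reduced_modulus <- function(S_c, A_c, beta = 1) {
  .assert_scalar(S_c, "S_c", lower = 0, allow_lower = FALSE)
  .assert_scalar(A_c, "A_c", lower = 0, allow_lower = FALSE)
  if (!(beta == 1 || (beta > 1.0226 && beta < 1.085))) {
    stop("beta must be 1 or within (1.0226, 1.085)", call. = FALSE)
  }
  sqrt(pi) / (2 * beta) * S_c / sqrt(A_c) * .N_PER_M_OVER_NM_TO_PA
}

#' Sample modulus from the reduced modulus
#'
#' Two elastic bodies in contact combine as \deqn{\frac{1}{E_r} =
#' \frac{1-\nu_{sample}^2}{E_{sample}} +
#' \frac{1-\nu_{indenter}^2}{E_{indenter}}.} When the indenter is far
#' stiffer than the sample (silicon tip, 169 GPa, vs. collagen at MPa-GPa),
#' the indenter term is negligible and the relation simplifies to
#' \eqn{E_{sample} = (1 - \nu_{sample}^2) E_r}.
#'
#' @param E_r Reduced modulus, Pa.
#' @param nu_sample Sample Poisson ratio, in `[0, 0.5]`.
#' @param mode `"simplified"` (rigid-indenter limit) or `"two_body"` (exact
#'   inversion).
#' @param E_indenter Indenter modulus, Pa (two-body mode).
#' @param nu_indenter Indenter Poisson ratio (two-body mode).
#' @return Sample modulus, Pa.
#' @examples
#' sample_modulus(4e6, 0.5)  # 3e6
#' @export
sample_modulus <- function(E_r, nu_sample = 0.5,
                           mode = c("simplified", "two_body"),
                           E_indenter = 169e9, nu_indenter = 0.27) {
  mode <- match.arg(mode)
  .assert_scalar(E_r, "E_r", lower = 0, allow_lower = FALSE)
  .assert_scalar(nu_sample, "nu_sample", lower = 0, upper = 0.5)
  if (mode == "simplified") {
    return((1 - nu_sample^2) * E_r)
  }
  .assert_scalar(E_indenter, "E_indenter", lower = 0, allow_lower = FALSE)
  inv <- 1 / E_r - (1 - nu_indenter^2) / E_indenter
  if (inv <= 0) {
    stop("E_r >= E_indenter/(1 - nu_indenter^2): non-physical input",
         call. = FALSE)
  }
  (1 - nu_sample^2) / inv
}

#' Analysis configuration for the contact-mechanics chain
#'
#' @param epsilon Contact-depth geometry factor (default conical,
#'   2(pi-2)/pi).
#' @param beta Indenter shape parameter in the reduced-modulus relation.
#' @param nu_sample Sample Poisson ratio.
#' @param mode Modulus inversion mode, see [sample_modulus()].
#' @param E_indenter,nu_indenter Indenter elastic constants (two-body mode).
#' @param fit_fraction Stiffness fit window, see [contact_stiffness()].
#'   The default uses the whole contact range: the sharp-cone law is
#'   globally quadratic, so the full range is the minimum-variance choice.
#' @param threshold_sd Contact-point detection threshold, see
#'   [find_contact_point()].
#' @param refine Jointly re-fit the contact point and the quadratic force
#'   law on the loading branch (exact-model refinement, recommended for
#'   sharp pyramidal/conical tips); the polynomial stiffness fit is the
#'   fallback.
#' @return A list of class `contact_config`.
#' @export
contact_config <- function(epsilon = 2 * (pi - 2) / pi, beta = 1,
                           nu_sample = 0.5,
                           mode = c("simplified", "two_body"),
                           E_indenter = 169e9, nu_indenter = 0.27,
                           fit_fraction = 1, threshold_sd = 5,
                           refine = TRUE) {
  mode <- match.arg(mode)
  structure(list(epsilon = epsilon, beta = beta, nu_sample = nu_sample,
                 mode = mode, E_indenter = E_indenter,
                 nu_indenter = nu_indenter, fit_fraction = fit_fraction,
                 threshold_sd = threshold_sd, refine = refine),
            class = "contact_config")
}

#' Analyze one force curve into an indentation modulus
#'
#' Runs the full contact-mechanics chain: contact-point detection, force /
#' separation conversion, contact stiffness at maximum load, contact depth,
#' projected area, reduced modulus and sample modulus. The result is termed
#' the *indentation modulus*: for a transversely isotropic fibril it mixes
#' transverse compressive and longitudinal tensile stiffness.
#'
#' @param curve A [force_curve()].
#' @param area_fn A [tip_area_function()]; default ideal 35 degree cone.
#' @param config A [contact_config()].
#' @return An object of class `contact_analysis` with all intermediate
#'   quantities, the configuration echo and a `valid` flag (FALSE when no
#'   contact was detected).
#' @examples
#' crv <- generate_force_curve(curve_sim_spec(1e9))
#' analyze_curve(crv)$E_sample_Pa
#' @export
analyze_curve <- function(curve, area_fn = tip_area_function(35),
                          config = contact_config()) {
  stopifnot(inherits(curve, "force_curve"))
  cp <- find_contact_point(curve, threshold_sd = config$threshold_sd)
  empty <- structure(list(valid = FALSE, no_contact = TRUE,
                          z0_nm = NA_real_, S_c_N_per_m = NA_real_,
                          P_max_nN = NA_real_, h_max_nm = NA_real_,
                          h_c_nm = NA_real_, A_c_nm2 = NA_real_,
                          E_r_Pa = NA_real_, E_sample_Pa = NA_real_,
                          epsilon = config$epsilon, beta = config$beta,
                          nu_sample = config$nu_sample,
                          nu_indenter = config$nu_indenter,
                          E_indenter_Pa = config$E_indenter,
                          r_squared = NA_real_, residual_sd = NA_real_,
                          baseline_rms_nN = cp$baseline_rms,
                          medium = curve$medium),
                     class = "contact_analysis")
  if (cp$no_contact) return(empty)
  res <- tryCatch({
    app <- curve$segment == "approach"
    k <- curve$spring_constant
    fit <- .stiffness_fit_z(curve$z[app], k * curve$deflection[app],
                            k, cp$z0, cp$baseline, config$fit_fraction)
    z0_used <- cp$z0
    if (isTRUE(config$refine)) {
      ref <- .sneddon_fit_z(curve$z[app], k * curve$deflection[app], k,
                            cp$z0, fit$S_c / (2 * fit$delta_max),
                            cp$baseline)
      if (!is.null(ref)) {
        z0_used <- ref$z0
        fit <- ref[c("S_c", "delta_max", "P_max", "r_squared",
                     "residual_sd")]
      }
    }
    h_max <- fit$delta_max
    h_c <- suppressWarnings(
      contact_depth(h_max, fit$P_max, fit$S_c, config$epsilon))
    if (h_c <= 0) stop("degenerate contact depth")
    A_c <- area_at_depth(area_fn, h_c)
    E_r <- reduced_modulus(fit$S_c, A_c, config$beta)
    E_s <- sample_modulus(E_r, config$nu_sample, config$mode,
                          config$E_indenter, config$nu_indenter)
    list(fit = fit, h_max = h_max, h_c = h_c, A_c = A_c,
         E_r = E_r, E_s = E_s, z0_used = z0_used)
  }, error = function(e) NULL)
  if (is.null(res)) return(empty)
  fit <- res$fit; h_max <- res$h_max; h_c <- res$h_c
  A_c <- res$A_c; E_r <- res$E_r; E_s <- res$E_s
  structure(list(valid = TRUE, no_contact = FALSE,
                 z0_nm = res$z0_used, S_c_N_per_m = fit$S_c,
                 P_max_nN = fit$P_max, h_max_nm = h_max, h_c_nm = h_c,
                 A_c_nm2 = A_c, E_r_Pa = E_r, E_sample_Pa = E_s,
                 epsilon = config$epsilon, beta = config$beta,
                 nu_sample = config$nu_sample,
                 nu_indenter = config$nu_indenter,
                 E_indenter_Pa = config$E_indenter,
                 r_squared = fit$r_squared, residual_sd = fit$residual_sd,
                 baseline_rms_nN = cp$baseline_rms,
                 medium = curve$medium),
            class = "contact_analysis")
}

#' @export
print.contact_analysis <- function(x, ...) {
  if (!x$valid) {
    cat("<contact_analysis> no contact detected\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<contact_analysis> E_sample = %.4g Pa (E_r = %.4g Pa)\n  S_c = %.4g N/m, h_c = %.4g nm, A_c = %.4g nm^2, R^2 = %.4f\n",
    x$E_sample_Pa, x$E_r_Pa, x$S_c_N_per_m, x$h_c_nm, x$A_c_nm2,
    x$r_squared))
  invisible(x)
}

#' Analyze a batch of force curves
#'
#' @param curves List of [force_curve()] objects.
#' @param area_fn,config Passed to [analyze_curve()].
#' @return A data frame with one row per curve (all `contact_analysis`
#'   scalar fields); invalid (no-contact) curves are flagged, not dropped.
#' @export
analyze_curves <- function(curves, area_fn = tip_area_function(35),
                           config = contact_config()) {
  rows <- lapply(curves, function(crv) {
    a <- analyze_curve(crv, area_fn, config)
    as.data.frame(a[!vapply(a, is.null, logical(1))])
  })
  out <- do.call(rbind, rows)
  out <- cbind(curve_id = seq_along(curves), out)
  rownames(out) <- NULL
  out
}
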