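# Internal helpers shared across modules.

# Boltzmann constant, J/K
.kB <- 1.380649e-23

# Conversion: S_c [N/m] / sqrt(A_c [nm^2]) -> Pa requires 1e9
# (1 N/m / 1 nm = 1e9 N/m^2).
.N_PER_M_OVER_NM_TO_PA <- 1e9

.assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                           allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  ok_lo <- if (allow_lower) x >= lower else x > lower
  ok_hi <- if (allow_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi) {
    stop(sprintf("'%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

.deg2rad <- function(deg) deg * pi / 180

# Least-absolute-deviations straight line fit y ~ a + b x.
# Two-parameter Nelder-Mead started from the least-squares solution; robust
# against the fibril flanks leaking into nominal substrate regions.
.lad_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  ls <- stats::lsfit(x, y)
  start <- ls$coefficients
  if (any(!is.finite(start))) start <- c(stats::median(y), 0)
  obj <- function(p) sum(abs(y - p[1] - p[2] * x))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  coef <- fit$par
  names(coef) <- c("intercept", "slope")
  coef
}

# Parabolic (three-point) refinement of a discrete peak location.
# Returns fractional offset in [-0.5, 0.5] relative to the centre sample.
.parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || denom == 0) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, off))
}

# Bilinear interpolation of a matrix at fractional (row, col) positions,
# 0-based pixel-centre coordinates. Out-of-range positions return NA.
.bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(row))
  ok <- row >= 0 & row <= nr - 1 & col >= 0 & col <= nc - 1
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  out[ok] <- (1 - fr) * (1 - fc) * m[i00] + (1 - fr) * fc * m[i01] +
    fr * (1 - fc) * m[i10] + fr * fc * m[i11]
  out
}

# Derive a reproducible stream seed from a master seed; kept < 2^31.
.derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}
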