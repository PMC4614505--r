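#' Triclinic unit cell
#'
#' Crystallographic cell with edges `a`, `b`, `c` (Angstrom) and angles
#' `alpha`, `beta`, `gamma` (degrees). The collagen microfibril packs into
#' such a cell (about 40.0 x 27.0 x 678 Angstrom, 89.2/94.6/105.6 degrees
#' for the in-situ type I structure, PDB 3HR2).
#'
#' @param a,b,c Cell edges, Angstrom (positive).
#' @param alpha,beta,gamma Cell angles, degrees, each in (0, 180).
#' @return An object of class `triclinic_cell`.
#' @export
triclinic_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  for (nm in c("a", "b", "c")) {
    .assert_scalar(get(nm), nm, lower = 0, allow_lower = FALSE)
  }
  for (nm in c("alpha", "beta", "gamma")) {
    .assert_scalar(get(nm), nm, lower = 0, upper = 180,
                   allow_lower = FALSE, allow_upper = FALSE)
  }
  ca <- cos(.deg2rad(alpha)); cb <- cos(.deg2rad(beta))
  cg <- cos(.deg2rad(gamma))
  rad <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (rad <= 0) {
    stop("angles do not define a positive-definite cell metric",
         call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma),
            class = "triclinic_cell")
}

#' Lattice vectors of a triclinic cell
#'
#' Standard Cartesian construction: `a` along x, `b` in the xy-plane.
#'
#' @param cell A [triclinic_cell()].
#' @return A 3x3 matrix with lattice vectors as rows, Angstrom.
#' @export
lattice_vectors <- function(cell) {
  stopifnot(inherits(cell, "triclinic_cell"))
  ca <- cos(.deg2rad(cell$alpha)); cb <- cos(.deg2rad(cell$beta))
  cg <- cos(.deg2rad(cell$gamma)); sg <- sin(.deg2rad(cell$gamma))
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  rbind(a = c(cell$a, 0, 0),
        b = c(cell$b * cg, cell$b * sg, 0),
        c = c(cell$c * cb, cell$c * (ca - cb * cg) / sg,
              cell$c * v / sg))
}

#' Triclinic cell volume
#'
#' \deqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#' 2\cos\alpha\cos\beta\cos\gamma}.}
#'
#' @param cell A [triclinic_cell()].
#' @return Volume, cubic Angstrom.
#' @examples
#' cell_volume(triclinic_cell(40, 27, 678, 89.2, 94.6, 105.6))
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "triclinic_cell"))
  ca <- cos(.deg2rad(cell$alpha)); cb <- cos(.deg2rad(cell$beta))
  cg <- cos(.deg2rad(cell$gamma))
  cell$a * cell$b * cell$c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Mass of a collagen trimer from its chain composition
#'
#' Collagen I is a trimer: heterotrimeric (wild-type) molecules carry two
#' alpha1(I) and one alpha2(I) chain, homotrimeric (oim) molecules three
#' alpha1(I) chains.
#'
#' @param chain_masses Named numeric vector of chain masses, kDa.
#' @param stoichiometry Named integer vector of per-trimer chain counts
#'   (same names); must sum to 3.
#' @return Trimer mass, kDa.
#' @examples
#' trimer_mass(c(a1 = 138.032, a2 = 129.557), c(a1 = 2, a2 = 1))  # 405.621
#' @export
trimer_mass <- function(chain_masses, stoichiometry) {
  if (is.null(names(chain_masses)) || is.null(names(stoichiometry))) {
    stop("chain_masses and stoichiometry must be named", call. = FALSE)
  }
  if (!all(names(stoichiometry) %in% names(chain_masses))) {
    stop("stoichiometry names missing from chain_masses", call. = FALSE)
  }
  if (any(chain_masses <= 0)) stop("chain masses must be positive",
                                   call. = FALSE)
  if (sum(stoichiometry) != 3) {
    stop("a collagen trimer has exactly 3 chains", call. = FALSE)
  }
  sum(stoichiometry * chain_masses[names(stoichiometry)])
}

#' Density ratio between two unit cells
#'
#' Ratio of mass densities \eqn{(m_x/V_x) / (m_{ref}/V_{ref})}, with the
#' percent deficit \eqn{(1 - ratio) \times 100} reported when the ratio is
#' below 1 (and the percent excess otherwise).
#'
#' @param mass_x,vol_x Mass (kDa) and volume (cubic Angstrom) of the cell
#'   of interest.
#' @param mass_ref,vol_ref Mass and volume of the reference cell.
#' @return List with `ratio` and `percent_difference` (positive = lower
#'   density than the reference).
#' @examples
#' density_ratio(1, 1.14, 1, 1)  # 12.3% lower at equal mass
#' @export
density_ratio <- function(mass_x, vol_x, mass_ref, vol_ref) {
  for (nm in c("mass_x", "vol_x", "mass_ref", "vol_ref")) {
    .assert_scalar(get(nm), nm, lower = 0, allow_lower = FALSE)
  }
  ratio <- (mass_x / vol_x) / (mass_ref / vol_ref)
  pct <- if (ratio < 1) (1 - ratio) * 100 else -(ratio - 1) * 100
  list(ratio = ratio, percent_difference = pct)
}

#' Signed percent difference relative to a reference
#'
#' \eqn{(ref - x)/ref \times 100}: positive when `x` is below the
#' reference.
#'
#' @param x Value of interest.
#' @param ref Reference value (non-zero).
#' @return Signed percent difference.
#' @examples
#' percent_difference(5.3, 7.9)   # ~33% lower
#' percent_difference(0.79, 1.05) # ~25% lower
#' @export
percent_difference <- function(x, ref) {
  if (any(ref == 0)) stop("reference must be non-zero", call. = FALSE)
  (ref - x) / ref * 100
}

#' Fit a polynomial stress-strain law
#'
#' Least-squares polynomial \eqn{\sigma(\epsilon)} of the requested degree,
#' optionally constrained through the origin.
#'
#' @param strain Strain responses, dimensionless.
#' @param stress Applied stress levels, Pa (distinct).
#' @param degree Polynomial degree; needs at least `degree + 1` points.
#' @param through_origin Force a zero intercept.
#' @return An object of class `stress_strain_fit`: coefficients `c0..cd`
#'   (ascending powers), degree, and the fitted strain/stress ranges.
#' @export
fit_stress_strain <- function(strain, stress, degree = 2,
                              through_origin = FALSE) {
  if (length(strain) != length(stress)) {
    stop("strain and stress must have equal length", call. = FALSE)
  }
  if (anyDuplicated(stress)) stop("stress levels must be distinct",
                                  call. = FALSE)
  if (length(strain) < degree + 1) {
    stop("need at least degree + 1 points", call. = FALSE)
  }
  if (through_origin) {
    X <- outer(strain, seq_len(degree), `^`)
    cf <- stats::lsfit(X, stress, intercept = FALSE)$coefficients
    coef <- c(0, cf)
  } else {
    X <- outer(strain, seq_len(degree), `^`)
    cf <- stats::lsfit(X, stress)$coefficients
    coef <- cf
  }
  names(coef) <- paste0("c", 0:degree)
  structure(list(coefficients = as.numeric(coef), degree = degree,
                 strain_range = range(strain),
                 stress_range = range(stress)),
            class = "stress_strain_fit")
}

.poly_eval <- function(coef, x) {
  drop(outer(x, seq_along(coef) - 1, `^`) %*% coef)
}

.poly_deriv_eval <- function(coef, x) {
  if (length(coef) < 2) return(rep(0, length(x)))
  dcoef <- coef[-1] * seq_len(length(coef) - 1)
  drop(outer(x, seq_along(dcoef) - 1, `^`) %*% dcoef)
}

#' Tangent modulus of a stress-strain law at a stress level
#'
#' Solves \eqn{\sigma(\epsilon^*) = \sigma_{level}} by bisection on the
#' monotone fitted interval and returns the slope \eqn{d\sigma/d\epsilon}
#' there — the tangent (transverse elastic) modulus at that stress.
#'
#' @param fit A [fit_stress_strain()] result, or a numeric coefficient
#'   vector `c0, c1, ...` (ascending powers; then supply `strain_range`).
#' @param stress_level Stress level, Pa, inside the fitted stress range.
#' @param strain_range Solve interval when `fit` is a bare coefficient
#'   vector.
#' @return Tangent modulus, Pa.
#' @examples
#' f <- fit_stress_strain(c(0, 0.05, 0.1, 0.2), 2e9 * c(0, 0.05, 0.1, 0.2), 1)
#' tangent_modulus(f, 1e8)  # 2e9
#' @export
tangent_modulus <- function(fit, stress_level, strain_range = NULL) {
  if (inherits(fit, "stress_strain_fit")) {
    coef <- fit$coefficients
    rng <- fit$strain_range
  } else {
    coef <- as.numeric(fit)
    if (is.null(strain_range)) {
      stop("strain_range required with bare coefficients", call. = FALSE)
    }
    rng <- sort(strain_range)
  }
  grid <- seq(rng[1], rng[2], length.out = 257)
  sig <- .poly_eval(coef, grid)
  if (any(diff(sig) <= 0)) {
    stop("sigma(epsilon) is not strictly increasing over the fitted range",
         call. = FALSE)
  }
  if (stress_level < min(sig) || stress_level > max(sig)) {
    stop(sprintf(
      "stress_level %g outside the fitted stress range [%g, %g]",
      stress_level, min(sig), max(sig)), call. = FALSE)
  }
  lo <- rng[1]; hi <- rng[2]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (.poly_eval(coef, mid) < stress_level) lo <- mid else hi <- mid
    if (hi - lo < 1e-14 * max(1, abs(hi))) break
  }
  eps_star <- (lo + hi) / 2
  .poly_deriv_eval(coef, eps_star)
}
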