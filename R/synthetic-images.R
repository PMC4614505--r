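#' Specification of a synthetic D-banded fibril topography
#'
#' Parameters of a simulated AFM height image containing a single collagen
#' fibril on a near-flat substrate: dry crest height, hydration swelling
#' fold, axial D-band period and relative band amplitude, apparent width,
#' pixel calibration, substrate roughness and optional tip dilation.
#'
#' @param height_dry Dry-state crest height above the substrate, nm.
#' @param swelling_true Ground-truth fold increase in height upon hydration
#'   (wet height = `height_dry * swelling_true`); at least 1.
#' @param d_period Axial banding period, nm. Must exceed `2 * pixel_size`
#'   (Nyquist).
#' @param band_amplitude_frac Amplitude of the axial height modulation as a
#'   fraction of local height, in `[0, 0.5]`.
#' @param fibril_width Apparent (full) width of the fibril cross-section, nm.
#' @param pixel_size Lateral calibration, nm per pixel.
#' @param image_shape Integer `c(rows, cols)` of the height grid.
#' @param substrate_roughness_sd Gaussian substrate roughness, nm.
#' @param tip_radius Tip radius for grayscale dilation, nm; 0 disables
#'   dilation.
#' @param angle_deg In-plane angle between the fibril axis and the image
#'   rows (0 = fibril runs along columns).
#' @param seed Optional integer seed.
#' @return An object of class `fibril_image_spec`.
#' @seealso [generate_fibril_image()]
#' @export
fibril_image_spec <- function(height_dry = 26,
                              swelling_true = 2.6,
                              d_period = 67,
                              band_amplitude_frac = 0.1,
                              fibril_width = 100,
                              pixel_size = 2,
                              image_shape = c(128, 320),
                              substrate_roughness_sd = 0.2,
                              tip_radius = 0,
                              angle_deg = 0,
                              seed = NULL) {
  .assert_scalar(height_dry, "height_dry", lower = 0, allow_lower = FALSE)
  .assert_scalar(swelling_true, "swelling_true", lower = 1)
  .assert_scalar(pixel_size, "pixel_size", lower = 0, allow_lower = FALSE)
  .assert_scalar(d_period, "d_period", lower = 2 * pixel_size,
                 allow_lower = FALSE)
  .assert_scalar(band_amplitude_frac, "band_amplitude_frac",
                 lower = 0, upper = 0.5)
  .assert_scalar(fibril_width, "fibril_width", lower = 0, allow_lower = FALSE)
  .assert_scalar(substrate_roughness_sd, "substrate_roughness_sd", lower = 0)
  .assert_scalar(tip_radius, "tip_radius", lower = 0)
  .assert_scalar(angle_deg, "angle_deg")
  if (length(image_shape) != 2L || any(image_shape < 8)) {
    stop("'image_shape' must be c(rows, cols) with both >= 8", call. = FALSE)
  }
  # the perpendicular field of view must hold the fibril plus flanking
  # substrate on both sides (baseline fitting needs the flanks)
  if (min(image_shape) * pixel_size < 2.5 * fibril_width) {
    stop("image too small to contain the fibril and flanking substrate",
         call. = FALSE)
  }
  if (!is.null(seed)) .assert_scalar(seed, "seed")
  structure(list(height_dry = height_dry, swelling_true = swelling_true,
                 d_period = d_period,
                 band_amplitude_frac = band_amplitude_frac,
                 fibril_width = fibril_width, pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 substrate_roughness_sd = substrate_roughness_sd,
                 tip_radius = tip_radius, angle_deg = angle_deg,
                 seed = seed),
            class = "fibril_image_spec")
}

# Grayscale dilation with a spherical-cap structuring element: the standard
# surrogate for AFM tip convolution. dilated(x) = max_u [ s(x+u) - t(u) ],
# t(u) = R - sqrt(R^2 - |u|^2) the tip surface about its apex.
.tip_dilate <- function(heights, tip_radius, pixel_size) {
  r_px <- floor(tip_radius / pixel_size)
  if (r_px < 1) return(heights)
  off <- -r_px:r_px
  grid <- expand.grid(dr = off, dc = off)
  dist2 <- (grid$dr^2 + grid$dc^2) * pixel_size^2
  keep <- dist2 <= tip_radius^2
  grid <- grid[keep, ]
  tip <- tip_radius - sqrt(tip_radius^2 - dist2[keep])
  nr <- nrow(heights); nc <- ncol(heights)
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(nrow(grid))) {
    dr <- grid$dr[i]; dc <- grid$dc[i]
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- pmax(out[rs, cs], heights[rs + dr, cs + dc] - tip[i])
  }
  out
}

#' Generate a synthetic fibril height image
#'
#' Renders one straight collagen fibril on a rough flat substrate. The
#' cross-section is a circular-segment cap of full width `fibril_width` and
#' crest height `height_dry` (dry) or `height_dry * swelling_true` (wet);
#' the height is modulated axially by a sinusoid of period `d_period`
#' emulating the D-banding. When `tip_radius > 0` the surface is dilated
#' with a spherical-cap structuring element (tip convolution surrogate).
#'
#' @param spec A [fibril_image_spec()].
#' @param state `"dry"` or `"wet"`.
#' @return A [topography_image()]; its `truth` attribute stores the spec and
#'   the rendered crest height.
#' @examples
#' img <- generate_fibril_image(fibril_image_spec(seed = 1), "dry")
#' dim(img$heights)
#' @export
generate_fibril_image <- function(spec, state = c("dry", "wet")) {
  stopifnot(inherits(spec, "fibril_image_spec"))
  state <- match.arg(state)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  px <- spec$pixel_size
  h_peak <- if (state == "wet") spec$height_dry * spec$swelling_true
            else spec$height_dry
  # physical coordinates of pixel centres (0-based convention)
  rows <- (seq_len(nr) - 1) * px
  cols <- (seq_len(nc) - 1) * px
  rc <- outer(rows, rep(1, nc))
  cc <- outer(rep(1, nr), cols)
  th <- .deg2rad(spec$angle_deg)
  # centre the fibril on a pixel centre so the crest is sampled exactly
  r0 <- rows[(nr + 1) %/% 2]; c0 <- cols[(nc + 1) %/% 2]
  # axial coordinate s along the fibril, perpendicular offset u
  s <- (cc - c0) * cos(th) + (rc - r0) * sin(th)
  u <- -(cc - c0) * sin(th) + (rc - r0) * cos(th)
  w2 <- spec$fibril_width / 2
  core <- 1 - (u / w2)^2
  core[core < 0] <- 0
  profile <- h_peak * sqrt(core)
  band <- 1 + spec$band_amplitude_frac * sin(2 * pi * s / spec$d_period)
  heights <- profile * band
  if (spec$substrate_roughness_sd > 0) {
    heights <- heights +
      matrix(stats::rnorm(nr * nc, sd = spec$substrate_roughness_sd), nr, nc)
  }
  if (spec$tip_radius > 0) {
    heights <- .tip_dilate(heights, spec$tip_radius, px)
  }
  img <- topography_image(heights, pixel_size = px, state = state,
                          medium = if (state == "wet") "PBS" else "air")
  attr(img, "truth") <- list(spec = spec, state = state,
                             crest_height = h_peak)
  img
}
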