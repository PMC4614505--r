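#' AFM height image container
#'
#' @param heights Numeric matrix of heights, nm; row-major grid with origin
#'   at top-left, heights positive-up. All values must be finite.
#' @param pixel_size Lateral calibration, nm per pixel.
#' @param state State tag, e.g. `"dry"` or `"wet"`.
#' @param medium Imaging medium tag.
#' @param meta Optional list of acquisition metadata.
#' @return An object of class `topography_image`.
#' @export
topography_image <- function(heights, pixel_size, state = "dry",
                             medium = "air", meta = list()) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop("heights must be finite",
                                     call. = FALSE)
  .assert_scalar(pixel_size, "pixel_size", lower = 0, allow_lower = FALSE)
  structure(list(heights = heights, pixel_size = pixel_size,
                 state = state, medium = medium, meta = meta),
            class = "topography_image")
}

#' @export
print.topography_image <- function(x, ...) {
  cat(sprintf(
    "<topography_image> %d x %d px @ %g nm/px (%s, %s), range %.2f..%.2f nm\n",
    nrow(x$heights), ncol(x$heights), x$pixel_size, x$state, x$medium,
    min(x$heights), max(x$heights)))
  invisible(x)
}

#' Trace the crest polyline of a fibril in a height image
#'
#' Detects a single ridge-like object: pixels well above the substrate
#' level are segmented, their principal axis (height-weighted PCA of pixel
#' coordinates) defines the fibril direction, and at unit-pixel stations
#' along that axis the crest is located as the maximum of the perpendicular
#' interpolated profile with sub-pixel parabolic refinement.
#'
#' @param image A [topography_image()].
#' @param min_prominence Minimum ridge prominence above the substrate,
#'   expressed as a multiple of the robust substrate spread (MAD); below it
#'   no ridge is reported.
#' @return A data frame of class `fibril_axis` with 0-based fractional
#'   pixel coordinates `row`, `col` and the axial position `s_nm`; zero
#'   rows when no ridge is found.
#' @export
trace_fibril_axis <- function(image, min_prominence = 10) {
  stopifnot(inherits(image, "topography_image"))
  h0 <- image$heights
  # robust plane flattening: fit on substrate-dominated (below-median)
  # pixels, twice, so a tilted or offset substrate does not mask the ridge
  nr <- nrow(h0); nc <- ncol(h0)
  rr <- as.vector(row(h0)); cc <- as.vector(col(h0)); hv <- as.vector(h0)
  sel <- hv <= stats::median(hv)
  for (it in 1:2) {
    cf <- stats::lsfit(cbind(rr[sel], cc[sel]), hv[sel])$coefficients
    resid <- hv - (cf[1] + cf[2] * rr + cf[3] * cc)
    sel <- resid <= stats::median(resid) + 2 * stats::mad(resid)
    if (sum(sel) < 16) break
  }
  h <- matrix(resid, nr, nc)
  base <- stats::median(h)
  # substrate spread from the below-median half (the ridge sits above)
  spread <- stats::mad(h[h <= base])
  amp <- max(h) - base
  empty <- structure(data.frame(row = numeric(0), col = numeric(0),
                                s_nm = numeric(0)),
                     class = c("fibril_axis", "data.frame"))
  if (amp <= 0 || (spread > 0 && amp < min_prominence * spread)) {
    return(empty)
  }
  mask <- h > base + 0.5 * amp
  if (sum(mask) < 8) return(empty)
  idx <- which(mask, arr.ind = TRUE)
  # 0-based pixel-centre coordinates, height-weighted PCA
  pts <- cbind(idx[, 1] - 1, idx[, 2] - 1)
  w <- h[mask] - base
  w <- w / sum(w)
  ctr <- colSums(pts * w)
  cen <- sweep(pts, 2, ctr)
  cov <- crossprod(cen * sqrt(w))
  ev <- eigen(cov, symmetric = TRUE)
  dir <- ev$vectors[, 1]            # axial unit vector (row, col)
  nrm <- c(-dir[2], dir[1])         # perpendicular
  t_ax <- cen %*% dir
  u_ax <- cen %*% nrm
  half_w <- max(abs(u_ax)) + 2
  stations <- seq(ceiling(min(t_ax)), floor(max(t_ax)), by = 1)
  ugrid <- seq(-half_w, half_w, by = 0.5)
  crest <- lapply(stations, function(t) {
    p0 <- ctr + t * dir
    rr <- p0[1] + ugrid * nrm[1]
    cc <- p0[2] + ugrid * nrm[2]
    prof <- .bilinear(h, rr, cc)
    ok <- is.finite(prof)
    if (sum(ok) < 5) return(NULL)
    prof <- prof[ok]; rr <- rr[ok]; cc <- cc[ok]
    i <- which.max(prof)
    if (prof[i] < base + 0.5 * amp) return(NULL)
    # a maximum at the window edge means the crest is clipped by the
    # image boundary (fibril running out of the corner): not a crest
    if (i <= 2 || i >= length(prof) - 1) return(NULL)
    off <- .parabolic_offset(prof[i - 1], prof[i], prof[i + 1])
    # neighbouring u samples are 0.5 px apart
    c(rr[i] + off * 0.5 * nrm[1], cc[i] + off * 0.5 * nrm[2])
  })
  keep <- !vapply(crest, is.null, logical(1))
  if (sum(keep) < 3) return(empty)
  xy <- do.call(rbind, crest[keep])
  out <- data.frame(row = xy[, 1], col = xy[, 2],
                    s_nm = (stations[keep] - min(stations[keep])) *
                      image$pixel_size)
  structure(out, class = c("fibril_axis", "data.frame"))
}

#' Extract a baseline-corrected cross-section profile
#'
#' Samples a height profile perpendicular to the local fibril axis at a
#' given station, optionally averaging over `avg_window` adjacent sections.
#' The substrate baseline is a least-absolute-deviations line fitted to the
#' flanking substrate only (points at least one apparent fibril width from
#' the crest), which makes the extracted height invariant to substrate tilt
#' and offset.
#'
#' @param image A [topography_image()].
#' @param axis A `fibril_axis` from [trace_fibril_axis()].
#' @param station Index of the station along the axis polyline; by default
#'   the crest maximum (the station with the largest smoothed crest
#'   height), so dry/wet height ratios compare like band phases.
#' @param avg_window Odd number of adjacent sections to average.
#' @return An object of class `cross_section_profile`: data frame
#'   `x_nm`/`height_nm` plus attributes `baseline` (intercept/slope in nm,
#'   nm/nm), `peak_height_nm` and `apparent_width_nm`.
#' @export
extract_profile <- function(image, axis, station = NULL, avg_window = 5) {
  stopifnot(inherits(image, "topography_image"),
            inherits(axis, "fibril_axis"))
  n <- nrow(axis)
  if (n < 3) stop("axis polyline too short", call. = FALSE)
  if (is.null(station)) {
    crest_h <- .bilinear(image$heights, axis$row, axis$col)
    crest_h[!is.finite(crest_h)] <- -Inf
    sm <- if (n >= 5) stats::runmed(crest_h, 5) else crest_h
    # keep clear of the polyline ends so the section window fits
    margin <- min(max(5L, ceiling(0.05 * n)), (n - 1) %/% 2)
    idx <- (1 + margin):(n - margin)
    station <- idx[which.max(sm[idx])]
  }
  if (station < 1 || station > n) stop("station not on axis", call. = FALSE)
  if (avg_window %% 2 != 1) stop("avg_window must be odd", call. = FALSE)
  h <- image$heights
  px <- image$pixel_size
  # local axial direction from neighbouring polyline points
  i0 <- max(1, station - 5); i1 <- min(n, station + 5)
  dir <- c(axis$row[i1] - axis$row[i0], axis$col[i1] - axis$col[i0])
  dir <- dir / sqrt(sum(dir^2))
  nrm <- c(-dir[2], dir[1])
  # lateral reach: to the nearest image edge along the normal
  p <- c(axis$row[station], axis$col[station])
  reach <- function(sgn) {
    lim <- Inf
    for (d in 1:2) {
      v <- sgn * nrm[d]
      bound <- if (v > 0) (dim(h)[d] - 1 - p[d]) / v
               else if (v < 0) (0 - p[d]) / v else Inf
      lim <- min(lim, bound)
    }
    lim
  }
  hw <- floor(min(reach(1), reach(-1)))
  if (hw < 4) stop("profile window does not fit the image", call. = FALSE)
  ugrid <- seq(-hw, hw, by = 0.5)
  half <- (avg_window - 1) %/% 2
  stas <- station + (-half:half)
  stas <- stas[stas >= 1 & stas <= n]
  prof <- rep(0, length(ugrid)); cnt <- rep(0, length(ugrid))
  for (s in stas) {
    ps <- c(axis$row[s], axis$col[s])
    vals <- .bilinear(h, ps[1] + ugrid * nrm[1], ps[2] + ugrid * nrm[2])
    ok <- is.finite(vals)
    prof[ok] <- prof[ok] + vals[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  ok <- cnt > 0
  x <- ugrid[ok] * px
  y <- prof[ok] / cnt[ok]
  # initial baseline from the outer 25% of each flank
  m <- length(x)
  outer_idx <- c(seq_len(max(3, floor(0.25 * m))),
                 seq(m - max(3, floor(0.25 * m)) + 1, m))
  bl <- .lad_line(x[outer_idx], y[outer_idx])
  corr <- y - (bl[1] + bl[2] * x)
  peak_i <- which.max(corr)
  peak <- corr[peak_i]
  # apparent width from the threshold crossing around the peak
  thr <- max(0.1 * peak, 3 * stats::mad(corr[outer_idx]))
  above <- corr > thr
  lo <- peak_i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- peak_i; while (hi < m && above[hi + 1]) hi <- hi + 1
  width <- x[hi] - x[lo]
  # refit on flanking substrate at >= 1 width from the crest
  flank <- abs(x - x[peak_i]) >= max(width, 4 * px)
  if (sum(flank) >= 6 && sum(flank & x < x[peak_i]) >= 2 &&
      sum(flank & x > x[peak_i]) >= 2) {
    bl <- .lad_line(x[flank], y[flank])
    corr <- y - (bl[1] + bl[2] * x)
    peak_i <- which.max(corr)
    peak <- corr[peak_i]
    above <- corr > max(0.1 * peak, thr)
    lo <- peak_i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- peak_i; while (hi < m && above[hi + 1]) hi <- hi + 1
    width <- x[hi] - x[lo]
  }
  out <- data.frame(x_nm = x, height_nm = y)
  structure(out, baseline = bl, peak_height_nm = max(peak, 0),
            apparent_width_nm = width,
            class = c("cross_section_profile", "data.frame"))
}

#' Fibril height above the substrate baseline
#'
#' @param profile A `cross_section_profile` from [extract_profile()].
#' @return Maximum height above the fitted baseline, nm.
#' @export
fibril_height <- function(profile) {
  stopifnot(inherits(profile, "cross_section_profile"))
  attr(profile, "peak_height_nm")
}

#' Estimate the axial D-band period of a fibril
#'
#' Extracts the height profile along the fibril crest and estimates its
#' dominant axial period, either from the zero-padded FFT power spectrum
#' (with parabolic sub-bin peak interpolation) or from the first local
#' maximum of the autocorrelation. The profile is detrended with a
#' least-squares line first, so the estimate is invariant to constant
#' offsets and linear height trends.
#'
#' @param image A [topography_image()].
#' @param axis Optional `fibril_axis`; traced automatically when omitted.
#' @param method `"fft"` or `"autocorrelation"`.
#' @return An object of class `d_period_estimate`: list with `period_nm`,
#'   `method`, `confidence` (spectral peak prominence, or autocorrelation
#'   peak value) and `low_confidence` flag.
#' @export
estimate_d_period <- function(image, axis = NULL,
                              method = c("fft", "autocorrelation")) {
  method <- match.arg(method)
  stopifnot(inherits(image, "topography_image"))
  if (is.null(axis)) axis <- trace_fibril_axis(image)
  if (nrow(axis) < 16) {
    return(structure(list(period_nm = NA_real_, method = method,
                          confidence = 0, low_confidence = TRUE),
                     class = "d_period_estimate"))
  }
  y <- .bilinear(image$heights, axis$row, axis$col)
  s <- axis$s_nm
  ok <- is.finite(y)
  y <- y[ok]; s <- s[ok]
  dx <- stats::median(diff(s))
  # linear detrend
  cf <- stats::lsfit(s, y)$coefficients
  y <- y - (cf[1] + cf[2] * s)
  N <- length(y)
  L <- N * dx
  if (stats::sd(y) == 0) {
    return(structure(list(period_nm = NA_real_, method = method,
                          confidence = 0, low_confidence = TRUE),
                     class = "d_period_estimate"))
  }
  if (method == "fft") {
    pad <- 8L
    Np <- pad * stats::nextn(N, 2)
    pw <- Mod(stats::fft(c(y * stats::spec.taper(rep(1, N), 0.05),
                           rep(0, Np - N))))^2
    freq <- (seq_len(Np) - 1) / (Np * dx)
    per <- 1 / freq
    sel <- which(per > 2 * dx & per < L / 2)
    if (!length(sel)) {
      return(structure(list(period_nm = NA_real_, method = method,
                            confidence = 0, low_confidence = TRUE),
                       class = "d_period_estimate"))
    }
    i <- sel[which.max(pw[sel])]
    off <- if (i > 1 && i < Np) .parabolic_offset(pw[i - 1], pw[i],
                                                  pw[i + 1]) else 0
    f_star <- (i - 1 + off) / (Np * dx)
    period <- 1 / f_star
    # confidence: fraction of in-band power inside the peak's main lobe
    # (about +-2 natural bins). Near 1 for a clean sinusoid, small for
    # broadband roughness.
    lobe <- sel[abs(sel - i) <= 2 * pad]
    conf <- sum(pw[lobe]) / sum(pw[sel])
    low <- conf < 0.2
  } else {
    ac <- stats::acf(y, lag.max = floor(N / 2), plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    # first local maximum after the central peak decays
    lag <- NA_integer_
    for (j in 3:(length(ac) - 1)) {
      if (ac[j] >= ac[j - 1] && ac[j] > ac[j + 1]) { lag <- j; break }
    }
    if (is.na(lag)) {
      return(structure(list(period_nm = NA_real_, method = method,
                            confidence = 0, low_confidence = TRUE),
                       class = "d_period_estimate"))
    }
    off <- .parabolic_offset(ac[lag - 1], ac[lag], ac[lag + 1])
    period <- (lag - 1 + off) * dx
    conf <- ac[lag]
    low <- conf < 0.2
  }
  structure(list(period_nm = as.numeric(period), method = method,
                 confidence = as.numeric(conf), low_confidence = low),
            class = "d_period_estimate")
}

#' @export
print.d_period_estimate <- function(x, ...) {
  cat(sprintf("<d_period_estimate> %.2f nm (%s, confidence %.1f%s)\n",
              x$period_nm, x$method, x$confidence,
              if (x$low_confidence) ", LOW" else ""))
  invisible(x)
}

#' Hydration swelling, water fraction and normalized density
#'
#' Swelling is the fold increase in fibril height upon hydration,
#' \eqn{S = h_{wet}/h_{dry}}. Under the height-proportional volume
#' convention (fibril length constant, apparent width tip-convolved and
#' unreliable, so volume fold = height fold), the water volume fraction of
#' the hydrated fibril is \eqn{\phi_w = 1 - 1/S} and the density normalized
#' to the dry state is \eqn{\rho_{norm} = 1/S}. The isotropic alternative
#' (`convention = "isotropic"`) takes volume fold = `S^2` (height and width
#' swell alike, length constant).
#'
#' @param h_dry Dry-state height, nm (positive).
#' @param h_wet Hydrated height, nm.
#' @param convention Volume-fold convention, `"height"` (default) or
#'   `"isotropic"`.
#' @return An object of class `swelling_result`: list with `h_dry_nm`,
#'   `h_wet_nm`, `S`, `water_volume_fraction`, `normalized_density`.
#' @examples
#' swelling(26, 67.6)  # S = 2.6, phi_w ~ 0.615
#' @export
swelling <- function(h_dry, h_wet, convention = c("height", "isotropic")) {
  convention <- match.arg(convention)
  .assert_scalar(h_dry, "h_dry", lower = 0, allow_lower = FALSE)
  .assert_scalar(h_wet, "h_wet", lower = 0)
  S <- h_wet / h_dry
  vfold <- if (convention == "height") S else S^2
  phi <- if (S >= 1) 1 - 1 / vfold else NA_real_
  structure(list(h_dry_nm = h_dry, h_wet_nm = h_wet, S = S,
                 water_volume_fraction = phi,
                 normalized_density = 1 / vfold,
                 convention = convention),
            class = "swelling_result")
}

#' @export
print.swelling_result <- function(x, ...) {
  cat(sprintf(
    "<swelling_result> S = %.3f (h %g -> %g nm), phi_w = %.3f, rho_norm = %.3f\n",
    x$S, x$h_dry_nm, x$h_wet_nm, x$water_volume_fraction,
    x$normalized_density))
  invisible(x)
}

#' Fold-change series across hydration/dehydration media
#'
#' Expresses per-medium fibril heights as fold changes relative to a
#' reference medium (fully hydrated PBS by default) and reports whether the
#' series decreases monotonically along the stated medium order.
#'
#' @param heights Named numeric vector of heights, nm; names are medium
#'   labels (e.g. `air`, `PBS`, `EtOH25`, `EtOH50`, `EtOH100`).
#' @param reference Reference medium label present in `heights`.
#' @param order Optional medium order for the monotonicity report; defaults
#'   to the order of `heights`.
#' @return A data frame `medium`, `height_nm`, `fold`, with attribute
#'   `monotone_decreasing`.
#' @export
shrinkage_series <- function(heights, reference = "PBS", order = NULL) {
  if (length(heights) < 2 || is.null(names(heights))) {
    stop("need a named vector of >= 2 medium heights", call. = FALSE)
  }
  if (!reference %in% names(heights)) {
    stop("reference medium not present", call. = FALSE)
  }
  if (is.null(order)) order <- names(heights)
  heights <- heights[order]
  fold <- heights / heights[[reference]]
  out <- data.frame(medium = names(heights),
                    height_nm = as.numeric(heights),
                    fold = as.numeric(fold))
  structure(out, monotone_decreasing = all(diff(out$fold) <= 0),
            class = c("shrinkage_series", "data.frame"))
}
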