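# File formats: curves as TSV with '#' metadata headers; images as
# 32-bit-float TIFF (via the optional 'tiff' package) or ASCII matrix, both
# with a JSON sidecar; cohorts as CSV; area functions as JSON; configs as
# YAML.

#' Write / read a force curve as TSV
#'
#' Columns `z_nm`, `deflection_nm`, `segment`; leading `#` header lines
#' carry the spring constant and medium.
#'
#' @param curve A [force_curve()].
#' @param path File path.
#' @return `write_force_curve` returns `path` invisibly;
#'   `read_force_curve` returns a [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# spring_constant_N_per_m: %.10g", curve$spring_constant),
    sprintf("# medium: %s", curve$medium),
    "# deflection_unit: nm"), con)
  utils::write.table(as.data.frame(curve), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default = NA) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  k <- as.numeric(get_meta("spring_constant_N_per_m"))
  if (!is.finite(k)) stop("missing spring constant header", call. = FALSE)
  medium <- get_meta("medium", "air")
  d <- utils::read.table(textConnection(lines[!grepl("^#", lines)]),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  force_curve(d$z_nm, d$deflection_nm, d$segment, spring_constant = k,
              medium = medium)
}

#' Write / read a topography image
#'
#' The height grid is stored as 32-bit-float TIFF in nm (paths ending
#' `.tif`/`.tiff`, requires the `tiff` package) or as a plain ASCII matrix;
#' either way a JSON sidecar `<path>.json` records
#' `{pixel_size_nm, medium, state}`.
#'
#' @param image A [topography_image()].
#' @param path File path (`.tif`/`.tiff` for TIFF, anything else ASCII).
#' @return `write_topography` returns `path` invisibly; `read_topography`
#'   returns a [topography_image()].
#' @export
write_topography <- function(image, path) {
  stopifnot(inherits(image, "topography_image"))
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  sidecar <- list(pixel_size_nm = image$pixel_size,
                  medium = image$medium, state = image$state)
  if (is_tiff) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required for TIFF output", call. = FALSE)
    }
    # TIFF samples are stored in [0, 1]; record the affine height mapping
    # in the sidecar so heights in nm round-trip
    h <- image$heights
    off <- min(h)
    scl <- max(h) - off
    if (scl == 0) scl <- 1
    tiff::writeTIFF((h - off) / scl, path, bits.per.sample = 32L,
                    reduce = FALSE)
    sidecar$height_offset_nm <- off
    sidecar$height_scale_nm <- scl
  } else {
    utils::write.table(image$heights, path, sep = " ",
                       row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topography
#' @export
read_topography <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing JSON sidecar: ", sidecar_path, call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is_tiff) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required for TIFF input", call. = FALSE)
    }
    h <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(h)) == 3) h <- h[, , 1]
    if (!is.null(sc$height_scale_nm)) {
      h <- h * sc$height_scale_nm + sc$height_offset_nm
    }
  } else {
    h <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(h) <- NULL
  }
  topography_image(h, pixel_size = sc$pixel_size_nm, state = sc$state,
                   medium = sc$medium)
}

#' Write / read a fibril cohort CSV
#'
#' Columns `fibril_id`, `genotype`, `medium`, `sex`, `modulus_Pa` (plus any
#' extra columns present).
#'
#' @param cohort Data frame of fibril records.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a data
#'   frame.
#' @export
write_cohort <- function(cohort, path) {
  req <- c("fibril_id", "genotype", "medium", "modulus_Pa")
  if (!all(req %in% names(cohort))) {
    stop("cohort is missing required columns", call. = FALSE)
  }
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a tip area function as JSON
#'
#' `{theta_deg, coefficients[]}`; an empty coefficient list means ideal
#' geometry.
#'
#' @param area_fn A [tip_area_function()].
#' @param path File path.
#' @return `write_area_function` returns `path` invisibly;
#'   `read_area_function` a [tip_area_function()].
#' @export
write_area_function <- function(area_fn, path) {
  stopifnot(inherits(area_fn, "tip_area_function"))
  jsonlite::write_json(list(theta_deg = area_fn$theta_deg,
                            coefficients = area_fn$coefficients %||%
                              numeric(0)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_area_function
#' @export
read_area_function <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- j$coefficients
  if (!length(co)) co <- NULL
  tip_area_function(theta_deg = j$theta_deg, coefficients = co)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Reads a nested YAML file and merges it over [default_config()], so a
#' config file only needs to state the values it changes.
#'
#' @param path YAML file path.
#' @return A config list as from [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  .merge_config(default_config(), user)
}

.merge_config <- function(base, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      .merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}
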