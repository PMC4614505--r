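#' Default pipeline configuration
#'
#' A nested list mirroring the module structure: simulated cohort
#' parameters per medium, per-medium cantilever and indentation settings
#' for the force-curve stage, topography image settings, the
#' contact-mechanics analysis configuration, statistics settings, and the
#' microfibril constants (unit cells, chain masses, volume excess and
#' endpoint tangent moduli) used by the derive stage.
#'
#' The cohort defaults parameterize the study conditions this pipeline
#' emulates: air-dried indentation moduli of 7.9 +/- 2.8 GPa (WT) vs 5.3
#' +/- 2.2 GPa (oim); fully hydrated (PBS) moduli of 3.3 +/- 0.5 MPa
#' (WT, n = 10) vs 16.2 +/- 3.0 MPa (oim, n = 8); an
#' ethanol-series hydrated trial at 1.2 +/- 0.4 vs 10.8 +/- 3.7 MPa; and
#' hydration swelling folds of 2.6 (WT) vs 1.5 (oim).
#'
#' @param seed Master seed; every stage derives its stream from it.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    cohorts = data.frame(
      genotype = c("WT", "OIM", "WT", "OIM", "WT", "OIM"),
      medium   = c("air", "air", "PBS", "PBS", "PBS-trial", "PBS-trial"),
      mean     = c(7.9e9, 5.3e9, 3.3e6, 16.2e6, 1.2e6, 10.8e6),
      sd       = c(2.8e9, 2.2e9, 0.5e6, 3.0e6, 0.4e6, 3.7e6),
      n        = c(20, 20, 10, 8, 6, 6)),
    distribution = "lognormal",
    curves = list(
      points_per_segment = 256,
      tip_half_angle = 35,
      contact_point = 150,
      noise_frac = 0.02,
      spring_constant = c(air = 44.5, PBS = 0.24, `PBS-trial` = 8.3),
      max_indentation = c(air = 20, PBS = 50, `PBS-trial` = 40)),
    images = list(
      height_dry = 26,
      swelling = c(WT = 2.6, OIM = 1.5),
      d_period = 67,
      band_amplitude_frac = 0.1,
      fibril_width = 100,
      pixel_size = 2,
      image_shape = c(128, 320),
      substrate_roughness_sd = 0.2),
    analysis = list(
      epsilon = 2 * (pi - 2) / pi, beta = 1, nu_sample = 0.5,
      mode = "simplified", E_indenter = 169e9, nu_indenter = 0.27,
      fit_fraction = 1, threshold_sd = 5),
    stats = list(factors = "genotype", alpha = 0.05),
    microfibril = list(
      cell_3hr2 = list(a = 40.0, b = 27.0, c = 678,
                       alpha = 89.2, beta = 94.6, gamma = 105.6),
      lattice_1atm = list(a_WT = 33.41, b_WT = 25.08,
                          a_OIM = 36.16, b_OIM = 25.54),
      chain_masses_kDa = c(a1 = 138.032, a2 = 129.557),
      volume_excess_OIM = 1.14,
      tangent_GPa_150MPa = c(WT = 1.05, OIM = 0.79))
  )
}

#' Run the simulate-analyze-derive-compare pipeline
#'
#' Orchestrates the full chain on synthetic data with known ground truth:
#' (1) draw per-fibril modulus cohorts; (2) synthesize one force curve per
#' fibril at its true modulus and re-measure the modulus through the
#' contact-mechanics chain; (3) generate dry/wet topography pairs per
#' genotype and re-measure swelling and the D-period; (4) compare groups
#' per medium with the log-scale model and Tukey contrasts; (5) derive the
#' microfibril unit-cell, mass, density and tangent-modulus quantities.
#' The run is deterministic under a fixed `config$seed`.
#'
#' @param config Configuration from [default_config()] or [read_config()].
#' @param outdir Optional output directory: per-stage CSVs, a JSON summary
#'   and a run log are written there.
#' @param stages Character subset of
#'   `c("simulate", "curves", "images", "stats", "derive")`. When
#'   `"curves"` is off the statistics stage consumes the drawn ground-truth
#'   moduli unchanged.
#' @return A `study_summary` list: `cohort` (records with true and measured
#'   moduli), `group_summary`, `comparisons`, headline ratios/percents,
#'   `swelling`, `d_period_nm` and `microfibril` constants.
#' @examples
#' \donttest{
#' res <- run_pipeline(default_config(seed = 7))
#' res$group_summary
#' }
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         stages = c("simulate", "curves", "images",
                                    "stats", "derive")) {
  t0 <- Sys.time()
  log_lines <- c(sprintf("fibrilmech pipeline run, seed %d", config$seed),
                 sprintf("stages: %s", paste(stages, collapse = ", ")))
  acfg <- do.call(contact_config, config$analysis)
  area_fn <- tip_area_function(config$curves$tip_half_angle)
  art <- list(config = config)

  if ("simulate" %in% stages) {
    spec <- cohort_sim_spec(config$cohorts,
                            distribution = config$distribution,
                            seed = .derive_seed(config$seed, 1))
    art$cohort <- generate_cohort(spec)
    log_lines <- c(log_lines,
                   sprintf("simulate: %d fibrils in %d groups",
                           nrow(art$cohort), nrow(config$cohorts)))
  }

  if ("curves" %in% stages && !is.null(art$cohort)) {
    cc <- config$curves
    rec <- art$cohort
    measured <- vapply(seq_len(nrow(rec)), function(i) {
      med <- rec$medium[i]
      k <- cc$spring_constant[[med]]
      dmax <- cc$max_indentation[[med]]
      E <- rec$modulus_true_Pa[i]
      C <- .sneddon_coefficient(E, acfg$nu_sample, cc$tip_half_angle)
      f_max <- C * dmax^2
      spec <- curve_sim_spec(
        modulus_true = E, poisson_sample = acfg$nu_sample,
        tip_half_angle = cc$tip_half_angle, spring_constant = k,
        contact_point = cc$contact_point, max_indentation = dmax,
        noise_sd = cc$noise_frac * f_max,
        points_per_segment = cc$points_per_segment,
        seed = .derive_seed(config$seed, 100 + i))
      a <- analyze_curve(generate_force_curve(spec), area_fn, acfg)
      if (a$valid) a$E_sample_Pa else NA_real_
    }, numeric(1))
    rec$modulus_Pa <- measured
    art$cohort <- rec
    log_lines <- c(log_lines,
                   sprintf("curves: %d/%d analyzed valid",
                           sum(is.finite(measured)), length(measured)))
  }

  if ("images" %in% stages) {
    ic <- config$images
    sw <- lapply(names(ic$swelling), function(g) {
      spec <- fibril_image_spec(
        height_dry = ic$height_dry, swelling_true = ic$swelling[[g]],
        d_period = ic$d_period,
        band_amplitude_frac = ic$band_amplitude_frac,
        fibril_width = ic$fibril_width, pixel_size = ic$pixel_size,
        image_shape = ic$image_shape,
        substrate_roughness_sd = ic$substrate_roughness_sd,
        seed = .derive_seed(config$seed, 200 + match(g,
                                                     names(ic$swelling))))
      dry <- generate_fibril_image(spec, "dry")
      wet <- generate_fibril_image(spec, "wet")
      h_d <- fibril_height(extract_profile(dry, trace_fibril_axis(dry)))
      h_w <- fibril_height(extract_profile(wet, trace_fibril_axis(wet)))
      s <- swelling(h_d, h_w)
      list(genotype = g, dry = dry, s = s)
    })
    art$swelling <- data.frame(
      genotype = vapply(sw, `[[`, character(1), "genotype"),
      h_dry_nm = vapply(sw, function(x) x$s$h_dry_nm, numeric(1)),
      h_wet_nm = vapply(sw, function(x) x$s$h_wet_nm, numeric(1)),
      S = vapply(sw, function(x) x$s$S, numeric(1)),
      water_volume_fraction = vapply(sw, function(x)
        x$s$water_volume_fraction, numeric(1)),
      normalized_density = vapply(sw, function(x)
        x$s$normalized_density, numeric(1)))
    art$d_period <- estimate_d_period(sw[[1]]$dry)
    log_lines <- c(log_lines,
                   sprintf("images: swelling %s; D-period %.2f nm",
                           paste(sprintf("%s=%.3f", art$swelling$genotype,
                                         art$swelling$S), collapse = ", "),
                           art$d_period$period_nm))
  }

  if ("stats" %in% stages && !is.null(art$cohort)) {
    rec <- art$cohort[is.finite(art$cohort$modulus_Pa), ]
    gs <- do.call(rbind, lapply(split(rec,
                                      rec[c("genotype", "medium")],
                                      drop = TRUE), function(d) {
      data.frame(medium = d$medium[1], genotype = d$genotype[1],
                 n = nrow(d), mean_Pa = mean(d$modulus_Pa),
                 sd_Pa = stats::sd(d$modulus_Pa))
    }))
    rownames(gs) <- NULL
    comps <- do.call(rbind, lapply(split(rec, rec$medium), function(d) {
      if (length(unique(d$genotype)) < 2) return(NULL)
      fit <- fit_log_model(d, factors = config$stats$factors)
      cmp <- tukey_pairwise(fit, alpha = config$stats$alpha)
      cbind(medium = d$medium[1], cmp)
    }))
    rownames(comps) <- NULL
    lsm <- do.call(rbind, lapply(split(rec, rec$medium), function(d) {
      if (length(unique(d$genotype)) < 2) return(NULL)
      fit <- fit_log_model(d, factors = config$stats$factors)
      cbind(medium = d$medium[1], lsmeans_log(fit))
    }))
    rownames(lsm) <- NULL
    gs <- merge(gs, lsm[, c("medium", "group", "lsmean")],
                by.x = c("medium", "genotype"), by.y = c("medium", "group"),
                all.x = TRUE)
    art$group_summary <- gs
    art$comparisons <- comps
    log_lines <- c(log_lines, sprintf("stats: %d pairwise comparisons",
                                      nrow(comps)))
  }

  if ("derive" %in% stages) {
    mf <- config$microfibril
    cell <- do.call(triclinic_cell, mf$cell_3hr2)
    lat <- mf$lattice_1atm
    dens <- density_ratio(1, mf$volume_excess_OIM, 1, 1)
    m_wt <- trimer_mass(mf$chain_masses_kDa, c(a1 = 2, a2 = 1))
    m_oim <- trimer_mass(mf$chain_masses_kDa, c(a1 = 3))
    art$microfibril <- list(
      cell_volume_A3 = cell_volume(cell),
      trimer_mass_WT_kDa = m_wt,
      trimer_mass_OIM_kDa = m_oim,
      trimer_mass_percent_difference =
        -percent_difference(m_oim, m_wt),
      lattice_a_percent_increase = -percent_difference(lat$a_OIM, lat$a_WT),
      lattice_b_percent_increase = -percent_difference(lat$b_OIM, lat$b_WT),
      density_percent_lower_OIM = dens$percent_difference,
      tangent_percent_difference =
        percent_difference(mf$tangent_GPa_150MPa[["OIM"]],
                           mf$tangent_GPa_150MPa[["WT"]]))
    log_lines <- c(log_lines, "derive: microfibril constants computed")
  }

  # headline quantities of the study summary
  summary <- list(cohort = art$cohort,
                  group_summary = art$group_summary,
                  comparisons = art$comparisons,
                  swelling = art$swelling,
                  d_period_nm = if (!is.null(art$d_period))
                    art$d_period$period_nm else NULL,
                  microfibril = art$microfibril)
  gs <- art$group_summary
  if (!is.null(gs)) {
    pick <- function(med, gen, col) {
      v <- gs[gs$medium == med & gs$genotype == gen, col]
      if (length(v)) v else NA_real_
    }
    if (all(is.finite(c(pick("air", "OIM", "mean_Pa"),
                        pick("air", "WT", "mean_Pa"))))) {
      summary$air_percent_difference <-
        percent_difference(pick("air", "OIM", "mean_Pa"),
                           pick("air", "WT", "mean_Pa"))
    }
    if (all(is.finite(c(pick("PBS", "OIM", "lsmean"),
                        pick("PBS", "WT", "lsmean"))))) {
      summary$pbs_fold <- fold_ratio(pick("PBS", "OIM", "lsmean"),
                                     pick("PBS", "WT", "lsmean"))
    }
    if (all(is.finite(c(pick("PBS-trial", "OIM", "lsmean"),
                        pick("PBS-trial", "WT", "lsmean"))))) {
      summary$etoh_trial_fold <- fold_ratio(
        pick("PBS-trial", "OIM", "lsmean"),
        pick("PBS-trial", "WT", "lsmean"))
    }
  }
  if (!is.null(art$swelling) &&
      all(c("WT", "OIM") %in% art$swelling$genotype)) {
    summary$swelling_deficit_percent <- percent_difference(
      art$swelling$S[art$swelling$genotype == "OIM"],
      art$swelling$S[art$swelling$genotype == "WT"])
  }
  summary$config <- config
  class(summary) <- "study_summary"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(art$cohort)) {
      write_cohort(art$cohort, file.path(outdir, "cohort.csv"))
    }
    if (!is.null(art$group_summary)) {
      utils::write.csv(art$group_summary,
                       file.path(outdir, "group_summary.csv"),
                       row.names = FALSE)
    }
    if (!is.null(art$comparisons)) {
      utils::write.csv(art$comparisons,
                       file.path(outdir, "comparisons.csv"),
                       row.names = FALSE)
    }
    if (!is.null(art$swelling)) {
      utils::write.csv(art$swelling, file.path(outdir, "swelling.csv"),
                       row.names = FALSE)
    }
    json <- summary
    json$cohort <- NULL
    json$config <- NULL
    jsonlite::write_json(json, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    log_lines <- c(log_lines,
                   sprintf("elapsed: %.2f s",
                           as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))),
                   "config:",
                   strsplit(yaml::as.yaml(.config_for_echo(config)),
                            "\n")[[1]])
    writeLines(log_lines, file.path(outdir, "run.log"))
  }
  summary
}

# data frames do not round-trip to YAML cleanly; echo them as lists
.config_for_echo <- function(config) {
  config$cohorts <- as.list(as.data.frame(config$cohorts))
  config
}

#' @export
print.study_summary <- function(x, ...) {
  cat("<study_summary>\n")
  if (!is.null(x$group_summary)) {
    cat("group summary:\n")
    print(x$group_summary)
  }
  if (!is.null(x$air_percent_difference)) {
    cat(sprintf("air-dried oim deficit: %.1f%%\n",
                x$air_percent_difference))
  }
  if (!is.null(x$pbs_fold)) {
    cat(sprintf("PBS oim/WT lsmean ratio: %.2f (%d-fold)\n",
                x$pbs_fold$ratio, x$pbs_fold$fold))
  }
  if (!is.null(x$swelling_deficit_percent)) {
    cat(sprintf("swelling deficit: %.1f%%\n", x$swelling_deficit_percent))
  }
  if (!is.null(x$d_period_nm)) {
    cat(sprintf("D-period: %.2f nm\n", x$d_period_nm))
  }
  invisible(x)
}
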