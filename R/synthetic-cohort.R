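#' Specification of a simulated fibril cohort
#'
#' Describes groups of per-fibril indentation moduli to draw: each group has
#' a label (genotype and medium), an arithmetic mean and standard deviation
#' on the modulus scale, and a sample size. Draws are lognormal by default,
#' matching the log-scale analysis the statistics module applies (moduli are
#' strictly positive and right-skewed), with a truncated-normal alternative.
#'
#' @param groups A data frame with columns `genotype`, `medium`, `mean`,
#'   `sd`, `n` (one row per group; `mean`/`sd` in Pa). An optional `sex`
#'   column is carried through.
#' @param distribution `"lognormal"` (moment-matched on the arithmetic
#'   mean/sd) or `"normal"` (truncated at 0 by resampling).
#' @param seed Optional integer seed.
#' @return An object of class `cohort_sim_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_sim_spec <- function(groups,
                            distribution = c("lognormal", "normal"),
                            seed = NULL) {
  distribution <- match.arg(distribution)
  groups <- as.data.frame(groups)
  req <- c("genotype", "medium", "mean", "sd", "n")
  if (!all(req %in% names(groups))) {
    stop("'groups' needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(groups$mean)) || any(groups$mean <= 0)) {
    stop("group means must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(groups$sd)) || any(groups$sd < 0)) {
    stop("group sds must be non-negative", call. = FALSE)
  }
  if (any(groups$n < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (!is.null(seed)) .assert_scalar(seed, "seed")
  structure(list(groups = groups, distribution = distribution, seed = seed),
            class = "cohort_sim_spec")
}

#' Draw a synthetic cohort of per-fibril moduli
#'
#' Draws `n` moduli per group from the specified distribution. Lognormal
#' draws are moment-matched so the arithmetic mean and standard deviation of
#' the generating distribution equal the group's stated `mean` and `sd`
#' (`sdlog^2 = log(1 + sd^2/mean^2)`, `meanlog = log(mean) - sdlog^2/2`).
#' `sd = 0` yields constant values equal to the mean.
#'
#' @param spec A [cohort_sim_spec()].
#' @return A data frame of fibril records with columns `fibril_id`,
#'   `genotype`, `medium`, `sex`, `modulus_Pa` and `modulus_true_Pa`
#'   (identical; downstream stages may overwrite `modulus_Pa` with measured
#'   values while keeping the ground truth).
#' @examples
#' spec <- cohort_sim_spec(data.frame(
#'   genotype = c("WT", "OIM"), medium = "PBS",
#'   mean = c(3.3e6, 16.2e6), sd = c(0.5e6, 3.0e6), n = c(10, 8)), seed = 1)
#' head(generate_cohort(spec))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  g <- spec$groups
  draws <- lapply(seq_len(nrow(g)), function(i) {
    n <- g$n[i]; m <- g$mean[i]; s <- g$sd[i]
    if (s == 0) {
      x <- rep(m, n)
    } else if (spec$distribution == "lognormal") {
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      x <- stats::rlnorm(n, meanlog, sdlog)
    } else {
      x <- stats::rnorm(n, m, s)
      while (any(x <= 0)) {
        bad <- x <= 0
        x[bad] <- stats::rnorm(sum(bad), m, s)
      }
    }
    data.frame(genotype = g$genotype[i], medium = g$medium[i],
               sex = if ("sex" %in% names(g)) g$sex[i] else NA_character_,
               modulus_Pa = x)
  })
  out <- do.call(rbind, draws)
  out <- cbind(fibril_id = sprintf("fib%03d", seq_len(nrow(out))), out)
  out$modulus_true_Pa <- out$modulus_Pa
  rownames(out) <- NULL
  out
}
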