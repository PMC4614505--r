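#' Fit a Gaussian linear model on natural-log moduli
#'
#' The group-comparison model: ordinary least squares on `ln(modulus)` with
#' categorical factors (full factorial when more than one factor is given).
#' The log transform corrects the unequal variances typical of modulus
#' cohorts; group summaries are least-square means on the log scale, whose
#' back-transforms are geometric-mean-type group values.
#'
#' @param records Data frame of fibril records with a positive modulus
#'   column and the factor columns.
#' @param factors Character vector of factor column names.
#' @param response Name of the modulus column, Pa.
#' @return An object of class `log_modulus_fit`: the `lm` fit, factor
#'   names, factor levels, residual df and variance.
#' @examples
#' rec <- data.frame(genotype = rep(c("WT", "OIM"), each = 4),
#'                   modulus_Pa = c(2, 4, 8, 4, 16, 32, 64, 32) * 1e6)
#' fit_log_model(rec, "genotype")
#' @export
fit_log_model <- function(records, factors = "genotype",
                          response = "modulus_Pa") {
  records <- as.data.frame(records)
  if (!all(c(factors, response) %in% names(records))) {
    stop("records is missing required columns", call. = FALSE)
  }
  y <- records[[response]]
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("moduli must be positive and finite for the log model",
         call. = FALSE)
  }
  d <- records
  d$.logy <- log(y)
  for (f in factors) d[[f]] <- factor(d[[f]])
  tab <- table(d[factors])
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab > 0 & tab < 2)) {
    stop("every non-empty group needs n >= 2", call. = FALSE)
  }
  fml <- stats::as.formula(paste(".logy ~", paste(factors, collapse = "*")))
  fit <- stats::lm(fml, data = d)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("singular design; aliased coefficients: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  structure(list(lm = fit, factors = factors, response = response,
                 levels = lapply(d[factors], levels),
                 df_residual = stats::df.residual(fit),
                 sigma2 = stats::sigma(fit)^2,
                 data = d),
            class = "log_modulus_fit")
}

#' @export
print.log_modulus_fit <- function(x, ...) {
  cat("<log_modulus_fit> ln(", x$response, ") ~ ",
      paste(x$factors, collapse = " * "),
      ", residual df = ", x$df_residual, "\n", sep = "")
  invisible(x)
}

# Contrast matrix rows giving lsmeans: one row per cell of the factor grid
# (specs = NULL) or per level of one factor, averaging with equal weights
# over the grid of the remaining factors (classic least-square means).
.lsmean_rows <- function(fit, specs = NULL) {
  grid <- expand.grid(fit$levels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = TRUE)
  tt <- stats::delete.response(stats::terms(fit$lm))
  X <- stats::model.matrix(tt, grid)
  if (is.null(specs)) {
    lab <- interaction(grid, sep = ":", drop = FALSE)
    rownames(X) <- as.character(lab)
    return(list(L = X, grid = grid))
  }
  if (!specs %in% fit$factors) stop("unknown factor: ", specs,
                                    call. = FALSE)
  lev <- fit$levels[[specs]]
  L <- t(vapply(lev, function(l) colMeans(X[grid[[specs]] == l, ,
                                            drop = FALSE]),
                numeric(ncol(X))))
  rownames(L) <- lev
  list(L = L, grid = data.frame(level = lev))
}

#' Least-square means of a log-modulus model
#'
#' Marginal means over the factor grid with equal weights. With
#' `specs = NULL` one lsmean per factor-combination cell is returned;
#' with a factor name, per-level lsmeans averaged over the other factors.
#'
#' @param fit A [fit_log_model()] result.
#' @param specs Optional factor name.
#' @return Data frame with `group`, `lsmean_log`, `se_log` and the
#'   back-transformed `lsmean` (geometric-mean scale, Pa).
#' @export
lsmeans_log <- function(fit, specs = NULL) {
  stopifnot(inherits(fit, "log_modulus_fit"))
  lr <- .lsmean_rows(fit, specs)
  b <- stats::coef(fit$lm)
  V <- stats::vcov(fit$lm)
  est <- drop(lr$L %*% b)
  se <- sqrt(diag(lr$L %*% V %*% t(lr$L)))
  data.frame(group = rownames(lr$L), lsmean_log = est, se_log = se,
             lsmean = exp(est), row.names = NULL)
}

#' Tukey-adjusted pairwise comparisons of lsmeans
#'
#' All pairwise contrasts among the least-square means, with p-values from
#' the studentized range distribution: \eqn{p = P(q_{k,df} \ge \sqrt{2}
#' |t|)}. At `k = 2` this reduces exactly to the pooled two-sample t-test.
#' The back-transformed lsmean ratio is a fold difference on the
#' geometric-mean scale.
#'
#' @param fit A [fit_log_model()] result.
#' @param specs Optional factor name (default: all factor-combination
#'   cells).
#' @param alpha Significance level for the `significant` flag.
#' @return A data frame of class `pairwise_comparison`: group labels,
#'   per-group lsmeans (log and back-transformed), `ratio` of
#'   back-transformed lsmeans, `t`, `df`, `p_tukey`, `significant`.
#' @export
tukey_pairwise <- function(fit, specs = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "log_modulus_fit"))
  lr <- .lsmean_rows(fit, specs)
  L <- lr$L
  b <- stats::coef(fit$lm)
  V <- stats::vcov(fit$lm)
  est <- drop(L %*% b)
  k <- nrow(L)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  df <- fit$df_residual
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    l <- L[i1, ] - L[i2, ]
    se <- sqrt(drop(t(l) %*% V %*% l))
    tval <- (est[i1] - est[i2]) / se
    p <- stats::ptukey(sqrt(2) * abs(tval), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(group1 = rownames(L)[i1], group2 = rownames(L)[i2],
               lsmean_log1 = est[i1], lsmean_log2 = est[i2],
               lsmean1 = exp(est[i1]), lsmean2 = exp(est[i2]),
               ratio = exp(est[i1] - est[i2]),
               t = tval, df = df, p_tukey = p,
               significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("pairwise_comparison", "data.frame"))
}

#' Fold ratio of back-transformed lsmeans
#'
#' The fold difference between two group summaries on the back-transformed
#' (geometric-mean) scale, with the nearest integer fold as reported in
#' prose ("fivefold", "9-fold").
#'
#' @param x Either a `pairwise_comparison` row (its `ratio` is used) or the
#'   first group's lsmean.
#' @param ref Second group's lsmean when `x` is numeric.
#' @return List with `ratio` and `fold` (nearest integer of the
#'   larger/smaller orientation).
#' @examples
#' fold_ratio(14.2, 2.8)  # ratio 5.07, fold 5
#' @export
fold_ratio <- function(x, ref = NULL) {
  if (inherits(x, "pairwise_comparison")) {
    if (nrow(x) != 1) stop("supply a single comparison row", call. = FALSE)
    r <- x$ratio
  } else {
    if (is.null(ref)) stop("ref required with numeric input", call. = FALSE)
    if (x <= 0 || ref <= 0) stop("lsmeans must be positive", call. = FALSE)
    r <- x / ref
  }
  list(ratio = r, fold = round(max(r, 1 / r)))
}
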