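# Sequence divergence vs body mass: least-absolute-deviation (LAD) regression
# of percent identity on log10(mass), bootstrap gradient errors, the
# mass-perturbation robustness check, and gradient-based isoform grouping.
#
# Units: the gradient is percent identity per log10(kg), i.e. per decade of
# body mass ("per log kg" is read as per 10-fold change).

#' Exact least-absolute-deviation line fit
#'
#' Minimises `sum(|y - a - b x|)`. A LAD optimum always exists at a line
#' interpolating two observations, so the fit enumerates every such candidate
#' line and keeps the best; ties (within 1e-9 of the optimum) are broken
#' toward the candidate with the smallest residual sum of squares.
#'
#' @param x,y numeric vectors of equal length (>= 2, x not constant).
#' @return list with `intercept`, `slope`, `objective` (the minimised L1
#'   residual sum).
#' @export
lad_fit <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 2L) fail("need two or more (x, y) points")
  if (diff(range(x)) == 0) fail("x is constant: LAD line is not identifiable")
  pr <- utils::combn(n, 2L)
  i <- pr[1L, ]; j <- pr[2L, ]
  ok <- x[i] != x[j]
  i <- i[ok]; j <- j[ok]
  b <- (y[j] - y[i]) / (x[j] - x[i])
  a <- y[i] - b * x[i]
  m <- length(b)
  res <- matrix(y, n, m) - matrix(a, n, m, byrow = TRUE) - outer(x, b)
  obj <- colSums(abs(res))
  best <- which(obj <= min(obj) + 1e-9)
  if (length(best) > 1L) best <- best[which.min(colSums(res[, best, drop = FALSE]^2))]
  list(intercept = a[best], slope = b[best], objective = obj[best])
}

#' Robust regression of sequence identity on log10 body mass
#'
#' Fits identity (percent, to a reference species) against log10(mass in kg)
#' by least absolute deviations, the criterion that down-weights outlying
#' species relative to ordinary least squares.
#'
#' @param series data.frame with columns `identity_pct` and `mass_kg`
#'   (e.g. from [identity_series()]).
#' @param exclude_reference drop the reference before fitting (default TRUE):
#'   its identity is 100 by definition. The reference is identified by
#'   `reference_id` when supplied, otherwise as any row with identity exactly
#'   100.
#' @param reference_id optional species id of the identity reference.
#' @param boot_reps species-bootstrap resamples for the gradient standard
#'   error (0 disables; default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `myo_fit`: `gradient` (% per log10 kg),
#'   `gradient_se`, `intercept` (%), `r_squared` (1 - SSres/SStot from the
#'   LAD residuals, clamped to \[0, 1\]), `r_squared_ols` (from the ordinary
#'   least-squares fit, for comparison), `n`, `boot_reps`, `seed`.
#' @export
fit_identity_mass <- function(series, exclude_reference = TRUE,
                              reference_id = NULL, boot_reps = 1000L,
                              seed = 1L) {
  df <- as.data.frame(series)
  if (exclude_reference) {
    drop <- if (!is.null(reference_id) && "species_id" %in% names(df))
      df$species_id == reference_id else df$identity_pct == 100
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) < 3L) fail("need at least 3 species to fit")
  if (any(df$mass_kg <= 0)) fail("masses must be positive")
  x <- log10(df$mass_kg)
  y <- df$identity_pct
  if (diff(range(x)) == 0) fail("all masses equal: regressor is degenerate")
  fit <- lad_fit(x, y)
  resid <- y - fit$intercept - fit$slope * x
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - sum(resid^2) / ss_tot)) else NA_real_
  se <- NA_real_
  if (boot_reps > 0L) {
    set.seed(seed)
    grads <- vapply(seq_len(boot_reps), function(r) {
      repeat {
        k <- sample.int(length(x), replace = TRUE)
        if (diff(range(x[k])) > 0) break
      }
      lad_fit(x[k], y[k])$slope
    }, 0)
    se <- stats::sd(grads)
  }
  structure(list(
    gradient = fit$slope, gradient_se = se, intercept = fit$intercept,
    r_squared = r2,
    r_squared_ols = if (ss_tot > 0)
      1 - sum(stats::lm(y ~ x)$residuals^2) / ss_tot else NA_real_,
    n = length(x), boot_reps = boot_reps, seed = seed
  ), class = "myo_fit")
}

#' @export
print.myo_fit <- function(x, ...) {
  cat(sprintf("LAD identity~log10(mass) fit: gradient %.3f %%/log10(kg)",
              x$gradient))
  if (is.finite(x$gradient_se)) cat(sprintf(" (SE %.3f)", x$gradient_se))
  cat(sprintf(", intercept %.2f%%, R^2 %.3f, n = %d\n",
              x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Mass-perturbation robustness check
#'
#' Each replicate multiplies every species mass by an independent uniform
#' draw in `[low, high]` (default 80%-120% of the recorded value), refits,
#' and records the gradient and R^2; summaries over replicates quantify how
#' sensitive the regression is to body-mass measurement error.
#'
#' @inheritParams fit_identity_mass
#' @param replicates number of perturbation replicates (default 1000).
#' @param low,high bounds of the uniform mass multiplier.
#' @return object of class `myo_perturbation`: `replicates`, `seed`, and a
#'   `summary` data.frame (rows gradient and r_squared; columns min, mean,
#'   max), plus the per-replicate vectors.
#' @export
perturb_masses <- function(series, replicates = 1000L, low = 0.8, high = 1.2,
                           seed = 1L, exclude_reference = TRUE,
                           reference_id = NULL) {
  if (replicates < 1L) fail("replicates must be >= 1")
  if (!(low <= high)) fail("low must be <= high")
  set.seed(seed)
  grad <- r2 <- numeric(replicates)
  for (r in seq_len(replicates)) {
    pert <- series
    pert$mass_kg <- pert$mass_kg * stats::runif(nrow(pert), low, high)
    f <- fit_identity_mass(pert, exclude_reference = exclude_reference,
                           reference_id = reference_id, boot_reps = 0L)
    grad[r] <- f$gradient
    r2[r] <- f$r_squared
  }
  summ <- data.frame(
    statistic = c("gradient", "r_squared"),
    min = c(min(grad), min(r2)),
    mean = c(mean(grad), mean(r2)),
    max = c(max(grad), max(r2))
  )
  structure(list(replicates = replicates, seed = seed, low = low, high = high,
                 summary = summ, gradient = grad, r_squared = r2),
            class = "myo_perturbation")
}

#' Residue changes per 10-fold increase in body mass
#'
#' Converts a divergence gradient (percent identity per log10 kg) over a
#' domain of given length into the number of amino acids changing per decade
#' of body mass: `|gradient| / 100 * domain_length`.
#'
#' @param gradient percent identity per log10(kg).
#' @param domain_length residues in the domain (e.g. 800 for a myosin motor).
#' @return amino-acid changes per 10-fold mass increase.
#' @export
residues_per_decade <- function(gradient, domain_length) {
  stopifnot_scalar_number(gradient, "gradient")
  if (domain_length < 1) fail("domain_length must be >= 1")
  abs(gradient) / 100 * domain_length
}

#' Group an isoform by the magnitude of its divergence gradient
#'
#' @param fit a `myo_fit`, or a numeric gradient.
#' @param strong,weak |gradient| thresholds (% per log10 kg): strong above
#'   `strong`, weak below `weak`, intermediate otherwise.
#' @return one of "strong", "weak", "intermediate".
#' @export
classify_gradient <- function(fit, strong = 0.5, weak = 0.1) {
  g <- if (inherits(fit, "myo_fit")) fit$gradient else fit
  stopifnot_scalar_number(g, "gradient")
  if (abs(g) > strong) "strong" else if (abs(g) < weak) "weak" else "intermediate"
}
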