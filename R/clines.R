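# Two-parameter sigmoid geographic clines.
#
# p(x) = (1 + tanh(2 (x - c) / w)) / 2 with center c (position of the 50%
# frequency, km) and width w (inverse of the maximum slope, km). Fitting is
# by maximum binomial likelihood over per-locality derived-allele counts,
# with multi-start bounded optimisation and 2-log-likelihood-unit profile
# intervals. Loci whose data decrease with distance are fitted on a
# reflected axis and mapped back, so every locus runs through one increasing
# canonical form.

#' Sigmoid cline frequency
#'
#' @param x Position along the transect (km), vectorised.
#' @param c Cline center (km).
#' @param w Cline width (km), the inverse of the maximum slope; must be
#'   positive.
#' @return Expected derived-allele frequency at `x`.
#' @export
cline_predict <- function(x, c, w) {
  stop_if(!is.numeric(w) || any(w <= 0), "cline width must be positive")
  (1 + tanh(2 * (x - c) / w)) / 2
}

#' Binomial cline log-likelihood
#'
#' Sum over localities of `log Binomial(derived; total, p(x))` with the
#' predicted frequency clamped to `[1e-6, 1 - 1e-6]`. Fractional counts
#' (effective allele counts for mean-ancestry pseudo-data) are handled
#' through the gamma-function form of the binomial coefficient.
#'
#' @param profile A [frequency_profile()] (rows for one locus).
#' @param c,w Cline parameters.
#' @return Log-likelihood (scalar).
#' @export
cline_loglik <- function(profile, c, w) {
  stop_if(any(profile$derived > profile$total), "derived count exceeds total")
  p <- clamp(cline_predict(profile$distance_km, c, w))
  k <- profile$derived; n <- profile$total
  # gamma form of the binomial coefficient: valid for fractional counts
  sum(lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
        k * log(p) + (n - k) * log1p(-p))
}

#' Fit a sigmoid cline by maximum likelihood
#'
#' Multi-start bounded optimisation (coarse center-by-width grid, then
#' L-BFGS-B refinement on (c, log w)) of [cline_loglik()], followed by
#' 2-log-likelihood-unit profile intervals: all parameter values whose
#' profile log-likelihood is within 2 units of the maximum.
#'
#' @param profile A [frequency_profile()] for a single locus (or pseudo-locus
#'   such as mean ancestry), with at least 3 localities and non-constant
#'   frequencies.
#' @param c_bounds,w_bounds Optional search bounds `c(lo, hi)`; defaults are
#'   the data range extended by 25% for the center, and `[0.05, 3 x range]`
#'   km for the width. Step-like data drive the width to its lower bound.
#' @param compute_ci Compute profile intervals (set `FALSE` for speed in
#'   large multi-locus scans).
#' @param kind Data kind tag: `"snp"`, `"mito"` or `"ancestry_q"`.
#' @return An object of class `cline_fit` with elements `center`, `width`,
#'   `loglik`, `center_ci`, `width_ci`, `n_localities`, `kind` and
#'   `reversed` (whether the derived allele was modelled on a reflected
#'   axis).
#' @export
fit_cline <- function(profile, c_bounds = NULL, w_bounds = NULL,
                      compute_ci = TRUE,
                      kind = c("snp", "mito", "ancestry_q")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(profile))
  stop_if(length(unique(profile$locality)) < 3,
          "cline fitting needs at least 3 localities")
  freq <- profile$derived / profile$total
  stop_if(stats::var(freq) == 0,
          "degenerate data: all frequencies identical")
  x <- profile$distance_km
  xr <- range(x); span <- diff(xr)
  stop_if(span <= 0, "localities span zero distance")

  # canonical orientation: frequency increasing with x; otherwise reflect
  slope <- stats::cor(freq, x)
  reversed <- is.finite(slope) && slope < 0
  refl <- xr[1] + xr[2]
  work <- profile
  if (reversed) work$distance_km <- refl - work$distance_km

  if (is.null(c_bounds)) c_bounds <- c(xr[1] - 0.25 * span, xr[2] + 0.25 * span)
  if (is.null(w_bounds)) w_bounds <- c(0.05, 3 * span)
  stop_if(w_bounds[1] <= 0, "width lower bound must be positive")

  nll <- function(par) -cline_loglik(work, par[1], exp(par[2]))
  lw_b <- log(w_bounds)

  # coarse grid of starts
  cg <- seq(max(c_bounds[1], xr[1]), min(c_bounds[2], xr[2]), length.out = 7)
  wg <- exp(seq(lw_b[1], lw_b[2], length.out = 7))
  grid <- expand.grid(c = cg, w = wg)
  gll <- mapply(function(c, w) cline_loglik(work, c, w), grid$c, grid$w)
  starts <- grid[order(-gll)[1:3], , drop = FALSE]

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(c(starts$c[i], log(starts$w[i])), nll,
                            method = "L-BFGS-B",
                            lower = c(c_bounds[1], lw_b[1]),
                            upper = c(c_bounds[2], lw_b[2])),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  stop_if(is.null(best), "cline optimisation failed")
  c_hat <- best$par[1]; w_hat <- exp(best$par[2]); ll <- -best$value

  c_ci <- w_ci <- c(NA_real_, NA_real_)
  if (compute_ci) {
    prof_c <- function(cc) {
      o <- stats::optimize(function(lw) -cline_loglik(work, cc, exp(lw)),
                           lw_b)
      -o$objective
    }
    prof_w <- function(ww) {
      o <- stats::optimize(function(cc) -cline_loglik(work, cc, ww),
                           c_bounds)
      -o$objective
    }
    c_ci <- profile_interval(prof_c, c_hat, ll - 2, c_bounds)
    w_ci_log <- profile_interval(function(lw) prof_w(exp(lw)),
                                 log(w_hat), ll - 2, lw_b)
    w_ci <- exp(w_ci_log)
  }

  if (reversed) {
    c_hat <- refl - c_hat
    c_ci <- rev(refl - c_ci)
  }

  structure(list(center = c_hat, width = w_hat, loglik = ll,
                 center_ci = c_ci, width_ci = w_ci,
                 n_localities = length(unique(profile$locality)),
                 kind = kind, reversed = reversed,
                 locus = if (length(unique(profile$locus)) == 1L)
                   profile$locus[1] else NA_character_),
            class = "cline_fit")
}

# Walk outward from the estimate until the profile log-likelihood drops
# below `target`, then bisect the crossing. Returns c(lo, hi) clipped to
# `bounds` when the likelihood never drops inside them.
profile_interval <- function(prof, est, target, bounds, n_grid = 40L) {
  edge <- function(dir) {
    lim <- if (dir < 0) bounds[1] else bounds[2]
    if (abs(lim - est) < 1e-12) return(lim)
    grid <- seq(est, lim, length.out = n_grid)[-1]
    inside <- est
    for (g in grid) {
      if (prof(g) >= target) inside <- g
      else {
        lo <- inside; hi <- g
        for (k in 1:30) {
          mid <- (lo + hi) / 2
          if (prof(mid) >= target) lo <- mid else hi <- mid
          if (abs(hi - lo) < 1e-6 * max(1, abs(est))) break
        }
        return(lo)
      }
    }
    lim
  }
  c(edge(-1), edge(+1))
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf(
    "<cline_fit:%s> center %.2f km (%.2f-%.2f), width %.2f km (%.2f-%.2f), logLik %.2f\n",
    x$kind, x$center, x$center_ci[1], x$center_ci[2],
    x$width, x$width_ci[1], x$width_ci[2], x$loglik))
  invisible(x)
}

#' Fit clines for every locus of a frequency profile
#'
#' @param profile A [frequency_profile()] covering one or more loci.
#' @param ... Passed to [fit_cline()].
#' @return Named list of `cline_fit` objects (failed loci are dropped with a
#'   message).
#' @export
fit_clines <- function(profile, ...) {
  by_locus <- split(seq_len(nrow(profile)), profile$locus)
  fits <- list()
  failed <- 0L
  for (loc in names(by_locus)) {
    f <- try(fit_cline(profile[by_locus[[loc]], , drop = FALSE], ...),
             silent = TRUE)
    if (inherits(f, "try-error")) failed <- failed + 1L
    else fits[[loc]] <- f
  }
  if (failed > 0) message(sprintf("dropped %d loci that failed to fit", failed))
  fits
}

#' Multi-locus cline summary with barrier flags
#'
#' Summarises per-locus fits: mean/median/SD of widths, mean center,
#' per-locus center deviations (delta_c = c_l - mean c), and flags candidate
#' barrier loci — loci of essentially null width, resisting introgression —
#' as those with fitted width below `barrier_threshold`.
#'
#' @param fits List of `cline_fit` objects (e.g. from [fit_clines()]).
#' @param barrier_threshold Width (km) under which a locus is flagged.
#' @return An object of class `multilocus_summary` with a per-locus table
#'   and summary statistics.
#' @export
summarize_multilocus <- function(fits, barrier_threshold = 2) {
  stop_if(length(fits) == 0, "no fits to summarise")
  w <- vapply(fits, function(f) f$width, 1)
  cc <- vapply(fits, function(f) f$center, 1)
  if (length(fits) == 1L) {
    warning("single fit: width SD reported as 0")
  }
  tab <- data.frame(
    locus = if (is.null(names(fits))) seq_along(fits) else names(fits),
    center_km = cc, width_km = w,
    center_lo = vapply(fits, function(f) f$center_ci[1], 1),
    center_hi = vapply(fits, function(f) f$center_ci[2], 1),
    width_lo = vapply(fits, function(f) f$width_ci[1], 1),
    width_hi = vapply(fits, function(f) f$width_ci[2], 1),
    delta_c_km = cc - mean(cc),
    barrier = w < barrier_threshold,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_locus = tab,
                 mean_width = mean(w), median_width = stats::median(w),
                 sd_width = sd0(w), mean_center = mean(cc),
                 barrier_threshold = barrier_threshold,
                 n_barrier = sum(tab$barrier)),
            class = "multilocus_summary")
}

#' @export
print.multilocus_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<multilocus_summary> %d loci | width %.1f +/- %.1f km ",
           "(median %.1f) | mean center %.1f km | %d barrier loci (< %g km)\n"),
    nrow(x$per_locus), x$mean_width, x$sd_width, x$median_width,
    x$mean_center, x$n_barrier, x$barrier_threshold))
  invisible(x)
}

#' Build frequency profiles from a genotype dataset
#'
#' Converts per-locality allele counts of a transect dataset into the
#' long-format [frequency_profile()] consumed by [fit_cline()]. Localities
#' without calls at a locus are omitted for that locus.
#'
#' @param ds A [genotype_dataset()] (transect individuals).
#' @param localities A [locality_table()] with transect distances filled.
#' @return A `frequency_profile`.
#' @export
profiles_from_dataset <- function(ds, localities) {
  af <- allele_frequencies(ds, "locality")
  d <- localities$transect_distance_km[match(af$groups, localities$locality)]
  stop_if(anyNA(d), "every locality needs a transect distance")
  rows <- which(af$n_called > 0, arr.ind = TRUE)
  frequency_profile(
    locus = af$loci[rows[, 1]],
    locality = af$groups[rows[, 2]],
    distance_km = d[rows[, 2]],
    derived = af$alt_count[rows],
    total = 2 * af$n_called[rows])
}

#' Mean-ancestry pseudo-profile for cline fitting
#'
#' Treats per-locality mean ancestry Q as a binomial proportion with an
#' effective allele count of 2 x individuals (documented assumption).
#'
#' @param mean_q Output of [population_mean_q()].
#' @param localities A [locality_table()] with distances.
#' @return A single-locus `frequency_profile` named `"ancestry_Q"`.
#' @export
q_profile <- function(mean_q, localities) {
  d <- localities$transect_distance_km[match(mean_q$locality,
                                             localities$locality)]
  stop_if(anyNA(d), "every locality needs a transect distance")
  frequency_profile("ancestry_Q", mean_q$locality, d,
                    mean_q$mean_Q * 2 * mean_q$n, 2 * mean_q$n)
}
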