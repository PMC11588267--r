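# Bioacoustic reinforcement test battery.
#
# Temperature adjustment of note duration, PCA of the four call parameters
# on the correlation matrix, and three ad hoc statistics comparing the two
# species between allopatric and parapatric contexts:
#   (1) weighted convex-hull overlap on the PC1/PC2 and PC3/PC4 planes,
#   (2) variance-weighted centroid distance,
#   (3) variance-weighted standard deviation per group.
# Each yields a Delta (parapatric minus allopatric) whose significance comes
# from a permutation null that reshuffles the four-level group label, plus a
# down-sampling variant for unequal group sizes.

GROUP_LEVELS <- c("allopatric-A", "allopatric-B", "parapatric-A",
                  "parapatric-B")
DELTA_STATS <- c("overlap", "centroid_distance", "sd_A", "sd_B",
                 "sd_cumulated")

#' Remove the temperature effect from note duration
#'
#' Replaces ND by the residuals of an ordinary least-squares regression of
#' ND on recording temperature; DF, RT and PR pass through unchanged.
#'
#' @param calls A [call_table()].
#' @return A list with `traits` (numeric matrix DF, ND, RT, PR; ND as
#'   residuals), `temp_nd_r` (the Pearson correlation between temperature
#'   and raw ND) and `group` (the group factor).
#' @export
temperature_adjust <- function(calls) {
  stopifnot(inherits(calls, "data.frame"))
  stop_if(anyNA(calls$temperature_C), "temperature missing for some individuals")
  stop_if(stats::var(calls$temperature_C) == 0,
          "all temperatures identical: regression undefined")
  fit <- stats::lm(ND_s ~ temperature_C, data = calls)
  traits <- cbind(DF = calls$DF_Hz, ND = stats::residuals(fit),
                  RT = calls$RT_s, PR = calls$PR_per_s)
  rownames(traits) <- calls$individual
  list(traits = traits,
       temp_nd_r = stats::cor(calls$temperature_C, calls$ND_s),
       group = factor(calls$group, levels = GROUP_LEVELS))
}

#' PCA of the four call parameters
#'
#' Traits are z-scored (PCA on the correlation matrix, since DF, ND, RT and
#' PR carry incommensurate units) and eigen-decomposed. Component signs are
#' fixed so each loading vector's largest-magnitude entry is positive.
#'
#' @param traits Numeric matrix (individuals x 4 traits), e.g.
#'   `temperature_adjust(calls)$traits`.
#' @return An object of class `call_pca`: `scores` (individuals x 4),
#'   `var_explained` (proportions summing to 1), `loadings`.
#' @export
run_call_pca <- function(traits) {
  stop_if(nrow(traits) < 5, "PCA needs at least 5 individuals")
  stop_if(ncol(traits) != 4, "expected the four call parameters")
  sds <- apply(traits, 2, stats::sd)
  stop_if(any(sds == 0), "constant trait column")
  pc <- stats::prcomp(traits, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  v <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, var_explained = v, loadings = rot),
            class = "call_pca")
}

#' @export
print.call_pca <- function(x, ...) {
  cat("<call_pca>", nrow(x$scores), "individuals; variance explained:",
      paste(sprintf("PC%d %.1f%%", 1:4, 100 * x$var_explained),
            collapse = ", "), "\n")
  invisible(x)
}

## ---- convex hulls --------------------------------------------------------

# Counterclockwise convex hull of a 2-column matrix.
ccw_hull <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  poly <- pts[h, , drop = FALSE]
  if (polygon_area_signed(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ,
                                                  drop = FALSE]
  poly
}

polygon_area_signed <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

# Sutherland-Hodgman clipping of convex polygon `subj` by convex `clip`
# (both counterclockwise). Returns the intersection polygon.
clip_convex <- function(subj, clip) {
  out <- subj
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    side <- (b[1] - a[1]) * (out[, 2] - a[2]) -
      (b[2] - a[2]) * (out[, 1] - a[1])
    keep <- side >= 0
    if (all(keep)) next
    ns <- nrow(out)
    nxt <- c(2:ns, 1)[seq_len(ns)]
    if (ns == 1L) nxt <- 1L
    res <- vector("list", 2L * ns)
    m <- 0L
    for (j in seq_len(ns)) {
      k <- nxt[j]
      if (keep[j]) { m <- m + 1L; res[[m]] <- out[j, ] }
      if (xor(keep[j], keep[k])) {
        t <- side[j] / (side[j] - side[k])
        m <- m + 1L
        res[[m]] <- out[j, ] + t * (out[k, ] - out[j, ])
      }
    }
    out <- if (m == 0L) matrix(numeric(0), 0, 2) else
      do.call(rbind, res[seq_len(m)])
  }
  out
}

#' Convex-hull overlap of two 2-D point sets
#'
#' Builds the convex hull of each set, computes the exact intersection area
#' by polygon clipping, and returns the mean of the two directed overlap
#' fractions `(I/area_a + I/area_b) / 2` (or the Jaccard fraction
#' `I / (area_a + area_b - I)` when `method = "jaccard"`). Disjoint hulls
#' give 0; a degenerate (zero-area) hull gives 0 with a warning.
#'
#' @param points_a,points_b Two-column matrices of at least 3 points each.
#' @param method Overlap definition.
#' @return Overlap fraction in `[0, 1]`.
#' @export
hull_overlap_2d <- function(points_a, points_b,
                            method = c("mean_directed", "jaccard")) {
  method <- match.arg(method)
  stop_if(nrow(points_a) < 3 || nrow(points_b) < 3,
          "each point set needs at least 3 points")
  ha <- ccw_hull(points_a)
  hb <- ccw_hull(points_b)
  area_a <- polygon_area_signed(ha)
  area_b <- polygon_area_signed(hb)
  if (area_a <= 0 || area_b <= 0) {
    warning("degenerate (zero-area) hull; overlap set to 0")
    return(0)
  }
  inter <- clip_convex(ha, hb)
  ai <- if (nrow(inter) < 3) 0 else abs(polygon_area_signed(inter))
  if (method == "mean_directed") (ai / area_a + ai / area_b) / 2
  else ai / (area_a + area_b - ai)
}

## ---- the three statistics ------------------------------------------------

split_label <- function(labels) {
  labels <- factor(labels, levels = GROUP_LEVELS)
  stop_if(anyNA(labels), "labels must be the four species-context groups")
  list(context = ifelse(grepl("^allopatric", as.character(labels)),
                        "allopatric", "parapatric"),
       species = ifelse(grepl("-A$", as.character(labels)), "A", "B"))
}

#' Weighted hull-overlap statistic between species in one context
#'
#' Hull overlap between the two species computed separately on the PC1/PC2
#' and PC3/PC4 planes and averaged with weights proportional to the
#' variance explained by each pair of components.
#'
#' @param pca A [run_call_pca()] result.
#' @param labels Group labels (the four species-context groups) per
#'   individual.
#' @param context `"allopatric"` or `"parapatric"`.
#' @return Weighted overlap in `[0, 1]`.
#' @export
overlap_statistic <- function(pca, labels,
                              context = c("allopatric", "parapatric")) {
  context <- match.arg(context)
  sl <- split_label(labels)
  a <- pca$scores[sl$context == context & sl$species == "A", , drop = FALSE]
  b <- pca$scores[sl$context == context & sl$species == "B", , drop = FALSE]
  stop_if(nrow(a) < 3 || nrow(b) < 3,
          "each species needs at least 3 individuals in the context")
  v <- pca$var_explained
  w12 <- (v[1] + v[2]) / sum(v)
  w34 <- (v[3] + v[4]) / sum(v)
  w12 * hull_overlap_2d(a[, 1:2, drop = FALSE], b[, 1:2, drop = FALSE]) +
    w34 * hull_overlap_2d(a[, 3:4, drop = FALSE], b[, 3:4, drop = FALSE])
}

#' Variance-weighted centroid distance between species in one context
#'
#' Group mean scores are weighted by the variance explained by each
#' component before taking the Euclidean distance:
#' `sqrt(sum_k (v_k (mean_Ak - mean_Bk))^2)`.
#'
#' @inheritParams overlap_statistic
#' @return Non-negative distance.
#' @export
centroid_distance_statistic <- function(pca, labels,
                                        context = c("allopatric",
                                                    "parapatric")) {
  context <- match.arg(context)
  sl <- split_label(labels)
  a <- pca$scores[sl$context == context & sl$species == "A", , drop = FALSE]
  b <- pca$scores[sl$context == context & sl$species == "B", , drop = FALSE]
  stop_if(nrow(a) == 0 || nrow(b) == 0, "empty species-context group")
  v <- pca$var_explained
  sqrt(sum((v * (colMeans(a) - colMeans(b)))^2))
}

#' Variance-weighted standard deviation of one species-context group
#'
#' `sum_k v_k sd_k(scores)` with the sample (n-1) standard deviation.
#'
#' @inheritParams overlap_statistic
#' @param species `"A"` or `"B"`.
#' @return Non-negative scalar.
#' @export
weighted_sd_statistic <- function(pca, labels, species = c("A", "B"),
                                  context = c("allopatric", "parapatric")) {
  species <- match.arg(species)
  context <- match.arg(context)
  sl <- split_label(labels)
  g <- pca$scores[sl$context == context & sl$species == species, ,
                  drop = FALSE]
  stop_if(nrow(g) < 2, "group needs at least 2 individuals")
  sum(pca$var_explained * apply(g, 2, stats::sd))
}

#' The five Delta statistics (parapatric minus allopatric)
#'
#' @inheritParams overlap_statistic
#' @return Data frame with one row per statistic (`overlap`,
#'   `centroid_distance`, `sd_A`, `sd_B`, `sd_cumulated`) and columns
#'   `allopatric`, `parapatric`, `delta`.
#' @export
delta_suite <- function(pca, labels) {
  sl <- split_label(labels)
  vals <- delta_suite_values(pca$scores, pca$var_explained,
                             sl$species, sl$context)
  data.frame(statistic = DELTA_STATS,
             allopatric = vals$allo, parapatric = vals$para,
             delta = vals$para - vals$allo,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Internal fast path shared with the permutation loop: species/context are
# plain character vectors, scores/v fixed.
delta_suite_values <- function(scores, v, species, context) {
  idx <- list(
    aA = which(context == "allopatric" & species == "A"),
    aB = which(context == "allopatric" & species == "B"),
    pA = which(context == "parapatric" & species == "A"),
    pB = which(context == "parapatric" & species == "B"))
  stop_if(any(lengths(idx) == 0), "all four groups must be populated")
  w12 <- v[1] + v[2]; w34 <- v[3] + v[4]
  ov <- function(i, j) {
    w12 * hull_overlap_2d(scores[i, 1:2, drop = FALSE],
                          scores[j, 1:2, drop = FALSE]) +
      w34 * hull_overlap_2d(scores[i, 3:4, drop = FALSE],
                            scores[j, 3:4, drop = FALSE])
  }
  cd <- function(i, j) {
    sqrt(sum((v * (colMeans(scores[i, , drop = FALSE]) -
                     colMeans(scores[j, , drop = FALSE])))^2))
  }
  ws <- function(i) sum(v * apply(scores[i, , drop = FALSE], 2, stats::sd))
  allo <- c(ov(idx$aA, idx$aB), cd(idx$aA, idx$aB), ws(idx$aA), ws(idx$aB))
  para <- c(ov(idx$pA, idx$pB), cd(idx$pA, idx$pB), ws(idx$pA), ws(idx$pB))
  allo <- c(allo, allo[3] + allo[4])
  para <- c(para, para[3] + para[4])
  list(allo = allo, para = para)
}

#' Permutation P-value rule
#'
#' Plain proportion of permuted statistics at least as extreme (in absolute
#' value) as the observed one: `P = #\{|Delta_perm| >= |Delta_obs|\} / B`.
#' No add-one correction, so a null sample of 1,000 permutations in which
#' exactly 22 exceed the observed value gives P = 0.022 exactly, and an
#' observed Delta of 0 gives P = 1.
#'
#' @param null_deltas Numeric vector (or matrix, statistics in columns) of
#'   permuted Delta values.
#' @param observed Observed Delta value(s), one per column.
#' @return P-value(s) in `{0, 1/B, ..., 1}`.
#' @export
perm_p_value <- function(null_deltas, observed) {
  if (is.matrix(null_deltas)) {
    stop_if(length(observed) != ncol(null_deltas),
            "one observed value per column is required")
    colMeans(sweep(abs(null_deltas), 2, abs(observed), ">="))
  } else {
    mean(abs(null_deltas) >= abs(observed))
  }
}

#' Permutation test for the five Delta statistics
#'
#' Reshuffles the four-level group label across all individuals (group sizes
#' preserved; PCA scores fixed, not refit) `B` times and, for each
#' statistic, computes `P = #\{|Delta_perm| >= |Delta_obs|\} / B`. When
#' `downsample` is `TRUE`, a second pass first randomly reduces every group
#' larger than `downsample_to` to that size, recomputes the observed Deltas
#' on the reduced data and permutes again, giving `P_downsampled`.
#'
#' @inheritParams overlap_statistic
#' @param B Number of permutations.
#' @param seed RNG seed for the permutation (and down-sampling) stream.
#' @param downsample_to Group-size cutoff for the down-sampling variant.
#' @param downsample Whether to run the down-sampling pass.
#' @return An object of class `delta_test`: a data frame with columns
#'   `statistic`, `allopatric`, `parapatric`, `delta`, `P`,
#'   `P_downsampled`, with the permutation null samples in
#'   `attr(, "null_deltas")` (B x 5 matrix).
#' @export
permutation_test <- function(pca, labels, B = 1000L, seed = NULL,
                             downsample_to = 10L, downsample = TRUE) {
  stop_if(!is_count(B) || B < 1, "B must be a positive integer")
  sl <- split_label(labels)
  scores <- pca$scores
  v <- pca$var_explained
  obs <- delta_suite_values(scores, v, sl$species, sl$context)
  d_obs <- obs$para - obs$allo

  run_perms <- function(scores, species, context, B) {
    n <- length(species)
    null_d <- matrix(NA_real_, B, 5,
                     dimnames = list(NULL, DELTA_STATS))
    for (b in seq_len(B)) {
      idx <- sample.int(n)
      vals <- delta_suite_values(scores, v, species[idx], context[idx])
      null_d[b, ] <- vals$para - vals$allo
    }
    null_d
  }

  with_seed(seed, {
    null_d <- run_perms(scores, sl$species, sl$context, B)
    P <- perm_p_value(null_d, d_obs)

    P_ds <- rep(NA_real_, 5)
    if (isTRUE(downsample)) {
      lab <- factor(paste(sl$context, sl$species, sep = "-"))
      keep <- unlist(lapply(split(seq_along(lab), lab), function(i) {
        if (length(i) > downsample_to) sample(i, downsample_to) else i
      }), use.names = FALSE)
      stop_if(any(table(lab[keep]) < 3),
              "a group has fewer than 3 individuals after down-sampling")
      ds_scores <- scores[keep, , drop = FALSE]
      ds_species <- sl$species[keep]; ds_context <- sl$context[keep]
      obs_ds <- delta_suite_values(ds_scores, v, ds_species, ds_context)
      d_ds <- obs_ds$para - obs_ds$allo
      null_ds <- run_perms(ds_scores, ds_species, ds_context, B)
      P_ds <- perm_p_value(null_ds, d_ds)
    }

    out <- data.frame(statistic = DELTA_STATS,
                      allopatric = obs$allo, parapatric = obs$para,
                      delta = d_obs, P = as.numeric(P),
                      P_downsampled = as.numeric(P_ds),
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "null_deltas") <- null_d
    attr(out, "B") <- as.integer(B)
    class(out) <- c("delta_test", "data.frame")
    out
  })
}

#' @export
print.delta_test <- function(x, ...) {
  cat(sprintf("<delta_test> B = %d permutations\n", attr(x, "B")))
  print.data.frame(
    transform(as.data.frame(x),
              allopatric = round(allopatric, 3),
              parapatric = round(parapatric, 3),
              delta = round(delta, 3)),
    row.names = FALSE)
  invisible(x)
}
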