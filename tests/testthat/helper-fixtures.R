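# Shared fixtures and independent oracles.

# Small genotype dataset with known entries.
tiny_dataset <- function() {
  g <- rbind(c(0L, 1L, 2L, NA),
             c(1L, 1L, 2L, 0L),
             c(2L, NA, 2L, 0L),
             c(0L, 0L, NA, 1L))
  genotype_dataset(g, paste0("i", 1:4), c("P1", "P1", "P2", "P2"),
                   paste0("L", 1:4))
}

random_dataset <- function(n = 12, L = 20, missing = 0.1, seed = 99) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  g[runif(n * L) < missing] <- NA_integer_
  genotype_dataset(g, sprintf("i%02d", 1:n),
                   rep(sprintf("P%d", 1:3), length.out = n),
                   sprintf("L%03d_%d", rep(1:(L / 2), each = 2), 1:2))
}

# Monte-Carlo estimate of the mean-directed hull-overlap fraction,
# independent of the polygon-clipping code: rejection sampling over the
# joint bounding box with sign-based point-in-convex-polygon tests.
mc_hull_overlap <- function(a, b, n = 1e5) {
  hull_ccw <- function(p) {
    h <- p[grDevices::chull(p), , drop = FALSE]
    # orient counterclockwise by shoelace sign
    nn <- nrow(h); j <- c(2:nn, 1)
    if (sum(h[, 1] * h[j, 2] - h[j, 1] * h[, 2]) < 0) h <- h[nn:1, ]
    h
  }
  in_hull <- function(pts, h) {
    nn <- nrow(h)
    ok <- rep(TRUE, nrow(pts))
    for (i in seq_len(nn)) {
      p1 <- h[i, ]; p2 <- h[if (i == nn) 1 else i + 1, ]
      cr <- (p2[1] - p1[1]) * (pts[, 2] - p1[2]) -
        (p2[2] - p1[2]) * (pts[, 1] - p1[1])
      ok <- ok & cr >= 0
    }
    ok
  }
  ha <- hull_ccw(a); hb <- hull_ccw(b)
  xr <- range(c(ha[, 1], hb[, 1])); yr <- range(c(ha[, 2], hb[, 2]))
  pts <- cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]))
  ina <- in_hull(pts, ha); inb <- in_hull(pts, hb)
  box <- diff(xr) * diff(yr)
  I <- mean(ina & inb) * box
  (I / (mean(ina) * box) + I / (mean(inb) * box)) / 2
}

random_convex_pair <- function(seed) {
  set.seed(seed)
  a <- cbind(rnorm(12), rnorm(12))
  shift <- runif(2, -1.5, 1.5)
  b <- cbind(rnorm(12) * runif(1, 0.5, 1.5) + shift[1],
             rnorm(12) * runif(1, 0.5, 1.5) + shift[2])
  list(a = a, b = b)
}

# Fake PCA object with chosen scores and weights (for statistic unit tests).
fake_pca <- function(scores, v = rep(0.25, 4)) {
  structure(list(scores = scores, var_explained = v,
                 loadings = diag(4)), class = "call_pca")
}

# Binomial count profile drawn from a known cline.
cline_profile <- function(c, w, n_alleles = 40, L = 170, n_loc = 19,
                          seed = 1) {
  set.seed(seed)
  x <- seq(0, L, length.out = n_loc)
  k <- rbinom(n_loc, n_alleles, cline_predict(x, c, w))
  frequency_profile("L1", sprintf("P%02d", seq_len(n_loc)), x, k,
                    rep(n_alleles, n_loc))
}
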