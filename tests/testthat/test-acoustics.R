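test_that("temperature adjustment follows OLS residual identities", {
  # ND orthogonal to centered temperature -> residuals are centered ND
  temp <- c(10, 12, 14, 16, 18, 20)
  # pattern orthogonal to centered temperature: zero in-sample slope
  nd <- 0.12 + c(1, -1, 0, 0, -1, 1) * 0.01
  stopifnot(abs(sum((temp - mean(temp)) * (nd - mean(nd)))) < 1e-12)
  calls <- call_table(sprintf("i%d", 1:6), rep("P", 6),
                      rep(c("allopatric-A", "allopatric-B"), 3),
                      temp, DF_Hz = 1200, ND_s = nd, RT_s = 0.05,
                      PR_per_s = 90)
  adj <- temperature_adjust(calls)
  expect_equal(unname(adj$traits[, "ND"]), nd - mean(nd), tolerance = 1e-12)

  # planted slope: residuals orthogonal to temperature (normal equations)
  set.seed(2)
  nd2 <- 0.2 - 0.005 * temp + rnorm(6, 0, 0.002)
  calls2 <- call_table(sprintf("i%d", 1:6), rep("P", 6),
                       rep("allopatric-A", 6), temp, DF_Hz = 1200,
                       ND_s = nd2, RT_s = 0.01, PR_per_s = 90)
  adj2 <- temperature_adjust(calls2)
  expect_lt(abs(cor(adj2$traits[, "ND"], temp)), 1e-10)
  expect_lt(adj2$temp_nd_r, 0)  # reported correlation

  calls3 <- calls
  calls3$temperature_C <- rep(15, 6)
  expect_error(temperature_adjust(calls3), "identical")
})

test_that("PCA satisfies its spectral contracts", {
  set.seed(5)
  x <- matrix(rnorm(2000 * 4), 2000, 4)
  colnames(x) <- c("DF", "ND", "RT", "PR")
  pca <- run_call_pca(x)
  expect_equal(sum(pca$var_explained), 1)
  expect_true(all(abs(pca$var_explained - 0.25) < 0.05))  # identity limit
  expect_true(all(abs(colMeans(pca$scores)) < 1e-10))     # centered
  # sign convention: dominant loading positive
  expect_true(all(apply(pca$loadings, 2, function(v) v[which.max(abs(v))]) > 0))

  # a dominant correlated pair pushes variance onto PC1
  y <- x
  y[, 2] <- y[, 1] + rnorm(2000, 0, 0.3)
  pcy <- run_call_pca(y)
  expect_gt(pcy$var_explained[1], pcy$var_explained[2])
  expect_true(all(diff(pcy$var_explained) <= 1e-12))      # sorted

  xc <- x; xc[, 3] <- 1
  expect_error(run_call_pca(xc), "constant")
})

test_that("hull overlap handles exact and degenerate geometries", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  shifted <- sweep(sq, 2, c(0.5, 0), "+")
  expect_equal(hull_overlap_2d(sq, shifted), 0.5)  # I = 0.5, areas 1
  expect_equal(hull_overlap_2d(sq, sq), 1)
  far <- sweep(sq, 2, c(10, 10), "+")
  expect_equal(hull_overlap_2d(sq, far), 0)
  expect_warning(o <- hull_overlap_2d(cbind(1:5, 1:5), sq), "degenerate")
  expect_equal(o, 0)
  # jaccard variant: 0.5 / (1 + 1 - 0.5)
  expect_equal(hull_overlap_2d(sq, shifted, method = "jaccard"), 1 / 3)
})

test_that("hull overlap is symmetric and rigid-motion invariant", {
  set.seed(8)
  for (i in 1:5) {
    pp <- random_convex_pair(300 + i)
    o1 <- hull_overlap_2d(pp$a, pp$b)
    expect_equal(hull_overlap_2d(pp$b, pp$a), o1, tolerance = 1e-12)
    th <- runif(1, 0, 2 * pi); R <- matrix(c(cos(th), sin(th),
                                             -sin(th), cos(th)), 2, 2)
    shift <- runif(2, -5, 5)
    rot <- function(p) sweep(p %*% R, 2, shift, "+")
    expect_equal(hull_overlap_2d(rot(pp$a), rot(pp$b)), o1, tolerance = 1e-9)
  }
})

test_that("polygon clipping agrees with the Monte-Carlo area oracle", {
  set.seed(10)
  for (i in 1:8) {
    pp <- random_convex_pair(i)
    expect_equal(hull_overlap_2d(pp$a, pp$b),
                 mc_hull_overlap(pp$a, pp$b, n = 2e5), tolerance = 0.012)
  }
})

test_that("overlap statistic behaves at its limits", {
  set.seed(12)
  n <- 400
  scores_same <- rbind(matrix(rnorm(n * 4), n, 4), matrix(rnorm(n * 4), n, 4))
  labels <- rep(c("allopatric-A", "allopatric-B"), each = n)
  # two species from one distribution: overlap near 1 at large n
  pca <- fake_pca(scores_same)
  expect_gt(overlap_statistic(pca, labels, "allopatric"), 0.7)
  # fully separated clusters on both planes: overlap 0
  scores_far <- scores_same
  scores_far[(n + 1):(2 * n), ] <- scores_far[(n + 1):(2 * n), ] + 100
  expect_equal(overlap_statistic(fake_pca(scores_far), labels, "allopatric"), 0)
  expect_error(overlap_statistic(pca, labels, "parapatric"), "at least 3")
})

test_that("centroid distance reduces to its formula and is translation-invariant", {
  v <- c(0.5, 0.3, 0.15, 0.05)
  base <- matrix(rnorm(40), 10, 4)
  shift1 <- base
  shift1[6:10, 1] <- shift1[6:10, 1] + 3   # delta on PC1 only
  shift1[6:10, 2:4] <- shift1[1:5, 2:4]    # identical on other PCs
  labels <- rep(c("parapatric-A", "parapatric-B"), each = 5)
  d <- centroid_distance_statistic(fake_pca(shift1, v), labels, "parapatric")
  delta1 <- mean(shift1[1:5, 1]) - mean(shift1[6:10, 1])
  expect_equal(d, v[1] * abs(delta1))

  moved <- sweep(shift1, 2, c(5, -2, 1, 9), "+")
  expect_equal(centroid_distance_statistic(fake_pca(moved, v), labels,
                                           "parapatric"), d)
  same <- rbind(shift1[1:5, ], shift1[1:5, ])
  expect_equal(centroid_distance_statistic(fake_pca(same, v), labels,
                                           "parapatric"), 0)
})

test_that("weighted SD is homogeneous and zero on identical points", {
  v <- c(0.4, 0.3, 0.2, 0.1)
  g <- matrix(rnorm(32), 8, 4)
  labels <- rep("allopatric-A", 8)
  s <- weighted_sd_statistic(fake_pca(g, v), labels, "A", "allopatric")
  expect_equal(weighted_sd_statistic(fake_pca(2 * g, v), labels, "A",
                                     "allopatric"), 2 * s)
  dup <- matrix(1, 8, 4) %*% diag(c(1, 2, 3, 4))
  expect_equal(weighted_sd_statistic(fake_pca(dup, v), labels, "A",
                                     "allopatric"), 0)
})

test_that("delta suite follows its sign convention and identities", {
  adj <- temperature_adjust(simulate_calls(call_scenario("null", seed = 3)))
  pca <- run_call_pca(adj$traits)
  d <- delta_suite(pca, adj$group)
  expect_identical(d$statistic, c("overlap", "centroid_distance", "sd_A",
                                  "sd_B", "sd_cumulated"))
  expect_equal(d$delta, d$parapatric - d$allopatric)
  expect_equal(d$delta[5], d$delta[3] + d$delta[4])  # cumulated = sum
  expect_equal(d$allopatric[5], d$allopatric[3] + d$allopatric[4])
})

test_that("deltas center on zero for exchangeable, size-balanced groups", {
  # with equal group sizes and no species/context effect, allopatric and
  # parapatric comparisons are symmetric, so every Delta is mean-zero;
  # unequal sizes bias the hull and centroid statistics (see vignette)
  set.seed(21)
  deltas <- replicate(40, {
    sc <- call_scenario("null", group_sizes = c(18L, 18L, 18L, 18L),
                        species_mean_shift = c(DF = 0, ND = 0, RT = 0,
                                               PR = 0),
                        seed = sample.int(1e6, 1))
    adj <- temperature_adjust(simulate_calls(sc))
    delta_suite(run_call_pca(adj$traits), adj$group)$delta
  })
  for (i in 1:5) {
    se <- sd(deltas[i, ]) / sqrt(ncol(deltas))
    expect_lt(abs(mean(deltas[i, ])), 3 * se + 0.01)
  }
})

test_that("the permutation P rule is the plain exceedance proportion", {
  # a null sample in which exactly 22 of 1,000 permuted |Delta| exceed
  null <- c(seq(0.5, 0.6, length.out = 22), runif(978, 0, 0.4))
  expect_identical(perm_p_value(null, 0.49), 0.022)
  expect_identical(perm_p_value(null, 0), 1)        # everything >= 0
  expect_identical(perm_p_value(rep(0, 100), 0.1), 0)
  m <- cbind(a = null, b = null)
  expect_identical(unname(perm_p_value(m, c(0.49, 0))), c(0.022, 1))
})

test_that("permutation_test is seeded, sized and internally consistent", {
  adj <- temperature_adjust(simulate_calls(call_scenario("null", seed = 6)))
  pca <- run_call_pca(adj$traits)
  pt <- permutation_test(pca, adj$group, B = 50, seed = 9)
  expect_s3_class(pt, "delta_test")
  null_d <- attr(pt, "null_deltas")
  expect_equal(dim(null_d), c(50L, 5L))
  expect_equal(pt$P, unname(perm_p_value(null_d, pt$delta)))
  expect_true(all(pt$P >= 0 & pt$P <= 1))
  expect_true(all(pt$P * 50 == round(pt$P * 50)))   # multiples of 1/B
  # determinism
  pt2 <- permutation_test(pca, adj$group, B = 50, seed = 9)
  expect_identical(as.data.frame(pt), as.data.frame(pt2))
  expect_error(permutation_test(pca, adj$group, B = 0), "positive")
})

test_that("species relabelling leaves overlap and centroid P-values unchanged", {
  adj <- temperature_adjust(simulate_calls(call_scenario("null", seed = 15)))
  pca <- run_call_pca(adj$traits)
  swap <- c("allopatric-A" = "allopatric-B", "allopatric-B" = "allopatric-A",
            "parapatric-A" = "parapatric-B", "parapatric-B" = "parapatric-A")
  pt1 <- permutation_test(pca, adj$group, B = 100, seed = 4,
                          downsample = FALSE)
  pt2 <- permutation_test(pca, swap[as.character(adj$group)], B = 100,
                          seed = 4, downsample = FALSE)
  expect_equal(pt1$P[1:2], pt2$P[1:2])
  # sd statistics swap between species
  expect_equal(pt1$P[3], pt2$P[4])
  expect_equal(pt1$delta[5], pt2$delta[5])
})

test_that("down-sampling reduces every group above the cutoff", {
  adj <- temperature_adjust(simulate_calls(call_scenario("null", seed = 18)))
  pca <- run_call_pca(adj$traits)
  pt <- permutation_test(pca, adj$group, B = 20, seed = 2, downsample_to = 10)
  expect_true(all(!is.na(pt$P_downsampled)))
  expect_error(permutation_test(pca, adj$group, B = 20, seed = 2,
                                downsample_to = 2),
               "fewer than 3")
})
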