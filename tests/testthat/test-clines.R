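test_that("cline_predict matches its closed form and width definition", {
  expect_equal(cline_predict(85, 85, 20), 0.5)
  expect_equal(cline_predict(85 + 20, 85, 20), (1 + tanh(2)) / 2)
  # width is the inverse of the maximum slope (numerical derivative at c)
  h <- 1e-5
  for (w in c(0.5, 5, 20.6, 80)) {
    slope <- (cline_predict(40 + h, 40, w) - cline_predict(40 - h, 40, w)) /
      (2 * h)
    expect_equal(slope, 1 / w, tolerance = 1e-6)
  }
  expect_error(cline_predict(0, 0, -1), "positive")
})

test_that("clines are point-symmetric about their center", {
  set.seed(4)
  for (i in 1:20) {
    c0 <- runif(1, 0, 170); w0 <- runif(1, 0.2, 60); x <- runif(5, -50, 220)
    expect_equal(cline_predict(x, c0, w0) + cline_predict(2 * c0 - x, c0, w0),
                 rep(1, 5), tolerance = 1e-12)
  }
})

test_that("cline_loglik equals the binomial oracle", {
  # p = 0.5 exactly at every locality (x = c), n = 2, k = 1
  prof <- frequency_profile("L", paste0("P", 1:3), rep(50, 3), rep(1, 3),
                            rep(2, 3))
  expect_equal(cline_loglik(prof, 50, 10), 3 * log(0.5))

  # generic integer case: independent dbinom oracle
  prof2 <- cline_profile(85, 20.6, n_alleles = 12, seed = 2)
  p <- pmin(pmax(cline_predict(prof2$distance_km, 85, 20.6), 1e-6), 1 - 1e-6)
  oracle <- sum(dbinom(prof2$derived, prof2$total, p, log = TRUE))
  expect_equal(cline_loglik(prof2, 85, 20.6), oracle, tolerance = 1e-10)

  # k = 0 with p clamped near zero contributes ~0
  p0 <- frequency_profile("L", "P1", 0, 0, 10)
  expect_lt(abs(cline_loglik(p0, 170, 1)), 1e-4)

  expect_error(cline_loglik(data.frame(distance_km = 1, derived = 5,
                                       total = 4), 0, 1),
               "exceeds")
})

test_that("likelihood prefers the generating parameters on rich data", {
  prof <- cline_profile(85, 20.6, n_alleles = 400, seed = 6)
  expect_gt(cline_loglik(prof, 85, 20.6), cline_loglik(prof, 95, 20.6))
  expect_gt(cline_loglik(prof, 85, 20.6), cline_loglik(prof, 85, 60))
})

test_that("fit_cline recovers parameters and honours its contracts", {
  prof <- cline_profile(85, 20.6, seed = 10)
  fit <- fit_cline(prof)
  expect_s3_class(fit, "cline_fit")
  expect_lt(abs(fit$center - 85), 6)
  # ML property: fitted likelihood at least that of the generating values
  expect_gte(fit$loglik, cline_loglik(prof, 85, 20.6))
  # profile intervals contain the point estimates
  expect_true(fit$center_ci[1] <= fit$center && fit$center <= fit$center_ci[2])
  expect_true(fit$width_ci[1] <= fit$width && fit$width <= fit$width_ci[2])

  # degenerate inputs
  flat <- frequency_profile("L", paste0("P", 1:4), c(0, 10, 20, 30),
                            rep(2, 4), rep(4, 4))
  expect_error(fit_cline(flat), "identical")
  expect_error(fit_cline(prof[1, ]), "3 localities")
})

test_that("step data drive the width to its lower search bound", {
  x <- seq(0, 170, length.out = 19)
  k <- ifelse(x < 85, 0, 40)
  prof <- frequency_profile("L", sprintf("P%02d", 1:19), x, k, rep(40, 19))
  fit <- fit_cline(prof)
  expect_equal(fit$width, 0.05, tolerance = 1e-6)
})

test_that("reversing the transect mirrors the center and keeps the width", {
  prof <- cline_profile(85, 20.6, seed = 12)
  rev_prof <- frequency_profile(prof$locus, prof$locality,
                                170 - prof$distance_km,
                                prof$total - prof$derived, prof$total)
  f1 <- fit_cline(prof, compute_ci = FALSE)
  f2 <- fit_cline(rev_prof, compute_ci = FALSE)
  expect_equal(f2$center, 170 - f1$center, tolerance = 1e-8)
  expect_equal(f2$width, f1$width, tolerance = 1e-8)
})

test_that("profile intervals shrink as allele counts grow", {
  widths <- vapply(c(10, 40, 160), function(n) {
    mean(vapply(1:4, function(s) {
      f <- fit_cline(cline_profile(85, 20.6, n_alleles = n, seed = 100 + s))
      diff(f$width_ci)
    }, 1))
  }, 1)
  expect_true(all(diff(widths) < 0))
})

test_that("multilocus summary computes hand-checked statistics", {
  fits <- list(
    A = structure(list(center = 80, width = 20, center_ci = c(70, 90),
                       width_ci = c(15, 30)), class = "cline_fit"),
    B = structure(list(center = 90, width = 22, center_ci = c(80, 100),
                       width_ci = c(16, 32)), class = "cline_fit"))
  s <- summarize_multilocus(fits)
  expect_equal(s$mean_width, 21)
  expect_equal(s$sd_width, sqrt(2))       # sample SD of {20, 22}
  expect_equal(s$mean_center, 85)
  expect_equal(s$per_locus$delta_c_km, c(-5, 5))
  expect_equal(sum(s$per_locus$delta_c_km), 0)
  expect_equal(s$n_barrier, 0L)

  expect_warning(s1 <- summarize_multilocus(fits[1]), "single fit")
  expect_equal(s1$sd_width, 0)
  expect_error(summarize_multilocus(list()), "no fits")
})

test_that("mito, ancestry-Q and SNP data share one fitting path", {
  sim <- simulate_transect(transect_config(n_loci = 4L,
                                           samples_per_locality = 10L,
                                           seed = 40L))
  mito <- sim$mito$by_locality
  f_mito <- fit_cline(frequency_profile("mito", mito$locality,
                                        mito$distance_km, mito$n_B, mito$n),
                      kind = "mito", compute_ci = FALSE)
  q <- fit_admixture_k2(sim$dataset, anchors = c("T190", "T001"))
  mq <- population_mean_q(q, sim$dataset$localities)
  f_q <- fit_cline(q_profile(mq, sim$localities), kind = "ancestry_q",
                   compute_ci = FALSE)
  prof <- profiles_from_dataset(sim$dataset, sim$localities)
  f_snp <- fit_clines(prof, compute_ci = FALSE)
  expect_equal(f_mito$kind, "mito")
  expect_equal(f_q$kind, "ancestry_q")
  expect_true(all(vapply(f_snp, function(f) f$kind, "") == "snp"))
  # all centers near the generating center
  centers <- c(f_mito$center, f_q$center,
               vapply(f_snp, function(f) f$center, 1))
  expect_true(all(abs(centers - 85) < 30))
})
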