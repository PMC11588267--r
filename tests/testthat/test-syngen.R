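test_that("transect generator honours its configuration", {
  cf <- transect_config(n_localities = 19L, transect_length = 170,
                        samples_per_locality = 3L, n_loci = 40L,
                        true_width_mean = 20.6, missing_rate = 0, seed = 2L)
  sim <- simulate_transect(cf)
  expect_equal(length(sim$dataset$individuals), 57L)  # 19 localities x 3
  expect_equal(length(sim$dataset$loci), 40L)
  expect_false(anyNA(sim$dataset$geno))               # missing_rate = 0
  expect_equal(sort(unique(sim$localities$transect_distance_km)),
               seq(0, 170, length.out = 19))

  # determinism: identical seed -> identical output; new seed -> different
  sim2 <- simulate_transect(cf)
  expect_identical(sim$dataset$geno, sim2$dataset$geno)
  expect_identical(sim$mito$individual$haplotype,
                   sim2$mito$individual$haplotype)
  cf3 <- cf; cf3$seed <- 3L
  expect_false(identical(sim$dataset$geno, simulate_transect(cf3)$dataset$geno))

  expect_error(transect_config(missing_rate = 1.2), "missing_rate")
  expect_error(transect_config(transect_length = -1), "positive")
  expect_error(transect_config(n_loci = 5L, n_barrier_loci = 6L), "exceed")
})

test_that("barrier loci are fixed beyond 5 km of the center (closed form)", {
  cf <- transect_config(n_localities = 18L, transect_length = 170,
                        n_loci = 30L, n_barrier_loci = 6L,
                        barrier_width = 0.5, center_sd = 0, seed = 8L)
  sim <- simulate_transect(cf)
  x <- sim$localities$transect_distance_km
  barrier <- names(which(sim$truth$barrier))
  expect_length(barrier, 6L)
  for (b in barrier) {
    p <- cline_predict(x, sim$truth$center[b], sim$truth$width[b])
    far <- abs(x - cf$true_center) >= 5
    expect_true(all(p[far] < 0.01 | p[far] > 0.99))
  }
})

test_that("per-locality frequencies converge on the generating cline", {
  cf <- transect_config(n_localities = 10L, samples_per_locality = 500L,
                        n_loci = 5L, center_sd = 0, missing_rate = 0,
                        seed = 31L)
  sim <- simulate_transect(cf)
  af <- allele_frequencies(sim$dataset, "locality")
  x <- sim$localities$transect_distance_km[
    match(af$groups, sim$localities$locality)]
  err <- vapply(seq_along(sim$dataset$loci), function(l) {
    truth <- cline_predict(x, sim$truth$center[l], sim$truth$width[l])
    max(abs(af$freq[l, ] - truth))
  }, 1)
  expect_lt(max(err), 0.08)   # 1000 alleles per locality
  expect_lt(mean(err), 0.04)
})

test_that("reference panels plant fixed and shared loci as stated", {
  pan <- simulate_reference_panels(20, 19, n_fixed = 100, n_shared = 400,
                                   seed = 5)
  expect_length(pan$loci, 500L)
  expect_length(pan$individuals, 39L)
  af <- allele_frequencies(pan, "panel")
  diff <- abs(af$freq[, "refA"] - af$freq[, "refB"])
  fixed <- grepl("^L", pan$loci)
  expect_true(all(diff[fixed] == 1))
  expect_equal(sum(fixed), 100L)

  # all loci diagnostic when no shared loci requested
  pan0 <- simulate_reference_panels(5, 5, n_fixed = 10, n_shared = 0, seed = 1)
  af0 <- allele_frequencies(pan0, "panel")
  expect_true(all(abs(af0$freq[, "refA"] - af0$freq[, "refB"]) == 1))

  expect_error(simulate_reference_panels(5, 5, 0, 0), "at least one locus")
})

test_that("shared-locus frequency differences behave like binomial sampling", {
  pan <- simulate_reference_panels(20, 19, n_fixed = 0, n_shared = 2000,
                                   seed = 13)
  af <- allele_frequencies(pan, "panel")
  rate <- mean(abs(af$freq[, "refA"] - af$freq[, "refB"]) < 0.5)
  expect_gte(rate, 0.99)
  # independent binomial oracle at the same panel sizes
  set.seed(14)
  p <- runif(20000, 0.05, 0.95)
  oracle <- mean(abs(rbinom(20000, 40, p) / 40 - rbinom(20000, 38, p) / 38)
                 < 0.5)
  expect_gte(oracle, 0.99)
})

test_that("call generator reproduces group sizes, scenarios and temperature", {
  sc <- call_scenario("null", seed = 1L)
  calls <- simulate_calls(sc)
  expect_equal(as.vector(table(calls$group)), c(27L, 22L, 9L, 13L))
  expect_identical(simulate_calls(sc)$DF_Hz, calls$DF_Hz)  # seeded

  # physical invariants hold by construction
  expect_true(all(calls$RT_s <= calls$ND_s))
  expect_true(all(calls$ND_s > 0))

  # planted temperature effect lands near the target correlation at n = 71
  expect_lt(abs(temperature_adjust(calls)$temp_nd_r - (-0.64)), 0.15)

  # scenario invariants
  expect_error(call_scenario("null", variance_factor = 0.5), "null scenario")
  expect_error(call_scenario(group_sizes = c(27, 22, 2, 13)), "at least 3")
})

test_that("variance reduction scales parapatric SDs by the stated factor", {
  sc <- call_scenario("variance_reduction", variance_factor = 0.5,
                      group_sizes = c(200L, 200L, 200L, 200L),
                      temp_slope = 0, seed = 9L)
  calls <- simulate_calls(sc)
  for (tr in c("DF_Hz", "ND_s", "RT_s", "PR_per_s")) {
    allo <- sd(calls[[tr]][calls$group == "allopatric-A"])
    para <- sd(calls[[tr]][calls$group == "parapatric-A"])
    expect_equal(para / allo, 0.5, tolerance = 0.15)
  }
})
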