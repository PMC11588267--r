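# Seeded synthetic-data generators.
#
# The generators state the world the downstream methods assume: a ~170 km
# transect of 19 localities (57 samples) genotyped at diagnostic SNPs whose
# frequencies follow sigmoid clines (mean width ~20.6 km, log-normal
# dispersion, a few near-zero-width barrier loci), unadmixed reference
# panels of 20 + 19 individuals with fixed differences, a narrower
# mitochondrial cline, and advertisement-call datasets of 71 individuals in
# four species-context groups (27/22/9/13) under three scenarios: null,
# character displacement, variance reduction.

#' Transect simulation configuration
#'
#' @param n_localities Number of evenly spaced localities.
#' @param transect_length Transect length (km).
#' @param samples_per_locality Individuals per locality.
#' @param n_loci Number of diagnostic SNP loci.
#' @param true_center Genome-average cline center (km).
#' @param true_width_mean,true_width_sd Mean and SD (km) of the log-normal
#'   per-locus width distribution.
#' @param center_sd SD (km) of the normal per-locus center scatter.
#' @param n_barrier_loci Number of loci forced to `barrier_width`.
#' @param barrier_width Width (km) given to barrier loci.
#' @param mito_width Width (km) of the (narrower) mitochondrial cline.
#' @param missing_rate Fraction of genotypes set missing.
#' @param seed RNG seed.
#' @return A list of class `transect_config`.
#' @export
transect_config <- function(n_localities = 19L, transect_length = 170,
                            samples_per_locality = 3L, n_loci = 1000L,
                            true_center = 85, true_width_mean = 20.6,
                            true_width_sd = 9.5, center_sd = 5,
                            n_barrier_loci = 0L, barrier_width = 0.5,
                            mito_width = 9.8, missing_rate = 0,
                            seed = 1L) {
  stop_if(transect_length <= 0, "transect_length must be positive")
  stop_if(true_width_mean <= 0 || barrier_width <= 0 || mito_width <= 0,
          "widths must be positive")
  stop_if(missing_rate < 0 || missing_rate > 1,
          "missing_rate must lie in [0, 1]")
  stop_if(!is_count(n_localities) || n_localities < 2,
          "need at least 2 localities")
  stop_if(!is_count(samples_per_locality) || samples_per_locality < 1,
          "samples_per_locality must be a positive integer")
  stop_if(!is_count(n_loci) || n_loci < 1, "n_loci must be a positive integer")
  stop_if(n_barrier_loci > n_loci, "n_barrier_loci cannot exceed n_loci")
  structure(as.list(environment()), class = "transect_config")
}

# Log-normal (meanlog, sdlog) matching a target mean and SD.
lognormal_pars <- function(mean, sd) {
  s2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a hybrid-zone genotype transect
#'
#' Localities are evenly spaced on `[0, transect_length]`; each locus gets a
#' width drawn log-normally around `true_width_mean` (barrier loci get
#' `barrier_width`) and a center drawn normally around `true_center`; each
#' individual's genotype at a locus is a binomial draw of two alleles with
#' the cline frequency at its locality. One binary mitochondrial haplotype
#' per individual follows its own, narrower cline. Synthetic WGS84
#' coordinates are laid out west-east at 43 N so that great-circle
#' distances reproduce the transect positions.
#'
#' @param config A [transect_config()].
#' @return A list with `dataset` ([genotype_dataset()]), `localities`
#'   ([locality_table()] with distances), `mito` (data frame of per-
#'   individual haplotypes A/B plus per-locality counts) and `truth`
#'   (per-locus generating centers/widths, per-individual expected ancestry
#'   `expected_q`, and the mitochondrial cline parameters).
#' @export
simulate_transect <- function(config) {
  stopifnot(inherits(config, "transect_config"))
  cf <- config
  with_seed(cf$seed, {
    x <- seq(0, cf$transect_length, length.out = cf$n_localities)
    loc_ids <- sprintf("P%02d", seq_len(cf$n_localities))
    n_ind <- cf$n_localities * cf$samples_per_locality
    ind_loc <- rep(loc_ids, each = cf$samples_per_locality)
    ind_x <- rep(x, each = cf$samples_per_locality)
    ind_ids <- sprintf("T%03d", seq_len(n_ind))

    lp <- lognormal_pars(cf$true_width_mean, cf$true_width_sd)
    w_l <- stats::rlnorm(cf$n_loci, lp$meanlog, lp$sdlog)
    c_l <- stats::rnorm(cf$n_loci, cf$true_center, cf$center_sd)
    barrier <- rep(FALSE, cf$n_loci)
    if (cf$n_barrier_loci > 0) {
      barrier[sample.int(cf$n_loci, cf$n_barrier_loci)] <- TRUE
      w_l[barrier] <- cf$barrier_width
    }
    loci <- sprintf("L%04d_1", seq_len(cf$n_loci))

    # expected derived-allele frequency per individual x locus
    pmat <- vapply(seq_len(cf$n_loci),
                   function(l) cline_predict(ind_x, c_l[l], w_l[l]),
                   numeric(n_ind))
    g <- matrix(stats::rbinom(length(pmat), 2L, pmat), n_ind, cf$n_loci)
    if (cf$missing_rate > 0) {
      g[stats::runif(length(g)) < cf$missing_rate] <- NA_integer_
    }
    colnames(g) <- loci

    mito_p <- cline_predict(ind_x, cf$true_center, cf$mito_width)
    mito_hap <- ifelse(stats::rbinom(n_ind, 1L, mito_p) == 1L, "B", "A")

    lat <- rep(43, cf$n_localities)
    lon_step <- x / (haversine_km(43, 0, 43, 1))
    localities <- locality_table(loc_ids, lat, lon_step,
                                 transect_distance_km = x,
                                 number = seq_len(cf$n_localities))

    mito_counts <- data.frame(
      locality = loc_ids,
      distance_km = x,
      n_B = as.integer(tapply(mito_hap == "B", ind_loc, sum)[loc_ids]),
      n = as.integer(table(ind_loc)[loc_ids]),
      stringsAsFactors = FALSE)

    list(dataset = genotype_dataset(g, ind_ids, ind_loc, loci),
         localities = localities,
         mito = list(individual = data.frame(individual = ind_ids,
                                             locality = ind_loc,
                                             haplotype = mito_hap,
                                             stringsAsFactors = FALSE),
                     by_locality = mito_counts),
         truth = list(center = stats::setNames(c_l, loci),
                      width = stats::setNames(w_l, loci),
                      barrier = stats::setNames(barrier, loci),
                      expected_q = stats::setNames(rowMeans(pmat), ind_ids),
                      mito_center = cf$true_center,
                      mito_width = cf$mito_width))
  })
}

#' Simulate unadmixed reference panels
#'
#' `n_fixed` loci are fixed for opposite alleles between the two panels
#' (alternate-allele frequency 0 in panel A, 1 in panel B); `n_shared` loci
#' are polymorphic with a common expected frequency drawn uniformly on
#' `[0.05, 0.95]` in both panels. Fixed loci are named `L%04d_1` (the same
#' namespace as [simulate_transect()] loci, so panels and transect share
#' their diagnostic loci by construction); shared loci are named `S%04d_1`.
#'
#' @param n_a,n_b Panel sizes.
#' @param n_fixed,n_shared Locus counts (at least one locus in total).
#' @param missing_rate Fraction of genotypes set missing.
#' @param seed RNG seed.
#' @return A [genotype_dataset()] with panel labels `refA`/`refB`.
#' @export
simulate_reference_panels <- function(n_a = 20L, n_b = 19L, n_fixed = 100L,
                                      n_shared = 400L, missing_rate = 0,
                                      seed = 1L) {
  stop_if(!is_count(n_a) || !is_count(n_b) || n_a < 1 || n_b < 1,
          "panel sizes must be positive integers")
  stop_if(n_fixed + n_shared < 1, "at least one locus must be requested")
  stop_if(missing_rate < 0 || missing_rate > 1,
          "missing_rate must lie in [0, 1]")
  with_seed(seed, {
    n <- n_a + n_b
    fixed_ids <- if (n_fixed > 0) sprintf("L%04d_1", seq_len(n_fixed))
      else character(0)
    shared_ids <- if (n_shared > 0) sprintf("S%04d_1", seq_len(n_shared))
      else character(0)
    g_fixed <- rbind(matrix(0L, n_a, n_fixed), matrix(2L, n_b, n_fixed))
    p_shared <- stats::runif(n_shared, 0.05, 0.95)
    g_shared <- matrix(stats::rbinom(n * n_shared, 2L,
                                     rep(p_shared, each = n)),
                       n, n_shared)
    g <- cbind(g_fixed, g_shared)
    if (missing_rate > 0) {
      g[stats::runif(length(g)) < missing_rate] <- NA_integer_
    }
    ids <- c(sprintf("A%03d", seq_len(n_a)), sprintf("B%03d", seq_len(n_b)))
    genotype_dataset(g, ids,
                     c(rep("refA_site", n_a), rep("refB_site", n_b)),
                     c(fixed_ids, shared_ids),
                     c(rep("refA", n_a), rep("refB", n_b)))
  })
}

#' Advertisement-call simulation scenario
#'
#' Baseline species-A trait means/SDs are free parameters of the generator,
#' set to realistic midwife-toad call values; species B is offset by
#' `species_mean_shift` (higher DF and PR). Under `displacement`, parapatric
#' groups are shifted by `displacement_shift` in opposite directions
#' (species A minus, species B plus); under `variance_reduction`, parapatric
#' within-group SDs are scaled by `variance_factor`.
#'
#' @param scenario `"null"`, `"displacement"` or `"variance_reduction"`.
#' @param group_sizes Sizes of allopatric-A, allopatric-B, parapatric-A,
#'   parapatric-B (each at least 3).
#' @param base_mean,base_sd Species-A trait means and SDs
#'   (DF Hz, ND s, RT s, PR s^-1).
#' @param species_mean_shift Trait offsets of species B relative to A.
#' @param displacement_shift Trait offsets applied to parapatric groups in
#'   opposite directions (0 under the other scenarios).
#' @param variance_factor Scale applied to parapatric within-group SDs
#'   (1 unless `variance_reduction`).
#' @param temp_slope ND change per degree C (calibrated so the temperature-
#'   ND correlation is about -0.64 at the default noise levels).
#' @param temp_range Uniform recording-temperature range (degrees C).
#' @param seed RNG seed.
#' @return A list of class `call_scenario`.
#' @export
call_scenario <- function(scenario = c("null", "displacement",
                                       "variance_reduction"),
                          group_sizes = c(27L, 22L, 9L, 13L),
                          base_mean = c(DF = 1250, ND = 0.13, RT = 0.05,
                                        PR = 95),
                          base_sd = c(DF = 100, ND = 0.018, RT = 0.012,
                                      PR = 10),
                          species_mean_shift = c(DF = 110, ND = -0.015,
                                                 RT = -0.005, PR = 12),
                          displacement_shift = NULL,
                          variance_factor = NULL,
                          temp_slope = -0.0052,
                          temp_range = c(12, 22),
                          seed = 1L) {
  scenario <- match.arg(scenario)
  stop_if(length(group_sizes) != 4 || any(group_sizes < 3),
          "four group sizes of at least 3 are required")
  if (is.null(displacement_shift)) {
    displacement_shift <- if (scenario == "displacement")
      c(DF = 55, ND = -0.008, RT = -0.002, PR = 6) else rep(0, 4)
  }
  if (is.null(variance_factor)) {
    variance_factor <- if (scenario == "variance_reduction") 0.6 else 1
  }
  stop_if(variance_factor <= 0, "variance_factor must be positive")
  if (scenario == "null") {
    stop_if(any(displacement_shift != 0) || variance_factor != 1,
            "null scenario requires zero displacement and variance_factor 1")
  }
  stop_if(any(base_sd <= 0), "trait SDs must be positive")
  structure(list(scenario = scenario,
                 group_sizes = as.integer(group_sizes),
                 base_mean = base_mean, base_sd = base_sd,
                 species_mean_shift = species_mean_shift,
                 displacement_shift = displacement_shift,
                 variance_factor = variance_factor,
                 temp_slope = temp_slope, temp_range = temp_range,
                 seed = as.integer(seed)),
            class = "call_scenario")
}

#' Simulate an advertisement-call dataset
#'
#' Draws each group's four traits from a group-specific (diagonal-
#' covariance) multivariate normal, applies the temperature effect to note
#' duration (`temp_slope * (T - mean T)` with T uniform on `temp_range`),
#' and enforces the physical constraints DF, ND, PR > 0, 0 <= RT <= ND by
#' resampling the rare violating individuals.
#'
#' @param scenario A [call_scenario()].
#' @return A [call_table()] with one row per individual.
#' @export
simulate_calls <- function(scenario) {
  stopifnot(inherits(scenario, "call_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    groups <- GROUP_LEVELS
    n <- sc$group_sizes
    mid_T <- mean(sc$temp_range)
    rows <- vector("list", 4)
    for (gi in 1:4) {
      species_b <- gi %in% c(2, 4)
      para <- gi %in% c(3, 4)
      mu <- sc$base_mean + if (species_b) sc$species_mean_shift else 0
      if (para) {
        mu <- mu + (if (species_b) 1 else -1) * sc$displacement_shift
      }
      sdv <- sc$base_sd * if (para) sc$variance_factor else 1
      draw_one <- function() {
        for (try in 1:100) {
          tr <- stats::rnorm(4, mu, sdv)
          temp <- stats::runif(1, sc$temp_range[1], sc$temp_range[2])
          tr[2] <- tr[2] + sc$temp_slope * (temp - mid_T)
          if (tr[1] > 0 && tr[2] > 0 && tr[4] > 0 && tr[3] >= 0 &&
              tr[3] <= tr[2]) {
            return(c(tr, temp))
          }
        }
        stop("could not draw a physically valid call; check scenario means",
             call. = FALSE)
      }
      mat <- t(vapply(seq_len(n[gi]), function(i) draw_one(), numeric(5)))
      rows[[gi]] <- data.frame(group = groups[gi],
                               DF = mat[, 1], ND = mat[, 2], RT = mat[, 3],
                               PR = mat[, 4], temp = mat[, 5],
                               stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    call_table(individual = sprintf("C%03d", seq_len(nrow(df))),
               locality = sprintf("CL%02d",
                                  as.integer(factor(df$group,
                                                    levels = groups))),
               group = df$group,
               temperature_C = df$temp,
               DF_Hz = df$DF, ND_s = df$ND, RT_s = df$RT, PR_per_s = df$PR)
  })
}
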