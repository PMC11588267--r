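# End-to-end pipeline: simulate (optional) -> diagnostic loci -> ancestry ->
# clines -> acoustics, with a reproducible run manifest.

#' Pipeline configuration
#'
#' @param seed Master seed; stage seeds are derived from it and recorded in
#'   the manifest.
#' @param out_dir Output directory (created if needed).
#' @param transect A [transect_config()] for the simulated transect (ignored
#'   when `genotype_csv` is supplied).
#' @param panels Arguments for [simulate_reference_panels()] as a list.
#' @param calls A [call_scenario()] (ignored when `call_csv` is supplied).
#' @param genotype_csv,locality_csv,call_csv Optional paths to user data in
#'   the package's CSV formats; when given, the corresponding simulation is
#'   skipped.
#' @param B Permutations for the acoustic tests (must be positive).
#' @param downsample_to Down-sampling cutoff for the permutation variant.
#' @param diagnostic_threshold Minimum between-panel frequency difference.
#' @param min_call_rate Within-locality call-rate filter `r`.
#' @param barrier_threshold Width (km) under which a locus is flagged.
#' @param snp_ci Compute profile intervals for every per-SNP cline (slower).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("clinecall_run_"),
                       transect = transect_config(n_loci = 120L,
                                                  n_barrier_loci = 5L,
                                                  missing_rate = 0.05),
                       panels = list(n_a = 20L, n_b = 19L, n_shared = 400L,
                                     missing_rate = 0.05),
                       calls = call_scenario("variance_reduction"),
                       genotype_csv = NULL, locality_csv = NULL,
                       call_csv = NULL,
                       B = 1000L, downsample_to = 10L,
                       diagnostic_threshold = 1, min_call_rate = 0.5,
                       barrier_threshold = 2, snp_ci = FALSE) {
  stop_if(!is_count(B) || B < 1, "B must be a positive integer")
  stop_if(diagnostic_threshold <= 0 || diagnostic_threshold > 1,
          "diagnostic_threshold must lie in (0, 1]")
  stop_if(min_call_rate <= 0 || min_call_rate > 1,
          "min_call_rate must lie in (0, 1]")
  stop_if(barrier_threshold <= 0, "barrier_threshold must be positive")
  structure(as.list(environment()), class = "run_config")
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.1f s", stage,
                  as.numeric(proc.time()[3]) - t0))
}

#' Run the full hybrid-zone pipeline
#'
#' Executes simulation (unless user data are supplied), diagnostic-locus
#' selection on the reference panels with whitelist re-filtering on the
#' transect, EM ancestry estimation, cline fitting for the mitochondrial,
#' mean-ancestry and per-SNP data, and the bioacoustic permutation battery.
#' Writes CSV outputs plus a JSON manifest into `config$out_dir`; identical
#' config and seed give byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @param until Last stage to execute: `"simulate"`, `"diagloci"`,
#'   `"ancestry"`, `"clines"` or `"acoustics"` (the default runs the full
#'   chain). `"acoustics_only"` skips the genetic stages and runs only the
#'   call battery.
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `whitelist`, `q`, `cline_summary`, `fits`, `acoustics`, `paths`).
#' @export
run_pipeline <- function(config = run_config(),
                         until = c("acoustics", "simulate", "diagloci",
                                   "ancestry", "clines", "acoustics_only")) {
  stopifnot(inherits(config, "run_config"))
  until <- match.arg(until)
  stage_rank <- c(simulate = 1, diagloci = 2, ancestry = 3, clines = 4,
                  acoustics = 5, acoustics_only = 5)
  run_genetics <- until != "acoustics_only"
  last <- stage_rank[[until]]
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  t0 <- as.numeric(proc.time()[3])

  ## stage 1: data ----------------------------------------------------------
  if (is.null(cfg$genotype_csv)) {
    tc <- cfg$transect
    tc$seed <- cfg$seed
    sim <- simulate_transect(tc)
    pn <- cfg$panels
    panel_ds <- simulate_reference_panels(
      n_a = pn$n_a, n_b = pn$n_b, n_fixed = tc$n_loci,
      n_shared = pn$n_shared,
      missing_rate = if (is.null(pn$missing_rate)) 0 else pn$missing_rate,
      seed = cfg$seed + 1L)
    transect_ds <- sim$dataset
    localities <- sim$localities
    mito <- sim$mito$by_locality
    paths$genotypes <- file.path(cfg$out_dir, "transect_genotypes.csv")
    write_genotype_csv(transect_ds, paths$genotypes)
    paths$localities <- file.path(cfg$out_dir, "localities.csv")
    write_locality_csv(localities, paths$localities)
  } else {
    transect_ds <- read_genotype_matrix(cfg$genotype_csv, "csv")
    localities <- read_locality_csv(cfg$locality_csv)
    panel_ds <- NULL
    mito <- NULL
  }
  if (is.null(cfg$call_csv)) {
    cs <- cfg$calls
    cs$seed <- cfg$seed + 2L
    calls <- simulate_calls(cs)
    paths$calls <- file.path(cfg$out_dir, "calls.csv")
    write_call_csv(calls, paths$calls)
  } else {
    calls <- read_call_csv(cfg$call_csv)
  }
  stage_msg("simulate/load", t0); t0 <- as.numeric(proc.time()[3])

  res <- list(dataset = transect_ds, localities = localities, calls = calls)

  ## stage 2: diagnostic loci -----------------------------------------------
  if (run_genetics && last >= 2) {
    if (!is.null(panel_ds)) {
      spec_ref <- locus_filter_spec(min_groups_present = 2L,
                                    min_call_rate = cfg$min_call_rate)
      panel_f <- apply_presence_filters(panel_ds, spec_ref, "panel")
      wl <- select_diagnostic_loci(allele_frequencies(panel_f, "panel"),
                                   min_difference = cfg$diagnostic_threshold)
    } else {
      wl <- transect_ds$loci
    }
    spec_tr <- locus_filter_spec(
      min_groups_present = length(unique(transect_ds$localities)),
      min_call_rate = cfg$min_call_rate, one_snp_per_locus = TRUE,
      seed = cfg$seed + 3L)
    keep <- intersect(wl, transect_ds$loci)
    stop_if(length(keep) == 0, "diagloci: no whitelisted loci on the transect")
    transect_wl <- apply_presence_filters(subset_dataset(transect_ds,
                                                         loci = keep),
                                          spec_tr, "locality")
    paths$whitelist <- file.path(cfg$out_dir, "whitelist.txt")
    write_whitelist(transect_wl$loci, paths$whitelist)
    res$whitelist <- transect_wl$loci
    stage_msg("diagloci", t0); t0 <- as.numeric(proc.time()[3])
  }

  ## stage 3: ancestry --------------------------------------------------------
  if (run_genetics && last >= 3) {
    anc_ds <- if (!is.null(panel_ds)) {
      combine_datasets(transect_wl, subset_dataset(
        panel_ds, loci = intersect(transect_wl$loci, panel_ds$loci)))
    } else transect_wl
    q <- fit_admixture_k2(anc_ds, seed = cfg$seed + 4L)
    on_transect <- anc_ds$panel == "transect"
    q_tr <- q
    q_tr$Q <- q$Q[on_transect]
    mean_q <- population_mean_q(q_tr, anc_ds$localities[on_transect])
    paths$q_table <- file.path(cfg$out_dir, "ancestry_q.csv")
    write_q_csv(q_tr, anc_ds$localities[on_transect], paths$q_table)
    res$q <- q_tr
    res$mean_q <- mean_q
    stage_msg("ancestry", t0); t0 <- as.numeric(proc.time()[3])
  }

  ## stage 4: clines ----------------------------------------------------------
  if (run_genetics && last >= 4) {
    fits <- list()
    if (!is.null(mito)) {
      mito_profile <- frequency_profile("mito", mito$locality,
                                        mito$distance_km, mito$n_B, mito$n)
      fits$mito <- fit_cline(mito_profile, kind = "mito")
    }
    fits$ancestry_q <- fit_cline(q_profile(mean_q, localities),
                                 kind = "ancestry_q")
    snp_profiles <- profiles_from_dataset(transect_wl, localities)
    snp_fits <- fit_clines(snp_profiles, compute_ci = cfg$snp_ci, kind = "snp")
    summary <- summarize_multilocus(snp_fits,
                                    barrier_threshold = cfg$barrier_threshold)
    paths$cline_fits <- file.path(cfg$out_dir, "cline_fits.csv")
    per_locus <- summary$per_locus
    names(per_locus) <- c("locus", "center_km", "width_km", "center_lo_km",
                          "center_hi_km", "width_lo_km", "width_hi_km",
                          "delta_c_km", "barrier_flag")
    utils::write.csv(per_locus, paths$cline_fits, row.names = FALSE)
    paths$cline_summary <- file.path(cfg$out_dir, "cline_summary.csv")
    sum_rows <- data.frame(
      dataset = c(if (!is.null(fits$mito)) "mito", "ancestry_Q",
                  "snp_mean", "snp_median", "snp_sd"),
      center_km = c(if (!is.null(fits$mito)) fits$mito$center,
                    fits$ancestry_q$center, summary$mean_center, NA, NA),
      width_km = c(if (!is.null(fits$mito)) fits$mito$width,
                   fits$ancestry_q$width, summary$mean_width,
                   summary$median_width, summary$sd_width),
      stringsAsFactors = FALSE)
    utils::write.csv(sum_rows, paths$cline_summary, row.names = FALSE)
    res$fits <- fits
    res$cline_summary <- summary
    stage_msg("clines", t0); t0 <- as.numeric(proc.time()[3])
  }

  ## stage 5: acoustics -------------------------------------------------------
  if (last >= 5) {
    adj <- temperature_adjust(calls)
    pca <- run_call_pca(adj$traits)
    tests <- permutation_test(pca, adj$group, B = cfg$B,
                              seed = cfg$seed + 5L,
                              downsample_to = cfg$downsample_to)
    paths$acoustic_tests <- file.path(cfg$out_dir, "acoustic_tests.csv")
    utils::write.csv(as.data.frame(tests), paths$acoustic_tests,
                     row.names = FALSE)
    paths$null_deltas <- file.path(cfg$out_dir, "null_deltas.csv")
    utils::write.csv(as.data.frame(attr(tests, "null_deltas")),
                     paths$null_deltas, row.names = FALSE)
    res$acoustics <- tests
    res$pca <- pca
    stage_msg("acoustics", t0)
  }

  ## manifest -----------------------------------------------------------------
  manifest <- list(
    package = "clinecall",
    version = as.character(utils::packageVersion("clinecall")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, until = until,
    config = list(B = cfg$B, downsample_to = cfg$downsample_to,
                  diagnostic_threshold = cfg$diagnostic_threshold,
                  min_call_rate = cfg$min_call_rate,
                  barrier_threshold = cfg$barrier_threshold,
                  call_scenario = if (is.null(cfg$call_csv))
                    cfg$calls$scenario else "user_data"))
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  res$paths <- paths
  invisible(res)
}
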