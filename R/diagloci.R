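# Locus filtering and species-diagnostic SNP selection.
#
# Mirrors the RAD-locus presence/call-rate filters applied when exporting
# per-population allele frequencies, and the fixed-difference rule used to
# flag species-diagnostic SNPs on unadmixed reference panels.

#' Locus filter specification
#'
#' @param min_groups_present `p`: a locus is kept only if at least `p` groups
#'   pass the per-group call-rate requirement.
#' @param min_call_rate `r`: within-group call rate (fraction of individuals
#'   with a non-missing genotype) a group needs to count as present.
#' @param one_snp_per_locus Keep a single SNP per RAD locus (locus ids of the
#'   form `"<radtag>_<snp>"` share a RAD tag), chosen uniformly at random
#'   under `seed`.
#' @param seed RNG seed for the SNP-per-locus draw.
#' @return A list of class `locus_filter_spec`.
#' @export
locus_filter_spec <- function(min_groups_present = 1L, min_call_rate = 0.5,
                              one_snp_per_locus = FALSE, seed = 1L) {
  stop_if(!is_count(min_groups_present) || min_groups_present < 1,
          "min_groups_present must be a positive integer")
  stop_if(!is.numeric(min_call_rate) || min_call_rate <= 0 || min_call_rate > 1,
          "min_call_rate must lie in (0, 1]")
  structure(list(min_groups_present = as.integer(min_groups_present),
                 min_call_rate = min_call_rate,
                 one_snp_per_locus = isTRUE(one_snp_per_locus),
                 seed = as.integer(seed)),
            class = "locus_filter_spec")
}

#' Per-group allele frequencies
#'
#' Frequency of the alternate allele per locus per group:
#' (sum of alternate-allele copies) / (2 x non-missing individuals).
#' Groups with zero calls at a locus get `NA` (an explicit no-data marker),
#' never 0.
#'
#' @param ds A [genotype_dataset()].
#' @param grouping Character/factor vector over individuals (e.g. locality or
#'   panel membership), or the name `"locality"`/`"panel"` to use the
#'   dataset's own columns.
#' @return A list of class `allele_freq_table` with matrices `freq`
#'   (loci x groups), `alt_count` and `n_called` (individuals with calls).
#' @export
allele_frequencies <- function(ds, grouping = "locality") {
  stopifnot(inherits(ds, "genotype_dataset"))
  g <- resolve_grouping(ds, grouping)
  stop_if(any(table(g) == 0), "empty group in grouping")
  groups <- levels(g)
  called <- !is.na(ds$geno)
  geno0 <- ds$geno; geno0[!called] <- 0L
  alt <- vapply(groups, function(k) colSums(geno0[g == k, , drop = FALSE]),
                numeric(ncol(ds$geno)))
  ncl <- vapply(groups, function(k) colSums(called[g == k, , drop = FALSE]),
                numeric(ncol(ds$geno)))
  if (ncol(ds$geno) == 1L) { alt <- rbind(alt); ncl <- rbind(ncl) }
  freq <- alt / (2 * ncl)
  freq[ncl == 0] <- NA_real_
  rownames(freq) <- rownames(alt) <- rownames(ncl) <- ds$loci
  structure(list(freq = freq, alt_count = alt, n_called = ncl,
                 groups = groups, loci = ds$loci),
            class = "allele_freq_table")
}

resolve_grouping <- function(ds, grouping) {
  if (is.character(grouping) && length(grouping) == 1L) {
    grouping <- switch(grouping,
                       locality = ds$localities,
                       panel = ds$panel,
                       stop("grouping must be 'locality', 'panel' or a vector",
                            call. = FALSE))
  }
  stop_if(length(grouping) != length(ds$individuals),
          "grouping must cover all individuals")
  stop_if(anyNA(grouping), "grouping must cover all individuals")
  factor(grouping)
}

#' Apply presence/call-rate filters and optional SNP thinning
#'
#' A group "passes" at a locus when its call rate is at least
#' `min_call_rate`; the locus is kept when at least `min_groups_present`
#' groups pass. With `one_snp_per_locus`, one SNP per RAD tag is then
#' retained uniformly at random under the spec's seed.
#'
#' @param ds A [genotype_dataset()].
#' @param spec A [locus_filter_spec()].
#' @param grouping As in [allele_frequencies()].
#' @return A filtered `genotype_dataset`.
#' @export
apply_presence_filters <- function(ds, spec, grouping = "locality") {
  stopifnot(inherits(ds, "genotype_dataset"),
            inherits(spec, "locus_filter_spec"))
  g <- resolve_grouping(ds, grouping)
  stop_if(spec$min_groups_present > nlevels(g),
          "min_groups_present exceeds the number of groups")
  sizes <- as.vector(table(g))
  af <- allele_frequencies(ds, g)
  rate <- sweep(af$n_called, 2, sizes, "/")
  pass <- rate >= spec$min_call_rate
  keep <- rowSums(pass) >= spec$min_groups_present
  loci <- ds$loci[keep]
  if (spec$one_snp_per_locus && length(loci) > 0) {
    tags <- rad_tag(loci)
    loci <- with_seed(spec$seed, {
      unlist(lapply(split(loci, tags), function(ids) {
        if (length(ids) == 1L) ids else sample(ids, 1L)
      }), use.names = FALSE)
    })
    loci <- loci[order(match(loci, ds$loci))]
  }
  subset_dataset(ds, loci = loci)
}

rad_tag <- function(loci) sub("_[^_]*$", "", loci)

#' Select species-diagnostic loci from two reference panels
#'
#' Flags loci whose between-panel alternate-allele frequency difference is at
#' least `min_difference` (default 1: fixed differences). The comparison is
#' exact on the integer allele counts (|k_A n_B - k_B n_A| vs
#' `min_difference` n_A n_B), avoiding float equality. Loci lacking data in
#' either panel are excluded, never treated as difference 1.
#'
#' @param freqs An [allele_frequencies()] table.
#' @param group_a,group_b Names of the two panels in `freqs$groups`.
#' @param min_difference Threshold in (0, 1].
#' @return Character vector of selected locus ids.
#' @export
select_diagnostic_loci <- function(freqs, group_a = "refA", group_b = "refB",
                                   min_difference = 1) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  stop_if(!is.numeric(min_difference) || min_difference <= 0 ||
            min_difference > 1, "min_difference must lie in (0, 1]")
  stop_if(!all(c(group_a, group_b) %in% freqs$groups),
          "requested groups not present in frequency table")
  ka <- freqs$alt_count[, group_a]; na <- 2 * freqs$n_called[, group_a]
  kb <- freqs$alt_count[, group_b]; nb <- 2 * freqs$n_called[, group_b]
  has_data <- na > 0 & nb > 0
  # exact rational comparison: |ka/na - kb/nb| >= d  <=>  |ka nb - kb na| >= d na nb
  lhs <- abs(ka * nb - kb * na)
  rhs <- min_difference * na * nb
  sel <- has_data & (lhs >= rhs - 1e-9 * pmax(1, rhs))
  freqs$loci[sel]
}

#' Write / read a locus whitelist
#'
#' One locus id per line, mirroring a SNP-caller whitelist file.
#'
#' @param loci Character vector of locus ids.
#' @param path File path.
#' @return `read_whitelist` returns the ids.
#' @export
write_whitelist <- function(loci, path) {
  writeLines(as.character(loci), path)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) readLines(path)
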