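# K = 2 ancestry estimation by EM on a binomial admixture likelihood.
#
# Each genotype g_il (copies of the alternate allele) is modelled as
# Binomial(2, Q_i f_Al + (1 - Q_i) f_Bl): Q_i is the proportion of
# individual i's genome drawn from cluster A, f_A / f_B the cluster allele
# frequencies. EM treats the ancestral origin of each allele copy as the
# latent variable; both the Q and f updates maximise a concave per-parameter
# Q-function, so the observed-data log-likelihood is non-decreasing even
# under the box constraint that keeps f inside [1e-6, 1 - 1e-6].

#' Estimate K = 2 admixture proportions by EM
#'
#' @param ds A [genotype_dataset()] with at least two individuals and one
#'   polymorphic locus. Missing genotypes are skipped in the likelihood.
#' @param tol Convergence threshold on the relative change in
#'   log-likelihood.
#' @param max_iter Iteration cap.
#' @param seed Seed for the random initialisation of cluster frequencies
#'   (used only when no reference panels are present).
#' @param anchors Optional character vector of two individual ids; after
#'   convergence labels are swapped if needed so the first anchor sits in
#'   cluster A. Without anchors, panel labels (refA/refB) orient the
#'   clusters; failing both, the first individual is forced toward A.
#' @return An object of class `q_estimates`: per-individual `Q` toward
#'   cluster A, per-locus `f_A`/`f_B`, the log-likelihood trace, iteration
#'   count and convergence flag.
#' @export
fit_admixture_k2 <- function(ds, tol = 1e-8, max_iter = 2000L, seed = NULL,
                             anchors = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  G <- ds$geno
  stop_if(nrow(G) < 2, "need at least two individuals")
  called <- !is.na(G)
  stop_if(any(rowSums(called) == 0),
          "individual with all genotypes missing")
  poly <- apply(G, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && length(unique(x)) > 1
  })
  stop_if(!any(poly), "no polymorphic loci")

  n <- nrow(G); L <- ncol(G)
  g0 <- G; g0[!called] <- 0L
  storage.mode(g0) <- "double"
  two_called <- 2 * called

  has_panels <- all(c("refA", "refB") %in% ds$panel)
  if (has_panels) {
    af <- allele_frequencies(ds, "panel")
    fA <- clamp(ifelse(is.na(af$freq[, "refA"]), 0.5, af$freq[, "refA"]))
    fB <- clamp(ifelse(is.na(af$freq[, "refB"]), 0.5, af$freq[, "refB"]))
  } else {
    fr <- with_seed(if (is.null(seed)) 1L else seed,
                    list(a = stats::runif(L), b = stats::runif(L)))
    fA <- clamp(fr$a); fB <- clamp(fr$b)
  }
  Q <- rep(0.5, n)

  lchoose2 <- sum(ifelse(G[called] == 1L, log(2), 0))
  loglik <- function(P) {
    ll <- g0 * log(P) + (two_called - g0) * log1p(-P)
    sum(ll[called]) + lchoose2
  }

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P <- Q %o% fA + (1 - Q) %o% fB        # n x L mixture allele frequency
    ll <- loglik(P)
    trace <- c(trace, ll)
    if (length(trace) > 1L) {
      rel <- abs(ll - trace[length(trace) - 1L]) /
        (abs(trace[length(trace) - 1L]) + .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
    if (iter >= max_iter) break
    # E-step: expected allele copies by (origin, allelic state)
    aAlt <- (Q %o% fA) / P                 # P(copy from A | alt copy)
    aRef <- (Q %o% (1 - fA)) / (1 - P)     # P(copy from A | ref copy)
    EA_alt <- g0 * aAlt
    EA_ref <- (two_called - g0) * aRef
    EB_alt <- g0 * (1 - aAlt)
    EB_ref <- (two_called - g0) * (1 - aRef)
    # M-step
    Q <- rowSums(EA_alt + EA_ref) / rowSums(two_called)
    fA <- clamp(colSums(EA_alt) / pmax(colSums(EA_alt + EA_ref), 1e-12))
    fB <- clamp(colSums(EB_alt) / pmax(colSums(EB_alt + EB_ref), 1e-12))
  }

  out <- structure(
    list(Q = stats::setNames(Q, ds$individuals),
         f_A = stats::setNames(fA, ds$loci),
         f_B = stats::setNames(fB, ds$loci),
         loglik = trace[length(trace)],
         loglik_trace = trace,
         iterations = iter,
         converged = converged),
    class = "q_estimates")

  swap <- FALSE
  if (!is.null(anchors)) {
    stop_if(length(anchors) != 2 || !all(anchors %in% ds$individuals),
            "anchors must name two individuals in the dataset")
    swap <- out$Q[anchors[1]] < out$Q[anchors[2]]
  } else if (has_panels) {
    swap <- mean(out$Q[ds$panel == "refA"]) < mean(out$Q[ds$panel == "refB"])
  } else {
    swap <- out$Q[1] < 0.5
  }
  if (swap) out <- swap_clusters(out)
  out
}

swap_clusters <- function(q) {
  tmp <- q$f_A; q$f_A <- q$f_B; q$f_B <- tmp
  q$Q <- 1 - q$Q
  q
}

#' @export
print.q_estimates <- function(x, ...) {
  cat(sprintf(
    "<q_estimates> %d individuals, %d loci | logLik %.2f after %d EM iterations%s\n",
    length(x$Q), length(x$f_A), x$loglik, x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Per-locality mean ancestry
#'
#' @param q A [fit_admixture_k2()] result.
#' @param localities Character vector mapping each individual in `q` to a
#'   locality (same order), or a [genotype_dataset()] to take the mapping
#'   from.
#' @return Data frame with `locality`, `mean_Q` and `n` individuals.
#' @export
population_mean_q <- function(q, localities) {
  stopifnot(inherits(q, "q_estimates"))
  if (inherits(localities, "genotype_dataset")) {
    loc <- localities$localities[match(names(q$Q), localities$individuals)]
  } else {
    loc <- as.character(localities)
  }
  stop_if(length(loc) != length(q$Q) || anyNA(loc),
          "every individual must be mapped to a locality")
  agg <- tapply(q$Q, loc, mean)
  n <- tapply(q$Q, loc, length)
  data.frame(locality = names(agg), mean_Q = as.numeric(agg),
             n = as.integer(n), row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an ancestry table as CSV
#'
#' @param q A `q_estimates` object.
#' @param localities Per-individual locality mapping (as in
#'   [population_mean_q()]).
#' @param path Output file.
#' @export
write_q_csv <- function(q, localities, path) {
  if (inherits(localities, "genotype_dataset")) {
    localities <- localities$localities[match(names(q$Q),
                                              localities$individuals)]
  }
  utils::write.csv(data.frame(individual = names(q$Q),
                              locality = localities,
                              Q = as.numeric(q$Q)),
                   path, row.names = FALSE)
  invisible(path)
}
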