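# Independent brute-force oracles and tiny fixture builders.  The oracles
# never call the code paths they check: coverage and unions are computed per
# base, posterior CDFs by numeric quadrature, minima by grid search.

mk_intervals <- function(chrom, start, end, svtype = NULL) {
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(svtype)) out$svtype <- svtype
  out
}

mk_exons <- function(chrom, start, end, gene_id) {
  out <- mk_intervals(chrom, start, end)
  out$gene_id <- gene_id
  out$exon_key <- exon_key(out)
  out
}

# per-base membership: which bases (0-based) of [lo, hi) are covered
oracle_base_set <- function(intervals, chrom, lo, hi) {
  covered <- logical(hi - lo)
  if (!is.null(intervals) && nrow(intervals)) {
    sub <- intervals[intervals$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      a <- max(sub$start[i], lo)
      b <- min(sub$end[i], hi)
      if (b > a) covered[(a - lo + 1L):(b - lo)] <- TRUE
    }
  }
  covered
}

oracle_coverage_fraction <- function(exon, intervals) {
  mean(oracle_base_set(intervals, exon$chrom, exon$start, exon$end))
}

# posterior CDF by trapezoid quadrature (no pbeta), vectorized grid
oracle_beta_cdf <- function(d, a, b, npts = 200001L) {
  g <- seq(0, 1, length.out = npts)
  dens <- stats::dbeta(g, a, b)
  dens[!is.finite(dens)] <- 0  # endpoint spikes for shapes < 1
  h <- g[2L] - g[1L]
  cum <- c(0, cumsum((dens[-1L] + dens[-npts]) / 2)) * h
  cum <- cum / cum[npts]
  stats::approx(g, cum, xout = d, rule = 2)$y
}

# bisection for the q-fractile on the numerically integrated CDF
oracle_fractile <- function(q, a, b, tol = 1e-7) {
  lo <- 0
  hi <- 1
  f <- function(d) {
    stats::integrate(function(t) stats::dbeta(t, a, b), 0, d,
                     rel.tol = 1e-12, abs.tol = 1e-14,
                     subdivisions = 2000L)$value - q
  }
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# expected piecewise-linear posterior loss by adaptive quadrature on each
# branch (robust to the integrable endpoint singularities of shapes < 1)
oracle_expected_loss <- function(d, a, b, t1, t2) {
  lo <- if (d > 0) {
    stats::integrate(function(t) (d - t) * stats::dbeta(t, a, b), 0, d,
                     rel.tol = 1e-10, subdivisions = 1000L)$value
  } else 0
  hi <- if (d < 1) {
    tryCatch(
      stats::integrate(function(t) (t - d) * stats::dbeta(t, a, b), d, 1,
                       rel.tol = 1e-10, subdivisions = 1000L)$value,
      error = function(e) {
        # integration-by-parts form with a bounded integrand:
        # int_d^1 (t - d) f(t) dt = int_d^1 (1 - F(t)) dt
        g <- seq(d, 1, length.out = 1000001L)
        surv <- 1 - stats::pbeta(g, a, b)
        sum((surv[-1L] + surv[-length(g)]) / 2) * (g[2L] - g[1L])
      })
  } else 0
  t1 * lo + t2 * hi
}

# shared small simulated study, computed once per test run
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.sim_cache$obj)) {
    cfg <- sim_config(seed = 421, n_genes = 250, exons_per_gene = 8)
    exons <- simulate_exome(cfg)
    truth <- simulate_truth(exons, cfg)
    callsets <- simulate_callsets(truth, exons, cfg)
    .sim_cache$obj <- list(cfg = cfg, exons = exons, truth = truth,
                           callsets = callsets)
  }
  .sim_cache$obj
}
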