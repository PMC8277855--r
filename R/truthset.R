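# Bayes estimation of the per-exon CNV probability.  With theta ~
# Beta(alpha, beta) and x CNV votes out of n describing sets, the posterior
# is Beta(alpha + x, beta + n - x).  Under the asymmetric piecewise-linear
# loss L(theta, d) = t1 (d - theta) for theta <= d (overestimation) and
# t2 (theta - d) for theta > d (underestimation), the Bayes estimator is the
# t2/(t1+t2) fractile of the posterior: I_d(alpha + x, beta + n - x) =
# t2/(t1+t2), with I the regularized incomplete beta function.

#' Asymmetric piecewise-linear loss parameters
#'
#' `t1` multiplies the overestimation branch (estimate above the true
#' probability), `t2` the underestimation branch.  The defaults t1 = 16,
#' t2 = 5 penalize calling an exon CNV on thin evidence 16/5 times more
#' heavily than missing one, which concentrates the truth set on confidently
#' supported CNV-exons.
#'
#' @param t1 overestimation penalty, `> 0`.
#' @param t2 underestimation penalty, `> 0`.
#' @return Object of class `loss_params`.
#' @export
loss_params <- function(t1 = 16, t2 = 5) {
  stopifnot(is.numeric(t1), is.numeric(t2), length(t1) == 1L, length(t2) == 1L,
            is.finite(t1), is.finite(t2), t1 > 0, t2 > 0)
  structure(list(t1 = t1, t2 = t2), class = "loss_params")
}

#' @export
print.loss_params <- function(x, ...) {
  cat(sprintf("piecewise-linear loss: t1 = %g (over), t2 = %g (under); fractile %g\n",
              x$t1, x$t2, x$t2 / (x$t1 + x$t2)))
  invisible(x)
}

#' Posterior shape parameters for exon evidence
#'
#' @param prior a [beta_prior()].
#' @param n,x evidence counts (vectors allowed), `0 <= x <= n`.
#' @return List with vectors `a = alpha + x` and `b = beta + n - x`.
#' @export
posterior_params <- function(prior, n, x) {
  stopifnot(inherits(prior, "beta_prior"), length(n) == length(x))
  if (any(x < 0 | x > n | n < 0)) {
    stop("evidence counts must satisfy 0 <= x <= n", call. = FALSE)
  }
  list(a = prior$alpha + x, b = prior$beta + n - x)
}

#' Expected posterior loss of a candidate estimate
#'
#' Evaluates `t1 * int_0^d (d - theta) pi(theta | x) dtheta +
#' t2 * int_d^1 (theta - d) pi(theta | x) dtheta` for a Beta(a, b) posterior,
#' in closed form through incomplete-beta terms (no quadrature): the partial
#' first moment of a Beta(a, b) below d is `a/(a+b) * I_d(a+1, b)`.
#'
#' @param d candidate estimate(s) in `[0, 1]`.
#' @param a,b posterior shape parameters.
#' @param loss a [loss_params()] object.
#' @return Non-negative numeric vector of expected losses.
#' @export
expected_posterior_loss <- function(d, a, b, loss = loss_params()) {
  stopifnot(all(d >= 0 & d <= 1), all(a > 0), all(b > 0))
  q1 <- stats::pbeta(d, a, b)
  q2 <- stats::pbeta(d, a + 1, b)
  m <- a / (a + b)
  val <- loss$t1 * (d * q1 - m * q2) + loss$t2 * (m * (1 - q2) - d * (1 - q1))
  if (any(!is.finite(val))) {
    stop("expected posterior loss is non-finite", call. = FALSE)
  }
  pmax(val, 0)
}

# Monotone bisection for I_d(a, b) = q on [lo, hi]; guards qbeta.
.bisect_fractile <- function(q, a, b, tol = 1e-10) {
  lo <- 1e-12
  hi <- 1 - 1e-12
  if (stats::pbeta(lo, a, b) >= q) return(lo)
  if (stats::pbeta(hi, a, b) <= q) return(hi)
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (stats::pbeta(mid, a, b) < q) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Bayes estimate of the per-exon CNV probability
#'
#' Solves `I_d(alpha + x, beta + n - x) = t2/(t1 + t2)` for each exon: the
#' posterior fractile that minimizes the expected asymmetric piecewise-linear
#' loss.  Computed with the inverse regularized incomplete beta function
#' ([stats::qbeta()]); any solution not verifying the defining equation to
#' `tol` is recomputed by monotone bisection on the posterior CDF.
#'
#' @param prior a [beta_prior()].
#' @param n,x evidence counts (vectors allowed).
#' @param loss a [loss_params()].
#' @param tol absolute tolerance on `d`, default `1e-10`.
#' @return Numeric vector of estimates, clamped to the open unit interval.
#' @export
bayes_estimate <- function(prior, n, x, loss = loss_params(), tol = 1e-10) {
  q <- loss$t2 / (loss$t1 + loss$t2)
  p <- posterior_params(prior, n, x)
  d <- stats::qbeta(q, p$a, p$b)
  chk <- abs(stats::pbeta(d, p$a, p$b) - q)
  bad <- which(!is.finite(d) | chk > 1e-8)
  for (i in bad) {
    d[i] <- .bisect_fractile(q, p$a[i], p$b[i], tol)
    if (abs(stats::pbeta(d[i], p$a[i], p$b[i]) - q) > 1e-6) {
      stop(sprintf("fractile solver failed for a = %g, b = %g, target = %g",
                   p$a[i], p$b[i], q), call. = FALSE)
    }
  }
  pmin(pmax(d, 1e-12), 1 - 1e-12)
}

#' Rank exon estimates
#'
#' Descending by estimate; ties broken by genomic coordinates then gene for
#' a deterministic, permutation-invariant order.
#'
#' @param estimates data.frame with columns `d`, `chrom`, `start`, `end`,
#'   `gene_id`.
#' @return The same data.frame, reordered.
#' @export
rank_exons <- function(estimates) {
  out <- estimates[order(-estimates$d, estimates$chrom, estimates$start,
                         estimates$end, estimates$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the CNV cutoff against validated CNV-exons
#'
#' Returns the largest cutoff `c`, taken from the observed estimates of the
#' validated exons, such that at least `target_accuracy` of the validated
#' exons satisfy `d >= c`.  Because every validated exon is a known CNV-exon,
#' accuracy here is the fraction of them the truth set recovers.
#'
#' @param estimates data.frame with `exon_key` and `d` columns.
#' @param validated character vector of validated CNV-exon keys.
#' @param target_accuracy required recovered fraction, in `(0, 1]`.
#' @return The cutoff value.
#' @export
calibrate_cutoff <- function(estimates, validated, target_accuracy = 0.95) {
  stopifnot(target_accuracy > 0, target_accuracy <= 1, length(validated) > 0)
  d <- estimates$d[match(validated, estimates$exon_key)]
  if (anyNA(d)) {
    stop(sprintf("%d validated exon(s) absent from the estimates (e.g. %s)",
                 sum(is.na(d)), validated[which(is.na(d))[1L]]), call. = FALSE)
  }
  m <- length(d)
  k <- ceiling(target_accuracy * m)
  cutoff <- sort(d, decreasing = TRUE)[k]
  if (mean(d >= cutoff) < target_accuracy) {
    stop("no cutoff attains the target accuracy with a non-empty CNV class",
         call. = FALSE)
  }
  cutoff
}

new_cnv_truthset <- function(estimates, prior, loss, cutoff, min_n,
                             n_excluded) {
  structure(list(estimates = estimates, cutoff = cutoff, prior = prior,
                 loss = loss, min_n = min_n, n_excluded = n_excluded),
            class = "cnv_truthset")
}

#' Fit an exon-level CNV truth set
#'
#' The central fitting function: computes the Bayes estimate of each exon's
#' CNV probability from its evidence counts, then labels exons `CNV` when
#' the estimate reaches the cutoff and `NON_CNV` otherwise.  The cutoff is
#' either given directly (default 0.45) or calibrated against a list of
#' externally validated CNV-exons via [calibrate_cutoff()]; supplying both
#' an explicit `cutoff` and `validated` is an error.
#'
#' @param evidence data.frame from [build_evidence()] (columns `chrom`,
#'   `start`, `end`, `gene_id`, `exon_key`, `n`, `x`).
#' @param prior a [beta_prior()]; default `beta_prior(0.33, 0.93)`.
#' @param loss a [loss_params()]; default `loss_params(16, 5)`.
#' @param cutoff decision threshold on the estimate, in `(0, 1)`.
#' @param validated optional character vector of validated CNV-exon keys;
#'   when given the cutoff is calibrated to `target_accuracy` on them.
#' @param target_accuracy calibration target, default 0.95.
#' @param min_n exons described by fewer than `min_n` sets are excluded
#'   (default 1: undescribed exons never enter the truth set).
#' @return Object of class `cnv_truthset` with components `estimates`
#'   (data.frame incl. `d` and `label`), `cutoff`, `prior`, `loss`, `min_n`,
#'   `n_excluded`.
#' @seealso [predict.cnv_truthset()], [write_truthset()],
#'   [benchmark_callsets()]
#' @export
cnv_truthset <- function(evidence, prior = beta_prior(0.33, 0.93),
                         loss = loss_params(16, 5), cutoff = 0.45,
                         validated = NULL, target_accuracy = 0.95,
                         min_n = 1L) {
  stopifnot(inherits(prior, "beta_prior"), inherits(loss, "loss_params"))
  if (!is.null(validated) && !missing(cutoff)) {
    stop("supply either an explicit cutoff or a validated exon list, not both",
         call. = FALSE)
  }
  need <- c("chrom", "start", "end", "gene_id", "exon_key", "n", "x")
  miss <- setdiff(need, names(evidence))
  if (length(miss)) {
    stop(sprintf("evidence lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  keep <- evidence$n >= min_n
  est <- evidence[keep, need, drop = FALSE]
  rownames(est) <- NULL
  est$d <- bayes_estimate(prior, est$n, est$x, loss)
  if (!is.null(validated)) {
    cutoff <- calibrate_cutoff(est, validated, target_accuracy)
  }
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff < 1)
  est$label <- ifelse(est$d >= cutoff, "CNV", "NON_CNV")
  new_cnv_truthset(est, prior, loss, cutoff, as.integer(min_n),
                   n_excluded = sum(!keep))
}

#' @export
print.cnv_truthset <- function(x, ...) {
  tab <- table(factor(x$estimates$label, levels = c("CNV", "NON_CNV")))
  cat("Exon-level CNV truth set\n")
  cat(sprintf("  prior:  Beta(%.4g, %.4g);  loss: t1 = %g, t2 = %g (fractile %.4g)\n",
              x$prior$alpha, x$prior$beta, x$loss$t1, x$loss$t2,
              x$loss$t2 / (x$loss$t1 + x$loss$t2)))
  cat(sprintf("  cutoff: %.6g;  min sets per exon: %d (excluded: %s)\n",
              x$cutoff, x$min_n,
              if (is.na(x$n_excluded)) "?" else x$n_excluded))
  cat(sprintf("  %d CNV-exon(s), %d non-CNV exon(s)\n",
              tab[["CNV"]], tab[["NON_CNV"]]))
  invisible(x)
}

#' @export
summary.cnv_truthset <- function(object, ...) {
  est <- object$estimates
  out <- list(
    counts = table(factor(est$label, levels = c("CNV", "NON_CNV"))),
    cutoff = object$cutoff,
    d_quantiles = stats::quantile(est$d, c(0, .25, .5, .75, 1)),
    evidence_depth = stats::quantile(est$n, c(0, .25, .5, .75, 1)),
    by_depth = table(cut(est$n, breaks = c(0, 1, 2, 5, 10, Inf),
                         labels = c("1", "2", "3-5", "6-10", ">10")),
                     est$label))
  class(out) <- "summary.cnv_truthset"
  out
}

#' @export
print.summary.cnv_truthset <- function(x, ...) {
  cat(sprintf("truth set: %d CNV / %d non-CNV exons at cutoff %.6g\n",
              x$counts[["CNV"]], x$counts[["NON_CNV"]], x$cutoff))
  cat("estimate quantiles:\n")
  print(signif(x$d_quantiles, 4))
  cat("label by number of describing sets:\n")
  print(x$by_depth)
  invisible(x)
}

#' @export
coef.cnv_truthset <- function(object, ...) {
  c(alpha = object$prior$alpha, beta = object$prior$beta,
    t1 = object$loss$t1, t2 = object$loss$t2, cutoff = object$cutoff)
}

#' Predict estimates or labels for new evidence counts
#'
#' Applies the fitted prior, loss and cutoff to new `(n, x)` evidence.
#'
#' @param object a [cnv_truthset()].
#' @param newdata data.frame with columns `n` and `x`.
#' @param type `"estimate"` for the Bayes estimate, `"label"` for the
#'   thresholded CNV/non-CNV call.
#' @param ... unused.
#' @return Numeric vector of estimates or character vector of labels.
#' @export
predict.cnv_truthset <- function(object, newdata,
                                 type = c("estimate", "label"), ...) {
  type <- match.arg(type)
  d <- bayes_estimate(object$prior, newdata$n, newdata$x, object$loss)
  if (type == "estimate") d else ifelse(d >= object$cutoff, "CNV", "NON_CNV")
}

#' Plot the distribution of truth-set estimates
#'
#' Histogram of the per-exon Bayes estimates with the decision cutoff marked;
#' the multi-modal shape reflects the discrete evidence configurations
#' (undescribed-as-CNV exons pile up near zero, unanimously confirmed exons
#' near one).
#'
#' @param x a [cnv_truthset()].
#' @param breaks histogram breaks, see [graphics::hist()].
#' @param ... further arguments to [graphics::hist()].
#' @return The histogram object, invisibly.
#' @export
plot.cnv_truthset <- function(x, breaks = 50, ...) {
  h <- graphics::hist(x$estimates$d, breaks = breaks,
                      main = "Per-exon CNV probability estimates",
                      xlab = "Bayes estimate d", ...)
  graphics::abline(v = x$cutoff, lty = 2)
  invisible(h)
}
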