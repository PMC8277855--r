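#' Beta prior on the per-exon CNV probability
#'
#' Construct a `beta_prior` directly from its shapes.  The package default,
#' `beta_prior(0.33, 0.93)`, is the maximum-likelihood fit to population CNV
#' frequencies over exons crossed by known CNV regions; use
#' [fit_beta_prior()] to refit on your own frequency map.
#'
#' @param alpha,beta shape parameters, both `> 0`.
#' @return Object of class `beta_prior`.
#' @export
beta_prior <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1L,
            length(beta) == 1L, is.finite(alpha), is.finite(beta),
            alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta prior: alpha = %.4g, beta = %.4g (mean %.4g)\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  if (!is.null(x$n)) {
    cat(sprintf("  fitted by ML on %d value(s); logLik %.4f; converged: %s\n",
                x$n, x$logLik, x$converged))
  }
  invisible(x)
}

#' @export
coef.beta_prior <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
logLik.beta_prior <- function(object, ...) {
  if (is.null(object$logLik)) stop("prior was not fitted to data", call. = FALSE)
  structure(object$logLik, df = 2L, nobs = object$n, class = "logLik")
}

.beta_loglik <- function(a, b, s1, s2, n) {
  n * ((a - 1) * s1 + (b - 1) * s2 - lbeta(a, b))
}

.beta_mom <- function(x) {
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m)) v <- m * (1 - m) / 2
  k <- m * (1 - m) / v - 1
  c(alpha = max(m * k, 1e-3), beta = max((1 - m) * k, 1e-3))
}

#' Fit a Beta prior by maximum likelihood
#'
#' Maximizes the Beta log-likelihood on fixed support `[0, 1]` (no location
#' or scale estimation) by a damped Newton iteration on the analytic
#' gradient, started from the method-of-moments estimate.  Values at exactly
#' 0 or 1 are clipped to `[eps, 1 - eps]` so the log-likelihood stays finite.
#'
#' @param x numeric vector of probabilities/frequencies in `[0, 1]`; at least
#'   10 usable values required.
#' @param eps clipping width, default `1e-6`.
#' @param grad_tol convergence tolerance on the log-likelihood gradient
#'   (absolute, per component), default `1e-8`.
#' @return A [beta_prior()] object with fit metadata: `logLik`, `n`,
#'   `converged`, `gradient`, and the method-of-moments start `mom`.
#' @export
fit_beta_prior <- function(x, eps = 1e-6, grad_tol = 1e-8) {
  x <- x[is.finite(x)]
  if (any(x < 0 | x > 1)) {
    stop("values must lie in [0, 1] (convert percents to fractions first)",
         call. = FALSE)
  }
  x <- pmin(pmax(x, eps), 1 - eps)
  n <- length(x)
  if (n < 10L) {
    stop(sprintf("need at least 10 usable values to fit the prior (got %d)", n),
         call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("all values identical after clipping; the likelihood is degenerate -- use a point prior instead",
         call. = FALSE)
  }
  s1 <- mean(log(x))
  s2 <- mean(log1p(-x))
  mom <- .beta_mom(x)
  a <- mom[["alpha"]]
  b <- mom[["beta"]]
  g <- c(Inf, Inf)
  for (it in seq_len(500L)) {
    g <- n * c(digamma(a + b) - digamma(a) + s1,
               digamma(a + b) - digamma(b) + s2)
    if (max(abs(g)) < grad_tol) break
    tg <- trigamma(a + b)
    H <- n * matrix(c(tg - trigamma(a), tg, tg, tg - trigamma(b)), 2L, 2L)
    step <- tryCatch(solve(H, g), error = function(e) g / abs(diag(H)))
    ll0 <- .beta_loglik(a, b, s1, s2, n)
    lam <- 1
    repeat {
      a1 <- a - lam * step[[1L]]
      b1 <- b - lam * step[[2L]]
      if (a1 > 0 && b1 > 0 &&
          .beta_loglik(a1, b1, s1, s2, n) >= ll0 - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-12) { a1 <- a; b1 <- b; break }
    }
    if (a1 == a && b1 == b) break
    a <- a1
    b <- b1
  }
  out <- beta_prior(a, b)
  out$logLik <- .beta_loglik(a, b, s1, s2, n)
  out$logLik_mom <- .beta_loglik(mom[["alpha"]], mom[["beta"]], s1, s2, n)
  out$n <- n
  out$mom <- mom
  out$gradient <- g
  out$converged <- max(abs(g)) < grad_tol
  out
}

#' Per-exon prior CNV probabilities from a population frequency map
#'
#' Only exons crossed by at least one frequency record (any overlap of at
#' least 1 bp) contribute; their prior probability aggregates the overlapping
#' records' frequencies.  The default aggregation is the maximum, which is
#' conservative toward CNV presence when records disagree; `"mean"` and
#' `"coverage"` (overlap-width-weighted mean) are available.
#'
#' @param exons exon data.frame (see [reduce_exons()]).
#' @param freq_map data.frame `chrom`, `start`, `end`, `frequency` (see
#'   [read_frequency_map()]).
#' @param aggregate aggregation rule across overlapping records.
#' @return data.frame `exon_key`, `probability`, one row per crossed exon.
#' @export
exon_prior_probabilities <- function(exons, freq_map,
                                     aggregate = c("max", "mean", "coverage")) {
  aggregate <- match.arg(aggregate)
  if (is.null(freq_map) || nrow(freq_map) == 0L) {
    stop("frequency map is empty", call. = FALSE)
  }
  exons <- .validate_intervals(exons, "exon")
  freq_map <- .validate_intervals(freq_map, "frequency map")
  keys <- if (is.null(exons$exon_key)) exon_key(exons) else exons$exon_key
  res_key <- character(0)
  res_p <- numeric(0)
  for (ch in intersect(unique(exons$chrom), unique(freq_map$chrom))) {
    ei <- which(exons$chrom == ch)
    fi <- which(freq_map$chrom == ch)
    ir_e <- .ir(exons$start[ei], exons$end[ei])
    ir_f <- .ir(freq_map$start[fi], freq_map$end[fi])
    hits <- IRanges::findOverlaps(ir_e, ir_f)
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits)
    f <- freq_map$frequency[fi][S4Vectors::subjectHits(hits)]
    p <- switch(aggregate,
      max = tapply(f, q, max),
      mean = tapply(f, q, mean),
      coverage = {
        w <- IRanges::width(IRanges::pintersect(
          ir_e[q], ir_f[S4Vectors::subjectHits(hits)]))
        tapply(f * w, q, sum) / tapply(w, q, sum)
      })
    idx <- as.integer(names(p))
    res_key <- c(res_key, keys[ei][idx])
    res_p <- c(res_p, as.numeric(p))
  }
  out <- data.frame(exon_key = res_key, probability = res_p,
                    stringsAsFactors = FALSE)
  out[order(match(out$exon_key, keys)), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write / read a fitted prior
#'
#' Two-number prior file with a fit report (n, log-likelihood, convergence).
#'
#' @param prior a [beta_prior()] object.
#' @param path file path.
#' @return `write_prior`: `path` invisibly; `read_prior`: a `beta_prior`.
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "beta_prior"))
  lines <- c("key\tvalue",
             sprintf("alpha\t%.15g", prior$alpha),
             sprintf("beta\t%.15g", prior$beta))
  if (!is.null(prior$n)) {
    lines <- c(lines,
               sprintf("n\t%d", prior$n),
               sprintf("logLik\t%.15g", prior$logLik),
               sprintf("converged\t%s", prior$converged))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  kv <- stats::setNames(df$value, df$key)
  prior <- beta_prior(as.numeric(kv[["alpha"]]), as.numeric(kv[["beta"]]))
  if ("n" %in% names(kv)) {
    prior$n <- as.integer(kv[["n"]])
    prior$logLik <- as.numeric(kv[["logLik"]])
    prior$converged <- as.logical(kv[["converged"]])
  }
  prior
}
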