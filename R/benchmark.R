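# Exon-level evaluation of CNV callers against a truth set, pairwise
# concordance between call sets, confirmation tiers and call-level summaries.

#' Evaluation domain: truth-set exons inside the target design
#'
#' Evaluation is only meaningful where a caller could have called: the
#' intersection of the truth set with the exome kit's target design.  The
#' default membership rule is any overlap (>= 1 bp); `rule = "fraction"`
#' applies the same >= `min_fraction` rule used for CNV membership.
#'
#' @param truthset a [cnv_truthset()].
#' @param design data.frame of target-design intervals.
#' @param rule membership rule.
#' @param min_fraction threshold for `rule = "fraction"`.
#' @return Character vector of exon keys.
#' @export
evaluation_domain <- function(truthset, design, rule = c("any", "fraction"),
                              min_fraction = 0.5) {
  rule <- match.arg(rule)
  est <- truthset$estimates
  cf <- coverage_fractions(est, design)
  keep <- if (rule == "any") cf > 0 else cf >= min_fraction
  if (!any(keep)) {
    stop("no truth-set exon overlaps the target design; evaluation is undefined",
         call. = FALSE)
  }
  est$exon_key[keep]
}

#' Exon-level confusion counts
#'
#' Set semantics: duplicated predictions count once, predictions outside the
#' evaluation domain are ignored.  `tp + fp + fn + tn` always equals the
#' domain size.
#'
#' @param truthset a [cnv_truthset()].
#' @param predicted character vector of exon keys a caller labels CNV.
#' @param domain evaluation domain (exon keys); defaults to every truth-set
#'   exon.
#' @return Object of class `confusion_counts` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_counts <- function(truthset, predicted,
                             domain = truthset$estimates$exon_key) {
  est <- truthset$estimates
  domain <- unique(domain)
  truth_cnv <- intersect(est$exon_key[est$label == "CNV"], domain)
  pred <- intersect(unique(predicted), domain)
  tp <- length(intersect(pred, truth_cnv))
  fp <- length(setdiff(pred, truth_cnv))
  fn <- length(setdiff(truth_cnv, pred))
  structure(list(tp = tp, fp = fp, fn = fn,
                 tn = length(domain) - tp - fp - fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Recall, precision and F1 from confusion counts
#'
#' `f1_convention = "standard"` is the harmonic mean `2RP/(R+P)`;
#' `"paper"` uses `RP/(R+P)` (half the harmonic mean), provided for
#' compatibility with reports that print the formula without the factor 2.
#' Metrics with a zero denominator are `NA` (undefined), distinguishing "no
#' predictions" from "all wrong"; when recall and precision are both zero
#' the F1 is 0.
#'
#' @param x a [confusion_counts()] object.
#' @param f1_convention `"standard"` or `"paper"`.
#' @return List with `recall`, `precision`, `f1`, `f1_convention`.
#' @export
benchmark_metrics <- function(x, f1_convention = c("standard", "paper")) {
  f1_convention <- match.arg(f1_convention)
  recall <- if (x$tp + x$fn > 0) x$tp / (x$tp + x$fn) else NA_real_
  precision <- if (x$tp + x$fp > 0) x$tp / (x$tp + x$fp) else NA_real_
  f1 <- if (is.na(recall) || is.na(precision)) {
    NA_real_
  } else if (recall + precision == 0) {
    0
  } else {
    fac <- if (f1_convention == "standard") 2 else 1
    fac * recall * precision / (recall + precision)
  }
  list(recall = recall, precision = precision, f1 = f1,
       f1_convention = f1_convention)
}

#' Pairwise concordance of two per-exon status maps
#'
#' `shared` counts exons described (not `UNOBSERVED`) by both sets;
#' `same_state` counts those with equal status (both CNV or both non-CNV).
#'
#' @param status_a,status_b factors from [classify_exons()], computed on the
#'   same exon model.
#' @return List `shared`, `same_state`, `rate`.
#' @export
pairwise_concordance <- function(status_a, status_b) {
  stopifnot(length(status_a) == length(status_b))
  both <- status_a != "UNOBSERVED" & status_b != "UNOBSERVED"
  shared <- sum(both)
  same <- sum(both & status_a == status_b)
  list(shared = shared, same_state = same,
       rate = if (shared > 0) same / shared else NA_real_)
}

#' Concordance matrix across call sets
#'
#' Diagonal entries report each set's own described-exon count; off-diagonal
#' entries hold the shared and same-state counts of the pair.
#'
#' @param exons exon data.frame.
#' @param callsets list of [callset()] objects.
#' @param min_fraction overlap rule threshold, see [classify_exons()].
#' @return Object of class `cnv_concordance` with matrices `shared` and
#'   `same_state`, vector `described`, and the status matrix.
#' @export
concordance_matrix <- function(exons, callsets, min_fraction = 0.5) {
  nm <- vapply(callsets, function(cs) cs$name, character(1L))
  status <- lapply(callsets, classify_exons, exons = exons,
                   min_fraction = min_fraction)
  k <- length(callsets)
  shared <- same <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  described <- vapply(status, function(s) sum(s != "UNOBSERVED"), numeric(1L))
  names(described) <- nm
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pc <- pairwise_concordance(status[[i]], status[[j]])
      shared[i, j] <- pc$shared
      same[i, j] <- pc$same_state
    }
  }
  structure(list(shared = shared, same_state = same, described = described,
                 status = status),
            class = "cnv_concordance")
}

#' @export
print.cnv_concordance <- function(x, ...) {
  k <- length(x$described)
  nm <- names(x$described)
  out <- matrix("", k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- if (i == j) {
        format(x$described[[i]])
      } else {
        sprintf("%d/%d", x$same_state[i, j], x$shared[i, j])
      }
    }
  }
  cat("pairwise concordance (diagonal: described exons; off-diagonal: same-state/shared)\n")
  print(out, quote = FALSE)
  invisible(x)
}

#' Confirmation tiers of predicted CNV-exons
#'
#' For each tool, every predicted CNV-exon is assigned the number of tools
#' predicting it (including the tool itself) and binned into tiers 1-2, 3-6
#' and over 6; singletons are exons predicted by exactly one tool.  Tier
#' fractions sum to 1 per tool.
#'
#' @param predictions named list (>= 2 tools) of character vectors of
#'   predicted CNV-exon keys.
#' @return Matrix tools x `c("tier_1_2", "tier_3_6", "tier_gt6",
#'   "singleton")` of fractions (`NaN` rows for tools without predictions).
#' @export
confirmation_tiers <- function(predictions) {
  if (length(predictions) < 2L) {
    stop("confirmation tiers need at least 2 tools", call. = FALSE)
  }
  predictions <- lapply(predictions, unique)
  counts <- table(unlist(predictions, use.names = FALSE))
  out <- t(vapply(predictions, function(p) {
    k <- as.integer(counts[p])
    c(tier_1_2 = mean(k <= 2), tier_3_6 = mean(k >= 3 & k <= 6),
      tier_gt6 = mean(k > 6), singleton = mean(k == 1L))
  }, numeric(4L)))
  out
}

#' Call-level summary of a call set
#'
#' Counts by type, target-region coverage and call lengths, mirroring the
#' usual per-tool CNV summary tables.  `targets` counts distinct design
#' regions overlapped by any call; `mean_targets` is the mean, over calls,
#' of the number of design regions each call overlaps (a region shared by
#' two calls counts once for `targets` but once per call for
#' `mean_targets`).  Lengths are reported in kb (1 kb = 1,000 bp).
#'
#' @param callset a [callset()] object.
#' @param design data.frame of target-design intervals.
#' @return Object of class `call_summary` (a one-row data.frame): `name`,
#'   `n_cnv`, `n_del`, `n_dup`, `targets`, `mean_targets`,
#'   `total_length_kb`, `mean_length_kb`, `min_length_kb`, `max_length_kb`.
#' @export
summarize_callset <- function(callset, design) {
  calls <- callset$calls
  if (nrow(calls) == 0L) {
    out <- data.frame(name = callset$name, n_cnv = 0L, n_del = 0L, n_dup = 0L,
                      targets = 0L, mean_targets = 0, total_length_kb = 0,
                      mean_length_kb = 0, min_length_kb = 0, max_length_kb = 0,
                      stringsAsFactors = FALSE)
    class(out) <- c("call_summary", class(out))
    return(out)
  }
  design <- .validate_intervals(design, "target design")
  len <- (calls$end - calls$start) / 1000
  per_call <- integer(nrow(calls))
  hit_regions <- logical(nrow(design))
  for (ch in intersect(unique(calls$chrom), unique(design$chrom))) {
    ci <- which(calls$chrom == ch)
    di <- which(design$chrom == ch)
    hits <- IRanges::findOverlaps(.ir(calls$start[ci], calls$end[ci]),
                                  .ir(design$start[di], design$end[di]))
    if (length(hits)) {
      tab <- table(S4Vectors::queryHits(hits))
      per_call[ci[as.integer(names(tab))]] <- as.integer(tab)
      hit_regions[di[unique(S4Vectors::subjectHits(hits))]] <- TRUE
    }
  }
  out <- data.frame(name = callset$name,
                    n_cnv = nrow(calls),
                    n_del = sum(calls$svtype == "DEL"),
                    n_dup = sum(calls$svtype == "DUP"),
                    targets = sum(hit_regions),
                    mean_targets = mean(per_call),
                    total_length_kb = sum(len),
                    mean_length_kb = mean(len),
                    min_length_kb = min(len),
                    max_length_kb = max(len),
                    stringsAsFactors = FALSE)
  class(out) <- c("call_summary", class(out))
  out
}

#' Benchmark call sets against a truth set
#'
#' Classifies each call set's predictions onto the exon model, restricts to
#' the evaluation domain, and reports per-tool confusion counts and metrics.
#'
#' @param truthset a [cnv_truthset()].
#' @param exons exon data.frame the truth set was built on.
#' @param callsets list of [callset()] objects to evaluate.
#' @param design optional target-design intervals; when given the domain is
#'   computed by [evaluation_domain()], otherwise all truth-set exons.
#' @param min_fraction overlap rule threshold.
#' @param f1_convention see [benchmark_metrics()].
#' @param domain_rule see [evaluation_domain()].
#' @return data.frame, one row per tool: counts, recall, precision, f1.
#' @export
benchmark_callsets <- function(truthset, exons, callsets, design = NULL,
                               min_fraction = 0.5,
                               f1_convention = c("standard", "paper"),
                               domain_rule = c("any", "fraction")) {
  f1_convention <- match.arg(f1_convention)
  domain <- if (is.null(design)) {
    truthset$estimates$exon_key
  } else {
    evaluation_domain(truthset, design, match.arg(domain_rule), min_fraction)
  }
  rows <- lapply(callsets, function(cs) {
    st <- classify_exons(exons, cs, min_fraction)
    pred <- names(st)[st == "CNV"]
    cc <- confusion_counts(truthset, pred, domain)
    m <- benchmark_metrics(cc, f1_convention)
    data.frame(name = cs$name, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
               recall = m$recall, precision = m$precision, f1 = m$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "f1_convention") <- f1_convention
  attr(out, "domain_size") <- length(unique(domain))
  out
}

#' Write a benchmark report
#'
#' @param report data.frame from [benchmark_callsets()].
#' @param path output path.
#' @param format `"auto"` picks JSON for a `.json` extension, TSV otherwise.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path,
                                   format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
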