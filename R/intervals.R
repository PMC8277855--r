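# Working representation throughout the package: a plain data.frame of
# 0-based half-open intervals (chrom, start, end).  GTF/GFF (1-based closed)
# is converted on ingest; BED passes through unchanged.  IRanges does all
# merge/overlap arithmetic behind these helpers.

.validate_intervals <- function(df, what = "interval") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    stop(sprintf("malformed %s record(s) (need 0 <= start < end) at row(s): %s",
                 what, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(start)
  df$end <- as.integer(end)
  df
}

# 0-based half-open -> IRanges (1-based closed)
.ir <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Stable exon identifier
#'
#' Exon identity is `(gene_id, interval)`: the same genomic interval
#' annotated under two genes yields two exon records.
#'
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @return Character vector of keys, one per row.
#' @export
exon_key <- function(exons) {
  sprintf("%s:%s:%d-%d", exons$gene_id, exons$chrom, exons$start, exons$end)
}

#' Build non-overlapping exons per gene
#'
#' Merges each gene's exon records into a disjoint set of intervals
#' (overlapping or book-ended records are unioned), the exon model every
#' downstream step works on.  Idempotent: applying it to its own output is
#' the identity.
#'
#' @param records data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param dedup_intervals if `TRUE`, intervals shared verbatim by several
#'   genes are kept once (first gene in sort order wins). Default `FALSE`:
#'   one exon record per gene.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `exon_key`, ordered by (chrom, start, end, gene_id).
#' @export
reduce_exons <- function(records, dedup_intervals = FALSE) {
  records <- .validate_intervals(records, "exon record")
  if (is.null(records$gene_id)) {
    stop("exon records need a 'gene_id' column", call. = FALSE)
  }
  records$gene_id <- as.character(records$gene_id)
  parts <- split(records, paste0(records$gene_id, "\r", records$chrom))
  out <- lapply(parts, function(p) {
    r <- IRanges::reduce(.ir(p$start, p$end))
    data.frame(chrom = p$chrom[[1L]],
               start = IRanges::start(r) - 1L,
               end = IRanges::end(r),
               gene_id = p$gene_id[[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
  if (isTRUE(dedup_intervals)) {
    out <- out[!duplicated(out[c("chrom", "start", "end")]), , drop = FALSE]
  }
  rownames(out) <- NULL
  out$exon_key <- exon_key(out)
  out
}

#' Fraction of each exon covered by a set of intervals
#'
#' Coverage is measured against the union of the intervals, so callers that
#' fragment one event into adjacent pieces are counted once per base.
#'
#' @param exons exon data.frame (see [reduce_exons()]).
#' @param intervals data.frame of intervals (`chrom`, `start`, `end`) or
#'   `NULL`/empty for zero coverage.
#' @return Numeric vector in `[0, 1]`, one value per exon.
#' @export
coverage_fractions <- function(exons, intervals) {
  exons <- .validate_intervals(exons, "exon")
  out <- numeric(nrow(exons))
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(out)
  }
  intervals <- .validate_intervals(intervals)
  for (ch in intersect(unique(exons$chrom), unique(intervals$chrom))) {
    ei <- which(exons$chrom == ch)
    ir_e <- .ir(exons$start[ei], exons$end[ei])
    ci <- intervals$chrom == ch
    ir_c <- IRanges::reduce(.ir(intervals$start[ci], intervals$end[ci]))
    hits <- IRanges::findOverlaps(ir_e, ir_c)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      w <- IRanges::width(IRanges::pintersect(ir_e[q],
                                              ir_c[S4Vectors::subjectHits(hits)]))
      cov <- tapply(w, q, sum)
      idx <- as.integer(names(cov))
      out[ei[idx]] <- as.numeric(cov) / IRanges::width(ir_e)[idx]
    }
  }
  out
}

#' @rdname coverage_fractions
#' @param exon single-row exon data.frame.
#' @export
coverage_fraction <- function(exon, intervals) {
  coverage_fractions(exon[1L, , drop = FALSE], intervals)[[1L]]
}

#' Exon-level CNV status under one call set
#'
#' An exon is a CNV-exon for a call set when the union of the set's CNV calls
#' spans at least `min_fraction` of the exon (boundary inclusive: exactly 50%
#' counts).  Otherwise, sets that carry explicit non-CNV evidence label the
#' exon `NON_CNV` when their assayed universe spans at least `min_fraction`
#' of it; every remaining exon is `UNOBSERVED` (the set says nothing about
#' it).
#'
#' @param exons exon data.frame.
#' @param callset a [callset()] object.
#' @param min_fraction overlap rule threshold in `(0, 1]`; default 0.5.
#' @return Factor with levels `CNV`, `NON_CNV`, `UNOBSERVED`, named by
#'   `exon_key`.
#' @export
classify_exons <- function(exons, callset, min_fraction = 0.5) {
  stopifnot(inherits(callset, "cnv_callset"),
            is.numeric(min_fraction), min_fraction > 0, min_fraction <= 1)
  cf <- coverage_fractions(exons, callset$calls)
  st <- rep.int("UNOBSERVED", nrow(exons))
  st[cf >= min_fraction] <- "CNV"
  if (isTRUE(callset$has_noncnv_evidence)) {
    uf <- coverage_fractions(exons, callset$universe)
    st[st != "CNV" & uf >= min_fraction] <- "NON_CNV"
  }
  out <- factor(st, levels = c("CNV", "NON_CNV", "UNOBSERVED"))
  names(out) <- if (is.null(exons$exon_key)) exon_key(exons) else exons$exon_key
  out
}

#' @rdname classify_exons
#' @param exon single-row exon data.frame.
#' @export
classify_exon <- function(exon, callset, min_fraction = 0.5) {
  classify_exons(exon[1L, , drop = FALSE], callset, min_fraction)[[1L]]
}

#' Per-exon evidence counts across call sets
#'
#' For each exon, `n` is the number of call sets that describe it at all
#' (status `CNV` or `NON_CNV`) and `x` the number describing it as a
#' CNV-exon; `(n, x)` feed the beta-binomial posterior.  Exons described by
#' no set are retained with `(0, 0)` and `described = FALSE`.
#'
#' @param exons exon data.frame.
#' @param callsets list of [callset()] objects with unique names.
#' @param min_fraction overlap rule threshold, see [classify_exons()].
#' @return data.frame: exon columns plus `n`, `x`, `described`.
#' @export
build_evidence <- function(exons, callsets, min_fraction = 0.5) {
  if (length(callsets) == 0L) stop("need at least one call set", call. = FALSE)
  nm <- vapply(callsets, function(cs) cs$name, character(1L))
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate call-set name(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  }
  status <- vapply(callsets,
                   function(cs) as.character(classify_exons(exons, cs, min_fraction)),
                   character(nrow(exons)))
  status <- matrix(status, nrow = nrow(exons))
  n <- rowSums(status != "UNOBSERVED")
  x <- rowSums(status == "CNV")
  out <- exons[c("chrom", "start", "end", "gene_id", "exon_key")]
  out$n <- as.integer(n)
  out$x <- as.integer(x)
  out$described <- out$n > 0L
  rownames(out) <- NULL
  out
}

#' Restrict a table to autosomes
#'
#' Keeps chromosomes 1-22 in either naming dialect (`chr1` or `1`); sex
#' chromosomes, mitochondria and unrecognized contigs are dropped with a
#' message reporting the count.
#'
#' @param x data.frame with a `chrom` column.
#' @return Filtered data.frame.
#' @export
filter_autosomes <- function(x) {
  stopifnot(!is.null(x$chrom))
  plain <- sub("^chr", "", as.character(x$chrom))
  keep <- plain %in% as.character(1:22)
  if (any(!keep)) {
    message(sprintf("filter_autosomes: dropped %d record(s) on non-autosomal or unrecognized chromosomes",
                    sum(!keep)))
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
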