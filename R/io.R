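# Readers reject malformed rows (reporting row numbers) rather than coercing;
# every writer has a reader that inverts it on valid data.

.read_table_chr <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (length(unique(ncol)) != 1L) {
    bad <- which(ncol != stats::median(ncol))
    stop(sprintf("%s: ragged rows (differing column counts) at row(s): %s",
                 what, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  mat <- matrix(unlist(parts), nrow = length(parts), byrow = TRUE)
  as.data.frame(mat, stringsAsFactors = FALSE)
}

.require_int <- function(v, what, col) {
  num <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(num) | num != floor(num) | num < 0)
  if (length(bad)) {
    stop(sprintf("%s: non-integer %s at row(s): %s", what, col,
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  as.integer(num)
}

#' Read a BED-like interval file
#'
#' Tab-separated, 0-based half-open.  Columns: chrom, start, end and an
#' optional fourth column read as the call type (`DEL`, `DUP` or `CNV`,
#' case-insensitive).  Lines starting with `#`, `track` or `browser` are
#' skipped.  Malformed rows are rejected with their row numbers.
#'
#' @param path file path.
#' @param svtype if `TRUE` (default) read column 4, when present, as svtype;
#'   absent values default to `"CNV"`.
#' @return data.frame with `chrom`, `start`, `end` and (when `svtype`)
#'   `svtype`; zero-row data.frame for an empty file.
#' @export
read_bed <- function(path, svtype = TRUE) {
  df <- .read_table_chr(path, "BED")
  if (is.null(df)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    if (svtype) out$svtype <- character()
    return(out)
  }
  if (ncol(df) < 3L) {
    stop(sprintf("BED %s: need at least 3 columns", path), call. = FALSE)
  }
  out <- data.frame(chrom = df[[1L]],
                    start = .require_int(df[[2L]], path, "start"),
                    end = .require_int(df[[3L]], path, "end"),
                    stringsAsFactors = FALSE)
  out <- .validate_intervals(out, sprintf("BED %s", path))
  if (svtype) {
    if (ncol(df) >= 4L) {
      sv <- toupper(df[[4L]])
      bad <- which(!sv %in% c("DEL", "DUP", "CNV"))
      if (length(bad)) {
        stop(sprintf("BED %s: svtype not in {DEL, DUP, CNV} at row(s): %s",
                     path, paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
      }
      out$svtype <- sv
    } else {
      out$svtype <- rep.int("CNV", nrow(out))
    }
  }
  out
}

.write_bed <- function(df, path, cols = c("chrom", "start", "end")) {
  cols <- intersect(c(cols, "svtype", "gene_id", "frequency"), names(df))
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Construct a CNV call set
#'
#' A call set is one study's or tool's CNV intervals plus, optionally, the
#' assayed universe -- the territory it actually interrogated -- and a flag
#' saying whether absence of a call inside that universe is evidence of a
#' non-CNV (diploid) exon.
#'
#' @param name unique set name.
#' @param calls data.frame of calls (`chrom`, `start`, `end`, optional
#'   `svtype`).
#' @param universe optional data.frame of assayed intervals.
#' @param has_noncnv_evidence logical; requires a non-empty `universe`.
#' @return Object of class `cnv_callset`.
#' @export
callset <- function(name, calls, universe = NULL, has_noncnv_evidence = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (nrow(calls) > 0L) {
    calls <- .validate_intervals(calls, sprintf("call set '%s'", name))
  }
  if (is.null(calls$svtype)) calls$svtype <- rep.int("CNV", nrow(calls))
  if (!all(calls$svtype %in% c("DEL", "DUP", "CNV"))) {
    stop(sprintf("call set '%s': svtype must be DEL, DUP or CNV", name),
         call. = FALSE)
  }
  if (!is.null(universe) && nrow(universe) > 0L) {
    universe <- .validate_intervals(universe, sprintf("universe of '%s'", name))
  }
  if (isTRUE(has_noncnv_evidence) &&
      (is.null(universe) || nrow(universe) == 0L)) {
    stop(sprintf("call set '%s': has_noncnv_evidence requires a non-empty universe",
                 name), call. = FALSE)
  }
  structure(list(name = name, calls = calls, universe = universe,
                 has_noncnv_evidence = isTRUE(has_noncnv_evidence)),
            class = "cnv_callset")
}

#' @export
print.cnv_callset <- function(x, ...) {
  cat(sprintf("<cnv_callset '%s'>  %d call(s)", x$name, nrow(x$calls)))
  if (!is.null(x$universe)) {
    cat(sprintf("; universe: %d interval(s)%s", nrow(x$universe),
                if (x$has_noncnv_evidence) " (non-CNV evidence)" else ""))
  }
  cat("\n")
  invisible(x)
}

#' @rdname callset
#' @param calls_path,universe_path BED file paths (see [read_bed()]).
#' @export
read_callset <- function(name, calls_path, universe_path = NULL,
                         has_noncnv_evidence = FALSE) {
  uni <- if (!is.null(universe_path)) read_bed(universe_path, svtype = FALSE)
  callset(name, read_bed(calls_path), uni, has_noncnv_evidence)
}

#' Load a call-set manifest
#'
#' A manifest lists the call sets of an analysis with per-set attributes.
#' YAML layout (`.yaml`/`.yml`):
#' ```yaml
#' sets:
#'   - name: phase3
#'     calls: phase3.bed
#'     universe: phase3_universe.bed   # optional
#'     noncnv_evidence: true           # default false
#'     role: evidence                  # or prediction; default evidence
#' ```
#' A TSV manifest (any other extension) needs a header with the same fields
#' (`universe` empty or `.` for none).  Relative paths resolve against the
#' manifest's directory.
#'
#' @param path manifest file.
#' @return List with `manifest` (data.frame of entries) and `callsets`
#'   (named list of [callset()] objects).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  }
  base <- dirname(path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (is.null(y$sets)) stop("manifest YAML needs a top-level 'sets' list",
                              call. = FALSE)
    entries <- do.call(rbind, lapply(y$sets, function(e) {
      data.frame(name = as.character(e$name %||% NA_character_),
                 calls = as.character(e$calls %||% NA_character_),
                 universe = as.character(e$universe %||% NA_character_),
                 noncnv_evidence = isTRUE(e$noncnv_evidence),
                 role = as.character(e$role %||% "evidence"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    entries <- utils::read.table(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE, na.strings = c("", "."))
    need <- c("name", "calls")
    miss <- setdiff(need, names(entries))
    if (length(miss)) stop(sprintf("manifest lacks column(s): %s",
                                   paste(miss, collapse = ", ")), call. = FALSE)
    if (is.null(entries$universe)) entries$universe <- NA_character_
    if (is.null(entries$noncnv_evidence)) entries$noncnv_evidence <- FALSE
    entries$noncnv_evidence <- as.logical(entries$noncnv_evidence)
    if (is.null(entries$role)) entries$role <- "evidence"
  }
  if (anyNA(entries$name) || anyNA(entries$calls)) {
    stop("manifest entries need 'name' and 'calls'", call. = FALSE)
  }
  if (anyDuplicated(entries$name)) {
    stop(sprintf("duplicate call-set name(s) in manifest: %s",
                 paste(unique(entries$name[duplicated(entries$name)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (!all(entries$role %in% c("evidence", "prediction"))) {
    stop("manifest 'role' must be 'evidence' or 'prediction'", call. = FALSE)
  }
  bad <- which(entries$noncnv_evidence & is.na(entries$universe))
  if (length(bad)) {
    stop(sprintf("manifest entry '%s': noncnv_evidence without a universe",
                 entries$name[bad[1L]]), call. = FALSE)
  }
  resolve <- function(p) ifelse(is.na(p) | grepl("^/", p), p, file.path(base, p))
  callsets <- lapply(seq_len(nrow(entries)), function(i) {
    read_callset(entries$name[i], resolve(entries$calls[i]),
                 if (!is.na(entries$universe[i])) resolve(entries$universe[i]),
                 entries$noncnv_evidence[i])
  })
  names(callsets) <- entries$name
  list(manifest = entries, callsets = callsets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a call-set manifest plus its BED files
#'
#' @param callsets named list of [callset()] objects.
#' @param dir output directory (created if needed).
#' @param roles character vector of roles (`evidence`/`prediction`), recycled.
#' @return Path of the written manifest, invisibly.
#' @export
write_manifest <- function(callsets, dir, roles = "evidence") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roles <- rep_len(roles, length(callsets))
  sets <- lapply(seq_along(callsets), function(i) {
    cs <- callsets[[i]]
    calls_file <- sprintf("%s.calls.bed", cs$name)
    .write_bed(cs$calls, file.path(dir, calls_file),
               c("chrom", "start", "end", "svtype"))
    entry <- list(name = cs$name, calls = calls_file, role = roles[i])
    if (!is.null(cs$universe)) {
      uni_file <- sprintf("%s.universe.bed", cs$name)
      .write_bed(cs$universe, file.path(dir, uni_file))
      entry$universe <- uni_file
      entry$noncnv_evidence <- cs$has_noncnv_evidence
    }
    entry
  })
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(sets = sets), path)
  invisible(path)
}

#' Read a population CNV-frequency map
#'
#' BED3 plus a numeric fourth column holding the population CNV frequency as
#' a fraction in `[0, 1]` (percent values must be pre-converted; rows outside
#' the unit interval are rejected).
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end`, `frequency`.
#' @export
read_frequency_map <- function(path) {
  df <- .read_table_chr(path, "frequency map")
  if (is.null(df) || ncol(df) < 4L) {
    stop(sprintf("frequency map %s: need 4 columns (chrom, start, end, frequency)",
                 path), call. = FALSE)
  }
  freq <- suppressWarnings(as.numeric(df[[4L]]))
  bad <- which(is.na(freq) | freq < 0 | freq > 1)
  if (length(bad)) {
    stop(sprintf("frequency map %s: frequency outside [0, 1] at row(s): %s",
                 path, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(chrom = df[[1L]],
                    start = .require_int(df[[2L]], path, "start"),
                    end = .require_int(df[[3L]], path, "end"),
                    frequency = freq, stringsAsFactors = FALSE)
  .validate_intervals(out, sprintf("frequency map %s", path))
}

#' Read a validated CNV-exon list
#'
#' One exon key per line, or a TSV with an `exon_key` column.
#'
#' @param path file path.
#' @return Character vector of exon keys.
#' @export
read_validated_exons <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("validated-exon file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) && grepl("\t", lines[[1L]])) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "#")
    if (is.null(df$exon_key)) {
      stop("validated-exon TSV needs an 'exon_key' column", call. = FALSE)
    }
    return(df$exon_key)
  }
  lines
}

#' Write / read a truth set as TSV
#'
#' Tab-separated with provenance header comments (prior, loss, cutoff) and
#' columns `chrom, start, end, gene_id, n, x, estimate, label`.  Estimates
#' are serialized with 15 significant digits so the pair round-trips within
#' 1e-9.
#'
#' @param x a [cnv_truthset()] object.
#' @param path output file.
#' @return `write_truthset`: `path` invisibly. `read_truthset`: a
#'   `cnv_truthset` object rebuilt from the file.
#' @export
write_truthset <- function(x, path) {
  stopifnot(inherits(x, "cnv_truthset"))
  est <- x$estimates
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cnvtruth truth set"),
    sprintf("# alpha=%.15g beta=%.15g t1=%.15g t2=%.15g cutoff=%.15g min_n=%d",
            x$prior$alpha, x$prior$beta, x$loss$t1, x$loss$t2, x$cutoff,
            x$min_n),
    paste(c("chrom", "start", "end", "gene_id", "n", "x", "estimate", "label"),
          collapse = "\t")), con)
  if (nrow(est)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%.15g\t%s",
                       est$chrom, est$start, est$end, est$gene_id,
                       est$n, est$x, est$d, est$label), con)
  }
  invisible(path)
}

#' @rdname write_truthset
#' @export
read_truthset <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("truth-set file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  hdr <- lines[grepl("^# alpha=", lines)]
  params <- c(alpha = NA_real_, beta = NA_real_, t1 = NA_real_, t2 = NA_real_,
              cutoff = NA_real_, min_n = 1)
  if (length(hdr)) {
    kv <- strsplit(strsplit(sub("^# ", "", hdr[[1L]]), " ")[[1L]], "=")
    for (p in kv) params[p[[1L]]] <- as.numeric(p[[2L]])
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L) stop("truth-set file has no header row", call. = FALSE)
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "integer",
                                         "numeric", "character"))
  if (!all(df$label %in% c("CNV", "NON_CNV"))) {
    stop("truth-set labels must be CNV or NON_CNV", call. = FALSE)
  }
  est <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    gene_id = df$gene_id, stringsAsFactors = FALSE)
  est$exon_key <- exon_key(est)
  est$n <- df$n
  est$x <- df$x
  est$d <- df$estimate
  est$label <- df$label
  new_cnv_truthset(est,
                   prior = beta_prior(params[["alpha"]], params[["beta"]]),
                   loss = loss_params(params[["t1"]], params[["t2"]]),
                   cutoff = params[["cutoff"]],
                   min_n = as.integer(params[["min_n"]]),
                   n_excluded = NA_integer_)
}

#' Read an exon annotation
#'
#' GTF/GFF3 (`exon` features with a `gene_id` attribute; 1-based closed
#' coordinates converted to the internal 0-based half-open convention) or a
#' BED file whose 4th column is the gene id.  Records are merged per gene
#' with [reduce_exons()].
#'
#' @param path annotation file; format chosen by extension
#'   (`.gtf`/`.gff`/`.gff3` vs BED otherwise).
#' @param ... passed to [reduce_exons()].
#' @return Exon data.frame (see [reduce_exons()]).
#' @export
read_exons <- function(path, ...) {
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF/GFF requires the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop(sprintf("no exon features in %s", path),
                               call. = FALSE)
    gid <- gr$gene_id %||% gr$Parent
    rec <- data.frame(chrom = as.character(GenomicRanges_seqnames(gr)),
                      start = GenomicRanges_start(gr) - 1L,
                      end = GenomicRanges_end(gr),
                      gene_id = as.character(gid), stringsAsFactors = FALSE)
  } else {
    df <- .read_table_chr(path, "exon BED")
    if (is.null(df) || ncol(df) < 4L) {
      stop(sprintf("exon BED %s: need 4 columns (chrom, start, end, gene_id)",
                   path), call. = FALSE)
    }
    rec <- data.frame(chrom = df[[1L]],
                      start = .require_int(df[[2L]], path, "start"),
                      end = .require_int(df[[3L]], path, "end"),
                      gene_id = df[[4L]], stringsAsFactors = FALSE)
  }
  reduce_exons(rec, ...)
}

# thin indirection so rtracklayer/GenomicRanges stay in Suggests
GenomicRanges_seqnames <- function(gr) {
  getExportedValue("GenomeInfoDb", "seqnames")(gr)
}
GenomicRanges_start <- function(gr) getExportedValue("BiocGenerics", "start")(gr)
GenomicRanges_end <- function(gr) getExportedValue("BiocGenerics", "end")(gr)
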