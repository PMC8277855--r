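# Seeded generator of exome models, ground-truth CNV events, heterogeneous
# evidence call sets and validated subsets.  Every artifact is a pure
# function of (config, seed); per-set child seeds derive from the root seed
# by a stable hash of the set name, so adding a set never perturbs another.

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# deterministic 31-adic string hash mod 2^31 - 1 (exact in doubles)
.hash_name <- function(x) {
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 31 + cp) %% 2147483647
  h
}

.child_seed <- function(root, name) {
  as.integer((root + .hash_name(name)) %% 2147483629 + 1)
}

.sampler <- function(x) {
  if (is.function(x)) x else function(n) rep.int(as.integer(x), n)
}

#' Default simulated call-set designs
#'
#' Sixteen heterogeneous sets: sensitivities spread over 0.30-0.80,
#' per-exon false-positive rates over 1e-4 to 1e-3, assayed-universe
#' fractions over 0.5-1, boundary jitter cycling through 0/30/60/90 bp, and
#' a minority of five sets carrying explicit non-CNV evidence -- mirroring
#' a mix of array studies (restricted universes, diploid calls) and
#' sequencing studies (CNV calls only).
#'
#' @param k number of sets, default 16.
#' @return data.frame of per-set parameters.
#' @export
default_set_table <- function(k = 16L) {
  data.frame(
    name = sprintf("set%02d", seq_len(k)),
    sensitivity = seq(0.30, 0.80, length.out = k),
    fpr = 10^seq(-4, -3, length.out = k),
    universe_fraction = seq(0.5, 1, length.out = k),
    has_noncnv_evidence = seq_len(k) %% 3 == 2 & seq_len(k) <= 14,
    boundary_jitter_bp = rep_len(c(0L, 30L, 60L, 90L), k),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator realizes: an exome of
#' `n_genes * exons_per_gene` exons laid out on autosomes 1-22, multi-exon
#' CNV events with a deletion bias, per-exon CNV probabilities drawn from a
#' Beta distribution, and K call sets with heterogeneous sensitivity,
#' false-positive rate and assayed-universe coverage.
#'
#' @param seed root seed; all randomness derives from it.
#' @param n_genes,exons_per_gene exome layout (defaults give 10,000 exons).
#' @param exon_length,intron_length positive-integer samplers (`function(n)`)
#'   or constants, in bp.
#' @param gene_gap gap between consecutive genes, bp.
#' @param prior_true [beta_prior()] the per-exon CNV probabilities are drawn
#'   from; default `beta_prior(0.33, 0.93)`.
#' @param event_length_exons sampler for CNV event lengths in exons.
#' @param del_fraction probability an event is a deletion, default 0.7
#'   (callers and call sets preferentially report deletions).
#' @param sets data.frame of per-set parameters (see [default_set_table()]).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, exons_per_gene = 10L,
                       exon_length = function(n)
                         pmax(60L, as.integer(round(stats::rlnorm(n, log(160), 0.55)))),
                       intron_length = function(n)
                         pmax(200L, as.integer(round(stats::rlnorm(n, log(2500), 0.8)))),
                       gene_gap = 20000L,
                       prior_true = beta_prior(0.33, 0.93),
                       event_length_exons = function(n) 1L + stats::rpois(n, 2),
                       del_fraction = 0.7,
                       sets = default_set_table()) {
  stopifnot(n_genes >= 1, exons_per_gene >= 1,
            inherits(prior_true, "beta_prior"),
            del_fraction >= 0, del_fraction <= 1,
            is.data.frame(sets),
            all(c("name", "sensitivity", "fpr", "universe_fraction",
                  "has_noncnv_evidence", "boundary_jitter_bp") %in% names(sets)),
            all(sets$sensitivity >= 0 & sets$sensitivity <= 1),
            all(sets$fpr >= 0 & sets$fpr <= 1),
            all(sets$universe_fraction >= 0 & sets$universe_fraction <= 1),
            !anyDuplicated(sets$name))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = .sampler(exon_length),
                 intron_length = .sampler(intron_length),
                 gene_gap = as.integer(gene_gap),
                 prior_true = prior_true,
                 event_length_exons = .sampler(event_length_exons),
                 del_fraction = del_fraction, sets = sets),
            class = "sim_config")
}

#' Simulate an exome model
#'
#' Lays genes round-robin across chromosomes chr1-chr22, each gene a run of
#' non-overlapping exons separated by introns.  Deterministic given the
#' config's seed.
#'
#' @param config a [sim_config()].
#' @param chrom_size chromosome size budget, bp; layouts exceeding it fail.
#' @return Exon data.frame (see [reduce_exons()]).
#' @export
simulate_exome <- function(config, chrom_size = 2.5e8) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    g <- config$n_genes
    e <- config$exons_per_gene
    chrom <- sprintf("chr%d", (seq_len(g) - 1L) %% 22L + 1L)
    lens <- matrix(config$exon_length(g * e), nrow = g)
    gaps <- matrix(config$intron_length(g * e), nrow = g)  # last col unused
    cursor <- stats::setNames(rep.int(10000, 22), sprintf("chr%d", 1:22))
    rec <- vector("list", g)
    for (i in seq_len(g)) {
      ch <- chrom[[i]]
      pos <- cursor[[ch]]
      starts <- integer(e)
      ends <- integer(e)
      for (j in seq_len(e)) {
        starts[[j]] <- pos
        ends[[j]] <- pos + lens[i, j]
        pos <- ends[[j]] + gaps[i, j]
      }
      cursor[[ch]] <- ends[[e]] + config$gene_gap
      if (cursor[[ch]] > chrom_size) {
        stop(sprintf("simulated layout exceeds the %s size budget (%g bp)",
                     ch, chrom_size), call. = FALSE)
      }
      rec[[i]] <- data.frame(chrom = ch, start = starts, end = ends,
                             gene_id = sprintf("gene%04d", i),
                             stringsAsFactors = FALSE)
    }
    reduce_exons(do.call(rbind, rec))
  })
}

#' Simulate ground-truth CNV events
#'
#' Walks each gene's exons in genomic order, tiling them into candidate
#' blocks whose lengths come from `event_length_exons`.  Each block draws a
#' CNV probability from `prior_true` and becomes a CNV event with that
#' probability; retained events span the block's exon run and are deletions
#' with probability `del_fraction`.  The implied CNV-exon keys follow the
#' >= 50% overlap rule via [classify_exons()].  All candidate blocks are
#' also emitted as a population frequency map (interval + drawn
#' probability), giving the prior-fitting stage a faithful input.
#'
#' @param exons exon data.frame from [simulate_exome()].
#' @param config a [sim_config()].
#' @return Object of class `cnv_ground_truth`: `events` (data.frame with
#'   `svtype`), `cnv_exon_keys`, `freq_map`, `n_candidates`.
#' @export
simulate_truth <- function(exons, config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 1L, {
    genes <- split(seq_len(nrow(exons)), exons$gene_id)
    events <- list()
    freq <- list()
    n_cand <- 0L
    for (idx in genes) {
      idx <- idx[order(exons$start[idx])]
      i <- 1L
      while (i <= length(idx)) {
        L <- max(1L, config$event_length_exons(1L))
        j <- min(i + L - 1L, length(idx))
        block <- idx[i:j]
        theta <- stats::rbeta(1L, config$prior_true$alpha,
                              config$prior_true$beta)
        n_cand <- n_cand + 1L
        freq[[n_cand]] <- data.frame(chrom = exons$chrom[block[[1L]]],
                                     start = exons$start[block[[1L]]],
                                     end = exons$end[block[[length(block)]]],
                                     frequency = theta,
                                     stringsAsFactors = FALSE)
        if (stats::runif(1L) < theta) {
          sv <- if (stats::runif(1L) < config$del_fraction) "DEL" else "DUP"
          events[[length(events) + 1L]] <-
            data.frame(chrom = exons$chrom[block[[1L]]],
                       start = exons$start[block[[1L]]],
                       end = exons$end[block[[length(block)]]],
                       svtype = sv, stringsAsFactors = FALSE)
        }
        i <- j + 1L
      }
    }
    events <- if (length(events)) {
      do.call(rbind, events)
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 svtype = character(), stringsAsFactors = FALSE)
    }
    cnv_keys <- if (nrow(events)) {
      cs <- callset("truth", events)
      st <- classify_exons(exons, cs)
      names(st)[st == "CNV"]
    } else {
      character(0)
    }
    structure(list(events = events, cnv_exon_keys = cnv_keys,
                   freq_map = do.call(rbind, freq), n_candidates = n_cand),
              class = "cnv_ground_truth")
  })
}

#' @export
print.cnv_ground_truth <- function(x, ...) {
  cat(sprintf("<cnv_ground_truth> %d event(s) over %d candidate block(s); %d CNV-exon(s)\n",
              nrow(x$events), x$n_candidates, length(x$cnv_exon_keys)))
  invisible(x)
}

# union of the exon intervals flagged TRUE, merged per chromosome
.exon_union <- function(exons, keep) {
  sub <- exons[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(sub, sub$chrom), function(p) {
    r <- IRanges::reduce(.ir(p$start, p$end))
    data.frame(chrom = p$chrom[[1L]], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate one call set from the ground truth
#'
#' The set assays a random whole-exon universe covering about
#' `universe_fraction` of the exome.  Each true event is detected with
#' probability `sensitivity`; a detected event is reported as its
#' intersection with the universe (probe/target footprints fragment events),
#' each fragment's ends perturbed by up to `boundary_jitter_bp`.  Each
#' non-CNV exon inside the universe spawns a false-positive call with
#' probability `fpr`.  The universe is attached to the returned call set
#' only when the set carries non-CNV evidence.  Deterministic given the
#' root seed and set name.
#'
#' @param truth a [simulate_truth()] result.
#' @param exons exon data.frame.
#' @param set_config one row of the config's `sets` table (or a list with
#'   the same fields).
#' @param root_seed root seed (the config's `seed`).
#' @param del_fraction deletion probability for false-positive calls.
#' @return A [callset()]; `$sim_info` records the per-event detection
#'   indicators and the universe membership used.
#' @export
simulate_callset <- function(truth, exons, set_config, root_seed,
                             del_fraction = 0.7) {
  sc <- as.list(set_config)
  .with_seed(.child_seed(root_seed, sc$name), {
    in_univ <- stats::runif(nrow(exons)) < sc$universe_fraction
    universe <- .exon_union(exons, in_univ)
    events <- truth$events
    detected <- if (nrow(events)) stats::runif(nrow(events)) < sc$sensitivity
                else logical(0)
    frags <- list()
    if (any(detected)) {
      dev <- events[detected, , drop = FALSE]
      for (ch in intersect(unique(dev$chrom), unique(universe$chrom))) {
        ci <- which(dev$chrom == ch)
        ui <- which(universe$chrom == ch)
        ir_e <- .ir(dev$start[ci], dev$end[ci])
        ir_u <- .ir(universe$start[ui], universe$end[ui])
        hits <- IRanges::findOverlaps(ir_e, ir_u)
        if (length(hits)) {
          pi <- IRanges::pintersect(ir_e[S4Vectors::queryHits(hits)],
                                    ir_u[S4Vectors::subjectHits(hits)])
          frags[[ch]] <- data.frame(
            chrom = ch, start = IRanges::start(pi) - 1L, end = IRanges::end(pi),
            svtype = dev$svtype[ci][S4Vectors::queryHits(hits)],
            stringsAsFactors = FALSE)
        }
      }
    }
    calls <- if (length(frags)) do.call(rbind, frags) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 svtype = character(), stringsAsFactors = FALSE)
    j <- as.integer(sc$boundary_jitter_bp)
    if (j > 0L && nrow(calls)) {
      calls$start <- pmax(0L, calls$start + sample.int(2L * j + 1L, nrow(calls),
                                                       replace = TRUE) - j - 1L)
      calls$end <- calls$end + sample.int(2L * j + 1L, nrow(calls),
                                          replace = TRUE) - j - 1L
      calls <- calls[calls$end > calls$start, , drop = FALSE]
    }
    noncnv <- in_univ & !(exons$exon_key %in% truth$cnv_exon_keys)
    fp_idx <- which(noncnv & stats::runif(nrow(exons)) < sc$fpr)
    if (length(fp_idx)) {
      sv <- ifelse(stats::runif(length(fp_idx)) < del_fraction, "DEL", "DUP")
      calls <- rbind(calls,
                     data.frame(chrom = exons$chrom[fp_idx],
                                start = exons$start[fp_idx],
                                end = exons$end[fp_idx],
                                svtype = sv, stringsAsFactors = FALSE))
    }
    calls <- calls[order(calls$chrom, calls$start, calls$end), , drop = FALSE]
    rownames(calls) <- NULL
    cs <- callset(sc$name, calls,
                  universe = if (isTRUE(sc$has_noncnv_evidence)) universe,
                  has_noncnv_evidence = isTRUE(sc$has_noncnv_evidence))
    cs$sim_info <- list(detected = detected, in_universe = in_univ,
                        sensitivity = sc$sensitivity, fpr = sc$fpr)
    cs
  })
}

#' @rdname simulate_callset
#' @param config a [sim_config()]; simulates every set in its `sets` table.
#' @return `simulate_callsets`: named list of call sets.
#' @export
simulate_callsets <- function(truth, exons, config) {
  out <- lapply(seq_len(nrow(config$sets)), function(i) {
    simulate_callset(truth, exons, config$sets[i, , drop = FALSE],
                     config$seed, config$del_fraction)
  })
  names(out) <- config$sets$name
  out
}

#' Simulate an externally validated CNV-exon subset
#'
#' Uniform sample without replacement of `k` ground-truth CNV-exons, the
#' stand-in for a PCR-validated exon list used to calibrate the cutoff.
#'
#' @param truth a [simulate_truth()] result.
#' @param k subset size (default 225).
#' @param seed seed for the draw.
#' @return Character vector of exon keys.
#' @export
simulate_validated_subset <- function(truth, k = 225L, seed = 1L) {
  keys <- sort(truth$cnv_exon_keys)
  if (k > length(keys)) {
    stop(sprintf("requested %d validated exons but the truth has only %d CNV-exons",
                 k, length(keys)), call. = FALSE)
  }
  if (k == 0L) return(character(0))
  .with_seed(seed, sample(keys, k))
}
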