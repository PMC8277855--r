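# End-to-end orchestration: simulate -> fit prior -> build truth set ->
# benchmark / concordance.  Every output is written atomically (temp file in
# the destination directory, then rename) with a provenance header echoing
# the effective parameters, so identical configs give byte-identical runs.

.atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop(sprintf("could not move output into place: %s", path), call. = FALSE)
  }
  ok <- TRUE
  invisible(path)
}

.provenance_header <- function(stage, params) {
  c(sprintf("# cnvtruth %s", stage),
    sprintf("# %s", paste(sprintf("%s=%s", names(params),
                                  vapply(params, format, character(1L))),
                          collapse = " ")))
}

#' Run the full truth-set pipeline on simulated data
#'
#' Simulates an exome, ground truth and call sets from `config`; fits the
#' Beta prior to the simulated population frequency map (unless an explicit
#' `prior` is given); builds the truth set with the cutoff calibrated on a
#' simulated validated subset (unless an explicit `cutoff` is given);
#' benchmarks every call set against the result and writes all artifacts to
#' `out_dir`.  Supplying both `cutoff` and `n_validated > 0` calibration is
#' resolved in favor of the explicit cutoff.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory, created if needed.
#' @param prior optional [beta_prior()]; default: fit from the simulated
#'   frequency map.
#' @param loss a [loss_params()].
#' @param cutoff optional explicit cutoff; default: calibrate.
#' @param n_validated size of the simulated validated subset (default 225).
#' @param target_accuracy calibration target (default 0.95).
#' @param min_fraction exon overlap rule threshold.
#' @param f1_convention see [benchmark_metrics()].
#' @return Invisibly, a list with the in-memory objects (`exons`, `truth`,
#'   `callsets`, `prior`, `truthset`, `benchmark`, `concordance`) and
#'   `paths` of the written files.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         prior = NULL, loss = loss_params(16, 5),
                         cutoff = NULL, n_validated = 225L,
                         target_accuracy = 0.95, min_fraction = 0.5,
                         f1_convention = "standard") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exons <- simulate_exome(config)
  truth <- simulate_truth(exons, config)
  callsets <- simulate_callsets(truth, exons, config)
  validated <- simulate_validated_subset(truth, n_validated,
                                         seed = config$seed + 2L)

  if (is.null(prior)) {
    pp <- exon_prior_probabilities(exons, truth$freq_map)
    prior <- fit_beta_prior(pp$probability)
  }
  evidence <- build_evidence(exons, callsets, min_fraction)
  ts <- if (is.null(cutoff)) {
    cnv_truthset(evidence, prior = prior, loss = loss, validated = validated,
                 target_accuracy = target_accuracy)
  } else {
    cnv_truthset(evidence, prior = prior, loss = loss, cutoff = cutoff)
  }
  bench <- benchmark_callsets(ts, exons, callsets,
                              f1_convention = f1_convention)
  conc <- concordance_matrix(exons, callsets, min_fraction)

  params <- list(seed = config$seed, alpha = prior$alpha, beta = prior$beta,
                 t1 = loss$t1, t2 = loss$t2, cutoff = ts$cutoff,
                 min_overlap = min_fraction, f1 = f1_convention)
  paths <- list()
  paths$exons <- .atomic_write(file.path(out_dir, "exons.bed"), function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(.provenance_header("exon model", params["seed"]), con)
    writeLines(sprintf("%s\t%d\t%d\t%s", exons$chrom, exons$start, exons$end,
                       exons$gene_id), con)
  })
  paths$truth_events <- .atomic_write(
    file.path(out_dir, "truth_events.bed"), function(p) {
      con <- file(p, "w")
      on.exit(close(con))
      writeLines(.provenance_header("ground-truth events", params["seed"]), con)
      writeLines(sprintf("%s\t%d\t%d\t%s", truth$events$chrom,
                         truth$events$start, truth$events$end,
                         truth$events$svtype), con)
    })
  paths$truth_exons <- .atomic_write(
    file.path(out_dir, "truth_cnv_exons.txt"), function(p) {
      writeLines(c(.provenance_header("ground-truth CNV-exons", params["seed"]),
                   sort(truth$cnv_exon_keys)), p)
    })
  paths$freq_map <- .atomic_write(
    file.path(out_dir, "frequency_map.bed"), function(p) {
      con <- file(p, "w")
      on.exit(close(con))
      writeLines(.provenance_header("population frequency map",
                                    params["seed"]), con)
      fm <- truth$freq_map
      writeLines(sprintf("%s\t%d\t%d\t%.15g", fm$chrom, fm$start, fm$end,
                         fm$frequency), con)
    })
  paths$validated <- .atomic_write(
    file.path(out_dir, "validated_exons.txt"), function(p) {
      writeLines(c(.provenance_header("validated CNV-exon subset",
                                      params["seed"]), validated), p)
    })
  paths$manifest <- write_manifest(callsets, out_dir)
  paths$prior <- .atomic_write(file.path(out_dir, "prior.tsv"),
                               function(p) write_prior(prior, p))
  paths$truthset <- .atomic_write(file.path(out_dir, "truthset.tsv"),
                                  function(p) write_truthset(ts, p))
  paths$benchmark <- .atomic_write(
    file.path(out_dir, "benchmark.tsv"), function(p) {
      writeLines(c(.provenance_header("benchmark", params),
                   utils::capture.output(
                     utils::write.table(bench, stdout(), sep = "\t",
                                        quote = FALSE, row.names = FALSE))), p)
    })
  paths$benchmark_json <- .atomic_write(
    file.path(out_dir, "benchmark.json"),
    function(p) write_benchmark_report(bench, p, format = "json"))
  paths$concordance <- .atomic_write(
    file.path(out_dir, "concordance.tsv"), function(p) {
      con <- file(p, "w")
      on.exit(close(con))
      writeLines(.provenance_header("concordance", params["seed"]), con)
      writeLines(utils::capture.output(print(conc)), con)
    })

  message(sprintf("pipeline: %d exons, %d sets, %d truth CNV-exons, %d truth-set CNV-exons, cutoff %.4g",
                  nrow(exons), length(callsets), length(truth$cnv_exon_keys),
                  sum(ts$estimates$label == "CNV"), ts$cutoff))
  invisible(list(exons = exons, truth = truth, callsets = callsets,
                 validated = validated, prior = prior, truthset = ts,
                 benchmark = bench, concordance = conc, paths = paths))
}
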