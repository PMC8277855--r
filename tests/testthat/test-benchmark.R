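mk_toy_truthset <- function() {
  # 12 exons, alternating labels, via evidence chosen to land on each side
  ev <- data.frame(chrom = "chr1", start = seq(0, by = 100, length.out = 12),
                   end = seq(50, by = 100, length.out = 12), gene_id = "g",
                   n = rep(10L, 12), x = rep(c(10L, 0L), 6),
                   stringsAsFactors = FALSE)
  ev$exon_key <- exon_key(ev)
  cnv_truthset(ev, cutoff = 0.45)
}

test_that("evaluation_domain restricts to design-overlapping exons", {
  ts <- mk_toy_truthset()
  all_design <- mk_intervals("chr1", 0, 10000)
  expect_setequal(evaluation_domain(ts, all_design), ts$estimates$exon_key)
  expect_error(evaluation_domain(ts, mk_intervals("chr2", 0, 10000)),
               "undefined")
  # random toy design equals a per-exon brute-force overlap check
  set.seed(8)
  des <- mk_intervals("chr1", s <- sample.int(1200L, 6L), s + 80L)
  dom <- evaluation_domain(ts, des)
  est <- ts$estimates
  want <- est$exon_key[vapply(seq_len(nrow(est)), function(i)
    any(oracle_base_set(des, est$chrom[i], est$start[i], est$end[i])),
    logical(1L))]
  expect_setequal(dom, want)
  # fraction rule is at least as strict
  dom50 <- evaluation_domain(ts, des, rule = "fraction")
  expect_true(all(dom50 %in% dom))
})

test_that("confusion counts partition the domain", {
  ts <- mk_toy_truthset()
  keys <- ts$estimates$exon_key
  truth_cnv <- keys[ts$estimates$label == "CNV"]

  cc <- confusion_counts(ts, truth_cnv)           # perfect predictions
  expect_equal(c(cc$fp, cc$fn), c(0L, 0L))
  expect_equal(cc$tp, length(truth_cnv))

  cc0 <- confusion_counts(ts, character(0))       # no predictions
  expect_equal(c(cc0$tp, cc0$fp), c(0L, 0L))
  expect_equal(cc0$fn, length(truth_cnv))

  # hand-enumerated toy: predict exons 1-4 (truth: 1,3 CNV; 2,4 non-CNV)
  cc2 <- confusion_counts(ts, keys[1:4])
  expect_equal(cc2$tp, 2L)
  expect_equal(cc2$fp, 2L)
  expect_equal(cc2$fn, 4L)
  expect_equal(cc2$tn, 4L)
  expect_equal(cc2$tp + cc2$fp + cc2$fn + cc2$tn, length(keys))

  # duplicated predictions and out-of-domain predictions are ignored
  dom <- keys[1:6]
  cc3 <- confusion_counts(ts, c(keys[1], keys[1], keys[8], "junk"), dom)
  expect_equal(cc3$tp, 1L)
  expect_equal(cc3$fp, 0L)
  expect_equal(cc3$tp + cc3$fp + cc3$fn + cc3$tn, length(dom))
})

test_that("metrics arithmetic matches the definitions in both F1 conventions", {
  cc <- structure(list(tp = 3L, fp = 1L, fn = 2L, tn = 10L),
                  class = "confusion_counts")
  m <- benchmark_metrics(cc)
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 2 / 3)
  expect_equal(benchmark_metrics(cc, "paper")$f1, 1 / 3)

  perfect <- structure(list(tp = 5L, fp = 0L, fn = 0L, tn = 5L),
                       class = "confusion_counts")
  mp <- benchmark_metrics(perfect)
  expect_equal(c(mp$recall, mp$precision, mp$f1), c(1, 1, 1))
  # the alternative convention caps at 0.5 for a perfect classifier
  expect_equal(benchmark_metrics(perfect, "paper")$f1, 0.5)

  allwrong <- structure(list(tp = 0L, fp = 4L, fn = 3L, tn = 2L),
                        class = "confusion_counts")
  ma <- benchmark_metrics(allwrong)
  expect_equal(c(ma$recall, ma$precision, ma$f1), c(0, 0, 0))

  # zero denominators are undefined, not zero
  nopred <- structure(list(tp = 0L, fp = 0L, fn = 3L, tn = 2L),
                      class = "confusion_counts")
  expect_true(is.na(benchmark_metrics(nopred)$precision))
  expect_equal(benchmark_metrics(nopred)$recall, 0)
  nocnv <- structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 2L),
                     class = "confusion_counts")
  expect_true(all(is.na(unlist(benchmark_metrics(nocnv)[1:3]))))
})

test_that("pairwise concordance counts shared and same-state exons", {
  lv <- c("CNV", "NON_CNV", "UNOBSERVED")
  a <- factor(c("CNV", "CNV", "NON_CNV", "UNOBSERVED", "NON_CNV"), levels = lv)
  b <- factor(c("CNV", "NON_CNV", "NON_CNV", "CNV", "UNOBSERVED"), levels = lv)
  pc <- pairwise_concordance(a, b)
  expect_equal(pc$shared, 3L)
  expect_equal(pc$same_state, 2L)
  expect_equal(pairwise_concordance(a, a)$same_state,
               sum(a != "UNOBSERVED"))
  disj <- factor(c(rep("UNOBSERVED", 4), "CNV"), levels = lv)
  expect_equal(pairwise_concordance(a, disj)$shared, 1L)
})

test_that("concordance matrix is symmetric with described counts on the diagonal", {
  sim <- shared_sim()
  cs <- sim$callsets[c(2, 5, 7)]
  cm <- concordance_matrix(sim$exons, cs)
  expect_equal(cm$shared, t(cm$shared))
  expect_equal(cm$same_state, t(cm$same_state))
  for (i in 1:3) {
    expect_equal(cm$shared[i, i], unname(cm$described[i]))
    expect_equal(cm$same_state[i, i], unname(cm$described[i]))
  }
  # spot-check one off-diagonal pair against an exhaustive recount
  st_a <- classify_exons(sim$exons, cs[[1]])
  st_b <- classify_exons(sim$exons, cs[[2]])
  both <- st_a != "UNOBSERVED" & st_b != "UNOBSERVED"
  expect_equal(cm$shared[1, 2], sum(both))
  expect_equal(cm$same_state[1, 2], sum(both & st_a == st_b))
})

test_that("confirmation tiers bin exons by supporting-tool counts", {
  preds <- list(t1 = c("a", "b"), t2 = c("b", "c"), t3 = c("b"),
                t4 = c("b", "d"), t5 = c("b"), t6 = c("b"), t7 = c("b"))
  tiers <- confirmation_tiers(preds)
  # exon 'b' is predicted by all 7 tools -> tier >6 for each
  expect_equal(unname(tiers["t3", "tier_gt6"]), 1)
  # 'a' is a singleton for t1
  expect_equal(unname(tiers["t1", c("tier_1_2", "singleton")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(tiers[, 1:3])), rep(1, 7))

  # brute-force check on a random 5-tool matrix
  set.seed(9)
  keys <- sprintf("e%02d", 1:30)
  preds2 <- lapply(1:5, function(i) sample(keys, sample(5:15, 1)))
  names(preds2) <- sprintf("tool%d", 1:5)
  tiers2 <- confirmation_tiers(preds2)
  for (tool in names(preds2)) {
    k <- vapply(preds2[[tool]], function(e)
      sum(vapply(preds2, function(p) e %in% p, logical(1L))), numeric(1L))
    expect_equal(unname(tiers2[tool, "tier_1_2"]), mean(k <= 2))
    expect_equal(unname(tiers2[tool, "tier_3_6"]), mean(k >= 3 & k <= 6))
    expect_equal(unname(tiers2[tool, "singleton"]), mean(k == 1))
  }
  expect_error(confirmation_tiers(preds[1]), "at least 2")
})

test_that("summarize_callset reports counts, targets and kb lengths", {
  design <- mk_intervals("chr1", c(0, 2000, 4000, 6000), c(1000, 3000, 5000, 7000))
  cs <- callset("t", mk_intervals("chr1", 500, 5500, "DEL"))
  s <- summarize_callset(cs, design)
  expect_equal(s$n_cnv, 1L)
  expect_equal(s$n_del, 1L)
  expect_equal(s$n_dup, 0L)
  expect_equal(s$targets, 3L)
  expect_equal(s$mean_targets, 3)
  expect_equal(s$total_length_kb, 5)

  # a region shared by two calls counts once for targets, per call for the mean
  cs2 <- callset("u", mk_intervals("chr1", c(100, 600), c(500, 900),
                                   c("DEL", "DUP")))
  s2 <- summarize_callset(cs2, design)
  expect_equal(s2$targets, 1L)
  expect_equal(s2$mean_targets, 1)
  expect_equal(s2$n_del + s2$n_dup, s2$n_cnv)

  empty <- summarize_callset(callset("e", mk_intervals(character(0),
                                                       integer(0), integer(0))),
                             design)
  expect_equal(empty$n_cnv, 0L)
  expect_equal(empty$targets, 0L)

  # brute-force overlap counting on a random toy
  set.seed(10)
  calls <- mk_intervals("chr1", st <- sample.int(6500L, 10L),
                        st + sample.int(900L, 10L, replace = TRUE),
                        sample(c("DEL", "DUP", "CNV"), 10L, replace = TRUE))
  s3 <- summarize_callset(callset("r", calls), design)
  per_call <- vapply(seq_len(nrow(calls)), function(i)
    sum(vapply(seq_len(nrow(design)), function(j)
      calls$start[i] < design$end[j] && design$start[j] < calls$end[i],
      logical(1L))), numeric(1L))
  expect_equal(s3$mean_targets, mean(per_call))
  hit <- vapply(seq_len(nrow(design)), function(j)
    any(calls$start < design$end[j] & design$start[j] < calls$end),
    logical(1L))
  expect_equal(s3$targets, sum(hit))
  expect_true(s3$n_del + s3$n_dup <= s3$n_cnv)
})

test_that("benchmark metrics are invariant to prediction duplication and order", {
  ts <- mk_toy_truthset()
  keys <- ts$estimates$exon_key
  pred <- keys[c(1, 3, 2)]
  b1 <- confusion_counts(ts, pred)
  b2 <- confusion_counts(ts, rev(c(pred, pred)))
  expect_equal(unclass(b1), unclass(b2))
})

test_that("simulated caller recall and precision land near their nominal rates", {
  cfg <- sim_config(seed = 77, n_genes = 500, exons_per_gene = 8,
                    sets = data.frame(name = "probe", sensitivity = 0.5,
                                      fpr = 5e-3, universe_fraction = 1,
                                      has_noncnv_evidence = FALSE,
                                      boundary_jitter_bp = 0L,
                                      stringsAsFactors = FALSE))
  exons <- simulate_exome(cfg)
  truth <- simulate_truth(exons, cfg)
  cs <- simulate_callsets(truth, exons, cfg)[[1]]
  # truth set built from a perfect oracle set so labels equal the ground truth
  oracle <- callset("oracle", truth$events,
                    universe = mk_intervals(exons$chrom, exons$start, exons$end),
                    has_noncnv_evidence = TRUE)
  ev <- build_evidence(exons, list(oracle))
  # any cutoff separating d(n=1,x=1) from d(n=1,x=0) recovers the truth
  mid <- mean(bayes_estimate(beta_prior(0.33, 0.93), c(1, 1), c(1, 0)))
  ts <- cnv_truthset(ev, cutoff = mid)
  expect_setequal(ts$estimates$exon_key[ts$estimates$label == "CNV"],
                  truth$cnv_exon_keys)

  bench <- benchmark_callsets(ts, exons, list(cs))
  s <- 0.5
  n_ev <- nrow(truth$events)
  # detection is Bernoulli per event; exon weighting inflates the SE a little
  se <- sqrt(s * (1 - s) / (0.8 * n_ev))
  expect_lt(abs(bench$recall - s), 3 * se)
  # precision -> s*pi / (s*pi + f*(1-pi)) with 3-sigma count fluctuations
  pi_hat <- length(truth$cnv_exon_keys) / nrow(exons)
  f <- 5e-3
  n_non <- nrow(exons) - length(truth$cnv_exon_keys)
  fp_mid <- f * n_non
  fp_sd <- sqrt(f * (1 - f) * n_non)
  tp_mid <- s * pi_hat * nrow(exons)
  prec_lo <- (tp_mid - 3 * se * tp_mid / s) /
    (tp_mid - 3 * se * tp_mid / s + fp_mid + 3 * fp_sd)
  prec_hi <- (tp_mid + 3 * se * tp_mid / s) /
    (tp_mid + 3 * se * tp_mid / s + max(fp_mid - 3 * fp_sd, 0))
  expect_gt(bench$precision, prec_lo)
  expect_lt(bench$precision, prec_hi)
})
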