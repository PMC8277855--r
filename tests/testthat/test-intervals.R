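test_that("reduce_exons merges overlapping and book-ended records per gene", {
  rec <- mk_intervals("chr1", c(100, 150), c(200, 250))
  rec$gene_id <- "G"
  out <- reduce_exons(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 250L)

  # book-ended records merge ([100,200) + [200,300))
  rec2 <- mk_intervals("chr1", c(100, 200), c(200, 300))
  rec2$gene_id <- "G"
  expect_equal(reduce_exons(rec2)$end, 300L)

  # disjoint inputs are fixed points
  rec3 <- mk_intervals("chr1", c(100, 300), c(200, 400))
  rec3$gene_id <- "G"
  out3 <- reduce_exons(rec3)
  expect_equal(out3$start, c(100L, 300L))
  expect_equal(out3$end, c(200L, 400L))

  # same interval under two genes stays duplicated unless dedup requested
  rec4 <- rbind(cbind(mk_intervals("chr1", 10, 50), gene_id = "A"),
                cbind(mk_intervals("chr1", 10, 50), gene_id = "B"))
  expect_equal(nrow(reduce_exons(rec4)), 2L)
  expect_equal(nrow(reduce_exons(rec4, dedup_intervals = TRUE)), 1L)
})

test_that("reduce_exons rejects malformed records with their identity", {
  rec <- mk_intervals("chr1", c(100, 500), c(200, 400))
  rec$gene_id <- "G"
  expect_error(reduce_exons(rec), "row")
  expect_error(reduce_exons(mk_intervals("chr1", 1, 5)), "gene_id")
})

test_that("reduce_exons matches a per-base union oracle on random records", {
  set.seed(31)
  n <- 1000L
  genes <- sprintf("g%02d", sample.int(50L, n, replace = TRUE))
  start <- sample.int(5000L, n, replace = TRUE)
  len <- sample.int(300L, n, replace = TRUE)
  rec <- data.frame(chrom = "chr7", start = start, end = start + len,
                    gene_id = genes, stringsAsFactors = FALSE)
  out <- reduce_exons(rec)
  for (g in unique(genes)) {
    got <- oracle_base_set(out[out$gene_id == g, ], "chr7", 0L, 6000L)
    want <- oracle_base_set(rec[rec$gene_id == g, ], "chr7", 0L, 6000L)
    expect_identical(got, want)
  }
  # per gene the reduced intervals are pairwise disjoint
  for (g in unique(genes)) {
    sub <- out[out$gene_id == g, ]
    if (nrow(sub) > 1L) expect_true(all(sub$start[-1L] > sub$end[-nrow(sub)]))
  }
  # idempotence
  again <- reduce_exons(out[c("chrom", "start", "end", "gene_id")])
  expect_identical(again, out)
})

test_that("coverage_fraction follows its definition and a per-base oracle", {
  ex <- mk_exons("chr1", 100, 200, "G")
  expect_equal(coverage_fraction(ex, mk_intervals("chr1", 100, 200)), 1.0)
  expect_equal(coverage_fraction(ex, mk_intervals("chr1", 150, 250)), 0.5)
  expect_equal(coverage_fraction(ex, mk_intervals("chr1", c(100, 140), c(130, 180))), 0.7)
  expect_equal(coverage_fraction(ex, NULL), 0)
  # other chromosomes are ignored
  expect_equal(coverage_fraction(ex, mk_intervals("chr2", 100, 200)), 0)

  set.seed(77)
  for (rep in 1:25) {
    k <- sample.int(6L, 1L)
    iv <- mk_intervals("chr1", s <- sample.int(400L, k, replace = TRUE) + 0L,
                       s + sample.int(150L, k, replace = TRUE))
    expect_equal(coverage_fraction(ex, iv), oracle_coverage_fraction(ex, iv))
  }
})

test_that("coverage is monotone under added intervals and split-invariant", {
  ex <- mk_exons("chr3", 1000, 1450, "G")
  set.seed(5)
  iv <- mk_intervals("chr3", s <- sample.int(1500L, 8L), s + 120L)
  base <- coverage_fraction(ex, iv)
  more <- coverage_fraction(ex, rbind(iv, mk_intervals("chr3", 1100, 1200)))
  expect_gte(more, base)
  # splitting one interval into adjacent pieces changes nothing
  split_iv <- rbind(iv[-1L, ],
                    mk_intervals("chr3", c(iv$start[1L], iv$start[1L] + 40L),
                                 c(iv$start[1L] + 40L, iv$end[1L])))
  expect_equal(coverage_fraction(ex, split_iv), base)
})

test_that("classify_exons applies the >= 50% rule with universe fallback", {
  ex <- mk_exons("chr1", c(100, 300, 500), c(200, 400, 600), c("A", "B", "C"))
  cs <- callset("s", mk_intervals("chr1", c(100, 500), c(200, 550), c("DEL", "DUP")),
                universe = mk_intervals("chr1", 0, 450),
                has_noncnv_evidence = TRUE)
  st <- classify_exons(ex, cs)
  expect_equal(as.character(st), c("CNV", "NON_CNV", "CNV"))
  # exactly 50% counts as CNV (boundary inclusive); exon C: [500,550) of [500,600)
  expect_equal(coverage_fraction(ex[3L, ], cs$calls), 0.5)
  # without non-CNV evidence the middle exon is unobserved
  cs2 <- callset("s2", cs$calls)
  expect_equal(as.character(classify_exons(ex, cs2)),
               c("CNV", "UNOBSERVED", "CNV"))
  # raising min_fraction never converts non-CNV/unobserved into CNV
  prev <- classify_exons(ex, cs, min_fraction = 0.2)
  for (f in c(0.5, 0.7, 0.9, 1)) {
    cur <- classify_exons(ex, cs, min_fraction = f)
    expect_true(all(which(cur == "CNV") %in% which(prev == "CNV")))
    prev <- cur
  }
})

test_that("build_evidence counts describing and CNV-calling sets", {
  ex <- mk_exons("chr1", 100, 200, "A")
  full <- mk_intervals("chr1", 100, 200)
  cs_cnv <- function(nm) callset(nm, full)
  ev <- build_evidence(ex, list(cs_cnv("a"), cs_cnv("b"), cs_cnv("c")))
  expect_equal(ev$n, 3L)
  expect_equal(ev$x, 3L)

  # a non-CNV-evidence set whose universe excludes the exon contributes nothing
  cs_far <- callset("far", mk_intervals("chr1", 9000, 9100),
                    universe = mk_intervals("chr1", 5000, 6000),
                    has_noncnv_evidence = TRUE)
  ev2 <- build_evidence(ex, list(cs_cnv("a"), cs_far))
  expect_equal(ev2$n, 1L)
  expect_equal(ev2$x, 1L)

  expect_error(build_evidence(ex, list(cs_cnv("a"), cs_cnv("a"))), "duplicate")
  expect_error(build_evidence(ex, list()), "at least one")
})

test_that("build_evidence equals exhaustive per-pair enumeration on a random toy", {
  set.seed(12)
  ex <- mk_exons("chr2", s <- seq(0, by = 500, length.out = 20L), s + 200L,
                 rep(c("g1", "g2"), each = 10L))
  sets <- lapply(1:6, function(i) {
    k <- sample.int(8L, 1L)
    cst <- sample.int(9500L, k)
    uni <- if (i <= 2) mk_intervals("chr2", c(0), c(sample(3000:9000, 1)))
    callset(sprintf("s%d", i),
            mk_intervals("chr2", cst, cst + sample.int(700L, k, replace = TRUE)),
            universe = uni, has_noncnv_evidence = i <= 2)
  })
  ev <- build_evidence(ex, sets)
  for (i in seq_len(nrow(ex))) {
    n_o <- 0L
    x_o <- 0L
    for (cs in sets) {
      cov <- oracle_coverage_fraction(ex[i, ], cs$calls)
      if (cov >= 0.5) {
        n_o <- n_o + 1L
        x_o <- x_o + 1L
      } else if (cs$has_noncnv_evidence &&
                 oracle_coverage_fraction(ex[i, ], cs$universe) >= 0.5) {
        n_o <- n_o + 1L
      }
    }
    expect_equal(ev$n[i], n_o)
    expect_equal(ev$x[i], x_o)
  }
  # count conservation: total x equals the sum of per-set CNV-exon counts
  per_set <- vapply(sets, function(cs)
    sum(classify_exons(ex, cs) == "CNV"), numeric(1L))
  expect_equal(sum(ev$x), sum(per_set))
})

test_that("filter_autosomes handles both naming dialects", {
  df <- data.frame(chrom = c("chr1", "chrX", "chr22"), v = 1:3)
  expect_message(out <- filter_autosomes(df), "dropped 1")
  expect_equal(out$chrom, c("chr1", "chr22"))

  df2 <- data.frame(chrom = c("1", "X", "MT", "21"), v = 1:4)
  expect_message(out2 <- filter_autosomes(df2), "dropped 2")
  expect_equal(out2$chrom, c("1", "21"))

  empty <- data.frame(chrom = character(), v = numeric())
  expect_equal(nrow(filter_autosomes(empty)), 0L)
})
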