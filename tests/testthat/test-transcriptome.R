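toy_table <- function() {
  tps <- c(10, 20, 30)
  genes <- paste0("g", 1:4)
  fc <- matrix(0, 4, 6, dimnames = list(
    genes, c(paste0("WT.", tps), paste0("mut.", tps))))
  fdr <- matrix(c(0.01, 0.5, 0.5,    # g1: 1 significant timepoint
                  0.01, 0.02, 0.5,   # g2: 2
                  0.01, 0.01, 0.01,  # g3: 3
                  0.5, 0.5, 0.5),    # g4: 0
                nrow = 4, byrow = TRUE, dimnames = list(genes, tps))
  expression_table(fc, list(mut = fdr), strains = c("WT", "mut"),
                   timepoints = tps)
}

test_that("responsive genes need significance at two or more timepoints", {
  tab <- toy_table()
  expect_identical(select_responsive(tab, "mut"), c("g2", "g3"))
  expect_identical(select_responsive(tab, "mut", min_timepoints = 1),
                   c("g1", "g2", "g3"))
  # tightening alpha never grows the list
  loose <- select_responsive(tab, "mut", alpha = 0.05)
  tight <- select_responsive(tab, "mut", alpha = 0.015)
  expect_true(all(tight %in% loose))
  expect_error(select_responsive(tab, "nope"), "contrast")
})

test_that("defect calls compare mutant magnitude in the wild-type direction", {
  expect_equal(call_defect(c(2, 2, 2), c(1, 1, 1)), "induction_defect")
  expect_equal(call_defect(c(-2, -2, -1), c(-0.5, -0.5, -0.2)),
               "repression_defect")
  expect_equal(call_defect(c(2, -2, 0), c(1, 1, 1)), "none")
  expect_equal(call_defect(c(0, 0, 0), c(1, 1, 1)), "none")
  # equal magnitudes are not a defect
  expect_equal(call_defect(c(2, 2, 2), c(2, 2, 2)), "none")
  # overshoot is not a defect
  expect_equal(call_defect(c(2, 2, 2), c(3, 3, 3)), "none")
  expect_error(call_defect(c(1, 2), c(1, 2)), "3 timepoints")
})

test_that("k-means partition recovers planted archetypes deterministically", {
  set.seed(31)
  centers <- matrix(c(3, 3, 0, 0, -3, -3, 0, 3, 0, -3, 3, 0), 4, 3,
                    byrow = TRUE)
  feats <- centers[rep(1:4, each = 30), ] + matrix(rnorm(360, 0, 0.3), 120, 3)
  rownames(feats) <- paste0("g", 1:120)
  part <- kmeans_partition(feats, k = 4, seed = 5)
  ari <- adjusted_rand_index(part$cluster, rep(1:4, each = 30))
  expect_gte(ari, 0.9)
  # deterministic for a fixed seed
  part2 <- kmeans_partition(feats, k = 4, seed = 5)
  expect_identical(part$cluster, part2$cluster)
  # identical genes co-cluster; k = 1 puts everything together
  feats[2, ] <- feats[1, ]
  p <- kmeans_partition(feats, k = 4, seed = 5)
  expect_equal(unname(p$cluster[1]), unname(p$cluster[2]))
  expect_true(all(kmeans_partition(feats, k = 1, seed = 1)$cluster == 1))
  expect_error(kmeans_partition(matrix(1, 3, 2), k = 2, seed = 1),
               "distinct")
})

test_that("motif scan counts non-overlapping hits on both strands", {
  expect_equal(scan_motif("AACCCCTAA", "CCCCT")$count, 1L)
  expect_equal(scan_motif("CCCCCT", "CCCCT")$count, 1L)
  # GATGAG on the reverse strand of CTCATC
  hit <- scan_motif("CTCATC", "GATGAG")
  expect_equal(hit$count, 1L)
  expect_equal(hit$hits$strand, "-")
  # overlapping tandem: CCCCTCCCCT has two disjoint hits
  expect_equal(scan_motif("CCCCTCCCCT", "CCCCT")$count, 2L)
  expect_equal(scan_motif("ACGTACGT", "CCCCT")$count, 0L)
  expect_error(scan_motif("ACGX", "CCCCT"), "A/C/G/T/N")
  expect_error(scan_motif("ACG", "CCCCT"), "longer")
})

test_that("greedy scan equals the brute-force maximum on random promoters", {
  set.seed(17)
  for (i in 1:200) {
    seqc <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                  collapse = "")
    motif <- sample(c("CCCCT", "GATGAG", "AGGGG"), 1)
    expect_equal(scan_motif(seqc, motif)$count,
                 brute_motif_count(seqc, motif))
  }
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  universe <- paste0("g", 1:20)
  cluster <- universe[1:5]
  sets <- list(hit = universe[1:10])
  res <- enrich(cluster, sets, universe)
  expect_equal(res$p, 252 / 15504, tolerance = 1e-12)
  expect_equal(res$fdr, res$p)  # BH of a single test is the test itself

  # random configurations against the factorial oracle
  set.seed(23)
  for (i in 1:20) {
    N <- sample(30:200, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(5:(N - 5), 1)
    n <- sample(5:(N - 5), 1)
    cl <- sample(uni, n)
    st <- list(s = sample(uni, K))
    r <- enrich(cl, st, uni)
    expect_equal(r$p, exact_hyper_upper(r$overlap, K, n, N),
                 tolerance = 1e-10)
  }

  # overlap at the independence expectation is unremarkable
  res2 <- enrich(universe[1:10], list(s = universe[c(1:5, 11:15)]), universe)
  expect_equal(res2$overlap, 5)
  expect_gte(res2$p, 0.5)

  # under-enrichment tail: a cluster devoid of set members
  res3 <- enrich(universe[11:20], list(s = universe[1:10]), universe,
                 tail = "lower")
  expect_lt(res3$p, 0.01)
  expect_error(enrich(c("zz"), list(s = universe[1:3]), universe),
               "universe")
})

test_that("BH adjustment is monotone in raw p order and capped at 1", {
  set.seed(29)
  universe <- paste0("g", 1:100)
  cluster <- sample(universe, 20)
  sets <- lapply(1:15, function(i) sample(universe, sample(5:40, 1)))
  names(sets) <- paste0("s", 1:15)
  res <- enrich(cluster, sets, universe)
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
  expect_true(all(res$fdr <= 1))
  expect_true(all(res$fdr >= res$p))
})

test_that("regulator count distributions flag regulator-rich clusters", {
  set.seed(37)
  genes <- paste0("g", 1:300)
  # background genes sit in few sets; the planted cluster in ~4x more
  tfs <- lapply(1:40, function(i) {
    base <- sample(genes[101:300], 20)
    rich <- sample(genes[1:50], 20)
    c(base, rich)
  })
  names(tfs) <- paste0("tf", 1:40)
  rcs <- regulator_count_stats(
    clusters = list(rich = genes[1:50], plain = genes[101:150]),
    tf_targets = tfs, background = genes[101:300])
  expect_lt(rcs$tests$fdr[rcs$tests$cluster == "rich"], 0.05)
  expect_gt(rcs$tests$p[rcs$tests$cluster == "plain"], 0.05)
  # a gene in no set scores log2(0 + 1) = 0
  rcs2 <- regulator_count_stats(list(a = c("lonely", "g1")),
                                tf_targets = tfs,
                                background = c("lonely", genes))
  expect_equal(unname(rcs2$counts["lonely"]), 0)
  expect_warning(
    regulator_count_stats(list(a = genes[1:5], b = character(0)),
                          tf_targets = tfs, background = genes),
    "empty")
})
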