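make_trace <- function(id, nf, ms = NULL, irfp = NULL, strain = NA) {
  ms <- ms %||% rep(500, length(nf))
  chans_nf <- list(GFP = nf)
  chans_ms <- list(GFP = ms)
  if (!is.null(irfp)) {
    chans_nf$iRFP <- rep(1, length(nf))
    chans_ms$iRFP <- irfp
  }
  cell_trace(id, chans_nf, chans_ms, strain_label = strain)
}

test_that("nuclear/cytoplasmic ratio matches its pixel definition", {
  expect_equal(nc_ratio(rep(3.5, 50)), 1)
  # 100 pixels: 95 at 1.0, 5 at 3.0 -> top-5 mean 3.0 over median 1.0
  px <- c(rep(1, 95), rep(3, 5))
  expect_equal(nc_ratio(px), 3)
  expect_equal(nc_ratio(px * 17), 3)  # scale invariance
  # moving mass into the top 5% raises the ratio
  brighter <- c(rep(1, 95), rep(4, 5))
  expect_gt(nc_ratio(brighter), nc_ratio(px))
  expect_error(nc_ratio(c(rep(0, 60), 1, 2)), "median")
  expect_error(nc_ratio(rep(1, 10)), "20")
})

test_that("peak height is the post-stress max minus the pre-stress min", {
  expect_equal(peak_height(make_trace("c1", rep(1, 40)), "GFP"), 0)
  nf <- rep(1, 40)
  nf[14:16] <- c(1.8, 1.6, 1.3)
  expect_equal(peak_height(make_trace("c2", nf), "GFP"), 0.8)
  # a trace whose post window max equals the pre window min scores 0
  declining <- seq(2, 1, length.out = 40)
  tr <- make_trace("c3", declining)
  expect_equal(peak_height(tr, "GFP"),
               max(declining[13:20]) - min(declining[11:13]))
  expect_lte(peak_height(tr, "GFP"), 0)
  short <- make_trace("c4", rep(1, 15))
  expect_error(peak_height(short, "GFP"), "T16")
})

test_that("abundance averages the median signal over index windows", {
  ms <- rep(640, 40)
  tr <- make_trace("c1", rep(1, 40), ms = ms)
  expect_equal(abundance(tr, "GFP", "pre"), 640)
  expect_equal(abundance(tr, "GFP", "post"), 640)
  halved <- make_trace("c2", rep(1, 40), ms = c(rep(640, 12), rep(320, 28)))
  expect_equal(abundance(halved, "GFP", "pre"), 640)
  expect_equal(abundance(halved, "GFP", "post"), 320)
  expect_error(abundance(tr, "GFP", c(30, 20)), "window")
  expect_error(abundance(make_trace("c3", rep(1, 15)), "GFP", "post"), "T")
})

test_that("noiseless generator pulses are recovered exactly", {
  sim <- gen_cell_traces(n_per_strain = 5, seed = 9, peak_wt = 1.2,
                         delta = 0.5, noise_sd = 0)
  m <- trace_metrics(sim$traces, nf_channel = "GFP")
  expect_equal(m$peak_height[m$strain_label == "WT"], rep(1.2, 5))
  expect_equal(m$peak_height[m$strain_label == "mutant"], rep(0.7, 5))
})

test_that("iRFP demultiplexing recovers strain identity", {
  sim <- gen_cell_traces(n_per_strain = 100, seed = 11, irfp_fold = 3)
  dm <- demux_by_irfp(sim$traces, seed = 11)
  truth <- ifelse(sim$truth$labels == "WT", "marked", "unmarked")
  expect_identical(dm$labels, truth)
  expect_gt(dm$silhouette, 0.5)

  # label assignment invariant to cell order
  perm <- sample(seq_along(sim$traces))
  dm2 <- demux_by_irfp(sim$traces[perm], seed = 11)
  expect_identical(dm2$labels, truth[perm])

  flat <- lapply(1:12, function(i)
    make_trace(paste0("c", i), rep(1, 40), irfp = rep(100, 40)))
  expect_error(demux_by_irfp(flat), "demultiplex")
})

test_that("population centering fixes every column median at 1", {
  set.seed(5)
  mat <- matrix(rlnorm(210, 0, 0.3), 21, 10)
  cen <- center_population(mat)
  # back on the ratio scale each timepoint's median is exactly 1
  expect_equal(apply(2^cen, 2, stats::median), rep(1, 10),
               tolerance = 1e-12)
  # columns with a single repeated value center to all zeros
  ones <- matrix(2, 5, 4)
  expect_true(all(center_population(ones) == 0))
  sub <- center_population(mat, mode = "subtract")
  expect_equal(apply(sub, 2, stats::median), rep(0, 10),
               tolerance = 1e-12)
  bad <- rbind(c(0, 1), c(0, 2))
  expect_error(center_population(bad), "median")
})

test_that("hierarchical clustering separates dynamic archetypes", {
  set.seed(21)
  frames <- 40
  strong <- t(vapply(1:50, function(i) {
    nf <- rep(1, frames); nf[13:20] <- 1 + 0.9 * stats::runif(8, 0.8, 1)
    nf + stats::rnorm(frames, 0, 0.02)
  }, numeric(frames)))
  weak <- t(vapply(1:50, function(i) {
    nf <- rep(1, frames); nf[13:20] <- 1 + 0.15 * stats::runif(8, 0.8, 1)
    nf + stats::rnorm(frames, 0, 0.02)
  }, numeric(frames)))
  cen <- center_population(rbind(strong, weak))
  cp <- cluster_cells(cen)
  groups <- cut_population(cp, 2)
  truth <- rep(1:2, each = 50)
  purity <- max(mean(groups == truth), mean(groups == 3 - truth))
  expect_gte(purity, 0.95)

  # a duplicated cell joins its twin at distance zero
  dup <- rbind(cen, cen[1, ])
  cpd <- cluster_cells(dup)
  merge_heights <- cpd$tree$height
  expect_equal(min(merge_heights), 0, tolerance = 1e-12)

  # deterministic leaf order for a fixed input order
  expect_identical(cluster_cells(cen)$order, cp$order)

  # all-zero rows cannot be placed in correlation space: flagged, last
  with_zero <- rbind(cen, 0)
  cpz <- cluster_cells(with_zero)
  expect_equal(cpz$flagged, nrow(with_zero))
  expect_equal(cpz$order[length(cpz$order)], nrow(with_zero))
})

test_that("abundance matching certifies subsets and preserves phenotype", {
  sim <- gen_cell_traces(n_per_strain = 50, seed = 13, delta = 0.3)
  m <- trace_metrics(sim$traces, nf_channel = "GFP")
  a <- m[m$strain_label == "WT", ]
  b <- m[m$strain_label == "mutant", ]
  mt <- match_abundance(a, b, range = c(600, 700))
  expect_true(mt$matched)  # equal abundance distributions by design
  expect_gt(mt$p_abundance, 0.05)
  # peak-height difference survives matching
  p_peak <- stats::wilcox.test(mt$a$peak_height, mt$b$peak_height)$p.value
  expect_lt(p_peak, 0.01)

  # identical groups: everything retained, no difference
  same <- match_abundance(a, a, range = range(a$abundance_pre))
  expect_equal(nrow(same$a), nrow(a))
  expect_gt(same$p_abundance, 0.99)
  shifted <- b
  shifted$abundance_pre <- shifted$abundance_pre + 1e4
  expect_error(match_abundance(a, shifted, range = c(600, 700)), "empty")
})
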