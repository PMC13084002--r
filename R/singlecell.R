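#' Nuclear/cytoplasmic ratio from a pixel patch
#'
#' Localization statistic for a transcription factor in one segmented cell at
#' one frame: the mean of the brightest 5% of pixels (the nuclear-enriched
#' tail) divided by the median of all pixels (the cytoplasmic background).
#' The top-5% pixel count is `ceiling(0.05 n)`, minimum one pixel. Invariant
#' under multiplicative intensity scaling.
#'
#' @param pixels Nonnegative pixel intensities of one segmented cell
#'   (>= 20 pixels).
#' @return The nuclear/cytoplasmic ratio, a single number.
#' @export
nc_ratio <- function(pixels) {
  stopifnot(is.numeric(pixels), length(pixels) >= 20)
  if (any(pixels < 0)) stop("pixel intensities must be nonnegative")
  med <- stats::median(pixels)
  if (med == 0) stop("undefined ratio: median pixel intensity is 0")
  k <- max(1L, ceiling(0.05 * length(pixels)))
  top <- sort(pixels, decreasing = TRUE)[seq_len(k)]
  mean(top) / med
}

#' Construct a single-cell fluorescence trace
#'
#' Per-frame summaries for one cell across the time-lapse: the nuclear
#' fraction (localization score) and the median signal, per channel. Frames
#' are indexed T1, T2, ...; stress (NaCl) is switched in after frame T12 in
#' the standard design.
#'
#' @param cell_id Identifier.
#' @param nuclear_fraction Named list of per-channel numeric vectors
#'   (frame-indexed), e.g. `list(GFP = ..., mCherry = ..., iRFP = ...)`.
#' @param median_signal Named list, same shape.
#' @param strain_label Optional truth or assigned strain label.
#' @return Object of class `cell_trace`.
#' @export
cell_trace <- function(cell_id, nuclear_fraction, median_signal,
                       strain_label = NA_character_) {
  stopifnot(is.list(nuclear_fraction), is.list(median_signal))
  lens <- c(lengths(nuclear_fraction), lengths(median_signal))
  if (length(unique(lens)) != 1L)
    stop("all channels must have the same frame count")
  structure(list(cell_id = cell_id,
                 n_frames = unname(lens[1L]),
                 nuclear_fraction = nuclear_fraction,
                 median_signal = median_signal,
                 strain_label = strain_label),
            class = "cell_trace")
}

check_window <- function(trace, frames, what) {
  missing <- frames[frames > trace$n_frames | frames < 1L]
  if (length(missing))
    stop(what, ": trace ", trace$cell_id, " is missing frames ",
         paste0("T", missing, collapse = ", "))
}

#' Acute-stress peak height of a nuclear-localization trace
#'
#' Maximum nuclear localization just after stress addition minus the minimum
#' just before: `max` over the post-stress window (default T13-T20) minus
#' `min` over the immediately pre-stress window (default T11-T13), both
#' inclusive. Windows are frame-index based.
#'
#' @param trace A [cell_trace()].
#' @param channel Channel name present in the trace.
#' @param pre_window,post_window Inclusive frame-index windows.
#' @return Peak height, a single dimensionless number.
#' @export
peak_height <- function(trace, channel, pre_window = c(11L, 13L),
                        post_window = c(13L, 20L)) {
  stopifnot(inherits(trace, "cell_trace"))
  nf <- trace$nuclear_fraction[[channel]]
  if (is.null(nf)) stop("channel not in trace: ", channel)
  pre <- seq.int(pre_window[1], pre_window[2])
  post <- seq.int(post_window[1], post_window[2])
  check_window(trace, c(pre, post), "peak_height")
  max(nf[post]) - min(nf[pre])
}

#' Mean protein abundance over a frame window
#'
#' Arithmetic mean of the per-frame median signal over the pre-stress
#' (T1-T12) or post-stress (T20-T36) window.
#'
#' @param trace A [cell_trace()].
#' @param channel Channel name.
#' @param window `"pre"`, `"post"`, or an explicit inclusive frame-index
#'   pair.
#' @return Mean median-signal over the window.
#' @export
abundance <- function(trace, channel, window = "pre") {
  stopifnot(inherits(trace, "cell_trace"))
  ms <- trace$median_signal[[channel]]
  if (is.null(ms)) stop("channel not in trace: ", channel)
  idx <- if (identical(window, "pre")) c(1L, 12L)
         else if (identical(window, "post")) c(20L, 36L)
         else as.integer(window)
  if (length(idx) != 2L || idx[1] > idx[2])
    stop("empty or invalid window")
  frames <- seq.int(idx[1], idx[2])
  check_window(trace, frames, "abundance")
  mean(ms[frames])
}

#' Compute the standard metrics for a list of traces
#'
#' @param traces List of [cell_trace()] objects.
#' @param nf_channel Channel carrying the nuclear-localization readout.
#' @param abundance_channel Channel for abundance (defaults to `nf_channel`).
#' @return data.frame: `cell_id`, `strain_label`, `peak_height`,
#'   `abundance_pre`, `abundance_post`, `auc_pre`, `auc_post` (trapezoidal
#'   area under the nuclear-fraction curve over the pre/post windows).
#' @export
trace_metrics <- function(traces, nf_channel, abundance_channel = nf_channel) {
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2)
  rows <- lapply(traces, function(tr) {
    nf <- tr$nuclear_fraction[[nf_channel]]
    data.frame(cell_id = tr$cell_id,
               strain_label = tr$strain_label,
               peak_height = peak_height(tr, nf_channel),
               abundance_pre = abundance(tr, abundance_channel, "pre"),
               abundance_post = abundance(tr, abundance_channel, "post"),
               auc_pre = trapz(nf[1:12]),
               auc_post = trapz(nf[20:min(36, tr$n_frames)]))
  })
  do.call(rbind, rows)
}

#' Demultiplex mixed strains by the iRFP marker channel
#'
#' In mixed-culture imaging only the wild-type carries a constitutive iRFP
#' tag. Each cell's iRFP median-signal vector across all frames is projected
#' onto the first principal component; 2-means on PC1 splits the population,
#' and the cluster with the higher mean iRFP is labeled `"marked"` (the
#' tagged strain), the other `"unmarked"`.
#'
#' @param traces List of >= 10 [cell_trace()] objects, all with an iRFP
#'   channel.
#' @param channel Marker channel name (default `"iRFP"`).
#' @param seed Seed for the 2-means split.
#' @return List: `labels` (character, per cell, `"marked"`/`"unmarked"`),
#'   `pc1` (scores), `silhouette` (mean silhouette width of the split on
#'   PC1).
#' @export
demux_by_irfp <- function(traces, channel = "iRFP", seed = 1L) {
  stopifnot(length(traces) >= 10)
  mat <- t(vapply(traces, function(tr) {
    ms <- tr$median_signal[[channel]]
    if (is.null(ms)) stop("trace ", tr$cell_id, " lacks channel ", channel)
    ms
  }, numeric(traces[[1L]]$n_frames)))
  if (all(apply(mat, 2L, stats::var) < .Machine$double.eps))
    stop("cannot demultiplex: marker signal has no variance across cells")
  pc1 <- stats::prcomp(mat, center = TRUE, scale. = FALSE)$x[, 1L]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- stats::kmeans(pc1, centers = 2L, nstart = 10L)
  mean_irfp <- tapply(rowMeans(mat), km$cluster, mean)
  marked_cluster <- as.integer(names(which.max(mean_irfp)))
  labels <- ifelse(km$cluster == marked_cluster, "marked", "unmarked")
  list(labels = labels, pc1 = pc1,
       silhouette = silhouette_1d(pc1, km$cluster))
}

# mean silhouette width for a 1-D split into two clusters (exact, no
# external dependency)
silhouette_1d <- function(x, cluster) {
  ks <- unique(cluster)
  stopifnot(length(ks) == 2L)
  s <- vapply(seq_along(x), function(i) {
    own <- abs(x[i] - x[cluster == cluster[i]])
    a <- if (length(own) > 1L) sum(own) / (length(own) - 1L) else 0
    b <- mean(abs(x[i] - x[cluster != cluster[i]]))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Center a nuclear-fraction matrix on the population median
#'
#' Divides each entry by its column (timepoint) median — so each frame's
#' population median becomes 1 — then log2-transforms for clustering and
#' blue-yellow display. A `mode = "subtract"` variant subtracts the column
#' median instead (no log).
#'
#' @param mat Cells x frames matrix of nuclear fractions.
#' @param mode `"ratio_log2"` (default) or `"subtract"`.
#' @return Centered matrix, same dimensions.
#' @export
center_population <- function(mat, mode = c("ratio_log2", "subtract")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need >= 2 cells to center on the population")
  med <- apply(mat, 2L, stats::median)
  if (mode == "ratio_log2") {
    if (any(med <= 0)) stop("zero or negative column median at frame(s) ",
                            paste(which(med <= 0), collapse = ", "))
    log2(sweep(mat, 2L, med, `/`))
  } else {
    sweep(mat, 2L, med, `-`)
  }
}

# uncentered correlation distance (Cluster 3.0 convention):
# d(x, y) = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2)); undefined for all-zero
# rows
uncentered_cor_dist <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  cross <- tcrossprod(mat)
  d <- 1 - cross / outer(norms, norms)
  d[!is.finite(d)] <- NA
  stats::as.dist(d)
}

#' Hierarchically cluster cells on population-centered dynamics
#'
#' Agglomerative clustering of cells with uncentered-correlation distance and
#' average linkage (the Cluster 3.0 defaults). Rows whose distance is
#' undefined (all-zero vectors) are flagged and placed last in the leaf
#' order.
#'
#' @param centered Cells x frames matrix from [center_population()].
#' @return Object of class `clustered_population`: list with `matrix`,
#'   `tree` (an `hclust`), `order` (leaf order, row indices), `flagged`
#'   (row indices excluded from the tree).
#' @export
cluster_cells <- function(centered) {
  centered <- as.matrix(centered)
  if (any(is.na(centered))) stop("centered matrix must have no missing rows")
  zero_rows <- which(rowSums(centered^2) == 0)
  use <- setdiff(seq_len(nrow(centered)), zero_rows)
  if (length(use) < 2) stop("need >= 2 clusterable cells")
  d <- uncentered_cor_dist(centered[use, , drop = FALSE])
  tree <- stats::hclust(d, method = "average")
  structure(list(matrix = centered, tree = tree,
                 order = c(use[tree$order], zero_rows),
                 flagged = zero_rows),
            class = "clustered_population")
}

#' Cut a clustered population into k groups
#'
#' @param cp A [cluster_cells()] result.
#' @param k Number of groups.
#' @return Integer vector of group labels per row of the original matrix
#'   (flagged rows get `NA`).
#' @export
cut_population <- function(cp, k) {
  stopifnot(inherits(cp, "clustered_population"))
  labels <- rep(NA_integer_, nrow(cp$matrix))
  use <- setdiff(seq_len(nrow(cp$matrix)), cp$flagged)
  labels[use] <- stats::cutree(cp$tree, k = k)
  labels
}

#' Abundance-matched subsetting of two cell groups
#'
#' Restricts both groups to cells whose abundance lies in a fixed signal
#' interval, then certifies the match with a Wilcoxon rank-sum test on the
#' retained abundances (matching requires p > 0.05, i.e. no detectable
#' abundance difference). Downstream phenotype comparisons (e.g. peak
#' height) on the matched subsets are then free of abundance confounding.
#'
#' @param group_a,group_b data.frames with at least an `abundance` column
#'   (e.g. [trace_metrics()] output with `abundance_pre` renamed, or pass
#'   `abundance_col`).
#' @param range Length-2 closed signal interval.
#' @param abundance_col Column holding the abundance (default
#'   `"abundance_pre"`).
#' @return List: `a`, `b` (matched subsets), `p_abundance` (rank-sum p),
#'   `matched` (logical, `p_abundance > 0.05`).
#' @export
match_abundance <- function(group_a, group_b, range,
                            abundance_col = "abundance_pre") {
  stopifnot(nrow(group_a) > 0, nrow(group_b) > 0, length(range) == 2)
  sel_a <- group_a[[abundance_col]] >= range[1] &
    group_a[[abundance_col]] <= range[2]
  sel_b <- group_b[[abundance_col]] >= range[1] &
    group_b[[abundance_col]] <= range[2]
  if (!any(sel_a) || !any(sel_b))
    stop("empty matched subset: ", sum(sel_a), " cells retained in A, ",
         sum(sel_b), " in B")
  a <- group_a[sel_a, , drop = FALSE]
  b <- group_b[sel_b, , drop = FALSE]
  p <- stats::wilcox.test(a[[abundance_col]], b[[abundance_col]],
                          exact = FALSE)$p.value
  list(a = a, b = b, p_abundance = p, matched = p > 0.05)
}
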