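#' Construct an expression table
#'
#' Per-gene log2 fold-changes across (strain, timepoint) conditions plus
#' per-timepoint FDR values for each mutant-vs-wild-type contrast. The
#' upstream differential-expression engine (read counting, GLM fitting,
#' normalization) is consumed, never computed here.
#'
#' @param log2fc Genes x conditions numeric matrix; column names
#'   `"<strain>.<timepoint>"`.
#' @param fdr Named list of genes x timepoints FDR matrices, one per
#'   contrast (e.g. `list(msn24 = ..., dot6tod6 = ...)`), rownames matching
#'   `log2fc`.
#' @param strains Character vector of strain labels present in `log2fc`.
#' @param timepoints Ordered numeric timepoints.
#' @return Object of class `expression_table`.
#' @export
expression_table <- function(log2fc, fdr, strains, timepoints) {
  log2fc <- as.matrix(log2fc)
  if (anyDuplicated(rownames(log2fc)))
    stop("duplicate gene ids in log2fc")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  for (ct in names(fdr)) {
    fdr[[ct]] <- as.matrix(fdr[[ct]])
    if (!identical(rownames(fdr[[ct]]), rownames(log2fc)))
      stop("fdr rownames for contrast ", ct, " do not match log2fc")
  }
  structure(list(log2fc = log2fc, fdr = fdr, strains = strains,
                 timepoints = timepoints,
                 genes = rownames(log2fc)),
            class = "expression_table")
}

fc_columns <- function(tab, strain) {
  cols <- paste0(strain, ".", tab$timepoints)
  missing <- setdiff(cols, colnames(tab$log2fc))
  if (length(missing))
    stop("missing fold-change columns: ", paste(missing, collapse = ", "))
  tab$log2fc[, cols, drop = FALSE]
}

#' Select genes responsive in a mutant contrast
#'
#' A gene is considered for analysis when its mutant-vs-wild-type contrast
#' is significant (FDR below `alpha`) in at least `min_timepoints`
#' timepoints.
#'
#' @param tab An [expression_table()].
#' @param contrast Name of an FDR contrast in `tab`.
#' @param alpha FDR cutoff (default 0.05).
#' @param min_timepoints Minimum significant timepoints (default 2).
#' @return Character vector of gene ids.
#' @export
select_responsive <- function(tab, contrast, alpha = 0.05,
                              min_timepoints = 2L) {
  stopifnot(inherits(tab, "expression_table"))
  f <- tab$fdr[[contrast]]
  if (is.null(f)) stop("unknown contrast: ", contrast)
  if (ncol(f) < min_timepoints)
    stop("fewer timepoints than min_timepoints")
  n_sig <- rowSums(f < alpha)
  tab$genes[n_sig >= min_timepoints]
}

#' Call an induction or repression defect for one gene
#'
#' The wild-type direction is the sign of its fold-change in a strict
#' majority of timepoints. The mutant has a defect in that direction when its
#' absolute fold-change is smaller than the wild-type's in a strict majority
#' of the timepoints where the wild-type moves in its majority direction.
#'
#' @param wt_fc,mut_fc Equal-length per-timepoint log2 fold-change vectors
#'   (>= 3 timepoints).
#' @return `"induction_defect"`, `"repression_defect"`, or `"none"`.
#' @export
call_defect <- function(wt_fc, mut_fc) {
  if (length(wt_fc) != length(mut_fc))
    stop("wt_fc and mut_fc must have equal length")
  if (length(wt_fc) < 3) stop("need >= 3 timepoints")
  n <- length(wt_fc)
  half <- n / 2
  n_up <- sum(wt_fc > 0)
  n_dn <- sum(wt_fc < 0)
  direction <- if (n_up > half) 1 else if (n_dn > half) -1 else 0
  if (direction == 0) return("none")
  idx <- which(sign(wt_fc) == direction)
  smaller <- sum(abs(mut_fc[idx]) < abs(wt_fc[idx]))
  if (smaller > length(idx) / 2) {
    if (direction > 0) "induction_defect" else "repression_defect"
  } else "none"
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance to the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[i] <- sample.int(n, 1L)
    } else {
      centers[i] <- sample.int(n, 1L, prob = d2)
    }
    di <- rowSums((x - matrix(x[centers[i], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, di)
  }
  x[centers, , drop = FALSE]
}

#' Partition genes by k-means on time-course features
#'
#' Clusters genes on the unscaled concatenation of per-strain log2
#' fold-change time courses and the per-timepoint mutant-minus-wild-type
#' log2 differences. Uses k-means++ initialization with multiple restarts;
#' deterministic for a fixed seed.
#'
#' @param features Genes x columns numeric matrix (no missing values).
#' @param k Number of clusters (default 10).
#' @param seed RNG seed.
#' @param restarts Independent k-means++ restarts (default 50).
#' @return List: `cluster` (named integer vector), `centers`,
#'   `tot_withinss`, `seed`.
#' @export
kmeans_partition <- function(features, k = 10L, seed = 1L, restarts = 50L) {
  features <- as.matrix(features)
  if (any(is.na(features))) stop("features must be complete (no NA)")
  if (k > nrow(unique(features)))
    stop("k exceeds the number of distinct feature rows")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(restarts)) {
    centers <- kmeanspp_centers(features, k)
    km <- suppressWarnings(
      stats::kmeans(features, centers = centers, iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  cl <- best$cluster
  names(cl) <- rownames(features)
  list(cluster = cl, centers = best$centers,
       tot_withinss = best$tot.withinss, seed = seed)
}

#' Build the k-means feature matrix from an expression table
#'
#' Concatenates, per gene: the log2 fold-change time course of each strain,
#' then each mutant's per-timepoint log2 difference versus wild-type.
#'
#' @param tab An [expression_table()].
#' @param wt Wild-type strain label.
#' @param mutants Mutant strain labels.
#' @param genes Optional gene subset.
#' @return Genes x features numeric matrix.
#' @export
expression_features <- function(tab, wt, mutants, genes = NULL) {
  stopifnot(inherits(tab, "expression_table"))
  blocks <- lapply(c(wt, mutants), function(s) fc_columns(tab, s))
  diffs <- lapply(mutants, function(s) {
    d <- fc_columns(tab, s) - fc_columns(tab, wt)
    colnames(d) <- paste0("diff_", s, ".", tab$timepoints)
    d
  })
  m <- do.call(cbind, c(blocks, diffs))
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  m
}

iupac_map <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

# all start offsets (1-based) where IUPAC motif matches seq exactly
motif_starts <- function(seq_chars, motif) {
  mlen <- nchar(motif)
  n <- length(seq_chars)
  if (mlen > n) return(integer(0))
  classes <- iupac_map[strsplit(motif, "")[[1L]]]
  if (any(is.na(classes))) stop("invalid IUPAC code in motif: ", motif)
  ok <- rep(TRUE, n - mlen + 1L)
  for (j in seq_len(mlen)) {
    allowed <- strsplit(classes[j], "")[[1L]]
    ok <- ok & seq_chars[seq.int(j, n - mlen + j)] %in% allowed
  }
  which(ok)
}

#' Scan a promoter for non-overlapping motif occurrences
#'
#' Finds matches to an IUPAC motif (e.g. the STRE pentamer `CCCCT` or the
#' PAC-type element `GATGAG`) on both strands of a promoter, then removes
#' overlaps greedily: match intervals are taken leftmost-first (forward
#' strand first on ties) and any interval overlapping an accepted one is
#' skipped. Overlap suppression spans strands: a reverse-strand hit occupying
#' the same interval as an accepted forward hit is dropped. On an interval
#' path the greedy leftmost rule returns a maximum non-overlapping set.
#'
#' @param sequence Promoter sequence (A/C/G/T/N), a single string.
#' @param motif IUPAC motif string, length <= promoter length.
#' @return List: `count`, `hits` (data.frame `start`, `end`, `strand`;
#'   1-based promoter coordinates).
#' @export
scan_motif <- function(sequence, motif) {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  chars <- strsplit(sequence, "")[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("promoter sequence must be over A/C/G/T/N")
  if (nchar(motif) > length(chars))
    stop("motif longer than promoter")
  mlen <- nchar(motif)
  fwd <- motif_starts(chars, motif)
  rev_ <- motif_starts(chars, revcomp(motif))
  hits <- rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+") else NULL,
    if (length(rev_)) data.frame(start = rev_, strand = "-") else NULL)
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(count = 0L,
                hits = data.frame(start = integer(0), end = integer(0),
                                  strand = character(0))))
  hits$end <- hits$start + mlen - 1L
  # leftmost-first, forward strand breaking ties
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  kept <- logical(nrow(hits))
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > last_end) {
      kept[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  out <- hits[kept, c("start", "end", "strand")]
  rownames(out) <- NULL
  list(count = sum(kept), hits = out)
}

#' Hypergeometric enrichment of gene sets in a cluster
#'
#' For each named set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when sampling the cluster from the universe
#' (over-enrichment), with Benjamini-Hochberg correction across all sets
#' tested. `tail = "lower"` tests under-enrichment (at most the observed
#' overlap), used e.g. to show a cluster is depleted of genes with an
#' upstream STRE.
#'
#' @param cluster Character vector of gene ids (must be within `universe`).
#' @param sets Named list of gene-id sets.
#' @param universe All scored gene ids.
#' @param tail `"upper"` (over-enrichment, default) or `"lower"`.
#' @return data.frame: `set`, `overlap`, `set_size`, `cluster_size`,
#'   `universe_size`, `p`, `fdr`.
#' @export
enrich <- function(cluster, sets, universe, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (length(universe) == 0) stop("empty universe")
  if (!all(cluster %in% universe))
    stop("cluster contains genes outside the universe")
  N <- length(universe)
  n <- length(cluster)
  res <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    K <- length(set)
    x <- length(intersect(set, cluster))
    p <- if (tail == "upper")
      stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    else
      stats::phyper(x, K, N - K, n, lower.tail = TRUE)
    data.frame(set = nm, overlap = x, set_size = K, cluster_size = n,
               universe_size = N, p = p)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out
}

#' Per-cluster distributions of regulator counts
#'
#' For each gene, counts the transcription-factor target sets containing it,
#' transforms as `log2(count + 1)` (the pseudocount admits genes with no
#' annotated regulator), and compares each cluster's distribution to the
#' background gene set by Wilcoxon rank-sum test with Benjamini-Hochberg
#' correction across clusters.
#'
#' @param clusters Named list of gene-id vectors.
#' @param tf_targets Named list of TF target sets.
#' @param background Character vector of background gene ids.
#' @return List: `counts` (named per-gene log2 regulator counts over the
#'   union of genes), `tests` (data.frame `cluster`, `n`, `median_log2`,
#'   `p`, `fdr`).
#' @export
regulator_count_stats <- function(clusters, tf_targets, background) {
  genes <- unique(c(unlist(clusters, use.names = FALSE), background))
  counts <- vapply(genes, function(g)
    sum(vapply(tf_targets, function(s) g %in% s, TRUE)), 0L)
  lc <- log2(counts + 1)
  names(lc) <- genes
  bg <- lc[background]
  rows <- list()
  for (nm in names(clusters)) {
    cl <- clusters[[nm]]
    if (length(cl) == 0) {
      warning("empty cluster skipped: ", nm)
      next
    }
    p <- stats::wilcox.test(lc[cl], bg, exact = FALSE)$p.value
    rows[[nm]] <- data.frame(cluster = nm, n = length(cl),
                             median_log2 = stats::median(lc[cl]), p = p)
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  tests$fdr <- bh_adjust(tests$p)
  list(counts = lc, tests = tests)
}
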