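#' Seeded synthetic OD600 curve pairs
#'
#' Emulates paired liquid growth assays: a wild-type and a mutant culture
#' grown side by side, sampled every 15 min, with exponential growth after an
#' optional acclimation lag and multiplicative lognormal noise. The default
#' post-stress wild-type:mutant rate ratio is 0.9, the fitted value in
#' salt-stressed cultures.
#'
#' @param n_pairs Number of replicate pairs.
#' @param seed RNG seed (fixed seed gives identical output).
#' @param rate_null Mutant exponential rate per minute.
#' @param ratio Wild-type rate as a fraction of the mutant rate.
#' @param noise_sd Lognormal sigma of the multiplicative OD noise (0.01 is
#'   1% noise).
#' @param lag_wt,lag_null Minutes of zero growth after t = 0.
#' @param od0 Starting OD600.
#' @param times Sampling times (minutes).
#' @return List: `pairs` (list of `list(wt = od_curve, mutant = od_curve)`),
#'   `truth` (list with the generating parameters, including `true_ratio`).
#' @export
gen_od_curves <- function(n_pairs = 100L, seed = 1L, rate_null = 0.005,
                          ratio = 0.9, noise_sd = 0.01,
                          lag_wt = 0, lag_null = 0, od0 = 0.1,
                          times = seq(0, 300, by = 15)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grow <- function(rate, lag) {
    teff <- pmax(times - lag, 0)
    od <- od0 * exp(rate * teff)
    if (noise_sd > 0) od <- od * exp(stats::rnorm(length(od), 0, noise_sd))
    od
  }
  pairs <- lapply(seq_len(n_pairs), function(i) {
    list(wt = od_curve(times, grow(rate_null * ratio, lag_wt),
                       strain = "WT", replicate = paste0("r", i)),
         mutant = od_curve(times, grow(rate_null, lag_null),
                           strain = "mutant", replicate = paste0("r", i)))
  })
  list(pairs = pairs,
       truth = list(seed = seed, n_pairs = n_pairs, rate_null = rate_null,
                    true_ratio = ratio, noise_sd = noise_sd,
                    lag_wt = lag_wt, lag_null = lag_null))
}

#' Seeded synthetic acquired-resistance viability panel
#'
#' Survival over an 11-dose peroxide series is logistic in dose with a
#' tolerated-dose midpoint (LD50) that rises with mild-stress pretreatment
#' time along saturating kinetics: `ld50(t) = ld50_base + amplitude *
#' (1 - exp(-(t - delay)/tau))` for `t > delay`. A protection-null strain has
#' `amplitude = 0`; a delayed-acquisition strain reaches the same plateau
#' later (`delay > 0`).
#'
#' @param seed RNG seed.
#' @param pretreat_times Minutes of pretreatment (must include 0).
#' @param doses Scored H2O2 doses in mM (11 by default, 2-20 mM; the
#'   zero-dose control is the normalization reference and not scored).
#' @param ld50_base mM tolerated without pretreatment.
#' @param amplitude mM of added tolerance at the plateau.
#' @param tau Minutes, acquisition time constant.
#' @param delay Minutes before acquisition starts.
#' @param width mM, logistic dose-response width.
#' @param noise_sd Gaussian noise on survival fractions (clamped to [0, 1]).
#' @param strain Label.
#' @return List: `panel` (a [viability_panel()]), `truth`.
#' @export
gen_viability_panel <- function(seed = 1L,
                                pretreat_times = c(0, 10, 20, 30, 40, 50,
                                                   60, 90, 120),
                                doses = seq(2, 20, length.out = 11),
                                ld50_base = 3, amplitude = 10, tau = 25,
                                delay = 0, width = 1.2, noise_sd = 0,
                                strain = "WT") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ld50 <- ld50_base + amplitude *
    (1 - exp(-pmax(pretreat_times - delay, 0) / tau))
  surv <- outer(ld50, doses, function(l, d) 1 / (1 + exp((d - l) / width)))
  if (noise_sd > 0)
    surv <- pmin(pmax(surv + stats::rnorm(length(surv), 0, noise_sd), 0), 1)
  list(panel = viability_panel(pretreat_times, doses, surv, strain = strain),
       truth = list(seed = seed, ld50_base = ld50_base,
                    amplitude = amplitude, tau = tau, delay = delay,
                    width = width, ld50 = ld50))
}

#' Seeded synthetic mixed-population cell traces
#'
#' Emulates a 50:50 mixed-culture time-lapse: every cell has a baseline
#' nuclear fraction near 1 and a post-stress nuclear pulse over frames
#' T13-T20 whose height is strain-specific (the mutant deficit `delta`
#' lowers it); per-cell protein abundance is lognormal around a
#' strain-specific mean; only marked (wild-type) cells carry an iRFP offset
#' above background.
#'
#' @param n_per_strain Cells per strain.
#' @param seed RNG seed.
#' @param n_frames Frames per trace (default 40).
#' @param peak_wt Pulse height of the marked (wild-type) strain.
#' @param delta Mutant peak-height deficit (`peak_mutant = peak_wt - delta`).
#' @param abundance_mean_wt,abundance_mean_mut Mean median-signal per strain.
#' @param abundance_cv Coefficient of variation of per-cell abundance.
#' @param irfp_background Background iRFP median signal.
#' @param irfp_fold iRFP offset of marked cells, as a fold over background.
#' @param noise_sd Additive noise on the nuclear fraction per frame.
#' @return List: `traces` (list of [cell_trace()]), `truth` (per-cell strain
#'   labels and generating parameters).
#' @export
gen_cell_traces <- function(n_per_strain = 50L, seed = 1L, n_frames = 40L,
                            peak_wt = 1.0, delta = 0.3,
                            abundance_mean_wt = 642,
                            abundance_mean_mut = 642,
                            abundance_cv = 0.05,
                            irfp_background = 100, irfp_fold = 5,
                            noise_sd = 0.03) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pulse_shape <- function(height) {
    nf <- rep(0, n_frames)
    idx <- 13:20
    # rise to the peak at T14-T15, decay back by T20
    shape <- c(0.6, 1, 1, 0.8, 0.55, 0.35, 0.2, 0.1)
    nf[idx] <- height * shape
    nf
  }
  make_cell <- function(i, strain, height, ab_mean, marked) {
    nf <- 1 + pulse_shape(height) +
      stats::rnorm(n_frames, 0, noise_sd)
    ab <- stats::rlnorm(1, log(ab_mean), sqrt(log(1 + abundance_cv^2)))
    ms <- ab * exp(stats::rnorm(n_frames, 0, 0.01))
    irfp_level <- if (marked) irfp_background * irfp_fold else irfp_background
    irfp <- irfp_level * exp(stats::rnorm(n_frames, 0, 0.05))
    cell_trace(cell_id = sprintf("%s_%03d", strain, i),
               nuclear_fraction = list(GFP = nf),
               median_signal = list(GFP = ms, iRFP = irfp),
               strain_label = strain)
  }
  wt <- lapply(seq_len(n_per_strain), make_cell, strain = "WT",
               height = peak_wt, ab_mean = abundance_mean_wt, marked = TRUE)
  mut <- lapply(seq_len(n_per_strain), make_cell, strain = "mutant",
                height = peak_wt - delta, ab_mean = abundance_mean_mut,
                marked = FALSE)
  traces <- c(wt, mut)
  list(traces = traces,
       truth = list(seed = seed,
                    labels = vapply(traces, `[[`, "", "strain_label"),
                    peak_wt = peak_wt, delta = delta,
                    irfp_fold = irfp_fold))
}

random_promoter <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

plant_motif <- function(seq, motif, n_sites) {
  if (n_sites == 0L) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  mlen <- nchar(motif)
  slots <- seq(1L, length(chars) - mlen + 1L, by = mlen + 2L)
  pos <- sample(slots, min(n_sites, length(slots)))
  mchars <- strsplit(motif, "")[[1L]]
  for (p in pos) chars[p:(p + mlen - 1L)] <- mchars
  paste(chars, collapse = "")
}

#' Seeded synthetic expression table with planted structure
#'
#' Genes are assigned to archetypal temporal programs — stress-induced,
#' induced with a mutant induction defect, repressed, repressed with a
#' mutant repression defect, and unresponsive — across a wild-type and two
#' mutant strains. FDR columns are emitted directly (consistent with the
#' effect: defect genes significant at all timepoints, others not), promoter
#' sequences carry Bernoulli-planted STRE (CCCCT) and PAC (GATGAG) motifs at
#' per-archetype densities, and TF target sets are biased toward their
#' archetype.
#'
#' @param n_per_class Genes per archetype.
#' @param seed RNG seed.
#' @param timepoints Minutes after stress.
#' @param fc_noise_sd Gaussian noise on log2 fold-changes.
#' @param stre_density,pac_density Probability that a promoter of the
#'   matching archetype carries a planted motif site (two sites are planted
#'   per hit to keep counts above background).
#' @param n_tfs Number of decoy TF target sets beside the two informative
#'   ones.
#' @return List: `table` (an [expression_table()]), `promoters` (named
#'   character vector), `tf_targets` (named list), `truth` (archetype and
#'   defect assignment per gene).
#' @export
gen_expression <- function(n_per_class = 40L, seed = 1L,
                           timepoints = c(10, 20, 30, 40, 50, 60),
                           fc_noise_sd = 0.15,
                           stre_density = 0.8, pac_density = 0.8,
                           n_tfs = 20L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  classes <- c("induced", "induced_defect", "repressed",
               "repressed_defect", "unresponsive")
  nt <- length(timepoints)
  # temporal archetypes: peak response at 20-30 min relaxing by 60 min
  shape <- c(0.8, 1, 1, 0.8, 0.6, 0.4)[seq_len(nt)]
  profile <- list(
    induced          = list(wt = 2.5 * shape, mut = 2.5 * shape),
    induced_defect   = list(wt = 2.5 * shape, mut = 1.0 * shape),
    repressed        = list(wt = -2.5 * shape, mut = -2.5 * shape),
    repressed_defect = list(wt = -2.5 * shape, mut = -0.8 * shape),
    unresponsive     = list(wt = 0 * shape, mut = 0 * shape))
  genes <- unlist(lapply(classes, function(cl)
    sprintf("%s_%02d", toupper(cl), seq_len(n_per_class))))
  class_of <- rep(classes, each = n_per_class)
  noise <- function(n) stats::rnorm(n, 0, fc_noise_sd)
  wt_fc <- t(vapply(class_of, function(cl)
    profile[[cl]]$wt + noise(nt), numeric(nt)))
  mut_fc <- t(vapply(class_of, function(cl)
    profile[[cl]]$mut + noise(nt), numeric(nt)))
  log2fc <- cbind(wt_fc, mut_fc)
  colnames(log2fc) <- c(paste0("WT.", timepoints),
                        paste0("mutant.", timepoints))
  rownames(log2fc) <- genes
  defect <- class_of %in% c("induced_defect", "repressed_defect")
  fdr <- matrix(ifelse(rep(defect, nt), 1e-4, 0.6),
                nrow = length(genes), ncol = nt,
                dimnames = list(genes, timepoints))
  tab <- expression_table(log2fc, fdr = list(mutant = fdr),
                          strains = c("WT", "mutant"),
                          timepoints = timepoints)
  # promoters: STRE planted in induced archetypes, PAC in repressed ones
  promoters <- vapply(seq_along(genes), function(i) {
    s <- random_promoter(500L)
    cl <- class_of[i]
    if (grepl("^induced", cl) && stats::runif(1) < stre_density)
      s <- plant_motif(s, "CCCCT", 2L)
    if (grepl("^repressed", cl) && stats::runif(1) < pac_density)
      s <- plant_motif(s, "GATGAG", 2L)
    s
  }, "")
  names(promoters) <- genes
  # TF target sets: two informative regulators plus decoys
  tf_targets <- list(
    MSN24_like = unique(c(
      genes[class_of %in% c("induced", "induced_defect") &
              stats::runif(length(genes)) < 0.7],
      sample(genes, round(0.05 * length(genes))))),
    DOT6_like = unique(c(
      genes[class_of %in% c("repressed", "repressed_defect") &
              stats::runif(length(genes)) < 0.7],
      sample(genes, round(0.05 * length(genes))))))
  for (i in seq_len(n_tfs)) {
    tf_targets[[sprintf("TF_%02d", i)]] <-
      sample(genes, round(stats::runif(1, 0.05, 0.2) * length(genes)))
  }
  list(table = tab, promoters = promoters, tf_targets = tf_targets,
       truth = list(seed = seed, class = stats::setNames(class_of, genes),
                    defect = stats::setNames(
                      ifelse(class_of == "induced_defect", "induction_defect",
                      ifelse(class_of == "repressed_defect",
                             "repression_defect", "none")), genes)))
}
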