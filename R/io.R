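#' Read and validate a delimited table
#'
#' Shared schema-checked reader for all tabular inputs. Comment lines
#' (starting `#`) are skipped; the header row is mandatory. Column presence
#' and type are validated, with errors naming the offending column and row.
#'
#' @param path File path (CSV or TSV; separator inferred from extension, or
#'   pass `sep`).
#' @param schema Named character vector of required columns ->
#'   `"numeric"`/`"character"`/`"logical"`.
#' @param sep Field separator; default inferred (`.tsv` -> tab, else comma).
#' @return data.frame with typed columns.
#' @export
read_table <- function(path, schema, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty input: ", path)
  for (col in names(schema)) {
    if (!col %in% names(df))
      stop("missing column '", col, "' in ", path)
    want <- schema[[col]]
    if (want == "numeric") {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad))
        stop("column '", col, "' is not numeric at row ", bad[1L],
             " in ", path)
      df[[col]] <- v
    } else if (want == "logical") {
      df[[col]] <- as.logical(df[[col]])
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  df
}

#' Read OD600 curves from a long-format table
#'
#' Expected columns: `time_min`, `od`, `strain`, `replicate`, `treated`.
#' Rows are split into one [od_curve()] per (strain, replicate, treated)
#' combination.
#'
#' @param path CSV/TSV path.
#' @return Named list of [od_curve()] objects
#'   (`<strain>.<replicate>.<treated>`).
#' @export
read_od_table <- function(path) {
  df <- read_table(path, c(time_min = "numeric", od = "numeric",
                           strain = "character", replicate = "character",
                           treated = "logical"))
  key <- interaction(df$strain, df$replicate, df$treated, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_min), ]
    od_curve(g$time_min, g$od, strain = g$strain[1L],
             replicate = g$replicate[1L], treated = g$treated[1L])
  })
  out
}

#' Write OD600 curves to a long-format CSV
#'
#' @param curves List of [od_curve()] objects.
#' @param path Output path.
#' @param config_hash Optional hash written as a header comment.
#' @export
write_od_table <- function(curves, path, config_hash = NULL) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(time_min = cv$time_min, od = cv$od,
               strain = attr(cv, "strain"),
               replicate = attr(cv, "replicate"),
               treated = attr(cv, "treated"))))
  write_with_header(df, path, sep = ",", config_hash = config_hash)
}

#' Read a viability panel
#'
#' Expected columns: `pretreat_time`, `dose_0` (the no-peroxide reference),
#' and one `dose_<mM>` column per scored dose. Survival fractions are each
#' dose column divided by the `dose_0` reference, clamped to \[0, 1\].
#'
#' @param path CSV path.
#' @param strain,replicate Labels.
#' @return A [viability_panel()].
#' @export
read_viability_table <- function(path, strain = "WT", replicate = "r1") {
  df <- read_table(path, c(pretreat_time = "numeric"))
  if (!"dose_0" %in% names(df))
    stop("missing reference column 'dose_0' in ", path)
  dose_cols <- grep("^dose_", names(df), value = TRUE)
  dose_cols <- setdiff(dose_cols, "dose_0")
  if (length(dose_cols) == 0) stop("no scored dose columns in ", path)
  doses <- as.numeric(sub("^dose_", "", dose_cols))
  ord <- order(doses)
  surv <- as.matrix(df[, dose_cols[ord], drop = FALSE]) / df$dose_0
  surv <- pmin(pmax(surv, 0), 1)
  viability_panel(df$pretreat_time, doses[ord], surv,
                  strain = strain, replicate = replicate)
}

#' Read single-cell traces from a long-format table
#'
#' Expected columns: `cell_id`, `frame`, `channel`, `nuclear_fraction`,
#' `median_signal`.
#'
#' @param path CSV/TSV path.
#' @return List of [cell_trace()] objects.
#' @export
read_trace_table <- function(path) {
  df <- read_table(path, c(cell_id = "character", frame = "numeric",
                           channel = "character",
                           nuclear_fraction = "numeric",
                           median_signal = "numeric"))
  lapply(split(df, df$cell_id), function(g) {
    chans <- split(g, g$channel)
    nf <- lapply(chans, function(cg) cg$nuclear_fraction[order(cg$frame)])
    ms <- lapply(chans, function(cg) cg$median_signal[order(cg$frame)])
    strain <- if ("strain" %in% names(g)) g$strain[1L] else NA_character_
    cell_trace(g$cell_id[1L], nf, ms, strain_label = strain)
  })
}

#' Write single-cell traces to a long-format CSV
#'
#' @param traces List of [cell_trace()] objects.
#' @param path Output path.
#' @param config_hash Optional hash written as a header comment.
#' @export
write_trace_table <- function(traces, path, config_hash = NULL) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    chans <- union(names(tr$nuclear_fraction), names(tr$median_signal))
    do.call(rbind, lapply(chans, function(ch)
      data.frame(cell_id = tr$cell_id, frame = seq_len(tr$n_frames),
                 channel = ch,
                 nuclear_fraction = tr$nuclear_fraction[[ch]] %||%
                   rep(NA_real_, tr$n_frames),
                 median_signal = tr$median_signal[[ch]] %||%
                   rep(NA_real_, tr$n_frames))))
  }))
  write_with_header(df, path, sep = ",", config_hash = config_hash)
}

#' Read a fold-change/FDR table into an expression table
#'
#' Expected long-format columns: `gene`, `strain`, `timepoint`, `log2fc`,
#' `fdr` (the FDR of the mutant-vs-wild-type contrast; ignored for the
#' wild-type rows).
#'
#' @param path TSV/CSV path.
#' @param wt Wild-type strain label (default `"WT"`).
#' @return An [expression_table()] with one FDR contrast per mutant strain.
#' @export
read_fc_table <- function(path, wt = "WT") {
  df <- read_table(path, c(gene = "character", strain = "character",
                           timepoint = "numeric", log2fc = "numeric",
                           fdr = "numeric"))
  genes <- unique(df$gene)
  tps <- sort(unique(df$timepoint))
  strains <- unique(df$strain)
  log2fc <- matrix(NA_real_, length(genes), length(strains) * length(tps),
                   dimnames = list(genes,
                                   paste0(rep(strains, each = length(tps)),
                                          ".", tps)))
  idx <- cbind(match(df$gene, genes),
               match(paste0(df$strain, ".", df$timepoint),
                     colnames(log2fc)))
  log2fc[idx] <- df$log2fc
  fdr <- list()
  for (s in setdiff(strains, wt)) {
    sub <- df[df$strain == s, ]
    m <- matrix(NA_real_, length(genes), length(tps),
                dimnames = list(genes, tps))
    m[cbind(match(sub$gene, genes), match(sub$timepoint, tps))] <- sub$fdr
    fdr[[s]] <- m
  }
  expression_table(log2fc, fdr, strains = strains, timepoints = tps)
}

#' Read promoter sequences from FASTA
#'
#' The record id is the first header token; sequences are uppercased and
#' records longer than `max_len` are truncated to their 3'-most `max_len`
#' bases (the window immediately upstream of the start codon) with a
#' warning.
#'
#' @param path FASTA path.
#' @param max_len Upstream window size (default 500).
#' @return Named character vector of promoter sequences.
#' @export
read_promoters <- function(path, max_len = 500L) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate promoter ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  too_long <- nchar(out) > max_len
  if (any(too_long)) {
    warning(sum(too_long), " promoter(s) longer than ", max_len,
            " bp truncated to the 3'-most ", max_len, " bases")
    out[too_long] <- substr(out[too_long],
                            nchar(out[too_long]) - max_len + 1L,
                            nchar(out[too_long]))
  }
  names(out) <- ids
  out
}

#' Write promoter sequences to FASTA
#'
#' @param promoters Named character vector.
#' @param path Output path.
#' @export
write_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path)
  invisible(path)
}

#' Read TF target sets (two-column TSV or GMT)
#'
#' Two-column format: `tf`, `target` (one pair per row). GMT: set name, a
#' description field, then member genes, tab-separated.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gmt"` (inferred from extension by default).
#' @return Named list of character vectors.
#' @export
read_tf_targets <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gmt$", path)) "gmt" else "tsv"
  if (format == "gmt") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t")
    out <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(out) <- vapply(parts, `[[`, "", 1L)
    out
  } else {
    df <- read_table(path, c(tf = "character", target = "character"),
                     sep = "\t")
    lapply(split(df$target, df$tf), unique)
  }
}

# polynomial rolling hash of a serialized object; stable fingerprint for
# run metadata and output headers (not cryptographic)
config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

write_with_header <- function(df, path, sep = ",", config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end synthetic run, serializable to
#' YAML. Unknown keys in a supplied config are rejected.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = seed,
    od = list(n_pairs = 100L, ratio = 0.9, noise_sd = 0.01,
              window = c(75, 225)),
    viability = list(amplitude = 10, delay = 0, tau = 25),
    traces = list(n_per_strain = 50L, delta = 0.3, irfp_fold = 5,
                  match_range = c(635, 650)),
    expression = list(n_per_class = 40L, k = 5L, alpha = 0.05,
                      min_timepoints = 2L,
                      motifs = c("CCCCT", "GATGAG"))),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Values in the file override the defaults; unknown keys are rejected.
#'
#' @param path YAML path.
#' @return `pipeline_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_block <- function(base, upd, prefix) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0(prefix, unknown), collapse = ", "))
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        merge_block(base[[k]], upd[[k]], paste0(prefix, k, "."))
      else upd[[k]]
    }
    base
  }
  structure(merge_block(unclass(cfg), user, ""), class = "pipeline_config")
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates every synthetic input class from the config seed, runs each
#' analysis stage on it, and writes all stage outputs plus a metadata JSON
#' (package version, config, config hash, per-stage seeds) into `out_dir`.
#' Reruns with an identical config reproduce identical outputs.
#'
#' @param cfg A `pipeline_config` (see [default_config()], [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(cfg))
  seed <- cfg$seed

  # growth stage
  od <- gen_od_curves(n_pairs = cfg$od$n_pairs, seed = seed,
                      ratio = cfg$od$ratio, noise_sd = cfg$od$noise_sd)
  ratios <- vapply(od$pairs, function(p)
    fit_growth_rate(p$wt, cfg$od$window)$rate /
      fit_growth_rate(p$mutant, cfg$od$window)$rate, 0)
  rates <- data.frame(replicate = seq_along(ratios), rate_ratio = ratios)
  write_with_header(rates, file.path(out_dir, "growth_rates.tsv"),
                    sep = "\t", config_hash = hash)

  # acquired-resistance stage
  vp <- gen_viability_panel(seed = seed + 1L,
                            amplitude = cfg$viability$amplitude,
                            delay = cfg$viability$delay,
                            tau = cfg$viability$tau)
  scores <- survival_score(vp$panel)
  write_with_header(as.data.frame(scores),
                    file.path(out_dir, "survival_scores.tsv"),
                    sep = "\t", config_hash = hash)

  # single-cell stage
  tr <- gen_cell_traces(n_per_strain = cfg$traces$n_per_strain,
                        seed = seed + 2L, delta = cfg$traces$delta,
                        irfp_fold = cfg$traces$irfp_fold)
  dm <- demux_by_irfp(tr$traces, seed = seed + 2L)
  metrics <- trace_metrics(tr$traces, nf_channel = "GFP")
  metrics$assigned <- dm$labels
  write_with_header(metrics, file.path(out_dir, "trace_metrics.tsv"),
                    sep = "\t", config_hash = hash)

  # transcriptome stage
  ex <- gen_expression(n_per_class = cfg$expression$n_per_class,
                       seed = seed + 3L)
  responsive <- select_responsive(ex$table, "mutant",
                                  alpha = cfg$expression$alpha,
                                  min_timepoints = cfg$expression$min_timepoints)
  feats <- expression_features(ex$table, wt = "WT", mutants = "mutant")
  part <- kmeans_partition(feats, k = cfg$expression$k, seed = seed + 3L)
  motif_counts <- do.call(rbind, lapply(cfg$expression$motifs, function(m)
    data.frame(gene = names(ex$promoters), motif = m,
               count = vapply(ex$promoters,
                              function(s) scan_motif(s, m)$count, 0L))))
  clusters <- split(names(part$cluster), part$cluster)
  enr <- do.call(rbind, lapply(names(clusters), function(cl) {
    e <- enrich(clusters[[cl]], ex$tf_targets, universe = ex$table$genes)
    e$cluster <- cl
    e
  }))
  write_with_header(data.frame(gene = names(part$cluster),
                               cluster = part$cluster),
                    file.path(out_dir, "expression_clusters.tsv"),
                    sep = "\t", config_hash = hash)
  write_with_header(motif_counts, file.path(out_dir, "motif_counts.tsv"),
                    sep = "\t", config_hash = hash)
  write_with_header(enr, file.path(out_dir, "enrichment.tsv"),
                    sep = "\t", config_hash = hash)

  meta <- list(package = "esrtools",
               version = as.character(utils::packageVersion("esrtools")),
               config = unclass(cfg), config_hash = hash,
               stage_seeds = list(od = seed, viability = seed + 1L,
                                  traces = seed + 2L,
                                  expression = seed + 3L))
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ratios = ratios, scores = scores, demux = dm,
                 metrics = metrics, partition = part,
                 enrichment = enr, metadata = meta))
}

#' Write a generator truth sidecar
#'
#' Serializes a generator's `truth` list to JSON next to the generated data
#' so downstream checks can consume known ground truth.
#'
#' @param truth A generator `truth` list.
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
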