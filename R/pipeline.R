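#' Pipeline configuration
#'
#' Collects every analysis setting in one validated list: the two
#' period windows (circadian 20-28 h, developmental 8-10 h), the grid
#' step, the q/amplitude thresholds used at different stages (strict
#' q < 0.05 for clustering, q < 0.10 with amplitude > 1 for the
#' phase-distribution set, q < 0.30 for weak-rhythm comparisons),
#' phase bins, motifs, the upstream window, permutation count and
#' seed. Overlapping phase bins or invalid thresholds are rejected
#' here, before any computation. Configurations round-trip losslessly
#' through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param circadian_window,developmental_window period windows in
#'   hours.
#' @param period_step grid step in hours.
#' @param q_strict,q_phase,q_weak q thresholds for the three analysis
#'   tiers.
#' @param amplitude_threshold amplitude cut used with `q_phase`.
#' @param bins a [phase_bins()] table (or data.frame coercible to one).
#' @param motifs a motif table (`name`, `iupac`).
#' @param planted_motifs names of the motifs the toy genome plants
#'   with cluster-dependent probability (default `"RORE"`; the other
#'   motifs are scanned but occur only at the background rate).
#' @param upstream_length regulatory upstream window (bases).
#' @param n_perm permutations for [rhythm_test()].
#' @param n_genes,frac_rhythmic synthetic-run size and rhythmic
#'   fraction.
#' @param noise_sd synthetic noise SD (log2 scale).
#' @param placement_probs named cluster -> probability map for
#'   [simulate_genome()].
#' @param background enrichment background mode (see
#'   [phase_enrichment()]).
#' @param n_clusters clusters for [hierarchical_cluster()].
#' @param seed integer seed.
#' @return a validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(circadian_window = c(20, 28),
                            developmental_window = c(8, 10),
                            period_step = 0.5,
                            q_strict = 0.05, q_phase = 0.10,
                            q_weak = 0.30,
                            amplitude_threshold = 1,
                            bins = phase_bins(),
                            motifs = motif_set(),
                            planted_motifs = "RORE",
                            upstream_length = 4000,
                            n_perm = 199L,
                            n_genes = 400L,
                            frac_rhythmic = 0.5,
                            noise_sd = 0.25,
                            placement_probs = c(magenta = 0.8,
                                                navy = 0.2,
                                                gray = 0.2,
                                                none = 0.2),
                            background = "all_other",
                            n_clusters = 4L,
                            seed = 1L) {
  stopifnot(length(circadian_window) == 2L,
            length(developmental_window) == 2L,
            circadian_window[1] <= circadian_window[2],
            developmental_window[1] <= developmental_window[2],
            period_step > 0, n_perm >= 99L, upstream_length >= 0)
  for (q in c(q_strict, q_phase, q_weak))
    if (q <= 0 || q > 1) stop("q thresholds must be in (0, 1]")
  if (!inherits(bins, "phase_bins"))
    bins <- phase_bins(bins$label, bins$lower, bins$upper)
  for (m in motifs$iupac) validate_iupac(m)
  if (!all(planted_motifs %in% motifs$name))
    stop("'planted_motifs' must name rows of 'motifs'")
  cfg <- list(circadian_window = as.numeric(circadian_window),
              developmental_window = as.numeric(developmental_window),
              period_step = period_step, q_strict = q_strict,
              q_phase = q_phase, q_weak = q_weak,
              amplitude_threshold = amplitude_threshold,
              bins = as.data.frame(bins), motifs = motifs,
              planted_motifs = planted_motifs,
              upstream_length = upstream_length,
              n_perm = as.integer(n_perm),
              n_genes = as.integer(n_genes),
              frac_rhythmic = frac_rhythmic, noise_sd = noise_sd,
              placement_probs = placement_probs,
              background = background,
              n_clusters = as.integer(n_clusters),
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Short content hash of a configuration
#'
#' Polynomial rolling hash (mod 2^31 - 1) over the deparsed
#' configuration; changes whenever any analysis-relevant field
#' changes. Used to stamp output files.
#'
#' @param config a `"pipeline_config"`.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  txt <- canonical_string(unclass(config))
  bytes <- utf8ToInt(txt)
  h <- 0
  # base-257 polynomial evaluated mod the Mersenne prime 2^31 - 1;
  # products stay below 2^53 so double arithmetic is exact
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

# canonical serialization: numerics at 12 significant digits (the
# precision YAML round trips preserve), names included
canonical_string <- function(x) {
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    parts <- vapply(seq_along(x), function(i)
      paste0(names(x)[i], "={", canonical_string(x[[i]]), "}"), "")
    return(paste(parts, collapse = ";"))
  }
  v <- if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
  paste(paste0(names(x), ":", v), collapse = ",")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline config [", config_hash(x), "]\n", sep = "")
  cat("  circadian window ", x$circadian_window[1], "-",
      x$circadian_window[2], " h; developmental ",
      x$developmental_window[1], "-", x$developmental_window[2],
      " h; step ", x$period_step, " h\n", sep = "")
  cat("  q thresholds ", x$q_strict, " / ", x$q_phase, " (amplitude > ",
      x$amplitude_threshold, ") / ", x$q_weak, "; ", x$n_perm,
      " permutations; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @rdname pipeline_config
#' @param config a `"pipeline_config"`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$placement_probs <- as.list(out$placement_probs)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$bins <- as.data.frame(raw$bins)
  raw$motifs <- as.data.frame(raw$motifs)
  raw$placement_probs <- unlist(raw$placement_probs)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the package's stages on a synthetic dataset with planted
#' ground truth: simulate a circadian expression time course ->
#' rhythm detection over the circadian window -> rhythmic-set
#' selection -> waveform clustering -> phase-bin assignment -> toy
#' genome with cluster-dependent RORE planting -> regulatory-region
#' motif scan -> phase-binned enrichment. Per-stage gene counts are
#' logged via `message()`; when `out_dir` is given, every output table
#' is written as TSV with the config hash and seed in a `#` header.
#' Reruns with the same config are identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list with `sim`, `rhythm`, `rhythmic` (gene ids),
#'   `clustering`, `bin_labels` (universe labelling used for
#'   enrichment), `genome`, `hits`, `enrichment`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bins <- phase_bins(config$bins$label, config$bins$lower,
                     config$bins$upper)
  stamp <- c(paste0("config_hash: ", config_hash(config)),
             paste0("seed: ", config$seed))

  message("stage simulate: ", config$n_genes, " genes")
  sim <- simulate_expression(
    design_circadian(seed = config$seed, noise_sd = config$noise_sd),
    n_genes = config$n_genes, frac_rhythmic = config$frac_rhythmic)

  tab <- rhythm_test(sim, period_min = config$circadian_window[1],
                     period_max = config$circadian_window[2],
                     period_step = config$period_step,
                     n_perm = config$n_perm, seed = config$seed,
                     q_threshold = config$q_phase,
                     amplitude_threshold = config$amplitude_threshold)
  rhythmic <- classify_rhythmic(tab, config$q_phase,
                                config$amplitude_threshold)
  message("stage rhythm: ", length(rhythmic), " rhythmic genes (q < ",
          config$q_phase, ", amplitude > ", config$amplitude_threshold,
          ")")

  clustering <- NULL
  if (length(rhythmic) >= config$n_clusters) {
    prof <- mean_profiles(sim$expr, sim$samples)
    clustering <- hierarchical_cluster(prof[rhythmic, , drop = FALSE],
                                       config$n_clusters)
    message("stage cluster: ", config$n_clusters, " clusters")
  }

  phase <- stats::setNames(tab$phase_rad, tab$gene_id)
  bin_labels <- stats::setNames(rep("arrhythmic", nrow(tab)),
                                tab$gene_id)
  bin_labels[rhythmic] <- assign_phase_bin(phase[rhythmic], bins)
  message("stage phasebin: ",
          paste(names(table(bin_labels[rhythmic])),
                table(bin_labels[rhythmic]), sep = "=",
                collapse = ", "))

  specs <- make_gene_specs(sim$truth$gene_id,
                           clusters = sim$truth$component,
                           upstream_length = min(config$upstream_length,
                                                 4000L))
  planted <- config$motifs[config$motifs$name %in%
                             config$planted_motifs, , drop = FALSE]
  genome <- simulate_genome(specs, motifs = planted,
                            placement_probs = config$placement_probs,
                            seed = config$seed)
  hits <- build_hit_table(genome$models, genome$genome,
                          motifs = config$motifs,
                          upstream_length = config$upstream_length)
  message("stage scan: ", sum(hits$present), " gene x motif presences")

  enr <- phase_enrichment(bin_labels, hits,
                          background = config$background)
  message("stage enrich: ", sum(enr$p_holm < 0.05, na.rm = TRUE),
          " significant bin x motif pairs (Holm < 0.05)")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_expression(sim, p("expression.tsv"), p("samples.tsv"),
                     header = stamp)
    write_rhythm_table(tab, p("rhythm.tsv"), header = stamp)
    if (!is.null(clustering))
      write_tsv_commented(
        data.frame(gene_id = names(clustering$labels),
                   cluster = unname(clustering$labels)),
        p("clusters.tsv"), stamp)
    write_tsv_commented(
      data.frame(gene_id = names(bin_labels),
                 phase_rad = signif(unname(phase[names(bin_labels)]), 6),
                 bin = unname(bin_labels)),
      p("phase_bins.tsv"), stamp)
    write_tsv_commented(hits, p("motif_hits.tsv"), stamp)
    write_tsv_commented(as.data.frame(enr), p("enrichment.tsv"), stamp)
    write_genome(genome, p("genome.fa"), p("genes.gff3"),
                 p("genome_truth.json"))
    write_pipeline_config(config, p("config.yaml"))
  }

  list(sim = sim, rhythm = tab, rhythmic = rhythmic,
       clustering = clustering, bin_labels = bin_labels,
       genome = genome, hits = hits, enrichment = enr,
       config = config)
}
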