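#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the probability-mass definition: with all
#' margins fixed, sum the hypergeometric probabilities of every table
#' whose probability does not exceed the observed table's
#' (alternative definitions exist and can differ in edge cases). The
#' odds ratio is the sample (unconditional) `ad/bc` — not the
#' conditional MLE that `stats::fisher.test()` reports — with `Inf`
#' when `bc = 0` and `ad > 0`, and `NaN` when both products are 0. If
#' any margin is zero only one table is possible, so `p = 1` and the
#' odds ratio is flagged undefined.
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   `rbind(c(a, b), c(c, d))` (rows: group, columns: with/without the
#'   feature). Alternatively pass a 2x2 matrix as `a`.
#' @return list with `odds_ratio`, `p`, `undefined_or` (TRUE when a
#'   zero margin makes the odds ratio meaningless), `table`.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)$p   # 2/choose(10, 5)
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    tab <- a
  } else {
    tab <- rbind(c(a, b), c(c, d))
  }
  if (any(tab < 0) || any(tab != round(tab)) || anyNA(tab))
    stop("cell counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]

  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)

  m1 <- a + b; m2 <- c + d; k <- a + c
  undefined_or <- (m1 == 0 || m2 == 0 || k == 0 || b + d == 0)
  if (undefined_or)
    return(list(odds_ratio = NaN, p = 1, undefined_or = TRUE,
                table = tab))

  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  # relative tolerance guards against ties lost to rounding
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p = p, undefined_or = FALSE, table = tab)
}

#' Holm step-down adjustment
#'
#' Family-wise error-rate control: sort p ascending, multiply the i-th
#' by `m - i + 1`, enforce monotonicity, cap at 1, return in input
#' order (delegates to `stats::p.adjust(method = "holm")`).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))   # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Phase-binned cis-element enrichment
#'
#' For every (phase bin, motif) pair, tests whether genes peaking in
#' that bin carry the motif in their regulatory region more often than
#' the background, using the binarised presence call and a two-sided
#' Fisher exact test, Holm-corrected across the tested family.
#'
#' The universe is `names(bin_labels)`. The default background for a
#' focal bin is every other universe gene (other peaks, unbinned
#' rhythmic genes and arrhythmic genes alike); `background =
#' "arrhythmic"` restricts it to genes labelled with
#' `arrhythmic_label`.
#'
#' @param bin_labels named character vector, gene id -> phase-bin
#'   label. Use `"other"` for rhythmic genes outside every bin and
#'   `arrhythmic_label` for non-rhythmic universe genes.
#' @param hits hit table from [build_hit_table()] (needs `gene_id`,
#'   `motif`, `present`); every universe gene must appear.
#' @param focal_bins bins to test (default: all labels except
#'   `"other"` and `arrhythmic_label`).
#' @param motifs motifs to test (default: all in `hits`).
#' @param background `"all_other"` (default) or `"arrhythmic"`.
#' @param family Holm family: `"all"` (all bin x motif pairs tested in
#'   this call, the default) or `"per_motif"`.
#' @param arrhythmic_label label marking arrhythmic universe genes.
#' @return data.frame of class `"enrichment_result"`: `bin`, `motif`,
#'   cell counts `a` (in bin, with motif), `b` (in bin, without), `c`
#'   (background, with), `d` (background, without), `odds_ratio`, `p`,
#'   `p_holm`, `empty_bin` flag.
#' @export
phase_enrichment <- function(bin_labels, hits, focal_bins = NULL,
                             motifs = NULL,
                             background = c("all_other", "arrhythmic"),
                             family = c("all", "per_motif"),
                             arrhythmic_label = "arrhythmic") {
  background <- match.arg(background)
  family <- match.arg(family)
  if (is.null(names(bin_labels)))
    stop("'bin_labels' must be named by gene id")
  universe <- names(bin_labels)
  if (is.null(motifs)) motifs <- unique(hits$motif)
  if (is.null(focal_bins))
    focal_bins <- setdiff(unique(bin_labels),
                          c("other", arrhythmic_label))
  missing <- setdiff(universe, unique(hits$gene_id))
  if (length(missing) > 0)
    stop("universe gene(s) absent from hit table: ",
         paste(utils::head(missing, 5), collapse = ", "))

  rows <- list()
  for (bin in focal_bins) {
    in_bin <- universe[bin_labels == bin]
    bg <- if (background == "all_other")
      setdiff(universe, in_bin)
    else
      universe[bin_labels == arrhythmic_label]
    for (mo in motifs) {
      present <- hits$gene_id[hits$motif == mo & hits$present]
      a <- sum(in_bin %in% present)
      b <- length(in_bin) - a
      cc <- sum(bg %in% present)
      d <- length(bg) - cc
      empty <- length(in_bin) == 0L
      if (empty) {
        warning("phase bin '", bin, "' contains no genes")
        ft <- list(odds_ratio = NaN, p = 1)
      } else {
        ft <- fisher_exact_2x2(a, b, cc, d)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(bin = bin, motif = mo, a = a, b = b, c = cc, d = d,
                   odds_ratio = ft$odds_ratio, p = ft$p,
                   empty_bin = empty, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (family == "all") {
    out$p_holm <- holm_adjust(out$p)
  } else {
    out$p_holm <- NA_real_
    for (mo in unique(out$motif)) {
      sel <- out$motif == mo
      out$p_holm[sel] <- holm_adjust(out$p[sel])
    }
  }
  out <- out[, c("bin", "motif", "a", "b", "c", "d", "odds_ratio",
                 "p", "p_holm", "empty_bin")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            background = background, family = family)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Cis-element enrichment (", attr(x, "background"),
      " background, Holm family '", attr(x, "family"), "')\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Overlap between two rhythmic gene sets
#'
#' Quantifies how many genes rhythmic at one period (e.g. circadian,
#' 20-28 h in adults) are also rhythmic at another (e.g. the 8-10 h
#' larval molting period): intersection size, the proportion of the
#' first set found in the second, optional per-phase-bin proportions,
#' and a hypergeometric over-representation p-value against the
#' universe.
#'
#' @param circadian,developmental character vectors of gene ids, both
#'   subsets of `universe`.
#' @param universe character vector of all analysed gene ids.
#' @param bins optional named vector gene -> phase-bin label for the
#'   circadian set, for per-bin proportions.
#' @return list of class `"overlap_result"`: `n_universe`,
#'   `n_circadian`, `n_developmental`, `n_intersect`, `proportion`
#'   (NA with `empty_circadian = TRUE` when the first set is empty),
#'   `proportion_universe` (developmental fraction of the universe),
#'   `per_bin` (data.frame `bin`, `n`, `n_overlap`, `proportion`),
#'   `p_hyper`.
#' @export
dual_period_overlap <- function(circadian, developmental, universe,
                                bins = NULL) {
  circadian <- unique(circadian)
  developmental <- unique(developmental)
  universe <- unique(universe)
  if (!all(circadian %in% universe) || !all(developmental %in% universe))
    stop("both gene sets must be subsets of the universe")
  inter <- intersect(circadian, developmental)
  empty <- length(circadian) == 0L
  prop <- if (empty) NA_real_ else length(inter) / length(circadian)
  p_hyper <- if (empty) NA_real_ else
    stats::phyper(length(inter) - 1L, length(developmental),
                  length(universe) - length(developmental),
                  length(circadian), lower.tail = FALSE)
  per_bin <- NULL
  if (!is.null(bins)) {
    labs <- unique(bins[circadian])
    labs <- labs[!is.na(labs)]
    per_bin <- do.call(rbind, lapply(sort(labs), function(l) {
      g <- circadian[!is.na(bins[circadian]) & bins[circadian] == l]
      data.frame(bin = l, n = length(g),
                 n_overlap = sum(g %in% developmental),
                 proportion = if (length(g) > 0)
                   sum(g %in% developmental) / length(g) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(n_universe = length(universe),
                 n_circadian = length(circadian),
                 n_developmental = length(developmental),
                 n_intersect = length(inter),
                 proportion = prop,
                 proportion_universe = length(developmental) /
                   length(universe),
                 per_bin = per_bin,
                 p_hyper = p_hyper,
                 empty_circadian = empty),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Dual-period overlap: ", x$n_intersect, "/", x$n_circadian,
      " circadian genes also rhythmic at the second period (",
      if (is.na(x$proportion)) "NA" else
        sprintf("%.1f%%", 100 * x$proportion),
      "; universe rate ",
      sprintf("%.1f%%", 100 * x$proportion_universe), ")\n", sep = "")
  if (!is.null(x$per_bin)) {
    cat("Per phase bin:\n")
    print(x$per_bin, row.names = FALSE, digits = 3)
  }
  cat("Hypergeometric over-representation p = ",
      format(x$p_hyper, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Time-shuffled null for rhythmic gene counts
#'
#' Builds an empirical null for "how many genes fall below each q
#' threshold" by permuting timepoint labels (replicate blocks kept
#' intact), re-running [rhythm_test()] on each shuffled matrix, and
#' recording the counts. Deterministic given `seed`.
#'
#' @inheritParams rhythm_test
#' @param n_shuffles number of shuffled datasets.
#' @param q_thresholds q cutoffs at which to count genes.
#' @param ... further arguments passed to [rhythm_test()]
#'   (`period_step`, `n_perm`, ...).
#' @return matrix `n_shuffles` x `length(q_thresholds)` of null
#'   counts, with the thresholds as column names.
#' @export
shuffle_null <- function(x, samples = NULL, period_min, period_max,
                         n_shuffles = 20L, seed = 1L, condition = NULL,
                         q_thresholds = c(0.05, 0.10, 0.30), ...) {
  if (inherits(x, "rhythm_sim")) {
    samples <- x$samples
    x <- x$expr
  }
  validate_expression(x, samples)
  if (!is.null(condition)) {
    samples <- samples[samples$condition == condition, , drop = FALSE]
    x <- x[, samples$sample_id, drop = FALSE]
  }
  tp <- sort(unique(samples$time_h))
  block <- match(samples$time_h, tp)
  out <- matrix(NA_integer_, n_shuffles, length(q_thresholds),
                dimnames = list(NULL, format(q_thresholds)))
  for (s in seq_len(n_shuffles)) {
    set.seed(as.integer(seed) + 7919L * s)
    shuf <- samples
    shuf$time_h <- tp[sample(length(tp))][block]
    tab <- rhythm_test(x, shuf, period_min = period_min,
                       period_max = period_max,
                       seed = as.integer(seed) + 104729L + s, ...)
    out[s, ] <- vapply(q_thresholds, function(qt) sum(tab$q < qt), 0L)
  }
  out
}

#' Compare rhythmicity between two conditions
#'
#' Runs an independent [rhythm_test()] per condition, counts genes
#' below each q threshold, and flags per-gene rhythm loss: rhythmic in
#' condition `a` but not in condition `b` under (`q_loss`,
#' `amplitude_loss`) — defaults select on q alone, the criterion used
#' for weak-rhythm datasets.
#'
#' @inheritParams rhythm_test
#' @param condition_a,condition_b condition labels (e.g. `"mock"` and
#'   `"auxin"`).
#' @param q_thresholds thresholds for the summary counts.
#' @param q_loss,amplitude_loss thresholds defining "rhythmic" for the
#'   loss flags (defaults 0.30 and 0).
#' @param ... further arguments passed to [rhythm_test()].
#' @return list of class `"condition_comparison"`: `table_a`,
#'   `table_b` (rhythm tables), `counts` (data.frame condition x
#'   threshold), `lost` (gene ids rhythmic in a, not in b),
#'   `rhythmic_a`, `rhythmic_b`.
#' @export
compare_conditions <- function(x, samples = NULL, condition_a,
                               condition_b, period_min, period_max,
                               q_thresholds = c(0.05, 0.10, 0.30),
                               q_loss = 0.30, amplitude_loss = 0,
                               seed = 1L, ...) {
  if (inherits(x, "rhythm_sim")) {
    samples <- x$samples
    x <- x$expr
  }
  validate_expression(x, samples)
  for (cond in c(condition_a, condition_b))
    if (!cond %in% samples$condition)
      stop("missing condition: ", cond)
  tab_a <- rhythm_test(x, samples, period_min = period_min,
                       period_max = period_max, seed = seed,
                       condition = condition_a, ...)
  tab_b <- rhythm_test(x, samples, period_min = period_min,
                       period_max = period_max, seed = seed,
                       condition = condition_b, ...)
  rhythmic_a <- classify_rhythmic(tab_a, q_loss, amplitude_loss)
  rhythmic_b <- classify_rhythmic(tab_b, q_loss, amplitude_loss)
  counts <- do.call(rbind, lapply(
    list(a = tab_a, b = tab_b), function(tab)
      vapply(q_thresholds, function(qt) sum(tab$q < qt), 0L)))
  counts <- data.frame(condition = c(condition_a, condition_b), counts)
  names(counts)[-1L] <- paste0("q_lt_", format(q_thresholds))
  structure(list(table_a = tab_a, table_b = tab_b, counts = counts,
                 lost = setdiff(rhythmic_a, rhythmic_b),
                 rhythmic_a = rhythmic_a, rhythmic_b = rhythmic_b,
                 condition_a = condition_a, condition_b = condition_b,
                 q_loss = q_loss, amplitude_loss = amplitude_loss),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison: ", x$condition_a, " vs ", x$condition_b,
      "\n", sep = "")
  print(x$counts, row.names = FALSE)
  cat("Rhythmic in ", x$condition_a, " (q < ", x$q_loss, "): ",
      length(x$rhythmic_a), "; lost in ", x$condition_b, ": ",
      length(x$lost), "\n", sep = "")
  invisible(x)
}
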