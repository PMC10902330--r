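#' Genome-wide rhythm detection with a block-permutation null
#'
#' For every gene, finds the best cosinor fit over a period grid and
#' tests it against an empirical null obtained by permuting timepoint
#' labels. The statistic is the variance explained at the best grid
#' period, `1 - rss_best / rss_null`. Permutations shuffle which
#' sampling time each timepoint block is labelled with, keeping all
#' replicates of a timepoint together so replicate correlation is
#' preserved, and the same permutations are applied to every gene.
#' Raw p-values use the standard add-one estimator
#' `(1 + #{permuted >= observed}) / (1 + n_perm)`; q-values are
#' Benjamini-Hochberg across genes.
#'
#' @param x a genes-by-samples numeric matrix of log2 expression with
#'   gene ids as rownames, or a `"rhythm_sim"` object from
#'   [simulate_expression()].
#' @param samples data.frame describing the columns of `x`, with
#'   columns `sample_id`, `time_h`, `condition`, `replicate` (not
#'   needed when `x` is a `"rhythm_sim"`).
#' @param period_min,period_max period window in hours.
#' @param period_step period grid step in hours (default 0.5).
#' @param n_perm number of label permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @param condition optional condition label; when given, only that
#'   condition's samples are analysed. Required if `x` contains more
#'   than one condition.
#' @param q_threshold,amplitude_threshold thresholds used to set the
#'   convenience `rhythmic` flag (defaults 0.10 and 1, i.e. q < 0.10
#'   with peak-to-trough amplitude above 1 on the log2 scale).
#' @return A `"rhythm_table"`: a data.frame with one row per gene and
#'   columns `gene_id`, `period_h`, `mesor`, `amplitude_log2`,
#'   `phase_rad`, `statistic`, `p_raw`, `q`, `rhythmic`. The period
#'   window, step, permutation count, seed and thresholds are attached
#'   as attributes.
#' @examples
#' sim <- simulate_expression(design_circadian(seed = 1), n_genes = 40,
#'                            frac_rhythmic = 0.5)
#' tab <- rhythm_test(sim, period_min = 20, period_max = 28,
#'                    n_perm = 99, seed = 1)
#' head(tab)
#' @export
rhythm_test <- function(x, samples = NULL, period_min, period_max,
                        period_step = 0.5, n_perm = 999, seed = 1,
                        condition = NULL,
                        q_threshold = 0.10, amplitude_threshold = 1) {
  if (inherits(x, "rhythm_sim")) {
    samples <- x$samples
    x <- x$expr
  }
  if (is.null(samples))
    stop("'samples' metadata is required when 'x' is a matrix")
  validate_expression(x, samples)
  if (n_perm < 99) stop("'n_perm' must be at least 99")

  if (!is.null(condition)) {
    keep <- samples$condition == condition
    if (!any(keep)) stop("unknown condition: ", condition)
    samples <- samples[keep, , drop = FALSE]
    x <- x[, samples$sample_id, drop = FALSE]
  } else if (length(unique(samples$condition)) > 1L) {
    stop("matrix contains multiple conditions; pass 'condition'")
  }

  times <- samples$time_h
  tp <- sort(unique(times))
  if (length(tp) < 8L)
    stop("rhythm_test needs at least 8 distinct timepoints (found ",
         length(tp), ")")

  grid <- period_grid(period_min, period_max, period_step)
  obs <- cosinor_grid_fit(x, times, grid)

  # same block permutations of timepoint labels for every gene
  block <- match(times, tp)
  set.seed(as.integer(seed))
  perm_stat <- matrix(NA_real_, nrow(x), n_perm)
  for (k in seq_len(n_perm)) {
    t_perm <- tp[sample(length(tp))][block]
    perm_stat[, k] <- cosinor_grid_stat(x, t_perm, grid, obs$rss_null)
  }
  exceed <- rowSums(perm_stat >= obs$statistic)
  p_raw <- (1 + exceed) / (1 + n_perm)
  q <- stats::p.adjust(p_raw, method = "BH")

  out <- data.frame(
    gene_id = rownames(x),
    period_h = obs$period,
    mesor = obs$mesor,
    amplitude_log2 = obs$amplitude,
    phase_rad = obs$phase,
    statistic = obs$statistic,
    p_raw = p_raw,
    q = q,
    rhythmic = q < q_threshold & obs$amplitude > amplitude_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            class = c("rhythm_table", "data.frame"),
            period_window = c(period_min, period_max),
            period_step = period_step,
            n_perm = n_perm,
            seed = seed,
            condition = condition,
            q_threshold = q_threshold,
            amplitude_threshold = amplitude_threshold)
}

# Full grid fit for a genes-by-samples matrix: per-gene best period,
# polar parameters and statistic. Ties in RSS go to the shortest period
# (grid is ascending, update on strict improvement).
cosinor_grid_fit <- function(Y, times, grid) {
  G <- nrow(Y)
  center <- Y - rowMeans(Y)
  rss_null <- rowSums(center^2)
  best_rss <- rep(Inf, G)
  best_period <- rep(NA_real_, G)
  best_cf <- matrix(NA_real_, 3L, G)
  for (p in grid) {
    X <- cosinor_design(times, p)
    qx <- qr(X)
    cf <- qr.coef(qx, t(Y))                      # 3 x G
    fitted <- X %*% cf
    rss <- colSums((t(Y) - fitted)^2)
    better <- rss < best_rss - 1e-12
    if (any(better)) {
      best_rss[better] <- rss[better]
      best_period[better] <- p
      best_cf[, better] <- cf[, better]
    }
  }
  best_rss <- pmin(best_rss, rss_null)
  a <- best_cf[2L, ]
  b <- best_cf[3L, ]
  amplitude <- 2 * sqrt(a^2 + b^2)
  phase <- ifelse(amplitude < 1e-8, 0, atan2(b, a) %% (2 * pi))
  statistic <- ifelse(rss_null > 0, 1 - best_rss / rss_null, 0)
  list(period = best_period, mesor = best_cf[1L, ], amplitude = amplitude,
       phase = phase, rss = best_rss, rss_null = rss_null,
       statistic = statistic)
}

# Statistic only (max variance explained over the grid); used in the
# permutation loop where parameters are not needed.
cosinor_grid_stat <- function(Y, times, grid, rss_null) {
  Yt <- t(Y)
  best_rss <- rep(Inf, nrow(Y))
  for (p in grid) {
    X <- cosinor_design(times, p)
    Q <- qr.Q(qr(X))
    proj <- crossprod(Q, Yt)                     # 3 x G
    rss <- colSums(Yt^2) - colSums(proj^2)
    best_rss <- pmin(best_rss, rss)
  }
  best_rss <- pmax(pmin(best_rss, rss_null), 0)
  ifelse(rss_null > 0, 1 - best_rss / rss_null, 0)
}

#' Select rhythmic genes from a rhythm table
#'
#' Applies the joint q-value and amplitude criterion (e.g. q < 0.10
#' with amplitude above 1 on the log2 scale; amplitude is strictly
#' greater than the threshold).
#'
#' @param table a `"rhythm_table"` from [rhythm_test()].
#' @param q_threshold FDR threshold (genes must have `q <` this).
#' @param amplitude_threshold peak-to-trough amplitude threshold
#'   (genes must have `amplitude_log2 >` this); use 0 to select on q
#'   alone.
#' @return character vector of gene ids.
#' @export
classify_rhythmic <- function(table, q_threshold = 0.10,
                              amplitude_threshold = 1) {
  stopifnot(is.data.frame(table))
  if (q_threshold <= 0 || q_threshold > 1)
    stop("'q_threshold' must be in (0, 1]")
  if (amplitude_threshold < 0)
    stop("'amplitude_threshold' must be non-negative")
  if (nrow(table) == 0L) return(character(0))
  table$gene_id[table$q < q_threshold &
                  table$amplitude_log2 > amplitude_threshold]
}

#' @export
print.rhythm_table <- function(x, ...) {
  w <- attr(x, "period_window")
  cat("Rhythm table: ", nrow(x), " genes, period window ",
      w[1], "-", w[2], " h, ", attr(x, "n_perm"), " permutations\n",
      sep = "")
  cat("  rhythmic (q < ", attr(x, "q_threshold"), ", amplitude > ",
      attr(x, "amplitude_threshold"), "): ", sum(x$rhythmic), "\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more genes\n", sep = "")
  invisible(x)
}

#' @export
summary.rhythm_table <- function(object, q_thresholds = c(0.05, 0.10, 0.30),
                                 ...) {
  counts <- vapply(q_thresholds, function(qt) sum(object$q < qt), 0L)
  out <- data.frame(q_threshold = q_thresholds, n_genes = counts)
  cat("Genes below q thresholds (no amplitude filter):\n")
  print(out, row.names = FALSE)
  invisible(out)
}
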