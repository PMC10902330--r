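#' Normalize an expression profile
#'
#' Two conventions are supported. `"amplitude"` (used before
#' clustering) mean-centres the series and scales it to unit Euclidean
#' norm, so clustering sees waveform shape only; it is invariant to
#' affine transforms `c*x + d` with `c > 0`. `"minmax"` (used for
#' heatmap-style displays) maps the series linearly so its maximum is 1
#' and its minimum 0; a constant series maps to all zeros by
#' convention.
#'
#' @param x numeric vector.
#' @param method `"amplitude"` or `"minmax"`.
#' @return normalized numeric vector.
#' @export
normalize_profile <- function(x, method = c("amplitude", "minmax")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (method == "amplitude") {
    cx <- x - mean(x)
    nrm <- sqrt(sum(cx^2))
    if (nrm == 0)
      stop("constant series cannot be amplitude-normalized")
    cx / nrm
  } else {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
}

#' Cosine distance between two profiles
#'
#' `1 - (x . y) / (||x|| ||y||)`, in \[0, 2\]: 0 for proportional
#' profiles, 1 for orthogonal, 2 for anti-phase.
#'
#' @param x,y numeric vectors of equal length with non-zero norm.
#' @return a single distance.
#' @export
cosine_distance <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine distance undefined for zero vectors")
  d <- 1 - sum(x * y) / (nx * ny)
  min(max(d, 0), 2)
}

# full pairwise cosine distance as a 'dist' object
cosine_dist_matrix <- function(profiles) {
  nrm <- sqrt(rowSums(profiles^2))
  if (any(nrm == 0)) stop("cosine distance undefined for zero vectors")
  sim <- tcrossprod(profiles / nrm)
  d <- 1 - sim
  d[d < 0] <- 0; d[d > 2] <- 2
  stats::as.dist(d)
}

#' Agglomerative clustering of waveforms on cosine distance
#'
#' Hierarchical clustering (default average linkage) of
#' amplitude-normalized expression profiles with cosine distance, cut
#' to a requested number of clusters. Deterministic for a given input;
#' `stats::hclust` resolves merge ties toward the lowest-index pair.
#'
#' @param profiles numeric matrix, genes in rows (rownames = gene ids),
#'   profile values in columns. Rows are amplitude-normalized
#'   internally unless `normalize = FALSE`.
#' @param n_clusters number of clusters to cut to (>= 1, <= genes).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param normalize amplitude-normalize rows first (default TRUE).
#' @return An object of class `"phase_clustering"`: list with `labels`
#'   (named integer vector gene -> cluster), `hclust` (the merge tree),
#'   `n_clusters`, `linkage`.
#' @export
hierarchical_cluster <- function(profiles, n_clusters,
                                 linkage = c("average", "complete",
                                             "single"),
                                 normalize = TRUE) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  if (n_clusters < 1L) stop("'n_clusters' must be >= 1")
  if (nrow(profiles) < n_clusters)
    stop("fewer genes (", nrow(profiles), ") than clusters (",
         n_clusters, ")")
  if (normalize)
    profiles <- t(apply(profiles, 1L, normalize_profile))
  hc <- stats::hclust(cosine_dist_matrix(profiles), method = linkage)
  labels <- stats::cutree(hc, k = n_clusters)
  structure(list(labels = labels, hclust = hc, n_clusters = n_clusters,
                 linkage = linkage),
            class = "phase_clustering")
}

#' @export
print.phase_clustering <- function(x, ...) {
  cat("Waveform clustering: ", length(x$labels), " genes in ",
      x$n_clusters, " clusters (", x$linkage,
      " linkage, cosine distance)\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Peak-phase bins
#'
#' Half-open phase intervals `[lower, upper)` in radians on
#' \[0, 2*pi). The default set is the three peaks seen in the adult
#' circadian phase distribution: `magenta` = \[pi/6, pi/2),
#' `navy` = \[pi/2, 5*pi/6), `gray` = \[4*pi/3, 5*pi/3). Bins must not
#' overlap; phases outside every bin are labelled `"other"` by
#' [assign_phase_bin()].
#'
#' @param labels character bin labels.
#' @param lower,upper numeric bin edges in radians, `0 <= lower <
#'   upper <= 2*pi`.
#' @return a `"phase_bins"` data.frame with columns `label`, `lower`,
#'   `upper`.
#' @export
phase_bins <- function(labels = c("magenta", "navy", "gray"),
                       lower = c(pi / 6, pi / 2, 4 * pi / 3),
                       upper = c(pi / 2, 5 * pi / 6, 5 * pi / 3)) {
  stopifnot(length(labels) == length(lower),
            length(lower) == length(upper))
  if (anyDuplicated(labels)) stop("bin labels must be unique")
  if (any(lower < 0) || any(upper > 2 * pi) || any(lower >= upper))
    stop("bins must satisfy 0 <= lower < upper <= 2*pi")
  o <- order(lower)
  if (length(lower) > 1L && any(upper[o][-length(o)] > lower[o][-1L] + 1e-12))
    stop("phase bins overlap")
  structure(data.frame(label = labels, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("phase_bins", "data.frame"))
}

#' Assign phases to peak-phase bins
#'
#' @param phase numeric vector of phases in radians (reduced mod
#'   2*pi).
#' @param bins a [phase_bins()] definition.
#' @return character vector: the containing bin's label, or `"other"`.
#' @examples
#' assign_phase_bin(c(pi / 3, pi, pi / 2), phase_bins())
#' @export
assign_phase_bin <- function(phase, bins = phase_bins()) {
  stopifnot(inherits(bins, "phase_bins"))
  phase <- phase %% (2 * pi)
  out <- rep("other", length(phase))
  for (i in seq_len(nrow(bins))) {
    hit <- phase >= bins$lower[i] & phase < bins$upper[i]
    out[hit] <- bins$label[i]
  }
  out[is.na(phase)] <- NA_character_
  out
}

#' Histogram of peak phases
#'
#' Counts over `n_bins` equal-width bins covering \[0, 2*pi).
#'
#' @param phases numeric vector of phases in radians.
#' @param n_bins number of bins (>= 2).
#' @return named integer vector of counts (names are interval
#'   midpoints in radians); counts sum to `length(phases)`.
#' @export
phase_histogram <- function(phases, n_bins = 12L) {
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  phases <- phases[!is.na(phases)] %% (2 * pi)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1L)
  idx <- pmin(findInterval(phases, edges), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  names(counts) <- format((edges[-1] + edges[-(n_bins + 1L)]) / 2,
                          digits = 3)
  counts
}

#' Replicate-averaged timepoint profiles
#'
#' Averages replicate samples so each gene has one value per timepoint
#' (per condition), the profile representation used for clustering.
#'
#' @param x genes-by-samples matrix.
#' @param samples sample metadata (`sample_id`, `time_h`, `condition`,
#'   `replicate`).
#' @param condition optional condition to restrict to.
#' @return genes-by-timepoints matrix; column names are the times in
#'   hours.
#' @export
mean_profiles <- function(x, samples, condition = NULL) {
  validate_expression(x, samples)
  if (!is.null(condition)) {
    samples <- samples[samples$condition == condition, , drop = FALSE]
    if (nrow(samples) == 0L) stop("unknown condition: ", condition)
  } else if (length(unique(samples$condition)) > 1L) {
    stop("matrix contains multiple conditions; pass 'condition'")
  }
  x <- x[, samples$sample_id, drop = FALSE]
  tp <- sort(unique(samples$time_h))
  prof <- vapply(tp, function(tt)
    rowMeans(x[, samples$time_h == tt, drop = FALSE]),
    numeric(nrow(x)))
  if (!is.matrix(prof))
    prof <- matrix(prof, nrow = nrow(x), dimnames = list(rownames(x)))
  colnames(prof) <- format(tp)
  prof
}
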