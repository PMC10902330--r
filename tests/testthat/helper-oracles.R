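# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the cosinor oracle is a brute-force
# grid search, the motif oracle is regex expansion, and the Fisher
# oracle enumerates hypergeometric tables from binomial coefficients.

# --- cosinor: iterative brute-force grid search over (m, a, b) -------
oracle_cosinor <- function(y, t, period, iters = 6L, pts = 21L) {
  X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
  center <- c(mean(y), 0, 0)
  width <- rep(max(2, 2 * diff(range(y))), 3)
  for (it in seq_len(iters)) {
    axes <- lapply(1:3, function(j)
      seq(center[j] - width[j], center[j] + width[j], length.out = pts))
    cand <- as.matrix(expand.grid(axes))
    rss <- colSums((y - X %*% t(cand))^2)
    best <- cand[which.min(rss), ]
    center <- best
    # shrink to a couple of grid cells around the optimum
    width <- width * (2 * 2 / (pts - 1))
  }
  a <- center[2]; b <- center[3]
  amplitude <- 2 * sqrt(a^2 + b^2)
  list(mesor = unname(center[1]), amplitude = unname(amplitude),
       phase = if (amplitude < 1e-6) 0 else
         unname(atan2(b, a) %% (2 * pi)),
       rss = sum((y - drop(X %*% center))^2))
}

# --- IUPAC scanning: regex expansion with lookahead for overlaps -----
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

oracle_iupac_regex <- function(iupac) {
  paste(vapply(strsplit(iupac, "")[[1]], function(l) {
    b <- ORACLE_IUPAC[[l]]
    if (nchar(b) == 1L) b else paste0("[", b, "]")
  }, ""), collapse = "")
}

oracle_revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

oracle_scan_count <- function(seq_chr, iupac, both_strands = TRUE) {
  count_one <- function(motif) {
    m <- gregexpr(paste0("(?=", oracle_iupac_regex(motif), ")"),
                  seq_chr, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  n <- count_one(iupac)
  if (both_strands) n <- n + count_one(oracle_revcomp(iupac))
  n
}

# --- Fisher: enumeration over tables with the observed margins ------
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  supp <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, supp) * choose(m2, k - supp) / choose(n, k)
  p_obs <- choose(m1, a) * choose(m2, c) / choose(n, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# --- misc helpers ----------------------------------------------------
circ_error <- function(x, y) {
  d <- (x - y) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
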