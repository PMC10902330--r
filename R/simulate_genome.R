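#' Gene layout specifications for the toy-genome generator
#'
#' One gene per contig, with a fixed exon/intron layout and an
#' upstream regulatory window; strands alternate so both orientations
#' are exercised. `cluster` links each gene to a phase cluster (for
#' example the `component` column of a simulation's truth table) and
#' controls its motif placement probability in [simulate_genome()].
#'
#' @param gene_ids character vector of gene ids.
#' @param clusters cluster label per gene (recycled).
#' @param n_exons exons per gene (>= 1).
#' @param exon_length,intron_length segment lengths in bases.
#' @param upstream_length regulatory upstream window in bases.
#' @param strands strand per gene (default alternating `+`/`-`).
#' @return data.frame of per-gene layout parameters.
#' @export
make_gene_specs <- function(gene_ids, clusters = "none", n_exons = 3L,
                            exon_length = 200L, intron_length = 400L,
                            upstream_length = 1000L,
                            strands = rep_len(c("+", "-"),
                                              length(gene_ids))) {
  stopifnot(n_exons >= 1L, exon_length >= 1L,
            n_exons == 1L || intron_length >= 1L)
  data.frame(gene_id = gene_ids,
             cluster = rep_len(as.character(clusters), length(gene_ids)),
             n_exons = as.integer(n_exons),
             exon_length = as.integer(exon_length),
             intron_length = as.integer(intron_length),
             upstream_length = as.integer(upstream_length),
             strand = strands,
             stringsAsFactors = FALSE)
}

#' Simulate a toy genome with planted motif instances
#'
#' Generates one contig per gene: background sequence drawn i.i.d.
#' from `background_base_probs`, a gene model laid out per
#' [make_gene_specs()], and — with the gene's cluster placement
#' probability — one concrete motif instance written into the
#' regulatory region (upstream + introns). The instance is a uniformly
#' chosen expansion of the IUPAC string, on a uniformly chosen strand,
#' at a position chosen uniformly over all placements that fit inside
#' a single regulatory segment (never crossing an exon boundary). The
#' truth table records every planted instance, so the motif scanner
#' can be checked against ground truth (scanned count >= planted
#' count; background matches can add to it).
#'
#' @param gene_specs layout table from [make_gene_specs()].
#' @param motifs data.frame with `name`, `iupac` (default
#'   [motif_set()] restricted to the RORE row).
#' @param placement_probs named vector, cluster label -> probability
#'   of planting one instance per gene x motif; clusters absent from
#'   the map get probability 0.
#' @param background_base_probs named probabilities for A/C/G/T.
#' @param seed integer seed.
#' @return An object of class `"toy_genome"`: list with `genome`
#'   ([Biostrings::DNAStringSet]), `models` ([gene_models()]),
#'   `planted` (data.frame `gene_id`, `motif`, `contig`, `start`
#'   (0-based), `strand`, `instance`), `planted_counts` (data.frame
#'   `gene_id`, `motif`, `planted`), and `gene_specs`.
#' @examples
#' specs <- make_gene_specs(c("gA", "gB"), clusters = c("magenta", "none"))
#' tg <- simulate_genome(specs, placement_probs = c(magenta = 1), seed = 1)
#' tg$planted_counts
#' @export
simulate_genome <- function(gene_specs,
                            motifs = motif_set()[1, , drop = FALSE],
                            placement_probs = c(),
                            background_base_probs = c(A = 0.25, C = 0.25,
                                                      G = 0.25, T = 0.25),
                            seed = 1L) {
  stopifnot(all(c("name", "iupac") %in% names(motifs)))
  if (any(placement_probs < 0) || any(placement_probs > 1))
    stop("placement probabilities must be in [0, 1]")
  if (abs(sum(background_base_probs) - 1) > 1e-8)
    stop("'background_base_probs' must sum to 1")
  for (m in motifs$iupac) validate_iupac(m)

  set.seed(as.integer(seed))
  pad <- 10L
  contigs <- list()
  exon_rows <- list()
  planted <- list()
  counts <- list()

  for (i in seq_len(nrow(gene_specs))) {
    sp <- gene_specs[i, ]
    contig <- paste0("ctg_", sp$gene_id)
    n_ex <- sp$n_exons
    body_len <- n_ex * sp$exon_length +
      max(0L, n_ex - 1L) * sp$intron_length
    clen <- pad + sp$upstream_length + body_len + pad

    bases <- sample(c("A", "C", "G", "T"), clen, replace = TRUE,
                    prob = background_base_probs)

    # exon coordinates, 0-based half-open; minus-strand genes are the
    # mirror layout (body first, then upstream toward the contig end)
    if (sp$strand == "+") {
      first_start <- pad + sp$upstream_length
    } else {
      first_start <- pad
    }
    starts <- first_start +
      (seq_len(n_ex) - 1L) * (sp$exon_length + sp$intron_length)
    ex <- data.frame(gene_id = sp$gene_id, contig = contig,
                     strand = sp$strand, start = starts,
                     end = starts + sp$exon_length,
                     stringsAsFactors = FALSE)

    # genomic intervals available for planting
    if (sp$strand == "+") {
      up <- c(pad, first_start)
    } else {
      up <- c(starts[n_ex] + sp$exon_length,
              starts[n_ex] + sp$exon_length + sp$upstream_length)
    }
    regions <- rbind(up,
                     if (n_ex > 1L)
                       cbind(ex$end[-n_ex], ex$start[-1L]))

    prob <- if (sp$cluster %in% names(placement_probs))
      placement_probs[[sp$cluster]] else 0
    for (k in seq_len(nrow(motifs))) {
      motif_len <- nchar(motifs$iupac[k])
      n_planted <- 0L
      if (stats::runif(1) < prob) {
        fits <- regions[, 2L] - regions[, 1L] >= motif_len
        if (!any(fits))
          stop("motif '", motifs$name[k],
               "' longer than every regulatory segment of gene '",
               sp$gene_id, "'")
        avail <- regions[fits, , drop = FALSE]
        n_pos <- avail[, 2L] - avail[, 1L] - motif_len + 1L
        # uniform over all valid start positions across segments
        pick <- sample.int(sum(n_pos), 1L)
        seg <- findInterval(pick - 1L, cumsum(c(0, n_pos)),
                            rightmost.closed = FALSE)
        pos0 <- avail[seg, 1L] + (pick - cumsum(c(0, n_pos))[seg]) - 1L
        inst <- expand_iupac(motifs$iupac[k])
        strand <- sample(c("+", "-"), 1L)
        written <- if (strand == "+") inst else revcomp_chr(inst)
        bases[(pos0 + 1L):(pos0 + motif_len)] <-
          strsplit(written, "")[[1L]]
        n_planted <- 1L
        planted[[length(planted) + 1L]] <-
          data.frame(gene_id = sp$gene_id, motif = motifs$name[k],
                     contig = contig, start = pos0, strand = strand,
                     instance = inst, stringsAsFactors = FALSE)
      }
      counts[[length(counts) + 1L]] <-
        data.frame(gene_id = sp$gene_id, motif = motifs$name[k],
                   planted = n_planted, stringsAsFactors = FALSE)
    }
    contigs[[contig]] <- paste(bases, collapse = "")
    exon_rows[[i]] <- ex
  }

  genome <- Biostrings::DNAStringSet(unlist(contigs))
  models <- gene_models(do.call(rbind, exon_rows))
  planted_df <- if (length(planted) > 0) do.call(rbind, planted) else
    data.frame(gene_id = character(0), motif = character(0),
               contig = character(0), start = integer(0),
               strand = character(0), instance = character(0))
  structure(list(genome = genome, models = models,
                 planted = planted_df,
                 planted_counts = do.call(rbind, counts),
                 gene_specs = gene_specs, seed = as.integer(seed)),
            class = "toy_genome")
}

# one concrete expansion of an IUPAC string, uniform over allowed bases
expand_iupac <- function(iupac) {
  letters <- validate_iupac(iupac)
  paste(vapply(letters, function(l) {
    opts <- IUPAC_BASES[[l]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' @export
print.toy_genome <- function(x, ...) {
  cat("Toy genome: ", length(x$genome), " contigs (",
      sum(Biostrings::width(x$genome)), " bp), ",
      length(unique(x$models$gene_id)), " genes, ",
      sum(x$planted_counts$planted), " planted motif instance(s)\n",
      sep = "")
  invisible(x)
}
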