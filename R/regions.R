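#' Gene models from an exon table
#'
#' Internal gene representation: one row per exon with 0-based
#' half-open coordinates (GFF3 input/output converts from/to 1-based
#' inclusive at the boundary). Exons of a gene must share contig and
#' strand, and be non-overlapping; they are stored sorted by start.
#'
#' @param exons data.frame with columns `gene_id`, `contig`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open, `start < end`).
#' @return a `"gene_models"` data.frame.
#' @export
gene_models <- function(exons) {
  req <- c("gene_id", "contig", "strand", "start", "end")
  miss <- setdiff(req, names(exons))
  if (length(miss) > 0)
    stop("exon table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(exons$strand %in% c("+", "-")))
    stop("unknown strand symbol (must be '+' or '-')")
  if (any(exons$start < 0) || any(exons$end <= exons$start))
    stop("malformed exon interval (need 0 <= start < end)")
  exons <- exons[order(exons$gene_id, exons$start), req, drop = FALSE]
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, ]
    if (length(unique(e$contig)) != 1L || length(unique(e$strand)) != 1L)
      stop("gene '", g, "' spans multiple contigs or strands")
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("gene '", g, "' has overlapping exons")
  }
  rownames(exons) <- NULL
  structure(exons, class = c("gene_models", "data.frame"))
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models: ", length(unique(x$gene_id)), " genes, ", nrow(x),
      " exons on ", length(unique(x$contig)), " contig(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# exon rows of one gene, sorted by genomic start
gene_exons <- function(models, gene_id) {
  e <- models[models$gene_id == gene_id, , drop = FALSE]
  if (nrow(e) == 0L) stop("unknown gene: ", gene_id)
  e[order(e$start), , drop = FALSE]
}

# genomic intervals (0-based half-open) of a gene's regulatory region:
# upstream of the first exon (strand-aware, truncated at contig
# bounds) and all introns
regulatory_intervals <- function(models, gene_id, contig_length,
                                 upstream_length = 4000) {
  e <- gene_exons(models, gene_id)
  strand <- e$strand[1L]
  if (strand == "+") {
    up <- c(max(0L, e$start[1L] - upstream_length), e$start[1L])
  } else {
    last_end <- e$end[nrow(e)]
    up <- c(last_end, min(contig_length, last_end + upstream_length))
  }
  introns <- NULL
  if (nrow(e) > 1L)
    introns <- cbind(e$end[-nrow(e)], e$start[-1L])
  list(strand = strand, contig = e$contig[1L],
       upstream = up, introns = introns)
}

#' Extract a gene's regulatory sequence
#'
#' Returns the upstream region (default 4 kb 5' of the first exon,
#' truncated at contig boundaries) followed by every intron, ordered
#' 5' to 3' along the gene. For minus-strand genes all sequences are
#' reverse-complemented so they read 5' to 3' of the gene.
#'
#' @param models a [gene_models()] table.
#' @param gene_id gene to extract.
#' @param genome a [Biostrings::DNAStringSet] keyed by contig name.
#' @param upstream_length upstream window in bases (default 4000).
#' @return named [Biostrings::DNAStringSet] with elements `upstream`
#'   (possibly empty), `intron_1`, `intron_2`, ...
#' @export
extract_regulatory_region <- function(models, gene_id, genome,
                                      upstream_length = 4000) {
  e <- gene_exons(models, gene_id)
  contig <- e$contig[1L]
  if (!contig %in% names(genome))
    stop("contig '", contig, "' not present in genome")
  clen <- Biostrings::width(genome[contig])
  if (any(e$end > clen))
    stop("exon of gene '", gene_id, "' extends beyond contig '",
         contig, "'")
  iv <- regulatory_intervals(models, gene_id, clen, upstream_length)
  seq_of <- function(int) {
    if (int[2L] <= int[1L])
      return(Biostrings::DNAString(""))
    Biostrings::subseq(genome[[contig]], int[1L] + 1L, int[2L])
  }
  segs <- list(upstream = seq_of(iv$upstream))
  if (!is.null(iv$introns)) {
    ord <- seq_len(nrow(iv$introns))
    if (iv$strand == "-") ord <- rev(ord)
    for (j in seq_along(ord))
      segs[[paste0("intron_", j)]] <- seq_of(iv$introns[ord[j], ])
  }
  out <- Biostrings::DNAStringSet(segs)
  if (iv$strand == "-") out <- Biostrings::reverseComplement(out)
  out
}

IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

validate_iupac <- function(iupac) {
  if (length(iupac) != 1L || !is.character(iupac) || nchar(iupac) == 0L)
    stop("IUPAC motif must be a non-empty string")
  letters <- strsplit(toupper(iupac), "")[[1L]]
  bad <- setdiff(letters, names(IUPAC_BASES))
  if (length(bad) > 0)
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  letters
}

#' Background match probability of a degenerate motif
#'
#' Probability that a random position matches the motif on one strand
#' under i.i.d. base probabilities: the product over motif positions of
#' the summed probabilities of the allowed bases. For the RORE
#' consensus `WAWNTRGGTCA` under uniform bases this is
#' `(1/2)(1/4)(1/2)(1)(1/4)(1/2)(1/4)^5 = 7.629e-06`.
#'
#' @param iupac motif string over the IUPAC nucleotide alphabet.
#' @param base_probs named probabilities for `A`, `C`, `G`, `T`
#'   (must sum to 1).
#' @return per-position, per-strand match probability.
#' @export
iupac_match_probability <- function(iupac,
                                    base_probs = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25)) {
  letters <- validate_iupac(iupac)
  if (abs(sum(base_probs) - 1) > 1e-8)
    stop("'base_probs' must sum to 1")
  prod(vapply(letters,
              function(l) sum(base_probs[IUPAC_BASES[[l]]]), 0))
}

#' Scan a sequence for a degenerate motif
#'
#' Counts every (possibly overlapping) start position matching the
#' IUPAC pattern. Degenerate codes in the motif are interpreted;
#' ambiguous bases in the sequence are treated literally, so an `N` in
#' the genome matches only the motif code `N`. With
#' `both_strands = TRUE`, matches of the reverse-complemented motif
#' are added and annotated with strand `"-"` (positions always refer
#' to the given sequence). A motif longer than the sequence yields
#' count 0.
#'
#' @param sequence a [Biostrings::DNAString] or single character
#'   string over `A/C/G/T/N`.
#' @param iupac motif string (IUPAC alphabet).
#' @param both_strands scan the reverse complement too (default TRUE;
#'   the RORE consensus is not palindromic).
#' @return list with `count` and `positions`, a data.frame of 1-based
#'   match `start`s and `strand`.
#' @examples
#' scan_motif("AATTTAGGTCA", "WAWNTRGGTCA")$count
#' @export
scan_motif <- function(sequence, iupac, both_strands = TRUE) {
  validate_iupac(iupac)
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (nchar(iupac) > length(sequence))
    return(list(count = 0L,
                positions = data.frame(start = integer(0),
                                       strand = character(0))))
  fwd <- Biostrings::matchPattern(iupac, sequence, fixed = "subject")
  starts <- Biostrings::start(fwd)
  strands <- rep("+", length(starts))
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(iupac)))
    rev <- Biostrings::matchPattern(rc, sequence, fixed = "subject")
    starts <- c(starts, Biostrings::start(rev))
    strands <- c(strands, rep("-", length(Biostrings::start(rev))))
  }
  o <- order(starts, strands)
  list(count = length(starts),
       positions = data.frame(start = starts[o], strand = strands[o],
                              stringsAsFactors = FALSE))
}

#' Default cis-element motif set
#'
#' The ROR response element consensus `WAWNTRGGTCA` plus working
#' consensus strings for the other clock-controlled elements tested
#' alongside it (D-box `TTATGYAA`, E-box `CACGTG`, E'-box `CACGTT`).
#' The non-RORE strings are configuration defaults, not literature
#' constants; override them by passing your own table wherever a
#' `motifs` argument is accepted.
#'
#' @return data.frame with columns `name`, `iupac`.
#' @export
motif_set <- function() {
  data.frame(name = c("RORE", "Dbox", "Ebox", "EpBox"),
             iupac = c("WAWNTRGGTCA", "TTATGYAA", "CACGTG", "CACGTT"),
             stringsAsFactors = FALSE)
}

#' Motif counts and presence per gene regulatory region
#'
#' For each gene, extracts the regulatory region (upstream + introns)
#' and sums motif matches over all segments; with
#' `both_strands = TRUE` both orientations are counted (so a
#' self-complementary motif is counted twice per site). `present` is
#' `count >= 1` — the binarised value the enrichment test uses.
#'
#' @param models a [gene_models()] table.
#' @param genome a [Biostrings::DNAStringSet].
#' @param motifs data.frame with `name` and `iupac` columns (default
#'   [motif_set()]).
#' @param upstream_length upstream window in bases (default 4000).
#' @param both_strands scan both strands (default TRUE).
#' @return data.frame with columns `gene_id`, `motif`, `count`,
#'   `present`.
#' @export
build_hit_table <- function(models, genome, motifs = motif_set(),
                            upstream_length = 4000,
                            both_strands = TRUE) {
  stopifnot(all(c("name", "iupac") %in% names(motifs)))
  ids <- unique(models$gene_id)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    segs <- extract_regulatory_region(models, ids[i], genome,
                                      upstream_length)
    counts <- vapply(motifs$iupac, function(m)
      sum(vapply(seq_along(segs), function(j)
        scan_motif(segs[[j]], m, both_strands)$count, 0L)),
      0L, USE.NAMES = FALSE)
    res[[i]] <- data.frame(gene_id = ids[i], motif = motifs$name,
                           count = counts, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$present <- out$count >= 1L
  rownames(out) <- NULL
  out
}
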