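#' Read an expression matrix and its sample metadata
#'
#' The matrix TSV has gene ids in the first column and one column per
#' sample; the metadata TSV has columns `sample_id`, `time_h`,
#' `condition`, `replicate`. Lines starting with `#` are ignored.
#' Validation names the offending gene/sample: duplicate gene ids,
#' non-numeric or non-finite cells, matrix columns missing from the
#' metadata and vice versa are all rejected.
#'
#' @param matrix_path,meta_path file paths.
#' @return list with `expr` (numeric matrix, genes x samples) and
#'   `samples` (data.frame).
#' @export
read_expression <- function(matrix_path, meta_path) {
  raw <- utils::read.delim(matrix_path, comment.char = "#",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression TSV needs gene ids plus samples")
  ids <- as.character(raw[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop("non-numeric or non-finite value for gene '", ids[bad[1L]],
           "', sample '", names(vals)[j], "'")
    vals[[j]] <- v
  }
  expr <- as.matrix(vals)
  rownames(expr) <- ids
  samples <- utils::read.delim(meta_path, comment.char = "#",
                               stringsAsFactors = FALSE)
  validate_expression(expr, samples)
  samples <- samples[match(colnames(expr), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  list(expr = expr, samples = samples)
}

#' Write an expression matrix and sample metadata as TSV
#'
#' Floats are written with 6 significant digits for reproducible
#' diffs; an optional `#`-prefixed header records provenance.
#'
#' @param x a `"rhythm_sim"` or a genes-by-samples matrix.
#' @param matrix_path,meta_path output paths.
#' @param samples sample metadata (when `x` is a matrix).
#' @param header optional character vector of comment lines (written
#'   prefixed with `#`).
#' @export
write_expression <- function(x, matrix_path, meta_path, samples = NULL,
                             header = NULL) {
  if (inherits(x, "rhythm_sim")) {
    samples <- x$samples
    x <- x$expr
  }
  validate_expression(x, samples)
  df <- data.frame(gene_id = rownames(x),
                   signif(x, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, matrix_path, header)
  write_tsv_commented(samples, meta_path, header)
  invisible(c(matrix_path, meta_path))
}

write_tsv_commented <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a rhythm table as TSV
#'
#' @param table a `"rhythm_table"`.
#' @param path output path.
#' @param header optional comment lines.
#' @export
write_rhythm_table <- function(table, path, header = NULL) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  write_tsv_commented(df, path, header)
  invisible(path)
}

#' Write a toy genome as FASTA + GFF3 (+ truth JSON)
#'
#' FASTA is wrapped at 60 columns. GFF3 features are `gene`, `mRNA`
#' and `exon` with `ID`/`Parent` attributes, 1-based inclusive
#' coordinates.
#'
#' @param tg a `"toy_genome"` from [simulate_genome()].
#' @param fasta_path,gff3_path output paths.
#' @param truth_path optional path for the planted-truth JSON.
#' @export
write_genome <- function(tg, fasta_path, gff3_path, truth_path = NULL) {
  stopifnot(inherits(tg, "toy_genome"))
  Biostrings::writeXStringSet(tg$genome, fasta_path, width = 60L)
  write_gene_models_gff3(tg$models, gff3_path)
  if (!is.null(truth_path)) {
    jsonlite::write_json(
      list(seed = tg$seed, planted = tg$planted,
           planted_counts = tg$planted_counts),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(fasta_path, gff3_path))
}

#' Write gene models as GFF3
#'
#' Internal 0-based half-open exon coordinates are converted to the
#' GFF3 1-based inclusive convention. Each gene is emitted as a
#' `gene` feature spanning its exons, one `mRNA` child, and `exon`
#' grandchildren.
#'
#' @param models a [gene_models()] table.
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  ids <- unique(models$gene_id)
  rows <- list()
  for (g in ids) {
    e <- gene_exons(models, g)
    span <- data.frame(contig = e$contig[1L], start = min(e$start) + 1L,
                       end = max(e$end), strand = e$strand[1L],
                       stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- cbind(
      span[c(1L, 1L), ],
      type = c("gene", "mRNA"),
      ID = c(g, paste0(g, ".t1")),
      Parent = c(NA_character_, g))
    rows[[length(rows) + 1L]] <- data.frame(
      contig = e$contig, start = e$start + 1L, end = e$end,
      strand = e$strand, type = "exon",
      ID = paste0(g, ".t1.exon", seq_len(nrow(e))),
      Parent = paste0(g, ".t1"), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$contig, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = factor(df$type, levels = c("gene", "mRNA", "exon")),
    ID = df$ID, Parent = df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models and genome from GFF3 + FASTA
#'
#' Exon features are grouped into genes by following `Parent`
#' attributes (exon -> mRNA -> gene, or exon -> gene directly).
#' Coordinates are converted from GFF3 1-based inclusive to the
#' internal 0-based half-open convention. Every feature's contig must
#' exist in the FASTA and exons must lie within contig bounds.
#'
#' @param gff3_path,fasta_path file paths.
#' @return list with `models` ([gene_models()]) and `genome`
#'   ([Biostrings::DNAStringSet]).
#' @export
read_annotation <- function(gff3_path, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  # map every feature ID to its gene ancestor
  id <- as.character(mc$ID)
  parent <- vapply(as.list(mc$Parent), function(p)
    if (length(p) == 0L) NA_character_ else p[[1L]], "")
  gene_of <- function(i) {
    j <- i
    for (step in 1:5) {
      if (type[j] == "gene") return(id[j])
      pj <- match(parent[j], id)
      if (is.na(pj)) return(parent[j])
      j <- pj
    }
    stop("could not resolve gene ancestry for feature ", id[i])
  }
  ex_idx <- which(type == "exon")
  if (length(ex_idx) == 0L) stop("GFF3 contains no exon features")
  exons <- data.frame(
    gene_id = vapply(ex_idx, gene_of, ""),
    contig = as.character(GenomicRanges::seqnames(gr))[ex_idx],
    strand = as.character(GenomicRanges::strand(gr))[ex_idx],
    start = GenomicRanges::start(gr)[ex_idx] - 1L,
    end = GenomicRanges::end(gr)[ex_idx],
    stringsAsFactors = FALSE)
  if (any(!exons$strand %in% c("+", "-")))
    stop("unknown strand symbol in GFF3")
  bad <- setdiff(unique(exons$contig), names(genome))
  if (length(bad) > 0)
    stop("contig(s) in GFF3 absent from FASTA: ",
         paste(bad, collapse = ", "))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  over <- exons$end > clen[exons$contig]
  if (any(over))
    stop("exon of gene '", exons$gene_id[which(over)[1L]],
         "' extends beyond contig end")
  list(models = gene_models(exons), genome = genome)
}

#' Read/write a motif definition table
#'
#' TSV with columns `name` and `iupac`.
#'
#' @param path file path.
#' @return data.frame with `name`, `iupac`.
#' @export
read_motifs <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("name", "iupac") %in% names(df)))
    stop("motif TSV needs 'name' and 'iupac' columns")
  for (m in df$iupac) validate_iupac(m)
  df
}

#' @rdname read_motifs
#' @param motifs data.frame with `name`, `iupac`.
#' @export
write_motifs <- function(motifs, path) {
  write_tsv_commented(motifs[, c("name", "iupac")], path)
  invisible(path)
}

#' Write regulatory regions as BED (0-based half-open) for audit
#'
#' @param models a [gene_models()] table.
#' @param genome a [Biostrings::DNAStringSet] (for contig bounds).
#' @param path output path.
#' @param upstream_length upstream window in bases.
#' @export
write_regions_bed <- function(models, genome, path,
                              upstream_length = 4000) {
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  rows <- list()
  for (g in unique(models$gene_id)) {
    e <- gene_exons(models, g)
    iv <- regulatory_intervals(models, g, clen[[e$contig[1L]]],
                               upstream_length)
    add <- function(int, label) {
      if (int[2L] > int[1L])
        rows[[length(rows) + 1L]] <<-
          data.frame(chrom = iv$contig, start = int[1L], end = int[2L],
                     name = paste0(g, ":", label), score = 0,
                     strand = iv$strand, stringsAsFactors = FALSE)
    }
    add(iv$upstream, "upstream")
    if (!is.null(iv$introns))
      for (j in seq_len(nrow(iv$introns)))
        add(iv$introns[j, ], paste0("intron_", j))
  }
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
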