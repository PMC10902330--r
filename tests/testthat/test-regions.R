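# hand-built fixture: 60-bp contig, 2-exon plus-strand gene with
# exons [10,20) and [30,40) (0-based half-open)
fixture_contig <- function(seed = 101) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
        collapse = "")
}

fixture_models <- function(strand = "+") {
  gene_models(data.frame(gene_id = "gX", contig = "c1",
                         strand = strand, start = c(10, 30),
                         end = c(20, 40)))
}

test_that("regulatory region of a hand-built plus-strand gene", {
  seq <- fixture_contig()
  genome <- Biostrings::DNAStringSet(c(c1 = seq))
  segs <- extract_regulatory_region(fixture_models("+"), "gX", genome,
                                    upstream_length = 4000)
  # upstream truncated at the contig start: positions [0,10)
  expect_equal(as.character(segs[["upstream"]]), substr(seq, 1, 10))
  # single intron = [20,30)
  expect_equal(length(segs), 2L)
  expect_equal(as.character(segs[["intron_1"]]), substr(seq, 21, 30))
})

test_that("minus-strand extraction is the reverse complement of the mirror", {
  seq <- fixture_contig()
  genome <- Biostrings::DNAStringSet(c(c1 = seq))
  segs <- extract_regulatory_region(fixture_models("-"), "gX", genome,
                                    upstream_length = 15)
  # minus-strand upstream: [40, 55) in contig coordinates, revcomped
  expect_equal(as.character(segs[["upstream"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(seq, 41, 55)))))
  expect_equal(as.character(segs[["intron_1"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(seq, 21, 30)))))
})

test_that("upstream truncation at contig boundary (single-exon gene)", {
  seq <- fixture_contig(5)
  genome <- Biostrings::DNAStringSet(c(c1 = seq))
  m <- gene_models(data.frame(gene_id = "g1", contig = "c1",
                              strand = "+", start = 30, end = 50))
  segs <- extract_regulatory_region(m, "g1", genome,
                                    upstream_length = 4000)
  expect_equal(as.character(segs[["upstream"]]), substr(seq, 1, 30))
  expect_equal(length(segs), 1L)
})

test_that("gene model validation catches malformed input", {
  df <- data.frame(gene_id = "g", contig = "c", strand = "+",
                   start = c(0, 5), end = c(10, 15))
  expect_error(gene_models(df), "overlapping exons")
  df$strand <- "?"
  expect_error(gene_models(df), "strand")
  expect_error(gene_models(data.frame(gene_id = "g", contig = "c",
                                      strand = "+", start = 5, end = 5)),
               "malformed")
  m <- fixture_models()
  genome <- Biostrings::DNAStringSet(c(c1 = fixture_contig()))
  expect_error(extract_regulatory_region(m, "nope", genome), "unknown gene")
  expect_error(
    extract_regulatory_region(m, "gX",
                              Biostrings::DNAStringSet(c(zz = "ACGT"))),
    "not present")
})

test_that("IUPAC match probabilities: closed-form values", {
  expect_equal(iupac_match_probability("N"), 1)
  expect_equal(iupac_match_probability("A"), 0.25)
  expect_equal(iupac_match_probability("WAWNTRGGTCA"),
               (1 / 2) * (1 / 4) * (1 / 2) * 1 * (1 / 4) * (1 / 2) *
                 (1 / 4)^5)
  expect_equal(iupac_match_probability("WAWNTRGGTCA"),
               7.62939453125e-06)
  # non-uniform bases
  bp <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  expect_equal(iupac_match_probability("WS", bp), 0.8 * 0.2)
  expect_error(iupac_match_probability("AXC"), "invalid IUPAC")
  expect_error(iupac_match_probability("A", c(A = 1, C = 1, G = 0, T = 0)),
               "sum to 1")
})

test_that("motif scanning: known matches, strands, overlaps, N handling", {
  rore <- "WAWNTRGGTCA"
  hit <- scan_motif("AATTTAGGTCA", rore, both_strands = FALSE)
  expect_equal(hit$count, 1L)
  expect_equal(hit$positions$start, 1L)

  expect_equal(scan_motif(strrep("C", 50), rore)$count, 0L)

  # reverse complement of a matching sequence found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("AATTTAGGTCA")))
  hit_rc <- scan_motif(rc, rore, both_strands = TRUE)
  expect_equal(hit_rc$count, 1L)
  expect_equal(hit_rc$positions$strand, "-")
  expect_equal(scan_motif(rc, rore, both_strands = FALSE)$count, 0L)

  # overlapping matches all counted
  expect_equal(scan_motif("AAAA", "AA", both_strands = FALSE)$count, 3L)

  # ambiguous genome base: N matches only the motif code N
  expect_equal(scan_motif("ANT", "AAT", both_strands = FALSE)$count, 0L)
  expect_equal(scan_motif("ANT", "ANT", both_strands = FALSE)$count, 1L)

  # motif longer than sequence: count 0, not an error
  expect_equal(scan_motif("ACG", rore)$count, 0L)
})

test_that("scanner equals the regex-expansion oracle on random sequences", {
  set.seed(19)
  motifs <- c("WAWNTRGGTCA", "TTATGYAA", "CACGTG", "RYN")
  for (i in 1:50) {
    s <- random_dna(200)
    for (m in motifs) {
      expect_equal(scan_motif(s, m, both_strands = TRUE)$count,
                   oracle_scan_count(s, m, both_strands = TRUE),
                   info = paste(i, m))
    }
  }
})

test_that("strand consistency: sequence and its revcomp give equal totals", {
  set.seed(23)
  for (i in 1:20) {
    s <- random_dna(300)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    expect_equal(scan_motif(s, "WAWNTRGGTCA", TRUE)$count,
                 scan_motif(rc, "WAWNTRGGTCA", TRUE)$count)
  }
})

test_that("hit table: construction guarantees, N-motif totals, planting recovery", {
  specs <- make_gene_specs(sprintf("g%02d", 1:10),
                           clusters = rep(c("magenta", "none"), 5),
                           upstream_length = 300L)
  tg <- simulate_genome(specs, placement_probs = c(magenta = 1),
                        seed = 9)
  hits <- build_hit_table(tg$models, tg$genome,
                          motifs = motif_set()[1, , drop = FALSE],
                          upstream_length = 300)
  planted <- merge(hits, tg$planted_counts,
                   by = c("gene_id", "motif"))
  # scanner always recovers at least the planted instances
  expect_true(all(planted$count >= planted$planted))
  mag <- specs$gene_id[specs$cluster == "magenta"]
  expect_true(all(hits$present[hits$gene_id %in% mag]))

  # motif "N": every position on both strands matches
  nhits <- build_hit_table(tg$models, tg$genome,
                           motifs = data.frame(name = "anyN",
                                               iupac = "N"),
                           upstream_length = 300)
  g1 <- extract_regulatory_region(tg$models, "g01", tg$genome, 300)
  expect_equal(nhits$count[nhits$gene_id == "g01"],
               2L * sum(Biostrings::width(g1)))
})

test_that("background match counts follow the closed-form rate", {
  set.seed(37)
  L <- 400000L
  s <- random_dna(L)
  n <- scan_motif(s, "WAWNTRGGTCA", both_strands = TRUE)$count
  rate <- iupac_match_probability("WAWNTRGGTCA")
  lambda <- 2 * (L - 11 + 1) * rate
  expect_gte(n, qpois(0.005, lambda))
  expect_lte(n, qpois(0.995, lambda))
})
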