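# a small deterministic two-exon gene: CDS split mid-codon by the intron
demo_gene <- function(strand = "+", region_start = 500) {
  set.seed(101)
  sense <- setdiff(as.vector(outer(as.vector(outer(
    c("A","C","G","T"), c("A","C","G","T"), paste0)),
    c("A","C","G","T"), paste0)), c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(sense, 38, replace = TRUE),
                             collapse = ""), "TAA")
  two_exon_gene("demo", "chrD", strand, region_start, cds,
                exon1_cds_len = 50, intron_seq = strrep("GATTACA", 20))
}

test_that("single-base substitutions classify by codon translation", {
  g <- demo_gene("+")
  cdspos <- poolscan:::cds_positions(g)
  s <- spliced_cds(g)

  # third-position GCx is always alanine: pick any codon and make a
  # synonymous third-position change via the wobble rule where one exists
  e <- classify_variant_effect(g, list(chrom = "chrD", pos = cdspos[1],
                                       ref = substr(s, 1, 1), alt = "C"))
  expect_equal(e$effect, "missense")          # start-codon loss
  expect_equal(e$aa_change$ref, "M")

  # force a nonsense change: find a codon one substitution from a stop
  hit <- NULL
  for (idx in seq(4, nchar(s) - 3)) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(s, idx, idx))) {
      if (oracle_snv_effect(s, idx, b) == "nonsense") {
        hit <- list(idx = idx, b = b); break
      }
    }
    if (!is.null(hit)) break
  }
  alt_genomic <- if (g$strand == "-")
    chartr("ACGT", "TGCA", hit$b) else hit$b
  e2 <- classify_variant_effect(g, list(
    chrom = "chrD", pos = cdspos[hit$idx],
    ref = poolscan:::region_base(g, cdspos[hit$idx]), alt = alt_genomic))
  expect_equal(e2$effect, "nonsense")
  expect_equal(e2$aa_change$alt, "*")
})

test_that("every codon substitution matches the translate-and-compare oracle on both strands", {
  cds <- all_codon_cds()
  for (strand in c("+", "-")) {
    g <- two_exon_gene("codons", "chrC", strand, 1000, cds,
                       exon1_cds_len = 100,
                       intron_seq = strrep("TTAACCGG", 30))
    cdspos <- poolscan:::cds_positions(g)
    s <- spliced_cds(g)
    expect_identical(s, cds)                  # strand-correct extraction
    mismatches <- 0L
    for (idx in seq(4, 3 + 64 * 3)) {         # all 64 codons, 9 subs each
      ref_coding <- substr(s, idx, idx)
      for (b in setdiff(c("A", "C", "G", "T"), ref_coding)) {
        genomic_ref <- poolscan:::region_base(g, cdspos[idx])
        genomic_alt <- if (strand == "-") chartr("ACGT", "TGCA", b) else b
        got <- classify_variant_effect(g, list(
          chrom = "chrC", pos = cdspos[idx], ref = genomic_ref,
          alt = genomic_alt))$effect
        want <- oracle_snv_effect(s, idx, b)
        if (!identical(got, want)) mismatches <- mismatches + 1L
      }
    }
    expect_equal(mismatches, 0L)
  }
})

test_that("reverse-strand genes classify identically to their forward construction", {
  cds <- all_codon_cds()
  gf <- two_exon_gene("fw", "chrS", "+", 2000, cds, 77,
                      strrep("ACGTT", 40))
  gr <- two_exon_gene("rv", "chrS", "-", 2000, cds, 77,
                      strrep("ACGTT", 40))
  pf <- poolscan:::cds_positions(gf)
  pr <- poolscan:::cds_positions(gr)
  set.seed(5)
  for (idx in sample(seq_len(nchar(cds)), 40)) {
    b <- sample(setdiff(c("A", "C", "G", "T"), substr(cds, idx, idx)), 1)
    ef <- classify_variant_effect(gf, list(
      chrom = "chrS", pos = pf[idx],
      ref = poolscan:::region_base(gf, pf[idx]), alt = b))
    er <- classify_variant_effect(gr, list(
      chrom = "chrS", pos = pr[idx],
      ref = poolscan:::region_base(gr, pr[idx]),
      alt = chartr("ACGT", "TGCA", b)))
    expect_equal(er$effect, ef$effect)
    expect_equal(er$codon_change, ef$codon_change)
  }
})

test_that("the truncating 8 bp deletion at CDS base 4 is a frameshift, and in-frame indels never are", {
  g <- demo_gene("+")
  cdspos <- poolscan:::cds_positions(g)
  # anchor at CDS base 3, deleting CDS bases 4-11 (8 bp, exon 1)
  anchor <- cdspos[3]
  ref <- poolscan:::region_base(g, anchor, 9L)
  e <- classify_variant_effect(g, list(chrom = "chrD", pos = anchor,
                                       ref = ref,
                                       alt = substr(ref, 1, 1)))
  expect_equal(e$effect, "frameshift")

  for (len in c(3L, 6L, 9L)) {               # length %% 3 == 0: never FS
    a <- cdspos[6]
    r <- poolscan:::region_base(g, a, len + 1L)
    del <- classify_variant_effect(g, list(chrom = "chrD", pos = a,
                                           ref = r,
                                           alt = substr(r, 1, 1)))
    expect_equal(del$effect, "in_frame_indel")
    ins <- classify_variant_effect(g, list(
      chrom = "chrD", pos = a, ref = substr(r, 1, 1),
      alt = paste0(substr(r, 1, 1), strrep("ACT", len / 3L))))
    expect_equal(ins$effect, "in_frame_indel")
  }
  for (len in c(1L, 2L, 4L, 8L)) {           # length %% 3 != 0: always FS
    a <- cdspos[6]
    r <- poolscan:::region_base(g, a, len + 1L)
    expect_equal(classify_variant_effect(g, list(
      chrom = "chrD", pos = a, ref = r,
      alt = substr(r, 1, 1)))$effect, "frameshift")
  }
})

test_that("splice-site and reference-mismatch rules hold", {
  g <- demo_gene("+")
  intron_start <- g$exons$end[1] + 1
  e <- classify_variant_effect(g, list(
    chrom = "chrD", pos = intron_start + 1,
    ref = poolscan:::region_base(g, intron_start + 1), alt = "A"))
  expect_equal(e$effect, "splice_site")
  deep <- classify_variant_effect(g, list(
    chrom = "chrD", pos = intron_start + 60,
    ref = poolscan:::region_base(g, intron_start + 60), alt = "A"))
  expect_equal(deep$effect, "noncoding")

  wrong <- setdiff(c("A", "C", "G", "T"),
                   poolscan:::region_base(g, intron_start + 60))[1]
  expect_error(classify_variant_effect(g, list(
    chrom = "chrD", pos = intron_start + 60, ref = wrong, alt = "T")),
    "reference mismatch")
  expect_error(classify_variant_effect(g, list(
    chrom = "chrX", pos = 1, ref = "A", alt = "G")),
    "does not match gene")

  # deletion spanning the exon 1 / intron junction
  a <- g$exons$end[1] - 2
  r <- poolscan:::region_base(g, a, 6L)
  expect_warning(ej <- classify_variant_effect(g, list(
    chrom = "chrD", pos = a, ref = r, alt = substr(r, 1, 1))),
    "exon/intron junction")
  expect_equal(ej$effect, "splice_site")
})

test_that("interval screening honors containment, severity ranking and the missense tally", {
  gm <- read_gene_models(fixture_path("synthetic_cx_locus.gff3"),
                         fixture_path("synthetic_cx_locus.fa"))
  vars <- read_variants_vcf(fixture_path("synthetic_cx_variants.vcf"))
  iv <- list(chrom = "chr5", start = 1, end = 1e6, status = "linked")
  rep <- screen_interval_candidates(iv, vars, gm)
  expect_equal(unname(rep$tally[["missense"]]), 2)
  expect_equal(unname(rep$tally[["synonymous"]]), 1)
  expect_true(all(diff(rep$variants$severity) >= 0))  # ranked, stable
  expect_true(all(rep$variants$pos >= iv$start &
                    rep$variants$pos <= iv$end))

  # variants strictly outside the interval yield an empty candidate list
  iv2 <- list(chrom = "chr1", start = 1, end = 1e6, status = "linked")
  rep2 <- screen_interval_candidates(iv2, vars, gm)
  expect_equal(nrow(rep2$variants), 0)

  # single nonsynonymous SNV, single gene
  one <- vars[vars$pos == 170, ]
  rep3 <- screen_interval_candidates(iv, one, gm)
  expect_equal(nrow(rep3$variants), 1)
  expect_equal(rep3$variants$effect, "missense")

  # no gene models in the interval: noncoding-only plus a warning
  expect_warning(rep4 <- screen_interval_candidates(iv, one, list()),
                 "no gene models")
  expect_equal(rep4$variants$effect, "noncoding")
})

test_that("the expression screen flags only significantly reduced genes", {
  ex <- data.frame(gene_id = c("flat", "planted", "up"),
                   mut_count = c(400, 100, 800),
                   wt_count = c(400, 500, 400))
  attr(ex, "lib_size") <- c(mut = 10000, wt = 10000)
  res <- expression_screen(ex, c("flat", "planted", "up"))
  expect_equal(res$flagged, c(FALSE, TRUE, FALSE))
  expect_lt(res$fold_change[res$gene_id == "planted"], 0.5)

  same <- data.frame(gene_id = "g", mut_count = 300, wt_count = 300)
  expect_false(expression_screen(same, "g")$flagged)

  expect_warning(expression_screen(ex, c("flat", "ghost")),
                 "absent from expression table")
})
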