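#' Simulate a marker genome for a mapping cross
#'
#' Builds a genome model for bulked-segregant simulations: a set of
#' chromosomes, each carrying strain-diagnostic biallelic SNP markers at
#' random positions, and optionally simple two-exon gene models with random
#' coding sequences. Defaults mirror a zebrafish-like genome: 25 chromosomes
#' of 50 Mb / 100 cM each.
#'
#' Marker positions are drawn uniformly then sorted, so they are strictly
#' increasing within a chromosome. Every marker segregates 0.5/0.5 in the F1
#' of an interstrain cross: the reference allele marks one parental strain
#' background, the alternate allele the other.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param markers_per_chrom markers per chromosome (>= 1).
#' @param genes_per_chrom two-exon gene models to place per chromosome
#'   (>= 0).
#' @param chrom_length_bp physical chromosome length in bp (recycled across
#'   chromosomes).
#' @param genetic_length_cM genetic chromosome length in centimorgans
#'   (recycled; > 0 unless recombination is deliberately suppressed with 0).
#' @param seed integer seed; the model is deterministic given the seed.
#' @return An object of class `genome_model`: a list with `chromosomes`
#'   (data.frame: `name`, `length_bp`, `length_cM`), `markers` (data.frame:
#'   `chrom`, `pos`, `ref`, `alt`) and `genes` (list of [gene_model()]
#'   objects).
#' @examples
#' g <- simulate_genome(n_chrom = 2, markers_per_chrom = 20, seed = 1)
#' head(g$markers)
#' @export
simulate_genome <- function(n_chrom = 25, markers_per_chrom = 200,
                            genes_per_chrom = 3, chrom_length_bp = 5e7,
                            genetic_length_cM = 100, seed = 1) {
  if (n_chrom < 1 || markers_per_chrom < 1)
    stop("n_chrom and markers_per_chrom must be >= 1", call. = FALSE)
  if (genes_per_chrom < 0)
    stop("genes_per_chrom must be >= 0", call. = FALSE)
  if (any(genetic_length_cM < 0))
    stop("genetic_length_cM must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))

  len_bp <- rep_len(as.numeric(chrom_length_bp), n_chrom)
  len_cM <- rep_len(as.numeric(genetic_length_cM), n_chrom)
  chroms <- data.frame(
    name = paste0("chr", seq_len(n_chrom)),
    length_bp = len_bp,
    length_cM = len_cM,
    stringsAsFactors = FALSE
  )

  bases <- c("A", "C", "G", "T")
  markers <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    pos <- sort(sample.int(len_bp[i] - 1L, markers_per_chrom))
    ref <- sample(bases, markers_per_chrom, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    data.frame(chrom = chroms$name[i], pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }))
  rownames(markers) <- NULL

  genes <- list()
  if (genes_per_chrom > 0) {
    for (i in seq_len(n_chrom)) {
      # spaced anchors (mid-chromosome included for odd counts) so gene
      # spans never overlap
      anchors <- round(seq(0.25, 0.75, length.out = genes_per_chrom) *
                         len_bp[i])
      for (j in seq_len(genes_per_chrom)) {
        id <- sprintf("gene_%s_%d", chroms$name[i], j)
        genes[[id]] <- random_two_exon_gene(
          id = id, chrom = chroms$name[i],
          region_start = anchors[j] + sample.int(1e4, 1L),
          strand = sample(c("+", "-"), 1L),
          n_codons = sample(100:300, 1L)
        )
      }
    }
  }

  structure(list(chromosomes = chroms, markers = markers, genes = genes),
            class = "genome_model")
}

#' @method print genome_model
#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$markers), "markers,", length(x$genes), "genes\n")
  invisible(x)
}

#' Construct a gene model
#'
#' A gene model anchors a spliced coding sequence to genomic coordinates:
#' exon intervals (1-based inclusive, ascending on the genome regardless of
#' strand), the strand, and the genomic sequence of the gene's span so that
#' variants can be checked against the reference and mapped into the CDS.
#'
#' The spliced CDS (exonic sequence concatenated in transcription order,
#' reverse-complemented for minus-strand genes) is validated: length
#' divisible by 3, starts with ATG, ends with a stop codon. Violations warn
#' but do not fail, mirroring how imperfect annotations are handled in
#' practice.
#'
#' @param id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (1-based inclusive, genomic,
#'   ascending, non-overlapping). Treated as CDS unless `cds` is given.
#' @param region_start genomic coordinate of the first base of `region_seq`.
#' @param region_seq character string of genome (forward-strand) sequence
#'   covering at least the full exon span.
#' @param cds optional data.frame like `exons` restricting the coding part.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(id, chrom, strand, exons, region_start, region_seq,
                       cds = exons) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (any(exons$end < exons$start) ||
      (nrow(exons) > 1 && any(utils::head(exons$end, -1) >=
                              utils::tail(exons$start, -1))))
    stop("exons must be non-overlapping, ordered intervals", call. = FALSE)
  span_end <- max(exons$end)
  if (region_start > min(exons$start) ||
      region_start + nchar(region_seq) - 1 < span_end)
    stop("region_seq does not cover the exon span of gene ", id,
         call. = FALSE)
  g <- structure(list(id = id, chrom = chrom, strand = strand,
                      exons = exons, cds = cds,
                      region_start = as.numeric(region_start),
                      region_seq = toupper(region_seq)),
                 class = "gene_model")
  s <- spliced_cds(g)
  if (nchar(s) %% 3 != 0)
    warning("gene ", id, ": spliced CDS length not divisible by 3",
            call. = FALSE)
  else {
    if (substr(s, 1, 3) != "ATG")
      warning("gene ", id, ": CDS does not begin with ATG", call. = FALSE)
    if (!substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
      warning("gene ", id, ": CDS does not end with a stop codon",
              call. = FALSE)
  }
  g
}

#' @method print gene_model
#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s  %s:%d-%d (%s), %d exon(s), CDS %d bp\n",
              x$id, x$chrom, min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), nchar(spliced_cds(x))))
  invisible(x)
}

# genomic base at a position inside the gene's sequenced region
region_base <- function(gene, pos, n = 1L) {
  off <- pos - gene$region_start + 1
  if (off < 1 || off + n - 1 > nchar(gene$region_seq)) return(NA_character_)
  substr(gene$region_seq, off, off + n - 1)
}

#' Spliced coding sequence of a gene model
#'
#' @param gene a [gene_model()].
#' @return Character string: CDS in transcription order (5' to 3' on the
#'   coding strand).
#' @export
spliced_cds <- function(gene) {
  parts <- vapply(seq_len(nrow(gene$cds)), function(i) {
    region_base(gene, gene$cds$start[i],
                gene$cds$end[i] - gene$cds$start[i] + 1L)
  }, "")
  s <- paste(parts, collapse = "")
  if (gene$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# genomic positions of CDS bases in transcription order
cds_positions <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$cds)),
                       function(i) gene$cds$start[i]:gene$cds$end[i]))
  if (gene$strand == "-") pos <- rev(pos)
  pos
}

#' Build a two-exon gene model from an explicit CDS
#'
#' Splits the given spliced CDS across two exons after `exon1_cds_len`
#' transcribed bases (the intron may interrupt a codon), inserts the intron
#' sequence, and lays the arrangement onto the genome on the requested
#' strand: for minus-strand genes the genomic region holds the reverse
#' complement and the exon order on the genome is the reverse of the
#' transcription order. Two-exon structure reflects the compact
#' connexin-family gene architecture this toolkit is aimed at.
#'
#' @param id,chrom,strand,region_start as in [gene_model()].
#' @param cds_seq spliced CDS, 5' to 3' on the coding strand.
#' @param exon1_cds_len transcribed bases in the first exon
#'   (`1 <= exon1_cds_len < nchar(cds_seq)`).
#' @param intron_seq intron sequence (coding-strand orientation).
#' @return A [gene_model()].
#' @export
two_exon_gene <- function(id, chrom, strand, region_start, cds_seq,
                          exon1_cds_len, intron_seq) {
  L <- nchar(cds_seq)
  stopifnot(exon1_cds_len >= 1, exon1_cds_len < L, nchar(intron_seq) >= 1)
  e1 <- exon1_cds_len
  intron_length <- nchar(intron_seq)
  layout <- paste0(substr(cds_seq, 1, e1), intron_seq,
                   substr(cds_seq, e1 + 1, L))
  if (strand == "-") {
    region_seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(layout)))
    lens <- c(L - e1, e1)                   # ascending genomic order
  } else {
    region_seq <- layout
    lens <- c(e1, L - e1)
  }
  s1 <- region_start
  exons <- data.frame(
    start = c(s1, s1 + lens[1] + intron_length),
    end = c(s1 + lens[1] - 1L, s1 + lens[1] + intron_length + lens[2] - 1L)
  )
  gene_model(id = id, chrom = chrom, strand = strand, exons = exons,
             region_start = region_start, region_seq = region_seq)
}

#' Generate a random two-exon gene model
#'
#' Draws a random CDS (ATG start, internal sense codons, TAA stop), splits
#' it across two exons at a random point, pads with a random intron, and
#' places it via [two_exon_gene()].
#'
#' @param id,chrom,strand,region_start as in [gene_model()].
#' @param n_codons CDS length in codons, including start and stop (>= 3).
#' @param intron_length intron length in bp.
#' @return A [gene_model()].
#' @export
random_two_exon_gene <- function(id, chrom, strand = "+", region_start = 1000,
                                 n_codons = 150, intron_length = 500) {
  stopifnot(n_codons >= 3, intron_length >= 1)
  sense <- setdiff(all_codons(), c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG",
                paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""),
                "TAA")
  two_exon_gene(id = id, chrom = chrom, strand = strand,
                region_start = region_start, cds_seq = cds,
                exon1_cds_len = sample.int(nchar(cds) - 1L, 1L),
                intron_seq = paste(sample(c("A", "C", "G", "T"),
                                          intron_length, replace = TRUE),
                                   collapse = ""))
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
}
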