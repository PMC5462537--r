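# shared fixture builders and independent oracles

# hand-built genome model with fully controlled marker positions
make_genome <- function(marker_pos, length_bp = 5e7, length_cM = 100,
                        genes = list()) {
  chroms <- data.frame(name = names(marker_pos),
                       length_bp = rep_len(length_bp, length(marker_pos)),
                       length_cM = rep_len(length_cM, length(marker_pos)),
                       stringsAsFactors = FALSE)
  markers <- do.call(rbind, lapply(names(marker_pos), function(cn) {
    data.frame(chrom = cn, pos = sort(marker_pos[[cn]]), ref = "A",
               alt = "G", stringsAsFactors = FALSE)
  }))
  rownames(markers) <- NULL
  structure(list(chromosomes = chroms, markers = markers, genes = genes),
            class = "genome_model")
}

# naive O(n*w) centered running mean; the independent oracle for the
# sliding-window statistic (same centering convention: for even w the
# window extends one marker further to the right)
naive_window_mean <- function(x, w) {
  n <- length(x)
  left <- (w - 1) %/% 2
  right <- w - 1 - left
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  for (i in seq_len(n)) {
    if (i - left >= 1 && i + right <= n)
      out[i] <- mean(x[(i - left):(i + right)])
  }
  out
}

# full-sequence translate-and-compare oracle for SNV consequence calls:
# mutates the spliced CDS, translates reference and mutant with
# Biostrings::translate, and derives the effect from the amino-acid pair
oracle_snv_effect <- function(cds_seq, cds_idx, alt_base_coding) {
  mut <- cds_seq
  substr(mut, cds_idx, cds_idx) <- alt_base_coding
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X"))
  p_ref <- tr(cds_seq)
  p_mut <- tr(mut)
  ci <- (cds_idx - 1) %/% 3 + 1
  ref_aa <- substr(p_ref, ci, ci)
  alt_aa <- substr(p_mut, ci, ci)
  if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "nonsense"
  else if (ref_aa == "*") "stop_loss"
  else "missense"
}

# deterministic CDS carrying all 64 codons once, framed by start and stop
all_codon_cds <- function() {
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# marker count table with explicit values, for filter/profile tests
make_counts <- function(chrom, pos, mut_ref, mut_alt, wt_ref = 25,
                        wt_alt = 25) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             mut_ref = mut_ref, mut_alt = mut_alt,
             wt_ref = rep_len(wt_ref, length(pos)),
             wt_alt = rep_len(wt_alt, length(pos)),
             stringsAsFactors = FALSE)
}

fixture_path <- function(file)
  system.file("extdata", file, package = "poolscan", mustWork = TRUE)
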