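# severity tiers for candidate ranking: truncating > missense > splice >
# silent/noncoding; total and deterministic
severity_order <- c(nonsense = 1L, frameshift = 2L, stop_loss = 3L,
                    missense = 4L, in_frame_indel = 5L, splice_site = 6L,
                    synonymous = 7L, noncoding = 8L)

complement_base <- function(b)
  chartr("ACGT", "TGCA", b)

# left-align a VCF-style anchored indel against the gene's reference
# sequence; returns list(pos, ref, alt)
normalize_indel <- function(gene, pos, ref, alt) {
  # trim shared suffix, then shared prefix beyond the anchor base
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  if (nchar(ref) > 1 && nchar(alt) == 1) {          # deletion
    repeat {
      prev <- region_base(gene, pos)
      last <- substr(ref, nchar(ref), nchar(ref))
      if (is.na(prev) || prev != last || pos - 1 < gene$region_start) break
      before <- region_base(gene, pos - 1)
      if (is.na(before)) break
      ref <- paste0(before, substr(ref, 1, nchar(ref) - 1))
      alt <- before
      pos <- pos - 1
    }
  } else if (nchar(alt) > 1 && nchar(ref) == 1) {   # insertion
    repeat {
      anchor <- region_base(gene, pos)
      last <- substr(alt, nchar(alt), nchar(alt))
      if (is.na(anchor) || anchor != last || pos - 1 < gene$region_start)
        break
      before <- region_base(gene, pos - 1)
      if (is.na(before)) break
      alt <- paste0(before, anchor, substr(alt, 2, nchar(alt) - 1))
      ref <- before
      pos <- pos - 1
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

# genomic positions within `d` bp of an exon boundary, on the intron side
near_splice <- function(gene, positions, d = 2L) {
  edges <- c(gene$exons$start, gene$exons$end)
  vapply(positions, function(p) {
    any(abs(p - edges) <= d)
  }, TRUE)
}

#' Classify the coding consequence of a variant against a gene model
#'
#' Maps a genomic variant into the gene's spliced CDS (strand-aware) and
#' classifies it: SNVs are translated codon-by-codon with the standard
#' nuclear genetic code (synonymous, missense, nonsense, stop_loss); indels
#' are left-aligned against the reference and classed frameshift when the
#' length difference is not divisible by 3, in_frame_indel otherwise.
#' Intronic positions within 2 bp of an exon boundary are splice_site;
#' other non-CDS positions are noncoding. Indels spanning an exon/intron
#' junction are splice_site with a warning. The variant's reference allele
#' is checked against the gene's reference sequence; a mismatch is a
#' data-integrity error.
#'
#' @param gene a [gene_model()].
#' @param variant list or one-row data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt` (VCF conventions: anchored indels).
#' @return A list of class `variant_effect`: `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `effect`, `codon_change` (e.g. `"TAC>TAA"`, SNVs in CDS
#'   only), `aa_change` (list: `pos`, `ref`, `alt`), `severity`.
#' @examples
#' g <- random_two_exon_gene("g1", "chr1", "+", 100, n_codons = 50)
#' classify_variant_effect(g, list(chrom = "chr1", pos = 100, ref = "A",
#'                                 alt = "G"))  # start-codon SNV
#' @export
classify_variant_effect <- function(gene, variant) {
  stopifnot(inherits(gene, "gene_model"))
  v <- as.list(variant)
  pos <- as.numeric(v$pos)
  ref <- toupper(as.character(v$ref))
  alt <- toupper(as.character(v$alt))
  if (!identical(as.character(v$chrom), gene$chrom))
    stop("variant chromosome ", v$chrom, " does not match gene ", gene$id,
         " on ", gene$chrom, call. = FALSE)

  obs <- region_base(gene, pos, nchar(ref))
  if (!is.na(obs) && obs != ref)
    stop(sprintf("reference mismatch at %s:%d: expected %s, got %s",
                 gene$chrom, as.integer(pos), obs, ref), call. = FALSE)

  mk <- function(effect, codon_change = NA_character_, aa_change = NULL)
    structure(list(chrom = gene$chrom, pos = pos, ref = ref, alt = alt,
                   gene_id = gene$id, effect = effect,
                   codon_change = codon_change, aa_change = aa_change,
                   severity = severity_order[[effect]]),
              class = "variant_effect")

  cdspos <- cds_positions(gene)
  span <- range(gene$exons$start, gene$exons$end)
  in_exon <- function(p) any(p >= gene$exons$start & p <= gene$exons$end)

  if (nchar(ref) == 1 && nchar(alt) == 1) {       # SNV
    idx <- match(pos, cdspos)
    if (!is.na(idx)) {
      s <- spliced_cds(gene)
      ci <- (idx - 1L) %/% 3L
      within <- (idx - 1L) %% 3L
      if ((ci + 1L) * 3L > nchar(s))
        return(mk("noncoding"))                   # trailing partial codon
      ref_codon <- substr(s, ci * 3L + 1L, ci * 3L + 3L)
      alt_base <- if (gene$strand == "-") complement_base(alt) else alt
      alt_codon <- ref_codon
      substr(alt_codon, within + 1L, within + 1L) <- alt_base
      ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
      alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
      effect <- if (ref_aa == alt_aa) "synonymous"
        else if (alt_aa == "*") "nonsense"
        else if (ref_aa == "*") "stop_loss"
        else "missense"
      return(mk(effect,
                codon_change = paste0(ref_codon, ">", alt_codon),
                aa_change = list(pos = ci + 1L, ref = ref_aa,
                                 alt = alt_aa)))
    }
    if (in_exon(pos)) return(mk("noncoding"))     # exonic, non-CDS (UTR)
    if (pos >= span[1] && pos <= span[2] && near_splice(gene, pos))
      return(mk("splice_site"))
    return(mk("noncoding"))
  }

  # indel: left-align, then locate the affected bases
  nv <- normalize_indel(gene, pos, ref, alt)
  pos <- nv$pos; ref <- nv$ref; alt <- nv$alt
  if (nchar(ref) > 1 && nchar(alt) > 1)
    stop("complex substitution at ", gene$chrom, ":", as.integer(pos),
         " is not supported; split into SNVs/indels", call. = FALSE)
  if (nchar(ref) > 1) {                           # deletion
    affected <- (pos + 1):(pos + nchar(ref) - 1)
  } else {                                        # insertion between pos,
    affected <- c(pos, pos + 1)                   # pos+1
  }
  indel_len <- abs(nchar(ref) - nchar(alt))
  in_cds <- affected %in% cdspos
  if (all(in_cds)) {
    effect <- if (indel_len %% 3L != 0L) "frameshift" else "in_frame_indel"
    return(mk(effect))
  }
  if (any(in_cds)) {
    warning("indel at ", gene$chrom, ":", as.integer(pos),
            " spans an exon/intron junction; classified splice_site",
            call. = FALSE)
    return(mk("splice_site"))
  }
  if (any(affected >= span[1] & affected <= span[2]) &&
      any(near_splice(gene, affected)))
    return(mk("splice_site"))
  mk("noncoding")
}

#' @method print variant_effect
#' @export
print.variant_effect <- function(x, ...) {
  aa <- if (!is.null(x$aa_change))
    sprintf(" p.%s%d%s", x$aa_change$ref, x$aa_change$pos, x$aa_change$alt)
  else ""
  cat(sprintf("%s:%d %s>%s  %s  [%s]%s\n", x$chrom, as.integer(x$pos),
              x$ref, x$alt, x$effect, x$gene_id, aa))
  invisible(x)
}

#' Screen a linkage interval for candidate causative lesions
#'
#' Classifies every variant overlapping the interval against the supplied
#' gene models, ranks candidates by severity (nonsense/frameshift >
#' missense > splice > synonymous/noncoding), tallies effect classes, and —
#' when expression counts are supplied — flags interval genes with
#' significantly reduced expression in the mutant pool.
#'
#' @param interval a `linkage_interval` (from [find_linkage_region()] or a
#'   [linkage_scan()] fit's `$interval`), or a list with `chrom`, `start`,
#'   `end`.
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, sorted by
#'   position.
#' @param gene_models list of [gene_model()] objects.
#' @param expression optional per-gene count table (see [simulate_cross()]).
#' @param alpha,min_fold expression-screen thresholds, see
#'   [expression_screen()].
#' @return A list of class `candidate_report`: `interval`, `variants`
#'   (classified, severity-ranked data.frame), `tally` (named counts per
#'   effect class), `reduced_expression` (data.frame or `NULL`).
#' @export
screen_interval_candidates <- function(interval, variants, gene_models,
                                       expression = NULL, alpha = 0.05,
                                       min_fold = 0.5) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (inherits(interval, "linkage_interval") &&
      interval$status != "linked")
    stop("cannot screen candidates: no linkage interval was called",
         call. = FALSE)
  inside <- variants$chrom == interval$chrom &
    variants$pos >= interval$start & variants$pos <= interval$end
  v <- variants[inside, , drop = FALSE]

  spans <- if (length(gene_models))
    data.frame(id = vapply(gene_models, `[[`, "", "id"),
               chrom = vapply(gene_models, `[[`, "", "chrom"),
               start = vapply(gene_models, function(g) min(g$exons$start), 0),
               end = vapply(gene_models, function(g) max(g$exons$end), 0),
               stringsAsFactors = FALSE)
  else data.frame(id = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0))
  interval_gene_ids <- spans$id[spans$chrom == interval$chrom &
                                  spans$end >= interval$start &
                                  spans$start <= interval$end]
  if (length(interval_gene_ids) == 0 && nrow(v) > 0)
    warning("no gene models overlap the interval; variants classified ",
            "noncoding", call. = FALSE)

  effects <- lapply(seq_len(nrow(v)), function(i) {
    gi <- which(spans$chrom == v$chrom[i] & spans$start <= v$pos[i] &
                  spans$end >= v$pos[i])
    if (length(gi) == 0)
      return(list(gene_id = NA_character_, effect = "noncoding",
                  codon_change = NA_character_, aa = NA_character_,
                  severity = severity_order[["noncoding"]]))
    e <- classify_variant_effect(gene_models[[gi[1]]], v[i, ])
    list(gene_id = e$gene_id, effect = e$effect,
         codon_change = e$codon_change,
         aa = if (is.null(e$aa_change)) NA_character_ else
           sprintf("p.%s%d%s", e$aa_change$ref, e$aa_change$pos,
                   e$aa_change$alt),
         severity = e$severity)
  })
  cls <- data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    gene_id = vapply(effects, `[[`, "", "gene_id"),
    effect = vapply(effects, `[[`, "", "effect"),
    codon_change = vapply(effects, `[[`, "", "codon_change"),
    aa_change = vapply(effects, `[[`, "", "aa"),
    severity = vapply(effects, `[[`, 1L, "severity"),
    stringsAsFactors = FALSE)
  cls <- cls[order(cls$severity, cls$chrom, cls$pos), , drop = FALSE]
  rownames(cls) <- NULL

  tally <- table(factor(cls$effect, levels = names(severity_order)))
  reduced <- NULL
  if (!is.null(expression) && length(interval_gene_ids))
    reduced <- expression_screen(expression, interval_gene_ids,
                                 alpha = alpha, min_fold = min_fold)

  structure(list(interval = interval, variants = cls,
                 tally = c(tally), reduced_expression = reduced),
            class = "candidate_report")
}

#' @method print candidate_report
#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("Candidate report for interval %s:%s-%s\n",
              x$interval$chrom, format(x$interval$start, big.mark = ","),
              format(x$interval$end, big.mark = ",")))
  nz <- x$tally[x$tally > 0]
  cat("  effect tallies:",
      if (length(nz)) paste(names(nz), nz, sep = "=", collapse = ", ")
      else "none", "\n")
  top <- x$variants[x$variants$severity <= severity_order[["missense"]], ,
                    drop = FALSE]
  if (nrow(top)) {
    cat("  damaging candidates:\n")
    print(top[, c("chrom", "pos", "ref", "alt", "gene_id", "effect",
                  "aa_change")], row.names = FALSE)
  }
  if (!is.null(x$reduced_expression)) {
    fl <- x$reduced_expression[x$reduced_expression$flagged, , drop = FALSE]
    cat("  reduced-expression genes:",
        if (nrow(fl)) paste(fl$gene_id, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' Screen interval genes for reduced expression in the mutant pool
#'
#' For each gene, computes the mutant/wildtype fold change on library-size-
#' normalized counts and a two-sided binomial test of the mutant-pool count
#' against its expectation under equal expression (the gene's pooled count
#' split by library-size proportion). Genes with fold change at or below
#' `min_fold` and Benjamini-Hochberg adjusted p at or below `alpha` are
#' flagged as reduced; increased expression is never flagged.
#'
#' @param expression data.frame with `gene_id`, `mut_count`, `wt_count`;
#'   library sizes taken from its `"lib_size"` attribute or computed as
#'   column sums.
#' @param genes character vector of gene ids to test (genes absent from the
#'   table are skipped with a warning).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param min_fold maximum fold change still called "reduced" (default 0.5).
#' @return data.frame: `gene_id`, `mut_count`, `wt_count`, `fold_change`,
#'   `p_value`, `p_adj`, `flagged`.
#' @export
expression_screen <- function(expression, genes, alpha = 0.05,
                              min_fold = 0.5) {
  stopifnot(all(c("gene_id", "mut_count", "wt_count") %in%
                  names(expression)))
  if (any(expression$mut_count < 0 | expression$wt_count < 0))
    stop("expression counts must be non-negative", call. = FALSE)
  lib <- attr(expression, "lib_size")
  if (is.null(lib))
    lib <- c(mut = sum(expression$mut_count),
             wt = sum(expression$wt_count))
  if (any(lib <= 0)) stop("library sizes must be > 0", call. = FALSE)

  missing <- setdiff(genes, expression$gene_id)
  if (length(missing))
    warning("gene(s) absent from expression table, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  rows <- expression[expression$gene_id %in% genes, , drop = FALSE]
  if (nrow(rows) == 0)
    return(data.frame(gene_id = character(0), mut_count = integer(0),
                      wt_count = integer(0), fold_change = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      flagged = logical(0)))

  p_mut <- lib[["mut"]] / sum(lib)
  res <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    m <- rows$mut_count[i]; w <- rows$wt_count[i]
    fold <- (m / lib[["mut"]]) / (w / lib[["wt"]])
    p <- if (m + w == 0) 1 else
      stats::binom.test(m, m + w, p = p_mut)$p.value
    data.frame(gene_id = rows$gene_id[i], mut_count = m, wt_count = w,
               fold_change = fold, p_value = p, stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res$flagged <- !is.na(res$fold_change) & res$fold_change <= min_fold &
    res$p_adj <= alpha
  rownames(res) <- NULL
  res
}
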