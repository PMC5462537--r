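#' Write a marker count table as a two-sample VCF
#'
#' Emits plain-text VCF 4.2 with samples `MUT` and `WT` carrying
#' `FORMAT AD:DP` (allelic depths ref,alt and total depth), positions
#' 1-based.
#'
#' @param counts marker count data.frame (see [select_mapping_markers()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_vcf <- function(counts, path) {
  check_counts(counts)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolscan",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0("##contig=<ID=", unique(counts$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "MUT", "WT"), collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
                  counts$chrom, as.integer(counts$pos), counts$ref,
                  counts$alt, counts$mut_ref, counts$mut_alt,
                  counts$mut_ref + counts$mut_alt, counts$wt_ref,
                  counts$wt_alt, counts$wt_ref + counts$wt_alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a two-pool marker count table from VCF
#'
#' Parses a VCF 4.x file with samples `MUT` and `WT` carrying `FORMAT AD`.
#' Biallelic SNV records are kept; multiallelic or indel records are
#' skipped with a message. Records are sorted by (chrom, pos) with a
#' warning if the input was unsorted.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return Marker count data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt`.
#' @export
read_counts_vcf <- function(path) {
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      mut_ref = integer(0), mut_alt = integer(0),
                      wt_ref = integer(0), wt_alt = integer(0))
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (nrow(v@fix) == 0) return(empty)
  smp <- colnames(v@gt)[-1]
  if (!all(c("MUT", "WT") %in% smp))
    stop("VCF must contain samples MUT and WT; found: ",
         paste(smp, collapse = ", "), call. = FALSE)
  fmt <- v@gt[, "FORMAT"]
  if (any(!grepl("(^|:)AD(:|$)", fmt)))
    stop("record ", which(!grepl("(^|:)AD(:|$)", fmt))[1],
         " lacks the AD FORMAT field", call. = FALSE)

  chrom <- v@fix[, "CHROM"]
  pos <- as.numeric(v@fix[, "POS"])
  ref <- v@fix[, "REF"]
  alt <- v@fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 &
    nchar(alt) == 1
  if (any(!keep))
    message(sum(!keep), " multiallelic/non-SNV record(s) skipped")

  ad <- vcfR::extract.gt(v, element = "AD")
  split_ad <- function(x) {
    m <- do.call(rbind, strsplit(x, ",", fixed = TRUE))
    matrix(as.integer(m), nrow = nrow(m))
  }
  mut <- split_ad(ad[, "MUT"])
  wt <- split_ad(ad[, "WT"])
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    mut_ref = mut[, 1], mut_alt = mut[, 2],
                    wt_ref = wt[, 1], wt_alt = wt[, 2],
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  ord <- order(match(out$chrom, unique(out$chrom)), out$pos)
  if (any(ord != seq_along(ord))) {
    warning("input VCF was not sorted; sorting by (chrom, pos)",
            call. = FALSE)
    out <- out[ord, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write / read a marker count table as TSV
#'
#' Tab-separated with columns `chrom`, `pos`, `ref`, `alt`, `mut_ref`,
#' `mut_alt`, `wt_ref`, `wt_alt`. Comment lines beginning `#` record
#' provenance (e.g. the marker filter applied) and are skipped on read.
#'
#' @param counts marker count data.frame.
#' @param path file path.
#' @param comments optional character vector written as leading `# ` lines.
#' @return `path` (write) / the data.frame (read).
#' @export
write_counts_tsv <- function(counts, path, comments = NULL) {
  check_counts(counts)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  out <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  check_counts(out)
  out
}

#' Write / read a per-gene expression count table as TSV
#'
#' @param expression data.frame with `gene_id`, `mut_count`, `wt_count`
#'   (and optionally `chrom`, `start`, `end`); the `lib_size` attribute is
#'   stored in `#` header lines and restored on read.
#' @param path file path.
#' @export
write_expression_tsv <- function(expression, path) {
  lib <- attr(expression, "lib_size")
  if (is.null(lib))
    lib <- c(mut = sum(expression$mut_count),
             wt = sum(expression$wt_count))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lib_size_mut=%d", as.integer(lib[["mut"]])), con)
  writeLines(sprintf("# lib_size_wt=%d", as.integer(lib[["wt"]])), con)
  utils::write.table(expression, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  out <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  get <- function(key) {
    m <- grep(paste0(key, "="), hdr, value = TRUE)
    if (length(m)) as.integer(sub(paste0(".*", key, "="), "", m[1]))
    else NA_integer_
  }
  lib <- c(mut = get("lib_size_mut"), wt = get("lib_size_wt"))
  if (!anyNA(lib)) attr(out, "lib_size") <- lib
  out
}

#' Write a per-marker allele-frequency profile as TSV
#'
#' @param scan a [linkage_scan()] fit or its `$profile` data.frame.
#' @param path file path.
#' @export
write_profile_tsv <- function(scan, path) {
  pr <- if (inherits(scan, "linkage_scan")) scan$profile else scan
  utils::write.table(pr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a linkage interval to and from BED
#'
#' The report and VCF use 1-based inclusive coordinates; BED is 0-based
#' half-open, so `start_bed = start - 1`, `end_bed = end`.
#'
#' @param interval a `linkage_interval` (status `"linked"`).
#' @param path BED file path.
#' @return `write_interval_bed`: `path` invisibly; `read_interval_bed`: a
#'   list with `chrom`, `start`, `end` (1-based inclusive) and `name`.
#' @export
write_interval_bed <- function(interval, path) {
  if (interval$status != "linked")
    stop("no linkage interval to write", call. = FALSE)
  line <- sprintf("%s\t%d\t%d\t%s\t%d", interval$chrom,
                  as.integer(interval$start) - 1L,
                  as.integer(interval$end), "linkage_interval",
                  as.integer(round(1000 * interval$peak_window_freq)))
  writeLines(line, path)
  invisible(path)
}

#' @rdname write_interval_bed
#' @export
read_interval_bed <- function(path) {
  f <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  list(chrom = f$V1[1], start = f$V2[1] + 1L, end = f$V3[1],
       name = if (ncol(f) >= 4) f$V4[1] else NA_character_)
}

#' Read gene models from GFF3 + FASTA
#'
#' Builds [gene_model()] objects from a GFF3 annotation and the reference
#' sequence of its contigs: CDS features are grouped by their `Parent`
#' transcript, exon features (if present) define the exon intervals, and
#' each model carries the genomic sequence of its span for reference
#' checking and CDS extraction.
#'
#' @param gff_path GFF3 file path.
#' @param fasta_path FASTA file path with the contigs named in the GFF3.
#' @return Named list of [gene_model()] objects (one per transcript).
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff_path)
  df <- as.data.frame(gr)
  parent_of <- function(d)
    vapply(d$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           "")
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) stop("no CDS features in ", gff_path, call. = FALSE)
  cds$parent <- parent_of(cds)
  exons <- df[df$type == "exon", , drop = FALSE]
  if (nrow(exons)) exons$parent <- parent_of(exons)

  models <- list()
  for (tx in unique(cds$parent)) {
    cc <- cds[cds$parent == tx, , drop = FALSE]
    ee <- if (nrow(exons) && any(exons$parent == tx))
      exons[exons$parent == tx, , drop = FALSE] else cc
    chrom <- as.character(cc$seqnames[1])
    if (!chrom %in% names(seqs))
      stop("contig ", chrom, " absent from ", fasta_path, call. = FALSE)
    span <- range(c(ee$start, ee$end))
    region_seq <- as.character(
      Biostrings::subseq(seqs[[chrom]], span[1], span[2]))
    id <- sub("^(transcript|mRNA):", "", tx)
    models[[id]] <- gene_model(
      id = id, chrom = chrom, strand = as.character(cc$strand[1]),
      exons = data.frame(start = ee$start, end = ee$end),
      cds = data.frame(start = cc$start, end = cc$end),
      region_start = span[1], region_seq = region_seq)
  }
  models
}

#' Read simple variants from a VCF
#'
#' Extracts `chrom`, `pos`, `ref`, `alt` for all records (sample columns,
#' if any, are ignored). Multiallelic records are split into one row per
#' alternate allele.
#'
#' @param path VCF file path.
#' @return data.frame sorted by (chrom, pos).
#' @export
read_variants_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (nrow(v@fix) == 0)
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0)))
  alt_split <- strsplit(v@fix[, "ALT"], ",", fixed = TRUE)
  n <- lengths(alt_split)
  out <- data.frame(chrom = rep(v@fix[, "CHROM"], n),
                    pos = rep(as.numeric(v@fix[, "POS"]), n),
                    ref = rep(v@fix[, "REF"], n),
                    alt = unlist(alt_split), stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the simulator ground truth as a YAML sidecar
#'
#' Records the causative locus, marker row, planted reduced-expression
#' gene, phenotyping-error tally, pool sizes and seed (not the per-
#' individual matrices, which stay in memory).
#'
#' @param truth a `cross_truth` (from [simulate_cross()]).
#' @param path output file path.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "cross_truth"))
  x <- list(
    causative = list(chrom = truth$causative$chrom,
                     pos = as.integer(truth$causative$pos)),
    causative_marker_row = if (is.na(truth$causative_marker)) NULL
      else as.integer(truth$causative_marker),
    planted_gene = truth$planted_gene,
    n_phenotyping_errors = as.integer(truth$n_phenotyping_errors),
    n_mutant_pool = truth$config$n_mutant_pool,
    n_wildtype_pool = truth$config$n_wildtype_pool,
    seed = truth$seed)
  yaml::write_yaml(x, path)
  invisible(path)
}
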