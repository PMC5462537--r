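#' Filter settings for mapping-marker discovery
#'
#' Mapping markers are SNPs that segregate in the wildtype-sibling pool:
#' positions heterozygous across the F1-derived sibling chromosomes, hence
#' informative for linkage. A position qualifies when the wildtype pool has
#' adequate depth and an intermediate alternate-allele fraction.
#'
#' @param min_depth minimum wildtype-pool depth (ref + alt reads);
#'   default 20.
#' @param wt_af_min,wt_af_max wildtype-pool alternate-allele fraction window
#'   (inclusive); defaults 0.2 and 0.8.
#' @param min_mut_depth optional minimum mutant-pool depth; default 0 (off):
#'   markers qualify on wildtype-pool evidence alone, and mutant-pool
#'   no-data markers are handled downstream.
#' @return A list of class `marker_filter`.
#' @export
marker_filter <- function(min_depth = 20, wt_af_min = 0.2, wt_af_max = 0.8,
                          min_mut_depth = 0) {
  if (min_depth < 1) stop("min_depth must be >= 1", call. = FALSE)
  if (!(wt_af_min >= 0 && wt_af_min < wt_af_max && wt_af_max <= 1))
    stop("need 0 <= wt_af_min < wt_af_max <= 1", call. = FALSE)
  structure(list(min_depth = min_depth, wt_af_min = wt_af_min,
                 wt_af_max = wt_af_max, min_mut_depth = min_mut_depth),
            class = "marker_filter")
}

#' Select mapping markers from the wildtype-sibling pool
#'
#' Retains the rows of a marker count table whose wildtype-pool depth and
#' alternate-allele fraction satisfy the filter, preserving input order.
#' Rejection tallies per criterion are attached as the `"rejections"`
#' attribute and reported via `message()`.
#'
#' @param counts marker count data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt` (e.g. from
#'   [simulate_cross()] or [read_counts_vcf()]).
#' @param filter a [marker_filter()].
#' @param quiet suppress the tally message.
#' @return The retained subset of `counts` (same columns, original order),
#'   with attributes `rejections` (named integer vector) and `filter`. An
#'   empty result warns and carries attribute `status = "no markers"`.
#' @examples
#' tab <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "A",
#'                   alt = "G", mut_ref = c(10, 0), mut_alt = c(10, 20),
#'                   wt_ref = c(25, 40), wt_alt = c(25, 0))
#' select_mapping_markers(tab, quiet = TRUE)  # second row is monomorphic
#' @export
select_mapping_markers <- function(counts, filter = marker_filter(),
                                   quiet = FALSE) {
  stopifnot(inherits(filter, "marker_filter"))
  check_counts(counts)
  wt_depth <- counts$wt_ref + counts$wt_alt
  wt_af <- ifelse(wt_depth > 0, counts$wt_alt / wt_depth, NA_real_)
  ok_depth <- wt_depth >= filter$min_depth
  ok_af <- !is.na(wt_af) & wt_af >= filter$wt_af_min &
    wt_af <= filter$wt_af_max
  ok_mut <- (counts$mut_ref + counts$mut_alt) >= filter$min_mut_depth
  keep <- ok_depth & ok_af & ok_mut

  rejections <- c(low_wt_depth = sum(!ok_depth),
                  wt_af_out_of_window = sum(ok_depth & !ok_af),
                  low_mut_depth = sum(ok_depth & ok_af & !ok_mut))
  if (!quiet)
    message(sprintf(
      "mapping markers: %d/%d retained (rejected: %d low wt depth, %d wt AF outside [%.2f, %.2f], %d low mut depth)",
      sum(keep), nrow(counts), rejections[["low_wt_depth"]],
      rejections[["wt_af_out_of_window"]], filter$wt_af_min,
      filter$wt_af_max, rejections[["low_mut_depth"]]))

  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  attr(out, "filter") <- filter
  if (nrow(out) == 0) {
    warning("no markers passed the filter", call. = FALSE)
    attr(out, "status") <- "no markers"
  }
  out
}

check_counts <- function(counts) {
  need <- c("chrom", "pos", "ref", "alt", "mut_ref", "mut_alt",
            "wt_ref", "wt_alt")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("marker count table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  num <- c("mut_ref", "mut_alt", "wt_ref", "wt_alt")
  if (any(vapply(counts[num], function(x) any(x < 0, na.rm = TRUE), TRUE)))
    stop("negative read counts in marker table", call. = FALSE)
  invisible(counts)
}
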