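#' Mutant-pool allele frequency at a marker
#'
#' The fraction of mutant-pool reads carrying the alternate allele,
#' `mut_alt / (mut_ref + mut_alt)`. Markers with zero mutant-pool depth get
#' `NA` ("no-data"); they are excluded from sliding windows downstream.
#'
#' @param mut_ref,mut_alt mutant-pool reference/alternate read counts
#'   (vectorized).
#' @return Numeric vector of frequencies in `[0, 1]`, `NA` at zero depth.
#' @examples
#' mutant_allele_frequency(c(0, 12, 1), c(10, 0, 3))  # 1.0, 0.0, 0.75
#' @export
mutant_allele_frequency <- function(mut_ref, mut_alt) {
  if (any(mut_ref < 0 | mut_alt < 0, na.rm = TRUE))
    stop("read counts must be non-negative", call. = FALSE)
  depth <- mut_ref + mut_alt
  ifelse(depth > 0, mut_alt / depth, NA_real_)
}

#' Fold an allele frequency into a homozygosity score
#'
#' `max(f, 1 - f)`: because the strain of origin of the lesion-bearing
#' haplotype is unknown per marker, the profile is polarized by folding, so
#' homozygosity reads near 1 whichever allele is fixed.
#'
#' @param raw_freq numeric vector in `[0, 1]` (`NA` passed through).
#' @return Folded frequencies in `[0.5, 1]`.
#' @export
fold_frequency <- function(raw_freq) {
  if (any(raw_freq < 0 | raw_freq > 1, na.rm = TRUE))
    stop("raw_freq must lie in [0, 1]", call. = FALSE)
  pmax(raw_freq, 1 - raw_freq)
}

# centered running mean of width w; NA outside full-window positions
window_mean <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (w < 1 || n < w) return(out)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- c(0, cumsum(x))
  idx <- (left + 1L):(n - right)
  out[idx] <- (cs[idx + right + 1L] - cs[idx - left]) / w
  out
}

#' Sliding-window allele-frequency profile
#'
#' Smooths per-marker frequencies with a window of `window` neighboring
#' loci (a marker-count window, not a physical distance): the value at
#' marker i is the arithmetic mean over the window centered at i. Windows
#' never span chromosome boundaries; markers within half a window of a
#' chromosome end, and chromosomes with fewer usable markers than the
#' window, get no window value. No-data markers (`NA` frequency) are
#' excluded: windows run over the usable markers of each chromosome.
#'
#' @param profile data.frame with columns `chrom`, `pos` and the frequency
#'   column named by `value`; sorted by (`chrom`, `pos`).
#' @param window window size in markers (>= 1); default 50.
#' @param value name of the column to average (default `"folded_freq"`).
#' @param quiet suppress messages about short chromosomes.
#' @return `profile` with a `window_freq` column added (`NA` where
#'   undefined).
#' @export
sliding_window_profile <- function(profile, window = 50,
                                   value = "folded_freq", quiet = FALSE) {
  stopifnot(window >= 1, all(c("chrom", "pos", value) %in% names(profile)))
  if (is.unsorted(order(match(profile$chrom, unique(profile$chrom)),
                        profile$pos)))
    stop("profile must be sorted by (chrom, pos)", call. = FALSE)
  profile$window_freq <- NA_real_
  for (cn in unique(profile$chrom)) {
    rows <- which(profile$chrom == cn)
    usable <- rows[!is.na(profile[[value]][rows])]
    if (length(usable) < window) {
      if (!quiet)
        message("chromosome ", cn, ": fewer than ", window,
                " usable markers; no window values")
      next
    }
    profile$window_freq[usable] <-
      window_mean(profile[[value]][usable], window)
  }
  profile
}

#' Call the linkage region from a windowed profile
#'
#' The peak is the global maximum of the windowed frequency (ties broken by
#' the longest plateau, then the lowest genomic coordinate). The interval is
#' the maximal contiguous run of markers around the peak whose windowed
#' frequency stays at or above the delimitation threshold — by default 0.98
#' of the peak height (`threshold_mode = "relative"`); with
#' `threshold_mode = "absolute"` the threshold is
#' `min(peak_threshold, peak)` so the peak marker itself always qualifies.
#' A run that reaches the first or last windowed marker of its chromosome is
#' extended to the chromosome's terminal marker, since the unwindowed flank
#' carries no evidence of decline. A flat profile (max - min < 0.01) yields
#' status `"no_linkage"`.
#'
#' @param profile data.frame with `chrom`, `pos`, `window_freq` (from
#'   [sliding_window_profile()]).
#' @param peak_threshold delimitation threshold in (0.5, 1]; default 0.98.
#' @param threshold_mode `"relative"` (fraction of peak height, default) or
#'   `"absolute"`.
#' @param quiet suppress tie messages.
#' @return A list of class `linkage_interval`: `chrom`, `start`, `end`
#'   (1-based inclusive marker positions), `peak_window_freq`,
#'   `n_markers_in_interval`, `threshold` (the applied absolute cut),
#'   `status` (`"linked"` or `"no_linkage"`), and `chrom_summary` (per-
#'   chromosome maxima, ranked).
#' @export
find_linkage_region <- function(profile, peak_threshold = 0.98,
                                threshold_mode = c("relative", "absolute"),
                                quiet = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  if (!(peak_threshold > 0.5 && peak_threshold <= 1))
    stop("peak_threshold must be in (0.5, 1]", call. = FALSE)
  wf <- profile$window_freq
  def <- which(!is.na(wf))
  if (length(def) == 0)
    stop("no defined window values in profile", call. = FALSE)

  chrom_summary <- do.call(rbind, lapply(unique(profile$chrom[def]),
    function(cn) {
      i <- def[profile$chrom[def] == cn]
      data.frame(chrom = cn, max_window_freq = max(wf[i]),
                 pos_at_max = profile$pos[i[which.max(wf[i])]],
                 stringsAsFactors = FALSE)
    }))
  chrom_summary <-
    chrom_summary[order(-chrom_summary$max_window_freq), , drop = FALSE]
  rownames(chrom_summary) <- NULL

  M <- max(wf[def])
  if (M - min(wf[def]) < 0.01)
    return(structure(list(chrom = NA_character_, start = NA_real_,
                          end = NA_real_, peak_window_freq = M,
                          n_markers_in_interval = 0L, threshold = NA_real_,
                          status = "no_linkage",
                          chrom_summary = chrom_summary),
                     class = "linkage_interval"))
  thr <- if (threshold_mode == "relative") peak_threshold * M
         else min(peak_threshold, M)

  # contiguous runs (within the defined-window sequence of one chromosome)
  # with window_freq >= thr that contain a global peak marker
  runs <- list()
  for (cn in unique(profile$chrom[def])) {
    i <- def[profile$chrom[def] == cn]
    above <- wf[i] >= thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- i[starts[k]:ends[k]]
      if (any(wf[seg] == M))
        runs[[length(runs) + 1L]] <-
          list(chrom = cn, rows = seg,
               at_left_edge = starts[k] == 1L,
               at_right_edge = ends[k] == length(i))
    }
  }
  lens <- vapply(runs, function(r) length(r$rows), 0L)
  best <- which(lens == max(lens))
  if (length(best) > 1L) {
    if (!quiet)
      message(length(best), " tied peak plateaus; choosing the one at the ",
              "lowest genomic coordinate")
    ord <- order(vapply(runs[best],
                        function(r) match(r$chrom, unique(profile$chrom)), 0),
                 vapply(runs[best], function(r) profile$pos[r$rows[1]], 0))
    best <- best[ord[1]]
  }
  run <- runs[[best]]

  chrom_rows <- which(profile$chrom == run$chrom)
  start <- profile$pos[run$rows[1]]
  end <- profile$pos[run$rows[length(run$rows)]]
  if (run$at_left_edge) start <- min(profile$pos[chrom_rows])
  if (run$at_right_edge) end <- max(profile$pos[chrom_rows])
  n_in <- sum(profile$pos[chrom_rows] >= start &
              profile$pos[chrom_rows] <= end)

  structure(list(chrom = run$chrom, start = start, end = end,
                 peak_window_freq = M, n_markers_in_interval = n_in,
                 threshold = thr, status = "linked",
                 chrom_summary = chrom_summary),
            class = "linkage_interval")
}

#' @method print linkage_interval
#' @export
print.linkage_interval <- function(x, ...) {
  if (x$status == "no_linkage") {
    cat("linkage_interval: no linkage detected (flat profile, peak",
        sprintf("%.3f)\n", x$peak_window_freq))
  } else {
    cat(sprintf(
      "linkage_interval: %s:%s-%s (%.2f Mb), peak window frequency %.3f, %d markers\n",
      x$chrom, format(x$start, big.mark = ","),
      format(x$end, big.mark = ","), (x$end - x$start) / 1e6,
      x$peak_window_freq, x$n_markers_in_interval))
  }
  invisible(x)
}

#' Fit a genome-wide homozygosity scan to pooled marker counts
#'
#' The central estimator of the package: computes per-marker mutant-pool
#' allele frequencies, folds them into homozygosity scores, smooths with a
#' sliding window of neighboring loci, and calls the linkage interval at
#' the genome-wide peak. In a recessive F2 mapping cross every pooled
#' mutant is homozygous for the lesion haplotype, so the mutant pool drifts
#' to allele frequency near 1 around the causative locus while unlinked
#' regions stay near 0.5.
#'
#' @param counts marker count table (typically [select_mapping_markers()]
#'   output).
#' @param window sliding-window size in markers; default 50.
#' @param peak_threshold,threshold_mode interval delimitation, see
#'   [find_linkage_region()].
#' @param statistic `"folded"` (default) to average orientation-free
#'   homozygosity scores, or `"raw"` to average raw alternate-allele
#'   frequencies.
#' @param quiet suppress progress messages.
#' @return An object of class `linkage_scan` with components `profile`
#'   (per-marker data.frame: `chrom`, `pos`, `raw_freq`, `folded_freq`,
#'   `window_freq`), `interval` (a `linkage_interval`), `n_no_data`, and
#'   `config`. Methods: `print`, `summary`, `plot`, `coef`.
#' @examples
#' g <- simulate_genome(n_chrom = 3, markers_per_chrom = 80, seed = 2)
#' cr <- simulate_cross(g, cross_config(seed = 2))
#' fit <- linkage_scan(cr$counts, quiet = TRUE)
#' fit
#' @export
linkage_scan <- function(counts, window = 50, peak_threshold = 0.98,
                         threshold_mode = c("relative", "absolute"),
                         statistic = c("folded", "raw"), quiet = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  statistic <- match.arg(statistic)
  check_counts(counts)
  if (window < 1) stop("window must be >= 1", call. = FALSE)

  profile <- data.frame(chrom = counts$chrom, pos = counts$pos,
                        stringsAsFactors = FALSE)
  profile$raw_freq <- mutant_allele_frequency(counts$mut_ref,
                                              counts$mut_alt)
  profile$folded_freq <- fold_frequency(profile$raw_freq)
  n_no_data <- sum(is.na(profile$raw_freq))
  if (n_no_data > 0 && !quiet)
    message(n_no_data,
            " marker(s) with zero mutant-pool depth excluded from windows")

  value <- if (statistic == "folded") "folded_freq" else "raw_freq"
  profile <- sliding_window_profile(profile, window = window, value = value,
                                    quiet = quiet)
  interval <- find_linkage_region(profile, peak_threshold = peak_threshold,
                                  threshold_mode = threshold_mode,
                                  quiet = quiet)
  structure(list(profile = profile, interval = interval,
                 n_no_data = n_no_data,
                 config = list(window = window,
                               peak_threshold = peak_threshold,
                               threshold_mode = threshold_mode,
                               statistic = statistic)),
            class = "linkage_scan")
}

#' @method print linkage_scan
#' @export
print.linkage_scan <- function(x, ...) {
  cat("Genome-wide homozygosity scan (", x$config$window,
      "-locus sliding window)\n", sep = "")
  cat("  markers:", nrow(x$profile), "(", x$n_no_data, "no-data )\n")
  print(x$interval)
  invisible(x)
}

#' @method summary linkage_scan
#' @export
summary.linkage_scan <- function(object, n = 5, ...) {
  print(object)
  cat("\nPer-chromosome window maxima:\n")
  print(utils::head(object$interval$chrom_summary, n), row.names = FALSE)
  invisible(object)
}

#' @method coef linkage_scan
#' @export
coef.linkage_scan <- function(object, ...) {
  iv <- object$interval
  c(peak_window_freq = iv$peak_window_freq, start = iv$start, end = iv$end)
}

#' Genome-scan plot of a linkage fit
#'
#' One panel across all chromosomes: per-marker folded frequencies in grey,
#' the sliding-window mean as a black line, chromosomes separated by
#' vertical lines and labeled at the bottom; the called interval, if any, is
#' shaded red.
#'
#' @param x a [linkage_scan()] fit.
#' @param ... passed to [graphics::plot()].
#' @method plot linkage_scan
#' @export
plot.linkage_scan <- function(x, ...) {
  pr <- x$profile
  chroms <- unique(pr$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cn)
    max(pr$pos[pr$chrom == cn]), 0)))
  names(offs) <- c(chroms, "end")
  gx <- pr$pos + offs[match(pr$chrom, chroms)]
  graphics::plot(gx, pr$folded_freq, pch = 16, cex = 0.3, col = "grey70",
                 xlab = "genomic position", xaxt = "n",
                 ylab = "mutant-pool homozygosity", ylim = c(0.45, 1.02),
                 ...)
  if (x$interval$status == "linked") {
    o <- offs[match(x$interval$chrom, chroms)]
    graphics::rect(o + x$interval$start, 0.45, o + x$interval$end, 1.02,
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  ok <- !is.na(pr$window_freq)
  for (cn in chroms) {
    i <- which(pr$chrom == cn & ok)
    if (length(i))
      graphics::lines(gx[i], pr$window_freq[i], lwd = 1.5)
  }
  graphics::abline(v = offs[-1], col = "grey85")
  mids <- (offs[-length(offs)] + offs[-1]) / 2
  graphics::axis(1, at = mids, labels = chroms, tick = FALSE, cex.axis = 0.6,
                 las = 2)
  invisible(x)
}
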