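#' Configuration for a simulated recessive mapping cross
#'
#' Describes an F2 incross of two heterozygous carriers on a mixed strain
#' background, phenotyped and pooled for bulked-segregant sequencing:
#' homozygous mutants in one pool, their wildtype siblings (+/+ and +/-,
#' segregating 1:2) in the other. Defaults follow the standard design of
#' pooling 108 larvae per pool at roughly 50x marker depth.
#'
#' @param n_mutant_pool number of phenotypically mutant (-/-) individuals
#'   pooled (default 108).
#' @param n_wildtype_pool number of wildtype siblings pooled (default 108).
#' @param causative causative locus as `list(chrom =, pos =)`, or `NULL` to
#'   plant it at the marker nearest the midpoint of the first chromosome.
#' @param mean_depth expected reads per marker per pool (Poisson mean).
#' @param seq_error_rate per-base probability that a read reports the other
#'   allele (symmetric); must be in `[0, 0.5)`.
#' @param phenotyping_error_rate probability that an individual pooled as
#'   "mutant" is actually a non-mutant sibling; caps the mapped peak below
#'   1 when positive. Default 0.
#' @param expr_planted_fold expression fold change applied to the planted
#'   reduced-expression gene in the mutant pool (default 0.2).
#' @param expr_planted_mean baseline expression mean of the planted gene
#'   (default 500 counts).
#' @param expr_base_meanlog,expr_base_sdlog lognormal parameters for the
#'   baseline expression means of all other genes.
#' @param nb_dispersion optional negative-binomial dispersion for expression
#'   counts (`NULL` = Poisson).
#' @param seed integer seed driving every random draw of the simulation.
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(n_mutant_pool = 108, n_wildtype_pool = 108,
                         causative = NULL, mean_depth = 50,
                         seq_error_rate = 0.005,
                         phenotyping_error_rate = 0,
                         expr_planted_fold = 0.2, expr_planted_mean = 500,
                         expr_base_meanlog = log(200), expr_base_sdlog = 0.7,
                         nb_dispersion = NULL, seed = 1) {
  if (n_mutant_pool < 1 || n_wildtype_pool < 1)
    stop("pool sizes must be >= 1", call. = FALSE)
  if (seq_error_rate < 0 || seq_error_rate >= 0.5)
    stop("seq_error_rate must be in [0, 0.5)", call. = FALSE)
  if (phenotyping_error_rate < 0 || phenotyping_error_rate >= 1)
    stop("phenotyping_error_rate must be in [0, 1)", call. = FALSE)
  if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  structure(list(n_mutant_pool = as.integer(n_mutant_pool),
                 n_wildtype_pool = as.integer(n_wildtype_pool),
                 causative = causative, mean_depth = mean_depth,
                 seq_error_rate = seq_error_rate,
                 phenotyping_error_rate = phenotyping_error_rate,
                 expr_planted_fold = expr_planted_fold,
                 expr_planted_mean = expr_planted_mean,
                 expr_base_meanlog = expr_base_meanlog,
                 expr_base_sdlog = expr_base_sdlog,
                 nb_dispersion = nb_dispersion,
                 seed = as.integer(seed)),
            class = "cross_config")
}

# alleles (0 = strain A / ref, 1 = strain B / alt) transmitted by one gamete
# at the given genetic positions (cM). Crossovers are Poisson with mean
# L/100 (no interference), breakpoints uniform on the genetic map.
gamete_alleles <- function(gpos, length_cM) {
  n_co <- stats::rpois(1L, length_cM / 100)
  start <- stats::rbinom(1L, 1L, 0.5)
  if (n_co == 0L) return(rep.int(start, length(gpos)))
  breaks <- sort(stats::runif(n_co, 0, length_cM))
  (start + findInterval(gpos, breaks)) %% 2L
}

#' Simulate a pooled-sequencing mapping cross
#'
#' Generates the inputs of a bulked-segregant mapping experiment together
#' with its ground truth. Each F2 individual is formed from two independent
#' gametes; each gamete recombines with Poisson crossover counts (mean =
#' genetic length / 100, no interference), breakpoints uniform on the
#' genetic map, and a constant cM/Mb scaling per chromosome. The causative
#' lesion rides the strain-B (alternate-allele) haplotype. Individuals enter
#' the mutant pool only if homozygous for the causative allele (subject to
#' `phenotyping_error_rate`); wildtype siblings are drawn from the remaining
#' genotype classes in their natural 1 (+/+) : 2 (+/-) proportions. Read
#' counts per marker per pool are Poisson-depth, binomial-allele draws with
#' symmetric sequencing error. Per-gene expression counts carry one planted
#' reduced-expression gene (the gene nearest the causative locus).
#'
#' @param genome a [simulate_genome()] result (or compatible
#'   `genome_model`).
#' @param config a [cross_config()].
#' @return A list of class `pool_cross` with elements `counts` (marker count
#'   data.frame: `chrom`, `pos`, `ref`, `alt`, `mut_ref`, `mut_alt`,
#'   `wt_ref`, `wt_alt`), `expression` (per-gene counts for both pools) and
#'   `truth` (class `cross_truth`: causative locus, per-individual marker
#'   dosages per pool, pre-sampling pool allele counts, planted gene, seed).
#' @examples
#' g <- simulate_genome(n_chrom = 2, markers_per_chrom = 30, seed = 1)
#' cr <- simulate_cross(g, cross_config(n_mutant_pool = 20,
#'                                      n_wildtype_pool = 20, seed = 1))
#' head(cr$counts)
#' @export
simulate_cross <- function(genome, config = cross_config()) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "cross_config"))
  set.seed(config$seed)
  chroms <- genome$chromosomes
  mk <- genome$markers

  causative <- config$causative
  if (is.null(causative)) {
    on1 <- mk[mk$chrom == chroms$name[1], ]
    i <- which.min(abs(on1$pos - chroms$length_bp[1] / 2))
    causative <- list(chrom = on1$chrom[i], pos = on1$pos[i])
  }
  ci <- match(causative$chrom, chroms$name)
  if (is.na(ci))
    stop("causative chromosome ", causative$chrom, " is not in the genome",
         call. = FALSE)
  if (!any(mk$chrom == causative$chrom))
    stop("no markers on the causative chromosome", call. = FALSE)
  if (causative$pos < 1 || causative$pos > chroms$length_bp[ci])
    stop("causative position lies outside chromosome ", causative$chrom,
         call. = FALSE)

  # per-chromosome marker genetic positions; causative appended to its own
  # chromosome so both are realized on the same gamete
  n_mark <- nrow(mk)
  chrom_idx <- lapply(chroms$name, function(cn) which(mk$chrom == cn))
  gpos <- lapply(seq_len(nrow(chroms)), function(i) {
    g <- mk$pos[chrom_idx[[i]]] / chroms$length_bp[i] * chroms$length_cM[i]
    if (i == ci)
      g <- c(g, causative$pos / chroms$length_bp[i] * chroms$length_cM[i])
    g
  })

  sim_batch <- function(n) {
    dos <- matrix(0L, nrow = n_mark, ncol = n)
    caus <- integer(n)
    for (k in seq_len(n)) {
      for (i in seq_len(nrow(chroms))) {
        a <- gamete_alleles(gpos[[i]], chroms$length_cM[i]) +
             gamete_alleles(gpos[[i]], chroms$length_cM[i])
        if (i == ci) {
          m <- length(a)
          caus[k] <- a[m]
          a <- a[-m]
        }
        dos[chrom_idx[[i]], k] <- a
      }
    }
    list(dos = dos, caus = caus)
  }

  n_mut <- config$n_mutant_pool
  n_wt <- config$n_wildtype_pool
  mispooled <- stats::runif(n_mut) < config$phenotyping_error_rate
  need_non <- n_wt + sum(mispooled)

  dos <- NULL; caus <- integer(0)
  while (sum(caus == 2L) < n_mut || sum(caus < 2L) < need_non) {
    b <- sim_batch(max(64L, 4L * (n_mut + n_wt) %/% 2L))
    dos <- if (is.null(dos)) b$dos else cbind(dos, b$dos)
    caus <- c(caus, b$caus)
  }
  mut_ids <- which(caus == 2L)[seq_len(n_mut)]
  non_ids <- which(caus < 2L)
  wt_ids <- non_ids[seq_len(n_wt)]
  extra <- non_ids[n_wt + seq_len(sum(mispooled))]
  pooled_mut <- mut_ids
  pooled_mut[mispooled] <- extra

  mut_dos <- dos[, pooled_mut, drop = FALSE]
  wt_dos <- dos[, wt_ids, drop = FALSE]
  mut_alt_true <- as.integer(rowSums(mut_dos))
  wt_alt_true <- as.integer(rowSums(wt_dos))

  sample_pool <- function(alt_true, n_ind) {
    p <- alt_true / (2 * n_ind)
    p <- p * (1 - config$seq_error_rate) + (1 - p) * config$seq_error_rate
    depth <- stats::rpois(n_mark, config$mean_depth)
    alt <- stats::rbinom(n_mark, depth, p)
    cbind(ref = depth - alt, alt = alt)
  }
  mut_reads <- sample_pool(mut_alt_true, n_mut)
  wt_reads <- sample_pool(wt_alt_true, n_wt)

  counts <- data.frame(chrom = mk$chrom, pos = mk$pos, ref = mk$ref,
                       alt = mk$alt,
                       mut_ref = mut_reads[, "ref"],
                       mut_alt = mut_reads[, "alt"],
                       wt_ref = wt_reads[, "ref"],
                       wt_alt = wt_reads[, "alt"],
                       stringsAsFactors = FALSE)

  # expression: one planted reduced-expression gene near the causative locus
  planted <- NULL
  expression <- data.frame(gene_id = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0),
                           mut_count = integer(0), wt_count = integer(0))
  if (length(genome$genes) > 0) {
    ginfo <- data.frame(
      gene_id = vapply(genome$genes, `[[`, "", "id"),
      chrom = vapply(genome$genes, `[[`, "", "chrom"),
      start = vapply(genome$genes, function(g) min(g$exons$start), 0),
      end = vapply(genome$genes, function(g) max(g$exons$end), 0),
      stringsAsFactors = FALSE)
    rownames(ginfo) <- NULL
    mu <- stats::rlnorm(nrow(ginfo), config$expr_base_meanlog,
                        config$expr_base_sdlog)
    on_c <- which(ginfo$chrom == causative$chrom)
    if (length(on_c) > 0) {
      pi <- on_c[which.min(abs((ginfo$start[on_c] + ginfo$end[on_c]) / 2 -
                               causative$pos))]
      mu[pi] <- config$expr_planted_mean
      planted <- list(gene_id = ginfo$gene_id[pi],
                      fold = config$expr_planted_fold)
    }
    mut_mu <- mu
    if (!is.null(planted)) mut_mu[pi] <- mu[pi] * config$expr_planted_fold
    draw <- function(m) {
      if (is.null(config$nb_dispersion)) stats::rpois(length(m), m)
      else stats::rnbinom(length(m), mu = m, size = 1 / config$nb_dispersion)
    }
    expression <- cbind(ginfo, data.frame(mut_count = draw(mut_mu),
                                          wt_count = draw(mu)))
    attr(expression, "lib_size") <- c(mut = sum(expression$mut_count),
                                      wt = sum(expression$wt_count))
  }

  truth <- structure(list(
    causative = causative,
    causative_marker = {
      hit <- which(mk$chrom == causative$chrom & mk$pos == causative$pos)
      if (length(hit)) hit[1] else NA_integer_
    },
    mutant_dosages = mut_dos,
    wildtype_dosages = wt_dos,
    mutant_causative_genotypes = caus[pooled_mut],
    true_counts = data.frame(chrom = mk$chrom, pos = mk$pos,
                             mut_alt_true = mut_alt_true,
                             mut_chromosomes = 2L * n_mut,
                             wt_alt_true = wt_alt_true,
                             wt_chromosomes = 2L * n_wt,
                             stringsAsFactors = FALSE),
    planted_gene = planted,
    n_phenotyping_errors = sum(mispooled),
    seed = config$seed,
    config = config), class = "cross_truth")

  structure(list(counts = counts, expression = expression, truth = truth,
                 genome = genome),
            class = "pool_cross")
}

#' @method print pool_cross
#' @export
print.pool_cross <- function(x, ...) {
  tr <- x$truth
  cat("pool_cross:", nrow(x$counts), "markers;",
      tr$config$n_mutant_pool, "mutants +",
      tr$config$n_wildtype_pool, "wildtype siblings pooled\n")
  cat(sprintf("  causative locus: %s:%d (marker row %s)\n",
              tr$causative$chrom, as.integer(tr$causative$pos),
              ifelse(is.na(tr$causative_marker), "none",
                     tr$causative_marker)))
  if (!is.null(tr$planted_gene))
    cat(sprintf("  planted reduced-expression gene: %s (fold %.2g)\n",
                tr$planted_gene$gene_id, tr$planted_gene$fold))
  invisible(x)
}
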