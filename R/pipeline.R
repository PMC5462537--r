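#' Pipeline configuration
#'
#' Collects every stage's settings with the package defaults: cross
#' simulation (pool sizes 108/108), marker discovery (wildtype depth >= 20,
#' allele-frequency window [0.2, 0.8]), linkage mapping (50-locus window)
#' and candidate annotation (alpha 0.05, fold 0.5). A config round-trips
#' through YAML unchanged via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param mode `"simulate"` (generate inputs with the cross simulator) or
#'   `"files"` (read user-supplied VCF/GFF3/FASTA/TSV).
#' @param seed global seed (drives simulation).
#' @param genome list of [simulate_genome()] arguments (simulate mode).
#' @param cross list of [cross_config()] arguments (simulate mode; `seed`
#'   is taken from the global seed).
#' @param filter list of [marker_filter()] arguments.
#' @param mapping list with `window`, `peak_threshold`, `threshold_mode`,
#'   `statistic` for [linkage_scan()].
#' @param annotation list with `alpha`, `min_fold` for the candidate
#'   screen.
#' @param input list of paths for files mode: `counts_vcf` or `counts_tsv`,
#'   optional `variants_vcf`, `gff`, `fasta`, `expression_tsv`.
#' @param out_dir output directory for artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"), seed = 1,
                            genome = list(), cross = list(),
                            filter = list(), mapping = list(),
                            annotation = list(), input = list(),
                            out_dir = "poolscan_out") {
  mode <- match.arg(mode)
  structure(list(
    mode = mode, seed = as.integer(seed),
    genome = utils::modifyList(
      list(n_chrom = 25L, markers_per_chrom = 200L, genes_per_chrom = 3L,
           chrom_length_bp = 5e7, genetic_length_cM = 100), genome),
    cross = cross,
    filter = utils::modifyList(
      list(min_depth = 20, wt_af_min = 0.2, wt_af_max = 0.8,
           min_mut_depth = 0), filter),
    mapping = utils::modifyList(
      list(window = 50L, peak_threshold = 0.98,
           threshold_mode = "relative", statistic = "folded"), mapping),
    annotation = utils::modifyList(
      list(alpha = 0.05, min_fold = 0.5), annotation),
    input = input, out_dir = out_dir), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config,
          x[intersect(names(x), names(formals(pipeline_config)))])
}

#' Run the full mapping pipeline
#'
#' Orchestrates simulate (or load) -> discover mapping markers -> linkage
#' scan -> candidate annotation, writing every artifact to `out_dir`:
#' marker VCF + TSV, per-marker profile TSV, interval BED, genome-scan
#' figure (PNG), candidate/expression report TSVs, and a run manifest
#' (YAML: config, its MD5, seed, package version, per-stage tallies).
#' Identical config + seed reproduce byte-identical TSV/BED artifacts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the `linkage_scan` fit, the
#'   `candidate_report`, the `cross_truth` (simulate mode) and artifact
#'   paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[poolscan] ", ...)
  paths <- list()
  tallies <- list()
  truth <- NULL
  gene_models <- list()
  variants <- data.frame(chrom = character(0), pos = numeric(0),
                         ref = character(0), alt = character(0))
  expression <- NULL

  if (config$mode == "simulate") {
    say("simulating genome and cross (seed ", config$seed, ")")
    genome <- do.call(simulate_genome,
                      c(config$genome, list(seed = config$seed)))
    cc <- do.call(cross_config,
                  c(config$cross, list(seed = config$seed)))
    cross <- simulate_cross(genome, cc)
    counts <- cross$counts
    truth <- cross$truth
    expression <- cross$expression
    gene_models <- genome$genes
    paths$counts_vcf <- file.path(out, "markers.vcf")
    write_counts_vcf(counts, paths$counts_vcf)
    paths$truth <- file.path(out, "truth.yaml")
    write_truth_yaml(truth, paths$truth)
    if (nrow(expression)) {
      paths$expression <- file.path(out, "expression.tsv")
      write_expression_tsv(expression, paths$expression)
    }
  } else {
    inp <- config$input
    if (!is.null(inp$counts_vcf)) {
      if (!file.exists(inp$counts_vcf))
        stop("input counts VCF not found: ", inp$counts_vcf, call. = FALSE)
      counts <- read_counts_vcf(inp$counts_vcf)
    } else if (!is.null(inp$counts_tsv)) {
      if (!file.exists(inp$counts_tsv))
        stop("input counts TSV not found: ", inp$counts_tsv, call. = FALSE)
      counts <- read_counts_tsv(inp$counts_tsv)
    } else stop("files mode needs input$counts_vcf or input$counts_tsv",
                call. = FALSE)
    if (!is.null(inp$variants_vcf)) {
      if (is.null(inp$gff) || is.null(inp$fasta))
        stop("variant annotation requires input$gff and input$fasta",
             call. = FALSE)
      variants <- read_variants_vcf(inp$variants_vcf)
    }
    if (!is.null(inp$gff)) {
      if (is.null(inp$fasta))
        stop("input$gff requires input$fasta for reference sequence",
             call. = FALSE)
      gene_models <- read_gene_models(inp$gff, inp$fasta)
    }
    if (!is.null(inp$expression_tsv))
      expression <- read_expression_tsv(inp$expression_tsv)
  }
  tallies$markers_input <- nrow(counts)

  say("discovering mapping markers")
  markers <- do.call(marker_filter, config$filter)
  retained <- select_mapping_markers(counts, markers, quiet = quiet)
  tallies$markers_retained <- nrow(retained)
  tallies$markers_rejected <- as.list(attr(retained, "rejections"))
  paths$markers_tsv <- file.path(out, "mapping_markers.tsv")
  write_counts_tsv(retained, paths$markers_tsv,
                   comments = sprintf(
                     "marker_filter: min_depth=%g wt_af=[%g,%g] min_mut_depth=%g",
                     markers$min_depth, markers$wt_af_min,
                     markers$wt_af_max, markers$min_mut_depth))

  say("fitting the homozygosity scan (window ", config$mapping$window, ")")
  fit <- linkage_scan(retained, window = config$mapping$window,
                      peak_threshold = config$mapping$peak_threshold,
                      threshold_mode = config$mapping$threshold_mode,
                      statistic = config$mapping$statistic, quiet = quiet)
  tallies$markers_no_data <- fit$n_no_data
  paths$profile <- file.path(out, "profile.tsv")
  write_profile_tsv(fit, paths$profile)
  if (fit$interval$status == "linked") {
    paths$interval_bed <- file.path(out, "interval.bed")
    write_interval_bed(fit$interval, paths$interval_bed)
  } else say("no linkage detected")
  paths$plot <- file.path(out, "genome_scan.png")
  grDevices::png(paths$plot, width = 1400, height = 420)
  plot(fit)
  grDevices::dev.off()

  report <- NULL
  if (fit$interval$status == "linked") {
    say("screening interval candidates")
    report <- withCallingHandlers(
      screen_interval_candidates(fit$interval, variants, gene_models,
                                 expression = expression,
                                 alpha = config$annotation$alpha,
                                 min_fold = config$annotation$min_fold),
      warning = function(w) {
        if (quiet) invokeRestart("muffleWarning")
      })
    paths$candidates <- file.path(out, "candidates.tsv")
    utils::write.table(report$variants, paths$candidates, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(report$reduced_expression)) {
      paths$reduced_expression <- file.path(out, "reduced_expression.tsv")
      utils::write.table(report$reduced_expression,
                         paths$reduced_expression, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    tallies$candidate_effects <- as.list(report$tally)
  }

  paths$config <- file.path(out, "config.yaml")
  write_pipeline_config(config, paths$config)
  manifest <- list(
    package = "poolscan",
    version = as.character(utils::packageVersion("poolscan")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(paths$config)),
    window_size = config$mapping$window,
    n_mutant_pool = if (config$mode == "simulate")
      do.call(cross_config,
              c(config$cross, list(seed = config$seed)))$n_mutant_pool
      else NA,
    n_wildtype_pool = if (config$mode == "simulate")
      do.call(cross_config,
              c(config$cross, list(seed = config$seed)))$n_wildtype_pool
      else NA,
    interval = if (fit$interval$status == "linked")
      list(chrom = fit$interval$chrom,
           start = as.integer(fit$interval$start),
           end = as.integer(fit$interval$end),
           peak_window_freq = fit$interval$peak_window_freq)
      else "no_linkage",
    tallies = tallies)
  paths$manifest <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  say("done; artifacts in ", normalizePath(out))

  invisible(list(scan = fit, report = report, truth = truth,
                 paths = paths, manifest = manifest))
}
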