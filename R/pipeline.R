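#' Assemble a BALM run configuration
#'
#' Captures every tunable of the pipeline with its default.  Defaults:
#' 50 bp initial windows stepped by 25 bp, Poisson-derived count threshold
#' (tail 1e-5), 10 kb GRAI bins, one-sided Fisher alpha 0.05, +/-1000 bp
#' model window with at least 500 tags per strand, K selected by BIC with 5
#' EM starts, component-to-CpG assignment radius 25 bp, methylation
#' calibration at the 95th percentile of per-component effective masses,
#' and t = 2 outer passes (scan -> model -> mixture, then refit from the
#' refined site list).
#'
#' @param tag_file path to the treatment tag file.
#' @param format tag file dialect (see \code{\link{read_tags}}).
#' @param assembly a \code{\link{genome_assembly}} (or path to a genome
#'   table readable by \code{\link{read_genome_table}}).
#' @param out_dir output directory (created if needed).
#' @param input_file optional input/control tag file.
#' @param input_format its dialect.
#' @param fasta optional FASTA path (or DNAStringSet) for CpG extraction.
#' @param cpg_map optional precomputed CpG map (overrides \code{fasta}).
#' @param custom_columns for CUSTOM dialects.
#' @param fragment_length known fragment length, or NULL to estimate.
#' @param window,step,threshold initial-scan controls.
#' @param base_threshold weighted-enrichment threshold (NULL: Poisson
#'   default).
#' @param alpha Fisher cutoff.
#' @param grai_bin GRAI bin width (bp).
#' @param dedup collapse duplicate tags.
#' @param iterations outer passes t (>= 1).
#' @param n_starts,K_max EM restarts and component cap per region.
#' @param min_tags_per_strand BALM fit minimum per strand.
#' @param support enrichment kernel half-width (bp).
#' @param assign_radius component-to-CpG radius (bp).
#' @param calibration saturation mass mapping to score 1 (NULL: 95th
#'   percentile rule).
#' @param seed master seed; all region-level EM seeds derive from it.
#' @param write_wig write enrichment and GRAI WIG tracks.
#' @return list of class \code{balm_config}.
#' @export
balm_config <- function(tag_file, format = "BED", assembly, out_dir,
                        input_file = NULL, input_format = format,
                        fasta = NULL, cpg_map = NULL, custom_columns = NULL,
                        fragment_length = NULL, window = 50L, step = 25L,
                        threshold = NULL, base_threshold = NULL,
                        alpha = 0.05, grai_bin = 10000L, dedup = FALSE,
                        iterations = 2L, n_starts = 5L, K_max = NULL,
                        min_tags_per_strand = 500L, support = 1000L,
                        assign_radius = 25L, calibration = NULL, seed = 1L,
                        write_wig = FALSE) {
  if (is.character(assembly)) assembly <- read_genome_table(assembly)
  stopifnot(inherits(assembly, "genome_assembly"), iterations >= 1)
  structure(as.list(environment()), class = "balm_config")
}

.write_run_log <- function(path, entries) {
  writeLines(sprintf("%s\t%s", names(entries),
                     vapply(entries, function(x)
                       paste(format(x), collapse = ","), character(1))),
             path)
}

#' Run the full BALM pipeline
#'
#' Executes the outer loop: initial tag-shifting scan (with Fisher
#' filtering and GRAI when input is given), BALM fit on the current site
#' list, weighted-enrichment scan, per-region EM/BIC mixture fitting, site
#' list update — repeated \code{iterations} times with the model refitted
#' from the refined sites — then per-CpG methylation scoring and output:
#' \code{regions.bed}, \code{sites.bed}, \code{cpg_scores.tsv},
#' \code{model.txt}, \code{run_log.tsv} and optional WIG tracks in
#' \code{out_dir}.
#'
#' @param config a \code{\link{balm_config}}.
#' @return list of class \code{balm_result}: \code{status} (0 on success,
#'   1 on empty input), \code{regions}, \code{sites},
#'   \code{region_models}, \code{scores}, \code{model}, \code{grai},
#'   \code{fragment_length}, \code{calibration}, \code{log}.
#' @export
run_balm <- function(config) {
  stopifnot(inherits(config, "balm_config"))
  cfg <- config
  asm <- cfg$assembly
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = cfg$seed)
  empty_out <- function(msg) {
    message(msg)
    for (f in c("regions.bed", "sites.bed", "cpg_scores.tsv"))
      writeLines(character(0), file.path(cfg$out_dir, f))
    .write_run_log(file.path(cfg$out_dir, "run_log.tsv"),
                   c(log, status = 1L, note = msg))
    structure(list(status = 1L, regions = NULL, sites = NULL,
                   region_models = list(), scores = NULL, model = NULL,
                   grai = NULL, log = log), class = "balm_result")
  }

  tags <- read_tags(cfg$tag_file, cfg$format, cfg$custom_columns)
  tags <- filter_tags(tags, asm, dedup = cfg$dedup)
  log$n_tags <- nrow(tags)
  log$dropped_treatment <- attr(tags, "n_dropped")
  if (nrow(tags) == 0) return(empty_out("no usable treatment tags"))

  input <- NULL; grai <- NULL
  if (!is.null(cfg$input_file)) {
    input <- read_tags(cfg$input_file, cfg$input_format, cfg$custom_columns)
    input <- filter_tags(input, asm, dedup = cfg$dedup)
    log$n_input <- nrow(input)
    if (nrow(input) > 0) grai <- compute_grai(input, asm, cfg$grai_bin)
    else message("input file contained no usable tags; GRAI disabled")
  }

  cpg_map <- cfg$cpg_map
  if (is.null(cpg_map) && !is.null(cfg$fasta))
    cpg_map <- extract_cpg_sites(cfg$fasta)

  fl <- cfg$fragment_length
  if (is.null(fl)) fl <- estimate_fragment_length(tags)
  log$fragment_length <- fl

  scan0 <- initial_scan(tags, shift = round(fl / 2), assembly = asm,
                        window = cfg$window, step = cfg$step,
                        threshold = cfg$threshold, grai = grai)
  regions <- scan0$regions
  log$initial_threshold <- scan0$threshold
  log$initial_regions <- nrow(regions)
  if (!is.null(input) && nrow(regions)) {
    regions$control_count <- count_tags_in_regions(input, regions)
    regions <- fisher_filter(regions, nrow(tags), nrow(input), cfg$alpha)
    log$initial_regions_after_fisher <- nrow(regions)
  }
  if (nrow(regions) == 0)
    return(empty_out("no enriched region found in the initial scan"))
  sites <- data.frame(chrom = regions$chrom, pos = regions$site,
                      stringsAsFactors = FALSE)

  model <- NULL; region_models <- list(); final_regions <- regions
  for (pass in seq_len(cfg$iterations)) {
    model <- fit_balm(tags, sites, window = cfg$support,
                      min_tags_per_strand = cfg$min_tags_per_strand,
                      fragment_length = fl)
    log[[paste0("gof_pass", pass)]] <- model$gof
    final_regions <- weighted_enrichment_scan(
      tags, model, asm, base_threshold = cfg$base_threshold, grai = grai,
      input_tags = input, alpha = cfg$alpha, support = cfg$support)
    if (nrow(final_regions) == 0) break
    region_models <- vector("list", nrow(final_regions))
    new_sites <- list()
    for (i in seq_len(nrow(final_regions))) {
      reg <- final_regions[i, , drop = FALSE]
      rt <- tags_in_region(tags, reg, model)
      if (nrow(rt) < 3) next
      set.seed((cfg$seed * 1000003L + pass * 1009L + i) %% .Machine$integer.max)
      rm_i <- select_components(rt, model, K_max = cfg$K_max,
                                n_starts = cfg$n_starts, region = reg)
      region_models[[i]] <- rm_i
      new_sites[[length(new_sites) + 1L]] <- data.frame(
        chrom = reg$chrom, pos = rm_i$components$center,
        stringsAsFactors = FALSE)
    }
    if (length(new_sites)) sites <- do.call(rbind, new_sites)
  }
  if (nrow(final_regions) == 0 || !length(region_models))
    return(empty_out("no region survived the weighted-enrichment scan"))
  region_models <- Filter(Negate(is.null), region_models)
  log$final_regions <- nrow(final_regions)
  log$n_sites <- nrow(sites)

  # methylation calibration: 95th percentile of per-component effective mass
  masses <- unlist(lapply(region_models, function(rm_i) {
    g <- .grai_factor(grai, rm_i$region$chrom, rm_i$components$center)
    rm_i$components$weight * rm_i$n_tags / g
  }))
  calibration <- cfg$calibration
  if (is.null(calibration))
    calibration <- max(stats::quantile(masses, 0.95, names = FALSE), 1)
  log$calibration <- calibration

  scores <- NULL
  if (!is.null(cpg_map)) {
    sc <- lapply(region_models, function(rm_i)
      suppressMessages(methylation_scores(rm_i, cpg_map, calibration,
                                          grai = grai,
                                          assign_radius = cfg$assign_radius)))
    scores <- do.call(rbind, sc)
    rownames(scores) <- NULL
  }

  # outputs
  write_bed(final_regions, file.path(cfg$out_dir, "regions.bed"),
            scores = final_regions$max_enrichment)
  site_rows <- do.call(rbind, lapply(seq_along(region_models), function(i) {
    rm_i <- region_models[[i]]
    data.frame(chrom = rm_i$region$chrom,
               start = as.integer(round(rm_i$components$center)),
               end = as.integer(round(rm_i$components$center)) + 1L,
               name = sprintf("region%d_comp%d", i,
                              seq_len(nrow(rm_i$components))),
               score = rm_i$components$weight * rm_i$n_tags,
               stringsAsFactors = FALSE)
  }))
  write_bed(site_rows, file.path(cfg$out_dir, "sites.bed"),
            names = site_rows$name, scores = site_rows$score)
  if (!is.null(scores))
    utils::write.table(
      data.frame(chrom = scores$chrom, pos = scores$pos,
                 score = sprintf("%.6f", scores$score),
                 effective_count = sprintf("%.4f", scores$effective_count)),
      file.path(cfg$out_dir, "cpg_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  else writeLines(character(0), file.path(cfg$out_dir, "cpg_scores.tsv"))
  write_balm_model(model, file.path(cfg$out_dir, "model.txt"))
  if (isTRUE(cfg$write_wig)) {
    tr <- weighted_enrichment(tags, model, asm, cfg$support)
    write_wig(lapply(tr, function(v) round(v, 4)),
              file.path(cfg$out_dir, "enrichment.wig"),
              mode = "fixed_step")
    if (!is.null(grai))
      write_wig(lapply(grai$values, function(v) round(v, 6)),
                file.path(cfg$out_dir, "grai.wig"), mode = "fixed_step",
                step = grai$bin_width)
  }
  .write_run_log(file.path(cfg$out_dir, "run_log.tsv"),
                 c(log, status = 0L))
  structure(list(status = 0L, regions = final_regions, sites = sites,
                 region_models = region_models, scores = scores,
                 model = model, grai = grai, fragment_length = fl,
                 calibration = calibration, log = log),
            class = "balm_result")
}

#' @export
print.balm_result <- function(x, ...) {
  if (x$status != 0) {
    cat("BALM run: no usable signal (status", x$status, ")\n")
    return(invisible(x))
  }
  cat(sprintf("BALM run: %d enriched region(s), %d predicted site(s)\n",
              nrow(x$regions), nrow(x$sites)))
  if (!is.null(x$scores))
    cat(sprintf("  %d CpG scores (%.1f%% > 0.8, %.1f%% < 0.2), calibration %.1f\n",
                nrow(x$scores), 100 * mean(x$scores$score > 0.8),
                100 * mean(x$scores$score < 0.2), x$calibration))
  invisible(x)
}
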