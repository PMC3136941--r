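#' Specification of a Monte-Carlo null/spiked simulation
#'
#' Describes one simulated dataset matched to observed data: uniform
#' background tags over the (non-excluded) genome, optionally modulated by
#' a GRAI track, plus peaks planted at random positions with depths
#' resampled from the observed per-region tag counts.
#'
#' @param assembly a \code{\link{genome_assembly}}.
#' @param background_count number of background tags.
#' @param peak_count number of planted peaks (0 for a pure null).
#' @param peak_depths vector of observed region tag counts to resample
#'   depths from (ignored when \code{peak_count = 0}).
#' @param model generating \code{\link{balm_model}}.
#' @param seed RNG seed; a fixed seed reproduces the dataset exactly.
#' @param grai optional \code{grai_track}: background counts scale with
#'   the local index.
#' @param tag_length read length (default 50).
#' @return list of class \code{null_sim_spec}.
#' @export
null_sim_spec <- function(assembly, background_count, peak_count = 0L,
                          peak_depths = NULL, model = default_balm_model(),
                          seed = 1L, grai = NULL, tag_length = 50L) {
  stopifnot(inherits(assembly, "genome_assembly"),
            background_count >= 0, peak_count >= 0)
  if (background_count == 0 && peak_count == 0)
    stop("simulation needs background tags or peaks")
  if (peak_count > 0 && is.null(peak_depths))
    stop("peak_depths required when planting peaks")
  structure(list(assembly = assembly,
                 background_count = as.integer(background_count),
                 peak_count = as.integer(peak_count),
                 peak_depths = peak_depths, model = model,
                 seed = as.integer(seed), grai = grai,
                 tag_length = as.integer(tag_length)),
            class = "null_sim_spec")
}

# sample k positions uniformly over the assembly (weighted by grai when
# given), avoiding exclusion intervals
.sample_positions <- function(k, assembly, grai = NULL) {
  chroms <- names(assembly$chrom_lengths)
  if (is.null(grai)) {
    w <- as.numeric(assembly$chrom_lengths)
    ch <- sample(chroms, k, replace = TRUE, prob = w)
    pos <- floor(stats::runif(k) * assembly$chrom_lengths[ch])
    out <- data.frame(chrom = ch, pos = as.integer(pos),
                      stringsAsFactors = FALSE)
  } else {
    # one multinomial draw over bins, weight = bin length * grai
    bins <- list()
    for (ch in chroms) {
      v <- grai$values[[ch]]; L <- grai$bin_lengths[[ch]]
      bins[[ch]] <- data.frame(chrom = ch,
                               start = (seq_along(v) - 1L) * grai$bin_width,
                               len = L, w = v * L,
                               stringsAsFactors = FALSE)
    }
    bins <- do.call(rbind, bins)
    if (all(bins$w == 0)) bins$w <- bins$len
    i <- sample.int(nrow(bins), k, replace = TRUE, prob = bins$w)
    pos <- bins$start[i] + floor(stats::runif(k) * bins$len[i])
    out <- data.frame(chrom = bins$chrom[i], pos = as.integer(pos),
                      stringsAsFactors = FALSE)
  }
  e <- assembly$exclude
  if (!is.null(e) && nrow(e)) {
    bad <- rep(FALSE, nrow(out))
    for (j in seq_len(nrow(e)))
      bad <- bad | (out$chrom == e$chrom[j] & out$pos >= e$start[j] &
                    out$pos < e$end[j])
    while (any(bad)) {               # resample excluded draws
      repl <- .sample_positions(sum(bad), assembly, grai)
      out[bad, ] <- repl
      bad <- rep(FALSE, nrow(out))
      for (j in seq_len(nrow(e)))
        bad <- bad | (out$chrom == e$chrom[j] & out$pos >= e$start[j] &
                      out$pos < e$end[j])
    }
  }
  out
}

#' Simulate one dataset of background plus planted peaks
#'
#' @param spec a \code{\link{null_sim_spec}}.
#' @return list with \code{tags} (tag table) and \code{truth} (data.frame
#'   chrom, pos, depth of every planted site; zero rows for a pure null).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "null_sim_spec"))
  set.seed(spec$seed)
  asm <- spec$assembly
  p5 <- numeric(0); strand <- character(0); chrom <- character(0)
  truth <- data.frame(chrom = character(), pos = integer(),
                      depth = integer(), stringsAsFactors = FALSE)
  if (spec$peak_count > 0) {
    sites <- .sample_positions(spec$peak_count, asm, NULL)
    depth <- sample(spec$peak_depths, spec$peak_count, replace = TRUE)
    truth <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        depth = as.integer(depth), stringsAsFactors = FALSE)
    site_pos <- rep(sites$pos, depth)
    site_ch <- rep(sites$chrom, depth)
    n <- length(site_pos)
    if (n) {
      s <- ifelse(stats::runif(n) < spec$model$strand_weights[[1]],
                  "+", "-")
      off <- numeric(n)
      off[s == "+"] <- rald(sum(s == "+"), spec$model$forward)
      off[s == "-"] <- rald(sum(s == "-"), spec$model$reverse)
      p5 <- c(p5, site_pos + off); strand <- c(strand, s)
      chrom <- c(chrom, site_ch)
    }
  }
  if (spec$background_count > 0) {
    bg <- .sample_positions(spec$background_count, asm, spec$grai)
    p5 <- c(p5, bg$pos)
    strand <- c(strand, sample(c("+", "-"), spec$background_count,
                               replace = TRUE))
    chrom <- c(chrom, bg$chrom)
  }
  tl <- spec$tag_length
  p5 <- round(p5)
  start <- ifelse(strand == "+", p5, p5 - tl + 1L)
  end <- start + tl
  clen <- asm$chrom_lengths[chrom]
  ok <- start >= 0 & end <= clen
  list(tags = aligned_tags(chrom[ok], start[ok], end[ok], strand[ok]),
       truth = truth)
}

#' Estimate FDR of a detection run against planted truth
#'
#' A detected region counts as a true detection if its midpoint (or, when
#' present, any mixture component center) lies within \code{match_radius}
#' of a planted site; FDR = false detections / max(1, detections).
#'
#' @param detected data.frame of regions (chrom, start, end), optionally
#'   with a \code{center} column of predicted site positions.
#' @param truth data.frame (chrom, pos) of planted sites.
#' @param match_radius matching radius in bp (default 100).
#' @return list: \code{fdr}, \code{n_detected}, \code{n_false},
#'   \code{n_true}.
#' @export
estimate_fdr <- function(detected, truth, match_radius = 100L) {
  n_det <- nrow(detected)
  if (n_det == 0) {
    warning("empty detection set; FDR reported as 0")
    return(list(fdr = 0, n_detected = 0L, n_false = 0L, n_true = 0L))
  }
  pred <- if ("center" %in% names(detected)) detected$center
          else (detected$start + detected$end) / 2
  is_true <- vapply(seq_len(n_det), function(i) {
    s <- truth[truth$chrom == detected$chrom[i], , drop = FALSE]
    nrow(s) > 0 && min(abs(s$pos - pred[i])) <= match_radius
  }, logical(1))
  list(fdr = sum(!is_true) / n_det, n_detected = n_det,
       n_false = sum(!is_true), n_true = sum(is_true))
}

#' FDR calibration table over a grid of enrichment thresholds
#'
#' Runs the weighted-enrichment detection on a simulated dataset once per
#' threshold (the enrichment track is computed once and re-thresholded)
#' and reports detections and FDR per threshold.  Detection sets shrink as
#' the threshold grows, so FDR cannot pick up new false detections from
#' nowhere.
#'
#' @param sim result of \code{\link{simulate_dataset}}.
#' @param model the \code{\link{balm_model}} used for detection.
#' @param assembly a \code{\link{genome_assembly}}.
#' @param thresholds vector of base thresholds to scan.
#' @param match_radius matching radius (bp).
#' @param grai optional \code{grai_track}.
#' @param support kernel half-width (bp).
#' @return data.frame threshold, n_detected, n_false, fdr.
#' @export
fdr_table <- function(sim, model, assembly, thresholds,
                      match_radius = 100L, grai = NULL, support = 1000L) {
  track <- weighted_enrichment(sim$tags, model, assembly, support)
  rows <- lapply(sort(thresholds), function(th) {
    det <- weighted_enrichment_scan(sim$tags, model, assembly,
                                    base_threshold = th, grai = grai,
                                    support = support, track = track)
    r <- suppressWarnings(estimate_fdr(det, sim$truth, match_radius))
    data.frame(threshold = th, n_detected = r$n_detected,
               n_false = r$n_false, fdr = r$fdr)
  })
  do.call(rbind, rows)
}

#' Write a planted-site truth table as TSV
#'
#' @param truth data.frame (chrom, pos, ...).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
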