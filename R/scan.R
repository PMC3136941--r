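#' Default count threshold from a Poisson background
#'
#' Smallest integer T with P(X >= T) < p_null for X ~ Poisson(lambda),
#' lambda = n_tags * window / genome_size: the expected tag count of a
#' window under a uniform background.
#'
#' @param n_tags total treatment tag count.
#' @param genome_size total genome length (bp).
#' @param window window width (bp, default 50).
#' @param p_null background tail probability (default 1e-5).
#' @return integer threshold (at least 2).
#' @export
default_threshold <- function(n_tags, genome_size, window = 50L,
                              p_null = 1e-5) {
  lambda <- n_tags * window / genome_size
  max(2L, stats::qpois(p_null, lambda, lower.tail = FALSE) + 1L)
}

#' Genome region amplification index (GRAI) from input tags
#'
#' Per fixed-width genome bin i, \code{grai_i = (n_i / L_i) / (N / L_g)}:
#' the ratio of the local input-tag density to the genome-wide input-tag
#' density.  Values near 1 indicate normal copy number; a k-fold amplified
#' region has GRAI near k.  Bins overlapping the assembly's exclusion
#' intervals are flagged.
#'
#' @param input_tags input (control) tag table.
#' @param assembly a \code{\link{genome_assembly}}.
#' @param bin_width bin width in bp (default 10000).
#' @return Object of class \code{grai_track}: per-chromosome bin values,
#'   bin width, flags, and the totals N and L_g.
#' @export
compute_grai <- function(input_tags, assembly, bin_width = 10000L) {
  stopifnot(inherits(assembly, "genome_assembly"))
  N <- nrow(input_tags)
  if (N == 0)
    stop("no input tags: run without input correction (grai = NULL)")
  L_g <- assembly$genome_size
  values <- list(); lengths_ <- list(); excluded <- list()
  for (ch in names(assembly$chrom_lengths)) {
    clen <- assembly$chrom_lengths[[ch]]
    nb <- as.integer(ceiling(clen / bin_width))
    p5 <- tag_pos5(input_tags[input_tags$chrom == ch, , drop = FALSE])
    cnt <- tabulate(p5 %/% bin_width + 1L, nbins = nb)
    L_i <- rep(bin_width, nb)
    L_i[nb] <- clen - (nb - 1L) * bin_width
    values[[ch]] <- (cnt / L_i) / (N / L_g)
    lengths_[[ch]] <- L_i
    ex <- rep(FALSE, nb)
    e <- assembly$exclude
    if (!is.null(e) && any(e$chrom == ch)) {
      es <- e[e$chrom == ch, , drop = FALSE]
      starts <- (seq_len(nb) - 1L) * bin_width
      ex <- IRanges::overlapsAny(
        IRanges::IRanges(starts + 1L, starts + L_i),
        IRanges::IRanges(es$start + 1L, es$end))
    }
    excluded[[ch]] <- ex
  }
  structure(list(values = values, bin_lengths = lengths_,
                 excluded = excluded, bin_width = as.integer(bin_width),
                 N = N, L_g = L_g),
            class = "grai_track")
}

#' Look up GRAI values at genomic positions
#'
#' @param grai a \code{grai_track} from \code{\link{compute_grai}}, or NULL
#'   (returns 1 everywhere: no correction).
#' @param chrom chromosome name (scalar).
#' @param pos 0-based positions.
#' @return GRAI values; positions outside the track return 1.
#' @export
grai_at <- function(grai, chrom, pos) {
  if (is.null(grai)) return(rep(1, length(pos)))
  v <- grai$values[[chrom]]
  if (is.null(v)) return(rep(1, length(pos)))
  i <- pos %/% grai$bin_width + 1L
  out <- rep(1, length(pos))
  ok <- i >= 1L & i <= length(v)
  out[ok] <- v[i[ok]]
  out
}

#' Length-weighted genome mean of a GRAI track
#'
#' The identity \eqn{\sum_i L_i \cdot grai_i / L_g = \sum_i n_i / N = 1}
#' holds exactly for any input; exposed for sanity checks.
#'
#' @param grai a \code{grai_track}.
#' @return numeric scalar (1 up to floating point).
#' @export
grai_weighted_mean <- function(grai) {
  num <- 0
  for (ch in names(grai$values))
    num <- num + sum(grai$values[[ch]] * grai$bin_lengths[[ch]])
  num / grai$L_g
}

# threshold multiplier: amplification raises thresholds, depletion never
# lowers them below the genome-wide baseline
.grai_factor <- function(grai, chrom, pos) {
  pmax(grai_at(grai, chrom, pos), 1)
}

#' Initial scan for enriched regions by tag shifting
#'
#' Shifts every forward-strand 5' position by \code{+shift} and every
#' reverse-strand 5' position by \code{-shift} (half the fragment length,
#' so fragment midpoints align), then slides a \code{window}-bp window in
#' \code{step}-bp increments and keeps windows whose shifted-tag count
#' exceeds \code{threshold} scaled by the local GRAI.  Overlapping
#' qualifying windows are merged into regions; the provisional target site
#' of a region is the mean shifted-tag position within it.
#'
#' @param tags tag table.
#' @param shift tag shift in bp (fragment_length / 2).
#' @param assembly a \code{\link{genome_assembly}}.
#' @param window sliding-window width (bp, default 50).
#' @param step window step (bp, default window/2).
#' @param threshold count threshold; default from
#'   \code{\link{default_threshold}}.
#' @param grai optional \code{grai_track} for copy-number scaling.
#' @return list with \code{regions} (data.frame chrom, start, end,
#'   treatment_count, site) and the \code{threshold} used.
#' @export
initial_scan <- function(tags, shift, assembly, window = 50L,
                         step = window %/% 2L, threshold = NULL,
                         grai = NULL) {
  stopifnot(inherits(assembly, "genome_assembly"))
  if (is.null(threshold))
    threshold <- default_threshold(nrow(tags), assembly$genome_size, window)
  if (threshold <= 0) stop("threshold must be positive")
  regions <- list()
  for (ch in intersect(names(assembly$chrom_lengths), unique(tags$chrom))) {
    clen <- assembly$chrom_lengths[[ch]]
    t <- tags[tags$chrom == ch, , drop = FALSE]
    sp <- tag_pos5(t) + ifelse(t$strand == "+", shift, -shift)
    sp <- pmin(pmax(sp, 0), clen - 1L)
    bin <- floor(sp / step)
    nb <- as.integer(ceiling(clen / step))
    cnt <- tabulate(bin + 1L, nbins = nb)
    nwin <- as.integer(window / step)          # step-bins per window
    # count in window starting at bin b = sum of bins b .. b+nwin-1
    wc <- cnt
    if (nwin > 1) {
      cs <- c(0, cumsum(cnt))
      b <- seq_len(nb)
      wc <- cs[pmin(b + nwin, nb + 1L)] - cs[b]
    }
    wstart <- (seq_len(nb) - 1L) * step
    thr <- threshold * .grai_factor(grai, ch, wstart)
    ok <- which(wc > thr)
    if (!length(ok)) next
    runs <- cumsum(c(TRUE, diff(ok) > nwin))
    for (r in split(ok, runs)) {
      lo <- (min(r) - 1L) * step
      hi <- min((max(r) - 1L) * step + window, clen)
      sel <- sp >= lo & sp < hi
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = lo, end = hi,
        treatment_count = sum(sel), site = mean(sp[sel]),
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions)
             else data.frame(chrom = character(), start = integer(),
                             end = integer(), treatment_count = integer(),
                             site = numeric(), stringsAsFactors = FALSE)
  list(regions = regions, threshold = threshold)
}

#' Count tags whose 5' end falls in each region
#'
#' @param tags tag table.
#' @param regions data.frame with chrom, start, end (0-based half-open).
#' @return integer vector of counts, one per region.
#' @export
count_tags_in_regions <- function(tags, regions) {
  n <- nrow(regions)
  out <- integer(n)
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    p5 <- sort(tag_pos5(tags[tags$chrom == ch, , drop = FALSE]))
    if (!length(p5)) next
    out[i] <- findInterval(regions$end[i] - 1L, p5) -
      findInterval(regions$start[i] - 1L, p5)
  }
  out
}

#' One-sided Fisher's exact filter of regions against input
#'
#' For each region the 2x2 table
#' \code{[[t_in, N_t - t_in], [c_in, N_c - c_in]]} is tested one-sided for
#' treatment enrichment (hypergeometric tail, identical to
#' \code{fisher.test(..., alternative = "greater")}); regions with
#' \code{p >= alpha} are removed and \code{fisher_p} is recorded on the
#' survivors.  With no input data the regions pass through unchanged and no
#' p-value is attached.
#'
#' @param regions data.frame with \code{treatment_count} and (if input is
#'   available) \code{control_count} columns.
#' @param treatment_total total treatment tag count N_t.
#' @param input_total total input tag count N_c, or NULL if no input.
#' @param alpha significance cutoff (default 0.05).
#' @return Filtered regions with a \code{fisher_p} column when input was
#'   available.
#' @export
fisher_filter <- function(regions, treatment_total, input_total,
                          alpha = 0.05) {
  if (is.null(input_total)) {
    message("no input data: Fisher filtering skipped")
    return(regions)
  }
  if (!nrow(regions)) {
    regions$fisher_p <- numeric(0)
    return(regions)
  }
  stopifnot("control_count" %in% names(regions),
            treatment_total >= max(regions$treatment_count),
            input_total >= max(regions$control_count))
  a <- regions$treatment_count
  c_ <- regions$control_count
  # P(X >= a), X ~ Hypergeom(m = N_t, n = N_c, k = a + c)
  p <- stats::phyper(a - 1, treatment_total, input_total, a + c_,
                     lower.tail = FALSE)
  regions$fisher_p <- p
  regions[p < alpha, , drop = FALSE]
}

# Mode-normalized kernel of one strand: g_s(d) = ALD_s(d) / ALD_s(theta_s),
# tabulated on integer offsets theta_s +/- support.
.strand_kernel <- function(params, support) {
  d <- seq(round(params$theta) - support, round(params$theta) + support)
  list(dmin = d[1], dmax = d[length(d)],
       g = dald(d, params) / dald(params$theta, params))
}

#' Weighted enrichment track
#'
#' At every genomic position, the sum over nearby tags of the BALM
#' probability that the tag arose from a target site at that position,
#' normalized so a perfectly placed tag contributes 1: for a tag with 5'
#' end p on strand s, its contribution to position pos is
#' \code{ALD_s(p - pos) / ALD_s(theta_s)}.  The score is linear in the
#' tags, so doubling every tag doubles the track.
#'
#' @param tags tag table.
#' @param model a \code{\link{balm_model}}.
#' @param assembly a \code{\link{genome_assembly}}.
#' @param support kernel half-width around each strand's mode (bp, default
#'   1000); contributions beyond it are treated as 0.
#' @return Named list (class \code{enrichment_track}) of per-chromosome
#'   numeric vectors, index i = 0-based position i - 1.
#' @export
weighted_enrichment <- function(tags, model, assembly, support = 1000L) {
  stopifnot(inherits(model, "balm_model"))
  kf <- .strand_kernel(model$forward, support)
  kr <- .strand_kernel(model$reverse, support)
  out <- list()
  for (ch in names(assembly$chrom_lengths)) {
    clen <- assembly$chrom_lengths[[ch]]
    E <- numeric(clen)
    t <- tags[tags$chrom == ch, , drop = FALSE]
    if (nrow(t)) {
      p5 <- tag_pos5(t)
      for (s in c("+", "-")) {
        k <- if (s == "+") kf else kr
        tp <- p5[t$strand == s]
        if (!length(tp)) next
        cnt <- table(tp)
        pos0 <- as.integer(names(cnt))
        m <- as.integer(cnt)
        for (u in seq_along(pos0)) {
          # tag at p contributes g(d) to position p - d  (d = offset)
          lo <- pos0[u] - k$dmax; hi <- pos0[u] - k$dmin
          a <- max(lo, 0L); b <- min(hi, clen - 1L)
          if (a > b) next
          # kernel index for position q: d = p - q -> g index dmax - (q-lo) ...
          gi <- (pos0[u] - a) - k$dmin + 1L
          idx <- (a:b) + 1L
          E[idx] <- E[idx] + m[u] * k$g[gi - seq_along(idx) + 1L]
        }
      }
    }
    out[[ch]] <- E
  }
  structure(out, class = "enrichment_track")
}

#' Scan the genome for regions of high weighted enrichment
#'
#' Computes the weighted enrichment track, keeps maximal runs of positions
#' whose score exceeds \code{base_threshold} scaled by the local GRAI,
#' extends each run by half the fragment length on both sides, merges the
#' results, counts treatment (and input) tags per region and applies the
#' one-sided Fisher filter when input is available.
#'
#' @param tags tag table.
#' @param model a \code{\link{balm_model}}.
#' @param assembly a \code{\link{genome_assembly}}.
#' @param base_threshold enrichment threshold in effective tag counts;
#'   default from \code{\link{default_threshold}}.
#' @param grai optional \code{grai_track}.
#' @param input_tags optional input tag table (enables Fisher filtering).
#' @param alpha Fisher cutoff (default 0.05).
#' @param support kernel half-width (bp).
#' @param track a precomputed \code{\link{weighted_enrichment}} track, to
#'   avoid recomputation.
#' @return data.frame of regions: chrom, start, end, treatment_count,
#'   (control_count, fisher_p,) max_enrichment, grai.
#' @export
weighted_enrichment_scan <- function(tags, model, assembly,
                                     base_threshold = NULL, grai = NULL,
                                     input_tags = NULL, alpha = 0.05,
                                     support = 1000L, track = NULL) {
  if (is.null(model)) stop("a fitted BALM is required")
  if (is.null(base_threshold))
    base_threshold <- default_threshold(nrow(tags), assembly$genome_size)
  if (is.null(track))
    track <- weighted_enrichment(tags, model, assembly, support)
  pad <- as.integer(round(model$fragment_length / 2))
  regions <- list()
  for (ch in names(track)) {
    E <- track[[ch]]
    clen <- length(E)
    thr <- base_threshold *
      .grai_factor(grai, ch, seq_len(clen) - 1L)
    r <- rle(E > thr)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    ir <- IRanges::reduce(IRanges::IRanges(
      pmax(starts[hit] - pad, 1L), pmin(ends[hit] + pad, clen)))
    for (j in seq_along(ir)) {
      s0 <- BiocGenerics::start(ir)[j] - 1L
      e0 <- BiocGenerics::end(ir)[j]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = s0, end = e0,
        max_enrichment = max(E[(s0 + 1L):e0]),
        grai = max(.grai_factor(grai, ch, c(s0, e0 - 1L))),
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions)
             else data.frame(chrom = character(), start = integer(),
                             end = integer(), max_enrichment = numeric(),
                             grai = numeric(), stringsAsFactors = FALSE)
  regions$treatment_count <- count_tags_in_regions(tags, regions)
  if (!is.null(input_tags) && nrow(regions)) {
    regions$control_count <- count_tags_in_regions(input_tags, regions)
    regions <- fisher_filter(regions, nrow(tags), nrow(input_tags), alpha)
  } else if (!is.null(input_tags)) {
    regions$control_count <- integer(0)
    regions$fisher_p <- numeric(0)
  }
  rownames(regions) <- NULL
  regions
}

#' Select the tags belonging to a region
#'
#' With a model, a tag belongs to the region when its implied site (5' end
#' minus the strand's modal offset) falls inside it — so flanking tags whose
#' fragments originate from sites in the region are included; without a
#' model, the tag's 5' end itself must fall inside.
#'
#' @param tags tag table.
#' @param region one-row data.frame (chrom, start, end).
#' @param model optional \code{\link{balm_model}}.
#' @return the matching rows of \code{tags}.
#' @export
tags_in_region <- function(tags, region, model = NULL) {
  on <- tags$chrom == region$chrom
  pos <- if (is.null(model)) tag_pos5(tags)
         else .implied_sites(tag_pos5(tags), tags$strand, model)
  tags[on & pos >= region$start & pos < region$end, , drop = FALSE]
}
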