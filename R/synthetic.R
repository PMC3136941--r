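#' Reference BALM used by the synthetic-data generators
#'
#' Emulates single-end tags from sonicated, size-selected DNA fragments
#' (roughly 100-200 bp, mean 150): the forward-strand 5'-end mode sits
#' 75 bp upstream of the site, the reverse-strand mode 75 bp downstream,
#' scale 30 bp, and a mild asymmetry (kappa 1.3 forward, 1/1.3 reverse)
#' putting the longer tail on the far side of the site, as size selection
#' truncates short fragments more sharply than long ones.
#'
#' @param fragment_length mean fragment length (bp, default 150).
#' @param sigma offset scale (bp, default 30).
#' @param kappa forward-strand asymmetry (default 1.3; reverse gets 1/kappa).
#' @return a \code{\link{balm_model}}.
#' @export
default_balm_model <- function(fragment_length = 150, sigma = 30,
                               kappa = 1.3) {
  balm_model(
    ald_params(-fragment_length / 2, kappa, sigma),
    ald_params(fragment_length / 2, 1 / kappa, sigma),
    strand_weights = c(0.5, 0.5),
    fragment_length = fragment_length)
}

# island sequence: a CG every `period` bp; the filler alphabet omits G so
# no unplanned CG can arise between the planted sites
.island_seq <- function(width, period = 10L) {
  filler <- function(k) paste(sample(c("A", "T", "C"), k,
                                     replace = TRUE), collapse = "")
  ncg <- width %/% period
  if (ncg == 0L) return(filler(width))
  parts <- character(ncg)
  for (i in seq_len(ncg)) parts[i] <- paste0("CG", filler(period - 2L))
  s <- paste(parts, collapse = "")
  substr(s, 1, width)
}

# background sequence with suppressed CG dinucleotides: ~95% of chance CGs
# are broken by mutating the G, leaving sparse background CpGs
.background_seq <- function(len) {
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
              prob = c(0.3, 0.2, 0.2, 0.3))
  cg <- which(b[-len] == "C" & b[-1] == "G")
  broken <- cg[stats::runif(length(cg)) < 0.95]
  b[broken + 1L] <- sample(c("A", "T"), length(broken), replace = TRUE)
  b
}

#' Generate a toy genome with CpG islands and known methylation truth
#'
#' One synthetic chromosome: CG-suppressed random background with embedded
#' CpG-rich islands carrying one CpG every \code{cpg_period} bp.  The
#' default period of 60 bp keeps island CpG density an order of magnitude
#' above background while spacing the sites at the mixture model's
#' resolution scale, so each methylated CpG can carry its own mixture
#' component.  Island methylation states cycle through fully methylated,
#' partially methylated and unmethylated in 6:3:2 proportions, echoing a
#' validation design of 6 fully, 3 partially and 2 unmethylated regions;
#' background CpGs are unmethylated.  Optional amplification intervals
#' carry integer copy numbers that the tag samplers honour.
#'
#' @param length chromosome length (bp, >= 10000; default 200000).
#' @param cpg_island_count number of islands (default 11).
#' @param seed RNG seed; the whole object is a pure function of it.
#' @param island_width island width (bp, default 600).
#' @param cpg_period island CpG spacing (bp, default 60).
#' @param amp_intervals optional data.frame (start, end, copy) of 0-based
#'   half-open amplified intervals with copy number > 1.
#' @param chrom chromosome name (default "chrS").
#' @return Object of class \code{synthetic_truth}: \code{seq}
#'   (a \code{DNAStringSet}), \code{cpg} (data.frame pos, state),
#'   \code{islands}, \code{sites} (methylated CpGs: pos, state),
#'   \code{amp}, \code{chrom}, \code{length}, \code{seed}.
#' @export
make_toy_genome <- function(length = 200000L, cpg_island_count = 11L,
                            seed = 1L, island_width = 600L,
                            cpg_period = 60L, amp_intervals = NULL,
                            chrom = "chrS") {
  if (length < 10000L) stop("toy genome must be at least 10 kb")
  set.seed(seed)
  gap <- (length - cpg_island_count * island_width) %/%
    (cpg_island_count + 1L)
  if (gap < island_width) stop("genome too short for that many islands")
  starts <- gap + (seq_len(cpg_island_count) - 1L) * (island_width + gap)
  base <- .background_seq(length)
  states_cycle <- c(1, 1, 0, 0.5, 1, 1, 0.5, 1, 0, 1, 0.5)  # 6:3:2 per 11
  st <- rep_len(states_cycle, cpg_island_count)
  for (i in seq_len(cpg_island_count)) {
    isl <- strsplit(.island_seq(island_width, cpg_period), "")[[1]]
    base[(starts[i] + 1L):(starts[i] + island_width)] <- isl
  }
  seqs <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(seqs) <- chrom
  cpg_pos <- extract_cpg_sites(seqs)[[chrom]]
  state <- rep(0, base::length(cpg_pos))
  for (i in seq_len(cpg_island_count)) {
    inside <- cpg_pos >= starts[i] & cpg_pos < starts[i] + island_width
    state[inside] <- st[i]
  }
  islands <- data.frame(start = starts, end = starts + island_width,
                        state = st)
  if (!is.null(amp_intervals))
    stopifnot(all(c("start", "end", "copy") %in% names(amp_intervals)),
              all(amp_intervals$copy >= 1))
  structure(list(
    seq = seqs, chrom = chrom, length = as.integer(length),
    cpg = data.frame(pos = cpg_pos, state = state),
    islands = islands,
    sites = data.frame(pos = cpg_pos[state > 0], state = state[state > 0]),
    amp = amp_intervals, seed = seed), class = "synthetic_truth")
}

#' Write the toy genome's sequence as FASTA
#'
#' @param truth a \code{synthetic_truth}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_toy_fasta <- function(truth, path) {
  Biostrings::writeXStringSet(truth$seq, path)
  invisible(path)
}

#' Assembly describing a toy genome
#'
#' @param truth a \code{synthetic_truth}.
#' @return a \code{\link{genome_assembly}} with the single toy chromosome.
#' @export
toy_assembly <- function(truth) {
  genome_assembly(stats::setNames(truth$length, truth$chrom))
}

# copy number at positions, from amp intervals (1 outside)
.copy_at <- function(amp, pos) {
  cn <- rep(1, length(pos))
  if (is.null(amp)) return(cn)
  for (k in seq_len(nrow(amp)))
    cn[pos >= amp$start[k] & pos < amp$end[k]] <- amp$copy[k]
  cn
}

# assemble a tag table from 5' positions and strands, clamped to bounds
.tags_from_pos5 <- function(chrom, p5, strand, tag_length, chrom_length) {
  p5 <- round(p5)
  start <- ifelse(strand == "+", p5, p5 - tag_length + 1L)
  end <- start + tag_length
  ok <- start >= 0 & end <= chrom_length
  aligned_tags(rep(chrom, sum(ok)), start[ok], end[ok], strand[ok])
}

#' Sample MBD-seq-like tags from a toy genome
#'
#' Per methylated site, the tag count is Poisson with mean
#' \code{tags_per_site * state} (partially methylated sites yield
#' proportionally fewer tags); each tag draws a strand from the model's
#' strand weights and a 5'-end offset from that strand's asymmetric
#' Laplace.  Background tags are uniform at \code{background_rate} per bp.
#' Within amplification intervals both background and (by default) signal
#' counts scale with the copy number.
#'
#' @param truth a \code{synthetic_truth}.
#' @param model generating \code{\link{balm_model}} (default
#'   \code{\link{default_balm_model}()}).
#' @param tags_per_site mean tags per fully methylated site (default 20).
#' @param background_rate background tags per bp (default 0.005).
#' @param seed RNG seed.
#' @param tag_length read length in bp (default 50).
#' @param amplify_signal scale signal tags by local copy number too
#'   (default TRUE, as amplified DNA is itself enriched).
#' @return a tag table.
#' @export
sample_tags <- function(truth, model = default_balm_model(),
                        tags_per_site = 20, background_rate = 0.005,
                        seed = 1L, tag_length = 50L, amplify_signal = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(model, "balm_model"))
  if (nrow(truth$sites) == 0 && background_rate == 0)
    stop("nothing to sample: no methylated sites and zero background")
  set.seed(seed)
  p5 <- numeric(0); strand <- character(0)
  if (nrow(truth$sites) && tags_per_site > 0) {
    cn <- if (amplify_signal) .copy_at(truth$amp, truth$sites$pos) else 1
    n_i <- stats::rpois(nrow(truth$sites),
                        tags_per_site * truth$sites$state * cn)
    site <- rep(truth$sites$pos, n_i)
    n <- length(site)
    if (n) {
      s <- ifelse(stats::runif(n) < model$strand_weights[[1]], "+", "-")
      off <- numeric(n)
      off[s == "+"] <- rald(sum(s == "+"), model$forward)
      off[s == "-"] <- rald(sum(s == "-"), model$reverse)
      p5 <- site + off
      strand <- s
    }
  }
  if (background_rate > 0) {
    # per-bp intensity = rate * copy number; sample segment-wise
    segs <- data.frame(start = 0L, end = truth$length, copy = 1)
    if (!is.null(truth$amp)) {
      cuts <- sort(unique(c(0L, truth$amp$start, truth$amp$end,
                            truth$length)))
      segs <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
      segs$copy <- .copy_at(truth$amp, segs$start)
    }
    for (k in seq_len(nrow(segs))) {
      lam <- background_rate * segs$copy[k] * (segs$end[k] - segs$start[k])
      nb <- stats::rpois(1, lam)
      if (!nb) next
      bp <- segs$start[k] + floor(stats::runif(nb) *
                                  (segs$end[k] - segs$start[k]))
      bs <- sample(c("+", "-"), nb, replace = TRUE)
      p5 <- c(p5, bp); strand <- c(strand, bs)
    }
  }
  .tags_from_pos5(truth$chrom, p5, strand, tag_length, truth$length)
}

#' Sample input (control) tags reflecting copy number only
#'
#' Uniform coverage at \code{rate} per bp, scaled by the copy number of the
#' truth's amplification intervals — methylation state plays no role.
#'
#' @param truth a \code{synthetic_truth}.
#' @param rate tags per bp (default 0.02).
#' @param seed RNG seed.
#' @param tag_length read length (default 50).
#' @return a tag table.
#' @export
sample_input_tags <- function(truth, rate = 0.02, seed = 2L,
                              tag_length = 50L) {
  bg <- truth
  bg$sites <- bg$sites[0, , drop = FALSE]
  sample_tags(bg, tags_per_site = 0, background_rate = rate, seed = seed,
              tag_length = tag_length)
}

#' Spike-in datasets of two closely spaced sites
#'
#' For each separation, plants exactly two sites that far apart at the
#' middle of an otherwise empty toy chromosome and samples
#' \code{depth} tags per site from the model plus sparse uniform
#' background.  Depth presets: low = 50, medium = 200, high = 500 tags per
#' site.
#'
#' @param separations center-to-center distances in bp (default
#'   \code{c(100, 50, 25)}).
#' @param depth tags per site: a count or one of "low", "medium", "high".
#' @param model generating \code{\link{balm_model}}.
#' @param seed RNG seed.
#' @param chrom_length toy chromosome length (default 20000).
#' @param background_rate uniform background tags per bp (default 5e-4).
#' @param tag_length read length (default 50).
#' @return Named list (one entry per separation) of lists with \code{tags},
#'   \code{sites} (the two planted positions), \code{separation},
#'   \code{depth}, \code{chrom}, \code{chrom_length}.
#' @export
spike_in <- function(separations = c(100L, 50L, 25L), depth = "high",
                     model = default_balm_model(), seed = 1L,
                     chrom_length = 20000L, background_rate = 5e-4,
                     tag_length = 50L) {
  stopifnot(all(separations > 0))
  presets <- c(low = 50L, medium = 200L, high = 500L)
  d <- if (is.character(depth)) presets[[match.arg(depth, names(presets))]]
       else as.integer(depth)
  out <- list()
  for (sep in separations) {
    set.seed(seed + sep)                # dataset a pure function of (seed, sep)
    s1 <- chrom_length %/% 2L
    sites <- c(s1, s1 + sep)
    n <- 2L * d
    site <- rep(sites, each = d)
    s <- ifelse(stats::runif(n) < model$strand_weights[[1]], "+", "-")
    off <- numeric(n)
    off[s == "+"] <- rald(sum(s == "+"), model$forward)
    off[s == "-"] <- rald(sum(s == "-"), model$reverse)
    p5 <- site + off
    strand <- s
    nb <- stats::rpois(1, background_rate * chrom_length)
    if (nb) {
      p5 <- c(p5, floor(stats::runif(nb) * chrom_length))
      strand <- c(strand, sample(c("+", "-"), nb, replace = TRUE))
    }
    out[[as.character(sep)]] <- list(
      tags = .tags_from_pos5("chrS", p5, strand, tag_length, chrom_length),
      sites = sites, separation = sep, depth = d, chrom = "chrS",
      chrom_length = chrom_length)
  }
  out
}

#' CpG coverage-saturation curves by nested subsampling
#'
#' Random tag subsamples of increasing fraction are nested (the f1-fraction
#' sample is a subset of the f2-fraction sample for f1 < f2), so coverage
#' is nondecreasing in the fraction by construction.  Each tag is extended
#' to a fragment of \code{fragment_length} bp from its 5' end; a CpG is
#' covered at depth d if at least d fragments overlap it.
#'
#' @param tags tag table.
#' @param cpg_map named list per chromosome of 0-based CpG positions.
#' @param fractions subsample fractions in (0, 1].
#' @param min_depth_levels depth thresholds d (default c(1, 5, 10)).
#' @param fragment_length fragment extension (bp, default 150).
#' @param seed RNG seed for the single permutation.
#' @return data.frame fraction, depth, covered, total, coverage.
#' @export
coverage_saturation <- function(tags, cpg_map, fractions = seq(0.1, 1, 0.1),
                                min_depth_levels = c(1L, 5L, 10L),
                                fragment_length = 150L, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  total <- sum(lengths(cpg_map))
  fractions <- sort(fractions)
  n <- nrow(tags)
  if (n == 0) {
    return(data.frame(fraction = rep(fractions, each = length(min_depth_levels)),
                      depth = rep(min_depth_levels, length(fractions)),
                      covered = 0L, total = total, coverage = 0))
  }
  set.seed(seed)
  perm <- sample.int(n)
  p5 <- tag_pos5(tags)
  fs <- ifelse(tags$strand == "+", p5, pmax(p5 - fragment_length + 1L, 0L))
  fe <- ifelse(tags$strand == "+", p5 + fragment_length, p5 + 1L)
  rows <- list()
  for (f in fractions) {
    idx <- perm[seq_len(ceiling(f * n))]
    depth_all <- integer(0)
    for (ch in names(cpg_map)) {
      cp <- cpg_map[[ch]]
      if (!length(cp)) next
      on <- idx[tags$chrom[idx] == ch]
      depth <- if (length(on))
        IRanges::countOverlaps(IRanges::IRanges(cp + 1L, cp + 1L),
                               IRanges::IRanges(fs[on] + 1L, fe[on]))
      else integer(length(cp))
      depth_all <- c(depth_all, depth)
    }
    for (d in min_depth_levels) {
      cov <- sum(depth_all >= d)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, depth = d, covered = cov, total = total,
        coverage = cov / total)
    }
  }
  do.call(rbind, rows)
}

#' Fit a reference BALM on simulated training data
#'
#' Simulates isolated point sites (peaks) with uniform background over a
#' toy genome, discovers them with the tag-shifting initial scan, and fits
#' the BALM on offsets pooled around the provisional sites — the same
#' bootstrap a real run performs before any spike-in or resolution
#' analysis.
#'
#' @param seed RNG seed.
#' @param n_peaks number of planted training sites (default 30).
#' @param depth tags per training site (default 500).
#' @param background uniform background tag count (default 2000).
#' @param genome_size training chromosome length (default 1e6).
#' @param model generating \code{\link{balm_model}}.
#' @return the fitted \code{\link{balm_model}}.
#' @export
simulated_training_fit <- function(seed = 5L, n_peaks = 30L, depth = 500L,
                                   background = 2000L, genome_size = 1e6L,
                                   model = default_balm_model()) {
  asm <- genome_assembly(stats::setNames(as.integer(genome_size), "chrT"))
  spec <- null_sim_spec(asm, background_count = background,
                        peak_count = n_peaks, peak_depths = depth,
                        model = model, seed = seed)
  sim <- simulate_dataset(spec)
  fl <- estimate_fragment_length(sim$tags)
  sc <- initial_scan(sim$tags, shift = round(fl / 2), assembly = asm)
  fit_balm(sim$tags,
           data.frame(chrom = sc$regions$chrom, pos = sc$regions$site,
                      stringsAsFactors = FALSE))
}

#' Two-site resolution benchmark
#'
#' Reproduces the spike-in resolution experiment: for each separation,
#' \code{n_seeds} datasets of two sites sampled from \code{fit} are
#' generated, the enriched region is detected by the initial scan, the
#' mixture is fitted with \code{\link{select_components}}, and a replicate
#' succeeds when exactly two components are selected with each center
#' within \code{tol_bp} of its planted site.
#'
#' @param fit the \code{\link{balm_model}} used both to sample and to
#'   detect (as in a real run, where the fitted model drives detection).
#' @param separations separation grid in bp (default c(100, 50, 25)).
#' @param depth preset name or tags per site (see \code{\link{spike_in}}).
#' @param n_seeds replicates per separation (default 20).
#' @param seed base seed.
#' @param tol_bp center accuracy tolerance (default 10).
#' @return data.frame separation, successes, n_seeds, rate, with attribute
#'   \code{"smallest_resolved"}: the smallest separation with rate >= 0.8
#'   (NA if none).
#' @export
resolution_benchmark <- function(fit, separations = c(100L, 50L, 25L),
                                 depth = "high", n_seeds = 20L, seed = 1L,
                                 tol_bp = 10) {
  asm <- genome_assembly(c(chrS = 20000L))
  rows <- lapply(separations, function(sep) {
    succ <- 0L
    for (s in seq_len(n_seeds)) {
      d <- spike_in(sep, depth = depth, model = fit,
                    seed = seed + 1000L * s)[[1]]
      sc <- initial_scan(d$tags, shift = round(fit$fragment_length / 2),
                         assembly = asm)
      if (!nrow(sc$regions)) next
      reg <- sc$regions[which.max(sc$regions$treatment_count), , drop = FALSE]
      rt <- tags_in_region(d$tags, reg, fit)
      set.seed(seed + 7L * s)
      rmod <- select_components(rt, fit, region = reg)
      if (nrow(rmod$components) == 2L &&
          all(abs(sort(rmod$components$center) - sort(d$sites)) <= tol_bp))
        succ <- succ + 1L
    }
    data.frame(separation = sep, successes = succ, n_seeds = n_seeds,
               rate = succ / n_seeds)
  })
  out <- do.call(rbind, rows)
  resolved <- out$separation[out$rate >= 0.8]
  attr(out, "smallest_resolved") <-
    if (length(resolved)) min(resolved) else NA_integer_
  out
}
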