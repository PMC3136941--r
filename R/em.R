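# Implied site position of each tag: the site at which the tag's offset
# would sit exactly at its strand's mode.
.implied_sites <- function(pos5, strand, model) {
  pos5 - ifelse(strand == "+", model$forward$theta, model$reverse$theta)
}

# log f_BALM(x_i, s_i | center c_j) for all tags x columns of centers:
# n x K matrix of log component densities.
.component_logdens <- function(pos5, strand, centers, model) {
  n <- length(pos5); K <- length(centers)
  out <- matrix(0, n, K)
  for (j in seq_len(K))
    out[, j] <- balm_density(pos5 - centers[j], strand, model, log = TRUE)
  out
}

# Exact M-step location update for one component: maximize
# sum_i r_i log f_{s_i}(x_i - c) over candidate centers, with kappa/sigma
# frozen.  The objective is piecewise linear in c with breakpoints at the
# tag-implied sites, so the optimum is attained at one of them; candidates
# are restricted to +/- window of the current center for stability.
# Evaluated for all candidates at once with prefix sums per strand.
.mstep_center <- function(pos5, strand, r, model, current, window = 200) {
  cand <- sort(unique(.implied_sites(pos5, strand, model)))
  near <- cand[abs(cand - current) <= window]
  if (!length(near)) near <- cand[which.min(abs(cand - current))]
  obj <- numeric(length(near))
  for (s in c("+", "-")) {
    sel <- strand == s
    if (!any(sel)) next
    p <- .strand_params(model, s)
    x <- pos5[sel]; w <- r[sel]
    o <- order(x); x <- x[o]; w <- w[o]
    cw <- cumsum(w); cwx <- cumsum(w * x)
    W <- cw[length(cw)]; WX <- cwx[length(cwx)]
    t_s <- near + p$theta               # split point in tag coordinates
    i <- findInterval(t_s, x)
    cw_le <- ifelse(i > 0, cw[pmax(i, 1L)], 0)
    cwx_le <- ifelse(i > 0, cwx[pmax(i, 1L)], 0)
    below <- t_s * cw_le - cwx_le        # sum w (t - x)^+
    above <- (WX - cwx_le) - t_s * (W - cw_le)
    obj <- obj - sqrt(2) / p$sigma *
      (p$kappa * above + below / p$kappa)
  }
  near[which.max(obj)]                  # ties -> smallest candidate
}

#' Fit a K-component BALM mixture to one region's tags by EM
#'
#' The mixture density of a tag with 5' end x on strand s is
#' \eqn{\sum_j \pi_j w_s \mathrm{ALD}_s(x - c_j)}: component centers
#' \eqn{c_j} are candidate target sites, the shared shape (kappa, sigma,
#' strand weights) comes from the globally fitted BALM and stays frozen, so
#' the free parameters are the K centers and K - 1 independent weights
#' (\code{k_free = 2K - 1}).  The E-step computes responsibilities, the
#' M-step updates weights by mean responsibility and each center by the
#' exact weighted ALD location MLE restricted to a neighbourhood of the
#' current center; the log-likelihood is nondecreasing across iterations.
#'
#' @param region_tags tag table restricted to one region.
#' @param K number of components (>= 1).
#' @param model the fitted \code{\link{balm_model}}.
#' @param init_centers optional numeric vector of K starting centers;
#'   defaults to quantile-spread implied sites.
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param weight_floor components whose weight falls below this are dropped
#'   (default 1e-3).
#' @param center_window M-step center search half-width (bp, default 200).
#' @param region optional region data.frame row carried into the result.
#' @return Object of class \code{region_model}: \code{components}
#'   (data.frame center, weight, sorted by center), \code{log_likelihood},
#'   \code{n_tags}, \code{k_free}, \code{bic}, \code{logL_trace},
#'   \code{converged}, \code{dropped}.
#' @export
em_fit <- function(region_tags, K, model, init_centers = NULL,
                   max_iter = 200L, tol = 1e-6, weight_floor = 1e-3,
                   center_window = 200, region = NULL) {
  stopifnot(K >= 1)
  pos5 <- tag_pos5(region_tags)
  strand <- region_tags$strand
  n <- length(pos5)
  if (n < K) stop("fewer tags than components")
  if (is.null(init_centers)) {
    imp <- .implied_sites(pos5, strand, model)
    init_centers <- unname(stats::quantile(imp, (seq_len(K) - 0.5) / K))
  }
  stopifnot(length(init_centers) == K)
  centers <- sort(as.numeric(init_centers))
  pi_j <- rep(1 / K, K)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  dropped <- 0L
  for (it in seq_len(max_iter)) {
    ld <- .component_logdens(pos5, strand, centers, model)
    lw <- sweep(ld, 2, log(pi_j), `+`)
    mx <- lw[, 1]
    for (j in seq_along(centers)[-1]) mx <- pmax(mx, lw[, j])
    lse <- mx + log(rowSums(exp(lw - mx)))
    logL <- sum(lse)
    trace <- c(trace, logL)
    r <- exp(lw - lse)                  # responsibilities, rows sum to 1
    if (is.finite(prev) && abs(logL - prev) <= tol * (abs(prev) + 1)) {
      converged <- TRUE
      break
    }
    prev <- logL
    pi_new <- colMeans(r)
    keep <- pi_new >= weight_floor
    if (!all(keep)) {
      if (sum(keep) == 0) keep[which.max(pi_new)] <- TRUE
      dropped <- dropped + sum(!keep)
      centers <- centers[keep]
      r <- r[, keep, drop = FALSE]
      pi_new <- colMeans(r)
      pi_new <- pi_new / sum(pi_new)
      prev <- -Inf                      # mixture changed; restart comparison
      trace <- numeric(0)               # trace reports the final mixture only
    }
    pi_j <- pi_new / sum(pi_new)
    for (j in seq_along(centers))
      centers[j] <- .mstep_center(pos5, strand, r[, j], model, centers[j],
                                  center_window)
  }
  o <- order(centers)
  centers <- centers[o]; pi_j <- pi_j[o]
  k_free <- 2L * length(centers) - 1L
  logL <- trace[length(trace)]
  structure(list(
    region = region,
    components = data.frame(center = centers, weight = pi_j),
    log_likelihood = logL, n_tags = n, k_free = k_free,
    bic = bic_value(logL, k_free, n),
    logL_trace = trace, converged = converged, dropped = dropped,
    model = model), class = "region_model")
}

#' Bayesian Information Criterion
#'
#' \code{k * log(n) - 2 * logL}; the model minimizing it is selected.
#'
#' @param logL log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (tags in the region).
#' @return BIC value.
#' @export
bic_value <- function(logL, k, n) k * log(n) - 2 * logL

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("BALM mixture: %d component(s), n = %d tags, logL = %.2f, BIC = %.2f\n",
              nrow(x$components), x$n_tags, x$log_likelihood, x$bic))
  print(x$components)
  invisible(x)
}

# k-means++-style seeding over implied site positions (1D): first center
# drawn uniformly, later centers with probability proportional to squared
# distance to the nearest chosen center.
.kmeanspp_centers <- function(imp, K) {
  centers <- numeric(K)
  centers[1] <- imp[sample.int(length(imp), 1L)]
  if (K > 1) {
    d2 <- (imp - centers[1])^2
    for (j in 2:K) {
      if (all(d2 == 0)) {
        centers[j:K] <- centers[1]
        break
      }
      centers[j] <- imp[sample.int(length(imp), 1L, prob = d2)]
      d2 <- pmin(d2, (imp - centers[j])^2)
    }
  }
  sort(centers)
}

#' Select the number of mixture components by BIC
#'
#' Fits BALM mixtures with K = 1 .. K_max components, each from
#' \code{n_starts} seedings (one deterministic quantile spread plus
#' k-means++ restarts), keeps the best log-likelihood per K and returns the
#' fit minimizing the BIC.  The default K_max grows with region length at
#' one component per 50 bp (the model's resolution scale), capped at 20.
#'
#' @param region_tags tag table restricted to one region.
#' @param model the fitted \code{\link{balm_model}}.
#' @param K_max maximum component count; default from the span of the tags.
#' @param n_starts EM restarts per K (default 5).
#' @param min_tags_per_component K is only tried while
#'   \code{n >= K * min_tags_per_component} (default 10); the same support
#'   requirement sets the component weight floor, so a component carried by
#'   fewer effective tags than this is dropped rather than reported as a
#'   site.
#' @param region optional region data.frame row carried into the result.
#' @param weight_floor override for the weight floor (default
#'   \code{min_tags_per_component / n}).
#' @param ... passed to \code{\link{em_fit}}.
#' @return The BIC-minimizing \code{region_model}; all per-K BIC values are
#'   attached as attribute \code{"bic_by_k"}.
#' @export
select_components <- function(region_tags, model, K_max = NULL,
                              n_starts = 5L, min_tags_per_component = 10L,
                              region = NULL, weight_floor = NULL, ...) {
  pos5 <- tag_pos5(region_tags)
  strand <- region_tags$strand
  imp <- .implied_sites(pos5, strand, model)
  if (is.null(weight_floor))
    weight_floor <- min(0.5, min_tags_per_component / length(pos5))
  if (is.null(K_max)) {
    span <- if (!is.null(region)) region$end - region$start
            else diff(stats::quantile(imp, c(0.05, 0.95)))
    K_max <- max(1L, min(20L, as.integer(span %/% 50)))
  }
  K_max <- max(1L, min(K_max, length(pos5) %/% min_tags_per_component,
                       length(unique(imp))))
  best <- NULL
  bics <- rep(NA_real_, K_max)
  worse <- 0L
  for (K in seq_len(K_max)) {
    fit_K <- NULL
    for (s in seq_len(n_starts)) {
      init <- if (s == 1)
        unname(stats::quantile(imp, (seq_len(K) - 0.5) / K))
      else .kmeanspp_centers(imp, K)
      f <- tryCatch(
        em_fit(region_tags, K, model, init_centers = init,
               region = region, weight_floor = weight_floor, ...),
        error = function(e) NULL)
      if (is.null(f)) next
      if (nrow(f$components) != K) next   # collapsed fit: not a K-model
      if (is.null(fit_K) || f$log_likelihood > fit_K$log_likelihood)
        fit_K <- f
    }
    if (is.null(fit_K)) next
    bics[K] <- fit_K$bic
    if (is.null(best) || fit_K$bic < best$bic) {
      best <- fit_K
      worse <- 0L
    } else {
      worse <- worse + 1L
      if (worse >= 2L) break         # BIC past its minimum; stop enlarging K
    }
  }
  if (is.null(best))                      # all fits degenerate: K = 1 direct
    best <- em_fit(region_tags, 1L, model, region = region,
                   weight_floor = weight_floor, ...)
  attr(best, "bic_by_k") <- bics
  best
}

#' Per-CpG methylation scores from a fitted region mixture
#'
#' Each mixture component is assigned to the nearest CpG within
#' \code{assign_radius}; the effective tag mass at a CpG is the sum of
#' \code{weight * n_tags} over its assigned components, divided by the
#' local GRAI (floored at 1, so amplification deflates the mass but
#' depletion never inflates it).  The score is
#' \code{min(1, mass / calibration)}: 0 for CpGs inside the region with no
#' assigned component, approaching 1 at saturating depth.  CpGs outside
#' the region are not emitted (unobserved).
#'
#' @param region_model a \code{region_model} from \code{\link{em_fit}} /
#'   \code{\link{select_components}}; its \code{region} field must carry
#'   chrom/start/end.
#' @param cpg_map named list per chromosome of sorted 0-based CpG positions.
#' @param calibration saturation mass: the effective mass that maps to
#'   score 1 (> 0).
#' @param grai optional \code{grai_track}.
#' @param assign_radius component-to-CpG assignment radius (bp, default 25).
#' @return data.frame chrom, pos, score, effective_count — one row per CpG
#'   inside the region.  Components with no CpG within radius are returned
#'   in attribute \code{"non_cpg_sites"}.
#' @export
methylation_scores <- function(region_model, cpg_map, calibration,
                               grai = NULL, assign_radius = 25) {
  stopifnot(inherits(region_model, "region_model"), calibration > 0)
  reg <- region_model$region
  if (is.null(reg)) stop("region_model carries no region coordinates")
  cpg <- cpg_map[[reg$chrom]]
  cpg <- cpg[cpg >= reg$start & cpg < reg$end]
  comp <- region_model$components
  empty <- data.frame(chrom = character(), pos = integer(),
                      score = numeric(), effective_count = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(cpg)) {
    message(sprintf("region %s:%d-%d contains no CpG site", reg$chrom,
                    reg$start, reg$end))
    attr(empty, "non_cpg_sites") <- comp
    return(empty)
  }
  mass <- numeric(length(cpg))
  unassigned <- rep(FALSE, nrow(comp))
  for (j in seq_len(nrow(comp))) {
    d <- abs(cpg - comp$center[j])
    i <- which.min(d)
    if (d[i] <= assign_radius) {
      g <- .grai_factor(grai, reg$chrom, cpg[i])
      mass[i] <- mass[i] + comp$weight[j] * region_model$n_tags / g
    } else {
      unassigned[j] <- TRUE
    }
  }
  out <- data.frame(chrom = reg$chrom, pos = cpg,
                    score = pmin(1, mass / calibration),
                    effective_count = mass, stringsAsFactors = FALSE)
  attr(out, "non_cpg_sites") <- comp[unassigned, , drop = FALSE]
  out
}
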