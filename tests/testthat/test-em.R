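test_that("K = 1 responsibilities are exactly 1 and weights sum to 1", {
  m0 <- default_balm_model()
  set.seed(101)
  d <- spike_in(500, depth = "low", model = m0, seed = 3)[[1]]
  f <- em_fit(d$tags, 1, m0)
  expect_equal(nrow(f$components), 1)
  expect_equal(sum(f$components$weight), 1)
  f2 <- em_fit(d$tags, 2, m0)
  expect_equal(sum(f2$components$weight), 1, tolerance = 1e-12)
})

test_that("EM log-likelihood is nondecreasing on seeded random inputs", {
  m0 <- default_balm_model()
  for (s in 1:50) {
    set.seed(s)
    n <- sample(50:200, 1)
    p5 <- round(c(rald(n, m0$forward), rald(n, m0$reverse)) +
                  sample(0:300, 2 * n, TRUE) + 5000)
    st <- rep(c("+", "-"), each = n)
    tags <- tags_from_p5(p5, st)
    K <- sample(1:3, 1)
    f <- em_fit(tags, K, m0)
    expect_true(all(diff(f$logL_trace) >= -1e-9),
                label = sprintf("ascent, seed %d", s))
  }
})

test_that("two sites 500 bp apart are recovered with tight centers and weights", {
  m0 <- default_balm_model()
  hits <- 0L
  errs <- c()
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    d <- spike_in(500, depth = "high", model = m0, seed = 300 + s)[[1]]
    set.seed(s)
    f <- em_fit(d$tags, 2, m0)
    cc <- sort(f$components$center)
    errs <- c(errs, cc - sort(d$sites))
    ok <- all(abs(cc - sort(d$sites)) <= 5) &&
      all(abs(f$components$weight - 0.5) <= 0.05)
    hits <- hits + ok
  }
  expect_gte(hits / n_seeds, 0.95)
  expect_lte(sqrt(mean(errs^2)), 5)          # center RMSE benchmark
})

test_that("BIC stored on a fit is consistent with its parts", {
  m0 <- default_balm_model()
  d <- spike_in(200, depth = "medium", model = m0, seed = 9)[[1]]
  f <- em_fit(d$tags, 2, m0)
  expect_identical(f$bic, bic_value(f$log_likelihood, f$k_free, f$n_tags))
  expect_identical(f$k_free, 2L * nrow(f$components) - 1L)
  expect_identical(f$n_tags, nrow(d$tags))
})

test_that("EM attains the grid-search oracle likelihood on small regions", {
  m0 <- default_balm_model()
  for (s in 1:3) {
    set.seed(400 + s)
    sites <- c(10000, 10100)
    n_per <- 90                                  # <= 200 tags total
    site <- rep(sites, each = n_per)
    st <- ifelse(runif(2 * n_per) < 0.5, "+", "-")
    off <- ifelse(st == "+", rald(2 * n_per, m0$forward),
                  rald(2 * n_per, m0$reverse))
    tags <- tags_from_p5(round(site + off), st)

    set.seed(s)
    f <- em_fit(tags, 2, m0, init_centers = c(9990, 10110))

    # oracle: exhaustive 1 bp grid over center pairs around the sites,
    # weights profiled by a fixed-point iteration independent of em_fit
    # (vectorized over the second center)
    p5 <- tag_pos5(tags)
    n <- length(p5)
    grid <- seq(sites[1] - 30, sites[2] + 30, by = 1)
    G <- length(grid)
    dens <- vapply(grid, function(cc)
      balm_density(p5 - cc, tags$strand, m0), numeric(n))
    best <- -Inf
    for (i in seq_len(G)) {
      di <- dens[, i]
      Dj <- dens[, i:G, drop = FALSE]
      m <- ncol(Dj)
      PI <- rep(0.5, m)
      Di <- matrix(di, n, m)
      for (it in 1:40) {
        num <- t(t(Di) * PI)
        den <- num + t(t(Dj) * (1 - PI))
        PI <- colMeans(num / den)
      }
      ll <- colSums(log(t(t(Di) * PI) + t(t(Dj) * (1 - PI))))
      best <- max(best, max(ll))
    }
    expect_gte(f$log_likelihood, best - 1e-3)
  }
})

test_that("BIC selects one component on single-site data", {
  fit <- reference_fit()
  n_seeds <- 20L
  k1 <- 0L
  for (s in seq_len(n_seeds)) {
    d <- spike_in(5000, depth = "medium", model = fit,
                  seed = 500 + s)[[1]]
    # keep only the first site's tags: a clean single-site region
    keep <- abs(tag_pos5(d$tags) - d$sites[1]) < 600
    rt <- d$tags[keep, , drop = FALSE]
    set.seed(s)
    f <- select_components(rt, fit,
                           region = data.frame(chrom = "chrS",
                                               start = d$sites[1] - 100,
                                               end = d$sites[1] + 100))
    if (nrow(f$components) == 1) k1 <- k1 + 1L
  }
  expect_gte(k1 / n_seeds, 0.9)
})

test_that("component weight collapse drops the component and flags it", {
  m0 <- default_balm_model()
  d <- spike_in(400, depth = "medium", model = m0, seed = 23)[[1]]
  keep <- abs(tag_pos5(d$tags) - d$sites[1]) < 450
  rt <- d$tags[keep, , drop = FALSE]
  # one center planted far away with negligible support
  f <- em_fit(rt, 3, m0, init_centers = c(d$sites[1] - 5, d$sites[1] + 5,
                                          d$sites[1] + 2000))
  expect_lt(nrow(f$components), 3)
  expect_gt(f$dropped, 0)
})

test_that("methylation scores respect the clamp, the radius and the GRAI", {
  comp <- data.frame(center = c(1000, 1200), weight = c(0.6, 0.4))
  rm_ <- structure(list(
    region = data.frame(chrom = "chr1", start = 900, end = 1300),
    components = comp, log_likelihood = -1, n_tags = 100L, k_free = 3L,
    bic = 1, logL_trace = -1, converged = TRUE, dropped = 0L),
    class = "region_model")
  cpg <- list(chr1 = c(950L, 1010L, 1195L))

  sc <- methylation_scores(rm_, cpg, calibration = 50)
  expect_equal(sc$pos, c(950, 1010, 1195))
  # component 1 (mass 60) -> CpG 1010 (10 bp away); component 2 (40) -> 1195
  expect_equal(sc$effective_count, c(0, 60, 40))
  expect_equal(sc$score, c(0, 1, 0.8))          # clamped at 1
  expect_true(all(sc$score >= 0 & sc$score <= 1))

  # a 2x amplified bin halves the effective mass
  grai2 <- structure(list(values = list(chr1 = 2),
                          bin_lengths = list(chr1 = 10000L),
                          excluded = list(chr1 = FALSE),
                          bin_width = 10000L, N = 1L, L_g = 10000),
                     class = "grai_track")
  sc2 <- methylation_scores(rm_, cpg, calibration = 50, grai = grai2)
  expect_equal(sc2$effective_count, c(0, 30, 20))

  # no CpG within radius: component reported as non-CpG site
  far <- rm_
  far$components <- data.frame(center = 1100, weight = 1)
  sc3 <- methylation_scores(far, cpg, calibration = 50)
  expect_equal(sc3$effective_count, c(0, 0, 0))
  expect_equal(nrow(attr(sc3, "non_cpg_sites")), 1)

  # region without CpGs: empty result, message
  none <- rm_
  none$region <- data.frame(chrom = "chr1", start = 5000, end = 5100)
  expect_message(sc4 <- methylation_scores(none, cpg, calibration = 50),
                 "no CpG")
  expect_equal(nrow(sc4), 0)

  expect_error(methylation_scores(rm_, cpg, calibration = 0))
})
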