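test_that("initial scan matches a brute-force window count oracle", {
  asm <- genome_assembly(c(chr1 = 5000L))
  # no tags -> no regions
  empty <- initial_scan(aligned_tags(), shift = 75, assembly = asm,
                        threshold = 10)
  expect_equal(nrow(empty$regions), 0)

  # 100 tags whose shifted positions land uniformly in [1000, 1050)
  set.seed(81)
  p5 <- 1000L + sample(0:49, 100, TRUE) - 75L     # forward shift +75
  tags <- tags_from_p5(p5, rep("+", 100))
  sc <- initial_scan(tags, shift = 75, assembly = asm, threshold = 10)
  expect_equal(nrow(sc$regions), 1)
  expect_lte(sc$regions$start, 1000)
  expect_gte(sc$regions$end, 1050)
  expect_equal(sc$regions$site, mean(p5 + 75), tolerance = 1)
  expect_equal(sc$regions$treatment_count, 100)

  # brute-force check: every 25 bp-stepped 50 bp window's count agrees
  shifted <- p5 + 75
  for (w0 in seq(900, 1100, by = 25)) {
    cnt <- sum(shifted >= w0 & shifted < w0 + 50)
    inside <- w0 >= sc$regions$start && (w0 + 50) <= sc$regions$end
    if (cnt > 10) expect_true(inside)
  }

  # GRAI = 20 in the peak's bin scales the threshold out of reach
  grai <- structure(list(values = list(chr1 = rep(20, 1)),
                         bin_lengths = list(chr1 = 5000L),
                         excluded = list(chr1 = FALSE),
                         bin_width = 5000L, N = 1L, L_g = 5000),
                    class = "grai_track")
  sc2 <- initial_scan(tags, shift = 75, assembly = asm, threshold = 10,
                      grai = grai)
  expect_equal(nrow(sc2$regions), 0)

  expect_error(initial_scan(tags, shift = 75, assembly = asm,
                            threshold = 0), "positive")
})

test_that("initial scan is translation-equivariant", {
  asm <- genome_assembly(c(chr1 = 50000L))
  set.seed(82)
  p5 <- round(10000 + c(rald(200, default_balm_model()$forward),
                        rald(200, default_balm_model()$reverse)))
  s <- rep(c("+", "-"), each = 200)
  tags <- tags_from_p5(p5, s)
  sc1 <- initial_scan(tags, shift = 75, assembly = asm, threshold = 10)
  tags2 <- tags_from_p5(p5 + 500L, s)
  sc2 <- initial_scan(tags2, shift = 75, assembly = asm, threshold = 10)
  expect_equal(sc2$regions$start, sc1$regions$start + 500L)
  expect_equal(sc2$regions$end, sc1$regions$end + 500L)
})

test_that("GRAI reproduces hand-computed values and its identity mean", {
  # uniform input: exactly one tag per bin start
  asm <- genome_assembly(c(chr1 = 100000L))
  p5 <- seq(0L, 99999L, by = 1000L)
  tags <- tags_from_p5(p5, rep("+", length(p5)))
  g <- compute_grai(tags, asm, bin_width = 10000L)
  expect_equal(unname(g$values$chr1), rep(1, 10))

  # 20 tags in one 10 kb bin, 1000 tags total over 1 Mb: (20/1e4)/(1000/1e6) = 2
  asm2 <- genome_assembly(c(chr1 = 1000000L))
  set.seed(83)
  p5 <- c(sample(0:9999, 20, TRUE),
          sample(10000:999999, 980, TRUE))
  tags2 <- tags_from_p5(p5, rep("+", 1000))
  g2 <- compute_grai(tags2, asm2, bin_width = 10000L)
  expect_equal(g2$values$chr1[1],
               (sum(p5 < 10000) / 10000) / (1000 / 1e6))

  # length-weighted mean is exactly 1 for arbitrary input
  expect_lt(abs(grai_weighted_mean(g2) - 1), 1e-9)
  expect_lt(abs(grai_weighted_mean(g) - 1), 1e-9)

  expect_error(compute_grai(aligned_tags(), asm), "no input tags")
})

test_that("grai_at looks up bins and defaults to 1 off-track", {
  asm <- genome_assembly(c(chr1 = 30000L))
  tags <- tags_from_p5(rep(5000L, 30), rep("+", 30))
  g <- compute_grai(tags, asm, bin_width = 10000L)
  expect_equal(grai_at(g, "chr1", c(0, 9999)), rep(g$values$chr1[1], 2))
  expect_equal(grai_at(g, "chr1", 15000), g$values$chr1[2])
  expect_equal(grai_at(g, "chrX", 0), 1)
  expect_equal(grai_at(NULL, "chr1", c(1, 2)), c(1, 1))
})

test_that("excluded bins are flagged in the GRAI track", {
  asm <- genome_assembly(c(chr1 = 30000L),
                         exclude = data.frame(chrom = "chr1", start = 10000L,
                                              end = 12000L))
  tags <- tags_from_p5(seq(0L, 29999L, by = 100L), rep("+", 300))
  g <- compute_grai(tags, asm, bin_width = 10000L)
  expect_equal(unname(g$excluded$chr1), c(FALSE, TRUE, FALSE))
})

test_that("Fisher filtering matches an exhaustive hypergeometric oracle", {
  # brute-force one-sided p: sum of dhyper over tables at least as enriched
  oracle_p <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    xs <- max(0, k - n):min(k, m)
    sum(stats::dhyper(xs[xs >= a], m, n, k))
  }
  cases <- list(c(10, 90, 1, 99), c(10, 90, 10, 90), c(0, 100, 5, 95),
                c(25, 75, 3, 197), c(3, 7, 2, 8))
  for (cs in cases) {
    regions <- data.frame(chrom = "chr1", start = 0, end = 100,
                          treatment_count = cs[1], control_count = cs[3])
    got <- fisher_filter(regions, cs[1] + cs[2], cs[3] + cs[4], alpha = 1.1)
    expect_equal(got$fisher_p, oracle_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }

  # identical proportions: p > 0.5, removed at alpha 0.05
  r <- data.frame(chrom = "chr1", start = 0, end = 100,
                  treatment_count = 10, control_count = 10)
  kept <- fisher_filter(r, 100, 100, alpha = 0.05)
  expect_equal(nrow(kept), 0)
  expect_gt(oracle_p(10, 90, 10, 90), 0.5)

  # zero treatment count: p = 1 one-sided, removed
  r0 <- data.frame(chrom = "chr1", start = 0, end = 100,
                   treatment_count = 0, control_count = 5)
  expect_equal(nrow(fisher_filter(r0, 100, 100, alpha = 0.05)), 0)

  # no input: pass-through without p-values
  expect_message(pass <- fisher_filter(r, 100, NULL), "skipped")
  expect_false("fisher_p" %in% names(pass))
})

test_that("weighted enrichment equals brute-force summation on a 5 kb toy", {
  model <- default_balm_model()
  asm <- genome_assembly(c(chr1 = 5000L))
  set.seed(91)
  n <- 120
  p5 <- sample(500:4500, n, TRUE)
  s <- sample(c("+", "-"), n, TRUE)
  tags <- tags_from_p5(p5, s)
  E <- weighted_enrichment(tags, model, asm, support = 1000L)$chr1

  kernel <- function(d, params) dald(d, params) / dald(params$theta, params)
  brute <- numeric(5000)
  for (pos in 1:5000) {
    d <- p5 - (pos - 1)
    g <- ifelse(s == "+", kernel(d, model$forward),
                kernel(d, model$reverse))
    # contributions beyond the tabulated support window are zero
    lim_f <- abs(d - round(model$forward$theta)) <= 1000
    lim_r <- abs(d - round(model$reverse$theta)) <= 1000
    g[s == "+" & !lim_f] <- 0
    g[s == "-" & !lim_r] <- 0
    brute[pos] <- sum(g)
  }
  expect_lt(max(abs(E - brute)), 1e-9)

  # linearity: doubling every tag doubles the track exactly
  tags2 <- rbind(tags, tags); class(tags2) <- class(tags)
  E2 <- weighted_enrichment(tags2, model, asm, support = 1000L)$chr1
  expect_equal(E2, 2 * E, tolerance = 1e-12)

  # a single perfectly placed forward tag contributes exactly 1 at the
  # position its strand mode points at
  one <- tags_from_p5(1000L, "+")
  E1 <- weighted_enrichment(one, model, asm, support = 1000L)$chr1
  expect_equal(max(E1), 1)
  expect_equal(which.max(E1) - 1L, 1000L - round(model$forward$theta))
  expect_equal(sum(E1 == 0), 5000 - 2001)
})

test_that("enrichment scan regions are disjoint, sorted, in bounds, and GRAI-scaled", {
  fit <- reference_fit()
  asm <- genome_assembly(c(chrS = 20000L))
  d <- spike_in(500, depth = "medium", model = fit, seed = 17)[[1]]
  regs <- weighted_enrichment_scan(d$tags, fit, asm, base_threshold = 5)
  expect_gt(nrow(regs), 0)
  expect_true(all(regs$start < regs$end))
  expect_true(all(regs$start >= 0 & regs$end <= 20000))
  if (nrow(regs) > 1) {
    expect_true(all(diff(regs$start) > 0))
    expect_true(all(regs$start[-1] >= regs$end[-nrow(regs)]))
  }
  # raising the local threshold 50-fold suppresses detection entirely
  grai_hi <- structure(list(values = list(chrS = 50),
                            bin_lengths = list(chrS = 20000L),
                            excluded = list(chrS = FALSE),
                            bin_width = 20000L, N = 1L, L_g = 20000),
                       class = "grai_track")
  regs2 <- weighted_enrichment_scan(d$tags, fit, asm, base_threshold = 5,
                                    grai = grai_hi)
  expect_equal(nrow(regs2), 0)

  expect_error(weighted_enrichment_scan(d$tags, NULL, asm), "required")
})

test_that("zero tags give a zero enrichment track and no regions", {
  fit <- reference_fit()
  asm <- genome_assembly(c(chr1 = 2000L))
  E <- weighted_enrichment(aligned_tags(), fit, asm)$chr1
  expect_true(all(E == 0))
  regs <- weighted_enrichment_scan(aligned_tags(), fit, asm,
                                   base_threshold = 2)
  expect_equal(nrow(regs), 0)
})

test_that("the Poisson default threshold respects its tail bound", {
  thr <- default_threshold(1e6, 3e9, window = 50)
  lam <- 1e6 * 50 / 3e9
  expect_lt(stats::ppois(thr - 1, lam, lower.tail = FALSE), 1e-5)
  expect_gte(stats::ppois(thr - 2, lam, lower.tail = FALSE), 1e-5)
})
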