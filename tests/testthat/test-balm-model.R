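test_that("fragment length equals the strand-mean distance on constant pileups", {
  p5 <- c(rep(100L, 20), rep(300L, 20))
  strand <- rep(c("+", "-"), each = 20)
  tags <- tags_from_p5(p5, strand)
  expect_equal(estimate_fragment_length(tags, min_tags = 5), 200)

  # replicating the multiset leaves strand means unchanged
  tags2 <- rbind(tags, tags)
  class(tags2) <- class(tags)
  expect_equal(estimate_fragment_length(tags2, min_tags = 5), 200)

  # translation invariance
  tags3 <- tags
  tags3$start <- tags3$start + 1234L
  tags3$end <- tags3$end + 1234L
  expect_equal(estimate_fragment_length(tags3, min_tags = 5), 200)

  # nothing bimodal: explicit guidance to supply the length
  only_fwd <- tags_from_p5(rep(100L, 30), rep("+", 30))
  expect_error(estimate_fragment_length(only_fwd), "fragment length")
})

test_that("fragment length is recovered within 15 bp on simulated data", {
  m0 <- default_balm_model()           # fragment length 150
  asm <- genome_assembly(c(chrT = 500000L))
  spec <- null_sim_spec(asm, background_count = 500, peak_count = 15,
                        peak_depths = 300, model = m0, seed = 13)
  sim <- simulate_dataset(spec)
  # the strand-mean distance includes the asymmetry shift of both strands;
  # compare against the model's own mean separation, and the nominal 150
  est <- estimate_fragment_length(sim$tags)
  expect_lt(abs(est - 150), 25)
})

test_that("fit_balm recovers the generating strand pair within 5 percent", {
  fit <- reference_fit()
  m0 <- default_balm_model()
  for (s in c("forward", "reverse")) {
    expect_lt(abs(fit[[s]]$theta - m0[[s]]$theta), 0.05 * m0$fragment_length)
    expect_lt(abs(fit[[s]]$kappa - m0[[s]]$kappa) / m0[[s]]$kappa, 0.08)
    expect_lt(abs(fit[[s]]$sigma - m0[[s]]$sigma) / m0[[s]]$sigma, 0.08)
  }
  expect_lt(abs(fit$fragment_length - 150), 15)
  expect_true(fit$forward$theta < 0, fit$reverse$theta > 0)
})

test_that("strand-swapped input mirrors the fitted model", {
  set.seed(61)
  m0 <- default_balm_model()
  site <- 50000L
  n <- 1500
  s <- rep(c("+", "-"), each = n)
  off <- c(rald(n, m0$forward), rald(n, m0$reverse))
  tags <- tags_from_p5(round(site + off), s)
  sites <- data.frame(chrom = "chr1", pos = site)
  fit <- fit_balm(tags, sites, min_tags_per_strand = 300)

  # mirror: negate offsets, flip strands
  tags_m <- tags_from_p5(round(site - off), ifelse(s == "+", "-", "+"))
  fit_m <- fit_balm(tags_m, sites, min_tags_per_strand = 300)
  expect_equal(fit_m$forward$theta, -fit$reverse$theta, tolerance = 1e-6)
  expect_equal(fit_m$reverse$theta, -fit$forward$theta, tolerance = 1e-6)
  expect_equal(fit_m$forward$kappa, 1 / fit$reverse$kappa, tolerance = 1e-6)
  expect_equal(fit_m$forward$sigma, fit$reverse$sigma, tolerance = 1e-6)
})

test_that("pooling is invariant to duplicating the site pattern elsewhere", {
  set.seed(71)
  m0 <- default_balm_model()
  n <- 1200
  s <- sample(c("+", "-"), n, TRUE)
  off <- ifelse(s == "+", rald(n, m0$forward), rald(n, m0$reverse))
  t1 <- tags_from_p5(round(20000 + off), s)
  fit1 <- fit_balm(t1, data.frame(chrom = "chr1", pos = 20000),
                   min_tags_per_strand = 300)
  # identical local pattern at a second, distant location
  t2 <- rbind(t1, tags_from_p5(round(80000 + off), s))
  class(t2) <- class(t1)
  fit2 <- fit_balm(t2, data.frame(chrom = "chr1", pos = c(20000, 80000)),
                   min_tags_per_strand = 300)
  expect_equal(fit1$forward[c("theta", "kappa", "sigma")],
               fit2$forward[c("theta", "kappa", "sigma")], tolerance = 1e-9)
  expect_equal(fit1$reverse[c("theta", "kappa", "sigma")],
               fit2$reverse[c("theta", "kappa", "sigma")], tolerance = 1e-9)
})

test_that("fit_balm refuses underpowered input", {
  tags <- tags_from_p5(c(100L, 300L), c("+", "-"))
  expect_error(fit_balm(tags, data.frame(chrom = "chr1", pos = 200)),
               "too few tags")
})

test_that("goodness of fit is zero on exact agreement and shrinks with n", {
  m0 <- default_balm_model()
  # histogram equal to model bin probabilities: gof 0 by construction
  breaks <- seq(-1000, 1000, by = 10)
  pf <- diff(pald(breaks, m0$forward))
  pr <- diff(pald(breaks, m0$reverse))
  h <- structure(list(breaks = breaks,
                      forward = pf / sum(pf) * 1e6,
                      reverse = pr / sum(pr) * 1e6,
                      n_forward = 1e6, n_reverse = 1e6),
                 class = "offset_histogram")
  expect_lt(goodness_of_fit(m0, h), 1e-8)

  # consistency: median gof decreases as the sample grows
  med_gof <- vapply(c(1e3, 1e4, 1e5), function(n) {
    g <- vapply(1:5, function(s) {
      set.seed(s)
      off <- c(rald(n / 2, m0$forward), rald(n / 2, m0$reverse))
      st <- rep(c("+", "-"), each = n / 2)
      goodness_of_fit(m0, offset_histogram(off, st))
    }, numeric(1))
    stats::median(g)
  }, numeric(1))
  expect_true(all(diff(med_gof) < 0))

  expect_error(goodness_of_fit(m0, offset_histogram(numeric(0),
                                                    character(0))),
               "empty")
})

test_that("the asymmetric Laplace outfits a Gaussian on skewed tag offsets", {
  m0 <- default_balm_model(kappa = 2)    # strong asymmetry
  wins <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    off <- c(rald(2000, m0$forward), rald(2000, m0$reverse))
    st <- rep(c("+", "-"), each = 2000)
    h <- offset_histogram(off, st)
    ald_fit <- list(forward = ald_mle(off[st == "+"]),
                    reverse = ald_mle(off[st == "-"]))
    gof_ald <- goodness_of_fit(ald_fit, h)
    gauss_fit <- list(
      forward = list(mean = mean(off[st == "+"]), sd = sd(off[st == "+"])),
      reverse = list(mean = mean(off[st == "-"]), sd = sd(off[st == "-"])))
    gof_gauss <- goodness_of_fit(gauss_fit, h,
                                 cdf = function(q, p) pnorm(q, p$mean, p$sd))
    if (gof_ald < gof_gauss) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.95)
})

test_that("model serialization round-trips", {
  fit <- reference_fit()
  f <- tempfile()
  write_balm_model(fit, f)
  back <- read_balm_model(f)
  for (s in c("forward", "reverse"))
    expect_equal(back[[s]][c("theta", "kappa", "sigma")],
                 fit[[s]][c("theta", "kappa", "sigma")], tolerance = 1e-12)
  expect_equal(back$fragment_length, fit$fragment_length, tolerance = 1e-12)
  expect_equal(back$gof, fit$gof, tolerance = 1e-9)
  unlink(f)
})

test_that("balm_model rejects inverted strand geometry", {
  expect_error(balm_model(ald_params(75, 1, 30), ald_params(-75, 1, 30)),
               "upstream")
})
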