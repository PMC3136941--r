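# shared fixtures, built once per test run

.cache <- new.env(parent = emptyenv())

# reference BALM fitted on simulated isolated peaks (the standard bootstrap)
reference_fit <- function() {
  if (is.null(.cache$fit)) .cache$fit <- simulated_training_fit(seed = 5L)
  .cache$fit
}

# quick tag table from 5' positions and strands (50 bp reads)
tags_from_p5 <- function(p5, strand, chrom = "chr1", len = 50L) {
  start <- ifelse(strand == "+", p5, p5 - len + 1L)
  aligned_tags(rep(chrom, length(p5)), start, start + len, strand)
}

# ten fixed tags used by the dialect round-trip tests
ten_tags <- function() {
  aligned_tags(
    chrom = rep(c("chr1", "chr2"), each = 5),
    start = c(100L, 250L, 399L, 1024L, 5000L, 7L, 88L, 1500L, 2750L, 9000L),
    end   = c(150L, 300L, 449L, 1074L, 5050L, 57L, 138L, 1550L, 2800L, 9050L),
    strand = c("+", "-", "+", "+", "-", "-", "+", "-", "+", "-"))
}

# numerical ALD maximum-likelihood oracle (parametrization-independent);
# multi-start since the profile surface is only piecewise smooth
ald_numeric_mle <- function(x) {
  obj <- function(p) -ald_loglik(x, ald_params(p[1], p[2], p[3]))
  best <- NULL
  for (k0 in c(0.5, 1, 2)) {
    for (q0 in c(0.25, 0.5, 0.75)) {
      st <- c(stats::quantile(x, q0, names = FALSE), k0,
              stats::mad(x) + 1)
      fit <- tryCatch(
        stats::optim(st, obj, method = "L-BFGS-B",
                     lower = c(-Inf, 1e-3, 1e-3),
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
  }
  list(params = ald_params(best$par[1], best$par[2], best$par[3]),
       logLik = -best$value)
}
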