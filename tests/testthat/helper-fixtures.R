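## shared fixture builders; everything is generated in code at test time

## small cohort with a modest planted architecture, fast enough for unit tests
small_cohort <- function(n = 300, p = 400, seed = 7, arch = NULL,
                         report = reporting_model()) {
  if (is.null(arch)) {
    arch <- effect_architecture(min(20L, p %/% 4L), min(10L, p %/% 8L),
                                min(5L, max(p %/% 16L, 1L)))
  }
  m <- simulate_methylome(n, p, n_batches = 2, seed = seed)
  simulate_phenotype(m, arch, report, seed = seed)
}

## cohort + EWAS inputs at the scale used for the sampler property checks
ewas_inputs <- function(n, p, arch, seed, report = reporting_model(1, 0, 0)) {
  m <- simulate_methylome(n, p, n_batches = 4, seed = seed)
  sc <- simulate_phenotype(m, arch, report, seed = seed)
  pre <- precorrect(m_values(sc$methyl), sc$cohort$units, sc$cohort$age,
                    sc$cohort$sex, sc$cohort$smoking, sc$cohort$batch)
  list(sc = sc, pre = pre)
}

## batch-means estimate of the Monte-Carlo variance of a chain mean
mc_var_of_mean <- function(z) {
  m <- length(z)
  b <- max(1L, floor(sqrt(m)))
  nb <- m %/% b
  bm <- colMeans(matrix(z[seq_len(nb * b)], nrow = b))
  if (nb < 2) return(stats::var(z) / m)
  b * stats::var(bm) / m
}

## independent step-up BH oracle, applied literally from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / seq(n, 1) * p[o]))
  adj[order(o)]
}
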