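# Independent oracles shared across test files. These deliberately avoid
# the package's own code paths: direct summation instead of log-sum-exp,
# quadrature instead of pbeta, linear scans instead of vectorized joins.

# naive direct-sum colocalization posteriors (no log-space tricks)
coloc_direct_oracle <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  bf1 <- exp(l1)
  bf2 <- exp(l2)
  s <- c(1,
         p1 * sum(bf1),
         p2 * sum(bf2),
         p1 * p2 * (sum(bf1) * sum(bf2) - sum(bf1 * bf2)),
         p12 * sum(bf1 * bf2))
  s / sum(s)
}

# beta CDF by adaptive quadrature on the density
beta_cdf_quadrature <- function(x, a, b) {
  stats::integrate(function(t) t^(a - 1) * (1 - t)^(b - 1) / beta(a, b),
                   0, x, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# every lead set reachable by iterative masking under some selection order
enumerate_signal_orders <- function(p, r2, p_thresh = 1e-4,
                                    r2_thresh = 0.01, max_signals = 3) {
  res <- list()
  recurse <- function(unmasked, leads) {
    cand <- which(unmasked & p < p_thresh)
    if (!length(cand) || length(leads) >= max_signals) {
      res[[length(res) + 1L]] <<- leads
      return(invisible(NULL))
    }
    for (i in cand) {
      um <- unmasked
      um[r2[i, ] > r2_thresh & !is.na(r2[i, ])] <- FALSE
      um[i] <- FALSE
      recurse(um, c(leads, i))
    }
  }
  recurse(rep(TRUE, length(p)), integer(0))
  res
}

random_gwas_records <- function(n, seed) {
  set.seed(seed)
  data.frame(chrom = "3",
             pos = sort(sample.int(1e6, n)),
             ref = sample(c("A", "C"), n, replace = TRUE),
             alt = sample(c("G", "T"), n, replace = TRUE),
             beta = rnorm(n),
             se = runif(n, 0.01, 1),
             pvalue = runif(n, .Machine$double.eps, 1),
             eaf = runif(n),
             stringsAsFactors = FALSE)
}

random_eqtl_records <- function(n, seed, genes = c("gA", "gB", "gC")) {
  set.seed(seed)
  data.frame(gene_id = sample(genes, n, replace = TRUE),
             chrom = "3",
             pos = sort(sample.int(1e6, n)),
             ref = sample(c("A", "C"), n, replace = TRUE),
             alt = sample(c("G", "T"), n, replace = TRUE),
             beta = rnorm(n),
             se = runif(n, 0.01, 1),
             pvalue = runif(n, .Machine$double.eps, 1),
             maf = runif(n, 0.01, 0.5),
             n = 500,
             stringsAsFactors = FALSE)
}

expect_same_records <- function(got, want, cols) {
  for (cl in cols) {
    g <- got[[cl]]
    w <- want[[cl]]
    if (is.numeric(g) || is.numeric(w)) {
      expect_equal(as.numeric(g), as.numeric(w), tolerance = 0)
    } else {
      expect_equal(as.character(g), as.character(w))
    }
  }
}
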