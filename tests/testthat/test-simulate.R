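# Synthetic-data generators: LD structure, marginal summary statistics,
# scenario truth labels, screen counts, inflation backgrounds.

adjacent_r2 <- function(dos) {
  m <- nrow(dos)
  vapply(seq_len(m - 1), function(i)
    suppressWarnings(cor(dos[i, ], dos[i + 1, ]))^2, numeric(1))
}

test_that("latent AR(1) genotypes show the requested LD decay", {
  g0 <- simulate_genotypes(ld_block_spec(n_individuals = 2000,
                                         n_variants = 50, rho = 0,
                                         seed = 50))
  expect_lt(mean(adjacent_r2(g0$dosages), na.rm = TRUE), 0.02)
  g9 <- simulate_genotypes(ld_block_spec(n_individuals = 2000,
                                         n_variants = 50, rho = 0.99,
                                         maf_range = c(0.2, 0.5), seed = 50))
  expect_gt(mean(adjacent_r2(g9$dosages), na.rm = TRUE), 0.5)
  # dosages live on {0,1,2}; realized frequencies track the targets
  expect_true(all(g9$dosages %in% 0:2))
  expect_lt(max(abs(rowMeans(g9$dosages) / 2 - g9$maf)), 0.06)
})

test_that("generators are pure functions of their spec", {
  s <- ld_block_spec(n_individuals = 100, n_variants = 20, seed = 51)
  expect_identical(simulate_genotypes(s)$dosages,
                   simulate_genotypes(s)$dosages)
  sc <- screen_spec(n_genes = 30, seed = 52, hit_genes = 3)
  expect_identical(simulate_screen_counts(sc)$counts,
                   simulate_screen_counts(sc)$counts)
  expect_identical(simulate_inflation_background(50, 10, 2, seed = 53),
                   simulate_inflation_background(50, 10, 2, seed = 53))
  g <- simulate_genotypes(s)
  sp <- scenario_spec("shared", causal_index_1 = 5L, seed = 54)
  expect_identical(simulate_trait_pair(g, sp), simulate_trait_pair(g, sp))
})

test_that("marginal quantitative statistics match lm and self-regression is exact", {
  g <- simulate_genotypes(ld_block_spec(n_individuals = 400, n_variants = 30,
                                        seed = 55))
  # regressing a variant's own dosage recovers beta = 1, p ~ 0
  y <- g$dosages[7, ]
  ss <- marginal_sumstats(g, y, "quant")
  expect_equal(ss$beta[7], 1, tolerance = 1e-12)
  expect_lt(ss$pvalue[7], 1e-100)
  # general-purpose regression oracle on random columns
  set.seed(56)
  y <- rnorm(400) + 0.2 * g$dosages[3, ]
  ss <- marginal_sumstats(g, y, "quant")
  for (i in sample.int(30, 10)) {
    if (ss$monomorphic[i]) next
    fit <- summary(lm(y ~ g$dosages[i, ]))$coefficients
    expect_equal(ss$beta[i], fit[2, 1], tolerance = 1e-8)
    expect_equal(ss$se[i], fit[2, 2], tolerance = 1e-8)
    expect_equal(ss$pvalue[i], fit[2, 4], tolerance = 1e-8)
  }
})

test_that("null p-values are uniform across variants", {
  g <- simulate_genotypes(ld_block_spec(n_individuals = 500,
                                        n_variants = 1000, rho = 0,
                                        seed = 57))
  set.seed(58)
  ss <- marginal_sumstats(g, rnorm(500), "quant")
  ks <- suppressWarnings(stats::ks.test(ss$pvalue[!ss$monomorphic], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the case-control score approximation agrees with the logistic fit", {
  g <- simulate_genotypes(ld_block_spec(n_individuals = 2000,
                                        n_variants = 10, seed = 59))
  set.seed(60)
  liab <- 0.3 * g$dosages[4, ] + rnorm(2000)
  y <- as.numeric(liab > quantile(liab, 0.5, names = FALSE))
  sc <- marginal_sumstats(g, y, "cc", method = "score")
  gl <- marginal_sumstats(g, y, "cc", method = "glm")
  z_sc <- sc$beta / sc$se
  z_gl <- gl$beta / gl$se
  expect_equal(z_sc, z_gl, tolerance = 0.05)
  expect_equal(sc$beta, gl$beta, tolerance = 0.05)
})

test_that("monomorphic variants are flagged with missing effects", {
  dos <- rbind(a = c(0, 0, 0, 0), b = c(0, 1, 2, 1))
  ss <- marginal_sumstats(dos, c(1.2, 0.3, -0.5, 0.8), "quant")
  expect_true(ss$monomorphic[1])
  expect_true(is.na(ss$beta[1]) && is.na(ss$pvalue[1]))
  expect_false(ss$monomorphic[2])
})

test_that("trait pairs carry correct truth labels and record invariants", {
  g <- simulate_genotypes(ld_block_spec(n_individuals = 300, n_variants = 40,
                                        seed = 61))
  sh <- simulate_trait_pair(g, scenario_spec("shared", causal_index_1 = 10L,
                                             seed = 62), gene_id = "gX")
  expect_equal(sh$truth$causal_gwas, sh$truth$causal_eqtl)
  expect_equal(sh$truth$causal_gwas, g$variants$variant_id[10])
  expect_equal(unique(sh$eqtl$gene_id), "gX")
  ok <- !sh$gwas$monomorphic
  expect_true(all(sh$gwas$se[ok] > 0))
  expect_true(all(sh$gwas$pvalue[ok] > 0 & sh$gwas$pvalue[ok] <= 1))
  expect_true(all(sh$eqtl$maf > 0 & sh$eqtl$maf <= 0.5))
  expect_equal(sh$gwas$n_cases[1] + sh$gwas$n_controls[1], 300)

  di <- simulate_trait_pair(g, scenario_spec("distinct", causal_index_1 = 5L,
                                             causal_index_2 = 35L, seed = 63))
  expect_false(di$truth$causal_gwas == di$truth$causal_eqtl)
  nu <- simulate_trait_pair(g, scenario_spec("null", seed = 64))
  expect_true(is.na(nu$truth$causal_gwas))
  expect_error(scenario_spec("shared", causal_index_1 = 1L,
                             causal_index_2 = 2L), "identical")
  expect_error(scenario_spec("distinct", causal_index_1 = 3L,
                             causal_index_2 = 3L), "different")
})

test_that("screen counts have the declared shape and respect hit designation", {
  sim <- simulate_screen_counts(screen_spec(n_genes = 50, guides_per_gene = 6,
                                            hit_genes = c("GENE0002"),
                                            n_control = 2, n_infected = 3,
                                            seed = 65))
  expect_equal(nrow(sim$counts), 300L)
  expect_equal(sum(grepl("^control_lowMOI", names(sim$counts))), 2L)
  expect_equal(sum(grepl("^infected_lowMOI", names(sim$counts))), 3L)
  expect_equal(sim$hit_genes, "GENE0002")
  expect_true(all(sim$counts$gene_id[sim$counts$guide_id == "GENE0002_g3"] ==
                    "GENE0002"))
  expect_error(simulate_screen_counts(
    screen_spec(n_genes = 5, hit_genes = "GENE9999")), "outside")
})

test_that("with zero enrichment planted hits rank uniformly", {
  n_genes <- 200
  med_rank <- numeric(100)
  for (s in 1:100) {
    sim <- simulate_screen_counts(
      screen_spec(n_genes = n_genes, hit_genes = sprintf("GENE%04d", 1:10),
                  hit_log2_enrichment = 0, depth_per_sample = 1e6,
                  seed = 7000 + s))
    sc <- screen_scores(sim$counts,
                        grep("^control", names(sim$counts), value = TRUE),
                        grep("^infected", names(sim$counts), value = TRUE))
    med_rank[s] <- median(sc$rank_sbscore[sc$gene_id %in% sim$hit_genes])
  }
  expect_gt(median(med_rank), n_genes / 2 - 30)
  expect_lt(median(med_rank), n_genes / 2 + 30)
})

test_that("inflation backgrounds realize the requested lambda multiplier", {
  lam <- function(mult, seed) {
    bg <- simulate_inflation_background(2000, 500, mult, seed = seed)
    lambda_quantile(bg$gwas$pvalue[bg$leads$gene_id %in% bg$target_genes])
  }
  l1 <- mean(vapply(1:10, function(s) lam(1, 660 + s), numeric(1)))
  expect_gt(l1, 0.9)
  expect_lt(l1, 1.1)
  l2 <- mean(vapply(1:10, function(s) lam(2, 670 + s), numeric(1)))
  expect_gt(l2, 1.8)
  expect_lt(l2, 2.2)
  bg2 <- simulate_inflation_background(2000, 500, 2, seed = 67)
  # generated records satisfy downstream invariants without coercion
  expect_true(all(bg2$gwas$pvalue > 0 & bg2$gwas$pvalue <= 1))
  expect_true(all(bg2$gwas$se > 0))
  expect_true(all(bg2$leads$fdr >= 0 & bg2$leads$fdr <= 1))
  expect_true(all(bg2$target_genes %in% bg2$leads$gene_id))
})
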