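# Seeded generators producing inputs with the statistical structure the
# analysis assumes: genotype dosages over an LD block, marginal regression
# summary statistics for quantitative and case-control traits, paired
# GWAS/eQTL scenarios (shared, distinct or no causal variant), negative
# binomial screen counts with planted hits, and lead-eQTL background sets
# with controlled inflation. Every generator is a pure function of its
# spec (seed included).

# -- LD block genotypes -----------------------------------------------------

#' Specification of a synthetic LD block
#'
#' Genotypes are generated from a latent Gaussian copula: each haplotype
#' carries a latent AR(1) vector with adjacent-site correlation `rho`
#' (correlation `rho^|i-j|` between sites), thresholded at each site's
#' allele-frequency quantile; a dosage is the sum of two independent
#' haplotypes. This gives analytically controllable LD decay without a
#' coalescent simulator.
#'
#' @param n_individuals,n_variants Panel dimensions.
#' @param maf_range Allele frequencies drawn uniformly from this interval,
#'   a subset of (0, 0.5\].
#' @param rho Adjacent-variant latent correlation in \[0, 1).
#' @param chrom,start_pos,spacing Variant coordinates: evenly spaced
#'   positions `start_pos + (0:(n_variants-1)) * spacing`.
#' @param seed Integer RNG seed.
#' @return Object of class `"ld_block_spec"`.
#' @export
ld_block_spec <- function(n_individuals = 2000, n_variants = 200,
                          maf_range = c(0.05, 0.5), rho = 0.9,
                          chrom = "3", start_pos = 45573240, spacing = 2500,
                          seed = 1L) {
  stopifnot(n_individuals >= 2, n_variants >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            rho >= 0, rho < 1, spacing >= 1)
  structure(list(n_individuals = n_individuals, n_variants = n_variants,
                 maf_range = maf_range, rho = rho, chrom = chrom,
                 start_pos = start_pos, spacing = spacing,
                 seed = as.integer(seed)),
            class = "ld_block_spec")
}

#' Simulate genotype dosages over an LD block
#'
#' @param spec [ld_block_spec()].
#' @return List with `dosages` (variant x individual integer matrix,
#'   rownames = variant ids), `variants` (data frame), `maf` (target
#'   allele frequencies) and `spec`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "ld_block_spec"))
  set.seed(spec$seed)
  m <- spec$n_variants
  n <- spec$n_individuals
  maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
  thr <- qnorm(maf)

  nh <- 2L * n
  z <- matrix(rnorm(m * nh), m, nh)
  if (m > 1 && spec$rho > 0) {
    sc <- sqrt(1 - spec$rho^2)
    for (i in 2:m) z[i, ] <- spec$rho * z[i - 1L, ] + sc * z[i, ]
  }
  hap <- z < thr # recycles thr down each column: site i vs thr[i]
  dos <- hap[, seq_len(n), drop = FALSE] +
    hap[, n + seq_len(n), drop = FALSE]

  alleles <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                      "G", "A", "C", "A", "G", "T", "C", "T"),
                    ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(alleles), m, replace = TRUE)
  variants <- data.frame(
    chrom = rep(normalize_chrom(spec$chrom), m),
    pos = spec$start_pos + (seq_len(m) - 1L) * spec$spacing,
    ref = alleles[pick, 1L], alt = alleles[pick, 2L],
    stringsAsFactors = FALSE
  )
  variants$variant_id <- make_variant_id(variants$chrom, variants$pos,
                                         variants$ref, variants$alt)
  dimnames(dos) <- list(variants$variant_id,
                        sprintf("ind%04d", seq_len(n)))
  list(dosages = dos, variants = variants, maf = maf, spec = spec)
}

# -- marginal summary statistics -------------------------------------------

#' Per-variant marginal association summary statistics
#'
#' Quantitative traits: simple linear regression per variant, closed-form,
#' with the Wald t-test p-value. Case-control traits: by default a
#' score-test-based approximation to logistic regression (one-step effect
#' `U/V` with `se = 1/sqrt(V)`, `V = ybar (1 - ybar) * Sxx`), which agrees
#' with the full ML fit at large samples and modest effects;
#' `method = "glm"` fits the exact logistic model per variant.
#' Monomorphic variants yield a row with missing effect and
#' `monomorphic = TRUE`.
#'
#' @param dosages Variant x individual matrix (or [simulate_genotypes()]
#'   output list).
#' @param phenotype Numeric vector (0/1 for case-control), one value per
#'   individual.
#' @param trait_type `"quant"` or `"cc"`.
#' @param method Case-control estimator: `"score"` (default) or `"glm"`.
#' @param variants Optional variant identity data frame to carry through.
#' @return Data frame shaped like GWAS/eQTL records: `chrom`, `pos`,
#'   `ref`, `alt`, `variant_id` (when identity is available), `beta`,
#'   `se`, `pvalue`, `maf`, `monomorphic`.
#' @export
marginal_sumstats <- function(dosages, phenotype,
                              trait_type = c("quant", "cc"),
                              method = c("score", "glm"), variants = NULL) {
  trait_type <- match.arg(trait_type)
  method <- match.arg(method)
  if (is.list(dosages) && !is.null(dosages$dosages)) {
    if (is.null(variants)) variants <- dosages$variants
    dosages <- dosages$dosages
  }
  g <- as.matrix(dosages)
  n <- ncol(g)
  y <- as.numeric(phenotype)
  stopifnot(length(y) == n)

  mx <- rowMeans(g)
  gc <- g - mx
  sxx <- rowSums(gc^2)
  mono <- sxx == 0

  if (trait_type == "quant") {
    yc <- y - mean(y)
    sxy <- as.vector(g %*% yc)
    beta <- sxy / sxx
    syy <- sum(yc^2)
    dfree <- n - 2L
    # pmax guards the perfect-fit case, where rounding can push the
    # residual sum of squares a hair below zero
    s2 <- pmax((syy - beta * sxy) / dfree, .Machine$double.xmin)
    se <- sqrt(s2 / sxx)
    pv <- 2 * pt(-abs(beta / se), dfree)
  } else if (method == "score") {
    if (!all(y %in% c(0, 1))) stop("case-control phenotype must be 0/1")
    p0 <- mean(y)
    if (p0 <= 0 || p0 >= 1) stop("phenotype has a single class")
    U <- as.vector(g %*% (y - p0))
    V <- p0 * (1 - p0) * sxx
    beta <- U / V
    se <- 1 / sqrt(V)
    pv <- 2 * pnorm(-abs(U / sqrt(V)))
  } else {
    if (!all(y %in% c(0, 1))) stop("case-control phenotype must be 0/1")
    beta <- se <- pv <- rep(NA_real_, nrow(g))
    for (i in which(!mono)) {
      fit <- suppressWarnings(glm(y ~ g[i, ], family = binomial()))
      cf <- summary(fit)$coefficients
      beta[i] <- cf[2L, 1L]
      se[i] <- cf[2L, 2L]
      pv[i] <- cf[2L, 4L]
    }
  }
  beta[mono] <- NA_real_
  se[mono] <- NA_real_
  pv[mono] <- NA_real_
  pv <- pmax(pv, .Machine$double.xmin)

  frq <- mx / 2
  out <- data.frame(beta = beta, se = se, pvalue = pv,
                    maf = pmin(frq, 1 - frq),
                    monomorphic = mono, stringsAsFactors = FALSE)
  if (is.null(variants) && !is.null(rownames(g))) {
    variants <- tryCatch(parse_variant_id(rownames(g)), error = function(e) NULL)
    if (!is.null(variants)) {
      variants$variant_id <- rownames(g)
    }
  }
  if (!is.null(variants)) {
    out <- cbind(variants[, intersect(c("chrom", "pos", "ref", "alt",
                                        "variant_id"), names(variants))],
                 out)
  }
  rownames(out) <- NULL
  out
}

# -- paired GWAS / eQTL scenarios ------------------------------------------

#' Specification of a GWAS/eQTL trait-pair scenario
#'
#' Three regimes: `"shared"` (one variant causal for both disease
#' liability and expression), `"distinct"` (different causal variants) and
#' `"null"` (no causal variant for either trait). Disease status follows a
#' liability-threshold model: `liability = beta_gwas * dosage + N(0, 1)`,
#' dichotomized at the empirical `1 - case_fraction` quantile; expression
#' is `beta_eqtl * dosage + N(0, noise_sd)`.
#'
#' @param scenario `"shared"`, `"distinct"` or `"null"`.
#' @param causal_index_1 GWAS causal variant index (ignored for null).
#' @param causal_index_2 eQTL causal variant index; defaults to
#'   `causal_index_1` for shared, `causal_index_1 + 80` for distinct.
#' @param beta_gwas Liability-scale effect of the GWAS causal dosage.
#' @param beta_eqtl Expression effect in trait-SD units per dosage.
#' @param case_fraction Fraction of individuals labelled cases.
#' @param noise_sd Expression noise SD.
#' @param seed Integer RNG seed.
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(scenario = c("shared", "distinct", "null"),
                          causal_index_1 = 60L, causal_index_2 = NULL,
                          beta_gwas = 0.5, beta_eqtl = 0.35,
                          case_fraction = 0.5, noise_sd = 1, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(causal_index_2)) {
    causal_index_2 <- switch(scenario,
                             shared = causal_index_1,
                             distinct = causal_index_1 + 80L,
                             null = NA_integer_)
  }
  if (scenario == "shared" && causal_index_1 != causal_index_2) {
    stop("shared scenario requires identical causal indices")
  }
  if (scenario == "distinct" && causal_index_1 == causal_index_2) {
    stop("distinct scenario requires different causal indices")
  }
  if (scenario == "null") causal_index_1 <- causal_index_2 <- NA_integer_
  stopifnot(case_fraction > 0, case_fraction < 1, noise_sd > 0)
  structure(list(scenario = scenario,
                 causal_index_1 = causal_index_1,
                 causal_index_2 = causal_index_2,
                 beta_gwas = beta_gwas, beta_eqtl = beta_eqtl,
                 case_fraction = case_fraction, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Simulate a paired GWAS / eQTL summary-statistic dataset
#'
#' @param genotypes [simulate_genotypes()] output.
#' @param scenario [scenario_spec()].
#' @param gene_id Gene id attached to the eQTL records.
#' @return List with `gwas` (GWAS-record data frame with `eaf`,
#'   `n_cases`, `n_controls`), `eqtl` (eQTL-record data frame with
#'   `gene_id`, `maf`, `n`) and `truth` (scenario label and causal variant
#'   ids).
#' @export
simulate_trait_pair <- function(genotypes, scenario, gene_id = "gene1") {
  stopifnot(inherits(scenario, "scenario_spec"))
  g <- genotypes$dosages
  n <- ncol(g)
  m <- nrow(g)
  if (scenario$scenario != "null") {
    stopifnot(scenario$causal_index_1 >= 1, scenario$causal_index_1 <= m,
              scenario$causal_index_2 >= 1, scenario$causal_index_2 <= m)
  }
  set.seed(scenario$seed)

  liab <- rnorm(n)
  if (scenario$scenario != "null") {
    liab <- liab + scenario$beta_gwas * g[scenario$causal_index_1, ]
  }
  thr <- quantile(liab, 1 - scenario$case_fraction, names = FALSE)
  y <- as.numeric(liab > thr)

  expr <- rnorm(n, 0, scenario$noise_sd)
  if (scenario$scenario != "null") {
    expr <- expr + scenario$beta_eqtl * g[scenario$causal_index_2, ]
  }

  gwas <- marginal_sumstats(g, y, "cc", variants = genotypes$variants)
  gwas$eaf <- rowMeans(g) / 2
  gwas$n_cases <- sum(y == 1)
  gwas$n_controls <- sum(y == 0)

  eqtl <- marginal_sumstats(g, expr, "quant", variants = genotypes$variants)
  eqtl <- cbind(gene_id = gene_id, eqtl, stringsAsFactors = FALSE)
  eqtl$n <- n

  truth <- list(
    scenario = scenario$scenario,
    causal_gwas = if (is.na(scenario$causal_index_1)) NA_character_
                  else genotypes$variants$variant_id[scenario$causal_index_1],
    causal_eqtl = if (is.na(scenario$causal_index_2)) NA_character_
                  else genotypes$variants$variant_id[scenario$causal_index_2]
  )
  list(gwas = gwas, eqtl = eqtl, truth = truth)
}

# -- CRISPR screen counts ---------------------------------------------------

#' Specification of a synthetic pooled CRISPR screen
#'
#' Control-sample counts are negative binomial with mean
#' `depth_per_sample / n_guides` and the given dispersion
#' (`var = mu + dispersion * mu^2`). In infected samples, guides targeting
#' hit genes have their expected abundance multiplied by
#' `2^hit_log2_enrichment`, and all expected abundances are rescaled so
#' the expected sequencing depth stays constant (a fixed-depth sequencing
#' run). Samples are independent.
#'
#' @param n_genes Number of genes; gene ids are `GENE0001`, ...
#' @param guides_per_gene Guides targeting each gene (>= 2); default 6.
#' @param hit_genes Character vector of hit gene ids, or a single count
#'   (that many genes sampled at random), or `NULL` for none.
#' @param hit_log2_enrichment log2 enrichment of hit-gene guides in
#'   infected samples.
#' @param dispersion Negative binomial dispersion.
#' @param depth_per_sample Expected total reads per sample.
#' @param n_control,n_infected Replicate sample counts.
#' @param moi MOI tag used in sample names (`"low"`/`"high"`).
#' @param seed Integer RNG seed.
#' @return Object of class `"screen_spec"`.
#' @export
screen_spec <- function(n_genes = 1000, guides_per_gene = 6,
                        hit_genes = 20, hit_log2_enrichment = 3,
                        dispersion = 0.25, depth_per_sample = 6e6,
                        n_control = 2, n_infected = 2, moi = "low",
                        seed = 1L) {
  stopifnot(guides_per_gene >= 2, n_genes >= 1, dispersion > 0,
            depth_per_sample > 0, n_control >= 1, n_infected >= 1)
  structure(list(n_genes = n_genes, guides_per_gene = guides_per_gene,
                 hit_genes = hit_genes,
                 hit_log2_enrichment = hit_log2_enrichment,
                 dispersion = dispersion,
                 depth_per_sample = depth_per_sample,
                 n_control = n_control, n_infected = n_infected,
                 moi = moi, seed = as.integer(seed)),
            class = "screen_spec")
}

#' Simulate guide-level screen read counts
#'
#' @param spec [screen_spec()].
#' @return List with `counts` (data frame: `guide_id`, `gene_id`, one
#'   column per sample), `hit_genes` (character vector) and `spec`.
#' @export
simulate_screen_counts <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  set.seed(spec$seed)
  genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
  gpg <- spec$guides_per_gene
  gene_of_guide <- rep(genes, each = gpg)
  guides <- paste0(gene_of_guide, "_g", rep(seq_len(gpg), spec$n_genes))
  n_guides <- length(guides)

  hits <- spec$hit_genes
  if (is.null(hits)) {
    hits <- character(0)
  } else if (is.numeric(hits) && length(hits) == 1L) {
    hits <- sort(sample(genes, hits))
  } else {
    hits <- as.character(hits)
    if (!all(hits %in% genes)) stop("hit_genes outside the gene panel")
  }

  mu0 <- spec$depth_per_sample / n_guides
  size <- 1 / spec$dispersion
  mu_inf <- rep(mu0, n_guides)
  is_hit_guide <- gene_of_guide %in% hits
  mu_inf[is_hit_guide] <- mu0 * 2^spec$hit_log2_enrichment
  mu_inf <- mu_inf * spec$depth_per_sample / sum(mu_inf)

  counts <- data.frame(guide_id = guides, gene_id = gene_of_guide,
                       stringsAsFactors = FALSE)
  for (r in seq_len(spec$n_control)) {
    counts[[sprintf("control_%sMOI_rep%d", spec$moi, r)]] <-
      rnbinom(n_guides, mu = mu0, size = size)
  }
  for (r in seq_len(spec$n_infected)) {
    counts[[sprintf("infected_%sMOI_rep%d", spec$moi, r)]] <-
      rnbinom(n_guides, mu = mu_inf, size = size)
  }
  list(counts = counts, hit_genes = hits, spec = spec)
}

# -- inflation-test backgrounds --------------------------------------------

#' Simulate a lead-eQTL background set with controlled GWAS inflation
#'
#' One lead variant per gene. Background genes get uniform GWAS p-values
#' (the survival probability of a chi-square(1) draw); target genes'
#' chi-square draws are multiplied by `target_lambda_multiplier` before
#' the survival transform, so the target set's realized inflation
#' statistic is approximately the multiplier.
#'
#' @param n_genes Background set size.
#' @param n_target Target set size (< `n_genes`); targets are sampled at
#'   random from the background genes.
#' @param target_lambda_multiplier Inflation multiplier (1 = null).
#' @param seed Integer RNG seed.
#' @return List with `leads` (lead-eQTL data frame: `gene_id`, variant
#'   identity, `fdr`), `target_genes` and `gwas` (GWAS records for the
#'   lead variants).
#' @export
simulate_inflation_background <- function(n_genes = 2000, n_target = 300,
                                          target_lambda_multiplier = 1,
                                          seed = 1L) {
  stopifnot(n_target < n_genes, n_target >= 1,
            target_lambda_multiplier > 0)
  set.seed(seed)
  genes <- sprintf("BG%05d", seq_len(n_genes))
  target <- sort(sample(genes, n_target))

  x <- rchisq(n_genes, df = 1)
  x[genes %in% target] <- x[genes %in% target] * target_lambda_multiplier
  p <- pmax(pchisq(x, df = 1, lower.tail = FALSE), .Machine$double.xmin)

  leads <- data.frame(gene_id = genes, chrom = "1",
                      pos = 1000000L + seq_len(n_genes) * 5000L,
                      ref = "A", alt = "G",
                      fdr = runif(n_genes, 0, 0.05),
                      stringsAsFactors = FALSE)
  leads$variant_id <- make_variant_id(leads$chrom, leads$pos, leads$ref,
                                      leads$alt)
  se <- rep(0.05, n_genes)
  z <- sqrt(x) * sample(c(-1, 1), n_genes, replace = TRUE)
  gwas <- data.frame(chrom = leads$chrom, pos = leads$pos, ref = leads$ref,
                     alt = leads$alt, variant_id = leads$variant_id,
                     beta = z * se, se = se, pvalue = p,
                     stringsAsFactors = FALSE)
  list(leads = leads, target_genes = target, gwas = gwas)
}
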