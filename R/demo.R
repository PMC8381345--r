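# End-to-end demonstration pipeline on synthetic data:
# simulate -> screen ranking -> inflation test -> colocalization (single
# and masked) -> prioritization table, with a content-hash manifest.
# Everything is a pure function of the seed, so two runs with the same
# seed produce bitwise-identical artifacts.

demo_config <- function(seed) {
  list(tool = "locustriage",
       version = as.character(packageVersion("locustriage")),
       seed = seed,
       inflation = list(q = 0.1, k = 1000),
       priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 5e-6),
       window = 5e5,
       eligibility = list(window = 1e5, p_thresh = 1e-4),
       mask = list(r2_thresh = 0.01, p_thresh = 1e-4, max_signals = 3),
       pp4_flag = 0.5)
}

coloc_result_list <- function(res) {
  list(pp0 = res$pp0, pp1 = res$pp1, pp2 = res$pp2, pp3 = res$pp3,
       pp4 = res$pp4, n_variants = res$n_variants,
       signal_index = res$signal_index,
       masked_variants = res$masked_variants,
       suggestive = res$suggestive,
       priors = unclass(res$priors))
}

#' Run the end-to-end synthetic demonstration pipeline
#'
#' Generates two screen arms (low/high MOI), a lead-eQTL background with a
#' mildly inflated target set, an LD block with three eQTL genes (one
#' sharing its causal variant with the GWAS, one with a distinct causal
#' variant, one with two independent eQTL signals of which one is shared),
#' runs every analysis stage, and writes all artifacts plus a manifest
#' with per-file md5 hashes and the resolved configuration into
#' `out_dir`. Runs in well under a minute on one CPU.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; all randomness derives from it.
#' @return Invisibly, a list with `out_dir`, `manifest` (data frame of
#'   file, md5, bytes), `config`, and the key in-memory results
#'   (`inflation`, `coloc_shared`, `coloc_distinct`, `coloc_masked`,
#'   `priority`).
#' @export
run_demo <- function(out_dir, seed = 1L) {
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- demo_config(seed)
  art <- function(name) file.path(out_dir, name)
  written <- character(0)

  locus_genes <- sprintf("GENE%04d", 1:8)
  shared_gene <- "GENE0003"
  distinct_gene <- "GENE0004"
  twosignal_gene <- "GENE0005"

  ## -- pooled CRISPR screen, two MOI arms -------------------------------
  hit_set <- c(shared_gene, twosignal_gene, sprintf("GENE%04d", 101:118))
  arms <- list(
    low = screen_spec(hit_genes = hit_set, moi = "low", seed = seed + 101L),
    high = screen_spec(hit_genes = hit_set, moi = "high",
                       hit_log2_enrichment = 2, seed = seed + 102L)
  )
  screen_ranks <- data.frame(gene_id = locus_genes, stringsAsFactors = FALSE)
  for (arm in names(arms)) {
    sim <- simulate_screen_counts(arms[[arm]])
    f <- art(sprintf("guide_counts_%sMOI.tsv", arm))
    write_guide_counts(sim$counts, f)
    written <- c(written, f)
    samp <- names(sim$counts)
    scores <- screen_scores(sim$counts,
                            control_samples = grep("^control_", samp, value = TRUE),
                            infected_samples = grep("^infected_", samp, value = TRUE))
    f <- art(sprintf("screen_scores_%sMOI.tsv", arm))
    write_priority_table(scores, f)
    written <- c(written, f)
    screen_ranks[[paste0("rank_", arm, "_moi")]] <-
      scores$rank_sbscore[match(locus_genes, scores$gene_id)]
  }

  ## -- inflation of GWAS signal at target lead eQTLs --------------------
  bg <- simulate_inflation_background(n_genes = 2000, n_target = 300,
                                      target_lambda_multiplier = 1.5,
                                      seed = seed + 7L)
  infl <- permutation_inflation_test(bg$target_genes, bg$leads, bg$gwas,
                                     q = cfg$inflation$q,
                                     k = cfg$inflation$k, seed = seed + 8L)
  f <- art("inflation.json")
  jsonlite::write_json(c(unclass(infl), list(provenance = cfg)), f,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, f)

  ## -- colocalization on one LD block -----------------------------------
  geno <- simulate_genotypes(ld_block_spec(seed = seed + 21L))
  n <- ncol(geno$dosages)
  priors <- coloc_priors(cfg$priors$p1, cfg$priors$p2, cfg$priors$p12)

  shared_pair <- simulate_trait_pair(
    geno, scenario_spec("shared", causal_index_1 = 100L, beta_gwas = 0.55,
                        beta_eqtl = 0.4, seed = seed + 22L),
    gene_id = shared_gene)
  distinct_pair <- simulate_trait_pair(
    geno, scenario_spec("distinct", causal_index_1 = 60L,
                        causal_index_2 = 140L, beta_gwas = 0.55,
                        beta_eqtl = 0.4, seed = seed + 23L),
    gene_id = distinct_gene)

  f <- art("gwas_shared.tsv")
  write_gwas(shared_pair$gwas[!shared_pair$gwas$monomorphic, ], f)
  written <- c(written, f)

  res_shared <- coloc_single(as_abf_dataset(shared_pair$eqtl, "quant"),
                             as_abf_dataset(shared_pair$gwas, "cc"), priors)
  res_distinct <- coloc_single(as_abf_dataset(distinct_pair$eqtl, "quant"),
                               as_abf_dataset(distinct_pair$gwas, "cc"),
                               priors)

  ## a gene with two independent eQTL signals, one shared with its GWAS
  set.seed(seed + 24L)
  liab2 <- 0.55 * geno$dosages[50L, ] + rnorm(n)
  y2 <- as.numeric(liab2 > quantile(liab2, 0.5, names = FALSE))
  expr2 <- 0.3 * geno$dosages[50L, ] + 0.55 * geno$dosages[150L, ] + rnorm(n)
  gwas2 <- marginal_sumstats(geno, y2, "cc")
  eqtl2 <- cbind(gene_id = twosignal_gene,
                 marginal_sumstats(geno, expr2, "quant"),
                 stringsAsFactors = FALSE)
  eqtl2$n <- n
  ld <- ld_r2(geno$dosages)
  ds_eq2 <- as_abf_dataset(eqtl2, "quant")
  ds_gw2 <- as_abf_dataset(gwas2, "cc")
  res_masked <- coloc_masked(ds_eq2, ds_gw2, ld, priors,
                             p_thresh = cfg$mask$p_thresh,
                             r2_thresh = cfg$mask$r2_thresh,
                             max_signals = cfg$mask$max_signals)
  res_single2 <- coloc_single(ds_eq2, ds_gw2, priors)

  for (it in list(list("coloc_shared.json", coloc_result_list(res_shared)),
                  list("coloc_distinct.json", coloc_result_list(res_distinct)))) {
    f <- art(it[[1L]])
    jsonlite::write_json(c(it[[2L]], list(provenance = cfg)), f,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  f <- art("coloc_masked.json")
  jsonlite::write_json(
    list(leads = res_masked$leads, max_pp4 = res_masked$max_pp4,
         signals = lapply(res_masked$results, coloc_result_list),
         single_mode = coloc_result_list(res_single2), provenance = cfg),
    f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, f)

  ## -- prioritization table ---------------------------------------------
  lead <- shared_pair$truth$causal_gwas
  datasets <- list(
    tissueA = rbind(shared_pair$eqtl, eqtl2),
    tissueB = distinct_pair$eqtl
  )
  pv <- lead_variant_pvalues(datasets, lead, locus_genes)
  best <- apply(pv$pvalues, 1L, function(x)
    suppressWarnings(min(x, na.rm = TRUE)))
  ord <- order(best, rownames(pv$pvalues))
  coloc_df <- data.frame(
    gene_id = c(shared_gene, twosignal_gene, distinct_gene),
    dataset_id = c("tissueA", "tissueA", "tissueB"),
    pp4 = c(res_shared$pp4, res_masked$max_pp4, res_distinct$pp4),
    stringsAsFactors = FALSE
  )
  priority <- build_priority_table(screen_ranks,
                                   pv$pvalues[ord, , drop = FALSE],
                                   coloc_df, pp4_threshold = cfg$pp4_flag)
  f <- art("priority.tsv")
  write_priority_table(priority, f)
  written <- c(written, f)

  ## -- manifest ----------------------------------------------------------
  manifest <- data.frame(
    file = basename(written),
    md5 = unname(tools::md5sum(written)),
    bytes = unname(file.size(written)),
    stringsAsFactors = FALSE
  )
  f <- art("manifest.json")
  jsonlite::write_json(list(config = cfg, files = manifest), f,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(out_dir = out_dir, manifest = manifest, config = cfg,
                 inflation = infl, coloc_shared = res_shared,
                 coloc_distinct = res_distinct, coloc_masked = res_masked,
                 coloc_single_two_signal = res_single2,
                 priority = priority))
}
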