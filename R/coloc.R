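# Bayesian colocalization of two summary-statistic datasets under a
# single-causal-variant model, via Wakefield approximate Bayes factors.
#
# Per variant, with z = beta/se, V = se^2 and W the prior effect variance,
# the log ABF against the null is
#     labf = 0.5 * log(1 - r) + 0.5 * r * z^2,   r = W / (V + W).
# Five hypotheses are scored for a region: H0 no association, H1/H2
# association with one trait only, H3 two distinct causal variants, H4 one
# shared causal variant. All hypothesis sums are accumulated in log space
# (log-sum-exp), so panels of thousands of variants with very large Bayes
# factors are handled without overflow.

#' Colocalization priors
#'
#' Per-variant prior probabilities: `p1` causal for trait 1 only, `p2`
#' causal for trait 2 only, `p12` causal for both. Defaults are the
#' conventional `1e-4`, `1e-4`, `5e-6`.
#'
#' @param p1,p2,p12 Positive priors with `p12 <= min(p1, p2)` and
#'   `p1 + p2 + p12 < 1`.
#' @return Object of class `"coloc_priors"`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0)
  if (p12 > min(p1, p2)) stop("p12 must not exceed min(p1, p2)")
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Log approximate Bayes factors for single-variant association
#'
#' @param beta,se Effect estimates and standard errors (`se > 0`).
#' @param prior_sd Prior standard deviation of the true effect (`W =
#'   prior_sd^2`).
#' @return Numeric vector of log ABFs; 0 effect gives
#'   `0.5 * log(1 - r) < 0`.
#' @export
#' @examples
#' compute_labf(0.3, 0.1, 0.15)
compute_labf <- function(beta, se, prior_sd) {
  stopifnot(prior_sd > 0)
  if (any(!is.finite(se) | se <= 0)) stop("se must be > 0")
  z <- beta / se
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * log(1 - r) + 0.5 * r * z^2
}

#' Estimate the trait standard deviation from summary statistics
#'
#' For a quantitative trait, `var(beta_hat_j) ~ sdY^2 / (2 n maf_j (1 -
#' maf_j))`, so `sdY^2` is the slope of the through-origin regression of
#' `2 n maf (1 - maf)` on `1 / vbeta`. Expression traits in the major
#' eQTL resources are rank-normalized, so `sdY = 1` is the usual default
#' and this estimator is opt-in.
#'
#' @param vbeta Squared standard errors, one per variant.
#' @param maf Minor allele frequencies in (0, 0.5].
#' @param n Sample size.
#' @return Estimated `sdY` (positive scalar).
#' @export
estimate_sdY <- function(vbeta, maf, n) {
  stopifnot(length(vbeta) == length(maf), all(vbeta > 0),
            all(maf > 0 & maf <= 0.5), n > 0)
  oneover <- 1 / vbeta
  nvx <- 2 * n * maf * (1 - maf)
  slope <- coef(lm(nvx ~ oneover - 1))[[1]]
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive slope estimating sdY; supply sdY = 1 explicitly ",
         "(rank-normalized trait) or check inputs")
  }
  sqrt(slope)
}

#' Assemble a dataset for ABF colocalization
#'
#' Bundles per-variant effects with the trait model and computes log ABFs.
#' The prior effect SD defaults to the single-variant ABF conventions: 0.2
#' on the log-odds scale for case-control traits and `0.15 * sdY` for
#' quantitative traits.
#'
#' @param variant_id Character vector of canonical variant ids
#'   ("chrom:pos:ref:alt"); must be unique.
#' @param beta,se Effect sizes and standard errors (`se > 0`).
#' @param type `"quant"` or `"cc"`.
#' @param sdY Trait SD (quantitative traits); see [estimate_sdY()].
#' @param prior_sd Override for the prior effect SD.
#' @param pvalues Optional per-variant p-values (needed for LD masking).
#' @param positions Optional integer positions (needed for region tools).
#' @return Object of class `"abf_dataset"`.
#' @export
abf_dataset <- function(variant_id, beta, se, type = c("quant", "cc"),
                        sdY = 1, prior_sd = NULL, pvalues = NULL,
                        positions = NULL) {
  type <- match.arg(type)
  variant_id <- as.character(variant_id)
  n <- length(variant_id)
  stopifnot(length(beta) == n, length(se) == n)
  if (anyDuplicated(variant_id)) stop("duplicate variant ids in dataset")
  if (!is.null(pvalues)) stopifnot(length(pvalues) == n)
  if (is.null(prior_sd)) {
    prior_sd <- if (type == "cc") 0.2 else 0.15 * sdY
  }
  structure(list(variants = variant_id, beta = beta, se = se, type = type,
                 sdY = sdY, prior_sd = prior_sd,
                 labf = compute_labf(beta, se, prior_sd),
                 pvalues = pvalues, positions = positions),
            class = "abf_dataset")
}

#' Build an ABF dataset from a summary-statistic record table
#'
#' Convenience wrapper around [abf_dataset()]: takes a GWAS/eQTL record
#' data frame (as produced by [read_gwas()], [read_eqtl()] or
#' [marginal_sumstats()]), drops rows with missing effect or standard
#' error (e.g. monomorphic variants), and carries p-values and positions
#' through.
#'
#' @param records Record data frame with `variant_id`, `beta`, `se`,
#'   `pvalue`, `pos`.
#' @inheritParams abf_dataset
#' @return Object of class `"abf_dataset"`.
#' @export
as_abf_dataset <- function(records, type = c("quant", "cc"), sdY = 1,
                           prior_sd = NULL) {
  ok <- is.finite(records$beta) & is.finite(records$se) & records$se > 0
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " record(s) with missing effect or se dropped")
  }
  records <- records[ok, , drop = FALSE]
  abf_dataset(records$variant_id, records$beta, records$se, type = type,
              sdY = sdY, prior_sd = prior_sd, pvalues = records$pvalue,
              positions = records$pos)
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, clamping floating-point ties to -Inf
logdiffexp <- function(a, b) {
  if (b >= a) {
    if (b - a < 1e-9) return(-Inf)
    stop("logdiffexp: negative difference")
  }
  a + log1p(-exp(b - a))
}

#' Colocalization of two datasets under one causal variant per trait
#'
#' Intersects the two datasets on their (pre-harmonized) variant ids and
#' scores the five colocalization hypotheses from the per-variant log ABFs
#' `l1`, `l2`:
#' `S0 = 1`, `S1 = p1 * sum(BF1)`, `S2 = p2 * sum(BF2)`,
#' `S3 = p1 p2 * (sum(BF1) sum(BF2) - sum(BF1 BF2))`,
#' `S4 = p12 * sum(BF1 BF2)`, with posteriors `PPi = Si / sum(S)`; all sums
#' are computed with log-sum-exp. A single shared variant is allowed
#' (`PP3` is then exactly 0).
#'
#' @param ds1,ds2 [abf_dataset()] objects on harmonized variant ids.
#' @param priors [coloc_priors()].
#' @return Object of class `"coloc_result"`: `pp0`..`pp4`, `n_variants`,
#'   `priors`, `signal_index` (0 in single mode), `masked_variants` (0 in
#'   single mode), and `suggestive` (`pp4 > 0.5`).
#' @export
coloc_single <- function(ds1, ds2, priors = coloc_priors()) {
  shared <- intersect(ds1$variants, ds2$variants)
  if (!length(shared)) stop("no shared variants between the two datasets")
  l1 <- ds1$labf[match(shared, ds1$variants)]
  l2 <- ds2$labf[match(shared, ds2$variants)]
  lse1 <- logsumexp(l1)
  lse2 <- logsumexp(l2)
  lse12 <- logsumexp(l1 + l2)
  logS <- c(pp0 = 0,
            pp1 = log(priors$p1) + lse1,
            pp2 = log(priors$p2) + lse2,
            pp3 = log(priors$p1) + log(priors$p2) +
              logdiffexp(lse1 + lse2, lse12),
            pp4 = log(priors$p12) + lse12)
  pp <- exp(logS - logsumexp(logS))
  pp <- pp / sum(pp)
  structure(list(pp0 = pp[["pp0"]], pp1 = pp[["pp1"]], pp2 = pp[["pp2"]],
                 pp3 = pp[["pp3"]], pp4 = pp[["pp4"]],
                 n_variants = length(shared), priors = priors,
                 signal_index = 0L, masked_variants = 0L,
                 suggestive = pp[["pp4"]] > 0.5),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d shared variants%s\n", x$n_variants,
              if (x$signal_index > 0)
                sprintf(" (signal %d, %d variants masked)",
                        x$signal_index, x$masked_variants) else ""))
  cat(sprintf("  PP0 %.4f  PP1 %.4f  PP2 %.4f  PP3 %.4f  PP4 %.4f\n",
              x$pp0, x$pp1, x$pp2, x$pp3, x$pp4))
  cat(sprintf("  suggestive colocalization (PP4 > 0.5): %s\n",
              if (x$suggestive) "yes" else "no"))
  invisible(x)
}

#' Eligibility filter for colocalization testing
#'
#' A gene is eligible if it has a cis-eQTL with nominal p-value below
#' `p_thresh` within `window` bases (closed) of the lead GWAS variant.
#'
#' @param eqtl Data frame of eQTL records (`gene_id`, `chrom`, `pos`,
#'   `pvalue`).
#' @param lead_variant Canonical variant id string, or a list/data frame
#'   with `chrom` and `pos`.
#' @param window Half-width in bases; default 100 kb.
#' @param p_thresh Nominal p-value threshold; default 1e-4.
#' @return Sorted character vector of eligible gene ids.
#' @export
eligibility_filter <- function(eqtl, lead_variant, window = 1e5,
                               p_thresh = 1e-4) {
  lead <- as_lead(lead_variant)
  hit <- normalize_chrom(eqtl$chrom) == lead$chrom &
    abs(eqtl$pos - lead$pos) <= window &
    eqtl$pvalue < p_thresh
  sort(unique(eqtl$gene_id[hit]))
}

as_lead <- function(lead_variant) {
  if (is.character(lead_variant)) {
    parsed <- parse_variant_id(lead_variant)
    list(chrom = parsed$chrom[1], pos = parsed$pos[1])
  } else {
    list(chrom = normalize_chrom(lead_variant$chrom[1]),
         pos = lead_variant$pos[1])
  }
}

#' Subset records to a window around a center variant
#'
#' Closed-interval subsetting: positions in `[center - halfwidth,
#' center + halfwidth]` on the center's chromosome.
#'
#' @param records Data frame with `chrom` and `pos`.
#' @inheritParams eligibility_filter
#' @param center_variant Canonical variant id string or list with
#'   `chrom`/`pos`.
#' @param halfwidth Positive half-width in bases.
#' @return The subset, row order preserved.
#' @export
region_subset <- function(records, center_variant, halfwidth) {
  stopifnot(halfwidth > 0)
  lead <- as_lead(center_variant)
  keep <- normalize_chrom(records$chrom) == lead$chrom &
    records$pos >= lead$pos - halfwidth & records$pos <= lead$pos + halfwidth
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

ld_r2_of <- function(ld, variants) {
  r2 <- if (inherits(ld, "ld_matrix")) ld$r2 else as.matrix(ld)
  if (is.null(rownames(r2))) stop("LD matrix must carry variant ids as dimnames")
  miss <- setdiff(variants, rownames(r2))
  if (length(miss)) {
    stop("LD matrix missing dataset variant(s): ",
         paste(head(miss, 5L), collapse = ", "))
  }
  r2[variants, variants, drop = FALSE]
}

#' Iterative selection of independent association signals with LD masking
#'
#' Greedy forward selection: repeatedly pick the unmasked variant with the
#' smallest p-value; stop when that p-value is not below `p_thresh` or
#' `max_signals` leads have been selected; after each pick, mask every
#' variant with `r^2 >` `r2_thresh` to the new lead. Selected leads are
#' therefore pairwise independent at the `r2_thresh` level and are
#' returned in p-value (selection) order. Missing `r^2` entries
#' (monomorphic reference variants) are treated as unlinked.
#'
#' @param ds [abf_dataset()] with `pvalues` set.
#' @param ld [ld_r2()] result (or a named symmetric `r^2` matrix) covering
#'   all dataset variants.
#' @param p_thresh Significance threshold for calling a (secondary)
#'   signal; default 1e-4.
#' @param r2_thresh `r^2` above which two variants are considered the same
#'   signal; default 0.01.
#' @param max_signals Maximum number of leads; default 3.
#' @return Character vector of lead variant ids (possibly empty).
#' @export
find_signals_masked <- function(ds, ld, p_thresh = 1e-4, r2_thresh = 0.01,
                                max_signals = 3) {
  if (is.null(ds$pvalues)) stop("dataset has no p-values; masking needs them")
  r2 <- ld_r2_of(ld, ds$variants)
  p <- ds$pvalues
  n <- length(p)
  unmasked <- rep(TRUE, n)
  leads <- integer(0)
  while (length(leads) < max_signals && any(unmasked)) {
    cand <- which(unmasked)
    i <- cand[which.min(p[cand])]
    if (p[i] >= p_thresh) break
    leads <- c(leads, i)
    linked <- which(r2[i, ] > r2_thresh & !is.na(r2[i, ]))
    unmasked[linked] <- FALSE
    unmasked[i] <- FALSE
  }
  ds$variants[leads]
}

abf_subset <- function(ds, keep) {
  structure(list(variants = ds$variants[keep], beta = ds$beta[keep],
                 se = ds$se[keep], type = ds$type, sdY = ds$sdY,
                 prior_sd = ds$prior_sd, labf = ds$labf[keep],
                 pvalues = ds$pvalues[keep],
                 positions = ds$positions[keep]),
            class = "abf_dataset")
}

#' Colocalization with iterative LD masking of secondary trait-1 signals
#'
#' Identifies up to `max_signals` independent signals in `ds1` (the trait
#' with LD information, typically the eQTL side) via
#' [find_signals_masked()], then runs one single-causal-variant
#' colocalization per signal on a panel from which every variant in
#' `r^2 >` `r2_thresh` with any *other* signal's lead has been removed.
#' The other trait (`ds2`, typically the GWAS) is treated as
#' single-signal. With zero or one signal found this reduces exactly to
#' [coloc_single()] on the full panel.
#'
#' @inheritParams find_signals_masked
#' @param ds1 [abf_dataset()] with `pvalues`; the masked trait.
#' @param ds2 [abf_dataset()]; the single-signal trait.
#' @param ld1 LD matrix covering `ds1`'s variants.
#' @param priors [coloc_priors()].
#' @return Object of class `"coloc_masked_result"`: list with `results`
#'   (one `"coloc_result"` per signal, `signal_index` and
#'   `masked_variants` filled in), `leads` (lead variant ids), and
#'   `max_pp4`.
#' @export
coloc_masked <- function(ds1, ds2, ld1, priors = coloc_priors(),
                         p_thresh = 1e-4, r2_thresh = 0.01,
                         max_signals = 3) {
  leads <- find_signals_masked(ds1, ld1, p_thresh, r2_thresh, max_signals)
  if (length(leads) <= 1L) {
    res <- coloc_single(ds1, ds2, priors)
    res$signal_index <- if (length(leads)) 1L else 0L
    out <- list(results = list(res), leads = leads, max_pp4 = res$pp4)
    return(structure(out, class = "coloc_masked_result"))
  }
  r2 <- ld_r2_of(ld1, ds1$variants)
  results <- vector("list", length(leads))
  for (k in seq_along(leads)) {
    others <- leads[-k]
    oidx <- match(others, ds1$variants)
    linked <- rep(FALSE, length(ds1$variants))
    for (o in oidx) linked <- linked | (r2[o, ] > r2_thresh & !is.na(r2[o, ]))
    res <- coloc_single(abf_subset(ds1, !linked), ds2, priors)
    res$signal_index <- k
    res$masked_variants <- sum(linked)
    results[[k]] <- res
  }
  structure(list(results = results, leads = leads,
                 max_pp4 = max(vapply(results, `[[`, numeric(1), "pp4"))),
            class = "coloc_masked_result")
}

#' @export
print.coloc_masked_result <- function(x, ...) {
  cat(sprintf("Masked colocalization: %d signal(s), max PP4 = %.4f\n",
              length(x$leads), x$max_pp4))
  for (res in x$results) print(res)
  invisible(x)
}
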