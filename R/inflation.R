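# Quantile-based inflation of GWAS signal at lead cis-eQTLs of a gene set,
# with a permutation null drawn from a background gene set.
#
# lambda_q compares the chi-square(1 df) quantile implied by the empirical
# q-quantile of a p-value set to the chi-square quantile at 1 - q; with
# q = 0.1 it measures inflation among the 10% most significant tests.
# lambda = 1 under a uniform null, > 1 for excess association signal.

#' Quantile-based genomic inflation statistic
#'
#' `lambda_q = Q_chisq1(1 - quantile_q(p)) / Q_chisq1(1 - q)` where
#' `quantile_q` is the empirical q-quantile of the p-values (R's default
#' type-7 linear interpolation) and `Q_chisq1` the chi-square(1 df)
#' quantile function.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param q Quantile of the statistic, in (0, 1); default 0.1.
#' @return The inflation statistic, a positive scalar.
#' @export
#' @examples
#' set.seed(1)
#' lambda_quantile(runif(1e4)) # ~ 1 under the uniform null
lambda_quantile <- function(pvalues, q = 0.1) {
  stopifnot(q > 0, q < 1)
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (length(pvalues) < ceiling(1 / q)) {
    stop("need at least ", ceiling(1 / q), " p-values for the ", q,
         "-quantile statistic")
  }
  pq <- quantile(pvalues, q, names = FALSE, type = 7)
  qchisq(1 - pq, df = 1) / qchisq(1 - q, df = 1)
}

#' Match lead cis-eQTL variants to GWAS p-values
#'
#' For each lead eQTL whose variant is present in the GWAS table, returns
#' the GWAS p-value (named by gene id, input order preserved). Leads absent
#' from the GWAS are counted, not errors; zero matches is an error.
#'
#' @param leads Data frame of lead eQTLs with `gene_id` and `variant_id`
#'   (or `chrom`/`pos`/`ref`/`alt`).
#' @param gwas Data frame of GWAS records with `variant_id` and `pvalue`.
#' @return List with `pvalues` (named numeric vector) and `dropped`
#'   (number of unmatched leads).
#' @export
match_leads_to_gwas <- function(leads, gwas) {
  vid <- leads$variant_id
  if (is.null(vid)) {
    vid <- make_variant_id(leads$chrom, leads$pos, leads$ref, leads$alt)
  }
  idx <- match(vid, gwas$variant_id)
  hit <- !is.na(idx)
  if (!any(hit)) stop("no lead eQTL variant is present in the GWAS")
  list(pvalues = setNames(gwas$pvalue[idx[hit]], leads$gene_id[hit]),
       dropped = sum(!hit))
}

#' Permutation test for inflation of GWAS signal at a gene set's lead eQTLs
#'
#' The observed statistic is `lambda_q` of the GWAS p-values at the lead
#' cis-eQTL variants of the target genes. The null is built by drawing
#' `|target|` genes uniformly without replacement from the background lead
#' set `k` times and recomputing `lambda_q`; each gene contributes one
#' p-value per draw. Permuted lambdas are log-transformed (making the null
#' distribution approximately symmetric) and the two-sided p-value is
#' `(1 + #\{|log(lambda_perm) - c| >= |log(lambda_obs) - c|\}) / (k + 1)`,
#' where the center `c` is the mean of the permuted log-lambdas
#' (`center = "mean"`, the default) or 0 (`center = "zero"`). The +1
#' correction keeps the p-value strictly positive.
#'
#' @param target_genes Character vector of target gene ids; must be a
#'   subset of the background genes. A target equal to the whole
#'   background is a degenerate self-comparison with p near 1.
#' @param leads Background lead eQTL set (one row per gene), as in
#'   [match_leads_to_gwas()].
#' @param gwas GWAS records with `variant_id` and `pvalue`.
#' @param q Quantile of the statistic; default 0.1.
#' @param k Number of permutations; default 10000.
#' @param seed Integer RNG seed; the result is bitwise reproducible.
#' @param center Centering of the two-sided extremity rule.
#' @return Object of class `"inflation_result"`: a list with `lambda_obs`,
#'   `log_lambda_obs`, `perm_log_lambdas` (length `k`), `p_two_sided`,
#'   `n_target`, `n_background`, `dropped`, and the resolved settings
#'   (`q`, `k`, `seed`, `center`, `quantile_type`).
#' @export
permutation_inflation_test <- function(target_genes, leads, gwas,
                                       q = 0.1, k = 10000, seed = 1L,
                                       center = c("mean", "zero")) {
  center <- match.arg(center)
  stopifnot(k >= 1)
  target_genes <- unique(as.character(target_genes))
  if (!all(target_genes %in% leads$gene_id)) {
    stop("target genes must be a subset of the background lead set")
  }
  matched <- match_leads_to_gwas(leads, gwas)
  bg_p <- matched$pvalues
  tg_p <- bg_p[names(bg_p) %in% target_genes]
  nt <- length(tg_p)
  nb <- length(bg_p)
  if (nt < ceiling(1 / q)) {
    stop("quantile undefined: only ", nt, " target leads matched, need >= ",
         ceiling(1 / q))
  }
  if (nb < nt) stop("background smaller than the target set")

  denom <- qchisq(1 - q, df = 1)
  lam <- function(p) qchisq(1 - quantile(p, q, names = FALSE, type = 7),
                            df = 1) / denom
  lambda_obs <- lam(tg_p)

  set.seed(seed)
  perm_log <- log(vapply(seq_len(k),
                         function(i) lam(bg_p[sample.int(nb, nt)]),
                         numeric(1)))
  cc <- if (center == "mean") mean(perm_log) else 0
  log_obs <- log(lambda_obs)
  p2 <- (1 + sum(abs(perm_log - cc) >= abs(log_obs - cc))) / (k + 1)

  structure(list(lambda_obs = lambda_obs,
                 log_lambda_obs = log_obs,
                 perm_log_lambdas = perm_log,
                 p_two_sided = p2,
                 n_target = nt,
                 n_background = nb,
                 dropped = matched$dropped,
                 q = q, k = k, seed = seed, center = center,
                 quantile_type = 7L),
            class = "inflation_result")
}

#' @export
print.inflation_result <- function(x, ...) {
  cat(sprintf("Inflation of GWAS signal at target lead cis-eQTLs\n"))
  cat(sprintf("  lambda_%.3g = %.4g (log = %.4g)\n", x$q, x$lambda_obs,
              x$log_lambda_obs))
  cat(sprintf("  permutation P (two-sided, %s-centered, k = %d) = %.4g\n",
              x$center, x$k, x$p_two_sided))
  cat(sprintf("  target leads matched: %d of background %d (%d dropped)\n",
              x$n_target, x$n_background, x$dropped))
  invisible(x)
}
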