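# Gene-level ranking of a pooled CRISPR loss-of-function screen from guide
# read counts. Enrichment means higher abundance in infected (surviving)
# samples: guides knocking out genes the virus needs are over-represented
# among survivors. Three rank statistics are computed per gene:
#   sbscore  - the second-highest guide log2 fold-change (robust to a single
#              outlier guide);
#   rra_rho  - robust rank aggregation: the minimum over the gene's guide
#              order statistics of the beta tail probability of seeing a
#              normalized rank that small by chance;
#   riger_ws - a weighted sum of the best and second-best normalized guide
#              ranks.

#' Normalize guide read counts across samples
#'
#' Default (and only) method is counts-per-million: each sample column is
#' scaled to sum to 10^6, removing sequencing-depth differences between
#' biological samples.
#'
#' @param counts Guide x sample matrix of non-negative counts, or a data
#'   frame as returned by [read_guide_counts()] (`guide_id`/`gene_id`
#'   columns become rownames/are dropped).
#' @param method Normalization method; `"cpm"`.
#' @return Numeric matrix with the same dimensions, columns summing to 10^6.
#' @export
#' @examples
#' normalize_counts(cbind(s1 = c(1, 1, 2)))
normalize_counts <- function(counts, method = c("cpm")) {
  method <- match.arg(method)
  m <- as_count_matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    stop("all-zero sample column(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  sweep(m, 2, tot, "/") * 1e6
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    sample_cols <- setdiff(names(counts), c("guide_id", "gene_id"))
    m <- as.matrix(counts[, sample_cols, drop = FALSE])
    mode(m) <- "numeric"
    if (!is.null(counts$guide_id)) rownames(m) <- counts$guide_id
    m
  } else {
    m <- as.matrix(counts)
    mode(m) <- "numeric"
    m
  }
}

#' Guide-level log2 fold-change, infected vs. uninfected control
#'
#' Replicate samples are averaged per condition on the normalized scale,
#' then `log2((infected + pc) / (control + pc))` is taken per guide. The
#' pseudocount keeps the ratio finite for guides that drop out of one
#' condition.
#'
#' @param norm_infected,norm_control Normalized guide x sample matrices (or
#'   vectors) for the two conditions, with matching guide rownames.
#' @param pseudocount Positive constant added to both conditions.
#' @return Named numeric vector of log2 fold-changes, one per guide, in the
#'   infected matrix's guide order.
#' @export
guide_log2fc <- function(norm_infected, norm_control, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  inf <- if (is.matrix(norm_infected)) norm_infected else cbind(norm_infected)
  ctl <- if (is.matrix(norm_control)) norm_control else cbind(norm_control)
  gi <- rownames(inf)
  gc <- rownames(ctl)
  if (is.null(gi) || is.null(gc)) {
    if (nrow(inf) != nrow(ctl)) stop("conditions have different guide counts")
  } else {
    only <- c(setdiff(gi, gc), setdiff(gc, gi))
    if (length(only)) {
      stop("guide(s) present in one condition only: ",
           paste(head(only, 10L), collapse = ", "))
    }
    ctl <- ctl[gi, , drop = FALSE]
  }
  lfc <- log2((rowMeans(inf) + pseudocount) / (rowMeans(ctl) + pseudocount))
  names(lfc) <- gi
  lfc
}

#' Second-best guide score per gene
#'
#' A gene's sbscore is the second-highest log2 fold-change among its
#' guides: a single spuriously enriched guide cannot carry a gene, while
#' two concordant guides can. Genes are ranked descending by sbscore.
#' Genes targeted by fewer than two guides are excluded and reported in
#' the `"excluded_genes"` attribute.
#'
#' @param log2fc Named numeric vector of guide log2 fold-changes.
#' @param gene Character vector of gene ids, parallel to `log2fc`.
#' @return Data frame with `gene_id`, `n_guides`, `sbscore`,
#'   `rank_sbscore` (1 = most enriched; ties broken by gene id).
#' @export
#' @examples
#' sbscore(c(8, 5, 3, 2, 1, 1), rep("g1", 6))
sbscore <- function(log2fc, gene) {
  stopifnot(length(log2fc) == length(gene))
  by_gene <- split(log2fc, as.character(gene))
  n_guides <- lengths(by_gene)
  excluded <- names(by_gene)[n_guides < 2]
  by_gene <- by_gene[n_guides >= 2]
  if (!length(by_gene)) stop("no gene has >= 2 guides")
  sc <- vapply(by_gene, function(x) sort(x, decreasing = TRUE)[2L], numeric(1))
  out <- data.frame(gene_id = names(sc), n_guides = lengths(by_gene),
                    sbscore = unname(sc), stringsAsFactors = FALSE)
  out <- out[order(-out$sbscore, out$gene_id), , drop = FALSE]
  out$rank_sbscore <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- excluded
  out
}

#' Robust rank aggregation rho statistic
#'
#' For a gene with `k` guides whose normalized ranks (guide rank within the
#' full guide list, divided by the number of guides) sorted ascending are
#' `r_(1) <= ... <= r_(k)`, the statistic is
#' `rho = min_j P(Beta(j, k - j + 1) <= r_(j))`:
#' the most surprising order statistic under the null that all guide ranks
#' are uniform. Smaller rho means stronger enrichment.
#'
#' @param normalized_ranks Numeric vector in (0, 1], the gene's guides'
#'   normalized ranks.
#' @return rho in (0, 1].
#' @export
#' @examples
#' rra_rho(c(0.1, 0.2)) # min(1 - 0.9^2, 0.2^2) = 0.04
rra_rho <- function(normalized_ranks) {
  k <- length(normalized_ranks)
  if (k == 0L) stop("k = 0: no guide ranks supplied")
  if (any(normalized_ranks <= 0 | normalized_ranks > 1)) {
    stop("normalized ranks must lie in (0, 1]")
  }
  r <- sort(normalized_ranks)
  j <- seq_len(k)
  min(pbeta(r, j, k - j + 1))
}

#' Weighted-sum score of the two best guide ranks
#'
#' `score = w * r_(1) + (1 - w) * r_(2)` on the gene's sorted normalized
#' guide ranks. With `w = 0` it reduces to the rank analogue of the
#' second-best score. Genes are ranked ascending by score.
#'
#' @inheritParams rra_rho
#' @param w Weight on the best rank, in \[0, 1\]; default 0.25.
#' @return Weighted-sum score.
#' @export
riger_weighted_sum <- function(normalized_ranks, w = 0.25) {
  if (length(normalized_ranks) < 2L) stop("need >= 2 guide ranks")
  stopifnot(w >= 0, w <= 1)
  r <- sort(normalized_ranks)
  w * r[1L] + (1 - w) * r[2L]
}

#' Gene-level screen scores by all three ranking methods
#'
#' Normalizes counts, averages replicates, computes guide log2
#' fold-changes, and aggregates them per gene by sbscore, RRA rho, and the
#' weighted sum of the two best guide ranks. Guide ranks are assigned over
#' the full guide list, descending by fold-change, with ties broken by
#' guide id so ranks are a strict permutation of `1..n_guides` (RRA's
#' order statistics require distinct ranks). Within each method, gene
#' ranks are a permutation of `1..G`, ties broken by gene id.
#'
#' @param counts Data frame from [read_guide_counts()] (columns `guide_id`,
#'   `gene_id`, samples).
#' @param control_samples,infected_samples Character vectors of sample
#'   column names for the two conditions.
#' @param pseudocount Pseudocount for [guide_log2fc()].
#' @param riger_w Weight for [riger_weighted_sum()].
#' @return Data frame with one row per gene (>= 2 guides): `gene_id`,
#'   `n_guides`, `sbscore`, `rra_rho`, `riger_ws`, `rank_sbscore`,
#'   `rank_rra`, `rank_riger`. Genes with fewer than two guides are listed
#'   in the `"excluded_genes"` attribute.
#' @export
screen_scores <- function(counts, control_samples, infected_samples,
                          pseudocount = 1, riger_w = 0.25) {
  miss <- setdiff(c(control_samples, infected_samples), names(counts))
  if (length(miss)) {
    stop("sample column(s) not in count table: ", paste(miss, collapse = ", "))
  }
  norm <- normalize_counts(counts)
  lfc <- guide_log2fc(norm[, infected_samples, drop = FALSE],
                      norm[, control_samples, drop = FALSE],
                      pseudocount = pseudocount)
  gene <- setNames(counts$gene_id, counts$guide_id)[names(lfc)]

  n <- length(lfc)
  ord <- order(-lfc, names(lfc))
  rank_vec <- integer(n)
  rank_vec[ord] <- seq_len(n)
  nr <- rank_vec / n

  sb <- sbscore(lfc, gene)
  by_gene_nr <- split(nr, unname(gene))
  by_gene_nr <- by_gene_nr[lengths(by_gene_nr) >= 2]
  rho <- vapply(by_gene_nr, rra_rho, numeric(1))
  ws <- vapply(by_gene_nr, riger_weighted_sum, numeric(1), w = riger_w)

  out <- sb[, c("gene_id", "n_guides", "sbscore")]
  out$rra_rho <- unname(rho[out$gene_id])
  out$riger_ws <- unname(ws[out$gene_id])
  out$rank_sbscore <- rank_strict(-out$sbscore, out$gene_id)
  out$rank_rra <- rank_strict(out$rra_rho, out$gene_id)
  out$rank_riger <- rank_strict(out$riger_ws, out$gene_id)
  out <- out[order(out$rank_sbscore), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- attr(sb, "excluded_genes")
  out
}

rank_strict <- function(key, tie_break) {
  ord <- order(key, tie_break)
  r <- integer(length(key))
  r[ord] <- seq_along(key)
  r
}

#' Union of the top-ranked genes across methods
#'
#' Takes the union of each method's `top_n` genes (by its rank column in a
#' [screen_scores()] table), optionally intersected with a gene universe
#' (e.g. protein-coding gene ids).
#'
#' @param scores Data frame from [screen_scores()].
#' @param top_n Number of genes per method.
#' @param methods Subset of `c("sbscore", "rra", "riger")`.
#' @param gene_universe Optional character vector restricting the result.
#' @return Sorted character vector of gene ids.
#' @export
top_ranked_union <- function(scores, top_n = 500,
                             methods = c("sbscore", "rra", "riger"),
                             gene_universe = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (top_n > nrow(scores)) {
    stop("top_n (", top_n, ") exceeds number of ranked genes (", nrow(scores), ")")
  }
  sets <- lapply(paste0("rank_", methods), function(cl) {
    scores$gene_id[scores[[cl]] <= top_n]
  })
  u <- Reduce(union, sets)
  if (!is.null(gene_universe)) u <- intersect(u, gene_universe)
  sort(u)
}
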