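# Integration of screen ranks, per-dataset lead-variant eQTL p-values and
# colocalization posteriors into a per-gene, per-dataset prioritization
# table for one locus.

#' Lead-variant eQTL p-values per gene and dataset
#'
#' For each eQTL dataset, extracts each gene's nominal p-value for the
#' lead GWAS variant. Genes are ranked by this p-value within a dataset
#' (the lead GWAS variant's association, not the gene's own lead eQTL).
#' A dataset is highlighted when its minimum p-value over the genes is
#' below `highlight_p`.
#'
#' @param eqtl_datasets Named list of eQTL record data frames (each with
#'   `gene_id`, `variant_id`, `pvalue`).
#' @param lead_variant Canonical variant id of the lead GWAS variant.
#' @param genes Character vector of locus gene ids; its order fixes the
#'   table's row order.
#' @param highlight_p Highlight threshold; default 1e-4.
#' @return List with `pvalues` (gene x dataset matrix, `NA` where the lead
#'   variant or gene is absent) and `highlighted` (character vector of
#'   dataset names).
#' @export
lead_variant_pvalues <- function(eqtl_datasets, lead_variant, genes,
                                 highlight_p = 1e-4) {
  stopifnot(is.list(eqtl_datasets), !is.null(names(eqtl_datasets)))
  tab <- sapply(eqtl_datasets, function(d) {
    hit <- d[d$variant_id == lead_variant, , drop = FALSE]
    setNames(hit$pvalue[match(genes, hit$gene_id)], genes)
  })
  tab <- matrix(tab, nrow = length(genes),
                dimnames = list(genes, names(eqtl_datasets)))
  if (all(is.na(tab))) {
    stop("lead variant ", lead_variant, " absent from every eQTL dataset")
  }
  mins <- apply(tab, 2L, function(x) suppressWarnings(min(x, na.rm = TRUE)))
  highlighted <- colnames(tab)[is.finite(mins) & mins < highlight_p]
  list(pvalues = tab, highlighted = highlighted)
}

#' Build the gene prioritization table for a locus
#'
#' Full outer join of the lead-variant p-value table and the
#' colocalization results on (gene, dataset), with screen ranks attached
#' per gene. Row order is deterministic: genes in the p-value table's row
#' order (callers typically order them by genomic position), then dataset
#' id. The `coloc_flag` marks suggestive colocalization
#' (`pp4 > pp4_threshold`).
#'
#' @param screen_ranks Data frame with `gene_id`, `rank_low_moi`,
#'   `rank_high_moi` (sbscore ranks from the two screen arms); missing
#'   genes get `NA` ranks.
#' @param pvalue_table Gene x dataset matrix from
#'   [lead_variant_pvalues()] (its `pvalues` element).
#' @param coloc_results Data frame with `gene_id`, `dataset_id`, `pp4`, or
#'   `NULL`; duplicate (gene, dataset) pairs are an error.
#' @param pp4_threshold Colocalization flag threshold; default 0.5.
#' @return Data frame with one row per (gene, dataset): `gene_id`,
#'   `dataset_id`, `lead_variant_p`, `pp4`, `coloc_flag`, `rank_low_moi`,
#'   `rank_high_moi`.
#' @export
build_priority_table <- function(screen_ranks, pvalue_table,
                                 coloc_results = NULL, pp4_threshold = 0.5) {
  genes <- rownames(pvalue_table)
  datasets <- sort(colnames(pvalue_table))
  out <- data.frame(
    gene_id = rep(genes, each = length(datasets)),
    dataset_id = rep(datasets, times = length(genes)),
    stringsAsFactors = FALSE
  )
  out$lead_variant_p <- pvalue_table[cbind(out$gene_id, out$dataset_id)]
  out$pp4 <- NA_real_
  if (!is.null(coloc_results) && nrow(coloc_results)) {
    key <- paste(coloc_results$gene_id, coloc_results$dataset_id, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (gene, dataset) colocalization results")
    }
    idx <- match(paste(out$gene_id, out$dataset_id, sep = "\r"), key)
    out$pp4 <- coloc_results$pp4[idx]
  }
  out$coloc_flag <- !is.na(out$pp4) & out$pp4 > pp4_threshold
  ridx <- match(out$gene_id, screen_ranks$gene_id)
  out$rank_low_moi <- screen_ranks$rank_low_moi[ridx]
  out$rank_high_moi <- screen_ranks$rank_high_moi[ridx]
  rownames(out) <- NULL
  out
}

#' Read gene coordinates from a BED file
#'
#' BED is 0-based, half-open; coordinates are converted to the package's
#' 1-based, closed convention (`start = bed_start + 1`, `end = bed_end`).
#'
#' @param path Path to a BED file with at least 4 columns (chrom, start,
#'   end, name).
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`, ordered as
#'   in the file.
#' @export
bed_to_genes <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("BED file must have at least 4 columns")
  data.frame(gene_id = as.character(raw[[4L]]),
             chrom = normalize_chrom(raw[[1L]]),
             start = as.integer(raw[[2L]]) + 1L,
             end = as.integer(raw[[3L]]),
             stringsAsFactors = FALSE)
}

#' Write a prioritization (or any records) table as TSV
#'
#' Missing values are rendered explicitly as `"NA"`.
#'
#' @param table Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_priority_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
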