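# Readers and writers for the tabular formats every pipeline stage
# consumes, with strict variant-identity and column-contract validation.
# Positions are 1-based and region filters are closed intervals
# [start, end]; the +/-100 kb and +/-500 kb analysis windows downstream
# depend on both conventions.

# -- column maps ------------------------------------------------------------

#' Default column maps for summary-statistic tables
#'
#' `gwas_column_map()` matches the COVID-19 Host Genetics Initiative
#' round-5 release headers; `eqtl_column_map()` matches GTEx v8
#' association files (with the combined `variant_id` column). Either map
#' can be replaced wholesale or per-field; `read_column_map()` loads one
#' from a YAML or JSON file. Required fields for GWAS tables are `chrom`,
#' `pos`, `ref`, `alt`, `beta`, `se`, `pvalue` (or a combined `variant`
#' column in place of the four identity fields); optional fields (`eaf`,
#' `n_cases`, `n_controls`, `rsid`, `maf`, `n`) are used only when the
#' mapped column exists in the file.
#'
#' @param ... Named overrides, e.g. `gwas_column_map(pvalue = "p")`.
#' @return Named list mapping canonical field names to file column names.
#' @export
gwas_column_map <- function(...) {
  map <- list(chrom = "#CHR", pos = "POS", ref = "REF", alt = "ALT",
              beta = "all_inv_var_meta_beta",
              se = "all_inv_var_meta_sebeta",
              pvalue = "all_inv_var_meta_p",
              eaf = "all_meta_AF",
              n_cases = "all_inv_var_meta_cases",
              n_controls = "all_inv_var_meta_controls",
              rsid = "rsid")
  utils::modifyList(map, list(...))
}

#' @rdname gwas_column_map
#' @export
eqtl_column_map <- function(...) {
  map <- list(gene_id = "gene_id", variant = "variant_id",
              beta = "slope", se = "slope_se", pvalue = "pval_nominal",
              maf = "maf", n = "n")
  utils::modifyList(map, list(...))
}

#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON (`.json`) file whose
#'   top level is a flat mapping of field names to column names.
#' @rdname gwas_column_map
#' @export
read_column_map <- function(path) {
  map <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as.list(map)
}

# -- internal validation helpers -------------------------------------------

stop_rows <- function(bad, what) {
  if (length(bad)) {
    stop(sprintf("%s on row(s): %s", what,
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

numeric_column <- function(raw, map, field) {
  v <- raw[[map[[field]]]]
  out <- suppressWarnings(as.numeric(v))
  stop_rows(which(is.na(out) & !is.na(v)),
            sprintf("parse error: non-numeric '%s'", field))
  out
}

require_mapped <- function(raw, map, fields) {
  have <- vapply(fields, function(f) {
    is.character(map[[f]]) && length(map[[f]]) == 1L && map[[f]] %in% names(raw)
  }, logical(1))
  if (!all(have)) {
    stop("format error: mapped column(s) not found for field(s): ",
         paste(fields[!have], collapse = ", "), call. = FALSE)
  }
}

has_mapped <- function(raw, map, field) {
  is.character(map[[field]]) && length(map[[field]]) == 1L &&
    map[[field]] %in% names(raw)
}

variant_identity <- function(raw, map) {
  if (has_mapped(raw, map, "variant") &&
      !all(vapply(c("chrom", "pos", "ref", "alt"), has_mapped,
                  logical(1), raw = raw, map = map))) {
    parse_variant_id(raw[[map[["variant"]]]])
  } else {
    require_mapped(raw, map, c("chrom", "pos", "ref", "alt"))
    pos <- numeric_column(raw, map, "pos")
    data.frame(chrom = normalize_chrom(raw[[map[["chrom"]]]]),
               pos = pos,
               ref = as.character(raw[[map[["ref"]]]]),
               alt = as.character(raw[[map[["alt"]]]]),
               stringsAsFactors = FALSE)
  }
}

check_variant_invariants <- function(rec) {
  stop_rows(which(!is.finite(rec$pos) | rec$pos < 1 | rec$pos != floor(rec$pos)),
            "invariant violation: position must be an integer >= 1")
  stop_rows(which(rec$ref == rec$alt),
            "invariant violation: ref equals alt")
  invisible(NULL)
}

check_assoc_invariants <- function(rec) {
  stop_rows(which(!is.finite(rec$se) | rec$se <= 0),
            "invariant violation: se must be > 0")
  stop_rows(which(!is.finite(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1),
            "invariant violation: pvalue outside (0, 1]")
  invisible(NULL)
}

read_tsv_raw <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "")
}

fmt_num <- function(x) {
  # full-precision text rendering so write/read round-trips are exact
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

# -- GWAS records -----------------------------------------------------------

#' Read and write GWAS summary statistics
#'
#' Reads a tab-delimited file with a header into one record per variant:
#' columns `chrom`, `pos`, `ref`, `alt`, `variant_id`, `beta`, `se`,
#' `pvalue`, plus `eaf`, `n_cases`, `n_controls` and `rsid` when mapped and
#' present. Row order is preserved. Rows violating the record invariants
#' (`se > 0`, `pvalue` in (0, 1], valid variant identity) are rejected with
#' their row numbers; duplicate variant identifiers are rejected.
#'
#' @param path File path.
#' @param column_map Named list mapping canonical fields to file columns;
#'   see [gwas_column_map()].
#' @return Data frame of GWAS records.
#' @seealso [read_eqtl()], [harmonize_sumstats()]
#' @export
read_gwas <- function(path, column_map = gwas_column_map()) {
  raw <- read_tsv_raw(path)
  rec <- variant_identity(raw, column_map)
  require_mapped(raw, column_map, c("beta", "se", "pvalue"))
  rec$beta <- numeric_column(raw, column_map, "beta")
  rec$se <- numeric_column(raw, column_map, "se")
  rec$pvalue <- numeric_column(raw, column_map, "pvalue")
  check_variant_invariants(rec)
  check_assoc_invariants(rec)
  for (f in c("eaf", "n_cases", "n_controls")) {
    if (has_mapped(raw, column_map, f)) rec[[f]] <- numeric_column(raw, column_map, f)
  }
  if (!is.null(rec$eaf)) {
    stop_rows(which(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1)),
              "invariant violation: eaf outside [0, 1]")
  }
  if (has_mapped(raw, column_map, "rsid")) {
    rec$rsid <- as.character(raw[[column_map[["rsid"]]]])
  }
  rec$variant_id <- make_variant_id(rec$chrom, rec$pos, rec$ref, rec$alt)
  dup <- duplicated(rec$variant_id)
  if (any(dup)) {
    stop("duplicate variant id(s): ",
         paste(head(unique(rec$variant_id[dup]), 5L), collapse = ", "))
  }
  rownames(rec) <- NULL
  rec
}

#' @param records Data frame as returned by the matching reader.
#' @rdname read_gwas
#' @export
write_gwas <- function(records, path, column_map = gwas_column_map()) {
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL,
                    a = records$chrom, b = records$pos, c = records$ref,
                    d = records$alt)
  names(out) <- unlist(column_map[c("chrom", "pos", "ref", "alt")])
  for (f in c("beta", "se", "pvalue", "eaf", "n_cases", "n_controls")) {
    if (!is.null(records[[f]])) out[[column_map[[f]]]] <- fmt_num(records[[f]])
  }
  if (!is.null(records$rsid)) out[[column_map[["rsid"]]]] <- records$rsid
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

# -- eQTL records -----------------------------------------------------------

#' Read and write cis-eQTL summary statistics
#'
#' As [read_gwas()], but each record carries a `gene_id`, and `maf` (minor
#' allele frequency, in (0, 0.5]) and `n` (sample size) when present.
#' Optional filters restrict the result: `gene_filter` keeps listed gene
#' identifiers, `region_filter` keeps variants on one chromosome inside a
#' closed interval. The filters compose conjunctively and are
#' order-independent.
#'
#' @inheritParams read_gwas
#' @param gene_filter Character vector of gene ids to keep, or `NULL`.
#' @param region_filter `list(chrom =, start =, end =)` closed interval,
#'   or `NULL`.
#' @return Data frame of eQTL records.
#' @export
read_eqtl <- function(path, column_map = eqtl_column_map(),
                      gene_filter = NULL, region_filter = NULL) {
  raw <- read_tsv_raw(path)
  require_mapped(raw, column_map, "gene_id")
  rec <- variant_identity(raw, column_map)
  require_mapped(raw, column_map, c("beta", "se", "pvalue"))
  rec$gene_id <- as.character(raw[[column_map[["gene_id"]]]])
  rec$beta <- numeric_column(raw, column_map, "beta")
  rec$se <- numeric_column(raw, column_map, "se")
  rec$pvalue <- numeric_column(raw, column_map, "pvalue")
  check_variant_invariants(rec)
  check_assoc_invariants(rec)
  for (f in c("maf", "n")) {
    if (has_mapped(raw, column_map, f)) rec[[f]] <- numeric_column(raw, column_map, f)
  }
  if (!is.null(rec$maf)) {
    stop_rows(which(!is.na(rec$maf) & (rec$maf <= 0 | rec$maf > 0.5)),
              "invariant violation: maf outside (0, 0.5]")
  }
  rec$variant_id <- make_variant_id(rec$chrom, rec$pos, rec$ref, rec$alt)
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(gene_filter)) keep <- keep & rec$gene_id %in% gene_filter
  if (!is.null(region_filter)) {
    keep <- keep &
      rec$chrom == normalize_chrom(region_filter$chrom) &
      rec$pos >= region_filter$start & rec$pos <= region_filter$end
  }
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' @rdname read_eqtl
#' @export
write_eqtl <- function(records, path, column_map = eqtl_column_map()) {
  cols <- list()
  cols[[column_map[["gene_id"]]]] <- records$gene_id
  if (!is.null(column_map[["variant"]])) {
    cols[[column_map[["variant"]]]] <-
      paste("chr", records$chrom, "_", records$pos, "_", records$ref, "_",
            records$alt, sep = "")
  } else {
    cols[[column_map[["chrom"]]]] <- records$chrom
    cols[[column_map[["pos"]]]] <- records$pos
    cols[[column_map[["ref"]]]] <- records$ref
    cols[[column_map[["alt"]]]] <- records$alt
  }
  for (f in c("beta", "se", "pvalue", "maf", "n")) {
    if (!is.null(records[[f]])) cols[[column_map[[f]]]] <- fmt_num(records[[f]])
  }
  write.table(as.data.frame(cols, check.names = FALSE,
                            stringsAsFactors = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# -- guide read counts ------------------------------------------------------

#' Read and write guide-level screen count tables
#'
#' The file is tab-delimited with columns `guide_id`, `gene_id`, then one
#' column of non-negative integer read counts per sample. Sample column
#' names are free-form but conventionally carry a condition tag
#' (control/infected) and an MOI tag (low/high), e.g.
#' `"infected_lowMOI_rep1"`. `guide_id` must be unique.
#'
#' @inheritParams read_gwas
#' @return Data frame with `guide_id`, `gene_id` and one numeric column per
#'   sample.
#' @export
read_guide_counts <- function(path) {
  raw <- read_tsv_raw(path)
  if (!all(c("guide_id", "gene_id") %in% names(raw))) {
    stop("format error: guide count table must have 'guide_id' and 'gene_id' columns")
  }
  sample_cols <- setdiff(names(raw), c("guide_id", "gene_id"))
  if (!length(sample_cols)) stop("format error: no sample columns")
  for (s in sample_cols) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    stop_rows(which((is.na(v) & !is.na(raw[[s]])) | !is.finite(v) |
                      v < 0 | v != floor(v)),
              sprintf("parse error: negative or non-integer count in sample '%s'", s))
    raw[[s]] <- v
  }
  dup <- duplicated(raw$guide_id)
  if (any(dup)) {
    stop("duplicate guide_id(s): ",
         paste(head(unique(raw$guide_id[dup]), 5L), collapse = ", "))
  }
  raw$guide_id <- as.character(raw$guide_id)
  raw$gene_id <- as.character(raw$gene_id)
  rownames(raw) <- NULL
  raw
}

#' @rdname read_guide_counts
#' @export
write_guide_counts <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- genotype dosages -------------------------------------------------------

#' Read and write genotype dosage matrices
#'
#' The tab-delimited format has one row per variant: columns `chrom`,
#' `pos`, `ref`, `alt`, then one dosage column per individual. Dosages
#' must lie in \[0, 2\].
#'
#' @inheritParams read_gwas
#' @return List with `dosages` (numeric matrix, variants x individuals,
#'   rownames = variant ids) and `variants` (data frame of variant
#'   identity).
#' @export
read_dosages <- function(path) {
  raw <- read_tsv_raw(path)
  idc <- c("chrom", "pos", "ref", "alt")
  if (!all(idc %in% names(raw))) {
    stop("format error: dosage table must have chrom/pos/ref/alt columns")
  }
  variants <- data.frame(chrom = normalize_chrom(raw$chrom),
                         pos = as.integer(raw$pos),
                         ref = as.character(raw$ref),
                         alt = as.character(raw$alt),
                         stringsAsFactors = FALSE)
  check_variant_invariants(variants)
  variants$variant_id <- make_variant_id(variants$chrom, variants$pos,
                                         variants$ref, variants$alt)
  ind <- setdiff(names(raw), idc)
  if (!length(ind)) stop("format error: no individual columns")
  m <- as.matrix(raw[, ind, drop = FALSE])
  mode(m) <- "numeric"
  if (any(!is.finite(m)) || any(m < 0) || any(m > 2)) {
    stop("invariant violation: dosage outside [0, 2]")
  }
  rownames(m) <- variants$variant_id
  list(dosages = m, variants = variants)
}

#' @param x List as returned by [read_dosages()], or with compatible
#'   `dosages`/`variants` elements.
#' @rdname read_dosages
#' @export
write_dosages <- function(x, path) {
  d <- matrix(fmt_num(x$dosages), nrow = nrow(x$dosages),
              dimnames = dimnames(x$dosages))
  out <- cbind(x$variants[, c("chrom", "pos", "ref", "alt")],
               as.data.frame(d, stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
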