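# Variant identity and allele harmonization.
#
# Every join across summary-statistic datasets uses the canonical
# "chrom:pos:ref:alt" identifier (GRCh38, 1-based). rsIDs are carried as
# annotation only and never used for matching: when combining meta-analysis
# releases with several eQTL resources they are not reliable join keys.

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix so that `"chr3"` and `"3"` compare equal
#' across datasets.
#'
#' @param chrom Character (or coercible) vector of chromosome labels.
#' @return Character vector without the `"chr"` prefix.
#' @export
#' @examples
#' normalize_chrom(c("chr3", "3", "chrX"))
normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Canonical variant identifiers
#'
#' `make_variant_id()` renders variants as `"chrom:pos:ref:alt"`, e.g.
#' `"3:45823240:T:C"`; `parse_variant_id()` inverts it, also accepting
#' underscore-separated identifiers with an optional trailing genome-build
#' tag (`"chr3_45823240_T_C_b38"`).
#'
#' @param chrom,pos,ref,alt Vectors of chromosome label, 1-based position,
#'   reference allele and alternate allele.
#' @return `make_variant_id()`: character vector of identifiers.
#'   `parse_variant_id()`: data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`.
#' @export
#' @examples
#' make_variant_id("chr3", 45823240, "T", "C")
#' parse_variant_id("chr3_45823240_T_C_b38")
make_variant_id <- function(chrom, pos, ref, alt) {
  pos <- as.numeric(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  bad <- which(!is.finite(pos) | pos < 1 | pos != floor(pos))
  if (length(bad)) {
    stop("invalid position (must be integer >= 1) on entries: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  bad <- which(ref == alt)
  if (length(bad)) {
    stop("ref allele equals alt allele on entries: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  paste(normalize_chrom(chrom), sprintf("%.0f", pos), ref, alt, sep = ":")
}

#' @param id Character vector of variant identifiers.
#' @rdname make_variant_id
#' @export
parse_variant_id <- function(id) {
  parts <- strsplit(as.character(id), "[:_]")
  parsed <- lapply(parts, function(p) {
    if (length(p) >= 5L && grepl("^b[0-9]+$", p[length(p)])) {
      p <- p[-length(p)]
    }
    if (length(p) != 4L) {
      stop("cannot parse variant id: ", paste(p, collapse = ":"))
    }
    p
  })
  out <- data.frame(
    chrom = normalize_chrom(vapply(parsed, `[`, "", 1L)),
    pos   = as.integer(vapply(parsed, `[`, "", 2L)),
    ref   = vapply(parsed, `[`, "", 3L),
    alt   = vapply(parsed, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$pos)) stop("non-numeric position in variant id")
  out
}

#' Strand-ambiguous allele pairs
#'
#' A/T and C/G variants cannot be oriented across datasets without strand
#' information: the allele pair is its own reverse complement.
#'
#' @param ref,alt Allele character vectors.
#' @return Logical vector.
#' @export
is_strand_ambiguous <- function(ref, alt) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  cc <- unname(comp[toupper(as.character(ref))])
  !is.na(cc) & cc == toupper(as.character(alt))
}

#' Harmonize two summary-statistic tables on shared positions
#'
#' Matches records of `x` and `y` by chromosome and position, then aligns
#' allele orientation to `x`:
#' records with identical ref/alt are kept as-is; records with swapped
#' ref/alt are aligned by flipping the sign of `y$beta` (and `eaf` to
#' `1 - eaf` when present); strand-ambiguous pairs (A/T, C/G) that do not
#' match exactly are dropped, as are pairs whose alleles cannot be
#' reconciled at all. Dropped counts are reported via a message.
#'
#' @param x,y Data frames with at least `chrom`, `pos`, `ref`, `alt`,
#'   `beta`; `eaf` and `variant_id` are updated when present.
#' @return List with elements `x`, `y` (aligned, same row order),
#'   `n_flipped` and `n_dropped`.
#' @export
harmonize_sumstats <- function(x, y) {
  kx <- paste(normalize_chrom(x$chrom), x$pos, sep = ":")
  ky <- paste(normalize_chrom(y$chrom), y$pos, sep = ":")
  shared <- intersect(kx, ky)
  xs <- x[match(shared, kx), , drop = FALSE]
  ys <- y[match(shared, ky), , drop = FALSE]
  same <- xs$ref == ys$ref & xs$alt == ys$alt
  swapped <- xs$ref == ys$alt & xs$alt == ys$ref & !same
  flip <- swapped & !is_strand_ambiguous(xs$ref, xs$alt)
  keep <- same | flip
  ys$beta[flip] <- -ys$beta[flip]
  if (!is.null(ys$eaf)) ys$eaf[flip] <- 1 - ys$eaf[flip]
  ys$ref[flip] <- xs$ref[flip]
  ys$alt[flip] <- xs$alt[flip]
  if (!is.null(ys$variant_id) && any(flip)) {
    ys$variant_id[flip] <- make_variant_id(ys$chrom[flip], ys$pos[flip],
                                           ys$ref[flip], ys$alt[flip])
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped,
            " record(s) dropped during allele harmonization (ambiguous or ",
            "irreconcilable alleles)")
  }
  list(x = xs[keep, , drop = FALSE],
       y = ys[keep, , drop = FALSE],
       n_flipped = sum(flip),
       n_dropped = n_dropped)
}
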