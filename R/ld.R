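# LD r^2 from genotype dosages, and weighted averaging across reference
# populations for regional-plot coloring.

#' Pairwise LD r-squared from genotype dosages
#'
#' `r^2(i, j)` is the squared Pearson correlation of the two variants'
#' dosage vectors across individuals. Monomorphic variants (zero dosage
#' variance) have undefined `r^2`: their rows/columns are `NA` and they
#' are listed in the result's `monomorphic` element.
#'
#' @param dosages Variant x individual numeric matrix with variant-id
#'   rownames, or the list returned by [read_dosages()].
#' @param population_label Optional label carried on the result.
#' @return Object of class `"ld_matrix"`: list with `variants`, `r2`
#'   (symmetric matrix, unit diagonal for polymorphic variants),
#'   `population_label`, `n_individuals`, `monomorphic`.
#' @export
ld_r2 <- function(dosages, population_label = NULL) {
  m <- if (is.list(dosages) && !is.null(dosages$dosages)) dosages$dosages
       else as.matrix(dosages)
  if (ncol(m) < 2L) stop("need >= 2 individuals to compute r^2")
  if (is.null(rownames(m))) rownames(m) <- paste0("v", seq_len(nrow(m)))
  v <- apply(m, 1L, var)
  r2 <- suppressWarnings(cor(t(m)))^2
  mono <- v == 0
  r2[mono, ] <- NA_real_
  r2[, mono] <- NA_real_
  diag(r2)[!mono] <- 1
  dimnames(r2) <- list(rownames(m), rownames(m))
  structure(list(variants = rownames(m), r2 = r2,
                 population_label = population_label,
                 n_individuals = ncol(m),
                 monomorphic = rownames(m)[mono]),
            class = "ld_matrix")
}

#' Weighted average of LD matrices across populations
#'
#' Elementwise weighted mean of per-population `r^2` matrices on a common
#' variant panel, with weights (e.g. population sample counts) normalized
#' to sum to one. Entries missing in some populations (monomorphic there)
#' are excluded pairwise, with the remaining weights renormalized; entries
#' missing everywhere stay `NA`.
#'
#' @param ld_matrices List of [ld_r2()] results (or named `r^2` matrices)
#'   on the same variant panel.
#' @param weights Positive numeric vector, one weight per matrix.
#' @return An `"ld_matrix"` with `population_label = "weighted"`.
#' @export
weighted_r2 <- function(ld_matrices, weights) {
  stopifnot(length(ld_matrices) == length(weights), all(weights > 0),
            length(ld_matrices) >= 1L)
  mats <- lapply(ld_matrices, function(ld) {
    if (inherits(ld, "ld_matrix")) ld$r2 else as.matrix(ld)
  })
  panel <- rownames(mats[[1L]])
  if (is.null(panel)) stop("LD matrices must carry variant ids as dimnames")
  for (m in mats[-1L]) {
    if (is.null(rownames(m)) || !setequal(rownames(m), panel)) {
      stop("all LD matrices must share the same variant panel")
    }
  }
  mats <- lapply(mats, function(m) m[panel, panel, drop = FALSE])
  w <- weights / sum(weights)
  num <- matrix(0, length(panel), length(panel))
  den <- matrix(0, length(panel), length(panel))
  for (i in seq_along(mats)) {
    ok <- !is.na(mats[[i]])
    num <- num + w[i] * ifelse(ok, mats[[i]], 0)
    den <- den + w[i] * ok
  }
  r2 <- num / den
  r2[den == 0] <- NA_real_
  dimnames(r2) <- list(panel, panel)
  structure(list(variants = panel, r2 = r2, population_label = "weighted",
                 n_individuals = NA_integer_,
                 monomorphic = panel[apply(is.na(r2), 1L, all)]),
            class = "ld_matrix")
}
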