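# Readers/writers: column contracts, invariant enforcement, round-trips,
# filter semantics, allele harmonization.

hgi_header <- "#CHR\tPOS\tREF\tALT\tall_inv_var_meta_beta\tall_inv_var_meta_sebeta\tall_inv_var_meta_p"

test_that("GWAS reader returns well-formed rows in input order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hgi_header,
               "3\t45823240\tT\tC\t0.35\t0.05\t1e-12",
               "chr3\t45823300\tA\tG\t-0.1\t0.2\t0.5",
               "3\t45823500\tG\tA\t0.0\t0.1\t1.0"), f)
  rec <- read_gwas(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$variant_id,
               c("3:45823240:T:C", "3:45823300:A:G", "3:45823500:G:A"))
  expect_equal(rec$chrom, rep("3", 3)) # "chr" prefix stripped
  expect_equal(rec$pvalue, c(1e-12, 0.5, 1))
})

test_that("invariant violations are rejected with the offending row numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hgi_header,
               "3\t100\tT\tC\t0.1\t0.1\t0.5",
               "3\t200\tA\tG\t0.1\t0.1\t0",
               "3\t300\tG\tA\t0.1\t0.1\t0.2"), f)
  expect_error(read_gwas(f), "pvalue outside \\(0, 1\\] on row\\(s\\): 2")

  writeLines(c(hgi_header,
               "3\t100\tT\tC\t0.1\t-0.1\t0.5"), f)
  expect_error(read_gwas(f), "se must be > 0")

  writeLines(c(hgi_header,
               "3\t100\tT\tC\t0.1\t0.1\t0.5",
               "3\t100\tT\tC\t0.2\t0.1\t0.1"), f)
  expect_error(read_gwas(f), "duplicate variant id")

  writeLines(c(hgi_header,
               "3\t100\tT\tC\tnot_a_number\t0.1\t0.5"), f)
  expect_error(read_gwas(f), "non-numeric 'beta'.*1")
})

test_that("missing mapped columns are a format error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("CHROM\tPOS", "3\t100"), f)
  expect_error(read_gwas(f), "format error.*chrom")
})

test_that("write then read reproduces GWAS tables field-for-field", {
  for (seed in c(11, 12, 13)) {
    rec <- random_gwas_records(50, seed)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_gwas(rec, f)
    back <- read_gwas(f)
    expect_same_records(back, rec,
                        c("chrom", "pos", "ref", "alt", "beta", "se",
                          "pvalue", "eaf"))
    # and the round-trip is a fixed point
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_gwas(back, f2)
    expect_equal(read_gwas(f2), back)
  }
})

test_that("column maps load from YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("chrom: CHR", "pos: BP", "pvalue: P"), fy)
  expect_equal(read_column_map(fy)$pos, "BP")
  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"chrom": "CHR", "pos": "BP"}', fj)
  expect_equal(read_column_map(fj)$chrom, "CHR")
})

test_that("eQTL reader parses combined GTEx-style variant ids and validates maf", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tvariant_id\tmaf\tpval_nominal\tslope\tslope_se",
               "ENSG1\tchr3_45823240_T_C_b38\t0.3\t1e-8\t0.4\t0.05",
               "ENSG1\tchr3_45824000_A_G_b38\t0.1\t0.2\t0.05\t0.05"), f)
  rec <- read_eqtl(f)
  expect_equal(rec$variant_id[1], "3:45823240:T:C")
  expect_equal(rec$maf, c(0.3, 0.1))

  writeLines(c("gene_id\tvariant_id\tmaf\tpval_nominal\tslope\tslope_se",
               "ENSG1\tchr3_45823240_T_C_b38\t0.7\t1e-8\t0.4\t0.05"), f)
  expect_error(read_eqtl(f), "maf outside \\(0, 0.5\\] on row\\(s\\): 1")
})

test_that("eQTL filters are conjunctive, closed-interval, order-independent", {
  rec <- random_eqtl_records(200, 21)
  rec$variant_id <- make_variant_id(rec$chrom, rec$pos, rec$ref, rec$alt)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eqtl(rec, f)

  all_rows <- read_eqtl(f)
  expect_equal(nrow(all_rows), 200L)

  # region exactly covering one variant's position keeps that row only
  p <- rec$pos[77]
  one <- read_eqtl(f, region_filter = list(chrom = "3", start = p, end = p))
  expect_true(all(one$pos == p))
  expect_equal(nrow(one), sum(rec$pos == p))

  for (seed in 1:5) {
    set.seed(seed)
    gf <- sample(unique(rec$gene_id), 2)
    lo <- sample.int(1e6, 1)
    hi <- min(lo + sample.int(3e5, 1), 1e6)
    rf <- list(chrom = "3", start = lo, end = hi)
    got <- read_eqtl(f, gene_filter = gf, region_filter = rf)
    # linear-scan oracle
    keep <- rec$gene_id %in% gf & rec$pos >= lo & rec$pos <= hi
    expect_equal(got$variant_id, rec$variant_id[keep])
    expect_equal(got$gene_id, rec$gene_id[keep])
    # sequential application in either order gives the same selection
    a <- read_eqtl(f, gene_filter = gf)
    a <- a[a$pos >= lo & a$pos <= hi, ]
    expect_equal(got$variant_id, a$variant_id)
  }
})

test_that("guide count reader enforces shape, integrality and unique guide ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  toy <- data.frame(guide_id = sprintf("g%02d", 1:12),
                    gene_id = rep(c("A", "B", "C"), each = 4),
                    s1 = 1:12, s2 = 0:11, s3 = rep(5L, 12))
  write_guide_counts(toy, f)
  back <- read_guide_counts(f)
  expect_equal(dim(back), c(12L, 5L))
  expect_same_records(back, toy, names(toy))

  bad <- toy
  bad$guide_id[2] <- "g01"
  write_guide_counts(bad, f)
  expect_error(read_guide_counts(f), "duplicate guide_id")

  bad <- toy
  bad$s2[3] <- -1L
  write_guide_counts(bad, f)
  expect_error(read_guide_counts(f), "negative or non-integer count.*s2")

  bad <- toy
  bad$s1 <- bad$s1 + 0.5
  write_guide_counts(bad, f)
  expect_error(read_guide_counts(f), "non-integer count")
})

test_that("dosage reader validates the [0,2] range and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hom <- list(dosages = matrix(0, 3, 4,
                               dimnames = list(NULL, paste0("i", 1:4))),
              variants = data.frame(chrom = "3", pos = 1:3 * 100,
                                    ref = "A", alt = "G",
                                    stringsAsFactors = FALSE))
  write_dosages(hom, f)
  back <- read_dosages(f)
  expect_true(all(back$dosages == 0))
  expect_equal(dim(back$dosages), c(3L, 4L))

  set.seed(5)
  x <- list(dosages = matrix(sample(0:2, 20, TRUE) + runif(20, 0, 0.01),
                             5, 4, dimnames = list(NULL, paste0("i", 1:4))),
            variants = data.frame(chrom = "3", pos = 1:5 * 100,
                                  ref = "A", alt = "G",
                                  stringsAsFactors = FALSE))
  x$dosages <- pmin(x$dosages, 2)
  write_dosages(x, f)
  back <- read_dosages(f)
  expect_equal(dim(back$dosages), c(5L, 4L))
  expect_equal(unname(back$dosages), unname(x$dosages), tolerance = 0)

  x$dosages[2, 2] <- 2.5
  write_dosages(x, f)
  expect_error(read_dosages(f), "dosage outside \\[0, 2\\]")
})

test_that("allele harmonization flips swapped alleles and drops ambiguous ones", {
  x <- data.frame(chrom = "3", pos = c(100, 200, 300, 400),
                  ref = c("T", "A", "A", "C"), alt = c("C", "G", "T", "A"),
                  beta = c(0.5, 0.2, 0.1, 0.3), eaf = c(0.4, 0.2, 0.3, 0.6),
                  stringsAsFactors = FALSE)
  y <- x
  # swapped non-ambiguous at pos 100; swapped ambiguous (A/T) at 300;
  # irreconcilable at 400
  y$ref[1] <- "C"; y$alt[1] <- "T"; y$beta[1] <- -0.5; y$eaf[1] <- 0.6
  y$ref[3] <- "T"; y$alt[3] <- "A"
  y$ref[4] <- "G"; y$alt[4] <- "T"
  h <- suppressMessages(harmonize_sumstats(x, y))
  expect_equal(h$n_flipped, 1L)
  expect_equal(h$n_dropped, 2L)
  expect_equal(h$x$pos, c(100, 200))
  expect_equal(h$y$beta[1], 0.5) # sign flipped back to x's orientation
  expect_equal(h$y$eaf[1], 0.4)
  expect_equal(h$y$ref, h$x$ref)
})
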