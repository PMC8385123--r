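test_that("epitope lists load, uppercase, dedupe and validate", {
  ep <- load_epitopes(example_epitope_file())
  expect_true("QILQQQLIPC" %in% ep$sequence)
  expect_true(all(ep$category %in% EPITOPE_CATEGORIES))
  # the cross-reactive entries appear once per category
  expect_equal(sum(ep$sequence == "YCCQQLAQFPGQ"), 2L)

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tcategory\tsource_id",
               "qqpfp\tR5\tx", "QQPFP\tR5\ty"), f)
  ep <- load_epitopes(f)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$sequence, "QQPFP")

  writeLines(c("sequence\tcategory\tsource_id", "QQPFP\tFOO\tx"), f)
  expect_error(load_epitopes(f), "unknown epitope category")
  writeLines(c("sequence\tcategory\tsource_id", "QQ1FP\tR5\tx"), f)
  expect_error(load_epitopes(f), "invalid epitope")
  writeLines(c("sequence\tcategory\tsource_id", "QQP\tR5\tx"), f)
  expect_error(load_epitopes(f), "shorter than 4")
})

test_that("the anaphylaxis epitope is found once at position 12 of its peptide", {
  ep <- data.frame(sequence = "QILQQQLIPC", category = "WDEIA",
                   source_id = "IEDB")
  m <- find_epitopes("QQQQQQQQILQQILQQQLIPCR", ep, mode = "strict")
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 12L)
  expect_equal(m$category, "WDEIA")
})

test_that("containment search reports overlaps and honors equivalence modes", {
  ep3 <- data.frame(sequence = "QQQ", category = "R5", source_id = "t")
  m <- find_epitopes("QQQQ", ep3)
  expect_equal(m$start, c(1L, 2L))

  epIL <- data.frame(sequence = "QILQ", category = "R5", source_id = "t")
  expect_equal(nrow(find_epitopes("AQLLQA", epIL, mode = "strict")), 0L)
  expect_equal(nrow(find_epitopes("AQLLQA", epIL, mode = "il_equivalent")),
               1L)
  epQE <- data.frame(sequence = "PQPE", category = "R5", source_id = "t")
  expect_equal(nrow(find_epitopes("APQPQA", epQE, mode = "strict")), 0L)
  expect_equal(nrow(find_epitopes("APQPQA", epQE, mode = "qe_equivalent")),
               1L)
})

test_that("strict matches are a subset of relaxed-mode matches", {
  set.seed(17)
  peps <- replicate(30, random_aa_seq(sample(8:25, 1),
                                      letters = c("Q", "P", "L", "I", "E",
                                                  "F", "S", "Y")))
  eps <- data.frame(sequence = replicate(8, random_aa_seq(4,
                      letters = c("Q", "P", "L", "I", "E"))),
                    category = "R5", source_id = "t")
  eps <- eps[!duplicated(eps$sequence), ]
  key <- function(m) paste(m$peptide, m$epitope, m$start)
  strict <- find_epitopes(peps, eps, "strict")
  il <- find_epitopes(peps, eps, "il_equivalent")
  both <- find_epitopes(peps, eps, "both")
  expect_true(all(key(strict) %in% key(il)))
  expect_true(all(key(il) %in% key(both)))

  # strict mode equals the brute-force double loop
  expected <- do.call(rbind, lapply(seq_len(nrow(eps)), function(j) {
    do.call(rbind, lapply(peps, function(p) {
      s <- oracle_occurrences(eps$sequence[j], p)
      if (length(s)) data.frame(peptide = p, epitope = eps$sequence[j],
                                start = s)
    }))
  }))
  if (is.null(expected)) {
    expect_equal(nrow(strict), 0L)
  } else {
    expect_setequal(key(strict),
                    paste(expected$peptide, expected$epitope,
                          expected$start))
  }
})

test_that("category abundance counts each peptide once per category", {
  norm <- toy_norm(rbind(rep(1, 8), c(1.5, 1.5, 1.5, 1.5, .5, .5, .5, .5)),
                   peptides = c("PEPA", "PEPB"))
  # PEPA carries two BA epitopes: counted once
  matches <- data.frame(
    peptide = c("PEPA", "PEPA", "PEPB"),
    epitope = c("E1", "E2", "E3"),
    category = c("BA", "BA", "WA"),
    start = 1L, mode = "strict")
  res <- category_abundance(matches, norm)
  ba <- res[res$category == "BA", ]
  expect_equal(ba$n_peptides, 1L)
  expect_equal(ba$ratio_percent, 100)
  # combined allergy total dedups across categories
  tot <- res[res$category == "all_allergy", ]
  expect_equal(tot$n_peptides, 2L)
  expect_equal(tot$ratio_percent, 100 * (1 + 1.5) / (1 + 0.5))

  # a peptide in both BA and WA contributes to each but once to the total
  m2 <- rbind(matches,
              data.frame(peptide = "PEPA", epitope = "E3", category = "WA",
                         start = 2L, mode = "strict"))
  res2 <- category_abundance(m2, norm)
  expect_equal(res2$n_peptides[res2$category == "WA"], 2L)
  expect_equal(res2$n_peptides[res2$category == "all_allergy"], 2L)
})

test_that("category abundance is invariant to duplicate matches and order", {
  norm <- toy_norm(matrix(runif(24, 0.5, 1.5), nrow = 3),
                   peptides = c("A1", "A2", "A3"))
  matches <- data.frame(peptide = c("A1", "A2", "A3"),
                        epitope = "E", category = "CD_HLA_DQ",
                        start = 1L, mode = "strict")
  base <- category_abundance(matches, norm)
  dup <- category_abundance(rbind(matches, matches), norm)
  shuf <- category_abundance(matches[c(3, 1, 2), ], norm)
  expect_equal(dup$ratio_percent, base$ratio_percent)
  expect_equal(shuf$ratio_percent, base$ratio_percent)
})

test_that("unquantified matches are skipped and zero MW flagged", {
  norm <- toy_norm(matrix(rep(1, 8), nrow = 1), peptides = "PEPA")
  matches <- data.frame(peptide = c("PEPA", "GHOST"), epitope = "E",
                        category = "BA", start = 1L, mode = "strict")
  expect_warning(res <- category_abundance(matches, norm),
                 "not quantified")
  expect_equal(res$n_peptides[res$category == "BA"], 1L)

  norm0 <- toy_norm(matrix(c(2, 2, 2, 2, 0, 0, 0, 0), nrow = 1),
                    peptides = "PEPA")
  res0 <- category_abundance(matches[1, ], norm0)
  expect_true(is.na(res0$ratio_percent[1]))
  expect_match(res0$flag[1], "MW total zero")
})
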