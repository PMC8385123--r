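test_that("quant table loading validates schema, labels and duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- toy_quant_df()
  write.csv(df, f, row.names = FALSE)
  tab <- load_quant_table(f)
  expect_s3_class(tab, "quant_table")
  expect_equal(length(unique(tab$peptide)), 2L)

  bad <- df; bad$area[1] <- -5
  write.csv(bad, f, row.names = FALSE)
  expect_error(load_quant_table(f), "negative area")

  bad <- df; bad$sample[1] <- "XX"
  write.csv(bad, f, row.names = FALSE)
  expect_error(load_quant_table(f), "GW, MW")

  write.csv(rbind(df, df[1, ]), f, row.names = FALSE)
  expect_error(load_quant_table(f), "duplicate")

  write.csv(df[, setdiff(names(df), "replicate")], f, row.names = FALSE)
  expect_error(load_quant_table(f), "replicate")
})

test_that("peptide areas sum transitions and mark missing cells", {
  df <- data.frame(
    peptide = "PEPA", protease = "trypsin",
    replicate = "GW_1", sample = "GW",
    transition = c("T1", "T2", "T3"), area = c(100, 200, 300))
  df <- rbind(df, data.frame(peptide = c("PEPA", "PEPB"),
                             protease = "trypsin",
                             replicate = "MW_1", sample = "MW",
                             transition = "T1", area = c(50, 70)))
  mat <- peptide_area(df)
  expect_equal(mat["PEPA", "GW_1"], 600)
  expect_equal(mat["PEPA", "MW_1"], 50)   # single transition passes through
  expect_true(is.na(mat["PEPB", "GW_1"]))
  expect_equal(unname(attr(mat, "samples")[c("GW_1", "MW_1")]),
               c("GW", "MW"))
})

test_that("normalization divides by the cross-replicate mean", {
  mat <- toy_norm(rbind(c(3, 3, 3, 3, 1, 1, 1, 1) * 2,
                        c(5, 5, 5, 5, 5, 5, 5, 5)))
  class(mat) <- NULL
  norm <- normalize_peptides(mat)
  expect_equal(unname(norm[1, ]), c(1.5, 1.5, 1.5, 1.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(unname(norm[2, ]), rep(1, 8))

  # peptide observed only in GW: mean over observed cells only
  m <- toy_norm(rbind(c(2, 2, 2, 2, NA, NA, NA, NA)))
  class(m) <- NULL
  norm <- normalize_peptides(m)
  expect_equal(unname(norm[1, 1:4]), rep(1, 4))
  expect_true(all(is.na(norm[1, 5:8])))
})

test_that("normalization is idempotent, scale invariant, and mean-one", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(10^runif(40, 2, 6), nrow = 5,
                dimnames = list(paste0("P", 1:5),
                                c(paste0("GW_", 1:4), paste0("MW_", 1:4))))
    attr(m, "samples") <- setNames(rep(c("GW", "MW"), each = 4),
                                   colnames(m))
    n1 <- normalize_peptides(m)
    expect_equal(unname(rowMeans(n1)), rep(1, 5), tolerance = 1e-9)
    n2 <- normalize_peptides(n1)
    expect_equal(unclass(n2), unclass(n1), tolerance = 1e-12,
                 ignore_attr = TRUE)
    scaled <- m
    scaled[3, ] <- scaled[3, ] * 1000  # peptide-wise rescaling
    expect_equal(unname(normalize_peptides(scaled)[3, ]),
                 unname(n1[3, ]), tolerance = 1e-12)
  }
})

test_that("all-zero peptides are dropped with a warning", {
  m <- toy_norm(rbind(rep(0, 8), rep(2, 8)))
  class(m) <- NULL
  expect_warning(norm <- normalize_peptides(m), "no positive signal")
  expect_equal(nrow(norm), 1L)
})

test_that("differential abundance reproduces the Welch reference to 1e-9", {
  set.seed(31)
  for (i in 1:20) {
    gw <- 10^rnorm(4, 0, 0.3)
    mw <- 10^rnorm(4, 0.2, 0.2)
    norm <- toy_norm(matrix(c(gw, mw), nrow = 1))
    res <- differential_abundance(norm)
    expect_equal(res$p_value, oracle_welch_p(log2(gw), log2(mw)),
                 tolerance = 1e-9)
    expect_equal(res$log2_fold_change, log2(mean(gw) / mean(mw)),
                 tolerance = 1e-12)
  }
})

test_that("differential abundance handles degenerate and one-sided peptides", {
  same <- toy_norm(matrix(rep(c(1.2, 0.8), each = 4), nrow = 1))
  # identical within-group values: fold change defined, p degenerate
  res <- differential_abundance(same)
  expect_equal(res$log2_fold_change, log2(1.5))
  expect_true(is.nan(res$p_value))
  expect_equal(res$flag, "degenerate-variance")
  expect_false(res$significant)

  flat <- toy_norm(matrix(rep(1, 8), nrow = 1))
  res <- differential_abundance(flat)
  expect_equal(res$log2_fold_change, 0)
  expect_false(res$significant)

  onesided <- toy_norm(matrix(c(NA, NA, NA, NA, 2, 2.1, 1.9, 2), nrow = 1))
  res <- differential_abundance(onesided)
  expect_equal(res$flag, "one-sided presence")
  expect_true(is.na(res$p_value))
})

test_that("significance needs both the fold-change and the p threshold", {
  set.seed(8)
  gw <- c(4.1, 3.9, 4.05, 3.95)
  mw <- c(1.02, 0.98, 1.01, 0.99)
  norm <- toy_norm(matrix(c(gw, mw), nrow = 1))
  res <- differential_abundance(norm)
  expect_true(res$significant)
  # same separation but below 2-fold
  res2 <- differential_abundance(toy_norm(matrix(c(mw * 1.5, mw), nrow = 1)))
  expect_false(res2$significant)
})

test_that("group sums partition the normalized signal and ratios follow", {
  norm <- toy_norm(rbind(c(1.5, 1.5, 1.5, 1.5, 0.5, 0.5, 0.5, 0.5),
                         c(0.5, 0.5, 0.5, 0.5, 1.5, 1.5, 1.5, 1.5)),
                   peptides = c("PEPA", "PEPB"))
  alloc <- data.frame(peptide = c("PEPA", "PEPB"), group = "hmw_gs")
  g <- group_abundance(norm, alloc)
  expect_equal(g$ratio_gw_mw, 1.0)
  expect_equal(g$mean_gw, 2.0)

  # single-peptide group equals the peptide itself
  alloc2 <- data.frame(peptide = c("PEPA", "PEPB"),
                       group = c("hmw_gs", "lmw_gs"))
  g2 <- group_abundance(norm, alloc2)
  expect_equal(g2$ratio_gw_mw[g2$group == "hmw_gs"], 3.0)

  set.seed(13)
  vals <- matrix(runif(80, 0.2, 2), nrow = 10,
                 dimnames = list(paste0("P", 1:10), NULL))
  norm <- toy_norm(vals, peptides = rownames(vals))
  alloc <- data.frame(peptide = rownames(vals),
                      group = sample(c("alpha_gliadin", "ati", "multiple"),
                                     10, replace = TRUE))
  g <- group_abundance(norm, alloc)
  # partition conservation per replicate-mean: group sums add to the total
  expect_equal(sum(g$mean_gw), sum(rowMeans(vals[, 1:4])), tolerance = 1e-9)
  expect_equal(sum(g$mean_mw), sum(rowMeans(vals[, 5:8])), tolerance = 1e-9)
  expect_error(group_abundance(norm, alloc[-1, ]), "do not cover")
})

test_that("net gluten percentage sums the five canonical groups only", {
  res <- data.frame(group = "hmw_gs", mean_gw = 2, mean_mw = 1)
  expect_warning(pct <- net_gluten_ratio(res), "absent")
  expect_equal(pct, 200)

  res <- data.frame(group = c(CANONICAL_GLUTEN_GROUPS, "ati"),
                    mean_gw = c(rep(1, 5), 50), mean_mw = c(rep(1, 5), 1))
  expect_equal(net_gluten_ratio(res), 100)  # ATI excluded

  res0 <- data.frame(group = "hmw_gs", mean_gw = 1, mean_mw = 0)
  expect_warning(expect_error(net_gluten_ratio(res0), "denominator"))
})
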