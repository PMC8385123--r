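test_that("monoisotopic masses and m/z match hand-computed references", {
  # 2 x glycine 57.02146 + water 18.010565
  expect_equal(peptide_mono_mass("GG", fixed_mods = NULL), 132.053485,
               tolerance = 1e-6)
  expect_equal(precursor_mz("GG", 1, fixed_mods = NULL), 133.060761,
               tolerance = 1e-6)
  # fixed-mod additivity on cysteine
  expect_equal(peptide_mono_mass("C"),
               peptide_mono_mass("C", fixed_mods = NULL) + 57.02146)
  # charge-state identity: mz(2) = (mz(1) + proton) / 2
  mz1 <- precursor_mz("PEPTIDE", 1)
  expect_equal(precursor_mz("PEPTIDE", 2), (mz1 + 1.007276) / 2)
  # fragment references: K + water + proton; G + proton
  expect_equal(fragment_mz("GK", "y", 1), 147.112801, tolerance = 1e-6)
  expect_equal(fragment_mz("GK", "b", 1), 58.028736, tolerance = 1e-6)
  # mass conservation: b1 + y(n-1) = neutral mass + 2 protons
  s <- "QLVPSAK"
  expect_equal(fragment_mz(s, "b", 1) + fragment_mz(s, "y", nchar(s) - 1),
               peptide_mono_mass(s) + 2 * 1.007276)
  # concatenation additivity
  expect_equal(peptide_mono_mass("GGPEPTIDE"),
               peptide_mono_mass("GG") + peptide_mono_mass("PEPTIDE") -
                 18.010565)
})

test_that("mass functions reject invalid input", {
  expect_error(peptide_mono_mass(""), "empty")
  expect_error(peptide_mono_mass("GXG"), "unknown residue")
  expect_error(precursor_mz("GG", 0), "charge")
  expect_error(fragment_mz("GK", "y", 2), "out of range")
})

test_that("transition QC keeps the top passing transitions and rejects weak peptides", {
  obs <- data.frame(
    peptide = "PEP1", transition = paste0("y", 3:7),
    observed_rt = 10, intensity = c(2000, 1500, 1200, 900, 50), snr = 10)
  sel <- qc_select_transitions(obs)
  expect_equal(sort(sel$accepted$intensity), c(1200, 1500, 2000))
  expect_equal(nrow(sel$rejected), 0L)

  weak <- transform(obs, intensity = c(2000, 1500, 900, 900, 50))
  sel <- qc_select_transitions(weak)
  expect_equal(sel$rejected$reason, "insufficient transitions")
  expect_equal(nrow(sel$accepted), 0L)

  # an intensity of exactly 1000 cps fails the strictly-greater filter
  edge <- transform(obs, intensity = c(2000, 1500, 1000, 900, 50))
  expect_equal(qc_select_transitions(edge)$rejected$reason,
               "insufficient transitions")

  # a transition eluting away from the precursor median is not counted
  drift <- transform(obs, observed_rt = c(10, 10, 10, 10, 14),
                     intensity = c(2000, 1500, 900, 900, 3000))
  expect_equal(qc_select_transitions(drift)$rejected$reason,
               "insufficient transitions")
})

test_that("QC selection never exceeds keep_top nor accepts below min_transitions", {
  set.seed(3)
  for (i in 1:10) {
    obs <- data.frame(
      peptide = rep(paste0("P", 1:5), each = 5),
      transition = rep(paste0("y", 1:5), 5),
      observed_rt = rep(runif(5, 5, 40), each = 5) + rnorm(25, 0, 0.05),
      intensity = 10^runif(25, 2, 4.5),
      snr = runif(25, 0, 30))
    sel <- qc_select_transitions(obs)
    if (nrow(sel$accepted) > 0) {
      counts <- table(sel$accepted$peptide)
      expect_true(all(counts <= 3))
      expect_true(all(counts >= 3))  # keep_top == min_transitions == 3
    }
    expect_setequal(c(sel$accepted$peptide, sel$rejected$peptide),
                    unique(obs$peptide))
  }
})

test_that("assay scheduling respects the concurrency cap with minimal greedy lists", {
  same <- data.frame(peptide = paste0("P", 1:4), expected_rt = 20)
  s <- schedule_assays(same, window_s = 60, max_concurrent = 2)
  expect_equal(sort(as.integer(table(s$list_index))), c(2L, 2L))

  disjoint <- data.frame(peptide = paste0("P", 1:5),
                         expected_rt = c(5, 15, 25, 35, 45))
  s <- schedule_assays(disjoint, window_s = 60, max_concurrent = 1)
  expect_equal(unique(s$list_index), 1L)

  # 10 co-eluting transitions at cap 3 need ceiling(10/3) = 4 lists
  ten <- data.frame(peptide = paste0("P", 1:10), expected_rt = 12)
  s <- schedule_assays(ten, window_s = 60, max_concurrent = 3)
  expect_equal(max(s$list_index), 4L)
  expect_true(validate_schedule(s, window_s = 60, max_concurrent = 3))

  expect_error(schedule_assays(ten, max_concurrent = 0), "max_concurrent")
})

test_that("random schedules pass the independent overlap validator", {
  set.seed(9)
  for (i in 1:10) {
    assays <- data.frame(peptide = paste0("P", 1:40),
                         expected_rt = runif(40, 0, 30))
    cap <- sample(2:6, 1)
    s <- schedule_assays(assays, window_s = 90, max_concurrent = cap)
    expect_true(validate_schedule(s, window_s = 90, max_concurrent = cap))
    expect_setequal(s$peptide, assays$peptide)
  }
})

test_that("cycle-time cap derivation is a floor of dwell slots", {
  expect_equal(max_concurrent_transitions(0.3, 0.005), 60L)
  expect_equal(max_concurrent_transitions(0.3, 0.007), 42L)
})
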