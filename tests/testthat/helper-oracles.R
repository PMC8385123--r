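# Independent brute-force oracles used to freeze expected values; these
# deliberately share no code with the package implementation.

# every fully specific digestion product with <= max_missed retained sites,
# by exhaustive enumeration of all substrings
oracle_digest <- function(sequence, cleave_after, suppress_before = "P",
                          max_missed = 0) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  # cleavage boundaries after position p (0 = N-terminus, n = C-terminus)
  site <- vapply(seq_len(n - 1), function(p) {
    res[p] %in% cleave_after && !(res[p + 1] %in% suppress_before)
  }, TRUE)
  boundary <- c(TRUE, site, TRUE)  # indexed by p + 1 for p in 0..n
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!boundary[i] || !boundary[j + 1]) next
      internal <- if (j > i) sum(site[seq(i, j - 1)]) else 0
      if (internal <= max_missed) {
        out[[length(out) + 1]] <- data.frame(
          peptide = paste(res[i:j], collapse = ""), start = i,
          missed_cleavages = internal, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# all overlapping start positions of sub in s by direct comparison
oracle_occurrences <- function(sub, s) {
  m <- nchar(sub)
  n <- nchar(s)
  if (m > n) return(integer(0))
  which(vapply(seq_len(n - m + 1),
               function(i) substr(s, i, i + m - 1) == sub, TRUE))
}

# two-sided Welch unequal-variance t-test p-value from first principles
oracle_welch_p <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * pt(-abs(t_stat), df)
}

# P(X >= k) for the hypergeometric by exhaustive enumeration of all draws
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the annotated ones
  mean(hits >= k)
}

# Benjamini-Hochberg step-up by its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

random_aa_seq <- function(n, letters = c("A", "C", "D", "E", "F", "G", "K",
                                         "L", "P", "Q", "R", "S", "V",
                                         "Y")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# small normalized matrix builder: values is peptide x replicate, first
# half of columns GW, second half MW
toy_norm <- function(values, peptides = paste0("PEP", seq_len(nrow(values)))) {
  n_rep <- ncol(values) / 2
  reps <- c(paste0("GW_", seq_len(n_rep)), paste0("MW_", seq_len(n_rep)))
  mat <- matrix(values, nrow = nrow(values),
                dimnames = list(peptides, reps))
  attr(mat, "samples") <- setNames(rep(c("GW", "MW"), each = n_rep), reps)
  class(mat) <- c("normalized_matrix", "matrix", "array")
  mat
}

toy_quant_df <- function() {
  expand.grid(peptide = c("AAAAAA", "CCCCCC"),
              replicate = c("GW_1", "GW_2", "MW_1", "MW_2"),
              transition = c("T1", "T2"),
              stringsAsFactors = FALSE) |>
    transform(protease = "trypsin",
              sample = sub("_.*", "", replicate),
              area = 100)
}
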