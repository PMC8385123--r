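#' Pipeline configuration
#'
#' Houses the thresholds used across the pipeline: candidate peptide length
#' bounds, the fold-change and p-value cut-offs of the volcano analysis, the
#' replicate design, and the scale on which group tests are run.
#'
#' @param min_len,max_len Candidate peptide length bounds (default 6, 30).
#' @param fc_threshold Fold-change significance threshold (default 2).
#' @param p_threshold P-value significance threshold (default 0.01).
#' @param n_replicates Technical replicates per sample (default 4).
#' @param log_transform Run Welch tests on log2 normalized values
#'   (default `TRUE`); multiplicative technical noise is closer to additive
#'   on the log scale.
#' @param qc A [qc_thresholds()] object.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_len = 6L, max_len = 30L, fc_threshold = 2,
                            p_threshold = 0.01, n_replicates = 4L,
                            log_transform = TRUE, qc = qc_thresholds()) {
  stopifnot(fc_threshold > 0, p_threshold > 0, min_len <= max_len,
            n_replicates >= 1)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 n_replicates = as.integer(n_replicates),
                 log_transform = isTRUE(log_transform), qc = qc),
            class = "pipeline_config")
}

validate_quant_table <- function(tab) {
  need <- c("peptide", "protease", "replicate", "sample", "transition",
            "area")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("quant table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$area <- as.numeric(tab$area)
  if (anyNA(tab$area)) stop("non-numeric area value(s)", call. = FALSE)
  if (any(tab$area < 0)) stop("negative area value(s)", call. = FALSE)
  bad <- setdiff(unique(tab$sample), SAMPLE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown sample label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(SAMPLE_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(tab$peptide, tab$replicate, tab$transition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (peptide, replicate, transition) row(s), e.g. ",
         gsub("\r", " / ", key[duplicated(key)][1]), call. = FALSE)
  }
  for (s in SAMPLE_LEVELS) {
    if (!any(tab$sample == s)) {
      stop("no replicates for sample ", s, call. = FALSE)
    }
  }
  rep_map <- unique(tab[, c("replicate", "sample")])
  if (anyDuplicated(rep_map$replicate)) {
    stop("replicate id(s) mapped to more than one sample: ",
         paste(rep_map$replicate[duplicated(rep_map$replicate)],
               collapse = ", "), call. = FALSE)
  }
  class(tab) <- c("quant_table", "data.frame")
  tab
}

#' Load a transition peak-area table
#'
#' Reads a delimited export (CSV or TSV, detected from the extension) with
#' columns `peptide`, `protease`, `replicate`, `sample` (GW or MW),
#' `transition`, `area`, and validates it.
#'
#' @param path Path to the delimited file.
#' @return A validated `quant_table` (a `data.frame` subclass).
#' @export
load_quant_table <- function(path) {
  if (!file.exists(path)) {
    stop("quantitation: file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_quant_table(tab)
}

#' Peptide-level areas from transition areas
#'
#' Sums the monitored transitions of each peptide within each replicate.
#' Peptide/replicate pairs with no rows are missing (`NA`).
#'
#' @param tab A `quant_table` (see [load_quant_table()]).
#' @return Numeric matrix peptides x replicates with attribute `"samples"`
#'   (named character vector replicate -> sample).
#' @export
peptide_area <- function(tab) {
  tab <- validate_quant_table(as.data.frame(tab))
  reps <- unique(tab[, c("replicate", "sample")])
  reps <- reps[order(match(reps$sample, SAMPLE_LEVELS), reps$replicate), ]
  peptides <- unique(tab$peptide)
  mat <- matrix(NA_real_, nrow = length(peptides), ncol = nrow(reps),
                dimnames = list(peptides, reps$replicate))
  agg <- stats::aggregate(area ~ peptide + replicate, data = tab, FUN = sum)
  mat[cbind(match(agg$peptide, peptides),
            match(agg$replicate, reps$replicate))] <- agg$area
  attr(mat, "samples") <- stats::setNames(reps$sample, reps$replicate)
  mat
}

#' Normalize peptide areas to their cross-replicate average
#'
#' Each peptide's area in each replicate is divided by that peptide's mean
#' area over all observed replicates of both samples, so a fully observed
#' peptide has mean exactly 1 across replicates. All-zero (or all-missing)
#' peptides are dropped with a warning. Idempotent.
#'
#' @param mat Peptide x replicate matrix from [peptide_area()] (attribute
#'   `"samples"` required).
#' @return Normalized matrix of class `normalized_matrix`, same attributes.
#' @export
normalize_peptides <- function(mat) {
  samples <- attr(mat, "samples")
  if (is.null(samples)) stop("matrix lacks 'samples' attribute",
                             call. = FALSE)
  m <- rowMeans(mat, na.rm = TRUE)
  drop <- !is.finite(m) | m == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " peptide(s) with no positive signal: ",
            paste(utils::head(rownames(mat)[drop], 5), collapse = ", "),
            call. = FALSE)
    mat <- mat[!drop, , drop = FALSE]
    m <- m[!drop]
  }
  out <- mat / m
  attr(out, "samples") <- samples
  class(out) <- c("normalized_matrix", class(matrix()))
  out
}

sample_columns <- function(norm, sample) {
  names(which(attr(norm, "samples") == sample))
}

# Welch test p-value with degenerate-variance handling
welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    return(list(p = NA_real_, flag = "insufficient replicates"))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(p = NaN, flag = "degenerate-variance"))
  }
  p <- tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
                error = function(e) NaN)
  if (is.nan(p)) return(list(p = NaN, flag = "degenerate-variance"))
  list(p = p, flag = "")
}

#' Peptide-level differential abundance (volcano statistics)
#'
#' For every peptide observed in both samples: log2 fold change of GW mean
#' over MW mean, a two-sided Welch unequal-variance t-test (on log2
#' normalized values by default), BH-adjusted q-values, and a significance
#' call at the configured fold-change and raw-p thresholds (the volcano
#' uses raw p; q is reported for transparency). Peptides observed in only
#' one sample are flagged `one-sided presence` and excluded from testing.
#'
#' @param norm A `normalized_matrix`.
#' @param config A [pipeline_config()].
#' @return `data.frame`: `peptide`, `mean_gw`, `mean_mw`,
#'   `log2_fold_change`, `p_value`, `q_value`, `significant`, `flag`.
#' @export
differential_abundance <- function(norm, config = pipeline_config()) {
  gw_cols <- sample_columns(norm, "GW")
  mw_cols <- sample_columns(norm, "MW")
  res <- lapply(rownames(norm), function(pep) {
    gw <- norm[pep, gw_cols]
    mw <- norm[pep, mw_cols]
    gw <- gw[!is.na(gw)]
    mw <- mw[!is.na(mw)]
    if (length(gw) == 0 || length(mw) == 0) {
      return(data.frame(peptide = pep, mean_gw = mean(gw), mean_mw = mean(mw),
                        log2_fold_change = NA_real_, p_value = NA_real_,
                        flag = "one-sided presence",
                        stringsAsFactors = FALSE))
    }
    l2fc <- log2(mean(gw) / mean(mw))
    wt <- if (config$log_transform) welch_p(log2(gw), log2(mw))
          else welch_p(gw, mw)
    data.frame(peptide = pep, mean_gw = mean(gw), mean_mw = mean(mw),
               log2_fold_change = l2fc, p_value = wt$p, flag = wt$flag,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  testable <- is.finite(res$p_value)
  res$q_value <- NA_real_
  res$q_value[testable] <- stats::p.adjust(res$p_value[testable],
                                           method = "BH")
  res$significant <- testable &
    abs(res$log2_fold_change) >= log2(config$fc_threshold) &
    res$p_value < config$p_threshold
  res[, c("peptide", "mean_gw", "mean_mw", "log2_fold_change", "p_value",
          "q_value", "significant", "flag")]
}

#' Group-level relative abundance
#'
#' Per replicate, the group value is the sum of normalized values of all
#' peptides (unique and shared alike) allocated to that group; per sample a
#' mean and SEM over its replicates are reported, with the GW/MW ratio of
#' sample means and a Welch p-value on the per-replicate group sums.
#'
#' @param norm A `normalized_matrix`.
#' @param allocations Output of [allocate_peptide_groups()] covering all
#'   quantified peptides.
#' @return `data.frame`: `group`, `n_peptides`, `mean_gw`, `sem_gw`,
#'   `mean_mw`, `sem_mw`, `ratio_gw_mw`, `p_value`.
#' @export
group_abundance <- function(norm, allocations) {
  missing_pep <- setdiff(rownames(norm), allocations$peptide)
  if (length(missing_pep) > 0) {
    stop("allocations do not cover ", length(missing_pep),
         " quantified peptide(s), e.g. ", missing_pep[1], call. = FALSE)
  }
  gw_cols <- sample_columns(norm, "GW")
  mw_cols <- sample_columns(norm, "MW")
  alloc <- allocations[match(rownames(norm), allocations$peptide), ]
  groups <- unique(alloc$group)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  res <- lapply(groups, function(g) {
    sub <- norm[alloc$group == g, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    gw_sum <- colSums(sub[, gw_cols, drop = FALSE], na.rm = TRUE)
    mw_sum <- colSums(sub[, mw_cols, drop = FALSE], na.rm = TRUE)
    wt <- welch_p(gw_sum, mw_sum)
    data.frame(group = g, n_peptides = nrow(sub),
               mean_gw = mean(gw_sum), sem_gw = sem(gw_sum),
               mean_mw = mean(mw_sum), sem_mw = sem(mw_sum),
               ratio_gw_mw = mean(gw_sum) / mean(mw_sum),
               p_value = wt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res[!vapply(res, is.null, TRUE)])
}

#' Net canonical gluten content, GW as a percentage of MW
#'
#' Adds the five gliadin and glutenin groups (alpha-, gamma-, omega-gliadin,
#' LMW-GS, HMW-GS) and reports 100 x sum(GW means) / sum(MW means). ALP,
#' ATI, multiple and non-gluten peptides are excluded. Missing canonical
#' groups contribute zero with a warning.
#'
#' @param group_results Output of [group_abundance()].
#' @return Net gluten percentage (scalar).
#' @export
net_gluten_ratio <- function(group_results) {
  canon <- group_results[group_results$group %in% CANONICAL_GLUTEN_GROUPS, ]
  absent <- setdiff(CANONICAL_GLUTEN_GROUPS, canon$group)
  if (length(absent) > 0) {
    warning("canonical group(s) absent, contributing 0: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  den <- sum(canon$mean_mw)
  if (nrow(canon) == 0 || den == 0) {
    stop("net gluten ratio undefined: MW denominator is 0", call. = FALSE)
  }
  100 * sum(canon$mean_gw) / den
}

#' Write the normalized matrix as TSV
#'
#' @param norm A `normalized_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalized_tsv <- function(norm, path) {
  out <- data.frame(peptide = rownames(norm), as.data.frame(unclass(norm)),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
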