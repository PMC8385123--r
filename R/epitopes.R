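#' Load an immune-epitope list
#'
#' Reads a TSV with columns `sequence`, `category`, `source_id`. Sequences
#' are uppercased and validated (standard amino acids, length >= 4);
#' duplicate (sequence, category) rows collapse to one entry.
#'
#' @param path Epitope TSV path. Lines starting with `#` are comments.
#' @return `data.frame` with `sequence`, `category`, `source_id`.
#' @export
load_epitopes <- function(path) {
  if (!file.exists(path)) {
    stop("epitope_mapping: file not found: ", path, call. = FALSE)
  }
  ep <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sequence", "category", "source_id")
  miss <- setdiff(need, names(ep))
  if (length(miss) > 0) {
    stop("epitope table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ep$sequence <- toupper(trimws(ep$sequence))
  check_aa_string(ep$sequence, what = "epitope", allow_x = FALSE)
  if (any(nchar(ep$sequence) < 4)) {
    stop("epitope sequence(s) shorter than 4 residues", call. = FALSE)
  }
  bad <- setdiff(unique(ep$category), EPITOPE_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown epitope category: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(EPITOPE_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  ep[!duplicated(ep[, c("sequence", "category")]), need]
}

#' Packaged example epitope list
#'
#' Path to the epitope table shipped with the package: the
#' wheat-dependent-anaphylaxis epitope QILQQQLIPC, Sollid-nomenclature
#' DQ2.5 coeliac 9-mers, the R5 and G12 antibody motifs, and synthetic
#' marker motifs for the baker's-asthma and wheat-allergy categories used
#' by the simulation scenario (see the file header for provenance labels).
#'
#' @return File path.
#' @export
example_epitope_file <- function() {
  system.file("extdata", "epitopes_default.tsv", package = "glutenquant",
              mustWork = TRUE)
}

canonicalize_mode <- function(x, mode) {
  switch(mode,
    strict = x,
    il_equivalent = gsub("I", "L", x, fixed = TRUE),
    qe_equivalent = gsub("E", "Q", x, fixed = TRUE),
    both = gsub("E", "Q", gsub("I", "L", x, fixed = TRUE), fixed = TRUE),
    stop("unknown mode: ", mode, call. = FALSE)
  )
}

#' Exact-containment epitope search within peptides
#'
#' Reports every occurrence (overlaps included) of each full-length epitope
#' inside each peptide. `strict` requires literal identity (100% sequence
#' identity); `il_equivalent` treats I and L as equal (indistinguishable by
#' mass), `qe_equivalent` treats Q and E as equal (deamidation), `both`
#' applies both relaxations. Matches under strict mode are a subset of
#' matches under any relaxation.
#'
#' @param peptides Character vector of peptide sequences.
#' @param epitopes Epitope table from [load_epitopes()].
#' @param mode One of `"strict"` (default), `"il_equivalent"`,
#'   `"qe_equivalent"`, `"both"`.
#' @return `data.frame`: `peptide`, `epitope`, `category`, `start`
#'   (1-based), `mode`.
#' @export
find_epitopes <- function(peptides, epitopes,
                          mode = c("strict", "il_equivalent",
                                   "qe_equivalent", "both")) {
  mode <- match.arg(mode)
  peptides <- unique(toupper(peptides))
  pep_c <- canonicalize_mode(peptides, mode)
  out <- list()
  for (j in seq_len(nrow(epitopes))) {
    epi_c <- canonicalize_mode(epitopes$sequence[j], mode)
    for (i in seq_along(peptides)) {
      starts <- find_occurrences(epi_c, pep_c[i])
      if (length(starts) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          peptide = peptides[i], epitope = epitopes$sequence[j],
          category = epitopes$category[j], start = starts, mode = mode,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(peptide = character(), epitope = character(),
                      category = character(), start = integer(),
                      mode = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-category epitope abundance and GW/MW ratios
#'
#' For each epitope category, the contributing peptides are the distinct
#' quantified peptides containing at least one epitope of that category
#' (a peptide with several epitopes counts once). The per-sample category
#' value is the sum over contributing peptides of the mean normalized
#' abundance across that sample's replicates; the ratio is reported as a
#' percentage, 100 x GW / MW, with SEMs from the per-replicate category
#' sums. A combined `all_allergy` row pools BA, WA and WDEIA with
#' cross-category peptide deduplication.
#'
#' @param matches Output of [find_epitopes()].
#' @param norm A `normalized_matrix` covering the matched peptides;
#'   matched peptides absent from the matrix are reported in a warning and
#'   skipped.
#' @return `data.frame`: `category`, `n_peptides`, `gw`, `sem_gw`, `mw`,
#'   `sem_mw`, `ratio_percent`, `flag`.
#' @export
category_abundance <- function(matches, norm) {
  absent <- setdiff(unique(matches$peptide), rownames(norm))
  if (length(absent) > 0) {
    warning(length(absent), " matched peptide(s) not quantified, skipped: ",
            paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    matches <- matches[!matches$peptide %in% absent, , drop = FALSE]
  }
  gw_cols <- sample_columns(norm, "GW")
  mw_cols <- sample_columns(norm, "MW")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summarize_set <- function(category, peps) {
    peps <- unique(peps)
    sub <- norm[peps, , drop = FALSE]
    gw_sum <- colSums(sub[, gw_cols, drop = FALSE], na.rm = TRUE)
    mw_sum <- colSums(sub[, mw_cols, drop = FALSE], na.rm = TRUE)
    mw <- mean(mw_sum)
    flag <- ""
    ratio <- if (mw == 0) {
      flag <- "MW total zero; ratio undefined"
      NA_real_
    } else 100 * mean(gw_sum) / mw
    data.frame(category = category, n_peptides = length(peps),
               gw = mean(gw_sum), sem_gw = sem(gw_sum),
               mw = mw, sem_mw = sem(mw_sum),
               ratio_percent = ratio, flag = flag, stringsAsFactors = FALSE)
  }
  cats <- intersect(EPITOPE_CATEGORIES, unique(matches$category))
  res <- lapply(cats, function(ct) {
    summarize_set(ct, matches$peptide[matches$category == ct])
  })
  allergy <- matches$peptide[matches$category %in% ALLERGY_CATEGORIES]
  if (length(allergy) > 0) {
    res <- c(res, list(summarize_set("all_allergy", allergy)))
  }
  do.call(rbind, res)
}
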