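#' Read a protein database from FASTA
#'
#' Reads an amino-acid FASTA file into a protein table. Sequences are
#' uppercased, trailing/internal `*` stop characters are stripped, and every
#' record starts in the `unassigned` group (see [classify_proteins()]).
#'
#' @param path Path to a FASTA file (multi-line sequences supported).
#' @return A `data.frame` with columns `id` (first token of the header),
#'   `description` (remainder of the header), `sequence` and `group`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 test protein", "MKR"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("digestion_io: file not found: ", path, call. = FALSE)
  }
  aa <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(aa) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(data.frame(id = character(), description = character(),
                      sequence = character(), group = character(),
                      stringsAsFactors = FALSE))
  }
  headers <- names(aa)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(id == "")) {
    stop("malformed header (empty identifier) at entry ",
         which(id == "")[1], call. = FALSE)
  }
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    stop("duplicate identifier in FASTA: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  sequence <- gsub("*", "", toupper(as.character(aa)), fixed = TRUE)
  if (any(sequence == "")) {
    stop("empty sequence for entry: ",
         paste(id[sequence == ""], collapse = ", "), call. = FALSE)
  }
  check_aa_string(sequence)
  data.frame(id = id, description = description, sequence = sequence,
             group = "unassigned", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a protein table as FASTA
#'
#' @param proteins Protein table as returned by [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- ifelse(nzchar(proteins$description),
                paste(proteins$id, proteins$description),
                proteins$id)
  lines <- as.vector(rbind(paste0(">", hdr), proteins$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Protease digestion rules
#'
#' Cleavage is C-terminal to any residue in `cleave_after`, suppressed when
#' the next residue is in `suppress_before`. Defaults encode the dominant
#' targeted-proteomics conventions: trypsin cleaves after K/R (not before P),
#' chymotrypsin after F/W/Y/L (not before P).
#'
#' @param protease `"trypsin"` or `"chymotrypsin"`.
#' @param cleave_after Residues cleaved after; `NULL` uses the protease
#'   default.
#' @param suppress_before Residues suppressing a following cleavage site.
#' @param max_missed Maximum number of missed cleavages (non-negative).
#' @return A list of class `digestion_rules`.
#' @export
digestion_rules <- function(protease = c("trypsin", "chymotrypsin"),
                            cleave_after = NULL,
                            suppress_before = "P",
                            max_missed = 0L) {
  protease <- match.arg(protease)
  if (is.null(cleave_after)) {
    cleave_after <- switch(protease,
      trypsin = c("K", "R"),
      chymotrypsin = c("F", "W", "Y", "L")
    )
  }
  if (length(cleave_after) == 0) {
    stop("cleave_after must be non-empty", call. = FALSE)
  }
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0) {
    stop("max_missed must be a non-negative integer", call. = FALSE)
  }
  structure(list(protease = protease,
                 cleave_after = toupper(cleave_after),
                 suppress_before = toupper(suppress_before),
                 max_missed = max_missed),
            class = "digestion_rules")
}

#' In-silico protease digestion of one sequence
#'
#' Enumerates all fully specific digestion products with up to
#' `rules$max_missed` internal retained cleavage sites. Peptide termini lie
#' at cleavage sites or at the protein ends; concatenating the zero-missed
#' products in order reconstructs the input.
#'
#' @param sequence Amino-acid string.
#' @param rules A [digestion_rules()] object.
#' @return `data.frame` with columns `peptide`, `start` (1-based) and
#'   `missed_cleavages`, ordered by start then missed cleavages.
#' @examples
#' digest("AKRPCRG", digestion_rules("trypsin"))
#' @export
digest <- function(sequence, rules = digestion_rules("trypsin")) {
  stopifnot(inherits(rules, "digestion_rules"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  empty <- data.frame(peptide = character(), start = integer(),
                      missed_cleavages = integer(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  check_aa_string(sequence)
  res <- strsplit(sequence, "")[[1]]
  is_site <- res %in% rules$cleave_after &
    !(c(res[-1], "") %in% rules$suppress_before)
  is_site[n] <- FALSE  # the chain end is a boundary regardless
  bounds <- c(0L, which(is_site), n)
  k <- length(bounds) - 1L  # number of zero-missed fragments
  out <- vector("list", k * (rules$max_missed + 1L))
  m <- 0L
  for (i in seq_len(k)) {
    for (mc in 0:rules$max_missed) {
      j <- i + mc
      if (j > k) break
      m <- m + 1L
      out[[m]] <- c(bounds[i] + 1L, bounds[j + 1L], mc)
    }
  }
  out <- do.call(rbind, out[seq_len(m)])
  data.frame(
    peptide = substring(sequence, out[, 1], out[, 2]),
    start = as.integer(out[, 1]),
    missed_cleavages = as.integer(out[, 3]),
    stringsAsFactors = FALSE
  )
}

#' Filter digestion products to assay candidates
#'
#' Keeps peptides whose length lies in `[min_len, max_len]`, optionally drops
#' peptides containing the ambiguous residue X (mass and exact matching are
#' undefined for X), and removes repeats, preserving first-occurrence order.
#' Idempotent.
#'
#' @param peptides Character vector of peptide sequences.
#' @param min_len,max_len Inclusive length bounds (defaults 6 and 30).
#' @param exclude_x Drop peptides containing X (default `TRUE`).
#' @return Character vector of deduplicated candidates.
#' @export
filter_candidates <- function(peptides, min_len = 6L, max_len = 30L,
                              exclude_x = TRUE) {
  if (min_len > max_len) {
    stop("min_len must be <= max_len", call. = FALSE)
  }
  len <- nchar(peptides)
  keep <- len >= min_len & len <= max_len
  if (exclude_x) keep <- keep & !grepl("X", peptides, fixed = TRUE)
  unique(peptides[keep])
}

# all (overlapping) start positions of `sub` in `s`
find_occurrences <- function(sub, s) {
  hits <- gregexpr(paste0("(?=", sub, ")"), s, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Map candidate peptides to their parent proteins
#'
#' Exact (100% identity) substring matching of every peptide against every
#' protein sequence. Overlapping occurrences within one protein count once
#' toward the parent set but every position is recorded. Peptides matching
#' no protein are retained as flagged orphans with a warning rather than
#' silently dropped.
#'
#' @param peptides Character vector of candidate peptide sequences.
#' @param proteins Protein table (columns `id`, `sequence`).
#' @return `data.frame` with columns `peptide`, `parent_ids`
#'   (semicolon-joined), `n_parents` and `is_unique`; the full occurrence
#'   list is attached as attribute `"positions"` (`peptide`, `protein_id`,
#'   `start`).
#' @export
map_peptides <- function(peptides, proteins) {
  if (nrow(proteins) == 0) stop("proteins must be non-empty", call. = FALSE)
  peptides <- unique(peptides)
  pos <- vector("list", length(peptides))
  parents <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    hits <- lapply(proteins$sequence, find_occurrences, sub = peptides[i])
    nhit <- lengths(hits)
    idx <- which(nhit > 0)
    parents[[i]] <- proteins$id[idx]
    if (length(idx) > 0) {
      pos[[i]] <- data.frame(
        peptide = peptides[i],
        protein_id = rep(proteins$id[idx], nhit[idx]),
        start = unlist(hits[idx], use.names = FALSE),
        stringsAsFactors = FALSE
      )
    }
  }
  n_parents <- lengths(parents)
  if (any(n_parents == 0)) {
    warning(sum(n_parents == 0), " orphan peptide(s) matched no protein: ",
            paste(utils::head(peptides[n_parents == 0], 5), collapse = ", "),
            call. = FALSE)
  }
  out <- data.frame(
    peptide = peptides,
    parent_ids = vapply(parents, paste, "", collapse = ";"),
    n_parents = n_parents,
    is_unique = n_parents == 1L,
    stringsAsFactors = FALSE
  )
  attr(out, "positions") <- do.call(
    rbind, c(pos[!vapply(pos, is.null, TRUE)],
             list(data.frame(peptide = character(), protein_id = character(),
                             start = integer(), stringsAsFactors = FALSE)))
  )
  out
}

#' Write a mapped-peptide table as TSV
#'
#' Columns: sequence, protease, missed_cleavages, parent_count, parent_ids
#' (semicolon-joined), unique (0/1).
#'
#' @param mapped Output of [map_peptides()].
#' @param path Output path.
#' @param protease Protease label recorded in the file.
#' @param missed_cleavages Missed-cleavage count recorded in the file.
#' @return `path`, invisibly.
#' @export
write_peptide_tsv <- function(mapped, path, protease = "trypsin",
                              missed_cleavages = 0L) {
  out <- data.frame(
    sequence = mapped$peptide,
    protease = protease,
    missed_cleavages = missed_cleavages,
    parent_count = mapped$n_parents,
    parent_ids = mapped$parent_ids,
    unique = as.integer(mapped$is_unique)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
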