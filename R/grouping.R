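#' Default protein-family classification rules
#'
#' Header regular expressions plus sequence motifs acting as lightweight
#' proxies for the diagnostic Pfam domain content of each family (gliadin
#' domain, HMW glutenin glutamine-rich repeat, cereal trypsin/alpha-amylase
#' inhibitor). Rules are data, not code: extend or replace them, and use the
#' `override` argument of [classify_proteins()] to reproduce any manual
#' curation.
#'
#' @return A list of rules, each with `group`, `header_patterns`,
#'   `sequence_motifs` and `priority`.
#' @export
default_group_rules <- function() {
  rule <- function(group, header_patterns, sequence_motifs = character(),
                   priority = 1L) {
    list(group = group, header_patterns = header_patterns,
         sequence_motifs = sequence_motifs, priority = priority)
  }
  list(
    rule("alpha_gliadin", c("alpha[/ -]?(beta[/ -]?)?gliadin"),
         c("PFPQPQLPY", "QQPFP")),
    rule("gamma_gliadin", c("gamma[/ -]?gliadin"), c("PQQSFPQQQ")),
    rule("omega_gliadin", c("omega[/ -]?[0-9.]*[/ -]?gliadin"),
         c("QQIPQQPQQF")),
    rule("lmw_gs", c("low[ -]molecular[ -]weight glutenin", "LMW[ -]?GS",
                     "glutenin.*low")),
    rule("hmw_gs", c("high[ -]molecular[ -]weight glutenin", "HMW[ -]?GS",
                     "glutenin.*high"), c("GQQGYYPTS")),
    rule("ati", c("alpha[ -]?amylase[ /-]?(trypsin)? ?inhibitor",
                  "\\bATI\\b", "trypsin inhibitor")),
    rule("alp", c("avenin[ -]?like", "\\bALP\\b"))
  )
}

#' Load classification rules from a YAML file
#'
#' Expected structure: a top-level `rules:` sequence of maps with keys
#' `group`, `header_patterns`, `sequence_motifs`, `priority`.
#'
#' @param path YAML rules file.
#' @return Rule list as in [default_group_rules()].
#' @export
load_group_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- if (!is.null(raw$rules)) raw$rules else raw
  lapply(rules, function(r) {
    if (is.null(r$group)) stop("rule without group", call. = FALSE)
    if (!r$group %in% GROUP_LEVELS) {
      stop("unknown group in rules file: ", r$group, call. = FALSE)
    }
    if (length(r$header_patterns) + length(r$sequence_motifs) == 0) {
      stop("rule for ", r$group, " has no pattern or motif", call. = FALSE)
    }
    list(group = r$group,
         header_patterns = as.character(r$header_patterns %||% character()),
         sequence_motifs = as.character(r$sequence_motifs %||% character()),
         priority = as.integer(r$priority %||% 1L))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

classify_one <- function(description, sequence, rules) {
  hit <- vapply(rules, function(r) {
    any(vapply(r$header_patterns, grepl, TRUE, x = description,
               ignore.case = TRUE, perl = TRUE)) ||
      any(vapply(r$sequence_motifs, grepl, TRUE, x = sequence,
                 fixed = TRUE))
  }, TRUE)
  groups <- unique(vapply(rules[hit], `[[`, "", "group"))
  if (length(groups) == 0) "non_gluten"
  else if (length(groups) == 1) groups
  else "mixed"
}

#' Classify proteins into prolamin / allergen families
#'
#' An explicit override wins; otherwise a protein whose header or sequence
#' fires rules of exactly one family gets that family, two or more families
#' give `mixed`, and no hit gives `non_gluten`.
#'
#' @param proteins Protein table (columns `id`, `description`, `sequence`).
#' @param rules Rule list (default [default_group_rules()]).
#' @param override Optional named character vector or two-column
#'   `data.frame` (`id`, `group`) of manual assignments.
#' @return The protein table with its `group` column filled in.
#' @export
classify_proteins <- function(proteins, rules = default_group_rules(),
                              override = NULL) {
  if (length(rules) == 0) stop("rules must be non-empty", call. = FALSE)
  if (is.data.frame(override)) {
    override <- stats::setNames(as.character(override$group),
                                override$id)
  }
  if (!is.null(override)) {
    bad <- setdiff(unique(override), GROUP_LEVELS)
    if (length(bad) > 0) {
      stop("unknown group in override: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  grp <- mapply(classify_one, proteins$description, proteins$sequence,
                MoreArgs = list(rules = rules), USE.NAMES = FALSE)
  if (!is.null(override)) {
    hit <- proteins$id %in% names(override)
    grp[hit] <- override[proteins$id[hit]]
  }
  proteins$group <- grp
  proteins
}

allocate_one <- function(parent_groups) {
  g <- unique(parent_groups)
  if (length(g) == 1 && g != "mixed") g else "multiple"
}

#' Allocate quantified peptides to a single group or "multiple"
#'
#' A peptide whose parents all belong to one family is allocated to that
#' family; parents spanning two or more families (or a single `mixed`
#' parent, which cannot be attributed) give `multiple`. The allocation
#' depends only on the set of parent groups, not on their order or
#' multiplicity.
#'
#' @param mapped Output of [map_peptides()] (columns `peptide`,
#'   `parent_ids`).
#' @param protein_groups Named character vector `id -> group` (e.g. from
#'   `setNames(proteins$group, proteins$id)`).
#' @return `data.frame` with `peptide`, `group` and `parent_groups`
#'   (semicolon-joined distinct parent families).
#' @export
allocate_peptide_groups <- function(mapped, protein_groups) {
  parent_sets <- strsplit(mapped$parent_ids, ";", fixed = TRUE)
  missing_ids <- setdiff(unlist(parent_sets), names(protein_groups))
  missing_ids <- setdiff(missing_ids, "")
  if (length(missing_ids) > 0) {
    stop("parent id(s) missing from group mapping: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  grp <- vapply(parent_sets, function(ids) {
    ids <- ids[nzchar(ids)]
    if (length(ids) == 0) return("unassigned")  # orphan peptide
    allocate_one(protein_groups[ids])
  }, "")
  evidence <- vapply(parent_sets, function(ids) {
    ids <- ids[nzchar(ids)]
    paste(sort(unique(protein_groups[ids])), collapse = ";")
  }, "")
  data.frame(peptide = mapped$peptide, group = grp,
             parent_groups = evidence, stringsAsFactors = FALSE)
}
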