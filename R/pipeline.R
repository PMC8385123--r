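#' Run the end-to-end quantitation pipeline
#'
#' Chains digestion, peptide mapping, family grouping, normalization,
#' group-level quantitation, epitope mapping and (when an annotation table
#' is supplied) term enrichment. Inputs come either from a synthetic
#' scenario or from files (FASTA database, quant table, epitope list,
#' optional group override and annotations).
#'
#' @param config Either a [scenario_config()], a path to a YAML config
#'   file, or a list with elements `fasta`, `quant`, `epitopes` (paths) and
#'   optional `override` (TSV path), `annotations` (TSV path with columns
#'   `protein_id`, `term_id`, `term_name`), `epitope_mode`, `min_len`,
#'   `max_len`, `max_missed`, `fc_threshold`, `p_threshold`.
#' @param out_dir Optional directory for all intermediate and final TSVs.
#' @return A `gluten_run_report`: list with `config_echo`, `counts`,
#'   `group_summary`, `net_gluten_percent`, `epitope_categories`,
#'   `differential`, `enrichment` (or `NULL`), `warnings`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  warnings <- character()
  note <- function(...) warnings <<- c(warnings, sprintf(...))

  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "scenario_config")) {
    sim <- simulate_scenario(config)
    proteins <- sim$proteome$proteins
    override <- sim$proteome$override
    quant <- sim$quant
    epitopes <- sim$proteome$epitopes
    annotations <- NULL
    cfg_echo <- list(mode = "scenario", seed = config$seed,
                     n_replicates = config$n_replicates,
                     peptide_cv = config$peptide_cv)
    pcfg <- pipeline_config()
    epitope_mode <- "strict"
    max_missed <- 0L
  } else {
    if (identical(config$scenario, "paper")) {
      return(run_pipeline(paper_scenario(seed = config$seed %||% 1L),
                          out_dir = out_dir))
    }
    for (f in c("fasta", "quant", "epitopes")) {
      if (is.null(config[[f]])) {
        stop("pipeline config missing input: ", f, call. = FALSE)
      }
    }
    proteins <- read_fasta(config$fasta)
    quant <- load_quant_table(config$quant)
    epitopes <- load_epitopes(config$epitopes)
    override <- if (!is.null(config$override)) {
      utils::read.delim(config$override, stringsAsFactors = FALSE)
    }
    annotations <- if (!is.null(config$annotations)) {
      utils::read.delim(config$annotations, stringsAsFactors = FALSE)
    }
    pcfg <- pipeline_config(
      min_len = config$min_len %||% 6L, max_len = config$max_len %||% 30L,
      fc_threshold = config$fc_threshold %||% 2,
      p_threshold = config$p_threshold %||% 0.01)
    epitope_mode <- config$epitope_mode %||% "strict"
    max_missed <- config$max_missed %||% 0L
    cfg_echo <- config
  }

  proteins <- classify_proteins(proteins, override = override)

  # digestion covers both proteases so observed peptides of either digest map
  digests <- unlist(lapply(c("trypsin", "chymotrypsin"), function(pz) {
    rules <- digestion_rules(pz, max_missed = max_missed)
    unlist(lapply(proteins$sequence, function(s) digest(s, rules)$peptide))
  }))
  candidates <- filter_candidates(digests, pcfg$min_len, pcfg$max_len)

  observed <- unique(quant$peptide)
  unmatched <- setdiff(observed, candidates)
  if (length(unmatched) > 0) {
    note("%d observed peptide(s) not among in-silico candidates",
         length(unmatched))
  }
  mapped <- withCallingHandlers(
    map_peptides(observed, proteins),
    warning = function(w) {
      note("%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  alloc <- allocate_peptide_groups(
    mapped, stats::setNames(proteins$group, proteins$id))

  mat <- peptide_area(quant)
  norm <- withCallingHandlers(
    normalize_peptides(mat),
    warning = function(w) {
      note("%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  diff <- differential_abundance(norm, pcfg)
  groups <- group_abundance(norm, alloc)
  net <- net_gluten_ratio(groups)

  matches <- find_epitopes(rownames(norm), epitopes, mode = epitope_mode)
  cats <- category_abundance(matches, norm)

  enr <- NULL
  if (!is.null(annotations)) {
    detected <- unique(unlist(strsplit(mapped$parent_ids, ";")))
    fc <- stats::setNames(diff$log2_fold_change, diff$peptide)
    sel_pep <- diff$peptide[diff$significant &
                              diff$log2_fold_change > 0 &
                              !is.na(diff$significant)]
    sel <- unique(unlist(strsplit(
      mapped$parent_ids[mapped$peptide %in% sel_pep], ";")))
    enr <- hypergeom_enrich(sel, detected, annotations)
  } else {
    note("enrichment stage skipped: no annotation table supplied")
  }

  report <- structure(list(
    config_echo = cfg_echo,
    counts = c(proteins = nrow(proteins),
               candidates = length(candidates),
               quantified_peptides = nrow(norm),
               epitope_matches = nrow(matches)),
    group_summary = groups,
    net_gluten_percent = net,
    epitope_categories = cats,
    differential = diff,
    enrichment = enr,
    warnings = warnings
  ), class = "gluten_run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peptide_tsv(mapped, file.path(out_dir, "mapped_peptides.tsv"))
    utils::write.table(alloc, file.path(out_dir, "allocations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_normalized_tsv(norm, file.path(out_dir, "normalized_matrix.tsv"))
    utils::write.table(diff, file.path(out_dir, "volcano.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(groups, file.path(out_dir, "group_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(matches, file.path(out_dir, "epitope_matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cats, file.path(out_dir, "epitope_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enr)) {
      utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(sprintf("net_gluten_percent\t%.6f", net),
               file.path(out_dir, "net_gluten.txt"))
  }
  report
}

#' @export
print.gluten_run_report <- function(x, ...) {
  cat("Gluten quantitation pipeline report\n")
  cat(sprintf("  proteins: %d | candidate peptides: %d | quantified: %d\n",
              x$counts["proteins"], x$counts["candidates"],
              x$counts["quantified_peptides"]))
  cat(sprintf("  net canonical gluten (GW vs MW): %.1f%%\n",
              x$net_gluten_percent))
  cat("  group ratios (GW/MW):\n")
  g <- x$group_summary
  for (i in seq_len(nrow(g))) {
    cat(sprintf("    %-14s %6.3f  (n=%d, p=%.3g)\n", g$group[i],
                g$ratio_gw_mw[i], g$n_peptides[i], g$p_value[i]))
  }
  cat("  epitope categories (ratio % GW/MW):\n")
  e <- x$epitope_categories
  for (i in seq_len(nrow(e))) {
    cat(sprintf("    %-12s %7.1f%%  (n=%d peptides)\n", e$category[i],
                e$ratio_percent[i], e$n_peptides[i]))
  }
  if (length(x$warnings)) {
    cat("  notes:\n")
    for (w in x$warnings) cat("    -", w, "\n")
  }
  invisible(x)
}

#' Volcano plot of peptide differential abundance
#'
#' @param diff Output of [differential_abundance()].
#' @param config A [pipeline_config()] supplying the drawn thresholds.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_volcano <- function(diff, config = pipeline_config()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_volcano requires ggplot2", call. = FALSE)
  }
  d <- diff[is.finite(diff$p_value), ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$log2_fold_change, y = -log10(.data$p_value),
    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(config$fc_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(config$p_threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change (GW / MW)", y = "-log10 p") +
    ggplot2::theme_minimal()
}
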