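# standard monoisotopic residue masses (Da)
MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MOD_CARBAMIDOMETHYL <- 57.02146

#' Default fixed modifications
#'
#' Carbamidomethylation of cysteine (+57.02146 Da), reflecting iodoacetamide
#' alkylation during sample preparation.
#'
#' @return Named numeric vector of residue mass shifts.
#' @export
default_fixed_mods <- function() c(C = MOD_CARBAMIDOMETHYL)

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water, with fixed
#' modifications added per matching residue.
#'
#' @param sequence Peptide sequence (no X).
#' @param fixed_mods Named numeric vector of residue mass shifts in Da;
#'   default carbamidomethyl-C. Use `NULL` or `numeric(0)` for none.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mono_mass("GG", fixed_mods = NULL)  # 132.05349
#' @export
peptide_mono_mass <- function(sequence, fixed_mods = default_fixed_mods()) {
  if (is.na(sequence) || nchar(sequence) == 0) {
    stop("empty peptide", call. = FALSE)
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(unique(res), names(MONO_RESIDUE_MASS))
  if (length(unknown) > 0) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mass <- sum(MONO_RESIDUE_MASS[res]) + MASS_WATER
  if (length(fixed_mods) > 0) {
    mass <- mass + sum(fixed_mods[res], na.rm = TRUE)
  }
  mass
}

#' Precursor m/z
#'
#' @param sequence Peptide sequence.
#' @param charge Positive integer charge state.
#' @param fixed_mods As in [peptide_mono_mass()].
#' @return m/z in Thomson: (M + z * proton) / z.
#' @export
precursor_mz <- function(sequence, charge,
                         fixed_mods = default_fixed_mods()) {
  if (charge < 1) stop("charge must be >= 1", call. = FALSE)
  (peptide_mono_mass(sequence, fixed_mods) + charge * MASS_PROTON) / charge
}

#' Fragment-ion m/z (b / y series)
#'
#' y_k is the C-terminal k residues plus water; b_k the N-terminal k
#' residues; both protonated and divided by charge.
#'
#' @param sequence Peptide sequence.
#' @param ion_type `"y"` or `"b"`.
#' @param index Fragment index, `1 <= index < nchar(sequence)`.
#' @param charge Positive integer fragment charge.
#' @param fixed_mods As in [peptide_mono_mass()].
#' @return m/z in Thomson.
#' @examples
#' fragment_mz("GK", "y", 1)  # 147.11280
#' @export
fragment_mz <- function(sequence, ion_type = c("y", "b"), index, charge = 1L,
                        fixed_mods = default_fixed_mods()) {
  ion_type <- match.arg(ion_type)
  n <- nchar(sequence)
  if (index < 1 || index >= n) {
    stop("fragment index out of range [1, ", n - 1, "]: ", index,
         call. = FALSE)
  }
  if (charge < 1) stop("charge must be >= 1", call. = FALSE)
  piece <- if (ion_type == "y") {
    substring(sequence, n - index + 1, n)
  } else {
    substring(sequence, 1, index)
  }
  res <- strsplit(toupper(piece), "")[[1]]
  mass <- sum(MONO_RESIDUE_MASS[res])
  if (length(fixed_mods) > 0) mass <- mass + sum(fixed_mods[res], na.rm = TRUE)
  if (ion_type == "y") mass <- mass + MASS_WATER
  (mass + charge * MASS_PROTON) / charge
}

#' Transition QC thresholds
#'
#' Acceptance requires at least `min_transitions` transitions with intensity
#' strictly over `min_intensity` cps, signal-to-noise strictly over
#' `min_snr`, and retention time within `rt_tolerance` minutes of the
#' precursor's median observed RT; the `keep_top` most intense passing
#' transitions are retained.
#'
#' @param min_transitions Minimum passing transitions (default 3).
#' @param min_intensity Minimum intensity, cps (default 1000, strict).
#' @param min_snr Minimum S/N (default 5, strict).
#' @param rt_tolerance Co-elution tolerance, minutes (default 0.2).
#' @param keep_top Transitions kept per accepted peptide (default 3).
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_transitions = 3L, min_intensity = 1000,
                          min_snr = 5, rt_tolerance = 0.2, keep_top = 3L) {
  stopifnot(min_transitions >= 1, min_intensity >= 0, min_snr >= 0,
            rt_tolerance >= 0, keep_top >= 1)
  structure(list(min_transitions = as.integer(min_transitions),
                 min_intensity = min_intensity, min_snr = min_snr,
                 rt_tolerance = rt_tolerance, keep_top = as.integer(keep_top)),
            class = "qc_thresholds")
}

#' Select quantifier transitions per peptide
#'
#' Applies intensity, signal-to-noise and RT co-elution filters to observed
#' transitions grouped by peptide; peptides with at least
#' `thresholds$min_transitions` passing transitions are accepted and their
#' `keep_top` most intense passing transitions kept (ties broken by
#' ascending fragment m/z for a deterministic output).
#'
#' @param observations `data.frame` with columns `peptide`, `transition`,
#'   `observed_rt` (min), `intensity` (cps), `snr`, and optionally
#'   `fragment_mz`.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `accepted` (kept transitions) and `rejected`
#'   (`peptide`, `reason`).
#' @export
qc_select_transitions <- function(observations,
                                  thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  need <- c("peptide", "transition", "observed_rt", "intensity", "snr")
  miss <- setdiff(need, names(observations))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(observations$fragment_mz)) observations$fragment_mz <- NA_real_
  accepted <- list()
  rejected <- list()
  for (pep in unique(observations$peptide)) {
    obs <- observations[observations$peptide == pep, , drop = FALSE]
    med_rt <- stats::median(obs$observed_rt)
    pass <- obs$intensity > thresholds$min_intensity &
      obs$snr > thresholds$min_snr &
      abs(obs$observed_rt - med_rt) <= thresholds$rt_tolerance
    if (sum(pass) < thresholds$min_transitions) {
      rejected[[pep]] <- data.frame(peptide = pep,
                                    reason = "insufficient transitions",
                                    stringsAsFactors = FALSE)
      next
    }
    kept <- obs[pass, , drop = FALSE]
    ord <- order(-kept$intensity, kept$fragment_mz, kept$transition)
    accepted[[pep]] <- kept[utils::head(ord, thresholds$keep_top), ,
                            drop = FALSE]
  }
  list(
    accepted = if (length(accepted)) do.call(rbind, c(accepted,
                                                      make.row.names = FALSE))
               else observations[0, , drop = FALSE],
    rejected = if (length(rejected)) do.call(rbind, c(rejected,
                                                      make.row.names = FALSE))
               else data.frame(peptide = character(), reason = character(),
                               stringsAsFactors = FALSE)
  )
}

#' Concurrency cap implied by the instrument cycle time
#'
#' The number of transitions that can be monitored concurrently at a given
#' maximum cycle time and minimum dwell time per transition.
#'
#' @param cycle_time_s Maximum cycle time in seconds (default 0.3).
#' @param min_dwell_s Minimum dwell time per transition in seconds
#'   (default 0.005).
#' @return Integer cap, `floor(cycle_time_s / min_dwell_s)`.
#' @export
max_concurrent_transitions <- function(cycle_time_s = 0.3,
                                       min_dwell_s = 0.005) {
  as.integer(floor(cycle_time_s / min_dwell_s))
}

# maximum number of simultaneously open RT windows among the given assays
max_window_overlap <- function(rt_min, window_s) {
  if (length(rt_min) == 0) return(0L)
  half <- window_s / 60 / 2
  ev <- rbind(cbind(rt_min - half, 1), cbind(rt_min + half, -1))
  # closed intervals: at a shared endpoint, openings count before closings
  ev <- ev[order(ev[, 1], -ev[, 2]), , drop = FALSE]
  max(cumsum(ev[, 2]))
}

#' Partition scheduled assays into transition lists
#'
#' First-fit assignment in ascending retention-time order: each transition
#' goes to the first list where adding it keeps the number of concurrently
#' open detection windows at or below `max_concurrent` at every time point.
#'
#' @param assays `data.frame` with at least `peptide` and `expected_rt`
#'   (minutes); other columns are carried through.
#' @param window_s Detection window width in seconds (default 60).
#' @param max_concurrent Concurrency cap per list (default derived from a
#'   0.3 s cycle via [max_concurrent_transitions()]).
#' @return The input with an added integer column `list_index`.
#' @export
schedule_assays <- function(assays, window_s = 60,
                            max_concurrent = max_concurrent_transitions()) {
  if (max_concurrent < 1) stop("max_concurrent must be >= 1", call. = FALSE)
  if (window_s <= 0) stop("window_s must be > 0", call. = FALSE)
  if (any(is.na(assays$expected_rt))) {
    stop("expected_rt must be set for all assays", call. = FALSE)
  }
  ord <- order(assays$expected_rt)
  lists <- list()  # vector of rt per list
  idx <- integer(nrow(assays))
  for (i in ord) {
    placed <- FALSE
    for (l in seq_along(lists)) {
      cand <- c(lists[[l]], assays$expected_rt[i])
      if (max_window_overlap(cand, window_s) <= max_concurrent) {
        lists[[l]] <- cand
        idx[i] <- l
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      lists[[length(lists) + 1L]] <- assays$expected_rt[i]
      idx[i] <- length(lists)
    }
  }
  assays$list_index <- idx
  assays
}

#' Validate the concurrency cap of a schedule
#'
#' Recomputes pairwise window overlaps per list and checks the cap.
#'
#' @param scheduled Output of [schedule_assays()].
#' @param window_s Detection window in seconds.
#' @param max_concurrent Concurrency cap.
#' @return `TRUE` if every list respects the cap, else `FALSE`.
#' @export
validate_schedule <- function(scheduled, window_s = 60,
                              max_concurrent = max_concurrent_transitions()) {
  all(vapply(split(scheduled$expected_rt, scheduled$list_index),
             max_window_overlap, numeric(1),
             window_s = window_s) <= max_concurrent)
}

#' Write a vendor-import-friendly transition list CSV
#'
#' Columns: peptide, precursor_mz, fragment_label, fragment_mz, rt_min,
#' window_s, list_index; m/z rounded to 5 decimals.
#'
#' @param scheduled Scheduled assay table with the above columns (before
#'   rounding).
#' @param path Output CSV path.
#' @param window_s Detection window recorded in the file.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(scheduled, path, window_s = 60) {
  out <- data.frame(
    peptide = scheduled$peptide,
    precursor_mz = round(scheduled$precursor_mz, 5),
    fragment_label = scheduled$fragment_label,
    fragment_mz = round(scheduled$fragment_mz, 5),
    rt_min = scheduled$expected_rt,
    window_s = window_s,
    list_index = scheduled$list_index
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
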