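#' Write a cohort trial table to CSV
#'
#' Writes the documented trial schema (`participant_id`, `block`, `trial`,
#' `majority_count`, `stimulus`, `response`, `correct`, `conf1`, `conf2`,
#' `shift`) as plain comma-separated text. An absent second rating is
#' encoded as an empty field.
#'
#' @param trials Trial data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "block", "trial", "majority_count", "stimulus",
            "response", "correct", "conf1", "conf2", "shift")
  stopifnot(all(cols %in% names(trials)))
  utils::write.csv(trials[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort trial table from CSV
#'
#' Parses and validates the documented trial schema. Empty `conf2` fields
#' become `NA` (extreme trials); rows where the second rating repeats the
#' first are rejected with their row numbers, as are missing columns and
#' non-numeric ratings. If the `shift` column is absent it is rebuilt with
#' [classify_shift()], and if present it is checked for consistency.
#'
#' @param path CSV file path.
#' @return A validated trial data.frame.
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (nrow(raw) == 0) stop("empty trial file: ", path)
  need <- c("participant_id", "block", "trial", "majority_count", "stimulus",
            "response", "correct", "conf1", "conf2")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("conf1", "conf2")) {
    if (!is.numeric(raw[[col]]))
      stop("non-numeric ratings in column ", col)
  }
  if (is.character(raw$correct)) raw$correct <- toupper(raw$correct) == "TRUE"
  if (!is.logical(raw$correct)) raw$correct <- as.logical(raw$correct)
  bad <- which(!is.na(raw$conf2) & raw$conf2 == raw$conf1)
  if (length(bad))
    stop("conf2 equals conf1 on data row(s) ", paste(bad, collapse = ", "))
  shift <- classify_shift(raw$conf1, raw$conf2)
  if (!is.null(raw$shift) && any(raw$shift != shift))
    stop("shift column inconsistent with conf1/conf2 on row(s) ",
         paste(which(raw$shift != shift), collapse = ", "))
  raw$shift <- shift
  raw
}

#' Pipeline configuration
#'
#' Collects everything one reproducible end-to-end run needs: the session
#' design, the generative observer, the cohort size, the master seed, and
#' the analysis knobs (confidence bins, permutation count, exclusion
#' thresholds, tail convention). Defaults follow the reference design (450
#' trials in 9 blocks, 2.5-SD accuracy rule, 50-shift minimum).
#'
#' @param session A [session_config()].
#' @param observer An [observer_params()] (or list of them, one per
#'   participant).
#' @param cohort_size Number of simulated participants.
#' @param seed Master seed; every downstream stream is derived from it.
#' @param n_bins Confidence bins for meta-d'.
#' @param n_permutations Permutations for the second-step chance level.
#' @param min_count Minimum up- and down-shift trials per participant.
#' @param z_cut Group-accuracy exclusion cut-off in SDs.
#' @param tails Tail convention for group tests.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(session = session_config(),
                            observer = observer_params(),
                            cohort_size = 20L,
                            seed = 1L,
                            n_bins = 5L,
                            n_permutations = 1000L,
                            min_count = 50L,
                            z_cut = 2.5,
                            tails = "two") {
  structure(list(session = session, observer = observer,
                 cohort_size = as.integer(cohort_size),
                 seed = as.integer(seed), n_bins = as.integer(n_bins),
                 n_permutations = as.integer(n_permutations),
                 min_count = as.integer(min_count), z_cut = z_cut,
                 tails = tails),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, applies the exclusion rules, fits the
#' three meta-d' values per participant, runs the second-step analysis
#' with its permutation chance level, and produces the group report. Fully
#' deterministic given the config's master seed: the simulation uses
#' `seed` and the permutation streams use `seed + 1`-derived streams. When
#' `out_dir` is given, every table is also written there as CSV together
#' with an exclusions log and a run manifest listing all knobs and seeds.
#'
#' @param config A [pipeline_config()].
#' @param trials Optional pre-loaded trial data.frame (e.g. from
#'   [read_trials()]); when supplied the simulation stage is skipped.
#' @param out_dir Optional output directory for CSV artifacts.
#' @return A list with `trials` (raw), `exclusions` (summary table with
#'   flags), `included` (filtered trials), and `report` (a
#'   [full_report()] result), plus `out_dir` when written.
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(trials)) {
    trials <- simulate_cohort(config$cohort_size, config$session,
                              config$observer, seed = config$seed)
  }
  excl <- apply_exclusions(trials, z_cut = config$z_cut,
                           min_count = config$min_count)
  if (length(excl$included_ids) == 0)
    stop("exclusion stage removed every participant; nothing to analyse")
  if (length(excl$included_ids) < 2)
    stop("fewer than 2 participants survive exclusion; group tests impossible")
  report <- full_report(excl$trials, n_bins = config$n_bins,
                        n_permutations = config$n_permutations,
                        seed = config$seed + 1L, tails = config$tails)
  out <- list(trials = trials, exclusions = excl$summaries,
              included = excl$trials, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(excl$summaries,
                     file.path(out_dir, "participant_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(report$meta_d, file.path(out_dir, "meta_d.csv"),
                     row.names = FALSE)
    utils::write.csv(report$second_step,
                     file.path(out_dir, "second_step.csv"),
                     row.names = FALSE)
    utils::write.csv(report$comparisons, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    exc <- excl$summaries[!excl$summaries$included, , drop = FALSE]
    writeLines(c("excluded participants:",
                 if (nrow(exc)) paste0("  ", exc$participant_id, ": ",
                                       exc$exclusion_reason)
                 else "  none"),
               file.path(out_dir, "exclusions.log"))
    manifest <- c(
      sprintf("seed: %d", config$seed),
      sprintf("cohort_size: %d", config$cohort_size),
      sprintf("n_trials: %d", config$session$n_trials),
      sprintf("n_blocks: %d", config$session$n_blocks),
      sprintf("n_bins: %d", config$n_bins),
      sprintf("n_permutations: %d", config$n_permutations),
      sprintf("min_count: %d", config$min_count),
      sprintf("z_cut: %g", config$z_cut),
      sprintf("tails: %s", config$tails),
      sprintf("included: %d of %d participants",
              length(excl$included_ids), nrow(excl$summaries)))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
    out$out_dir <- out_dir
  }
  out
}
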