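#' Extract participant-level eye metrics from a cohort bundle
#'
#' Runs fixation detection, quality screening, flash synchronization and
#' quiet-eye extraction on every trial, then aggregates to participant
#' level with the reliability exclusions (trials failing the tracking or
#' fixation ratio; participants with fewer than `min_valid` reliable
#' trials).
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()] or
#'   [read_cohort()].
#' @param dispersion_deg,min_duration_ms,gap_tolerance_ms I-DT detector
#'   parameters, see [detect_fixations()].
#' @param tracking_min,fixation_min Reliability thresholds, see
#'   [compute_quality()].
#' @param window_ms Pre-throw window width (ms).
#' @param qe_radius_deg Quiet-eye spatial criterion (degrees).
#' @param min_valid Minimum reliable trials per participant.
#' @return A list with `trials` (per-trial metrics data.frame) and
#'   `participants` (one row per participant, see
#'   [aggregate_participant()]).
#' @export
extract_cohort <- function(bundle, dispersion_deg = 1.0,
                           min_duration_ms = 100, gap_tolerance_ms = 75,
                           tracking_min = 0.85, fixation_min = 0.60,
                           window_ms = 2000, qe_radius_deg = 1.0,
                           min_valid = 5) {
  all_rows <- list()
  part_rows <- list()
  for (p in bundle$participants) {
    rows <- lapply(p$trials, function(tr) {
      fix <- detect_fixations(tr$trace, dispersion_deg, min_duration_ms,
                              gap_tolerance_ms)
      qual <- compute_quality(tr$trace, fix, tracking_min, fixation_min)
      off <- estimate_sync_offset(tr$events)
      trial_metrics(fix, tr$events, off, qual, window_ms, qe_radius_deg)
    })
    col <- function(nm, miss) vapply(rows, function(r) r[[nm]], miss)
    tdf <- quick_df(list(
      participant_id = col("participant_id", ""),
      trial_id = col("trial_id", ""),
      reliable = col("reliable", TRUE),
      qe_onset_ms = col("qe_onset_ms", 0),
      qe_duration_ms = col("qe_duration_ms", 0),
      n_fixations = col("n_fixations", 0L),
      tt_ms = col("tt_ms", 0),
      catch = col("catch", TRUE)))
    all_rows[[p$id]] <- tdf
    part_rows[[p$id]] <- aggregate_participant(tdf, min_valid)
  }
  list(trials = do.call(rbind, c(all_rows, make.row.names = FALSE)),
       participants = do.call(rbind, c(part_rows, make.row.names = FALSE)))
}

#' Score the attention instruments for a cohort bundle
#'
#' @param bundle A `cohort_bundle`.
#' @param norms Norm table from [read_norm_table()].
#' @return Data.frame with one row per participant: `participant_id`,
#'   `pct_errors_ss`, `cp_ss`, `rt_mean`, `sdrt`, `cvrt`, `corr_resp`.
#' @export
score_cohort <- function(bundle, norms = read_norm_table()) {
  sheet <- d2_sheet()
  rows <- lapply(bundle$participants, function(p) {
    d2 <- score_d2(sheet, p$d2_marks, norms, age = p$age,
                   processed = p$d2_processed)
    rta <- score_rta(p$rta_log)
    data.frame(participant_id = p$id,
               pct_errors_ss = d2$pct_errors_ss, cp_ss = d2$cp_ss,
               rt_mean = rta$rt_mean_ms, sdrt = rta$sdrt_ms,
               cvrt = rta$cvrt_pct, corr_resp = rta$corr_resp)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Assemble the participant-by-variable cohort table
#'
#' Joins the eye metrics with the attention scores, dropping excluded
#' participants; rows entering the multivariate analyses must be
#' listwise-complete.
#'
#' @param eye `participants` data.frame from [extract_cohort()].
#' @param attention Data.frame from [score_cohort()].
#' @return The merged cohort table (one row per retained participant).
#' @export
build_cohort_table <- function(eye, attention) {
  eye <- eye[!eye$excluded, , drop = FALSE]
  merge(eye[, c("participant_id", "n_fixations", "tt_ms", "qe_onset_ms",
                "qe_duration_ms", "n_catches")],
        attention, by = "participant_id")
}

eye_vars <- c("n_fixations", "tt_ms", "qe_onset_ms", "qe_duration_ms")
attention_vars <- c("pct_errors_ss", "cp_ss", "rt_mean", "sdrt", "cvrt",
                    "corr_resp")

#' Statistical linkage of eye behaviour and attention scores
#'
#' Produces the full statistical report for a cohort table: per-variable
#' descriptives, the eye-by-attention Pearson correlation matrix with t and
#' pairs-bootstrap p-values (pairwise-complete), the shared variance of
#' each attention variable (and the catch count) with the four eye
#' variables (listwise), and canonical correlation analysis with
#' sequential Wilks-lambda permutation p-values.
#'
#' @param tab Cohort table from [build_cohort_table()].
#' @param B_boot Bootstrap resamples for correlation p-values.
#' @param B_perm Permutations for the Wilks test.
#' @param seed Integer seed for both resampling procedures.
#' @return A list with `descriptives`, `correlations`, `shared_variance`,
#'   `cca` ([cca()] result), `cca_p` ([cca_permutation_p()] result), `n`.
#' @export
link_cohort <- function(tab, B_boot = 9999, B_perm = 999, seed = 1) {
  vars <- c(attention_vars, eye_vars)
  desc <- do.call(rbind, lapply(vars, function(v) {
    d <- descriptives(tab[[v]])
    data.frame(variable = v, n = d$n, mean = d$mean, sd = d$sd,
               min = d$min, q1 = d$q1, median = d$median, q3 = d$q3,
               max = d$max, skewness = d$skewness, shapiro_p = d$shapiro_p)
  }))
  pairs <- expand.grid(attention = c(attention_vars, "n_catches"),
                       eye = eye_vars, stringsAsFactors = FALSE)
  cors <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    x <- tab[[pairs$eye[i]]]
    y <- tab[[pairs$attention[i]]]
    ct <- pearson_with_t(x, y)
    data.frame(attention = pairs$attention[i], eye = pairs$eye[i],
               r = ct$r, t_stat = ct$t_stat, p_t = ct$p_t,
               p_bootstrap = bootstrap_p(x, y, B = B_boot, seed = seed),
               n = ct$n)
  }))
  cc <- stats::complete.cases(tab[, c(eye_vars, attention_vars)])
  X <- as.matrix(tab[cc, eye_vars])
  Y <- as.matrix(tab[cc, attention_vars])
  r2 <- do.call(rbind, lapply(c(attention_vars, "n_catches"), function(v) {
    sv <- shared_variance(tab[cc, v], X)
    data.frame(criterion = v, r_squared = sv$r_squared, f_stat = sv$f_stat,
               p_f = sv$p_f, k = sv$k, n = sv$n)
  }))
  fit <- cca(X, Y)
  perm <- cca_permutation_p(X, Y, B = B_perm, seed = seed)
  list(descriptives = desc, correlations = cors, shared_variance = r2,
       cca = fit, cca_p = perm, n = sum(cc))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages `simulate` (generate a synthetic cohort and
#' write its raw bundle), `extract` (gaze to per-trial and participant eye
#' metrics), `score` (attention instruments) and `link` (statistics), with
#' every output persisted as CSV/JSON under `out_dir`. Stages read their
#' inputs from `out_dir`, so any stage can be re-run from persisted
#' intermediates. Every reliability exclusion is recorded in
#' `exclusions.csv` with the rule that triggered it.
#'
#' @param out_dir Output (and working) directory.
#' @param stages Character subset of
#'   `c("simulate", "extract", "score", "link")`.
#' @param config A [cohort_config()] (used by `simulate`).
#' @param cohort_dir Directory holding the raw cohort; defaults to
#'   `file.path(out_dir, "cohort")`.
#' @param norms Norm table for d2-R standard scores.
#' @param B_boot,B_perm,seed Statistics parameters, see [link_cohort()].
#' @param ... Extraction parameters passed to [extract_cohort()].
#' @return Invisibly, a list with the stage outputs that were produced.
#' @export
run_pipeline <- function(out_dir,
                         stages = c("simulate", "extract", "score", "link"),
                         config = cohort_config(),
                         cohort_dir = file.path(out_dir, "cohort"),
                         norms = read_norm_table(),
                         B_boot = 999, B_perm = 999, seed = 1, ...) {
  stages <- match.arg(stages, c("simulate", "extract", "score", "link"),
                      several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  if ("simulate" %in% stages) {
    bundle <- simulate_cohort(config)
    write_cohort(bundle, cohort_dir)
    res$bundle <- bundle
  }
  if (any(c("extract", "score") %in% stages)) {
    bundle <- if (!is.null(res$bundle)) res$bundle else read_cohort(cohort_dir)
  }
  if ("extract" %in% stages) {
    ex <- extract_cohort(bundle, ...)
    utils::write.csv(ex$trials, file.path(out_dir, "trial_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(ex$participants,
                     file.path(out_dir, "participant_eye_metrics.csv"),
                     row.names = FALSE)
    excl <- ex$trials[!ex$trials$reliable,
                      c("participant_id", "trial_id"), drop = FALSE]
    if (nrow(excl) > 0) excl$rule <- "tracking or fixation ratio below threshold"
    pex <- ex$participants[ex$participants$excluded, "participant_id"]
    if (length(pex) > 0) {
      excl <- rbind(excl, data.frame(participant_id = pex, trial_id = NA,
                                     rule = "fewer reliable trials than min_valid"))
    }
    utils::write.csv(excl, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    res$extract <- ex
  }
  if ("score" %in% stages) {
    sc <- score_cohort(bundle, norms)
    utils::write.csv(sc, file.path(out_dir, "attention_scores.csv"),
                     row.names = FALSE)
    res$score <- sc
  }
  if ("link" %in% stages) {
    # always read the persisted intermediates so that a stand-alone link
    # run is byte-identical to an all-in-one run
    eye <- utils::read.csv(file.path(out_dir, "participant_eye_metrics.csv"))
    att <- utils::read.csv(file.path(out_dir, "attention_scores.csv"))
    tab <- build_cohort_table(eye, att)
    utils::write.csv(tab, file.path(out_dir, "cohort_table.csv"),
                     row.names = FALSE)
    link <- link_cohort(tab, B_boot = B_boot, B_perm = B_perm, seed = seed)
    utils::write.csv(link$descriptives,
                     file.path(out_dir, "descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(link$correlations,
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(link$shared_variance,
                     file.path(out_dir, "shared_variance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(canonical_correlations = link$cca$cor,
           loadings_eye = as.data.frame(link$cca$loadings_x),
           loadings_attention = as.data.frame(link$cca$loadings_y),
           wilks = link$cca$wilks, p_permutation = link$cca_p$p,
           n = link$n, B = link$cca_p$B),
      file.path(out_dir, "cca.json"), digits = NA)
    res$link <- link
  }
  invisible(res)
}
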