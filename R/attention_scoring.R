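#' Load the bundled d2-R stimulus sheet
#'
#' The d2-R test presents 14 rows of 57 letters `d` and `p`, each carrying
#' one to four dashes; the target character is a `d` with exactly two
#' dashes. The bundled fixed sheet contains exactly 308 targets and 376
#' distractors in rows 2-13 (the first and last rows are excluded from
#' scoring). Each row is worked for 20 s, so the instrument totals 280 s.
#'
#' @param file Optional path to an alternative sheet CSV with columns
#'   `row`, `position`, `letter`, `dashes`.
#' @return A data.frame with columns `row`, `position`, `letter`, `dashes`
#'   and a logical `target` column, plus attributes `row_time_s` (20) and
#'   `total_time_s` (280).
#' @export
d2_sheet <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "d2_sheet.csv", package = "quieteye")
  }
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("row", "position", "letter", "dashes") %in% names(d)))
  if (nrow(d) != 14 * 57) {
    stop("d2 sheet must contain exactly 14 rows x 57 characters",
         call. = FALSE)
  }
  d$target <- d$letter == "d" & d$dashes == 2L
  structure(d, row_time_s = 20, total_time_s = 14 * 20)
}

#' Load a d2-R norm table
#'
#' Maps raw scores to standard scores (SS) per instrument and age band,
#' monotonically in the raw score. The bundled table
#' (`d2_norms_synthetic.csv`) is a synthetic surrogate -- a linear raw-to-SS
#' map anchored so the synthetic norm population has mean 100 and SD 10 --
#' because the real d2-R norms are proprietary; any licensed table in the
#' same format can be dropped in.
#'
#' @param file Path to a norms CSV with columns `instrument` (`"cp"` or
#'   `"pct_errors"`), `age_lo`, `age_hi`, `raw`, `ss`. Defaults to the
#'   bundled synthetic surrogate.
#' @return The norm table data.frame.
#' @export
read_norm_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "d2_norms_synthetic.csv",
                        package = "quieteye")
  }
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("instrument", "age_lo", "age_hi", "raw", "ss") %in% names(d)))
  d
}

norm_lookup <- function(norms, instrument, age, raw) {
  band <- norms[norms$instrument == instrument &
                norms$age_lo <= age & age <= norms$age_hi, , drop = FALSE]
  if (nrow(band) == 0) {
    stop(sprintf("no %s norm band covers age %.1f", instrument, age),
         call. = FALSE)
  }
  band <- band[order(band$raw), ]
  stats::approx(band$raw, band$ss, xout = raw, rule = 2)$y
}

#' Score a d2-R response record
#'
#' Scores rows 2-13 only. The processed span of a row runs from position 1
#' to the row's last processed position (by default the rightmost mark in
#' that row; an explicit `processed` table overrides this). Counts:
#' \describe{
#'   \item{commission}{marked distractors within the processed span.}
#'   \item{omission}{processed targets left unmarked.}
#'   \item{cp_raw}{correctly marked targets minus commissions (concentration
#'     performance).}
#'   \item{pct_errors_raw}{`100 * (commission + omission) / processed
#'     targets`.}
#' }
#' Standard scores are looked up in the norm table for the participant's
#' age. Setting `cp_literal = TRUE` uses all processed targets (marked or
#' not) minus commissions instead of correctly marked targets minus
#' commissions.
#'
#' @param sheet Sheet from [d2_sheet()].
#' @param marks Data.frame of marks with columns `row`, `position`.
#' @param norms Norm table from [read_norm_table()].
#' @param age Participant age in years.
#' @param processed Optional data.frame `row`, `last_pos` giving explicit
#'   end-of-progress per row; defaults to the rightmost mark per row (rows
#'   without marks count as unprocessed).
#' @param cp_literal Use the literal "processed targets minus commissions"
#'   reading of CP.
#' @return A list with `processed_targets`, `commission`, `omission`,
#'   `cp_raw`, `pct_errors_raw`, `cp_ss`, `pct_errors_ss`.
#' @export
score_d2 <- function(sheet, marks, norms = read_norm_table(), age = 10,
                     processed = NULL, cp_literal = FALSE) {
  stopifnot(all(c("row", "position") %in% names(marks)))
  if (any(marks$position < 1 | marks$position > 57)) {
    stop("mark positions must lie within 1..57", call. = FALSE)
  }
  last_pos <- rep(0L, 14)
  if (is.null(processed)) {
    agg <- tapply(marks$position, marks$row, max)
    last_pos[as.integer(names(agg))] <- as.integer(agg)
  } else {
    last_pos[processed$row] <- as.integer(processed$last_pos)
    bad <- merge(marks, data.frame(row = 1:14, last_pos = last_pos))
    if (any(bad$position > bad$last_pos)) {
      stop("mark found outside the processed span of its row", call. = FALSE)
    }
  }
  score_rows <- 2:13
  sh <- sheet[sheet$row %in% score_rows, , drop = FALSE]
  sh$in_span <- sh$position <= last_pos[sh$row]
  key <- function(r, p) r * 100L + p
  marked <- key(marks$row, marks$position)
  sh$marked <- key(sh$row, sh$position) %in% marked
  proc_targets <- sum(sh$target & sh$in_span)
  commission <- sum(!sh$target & sh$marked & sh$in_span)
  omission <- sum(sh$target & sh$in_span & !sh$marked)
  hit <- sum(sh$target & sh$in_span & sh$marked)
  cp_raw <- (if (cp_literal) proc_targets else hit) - commission
  pct_errors_raw <- if (proc_targets > 0) {
    100 * (commission + omission) / proc_targets
  } else {
    NA_real_
  }
  list(processed_targets = proc_targets,
       commission = commission,
       omission = omission,
       cp_raw = cp_raw,
       pct_errors_raw = pct_errors_raw,
       cp_ss = norm_lookup(norms, "cp", age, cp_raw),
       pct_errors_ss = norm_lookup(norms, "pct_errors", age, pct_errors_raw))
}

#' Score a reaction-time alertness (RTA) trial log
#'
#' Scores the 28-trial non-signal set of a simple visual reaction-time
#' alertness test (stimulus shown without warning, response within 1000 ms;
#' inter-stimulus intervals 2500-6500 ms). A response counts as correct
#' when it occurs within the response window and is not an anticipation
#' (RT below `anticipation_ms`; anticipations are treated as incorrect, a
#' standard RT-hygiene rule). Mean RT and SDRT (sample SD, n-1) use correct
#' responses only; CVRT = 100 * SDRT / mean RT.
#'
#' @param log Data.frame with columns `trial`, `isi_ms`, `rt_ms` (`NA` when
#'   no response), `responded` (logical).
#' @param max_rt_ms Response window (ms).
#' @param anticipation_ms Anticipation threshold (ms).
#' @return A list with `rt_mean_ms`, `sdrt_ms`, `cvrt_pct`, `corr_resp`.
#' @export
score_rta <- function(log, max_rt_ms = 1000, anticipation_ms = 100) {
  stopifnot(all(c("isi_ms", "rt_ms", "responded") %in% names(log)))
  if (nrow(log) != 28) {
    stop("RTA non-signal set must contain exactly 28 trials", call. = FALSE)
  }
  correct <- log$responded & !is.na(log$rt_ms) &
    log$rt_ms <= max_rt_ms & log$rt_ms >= anticipation_ms
  rts <- log$rt_ms[correct]
  if (length(rts) < 2) {
    stop("fewer than 2 correct responses; RT variability undefined",
         call. = FALSE)
  }
  m <- mean(rts)
  s <- stats::sd(rts)
  list(rt_mean_ms = m, sdrt_ms = s, cvrt_pct = 100 * s / m,
       corr_resp = sum(correct))
}
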