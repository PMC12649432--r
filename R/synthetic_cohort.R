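#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a cohort of
#' children performing a wall-throw-and-catch task (10 test trials) with
#' 60 Hz mobile eye tracking, a d2-R attention test and a 28-trial
#' reaction-time alertness test. Marginal means and SDs default to values
#' typical of children with ADHD on these instruments. Cross-domain
#' dependence is induced by a single standard-normal latent attention factor
#' `A`: participant-level eye and attention parameters load on `A` and carry
#' independent residual noise.
#'
#' `r_target` is the population Pearson correlation between the two
#' *observable* participant-level variables mean quiet-eye onset and d2-R
#' %errors standard score. Because observables are attenuated relative to
#' the latent participant parameters (quiet-eye onset is a 10-trial mean
#' with trial-to-trial scatter; d2 errors carry mark-level binomial noise),
#' the generator disattenuates the planted latent correlation by the
#' analytically derived reliability product, so that the pipeline's
#' estimate is centred on `r_target`.
#'
#' @param n_participants Cohort size.
#' @param trials Test trials per participant.
#' @param r_target Planted quiet-eye-onset / %errors-SS population
#'   correlation, in (-0.9, 0.9).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param sample_rate_hz Gaze sampling rate (Hz).
#' @param window_ms Pre-throw window width (ms).
#' @param qe_onset_mean,qe_onset_sd Mean / SD (ms) of the participant-level
#'   mean quiet-eye onset.
#' @param qe_onset_trial_sd Within-participant trial-to-trial SD (ms).
#' @param qe_dur_mean,qe_dur_sd,qe_dur_trial_sd Quiet-eye duration (ms),
#'   analogous.
#' @param fix_dur_mean,fix_dur_sd Participant-level mean filler-fixation
#'   duration (ms) and its between-participant SD; trial durations are
#'   gamma-distributed with shape `fix_dur_shape`.
#' @param fix_dur_shape Gamma shape for filler fixation durations.
#' @param long_gap_prob Probability that an inter-fixation gap is an
#'   unstable-gaze episode (150-350 ms) rather than a 33-50 ms saccade.
#' @param jitter_sd Within-fixation gaze jitter (degrees); 0 gives
#'   noise-free traces.
#' @param invalid_frac Fraction of samples with lost gaze signal.
#' @param d2_err_mean,d2_err_sd Participant-level true d2-R error
#'   percentage, mean and between-participant SD.
#' @param d2_speed_mean,d2_speed_sd Characters processed per 20-s row.
#' @param commission_ratio Commission probability as a fraction of the
#'   omission probability.
#' @param rt_mean,rt_sd,sdrt_mean,sdrt_sd Reaction-time alertness
#'   parameters (ms): participant mean RT and intraindividual SD, with
#'   their between-participant SDs.
#' @param lapse_base Baseline probability of missing a stimulus.
#' @param loadings Named list of secondary loadings on the latent factor
#'   `A` (all in `[0, 1)`): `qe_dur`, `fix_dur`, `d2_speed`, `rt`, `sdrt`,
#'   `lapse`, `catch`. Signs are fixed by the emulated direction of effect
#'   (e.g. higher `A` means shorter quiet-eye duration, faster and steadier
#'   responses, more catches).
#' @return A list of class `cohort_config`, including the derived latent
#'   correlation (`rho_latent`) and the reliability terms used to obtain it.
#' @export
cohort_config <- function(n_participants = 57,
                          trials = 10,
                          r_target = -0.417,
                          seed = NULL,
                          sample_rate_hz = 60,
                          window_ms = 2000,
                          qe_onset_mean = 474.14, qe_onset_sd = 226.73,
                          qe_onset_trial_sd = 150,
                          qe_dur_mean = 754.49, qe_dur_sd = 289.25,
                          qe_dur_trial_sd = 180,
                          fix_dur_mean = 380, fix_dur_sd = 80,
                          fix_dur_shape = 2,
                          long_gap_prob = 0.25,
                          jitter_sd = 0.15,
                          invalid_frac = 0.02,
                          d2_err_mean = 10, d2_err_sd = 5,
                          d2_speed_mean = 44, d2_speed_sd = 5,
                          commission_ratio = 0.25,
                          rt_mean = 356.63, rt_sd = 54.44,
                          sdrt_mean = 55.86, sdrt_sd = 18.95,
                          lapse_base = 0.045,
                          loadings = list(qe_dur = 0.5, fix_dur = 0.35,
                                          d2_speed = 0.4, rt = 0.15,
                                          sdrt = 0.25, lapse = 0.4,
                                          catch = 0.3)) {
  stopifnot(n_participants >= 12, trials >= 1, abs(r_target) < 0.9,
            qe_onset_sd > 0, qe_onset_trial_sd >= 0, d2_err_sd > 0)
  # reliability of the 10-trial mean quiet-eye onset. Trial draws are
  # truncated below (a quiet-eye onset must stay positive and inside the
  # trace), which both adds averaging noise and compresses the tails of the
  # participant distribution; the attenuation of the participant-level
  # correlation is therefore obtained by integrating the truncated-normal
  # trial mean/variance over the latent participant distribution rather
  # than from the plain additive-noise reliability.
  between_var <- qe_onset_sd^2 - qe_onset_trial_sd^2 / trials
  if (between_var <= 0) {
    stop("qe_onset_trial_sd too large for the stated participant-level SD",
         call. = FALSE)
  }
  sb <- sqrt(between_var)
  if (qe_onset_trial_sd > 0) {
    z <- seq(-6, 6, length.out = 1201)
    wgt <- stats::dnorm(z)
    wgt <- wgt / sum(wgt)
    m <- qe_onset_mean + sb * z
    s_t <- qe_onset_trial_sd
    lo <- (40 - m) / s_t
    hi <- (2180 - m) / s_t          # typical feasibility cap inside a trial
    zmass <- stats::pnorm(hi) - stats::pnorm(lo)
    dlo <- stats::dnorm(lo)
    dhi <- stats::dnorm(hi)
    g <- m + s_t * (dlo - dhi) / zmass        # truncated trial mean
    vtr <- s_t^2 * (1 + (lo * dlo - hi * dhi) / zmass -
                      ((dlo - dhi) / zmass)^2)
    eg <- sum(wgt * g)
    cov_mg <- sum(wgt * (m - qe_onset_mean) * g)
    var_pm <- sum(wgt * (g - eg)^2) + sum(wgt * vtr) / trials
    atten_x <- cov_mg / (sb * sqrt(var_pm))
  } else {
    atten_x <- 1
  }
  rel_x <- atten_x^2
  # reliability of the d2 %errors score: mark-level binomial noise
  dt_ratio <- 376 / 308                       # distractors per target, rows 2-13
  frac <- d2_speed_mean / 57
  t_proc <- 308 * frac
  d_proc <- 376 * frac
  p_om <- (d2_err_mean / 100) / (1 + commission_ratio * dt_ratio)
  p_co <- commission_ratio * p_om
  v_bin <- 1e4 * (t_proc * p_om * (1 - p_om) + d_proc * p_co * (1 - p_co)) /
    t_proc^2
  rel_y <- d2_err_sd^2 / (d2_err_sd^2 + v_bin)
  rho_latent <- r_target / (atten_x * sqrt(rel_y))
  if (abs(rho_latent) > 0.95) {
    stop("r_target is not attainable under the configured noise levels",
         call. = FALSE)
  }
  structure(list(
    n_participants = n_participants, trials = trials, r_target = r_target,
    seed = seed, sample_rate_hz = sample_rate_hz, window_ms = window_ms,
    qe_onset_mean = qe_onset_mean, qe_onset_sd = qe_onset_sd,
    qe_onset_between_sd = sqrt(between_var),
    qe_onset_trial_sd = qe_onset_trial_sd,
    qe_dur_mean = qe_dur_mean, qe_dur_sd = qe_dur_sd,
    qe_dur_between_sd = sqrt(max(qe_dur_sd^2 - qe_dur_trial_sd^2 / trials,
                                 1e-6)),
    qe_dur_trial_sd = qe_dur_trial_sd,
    fix_dur_mean = fix_dur_mean, fix_dur_sd = fix_dur_sd,
    fix_dur_shape = fix_dur_shape, long_gap_prob = long_gap_prob,
    jitter_sd = jitter_sd, invalid_frac = invalid_frac,
    d2_err_mean = d2_err_mean, d2_err_sd = d2_err_sd,
    d2_speed_mean = d2_speed_mean, d2_speed_sd = d2_speed_sd,
    commission_ratio = commission_ratio,
    rt_mean = rt_mean, rt_sd = rt_sd,
    sdrt_mean = sdrt_mean, sdrt_sd = sdrt_sd,
    lapse_base = lapse_base, loadings = loadings,
    rel_x = rel_x, rel_y = rel_y, rho_latent = rho_latent
  ), class = "cohort_config")
}

# participant-level latent draws
draw_participant <- function(id, config) {
  A <- stats::rnorm(1)
  w <- sqrt(abs(config$rho_latent))
  mix <- function(wt, sgn) {
    sgn * wt * A + sqrt(1 - wt^2) * stats::rnorm(1)
  }
  ld <- config$loadings
  z_qon <- mix(w, -1)                        # higher A -> earlier QE onset
  z_err <- mix(w, sign(config$r_target))     # sign chosen so SS corr = r_target
  list(
    id = id, A = A,
    age = stats::runif(1, 9, 12),
    clock_offset = stats::runif(1, -5000, 5000),
    qon_mean = config$qe_onset_mean + config$qe_onset_between_sd * z_qon,
    qd_mean = config$qe_dur_mean +
      config$qe_dur_between_sd * mix(ld$qe_dur, -1),
    fd_mean = max(150, config$fix_dur_mean +
                    config$fix_dur_sd * mix(ld$fix_dur, -1)),
    err_pct = max(0.5, config$d2_err_mean + config$d2_err_sd * z_err),
    speed = min(57, max(20, config$d2_speed_mean +
                          config$d2_speed_sd * mix(ld$d2_speed, +1))),
    rt_mu = max(220, config$rt_mean + config$rt_sd * mix(ld$rt, -1)),
    rt_s = max(18, config$sdrt_mean + config$sdrt_sd * mix(ld$sdrt, -1)),
    lapse_p = stats::plogis(stats::qlogis(config$lapse_base) -
                              ld$lapse * A + 0.3 * stats::rnorm(1)),
    catch_p = stats::plogis(0.3 + ld$catch * A)
  )
}

# filler fixation centroid away from the target and the previous centroid
filler_centroid <- function(target, prev) {
  for (i in 1:30) {
    c_ <- c(stats::runif(1, -8, 8), stats::runif(1, -6, 6))
    if (sqrt(sum((c_ - target)^2)) >= 2.5 &&
        (is.null(prev) || sqrt(sum((c_ - prev)^2)) >= 2.5)) {
      return(c_)
    }
  }
  target + c(4, 3)
}

#' Simulate one throwing trial
#'
#' Builds a 2.5-3.5 s gaze trace as alternating fixations
#' (gamma-distributed durations) and saccade gaps (33-50 ms, occasionally a
#' longer unstable-gaze episode), with one target-anchored quiet-eye
#' fixation whose onset precedes movement initiation by the participant's
#' quiet-eye-onset draw and whose centroid lies within 1 degree of the
#' annotated virtual target. Movement initiation is placed about 600 ms
#' before ball release, release near the trace end. Within-fixation
#' Gaussian jitter and a configurable fraction of invalid (signal-loss)
#' samples are added; during gaps the gaze follows a fast zigzag path so no
#' spurious fixation can form.
#'
#' @param p Participant state from the generator (internal list).
#' @param config A [cohort_config()].
#' @param trial_id Trial identifier.
#' @return A list with `trace` ([gaze_trace()]), `events`
#'   ([trial_events()]), and `planted` (quiet-eye onset/duration and filler
#'   fixation table).
#' @export
simulate_trial <- function(p, config, trial_id = "T01") {
  dt <- 1000 / config$sample_rate_hz
  release <- stats::runif(1, 2400, 3400)
  initiation <- release - min(720, max(480, stats::rnorm(1, 600, 40)))
  trace_end <- release + stats::runif(1, 150, 400)

  # quiet-eye onset draw (ms before initiation), redrawn while infeasible
  qon <- NA_real_
  for (i in 1:20) {
    cand <- p$qon_mean + stats::rnorm(1, 0, config$qe_onset_trial_sd)
    if (cand >= 40 && cand <= initiation - 120) {
      qon <- cand
      break
    }
  }
  if (is.na(qon)) {
    warning("quiet-eye onset draw repeatedly infeasible; clamping",
            call. = FALSE)
    qon <- min(max(p$qon_mean, 40), initiation - 120)
  }
  # snap quiet-eye boundaries to the sample grid so that noise-free traces
  # recover the planted values exactly (to one inter-sample interval)
  qe_on <- round((initiation - qon) / dt) * dt
  qon <- initiation - qe_on
  qdur <- max(150, p$qd_mean + stats::rnorm(1, 0, config$qe_dur_trial_sd))
  qe_off <- round(min(qe_on + qdur, trace_end - 60) / dt) * dt

  target <- c(0, -2) + stats::rnorm(2, 0, 0.5)
  repeat {
    off <- stats::rnorm(2, 0, 0.28)
    if (sqrt(sum(off^2)) <= 0.8) break
  }
  qe_centroid <- target + off

  # segment plan: rows of (start, end, type, cx, cy); type 1 fixation, 0 gap
  segs <- matrix(numeric(0), ncol = 5)
  fillers <- NULL
  prev_c <- NULL
  cursor <- 0
  add_fillers <- function(from, until, segs, prev_c) {
    # alternate fixation + gap from `from` until `until`
    cur <- from
    while (cur < until - 45) {
      fd <- min(900, max(60, stats::rgamma(1, shape = config$fix_dur_shape,
                                           scale = p$fd_mean /
                                             config$fix_dur_shape)))
      gap <- if (stats::runif(1) < config$long_gap_prob) {
        stats::runif(1, 150, 350)
      } else {
        stats::runif(1, 33, 50)
      }
      fend <- min(cur + fd, until - 40)
      if (fend - cur >= 60) {
        cc <- filler_centroid(target, prev_c)
        prev_c <- cc
        segs <- rbind(segs, c(cur, fend, 1, cc[1], cc[2]))
        fillers <<- rbind(fillers, c(cur, fend))
      } else if (fend > cur) {
        segs <- rbind(segs, c(cur, fend, 0, NA, NA))
      }
      cur <- min(fend + gap, until)
    }
    list(segs = segs, prev_c = prev_c, cursor = cur)
  }
  pre <- add_fillers(0, qe_on, segs, prev_c)
  segs <- pre$segs
  if (pre$cursor < qe_on) segs <- rbind(segs, c(pre$cursor, qe_on, 0, NA, NA))
  segs <- rbind(segs, c(qe_on, qe_off, 1, qe_centroid[1], qe_centroid[2]))
  post_start <- qe_off + stats::runif(1, 33, 50)
  if (post_start < trace_end) {
    segs <- rbind(segs, c(qe_off, post_start, 0, NA, NA))
    post <- add_fillers(post_start, trace_end, segs, qe_centroid)
    segs <- post$segs
  }
  segs <- segs[order(segs[, 1]), , drop = FALSE]

  # sample the plan at the nominal rate
  t <- seq(0, trace_end, by = dt)
  n <- length(t)
  x <- numeric(n)
  y <- numeric(n)
  seg_idx <- findInterval(t, segs[, 1])
  seg_idx[seg_idx < 1] <- 1
  in_fix <- segs[seg_idx, 3] == 1 & t < segs[seg_idx, 2]
  x[in_fix] <- segs[seg_idx[in_fix], 4]
  y[in_fix] <- segs[seg_idx[in_fix], 5]
  if (config$jitter_sd > 0) {
    x[in_fix] <- x[in_fix] + stats::rnorm(sum(in_fix), 0, config$jitter_sd)
    y[in_fix] <- y[in_fix] + stats::rnorm(sum(in_fix), 0, config$jitter_sd)
  }
  # gap samples: fast zigzag between the surrounding fixation centroids
  gap_i <- which(!in_fix)
  if (length(gap_i) > 0) {
    fix_rows <- which(segs[, 3] == 1)
    fix_starts <- segs[fix_rows, 1]
    for (i in gap_i) {
      k <- findInterval(t[i], fix_starts)
      prv <- if (k >= 1) fix_rows[k] else NA_integer_
      nxt <- if (k + 1 <= length(fix_rows)) fix_rows[k + 1] else NA_integer_
      c1 <- if (is.na(prv)) c(0, 0) else segs[prv, 4:5]
      c2 <- if (is.na(nxt)) c1 + c(5, 0) else segs[nxt, 4:5]
      g0 <- if (is.na(prv)) 0 else segs[prv, 2]
      g1 <- if (is.na(nxt)) trace_end else segs[nxt, 1]
      f <- if (g1 > g0) min(1, max(0, (t[i] - g0) / (g1 - g0))) else 0.5
      base <- c1 + f * (c2 - c1)
      x[i] <- base[1] + ((-1)^i) * 1.1
      y[i] <- base[2] + ((-1)^i) * 0.7
    }
  }
  valid <- rep(TRUE, n)
  if (config$invalid_frac > 0) {
    valid <- stats::runif(n) >= config$invalid_frac
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_

  flash_eye <- 100
  ev <- trial_events(flash_t_eye_ms = flash_eye,
                     flash_t_ext_ms = flash_eye + p$clock_offset,
                     initiation_ms = initiation + p$clock_offset,
                     release_ms = release + p$clock_offset,
                     target_deg = target,
                     catch = stats::runif(1) < p$catch_p,
                     participant_id = p$id, trial_id = trial_id)
  list(
    trace = gaze_trace(t, x, y, valid, participant_id = p$id,
                       trial_id = trial_id),
    events = ev,
    planted = list(qe_onset_ms = qon, qe_duration_ms = qe_off - qe_on,
                   qe_on_t = qe_on, qe_off_t = qe_off,
                   initiation_eye = initiation, release_eye = release,
                   fillers = fillers)
  )
}

#' Simulate attention-test response records for one participant
#'
#' d2-R marks are generated by scanning the fixed stimulus sheet row by
#' row up to the participant's processing speed, with omission and
#' commission probabilities decreasing in the latent attention factor;
#' the reaction-time log draws 28 ex-Gaussian RTs (inter-stimulus
#' intervals uniform on 2500-6500 ms) with occasional lapses and
#' anticipations, responses beyond 1000 ms recorded as missed.
#'
#' @param p Participant state (internal list).
#' @param config A [cohort_config()].
#' @param sheet Sheet from [d2_sheet()].
#' @return A list with `d2_marks` (`row`, `position`), `d2_processed`
#'   (`row`, `last_pos`), and `rta_log`.
#' @export
simulate_attention <- function(p, config, sheet = d2_sheet()) {
  p_om <- (p$err_pct / 100) / (1 + config$commission_ratio * 376 / 308)
  p_co <- config$commission_ratio * p_om
  last_pos <- pmin(57L, pmax(15L, as.integer(round(
    p$speed + stats::rnorm(14, 0, 2)))))
  in_span <- sheet$position <= last_pos[sheet$row]
  u <- stats::runif(nrow(sheet))
  marked <- in_span & ifelse(sheet$target, u >= p_om, u < p_co)
  d2_marks <- data.frame(row = sheet$row[marked],
                         position = sheet$position[marked])
  d2_processed <- data.frame(row = 1:14, last_pos = last_pos)

  n_rta <- 28
  isi <- stats::runif(n_rta, 2500, 6500)
  tau <- 0.4 * p$rt_s
  sig <- p$rt_s * sqrt(1 - 0.16)
  rt <- (p$rt_mu - tau) + stats::rnorm(n_rta, 0, sig) + stats::rexp(n_rta,
                                                                    1 / tau)
  lapse <- stats::runif(n_rta) < p$lapse_p
  anticip <- !lapse & stats::runif(n_rta) < 0.01
  rt[anticip] <- stats::runif(sum(anticip), 30, 95)
  responded <- !lapse & rt <= 1000
  rt[!responded] <- NA_real_
  rta_log <- data.frame(trial = seq_len(n_rta), isi_ms = isi,
                        rt_ms = rt, responded = responded)
  list(d2_marks = d2_marks, d2_processed = d2_processed, rta_log = rta_log)
}

#' Simulate a full synthetic cohort
#'
#' Generates raw, pipeline-ready data for `n_participants`: per-trial gaze
#' traces and kinematic event annotations, d2-R marks over the bundled
#' stimulus sheet, and reaction-time alertness logs, together with the
#' ground truth (latent factor, true participant parameters, planted
#' quiet-eye values per trial).
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_bundle`: `config`, `participants` (each
#'   with `id`, `age`, `trials` = list of [simulate_trial()] outputs,
#'   `d2_marks`, `d2_processed`, `rta_log`), and `ground_truth`
#'   (data.frame of participant-level latent values).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  sheet <- d2_sheet()
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  participants <- vector("list", config$n_participants)
  gt <- vector("list", config$n_participants)
  for (i in seq_along(ids)) {
    p <- draw_participant(ids[i], config)
    trials <- lapply(seq_len(config$trials), function(k) {
      simulate_trial(p, config, trial_id = sprintf("T%02d", k))
    })
    att <- simulate_attention(p, config, sheet)
    participants[[i]] <- list(id = p$id, age = p$age, trials = trials,
                              d2_marks = att$d2_marks,
                              d2_processed = att$d2_processed,
                              rta_log = att$rta_log)
    gt[[i]] <- data.frame(participant_id = p$id, A = p$A,
                          qon_mean = p$qon_mean, qd_mean = p$qd_mean,
                          err_pct = p$err_pct, speed = p$speed,
                          rt_mu = p$rt_mu, rt_s = p$rt_s)
  }
  structure(list(config = config, participants = participants,
                 ground_truth = do.call(rbind, gt)),
            class = "cohort_bundle")
}

#' Write a simulated cohort to the pipeline's input formats
#'
#' Lays out one directory per participant with per-trial gaze CSVs
#' (`gaze_T01.csv`, ...), an `events.csv`, `d2_marks.csv`,
#' `d2_processed.csv` and `rta.csv`, plus cohort-level `participants.csv`
#' (ids and ages) and `ground_truth.json`.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in bundle$participants) {
    pd <- file.path(dir, p$id)
    dir.create(pd, showWarnings = FALSE)
    for (tr in p$trials) {
      write_gaze_table(tr$trace,
                       file.path(pd, sprintf("gaze_%s.csv",
                                             attr(tr$trace, "trial_id"))))
    }
    write_trial_events(lapply(p$trials, `[[`, "events"),
                       file.path(pd, "events.csv"))
    utils::write.csv(p$d2_marks, file.path(pd, "d2_marks.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(p$d2_processed, file.path(pd, "d2_processed.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(p$rta_log, file.path(pd, "rta.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(
    data.frame(participant_id = vapply(bundle$participants, `[[`, "", "id"),
               age_years = vapply(bundle$participants, `[[`, 0, "age")),
    file.path(dir, "participants.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$ground_truth,
                       file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `cohort_bundle` (without generator config; `ground_truth` is
#'   loaded if present).
#' @export
read_cohort <- function(dir) {
  info <- utils::read.csv(file.path(dir, "participants.csv"),
                          stringsAsFactors = FALSE)
  participants <- lapply(seq_len(nrow(info)), function(i) {
    pid <- info$participant_id[i]
    pd <- file.path(dir, pid)
    events <- read_trial_events(file.path(pd, "events.csv"))
    trials <- lapply(events, function(ev) {
      trace <- read_gaze_table(
        file.path(pd, sprintf("gaze_%s.csv", ev$trial_id)),
        participant_id = pid, trial_id = ev$trial_id)
      list(trace = trace, events = ev)
    })
    list(id = pid, age = info$age_years[i], trials = trials,
         d2_marks = utils::read.csv(file.path(pd, "d2_marks.csv")),
         d2_processed = utils::read.csv(file.path(pd, "d2_processed.csv")),
         rta_log = utils::read.csv(file.path(pd, "rta.csv")))
  })
  gt_file <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_file)) jsonlite::fromJSON(gt_file) else NULL
  structure(list(config = NULL, participants = participants,
                 ground_truth = gt),
            class = "cohort_bundle")
}
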