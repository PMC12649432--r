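sheet <- d2_sheet()
norms <- read_norm_table()

test_that("the bundled sheet matches the instrument structure", {
  expect_equal(nrow(sheet), 14 * 57)
  mid <- sheet[sheet$row %in% 2:13, ]
  expect_equal(sum(mid$target), 308)
  expect_equal(sum(!mid$target), 376)
  expect_equal(attr(sheet, "row_time_s"), 20)
  expect_equal(attr(sheet, "total_time_s"), 280)
})

test_that("marking exactly the targets yields error-free scores", {
  marks <- sheet[sheet$target & sheet$row %in% 2:13, c("row", "position")]
  sc <- score_d2(sheet, marks, norms, age = 10)
  expect_equal(sc$commission, 0)
  expect_equal(sc$omission, 0)
  expect_equal(sc$pct_errors_raw, 0)
  expect_equal(sc$cp_raw, sc$processed_targets)
})

test_that("error percentage and CP follow their definitions", {
  # take full rows 2-13 as processed, plant 10 omissions and 5 commissions
  tg <- sheet[sheet$target & sheet$row %in% 2:13, c("row", "position")]
  ds <- sheet[!sheet$target & sheet$row %in% 2:13, c("row", "position")]
  marks <- rbind(tg[-(1:10), ], ds[1:5, ])
  proc <- data.frame(row = 2:13, last_pos = 57)
  sc <- score_d2(sheet, marks, norms, age = 10, processed = proc)
  expect_equal(sc$processed_targets, 308)
  expect_equal(sc$omission, 10)
  expect_equal(sc$commission, 5)
  expect_equal(sc$pct_errors_raw, 100 * 15 / 308)
  expect_equal(sc$cp_raw, (308 - 10) - 5)
  # literal CP variant: all processed targets minus commissions
  sc2 <- score_d2(sheet, marks, norms, age = 10, processed = proc,
                  cp_literal = TRUE)
  expect_equal(sc2$cp_raw, 308 - 5)
})

test_that("rows 1 and 14 are excluded and span violations are caught", {
  tg <- sheet[sheet$target & sheet$row %in% 2:13, c("row", "position")]
  edge <- sheet[sheet$row %in% c(1, 14), c("row", "position")]
  sc <- score_d2(sheet, rbind(tg, edge), norms, age = 10)   # mark everything outside too
  expect_equal(sc$commission, 0)   # row 1/14 marks never count
  expect_error(score_d2(sheet, data.frame(row = 3, position = 58), norms, 10),
               "1..57")
  expect_error(score_d2(sheet, data.frame(row = 3, position = 40), norms, 10,
                        processed = data.frame(row = 3, last_pos = 30)),
               "outside the processed span")
  expect_error(score_d2(sheet, tg, norms, age = 35), "norm band")
})

test_that("scoring is invariant to permuting rows 2-13 wholesale", {
  tg <- sheet[sheet$target & sheet$row %in% 2:13 & sheet$position <= 50,
              c("row", "position")]
  marks <- tg[-(1:7), ]
  proc <- data.frame(row = 2:13, last_pos = 50)
  base <- score_d2(sheet, marks, norms, 10, processed = proc)
  # swap rows 5 and 9 in both sheet and marks
  swap <- function(v) ifelse(v == 5, 9L, ifelse(v == 9, 5L, v))
  sheet2 <- sheet
  sheet2$row <- swap(sheet2$row)
  marks2 <- marks
  marks2$row <- swap(marks2$row)
  perm <- score_d2(sheet2, marks2, norms, 10, processed = proc)
  expect_equal(perm[c("cp_raw", "pct_errors_raw", "commission", "omission")],
               base[c("cp_raw", "pct_errors_raw", "commission", "omission")])
})

test_that("norm lookup is monotone and interpolates", {
  ss <- vapply(c(100, 150, 200, 250), function(r) {
    quieteye:::norm_lookup(norms, "cp", 10, r)
  }, numeric(1))
  expect_true(all(diff(ss) > 0))
  ss_e <- vapply(c(0, 5, 10, 20), function(r) {
    quieteye:::norm_lookup(norms, "pct_errors", 10, r)
  }, numeric(1))
  expect_true(all(diff(ss_e) < 0))
})

rta_log <- function(rt, responded = TRUE) {
  n <- length(rt)
  data.frame(trial = seq_len(n), isi_ms = runif(n, 2500, 6500),
             rt_ms = rt, responded = rep_len(responded, n))
}

test_that("RTA scores reproduce hand-computed cases", {
  base <- rep(500, 25)
  sc <- score_rta(rta_log(c(300, 300, 300, base)))
  # all 28 correct; check with a homogeneous tail removed via direct case
  expect_equal(sc$corr_resp, 28)
  sc2 <- score_rta(rta_log(c(300, 400, rep(NA, 26)),
                           responded = c(TRUE, TRUE, rep(FALSE, 26))))
  expect_equal(sc2$rt_mean_ms, 350)
  expect_equal(sc2$sdrt_ms, sd(c(300, 400)))
  expect_equal(round(sc2$sdrt_ms, 2), 70.71)
  expect_equal(round(sc2$cvrt_pct, 2), 20.2)
  expect_equal(sc2$corr_resp, 2)
})

test_that("anticipations, late and absent responses are incorrect", {
  rt <- c(50, rep(400, 26), NA)
  resp <- c(rep(TRUE, 27), FALSE)
  sc <- score_rta(rta_log(rt, resp))
  expect_equal(sc$corr_resp, 26)         # anticipation and miss excluded
  expect_equal(sc$rt_mean_ms, 400)
  expect_error(score_rta(rta_log(rep(400, 27))), "28 trials")
  expect_error(score_rta(rta_log(c(300, rep(NA, 27)),
                                 c(TRUE, rep(FALSE, 27)))),
               "fewer than 2")
})

test_that("CVRT is invariant to rescaling all reaction times", {
  set.seed(11)
  rt <- runif(28, 250, 600)
  a <- score_rta(rta_log(rt))
  b <- score_rta(rta_log(rt * 1.5))
  expect_equal(a$cvrt_pct, b$cvrt_pct)
})
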