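test_that("response tables round-trip through disk unchanged", {
  des <- english_preset$design
  prof <- simulation_profile(n_participants_per_grade = c("2" = 3L),
                             true_beta = list("2" = c(0.2, 0.7, 0.1)),
                             consonant_error_rate = 0.1, seed = 5)
  records <- simulate_study(prof, des, english_preset$probs)
  expect_gte(nrow(records), 200)
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_responses(records, path)
    back <- read_responses(path, des)
    expect_equal(as.data.frame(back), as.data.frame(records))
  }
})

test_that("validation is fatal with row numbers for bad labels", {
  des <- english_preset$design
  good <- dplyr::bind_rows(rec(), rec(item_id = "hact_02"),
                           rec(item_id = "wact_01", condition = "wact"))
  expect_s3_class(validate_responses(good, des), "tbl_df")

  bad_cond <- dplyr::bind_rows(rec(), rec(item_id = "x", condition = "hactX"))
  expect_error(validate_responses(bad_cond, des), "hactX.*row 2")

  bad_cat <- dplyr::bind_rows(rec(), rec(item_id = "x",
                                         response_category = "zz"))
  expect_error(validate_responses(bad_cat, des), "zz.*row 2")

  dup <- dplyr::bind_rows(rec(), rec())
  expect_error(validate_responses(dup, des), "duplicate.*row 2")

  expect_error(validate_responses(rec()[, -1], des), "participant_id")

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cbind(good, extra = 1), path)
  expect_warning(read_responses(path, des), "unknown column")
})

test_that("participant filter uses a strict threshold", {
  # error counts {2, 6, 11, 0, 20} of 20 trials: only 11/20 and 20/20 > 0.5
  errs <- c(p1 = 2, p2 = 6, p3 = 11, p4 = 0, p5 = 20)
  records <- dplyr::bind_rows(lapply(names(errs), function(p) {
    cats <- c(rep("consonant_error", errs[[p]]), rep("ae", 20 - errs[[p]]))
    trials_for(p, cats)
  }))
  out <- filter_participants(records, 0.5)
  expect_setequal(out$removed$participant_id, c("p3", "p5"))
  expect_false(any(out$records$participant_id %in% c("p3", "p5")))

  # exactly at the threshold is kept
  half <- trials_for("p6", c(rep("consonant_error", 10), rep("ae", 10)))
  expect_equal(nrow(filter_participants(half, 0.5)$removed), 0)

  # 12/20 errors is removed
  most <- trials_for("p7", c(rep("consonant_error", 12), rep("ae", 8)))
  expect_equal(filter_participants(most, 0.5)$removed$participant_id, "p7")

  empty <- filter_participants(records[0, ], 0.5)
  expect_equal(nrow(empty$records), 0)
  expect_equal(nrow(empty$removed), 0)
})

test_that("item filter mirrors the participant filter per item", {
  # item A: 61% errors of 100 trials -> removed; item B: 60% exactly -> kept
  make_item <- function(item, n_err, n_tot) {
    tibble::tibble(
      participant_id = sprintf("p%03d", seq_len(n_tot)), grade = 2L,
      item_id = item, condition = "hact", session = 1L,
      response_category = c(rep("consonant_error", n_err),
                            rep("ae", n_tot - n_err)),
      consonant_correct = c(rep(FALSE, n_err), rep(TRUE, n_tot - n_err)),
      is_error = c(rep(TRUE, n_err), rep(FALSE, n_tot - n_err))
    )
  }
  records <- dplyr::bind_rows(make_item("itA", 61, 100),
                              make_item("itB", 60, 100),
                              make_item("itC", 0, 100))
  out <- filter_items(records, 0.6)
  expect_equal(out$removed$item_id, "itA")
  # brute-force cross-check of every item's error rate
  rates <- tapply(records$is_error, records$item_id, mean)
  expect_setequal(out$removed$item_id, names(rates)[rates > 0.6])
})

test_that("filters are idempotent and the pipeline order is participants-first", {
  prof <- simulation_profile(n_participants_per_grade = c("2" = 6L),
                             true_beta = list("2" = c(0.2, 0.7, 0.1)),
                             consonant_error_rate = 0.4, seed = 9)
  records <- simulate_study(prof, english_preset$design, english_preset$probs)
  once <- filter_participants(records, 0.4)$records
  twice <- filter_participants(once, 0.4)$records
  expect_identical(once, twice)
  once_i <- filter_items(records, 0.4)$records
  expect_identical(once_i, filter_items(once_i, 0.4)$records)

  # apply_filters computes both reports on the raw table, so its result equals
  # participant removal followed by removing the raw-table item report
  both <- apply_filters(records, 0.4, 0.4)
  expect_identical(both$removed_participants,
                   filter_participants(records, 0.4)$removed)
  expect_identical(both$removed_items, filter_items(records, 0.4)$removed)
  manual <- filter_participants(records, 0.4)$records
  manual <- manual[!manual$item_id %in% both$removed_items$item_id, ]
  expect_identical(both$records, manual)
})

test_that("condition summaries average per-participant counts correctly", {
  des <- english_preset$design
  one <- trials_for("p1", rep("ae", 16))
  s <- condition_summary(one, des)
  ae_row <- s[s$category == "ae", ]
  expect_equal(ae_row$mean, 16)
  expect_true(is.na(ae_row$sd))

  two <- dplyr::bind_rows(trials_for("p1", rep("ae", 10)),
                          trials_for("p1", rep("open_o", 2), item_offset = 10),
                          trials_for("p2", rep("ae", 12)))
  s2 <- condition_summary(two, des)
  ae2 <- s2[s2$category == "ae", ]
  expect_equal(ae2$mean, 11)                      # mean of counts {10, 12}
  expect_equal(ae2$sd, stats::sd(c(10, 12)))      # sample SD ~ 1.41
  expect_equal(ae2$sd, sqrt(2), tolerance = 1e-12)
})

test_that("percentage summaries normalise to 100 and counts conserve trials", {
  des <- german_preset$design
  prof <- simulation_profile(
    n_participants_per_grade = c("2" = 4L),
    true_beta = list("2" = c(0.5, 0.4, 0.1)),
    consonant_error_rate = 0.1, seed = 3
  )
  records <- simulate_study(prof, des, german_preset$probs)
  pct <- condition_summary(records, des, as_percentage = TRUE)
  sums <- tapply(pct$mean, pct$condition, sum)
  expect_equal(as.numeric(sums), rep(100, 4), tolerance = 1e-9)

  counts <- condition_summary(records, des, as_percentage = FALSE)
  total <- sum(counts$mean * counts$n_participants)
  expect_equal(total, nrow(records))
})
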