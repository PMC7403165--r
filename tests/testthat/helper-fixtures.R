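# shared builders for the test suite; everything is constructed in code

english_preset <- preset_designs()$english
german_preset <- preset_designs()$german

# one response row with sensible defaults
rec <- function(participant_id = "p1", grade = 2L, item_id = "hact_01",
                condition = "hact", session = 1L, response_category = "ae",
                consonant_correct = TRUE, is_error = FALSE) {
  tibble::tibble(participant_id = participant_id, grade = grade,
                 item_id = item_id, condition = condition, session = session,
                 response_category = response_category,
                 consonant_correct = consonant_correct, is_error = is_error)
}

# n trials for one participant in one condition with given categories
trials_for <- function(participant_id, categories, condition = "hact",
                       grade = 2L, session = 1L, item_offset = 0L) {
  n <- length(categories)
  tibble::tibble(
    participant_id = participant_id, grade = grade,
    item_id = sprintf("%s_%02d", condition, item_offset + seq_len(n)),
    condition = condition, session = session,
    response_category = categories,
    consonant_correct = categories != "consonant_error",
    is_error = categories == "consonant_error"
  )
}

# independent brute-force oracle: loss over a step-0.01 grid on the simplex
simplex_grid <- function(step = 0.01) {
  b1 <- seq(0, 1, by = step)
  grid <- do.call(rbind, lapply(b1, function(x) {
    b2 <- seq(0, 1 - x, by = step)
    cbind(x, b2, pmax(0, 1 - x - b2))
  }))
  unname(grid)
}

grid_min_loss <- function(X, y, grid = simplex_grid()) {
  pred <- X %*% t(grid)                     # cells x points
  min(colSums((pred - y)^2))
}

# observed table (condition, category, proportion) generated exactly from a
# weight vector and a probability table
exact_observed <- function(beta, probs) {
  design <- attr(probs, "design")
  dplyr::bind_rows(lapply(design$conditions, function(cd) {
    p <- predict_probabilities(beta, probs, cd)
    tibble::tibble(condition = cd, category = names(p), proportion = p)
  }))
}
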