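conds <- enumerate_conditions()

# build a small clean listener/salience trial table by hand from items,
# choosing responses by role so the expected proportions are known exactly
make_trials <- function(condition_id, task, role_choices,
                        word_override = NULL, native = TRUE,
                        attention = TRUE) {
  cond <- conds[condition_id, ]
  items <- generate_item_set(cond, length(role_choices), seed = 9)
  rows <- lapply(seq_along(role_choices), function(i) {
    it <- items[i, ]
    ctx <- item_context(it)
    roles <- roles_for_context(ctx, cond$category)
    pos <- position_labels()[match(role_choices[i], roles)]
    word <- if (task == "listener") {
      if (is.null(word_override)) ctx[[cond$word_dim]][2] else word_override
    } else NA_character_
    data.frame(experiment = 1, task = task,
               condition_id = condition_id, item_id = it$item_id,
               shape_left = it$shape_left, color_left = it$color_left,
               shape_middle = it$shape_middle,
               color_middle = it$color_middle,
               shape_right = it$shape_right, color_right = it$color_right,
               word = word, response = pos,
               native_fluent = native, attention_passed = attention,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trial_data", "data.frame")
  out
}

test_that("trial files round-trip and malformed rows go to the rejects", {
  trials <- make_trials("2s2c.b.color", "listener",
                        rep(c("pragmatic", "comp.color"), 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(nrow(back), 10L)
  expect_equal(nrow(attr(back, "rejects")), 0L)
  expect_equal(back$response, trials$response)

  # corrupt one row: unknown shape token
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$shape_left[4] <- "hexagon"
  utils::write.csv(raw, path, row.names = FALSE)
  back <- read_trials(path)
  expect_equal(nrow(back), 9L)
  rejects <- attr(back, "rejects")
  expect_equal(nrow(rejects), 1L)
  expect_match(rejects$reason, "shape_left")

  # schema errors and empty files are loud
  expect_error(read_trials(withr::local_tempfile(lines = "a,b\n1,2")),
               "lacks mapped column")
  expect_error(read_trials(withr::local_tempfile(lines = "a,b")), "empty")
})

test_that("a remapped schema reads files with foreign column names", {
  trials <- make_trials("2s3c.color", "listener", rep("competitor", 4))
  renamed <- as.data.frame(trials)
  names(renamed)[names(renamed) == "response"] <- "chosen_object"
  names(renamed)[names(renamed) == "word"] <- "utterance"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(renamed, path, row.names = FALSE)
  schema <- default_schema()
  schema[["response"]] <- "chosen_object"
  schema[["word"]] <- "utterance"
  back <- read_trials(path, schema = schema)
  expect_equal(back$response, trials$response)
})

test_that("exclusion rules remove the right participants, in order", {
  clean <- make_trials("2s2c.b.color", "listener",
                       rep(c("pragmatic", "comp.color"), 4))
  ex <- apply_exclusions(clean)
  expect_equal(nrow(ex$trials), nrow(clean))
  expect_equal(ex$report$non_native + ex$report$attention +
                 ex$report$non_literal, 0L)

  mixed <- clean
  mixed$native_fluent[1:2] <- FALSE
  mixed$attention_passed[3] <- FALSE
  ex <- apply_exclusions(mixed)
  expect_equal(ex$report$non_native, 2L)
  expect_equal(ex$report$attention, 1L)
  expect_equal(ex$report$n_included, 5L)

  # a listener who picks an object the word excludes is non-literal
  nonlit <- make_trials("2s2c.b.color", "listener",
                        c("comp.shape", "pragmatic"))
  ex <- apply_exclusions(nonlit)
  expect_equal(ex$report$non_literal, 1L)
  expect_equal(nrow(ex$trials), 1L)
})

test_that("aggregation recovers simulated role proportions exactly", {
  choices <- rep(c("pragmatic", "pragmatic", "comp.color", "comp.shape"), 5)
  trials <- make_trials("2s2c.b.shape", "salience", choices)
  tab <- aggregate_choices(trials, "salience", conds)
  got <- tab[tab$condition_id == "2s2c.b.shape", ]
  expect_equal(got$n, rep(20L, 3))
  expect_equal(got$prop[got$role == "pragmatic"], 0.5)
  expect_equal(got$prop[got$role == "comp.color"], 0.25)
  expect_equal(got$prop[got$role == "comp.shape"], 0.25)
  expect_equal(sum(got$prop), 1)

  # permutation invariance over trial order
  perm <- trials[sample(nrow(trials)), ]
  class(perm) <- class(trials)
  expect_equal(aggregate_choices(perm, "salience", conds), tab)

  # conditions with no trials are flagged, not dropped
  empty <- tab[tab$condition_id == "3s3c.color", ]
  expect_equal(empty$n, rep(0L, length(empty$n)))
  expect_true(all(is.na(empty$prop)))
})

test_that("speaker aggregation keeps one shape-word share per condition", {
  cond <- conds["1s1c.shape", ]
  items <- generate_item_set(cond, 6, seed = 4)
  rows <- lapply(seq_len(nrow(items)), function(i) {
    it <- items[i, ]
    word <- if (i <= 4) it$shape_middle else it$color_middle
    data.frame(experiment = 1, task = "speaker",
               condition_id = cond$condition_id, item_id = it$item_id,
               shape_left = it$shape_left, color_left = it$color_left,
               shape_middle = it$shape_middle,
               color_middle = it$color_middle,
               shape_right = it$shape_right, color_right = it$color_right,
               word = word, response = NA_character_,
               native_fluent = TRUE, attention_passed = TRUE,
               stringsAsFactors = FALSE)
  })
  trials <- do.call(rbind, rows)
  tab <- aggregate_choices(trials, "speaker", conds)
  expect_equal(tab$prop_shape[tab$condition_id == "1s1c.shape"], 4 / 6)
  expect_equal(tab$n[tab$condition_id == "1s1c.shape"], 6L)
})

test_that("item-level aggregation keys cells by visual context", {
  trials <- make_trials("2s2c.b.color", "listener",
                        rep(c("pragmatic", "comp.color"), 3))
  tab <- aggregate_choices(trials, "listener", conds, by = "item")
  expect_true(all(c("condition_id", "item_id") %in% names(tab)))
  expect_equal(sort(unique(tab$item_id)), 1:6)
  expect_true(all(tab$n == 1L))
})

test_that("degenerate cells are dropped exactly where semantics force them", {
  preds <- condition_predictions(conds)
  trials <- make_trials("2s2c.b.color", "listener",
                        rep(c("pragmatic", "comp.color"), 6))
  obs <- aggregate_choices(trials, "listener", conds)
  obs <- obs[obs$condition_id == "2s2c.b.color", ]
  p <- preds[preds$condition_id == "2s2c.b.color", ]

  kept <- align_cells(p, obs, drop_degenerate = TRUE)
  expect_equal(nrow(kept), 2L)  # the shape competitor (prediction 0) drops
  expect_false("comp.shape" %in% kept$role)
  all3 <- align_cells(p, obs, drop_degenerate = FALSE)
  expect_equal(nrow(all3), 3L)

  # a trivial condition loses every cell
  p_triv <- preds[preds$condition_id == "1s1c.color", ]
  expect_true(all(p_triv$degenerate))

  # key mismatches are an error naming the offending cells
  expect_error(align_cells(preds[preds$condition_id == "2s3c.color", ],
                           obs, drop_degenerate = FALSE),
               "mismatch")
})
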