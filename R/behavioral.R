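#' Default column mapping for trial-level CSV files
#'
#' Trial files carry one row per participant (the paradigm is one-shot:
#' every participant contributes a single trial). The reader works through
#' a schema, a named character vector mapping the canonical field names used
#' internally to the column names found in the file, so files with other
#' dialects can be read by editing the mapping.
#'
#' Canonical fields: `experiment`, `task` (speaker/salience/listener),
#' `condition_id`, `item_id`, the six context columns `shape_left`,
#' `color_left`, `shape_middle`, `color_middle`, `shape_right`,
#' `color_right`, `word` (the word shown to a listener, or chosen by a
#' speaker; empty for salience), `response` (the position chosen in the
#' salience/listener tasks; empty for speaker), `native_fluent` and
#' `attention_passed` (exclusion metadata).
#'
#' @return Named character vector (canonical name -> file column).
#' @export
default_schema <- function() {
  fields <- c("experiment", "task", "condition_id", "item_id",
              "shape_left", "color_left", "shape_middle", "color_middle",
              "shape_right", "color_right", "word", "response",
              "native_fluent", "attention_passed")
  stats::setNames(fields, fields)
}

#' Read trial-level behavioral data
#'
#' Reads a CSV of one-shot trials and validates each row against the active
#' vocabulary. Malformed rows (unknown task, feature tokens outside the
#' vocabulary, an invalid response position, a missing word where the task
#' requires one) are not silently dropped: they are collected in a rejects
#' table attached as the `"rejects"` attribute, with one reason per row.
#'
#' @param path CSV file path (header row, comma separated).
#' @param schema Column mapping, see [default_schema()].
#' @param vocab A [vocabulary()].
#' @return A data frame of class `trial_data` with canonical column names;
#'   `attr(, "rejects")` holds the rejected rows and their reasons.
#' @export
read_trials <- function(path, schema = default_schema(),
                        vocab = default_vocabulary()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty trial file: ", path, call. = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing) > 0L) {
    stop("trial file lacks mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  trials <- raw[, unname(schema)]
  names(trials) <- names(schema)
  validate_trials(trials, vocab)
}

validate_trials <- function(trials, vocab = default_vocabulary()) {
  trials$task <- tolower(as.character(trials$task))
  trials$word <- as.character(trials$word)
  trials$response <- as.character(trials$response)
  trials$native_fluent <- as.logical(trials$native_fluent)
  trials$attention_passed <- as.logical(trials$attention_passed)

  reason <- character(nrow(trials))
  bad <- function(cond, why) ifelse(cond & reason == "", why, reason)
  reason <- bad(!trials$task %in% c("speaker", "salience", "listener"),
                "unknown task")
  for (col in grep("^shape_", names(trials), value = TRUE)) {
    reason <- bad(!trials[[col]] %in% vocab$shape,
                  paste("invalid token in", col))
  }
  for (col in grep("^color_", names(trials), value = TRUE)) {
    reason <- bad(!trials[[col]] %in% vocab$color,
                  paste("invalid token in", col))
  }
  needs_word <- trials$task %in% c("speaker", "listener")
  known_word <- trials$word %in% c(vocab$shape, vocab$color)
  reason <- bad(needs_word & !known_word, "missing or unknown word")
  needs_resp <- trials$task %in% c("salience", "listener")
  ok_resp <- trials$response %in% position_labels()
  reason <- bad(needs_resp & !ok_resp, "invalid response position")
  reason <- bad(is.na(trials$native_fluent) | is.na(trials$attention_passed),
                "missing exclusion flags")

  keep <- reason == ""
  rejects <- trials[!keep, , drop = FALSE]
  if (nrow(rejects) > 0L) rejects$reason <- reason[!keep]
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  class(out) <- c("trial_data", "data.frame")
  out
}

#' @rdname read_trials
#' @param trials A `trial_data` data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' Apply participant exclusion rules
#'
#' Removes, in order: participants who self-identified as non-native or
#' non-fluent speakers; participants who failed one or both attention
#' checks; and listener-task participants whose chosen object does not
#' match the literal meaning of the word they were shown (a response no
#' literal or pragmatic interpretation licenses). Each category is counted
#' in the report; the categories are disjoint because the rules apply
#' sequentially.
#'
#' @param trials A `trial_data` data frame.
#' @param vocab A [vocabulary()].
#' @return A list with `trials` (the included rows) and `report` (counts:
#'   `n_input`, `non_native`, `attention`, `non_literal`, `n_included`).
#' @export
apply_exclusions <- function(trials, vocab = default_vocabulary()) {
  n_input <- nrow(trials)
  keep <- trials$native_fluent
  non_native <- sum(!keep)
  trials <- trials[keep, , drop = FALSE]

  keep <- trials$attention_passed
  attention <- sum(!keep)
  trials <- trials[keep, , drop = FALSE]

  non_literal <- 0L
  if (any(trials$task == "listener")) {
    lit_ok <- rep(TRUE, nrow(trials))
    for (i in which(trials$task == "listener")) {
      ctx <- item_context(trials[i, ], vocab)
      pos <- match(trials$response[i], position_labels())
      lit_ok[i] <- truth_value(trials$word[i], context_object(ctx, pos),
                               vocab) == 1L
    }
    non_literal <- sum(!lit_ok)
    trials <- trials[lit_ok, , drop = FALSE]
  }
  rownames(trials) <- NULL
  class(trials) <- c("trial_data", "data.frame")
  list(trials = trials,
       report = list(n_input = n_input, non_native = non_native,
                     attention = attention, non_literal = non_literal,
                     n_included = nrow(trials)))
}

#' Aggregate trials into condition-level choice proportions
#'
#' Computes mean behavioral responses per condition. For the salience and
#' listener tasks the unit is the object role (see [roles_for_context()]),
#' so mirrored items collapse into the same cells; proportions per
#' condition sum to 1 over roles. For the speaker task one value is kept
#' per condition: the proportion of participants choosing the
#' shape-dimension word (the color-word proportion is its complement).
#'
#' With `by = "item"` the aggregation keys are (condition, item) instead,
#' the unit used when every distinct visual context is analysed separately.
#'
#' @param trials A `trial_data` data frame (post-exclusion).
#' @param task `"speaker"`, `"salience"` or `"listener"`; rows of other
#'   tasks are ignored.
#' @param conditions Condition set, used to enumerate the role universe and
#'   to flag conditions with no trials (`n = 0`, `prop = NA`).
#' @param by Aggregation unit: `"condition"` (default) or `"item"`.
#' @param vocab A [vocabulary()].
#' @return A data frame of class `choice_table`. For salience/listener:
#'   columns `condition_id` (, `item_id`), `role`, `n`, `prop`. For
#'   speaker: `condition_id`, `n`, `prop_shape`.
#' @export
aggregate_choices <- function(trials, task, conditions = enumerate_conditions(),
                              by = c("condition", "item"),
                              vocab = default_vocabulary()) {
  by <- match.arg(by)
  task <- match.arg(task, c("speaker", "salience", "listener"))
  trials <- trials[trials$task == task, , drop = FALSE]

  if (task == "speaker") {
    out <- lapply(conditions$condition_id, function(id) {
      g <- trials[trials$condition_id == id, , drop = FALSE]
      n <- nrow(g)
      prop <- if (n == 0L) NA_real_ else {
        mean(vapply(g$word, word_dimension, character(1),
                    vocab = vocab) == "shape")
      }
      data.frame(condition_id = id, n = n, prop_shape = prop,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    class(res) <- c("choice_table", "data.frame")
    attr(res, "task") <- task
    attr(res, "by") <- "condition"
    return(res)
  }

  if (nrow(trials) > 0L) {
    chosen_role <- character(nrow(trials))
    for (i in seq_len(nrow(trials))) {
      row <- trials[i, ]
      cond <- find_condition(row$condition_id, conditions)
      ctx <- item_context(row, vocab)
      roles <- roles_for_context(ctx, cond$category)
      chosen_role[i] <- roles[match(row$response, position_labels())]
    }
    trials$.role <- chosen_role
  }

  keys <- if (by == "condition") {
    data.frame(condition_id = conditions$condition_id,
               stringsAsFactors = FALSE)
  } else {
    unique(trials[, c("condition_id", "item_id"), drop = FALSE])
  }
  out <- lapply(seq_len(nrow(keys)), function(k) {
    id <- keys$condition_id[k]
    cond <- find_condition(id, conditions)
    role_set <- sort(unique(c(cond$role_left, cond$role_middle,
                              cond$role_right)))
    g <- trials[trials$condition_id == id, , drop = FALSE]
    if (by == "item") g <- g[g$item_id == keys$item_id[k], , drop = FALSE]
    n <- nrow(g)
    props <- if (n == 0L) rep(NA_real_, length(role_set)) else {
      as.numeric(table(factor(g$.role, levels = role_set)) / n)
    }
    cbind(keys[k, , drop = FALSE],
          data.frame(role = role_set, n = n, prop = props,
                     stringsAsFactors = FALSE),
          row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("choice_table", "data.frame")
  attr(res, "task") <- task
  attr(res, "by") <- by
  res
}

#' Pair model predictions with observed proportions
#'
#' Joins a prediction table with an observed choice table on the
#' (condition [, item], role) keys, producing the paired vectors that the
#' correlation-based model fits consume. With `drop_degenerate = TRUE`
#' (the conservative comparison), cells whose prediction is forced to 0 or
#' 100% by literal semantics alone -- the word excludes the object, or
#' uniquely identifies it -- are removed, because every model under
#' consideration agrees on them.
#'
#' @param predictions A `prediction_table` (see [condition_predictions()]).
#' @param observations A `choice_table` from the listener or salience task.
#' @param drop_degenerate Remove literally-forced 0/1 cells. Default `TRUE`.
#' @return A data frame with the key columns, `category`, `word_dim`, the
#'   model columns `rsa`, `literal`, `rsa_uniform`, the `degenerate` flag,
#'   and the observed `prop` and `n`. Conditions with no observations
#'   (`n = 0`) are dropped with a warning.
#' @export
align_cells <- function(predictions, observations, drop_degenerate = TRUE) {
  keys <- intersect(c("condition_id", "item_id"), names(predictions))
  if (!all(keys %in% names(observations))) {
    stop("prediction and observation tables use different aggregation units",
         call. = FALSE)
  }
  empty <- observations$n == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d cell(s) with no observations",
                    sum(empty)), call. = FALSE)
    observations <- observations[!empty, , drop = FALSE]
  }
  merged <- merge(predictions, observations[, c(keys, "role", "n", "prop")],
                  by = c(keys, "role"), all = TRUE)
  unmatched <- is.na(merged$rsa) | is.na(merged$prop)
  if (any(unmatched)) {
    off <- merged[unmatched, c(keys, "role"), drop = FALSE]
    stop("prediction/observation key mismatch for: ",
         paste(apply(off, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  if (drop_degenerate) {
    merged <- merged[!merged$degenerate, , drop = FALSE]
  }
  ord <- do.call(order, merged[c(keys, "role")])
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}
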