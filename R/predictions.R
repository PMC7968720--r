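#' Empirical salience prior for a condition
#'
#' The prior probability of referring to each object, operationalised as
#' its contextual salience: the observed choice proportions from the
#' salience task, used unsmoothed. Proportions are looked up per object
#' role and returned in the position order of the condition's canonical
#' context.
#'
#' @param salience_table A `choice_table` aggregated from salience trials
#'   (per condition).
#' @param condition A `condition_id` or condition row.
#' @param conditions Condition set.
#' @return Numeric prior over (left, middle, right) of the canonical
#'   context, summing to 1.
#' @export
empirical_prior <- function(salience_table, condition,
                            conditions = enumerate_conditions()) {
  row <- find_condition(condition, conditions)
  tab <- salience_table[salience_table$condition_id == row$condition_id, ,
                        drop = FALSE]
  if (nrow(tab) == 0L || all(is.na(tab$prop))) {
    stop(sprintf("no salience data for condition '%s'", row$condition_id),
         call. = FALSE)
  }
  roles <- c(row$role_left, row$role_middle, row$role_right)
  prior <- tab$prop[match(roles, tab$role)]
  if (anyNA(prior)) {
    stop(sprintf("salience table lacks role(s) %s for condition '%s'",
                 paste(roles[is.na(prior)], collapse = ", "),
                 row$condition_id), call. = FALSE)
  }
  check_prior(prior)
}

# rsa / literal / uniform-prior-rsa predictions for one context
predict_one <- function(ctx, word, prior_pos, alpha, vocab) {
  ext <- word_extension(word, ctx, vocab)
  list(rsa = rsa_posterior(word, ctx, prior_pos, alpha, vocab),
       literal = literal_posterior(word, ctx, prior_pos, vocab),
       rsa_uniform = rsa_posterior(word, ctx, uniform_prior(), alpha, vocab),
       degenerate = ext == 0L | sum(ext) == 1L)
}

#' Model predictions per condition
#'
#' Computes, for every condition, the predicted choice distribution over
#' object roles under three models: the RSA pragmatic listener, the
#' baseline literal listener (both under the supplied prior), and the RSA
#' listener under a uniform prior (used to isolate the contribution of the
#' salience prior). Cells forced to 0 or 1 by literal semantics alone are
#' flagged `degenerate`.
#'
#' @param conditions Condition set from [enumerate_conditions()].
#' @param prior `NULL` for a uniform prior, or a salience `choice_table`
#'   (per condition) supplying empirical priors.
#' @param alpha Speaker rationality used inside RSA. Default 1, the basic
#'   model.
#' @param vocab A [vocabulary()].
#' @return A data frame of class `prediction_table`: `condition_id`,
#'   `category`, `word_dim`, `role`, `rsa`, `literal`, `rsa_uniform`,
#'   `degenerate`.
#' @examples
#' preds <- condition_predictions(enumerate_conditions())
#' subset(preds, condition_id == "2s2c.b.color")
#' @export
condition_predictions <- function(conditions = enumerate_conditions(),
                                  prior = NULL, alpha = 1,
                                  vocab = default_vocabulary()) {
  out <- lapply(seq_len(nrow(conditions)), function(i) {
    row <- conditions[i, ]
    ctx <- condition_context_row(row)
    roles <- c(row$role_left, row$role_middle, row$role_right)
    prior_pos <- if (is.null(prior)) uniform_prior() else {
      empirical_prior(prior, row, conditions)
    }
    p <- predict_one(ctx, row$word, prior_pos, alpha, vocab)
    data.frame(condition_id = row$condition_id, category = row$category,
               word_dim = row$word_dim, role = roles,
               rsa = p$rsa, literal = p$literal,
               rsa_uniform = p$rsa_uniform, degenerate = p$degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("prediction_table", "data.frame")
  res
}

#' Model predictions per visual context
#'
#' Like [condition_predictions()], but computed on each generated item's
#' own context, keyed by (condition, item). This is the unit used when
#' every distinct visual context is analysed separately rather than
#' averaged into its condition.
#'
#' @param items An `item_set` data frame.
#' @param conditions Condition set.
#' @param prior `NULL` for uniform, or a salience `choice_table`; a table
#'   aggregated `by = "item"` supplies one prior per context, a
#'   per-condition table one prior per condition.
#' @param alpha Speaker rationality.
#' @param vocab A [vocabulary()].
#' @return A `prediction_table` with an additional `item_id` key column.
#' @export
item_predictions <- function(items, conditions = enumerate_conditions(),
                             prior = NULL, alpha = 1,
                             vocab = default_vocabulary()) {
  by_item_prior <- !is.null(prior) && "item_id" %in% names(prior)
  out <- lapply(seq_len(nrow(items)), function(i) {
    it <- items[i, ]
    cond <- find_condition(it$condition_id, conditions)
    ctx <- item_context(it, vocab)
    roles <- roles_for_context(ctx, cond$category)
    word <- ctx[[cond$word_dim]][ctx$target]
    prior_pos <- if (is.null(prior)) {
      uniform_prior()
    } else if (by_item_prior) {
      tab <- prior[prior$condition_id == it$condition_id &
                   prior$item_id == it$item_id, , drop = FALSE]
      if (nrow(tab) == 0L || anyNA(tab$prop)) {
        stop(sprintf("no salience data for item %s/%s", it$condition_id,
                     it$item_id), call. = FALSE)
      }
      check_prior(tab$prop[match(roles, tab$role)])
    } else {
      # per-condition salience, mapped onto this item's role layout
      prior_roles <- empirical_prior(prior, cond, conditions)
      cond_roles <- c(cond$role_left, cond$role_middle, cond$role_right)
      check_prior(prior_roles[match(roles, cond_roles)])
    }
    p <- predict_one(ctx, word, prior_pos, alpha, vocab)
    data.frame(condition_id = it$condition_id, item_id = it$item_id,
               category = cond$category, word_dim = cond$word_dim,
               role = roles, rsa = p$rsa, literal = p$literal,
               rsa_uniform = p$rsa_uniform, degenerate = p$degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("prediction_table", "data.frame")
  res
}

#' Speaker-model predictions per condition
#'
#' Predicted probability that an informative speaker chooses the
#' shape-dimension word for the (middle) target of each condition's
#' canonical context.
#'
#' @inheritParams condition_predictions
#' @return Data frame with `condition_id` and `pred_shape`.
#' @export
speaker_predictions <- function(conditions = enumerate_conditions(),
                                alpha = 1, vocab = default_vocabulary()) {
  pred <- vapply(seq_len(nrow(conditions)), function(i) {
    row <- conditions[i, ]
    ctx <- condition_context_row(row)
    p <- informative_speaker(ctx$target, ctx, alpha, vocab)
    unname(p[1])  # words_for() lists the shape word first
  }, numeric(1))
  data.frame(condition_id = conditions$condition_id, pred_shape = pred,
             stringsAsFactors = FALSE)
}
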