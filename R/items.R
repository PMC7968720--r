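#' Generate a counterbalanced item set for a condition
#'
#' Randomly generates `n_items` visual contexts instantiating a condition's
#' feature pattern, the way experimental items are produced for each of the
#' 24 conditions:
#'
#' * the target's shape-color combination cycles through a random order of
#'   all unique combinations in the vocabulary, so each combination occurs
#'   an approximately equal number of times as the target;
#' * features not constrained by the condition (e.g. the color of a
#'   distractor that shares nothing with the target) are drawn uniformly
#'   from the remaining alphabet;
#' * for conditions whose left and right objects differ, items alternate
#'   between the canonical and the mirrored left/right arrangement, giving
#'   an exact half/half split (up to one item when `n_items` is odd).
#'
#' Generation is deterministic given `seed`.
#'
#' @param condition A `condition_id` string or one row of
#'   [enumerate_conditions()].
#' @param n_items Number of items (>= 1).
#' @param seed Integer seed.
#' @param vocab A [vocabulary()].
#' @param conditions The condition set to resolve `condition` in.
#' @return A data frame of class `item_set`: columns `item_id`,
#'   `condition_id`, `mirrored`, and the six feature columns `shape_left`
#'   .. `color_right`.
#' @examples
#' items <- generate_item_set("2s2c.b.color", 6, seed = 1)
#' items$mirrored
#' @export
generate_item_set <- function(condition, n_items, seed,
                              vocab = default_vocabulary(),
                              conditions = enumerate_conditions(vocab)) {
  if (length(vocab$shape) < 3L || length(vocab$color) < 3L) {
    # two distinct non-target tokens per dimension may be required
    stop("vocabulary too small to instantiate all feature constraints",
         call. = FALSE)
  }
  row <- find_condition(condition, conditions)
  if (n_items < 1L) stop("n_items must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  combos <- expand.grid(shape = vocab$shape, color = vocab$color,
                        stringsAsFactors = FALSE)
  order_ <- sample(nrow(combos))
  sh <- matrix(NA_character_, nrow = n_items, ncol = 3)
  co <- matrix(NA_character_, nrow = n_items, ncol = 3)
  mirrored <- seq_len(n_items) %% 2L == 0L
  for (i in seq_len(n_items)) {
    combo <- combos[order_[((i - 1L) %% nrow(combos)) + 1L], ]
    s0 <- combo$shape
    c0 <- combo$color
    other_s <- setdiff(vocab$shape, s0)
    other_c <- setdiff(vocab$color, c0)
    s1 <- sample(other_s, 1L)
    s2 <- sample(setdiff(other_s, s1), 1L)
    c1 <- sample(other_c, 1L)
    c2 <- sample(setdiff(other_c, c1), 1L)
    ctx <- canonical_context(row$basic_type, row$qualifier, vocab,
                             target_shape = s0, target_color = c0,
                             s1 = s1, s2 = s2, c1 = c1, c2 = c2)
    sh[i, ] <- if (mirrored[i]) rev(ctx$shape) else ctx$shape
    co[i, ] <- if (mirrored[i]) rev(ctx$color) else ctx$color
  }
  items <- data.frame(
    item_id = seq_len(n_items), condition_id = row$condition_id,
    mirrored = mirrored,
    shape_left = sh[, 1], color_left = co[, 1],
    shape_middle = sh[, 2], color_middle = co[, 2],
    shape_right = sh[, 3], color_right = co[, 3],
    stringsAsFactors = FALSE)
  class(items) <- c("item_set", "data.frame")
  items
}

# visual_context from one item row (also accepts trial rows, which carry
# the same six feature columns)
item_context <- function(row, vocab = default_vocabulary()) {
  visual_context(c(row$shape_left, row$shape_middle, row$shape_right),
                 c(row$color_left, row$color_middle, row$color_right),
                 vocab)
}

#' Write and read item sets as tabular text
#'
#' Serializes items with one row per object: `item_id`, `condition_id`,
#' `position` (left/middle/right), `shape`, `color`, `is_target`. The
#' target is always the middle object. `read_contexts()` inverts the
#' format.
#'
#' @param items An `item_set` data frame (see [generate_item_set()]).
#' @param path File path for the CSV.
#' @return `write_contexts()` returns `path` invisibly; `read_contexts()`
#'   returns an `item_set` data frame.
#' @export
write_contexts <- function(items, path) {
  pos <- position_labels()
  rows <- lapply(seq_len(nrow(items)), function(i) {
    r <- items[i, ]
    data.frame(item_id = r$item_id, condition_id = r$condition_id,
               position = pos,
               shape = c(r$shape_left, r$shape_middle, r$shape_right),
               color = c(r$color_left, r$color_middle, r$color_right),
               is_target = pos == "middle", stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contexts
#' @export
read_contexts <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("item_id", "condition_id", "position", "shape", "color",
              "is_target")
  missing <- setdiff(needed, names(long))
  if (length(missing) > 0L) {
    stop("context file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(long$condition_id, long$item_id, drop = TRUE)
  out <- lapply(split(long, key), function(g) {
    g <- g[match(position_labels(), g$position), ]
    if (anyNA(g$position)) {
      stop("each item needs exactly one object per position", call. = FALSE)
    }
    data.frame(item_id = g$item_id[1], condition_id = g$condition_id[1],
               mirrored = NA,
               shape_left = g$shape[1], color_left = g$color[1],
               shape_middle = g$shape[2], color_middle = g$color[2],
               shape_right = g$shape[3], color_right = g$color[3],
               stringsAsFactors = FALSE)
  })
  items <- do.call(rbind, out)
  items <- items[order(items$condition_id, items$item_id), ]
  rownames(items) <- NULL
  class(items) <- c("item_set", "data.frame")
  items
}
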