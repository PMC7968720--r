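#' Classify the listener's reasoning problem in a context
#'
#' Given a visual context and the dimension of the word the listener
#' observes (the word is the target's own feature on that dimension, and the
#' target is always the middle object), the condition falls into one of four
#' pragmatic categories, determined algorithmically from the model
#' posteriors under a uniform prior:
#'
#' * `trivial` -- the word's extension is a single object; literal meaning
#'   alone resolves the referent.
#' * `ambiguous` -- the RSA posterior equals the literal posterior; no
#'   amount of speaker reasoning helps.
#' * `solvable` -- the RSA posterior has a strict unique maximum that the
#'   literal listener does not share: pragmatic reasoning can single out a
#'   referent.
#' * `reducible` -- the word fits all three objects but exactly two tie for
#'   the RSA maximum: speaker reasoning demotes one object without
#'   resolving the rest.
#'
#' Equality of distributions is tested cell-wise with an absolute tolerance
#' of 1e-9; all quantities involved are small exact rationals represented in
#' floating point, so this tolerance is conservative.
#'
#' @param context A [visual_context()]. The middle object is the speaker's
#'   target.
#' @param word_dimension `"shape"` or `"color"`: the dimension of the word
#'   shown to the listener.
#' @param vocab A [vocabulary()].
#' @return One of `"trivial"`, `"ambiguous"`, `"solvable"`, `"reducible"`.
#' @examples
#' classify_condition(
#'   visual_context(c("boot", "boot", "mitt"), c("blue", "green", "blue")),
#'   "color")  # solvable
#' classify_condition(
#'   visual_context(c("boot", "boot", "mitt"), c("blue", "blue", "blue")),
#'   "color")  # reducible
#' @export
classify_condition <- function(context, word_dimension,
                               vocab = default_vocabulary()) {
  word_dimension <- match.arg(word_dimension, c("shape", "color"))
  word <- context[[word_dimension]][context$target]
  ext <- word_extension(word, context, vocab)
  if (ext[context$target] != 1L) {
    stop("word does not literally apply to the target", call. = FALSE)
  }
  n_ext <- sum(ext)
  if (n_ext == 1L) return("trivial")
  tol <- 1e-9
  rsa <- rsa_posterior(word, context, alpha = 1, vocab = vocab)
  lit <- literal_posterior(word, context, vocab = vocab)
  if (max(abs(rsa - lit)) < tol) return("ambiguous")
  mx <- max(rsa)
  n_at_max <- sum(rsa > mx - tol)
  if (n_ext == 3L && n_at_max == 2L) return("reducible")
  if (n_at_max == 1L) return("solvable")
  # word fits two objects and RSA ties on them differently from literal:
  # cannot arise with two-word alternative sets, but classify defensively
  "ambiguous"
}

# ---------------------------------------------------------------------------
# The 24-condition space
#
# Basic context types are named #s#c: the number of objects (including the
# target) sharing the target's shape, and sharing its color. 2s2c splits
# into 2s2c.a (one competitor shares both features) and 2s2c.b (one shares
# shape, the other color). Competitor feature overlap is manipulated only
# for the (type, listener word) combinations where it changes the RSA
# predictions: (1s2c, color), (2s1c, shape), (1s3c, color), (3s1c, shape).
# Qualifiers: ss/ds = competitors have the same/different shape,
# sc/dc = same/different color.
# ---------------------------------------------------------------------------

basic_types <- function() {
  c("1s1c", "1s2c", "2s1c", "1s3c", "3s1c",
    "2s2c.a", "2s2c.b", "2s3c", "3s2c", "3s3c")
}

# qualifier levels for a (type, word) combination; "none" when competitor
# overlap does not change the RSA predictions
qualifiers_for <- function(basic_type, word_dim) {
  key <- paste(basic_type, word_dim)
  switch(key,
         "1s2c color" = c("ss", "ds"),
         "2s1c shape" = c("sc", "dc"),
         "1s3c color" = c("ss", "ds"),
         "3s1c shape" = c("sc", "dc"),
         "none")
}

condition_id <- function(basic_type, qualifier, word_dim) {
  if (qualifier == "none") paste(basic_type, word_dim, sep = ".")
  else paste(basic_type, qualifier, word_dim, sep = ".")
}

# Canonical context for a condition, built from fixed representative tokens.
# Free features (those whose identity does not affect any model prediction
# for the condition) take fixed distinct defaults here; generate_item_set()
# randomizes them.
canonical_context <- function(basic_type, qualifier,
                              vocab = default_vocabulary(),
                              target_shape = vocab$shape[1],
                              target_color = vocab$color[1],
                              s1 = NULL, s2 = NULL, c1 = NULL, c2 = NULL) {
  s0 <- target_shape
  c0 <- target_color
  other_s <- setdiff(vocab$shape, s0)
  other_c <- setdiff(vocab$color, c0)
  if (is.null(s1)) s1 <- other_s[1]
  if (is.null(s2)) s2 <- setdiff(other_s, s1)[1]
  if (is.null(c1)) c1 <- other_c[1]
  if (is.null(c2)) c2 <- setdiff(other_c, c1)[1]
  obj <- function(s, c) c(s, c)
  pair <- switch(paste(basic_type, qualifier),
    "1s1c none"   = list(obj(s1, c1), obj(s2, c2)),
    "1s2c ss"     = list(obj(s1, c0), obj(s1, c1)),
    "1s2c ds"     = ,
    "1s2c none"   = list(obj(s1, c0), obj(s2, c1)),
    "2s1c sc"     = list(obj(s0, c1), obj(s1, c1)),
    "2s1c dc"     = ,
    "2s1c none"   = list(obj(s0, c1), obj(s1, c2)),
    "1s3c ss"     = list(obj(s1, c0), obj(s1, c0)),
    "1s3c ds"     = ,
    "1s3c none"   = list(obj(s1, c0), obj(s2, c0)),
    "3s1c sc"     = list(obj(s0, c1), obj(s0, c1)),
    "3s1c dc"     = ,
    "3s1c none"   = list(obj(s0, c1), obj(s0, c2)),
    "2s2c.a none" = list(obj(s0, c0), obj(s1, c1)),
    "2s2c.b none" = list(obj(s1, c0), obj(s0, c1)),
    "2s3c none"   = list(obj(s0, c0), obj(s1, c0)),
    "3s2c none"   = list(obj(s0, c0), obj(s0, c1)),
    "3s3c none"   = list(obj(s0, c0), obj(s0, c0)),
    stop(sprintf("unknown context pattern '%s' + '%s'", basic_type,
                 qualifier), call. = FALSE))
  left <- pair[[1]]
  right <- pair[[2]]
  visual_context(c(left[1], s0, right[1]), c(left[2], c0, right[2]), vocab)
}

#' Enumerate the full experimental condition space
#'
#' Builds the 24 conditions spanned by the 10 basic context types, the
#' listener-word dimension (shape or color), and -- only where it changes
#' the RSA predictions -- the feature overlap between competitors. Each
#' condition's pragmatic category is computed by [classify_condition()] on
#' its canonical context, never hard-coded.
#'
#' @param vocab A [vocabulary()].
#' @return A data frame of class `condition_set` with one row per condition:
#'   `condition_id`, `basic_type`, `qualifier`, `word_dim`, `category`, the
#'   canonical context (`shape_left` .. `color_right`), the canonical word
#'   token, and the role of each position (`role_left`, `role_middle`,
#'   `role_right`).
#' @examples
#' conds <- enumerate_conditions()
#' nrow(conds)              # 24
#' table(conds$category)    # 6 trivial, 10 ambiguous, 4 solvable, 4 reducible
#' @export
enumerate_conditions <- function(vocab = default_vocabulary()) {
  rows <- list()
  for (bt in basic_types()) {
    for (wd in c("shape", "color")) {
      for (q in qualifiers_for(bt, wd)) {
        ctx <- canonical_context(bt, q, vocab)
        cat_ <- classify_condition(ctx, wd, vocab)
        roles <- roles_for_context(ctx, cat_)
        rows[[length(rows) + 1L]] <- data.frame(
          condition_id = condition_id(bt, q, wd),
          basic_type = bt, qualifier = q, word_dim = wd, category = cat_,
          shape_left = ctx$shape[1], color_left = ctx$color[1],
          shape_middle = ctx$shape[2], color_middle = ctx$color[2],
          shape_right = ctx$shape[3], color_right = ctx$color[3],
          word = ctx[[wd]][2],
          role_left = roles[1], role_middle = roles[2], role_right = roles[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$condition_id
  class(out) <- c("condition_set", "data.frame")
  out
}

#' Map context positions to object roles
#'
#' Roles are assigned from the feature structure of the context so that
#' mirrored items land in the same aggregation cells:
#'
#' * solvable contexts have the form \{shape competitor, pragmatic referent,
#'   color competitor\} up to ordering: the pragmatic referent is the object
#'   sharing a feature with both others; the object sharing its color is the
#'   color competitor, the one sharing its shape the shape competitor.
#' * reducible contexts contain an identical pair (`pragmatic.1` at the
#'   smaller position, `pragmatic.2`) and a `competitor` with one unique
#'   feature.
#' * trivial and ambiguous contexts have no distinguished pragmatic
#'   structure: the middle object is the `target` and each competitor is
#'   labeled by the features it shares with the target (`comp.both`,
#'   `comp.shape`, `comp.color`, `comp.none`), with a positional suffix when
#'   both competitors share the same label.
#'
#' @param context A [visual_context()].
#' @param category The pragmatic category of the condition the context
#'   instantiates (see [classify_condition()]).
#' @return Character vector of length 3: the role of the left, middle and
#'   right object.
#' @export
roles_for_context <- function(context, category) {
  sh <- context$shape
  co <- context$color
  same <- function(i, j) (sh[i] == sh[j]) + (co[i] == co[j])
  if (category == "solvable") {
    shares <- vapply(1:3, function(i) {
      others <- setdiff(1:3, i)
      all(vapply(others, function(j) same(i, j) > 0, logical(1)))
    }, logical(1))
    hub <- which(shares)
    if (length(hub) != 1L) {
      stop("context lacks the solvable feature structure", call. = FALSE)
    }
    roles <- character(3)
    roles[hub] <- "pragmatic"
    for (j in setdiff(1:3, hub)) {
      roles[j] <- if (co[j] == co[hub]) "comp.color" else "comp.shape"
    }
    return(roles)
  }
  if (category == "reducible") {
    pairs <- utils::combn(3, 2)
    dup <- which(apply(pairs, 2, function(p) same(p[1], p[2]) == 2))
    if (length(dup) != 1L) {
      stop("context lacks the reducible feature structure", call. = FALSE)
    }
    twin <- pairs[, dup]
    roles <- rep("competitor", 3)
    roles[twin[1]] <- "pragmatic.1"
    roles[twin[2]] <- "pragmatic.2"
    return(roles)
  }
  # trivial / ambiguous: target-relative labels
  t <- context$target
  roles <- character(3)
  roles[t] <- "target"
  for (j in setdiff(1:3, t)) {
    roles[j] <- switch(as.character(same(j, t)),
                       "2" = "comp.both",
                       "0" = "comp.none",
                       if (sh[j] == sh[t]) "comp.shape" else "comp.color")
  }
  others <- setdiff(1:3, t)
  if (roles[others[1]] == roles[others[2]]) {
    roles[others] <- paste(roles[others], 1:2, sep = ".")
  }
  roles
}

# retrieve one condition row (by id or row) from a condition_set
find_condition <- function(condition, conditions = enumerate_conditions()) {
  if (is.character(condition) && length(condition) == 1L) {
    if (!condition %in% conditions$condition_id) {
      stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
    }
    return(conditions[condition, , drop = FALSE])
  }
  if (is.data.frame(condition) && nrow(condition) == 1L) return(condition)
  stop("condition must be a condition_id or a single condition row",
       call. = FALSE)
}

condition_context_row <- function(row) {
  visual_context(c(row$shape_left, row$shape_middle, row$shape_right),
                 c(row$color_left, row$color_middle, row$color_right))
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf("Condition set: %d conditions (%s)\n", nrow(x),
              paste(sprintf("%d %s", table(x$category)[unique(x$category)],
                            unique(x$category)), collapse = ", ")))
  print.data.frame(x[, c("condition_id", "basic_type", "qualifier",
                         "word_dim", "category")], row.names = FALSE)
  invisible(x)
}
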