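#' Vocabulary of shape and color words
#'
#' A vocabulary pairs a finite alphabet of shape words with a finite alphabet
#' of color words. Every object in a visual context is fully described by one
#' shape token and one color token, so it is nameable by exactly two words:
#' its shape word (a noun) and its color word (an adjective).
#'
#' @param shapes Character vector of shape tokens.
#' @param colors Character vector of color tokens. Must be disjoint from
#'   `shapes`.
#' @return An object of class `vocabulary`: a list with elements `shape` and
#'   `color`.
#' @examples
#' default_vocabulary()
#' vocabulary(c("circle", "square"), c("blue", "green"))
#' @export
vocabulary <- function(shapes, colors) {
  shapes <- as.character(shapes)
  colors <- as.character(colors)
  if (anyDuplicated(shapes) || anyDuplicated(colors)) {
    stop("vocabulary alphabets must not contain duplicates", call. = FALSE)
  }
  if (length(intersect(shapes, colors)) > 0L) {
    stop("shape and color alphabets must be disjoint", call. = FALSE)
  }
  if (length(shapes) < 2L || length(colors) < 2L) {
    stop("each alphabet needs at least two tokens", call. = FALSE)
  }
  structure(list(shape = shapes, color = colors), class = "vocabulary")
}

#' @describeIn vocabulary The stimulus set used throughout: four iconic
#'   shapes (fish, boot, table, mitt) crossed with four colors
#'   (blue, green, orange, purple), giving 16 unique objects.
#' @export
default_vocabulary <- function() {
  vocabulary(c("fish", "boot", "table", "mitt"),
             c("blue", "green", "orange", "purple"))
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("Vocabulary\n")
  cat("  shape words:", paste(x$shape, collapse = ", "), "\n")
  cat("  color words:", paste(x$color, collapse = ", "), "\n")
  invisible(x)
}

#' Dimension of a word token
#'
#' @param word A single word token.
#' @param vocab A [vocabulary()].
#' @return `"shape"` or `"color"`. Unknown tokens are an error: the models
#'   are only defined over the active vocabulary.
#' @examples
#' word_dimension("blue")
#' word_dimension("mitt")
#' @export
word_dimension <- function(word, vocab = default_vocabulary()) {
  stopifnot(is.character(word), length(word) == 1L)
  if (word %in% vocab$shape) return("shape")
  if (word %in% vocab$color) return("color")
  stop(sprintf("unknown word token '%s' (not in vocabulary)", word),
       call. = FALSE)
}

#' Construct an object specification
#'
#' @param shape,color Tokens drawn from the vocabulary alphabets.
#' @param vocab A [vocabulary()].
#' @return A named character vector `c(shape = , color = )`.
#' @export
object_spec <- function(shape, color, vocab = default_vocabulary()) {
  if (!shape %in% vocab$shape) {
    stop(sprintf("unknown shape token '%s'", shape), call. = FALSE)
  }
  if (!color %in% vocab$color) {
    stop(sprintf("unknown color token '%s'", color), call. = FALSE)
  }
  c(shape = shape, color = color)
}

#' Construct a three-object visual context
#'
#' A visual context is an ordered triple of colored shapes, displayed left,
#' middle, right. The speaker's target is always the middle object: in the
#' generated item sets the speaker refers to the middle object so that
#' participants consider the whole display.
#'
#' @param shapes Character vector of length 3 (left, middle, right).
#' @param colors Character vector of length 3.
#' @param vocab A [vocabulary()]; all tokens must be drawn from it.
#' @return An object of class `visual_context`: a list with elements `shape`
#'   and `color` (each length 3) and `target` (always 2, the middle
#'   position).
#' @examples
#' visual_context(c("boot", "boot", "mitt"), c("blue", "blue", "blue"))
#' @export
visual_context <- function(shapes, colors, vocab = default_vocabulary()) {
  shapes <- as.character(shapes)
  colors <- as.character(colors)
  if (length(shapes) != 3L || length(colors) != 3L) {
    stop("a visual context holds exactly three objects", call. = FALSE)
  }
  if (!all(shapes %in% vocab$shape)) {
    stop("unknown shape token(s): ",
         paste(setdiff(shapes, vocab$shape), collapse = ", "), call. = FALSE)
  }
  if (!all(colors %in% vocab$color)) {
    stop("unknown color token(s): ",
         paste(setdiff(colors, vocab$color), collapse = ", "), call. = FALSE)
  }
  structure(list(shape = shapes, color = colors, target = 2L),
            class = "visual_context")
}

#' @export
print.visual_context <- function(x, ...) {
  lab <- paste(x$color, x$shape)
  lab[x$target] <- paste0("[", lab[x$target], "]")
  cat("Visual context (target bracketed):", paste(lab, collapse = " | "), "\n")
  invisible(x)
}

#' @export
format.visual_context <- function(x, ...) {
  paste(paste(x$color, x$shape), collapse = " | ")
}

position_labels <- function() c("left", "middle", "right")

#' Literal truth value of a word for an object
#'
#' The meaning of a word is a binary truth function over objects: a word is
#' true of an object exactly when the object's feature on the word's
#' dimension equals the token. `"blue"` fits a blue boot; `"boot"` fits a
#' blue boot; `"blue"` does not fit a green boot.
#'
#' @param word A single word token from the vocabulary.
#' @param object An object as returned by [object_spec()], or any named
#'   vector/list with `shape` and `color` entries.
#' @param vocab A [vocabulary()].
#' @return 0 or 1.
#' @examples
#' truth_value("blue", object_spec("boot", "blue"))   # 1
#' truth_value("blue", object_spec("boot", "green"))  # 0
#' @export
truth_value <- function(word, object, vocab = default_vocabulary()) {
  dim <- word_dimension(word, vocab)
  as.integer(identical(unname(object[[dim]]), word))
}

#' Size of a word's extension in a context
#'
#' The number of objects in the context that the word can literally refer
#' to, written |w| in the speaker model: more specific words have smaller
#' extensions and are therefore more informative.
#'
#' @param word A single word token.
#' @param context A [visual_context()].
#' @param vocab A [vocabulary()].
#' @return Integer count in 0..3.
#' @export
extension_size <- function(word, context, vocab = default_vocabulary()) {
  sum(word_extension(word, context, vocab))
}

# binary vector over the three positions; validates the token
word_extension <- function(word, context, vocab = default_vocabulary()) {
  dim <- word_dimension(word, vocab)
  as.integer(context[[dim]] == word)
}

#' Words that can refer to an object
#'
#' The alternative set W for a referent: exactly its shape word and its
#' color word, in that order. This is the set the informative speaker
#' normalizes over.
#'
#' @inheritParams truth_value
#' @return Character vector of length 2: `c(shape word, color word)`.
#' @examples
#' words_for(object_spec("boot", "blue"))  # "boot" "blue"
#' @export
words_for <- function(object, vocab = default_vocabulary()) {
  obj <- object_spec(unname(object[["shape"]]), unname(object[["color"]]),
                     vocab)
  c(unname(obj[["shape"]]), unname(obj[["color"]]))
}

# object at position i of a context
context_object <- function(context, i) {
  c(shape = context$shape[i], color = context$color[i])
}
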