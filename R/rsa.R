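#' Informative speaker model
#'
#' Probability that a rational speaker uses each available word to refer to
#' a referent in context. Word utility is informativeness (log specificity,
#' with constant cost), so the softmax choice rule reduces to
#' \deqn{P(w \mid r, C) = \frac{|w|^{-\alpha}}{\sum_{w' \in W} |w'|^{-\alpha}}}
#' where |w| is the extension size of w in C and W the two words (shape,
#' color) that fit the referent. At `alpha = 1` this is the Luce choice rule
#' of the basic RSA speaker; at `alpha = 0` the speaker picks uniformly
#' among the literally true words, which is the likelihood the literal
#' listener inverts.
#'
#' @param referent Position (1..3) of the referent in `context`, or an
#'   object spec that occurs in the context.
#' @param context A [visual_context()].
#' @param alpha Non-negative rationality exponent. Default 1.
#' @param vocab A [vocabulary()].
#' @return Named numeric vector of probabilities over `words_for(referent)`,
#'   shape word first; sums to 1.
#' @examples
#' ctx <- visual_context(c("boot", "mitt", "boot"),
#'                       c("blue", "blue", "green"))
#' informative_speaker(2, ctx)          # mitt 2/3, blue 1/3
#' informative_speaker(2, ctx, alpha = 0)
#' @export
informative_speaker <- function(referent, context, alpha = 1,
                                vocab = default_vocabulary()) {
  stopifnot(alpha >= 0)
  idx <- resolve_referent(referent, context)
  obj <- context_object(context, idx)
  W <- words_for(obj, vocab)
  sizes <- vapply(W, extension_size, integer(1), context = context,
                  vocab = vocab)
  wt <- sizes^(-alpha)
  p <- wt / sum(wt)
  names(p) <- W
  p
}

resolve_referent <- function(referent, context) {
  if (is.numeric(referent) && length(referent) == 1L) {
    idx <- as.integer(referent)
    if (idx < 1L || idx > 3L) stop("referent position out of range",
                                   call. = FALSE)
    return(idx)
  }
  hit <- which(context$shape == unname(referent[["shape"]]) &
               context$color == unname(referent[["color"]]))
  if (length(hit) == 0L) {
    stop("referent does not occur in the context", call. = FALSE)
  }
  hit[1L]
}

#' Uniform prior over the three objects
#'
#' @param context A [visual_context()] (only its length matters).
#' @return Numeric vector `c(1/3, 1/3, 1/3)`.
#' @export
uniform_prior <- function(context = NULL) {
  rep(1 / 3, 3L)
}

check_prior <- function(prior) {
  prior <- as.numeric(prior)
  if (length(prior) != 3L || any(prior < 0) || abs(sum(prior) - 1) > 1e-9) {
    stop("prior must be three non-negative values summing to 1",
         call. = FALSE)
  }
  prior
}

#' RSA pragmatic-listener posterior
#'
#' Bayesian inversion of the informative speaker: the posterior probability
#' of each referent given an observed word is proportional to the speaker
#' likelihood of that word times the referent's prior (its contextual
#' salience),
#' \deqn{P(r \mid w, C) \propto P(w \mid r, C)\, P(r).}
#' The likelihood is defined to be zero when the word is not literally true
#' of the referent, so the posterior is supported on the word's extension.
#'
#' @param word Word token observed by the listener.
#' @param context A [visual_context()].
#' @param prior Numeric prior over the three positions; defaults to uniform.
#' @param alpha Speaker rationality; `alpha = 0` reproduces the literal
#'   listener exactly.
#' @param vocab A [vocabulary()].
#' @return Numeric posterior vector over positions (left, middle, right),
#'   summing to 1.
#' @examples
#' # canonical pragmatically solvable context, uniform prior
#' ctx <- visual_context(c("boot", "boot", "mitt"),
#'                       c("blue", "green", "blue"))
#' rsa_posterior("blue", ctx)      # prefers the pragmatic referent
#' literal_posterior("blue", ctx)  # guesses between the two blues
#' @export
rsa_posterior <- function(word, context, prior = uniform_prior(context),
                          alpha = 1, vocab = default_vocabulary()) {
  prior <- check_prior(prior)
  ext <- word_extension(word, context, vocab)
  if (sum(ext) == 0L) {
    stop(sprintf("word '%s' applies to no object in the context", word),
         call. = FALSE)
  }
  lik <- numeric(3L)
  for (i in which(ext == 1L)) {
    lik[i] <- informative_speaker(i, context, alpha, vocab)[[word]]
  }
  post <- lik * prior
  if (sum(post) == 0) {
    stop("posterior has empty support (zero prior on every matching object)",
         call. = FALSE)
  }
  post / sum(post)
}

#' Baseline literal-listener posterior
#'
#' The literal listener replaces the informative-speaker likelihood with the
#' literal truth function: the probability of a true word given a referent
#' is uniform over the referent's two names. The posterior then reduces to
#' the prior renormalized over the objects that the word literally fits, so
#' this baseline is driven by literal meaning and salience alone.
#'
#' @inheritParams rsa_posterior
#' @return Numeric posterior vector over positions, summing to 1.
#' @export
literal_posterior <- function(word, context, prior = uniform_prior(context),
                              vocab = default_vocabulary()) {
  prior <- check_prior(prior)
  ext <- word_extension(word, context, vocab)
  if (sum(ext) == 0L) {
    stop(sprintf("word '%s' applies to no object in the context", word),
         call. = FALSE)
  }
  post <- ext * prior
  if (sum(post) == 0) {
    stop("posterior has empty support (zero prior on every matching object)",
         call. = FALSE)
  }
  post / sum(post)
}
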