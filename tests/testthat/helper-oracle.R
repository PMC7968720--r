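# Independent oracles used by the tests. These re-derive model quantities
# from first principles (exact rational arithmetic, exhaustive enumeration)
# without going through the package's computation paths.

# --- exact rational arithmetic on integer pairs c(numerator, denominator) --
frac_gcd <- function(a, b) if (b == 0) a else frac_gcd(b, a %% b)
frac <- function(n, d = 1) {
  g <- frac_gcd(abs(n), abs(d))
  if (g == 0) return(c(0, 1))
  c(n / g, d / g)
}
frac_add <- function(x, y) frac(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
frac_mul <- function(x, y) frac(x[1] * y[1], x[2] * y[2])

# Exact brute-force pragmatic-listener posterior: speaker likelihoods from
# extension counts, multiplied by a rational prior, normalized -- all in
# integer arithmetic until the final division.
oracle_rsa_posterior <- function(word, context, prior_num = c(1, 1, 1),
                                 vocab = default_vocabulary()) {
  dim_of <- function(tok) if (tok %in% vocab$shape) "shape" else "color"
  ext_count <- function(tok) sum(context[[dim_of(tok)]] == tok)
  lik <- vector("list", 3)
  for (i in 1:3) {
    true_of_i <- context[[dim_of(word)]][i] == word
    if (!true_of_i) {
      lik[[i]] <- c(0, 1)
    } else {
      a <- ext_count(word)
      b <- ext_count(context$shape[i])
      c_ <- ext_count(context$color[i])
      # (1/a) / (1/b + 1/c) = bc / (a (b + c))
      lik[[i]] <- frac(b * c_, a * (b + c_))
    }
  }
  nums <- lapply(1:3, function(i) frac_mul(lik[[i]], frac(prior_num[i])))
  total <- Reduce(frac_add, nums)
  vapply(nums, function(f) (f[1] * total[2]) / (f[2] * total[1]),
         numeric(1))
}

# literal listener from the definition: prior renormalized over the
# literal extension
oracle_literal_posterior <- function(word, context, prior = rep(1 / 3, 3),
                                     vocab = default_vocabulary()) {
  dim <- if (word %in% vocab$shape) "shape" else "color"
  ind <- as.numeric(context[[dim]] == word)
  (ind * prior) / sum(ind * prior)
}

# exhaustive two-sided binomial p value: sum outcome probabilities no
# larger than the observed one
oracle_binomial <- function(k, n, p0) {
  probs <- vapply(0:n, function(x) choose(n, x) * p0^x * (1 - p0)^(n - x),
                  numeric(1))
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# exhaustive three-category multinomial p value via nested loops over the
# outcome space
oracle_multinomial3 <- function(counts, probs) {
  n <- sum(counts)
  pmf <- function(x) {
    factorial(n) / prod(factorial(x)) * prod(probs^x)
  }
  p_obs <- pmf(counts)
  total <- 0
  for (x1 in 0:n) for (x2 in 0:(n - x1)) {
    p <- pmf(c(x1, x2, n - x1 - x2))
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  total
}

# --- random-case generators for property tests ----------------------------
rand_context <- function(vocab = default_vocabulary()) {
  visual_context(sample(vocab$shape, 3, replace = TRUE),
                 sample(vocab$color, 3, replace = TRUE), vocab)
}

# a word applying to at least one object: a feature of a random object
rand_word <- function(context) {
  obj <- sample(1:3, 1)
  dim <- sample(c("shape", "color"), 1)
  context[[dim]][obj]
}

rand_prior <- function() {
  g <- stats::rgamma(3, shape = 1)
  g / sum(g)
}

# canonical solvable / reducible fixtures used across test files
solvable_ctx <- function() {
  # {blue boot, blue mitt, green boot}: target blue mitt (middle)
  visual_context(c("boot", "mitt", "boot"), c("blue", "blue", "green"))
}
reducible_ctx <- function() {
  # {blue boot, blue boot, blue mitt}
  visual_context(c("boot", "boot", "mitt"), c("blue", "blue", "blue"))
}
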