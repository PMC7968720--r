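#' Configuration for the synthetic-agent generator
#'
#' Describes a population of simulated one-shot participants with the
#' statistical structure the analysis assumes: informative speakers with a
#' noun bias, salience choosers with a middle-position bump (and a strong
#' preference for the unique-featured object in reducible contexts), and
#' listeners that mix a pragmatic (RSA) strategy with a literal one.
#'
#' The defaults encode the observed behavioral landscape of one-shot
#' web-based reference games: speakers choose the more informative word
#' nearly deterministically (`alpha_speaker = 4` puts ~94% of choices on a
#' word that is twice as specific) and prefer shape words (nouns) at a rate
#' of 0.70 when both words are equally informative; middle objects are
#' about 16% more salient than side objects; the unique-featured competitor
#' in reducible contexts draws about 75% of salience choices; and
#' listeners behave literally (`lambda = 0`) except in the
#' pragmatically solvable color-word conditions, where the pragmatic
#' strategy dominates.
#'
#' @param experiment `NULL` for a fully manual configuration, or 1, 2 or 3
#'   to load a study preset: experiment 1 runs all 24 conditions and all
#'   three tasks with literal listeners throughout; experiment 2 runs the
#'   solvable conditions (salience + listener) with pragmatic listeners in
#'   the color-word cells; experiment 3 runs all eight pragmatic conditions
#'   (salience + listener), also with pragmatic color-word listeners.
#' @param n_per_condition Trials (= participants) per condition per task.
#' @param alpha_speaker Rationality of the simulated speakers.
#' @param alpha_listener Rationality inside the simulated pragmatic
#'   listener's RSA posterior.
#' @param noun_bias Probability of choosing the shape word when both words
#'   are equally informative.
#' @param salience_bump Relative salience increment for the middle
#'   position.
#' @param reducible_competitor_salience Base salience share of the
#'   unique-featured competitor in reducible contexts.
#' @param lambda Named numeric: probability that a listener trial follows
#'   the RSA posterior rather than the literal posterior. Must contain a
#'   `default` entry; entries named `"<category>.<word_dim>"` (e.g.
#'   `"solvable.color"`) override it per cell type.
#' @param lapse Probability of a uniform guess over the literally matching
#'   objects (listeners only).
#' @param p_nonnative,p_attention_fail Rates of trials flagged non-native /
#'   failing the attention check (these trials still carry responses, as in
#'   deposited data, and are removed by [apply_exclusions()]).
#' @param p_random Rate of inattentive responders who answer uniformly at
#'   random (their listener responses may violate literal meaning and are
#'   then excluded as non-literal).
#' @param tasks Character vector of tasks to simulate.
#' @param condition_ids `NULL` for all conditions in the set, or a subset.
#' @param seed Integer base seed; every sampler derives its stream from it.
#' @return An object of class `synth_config` (a validated list).
#' @examples
#' synth_config(experiment = 3, n_per_condition = 20, seed = 7)
#' @export
synth_config <- function(experiment = NULL,
                         n_per_condition = 50,
                         alpha_speaker = 4,
                         alpha_listener = 1,
                         noun_bias = 0.70,
                         salience_bump = 0.16,
                         reducible_competitor_salience = 0.75,
                         lambda = c(default = 0, solvable.color = 1),
                         lapse = 0,
                         p_nonnative = 0.10,
                         p_attention_fail = 0.03,
                         p_random = 0.01,
                         tasks = c("speaker", "salience", "listener"),
                         condition_ids = NULL,
                         seed = 1) {
  if (!is.null(experiment)) {
    experiment <- as.integer(experiment)
    stopifnot(experiment %in% 1:3)
    conds <- enumerate_conditions()
    preset <- switch(experiment,
      list(tasks = c("speaker", "salience", "listener"),
           condition_ids = NULL, lambda = c(default = 0)),
      list(tasks = c("salience", "listener"),
           condition_ids = conds$condition_id[conds$category == "solvable"],
           lambda = c(default = 0, solvable.color = 1)),
      list(tasks = c("salience", "listener"),
           condition_ids = conds$condition_id[conds$category %in%
                                                c("solvable", "reducible")],
           lambda = c(default = 0, solvable.color = 1)))
    # presets fill in only what the call left unspecified
    if (missing(tasks)) tasks <- preset$tasks
    if (missing(condition_ids)) condition_ids <- preset$condition_ids
    if (missing(lambda)) lambda <- preset$lambda
  } else {
    experiment <- 0L  # synthetic, no preset
  }
  probs <- c(noun_bias = noun_bias, salience_bump = salience_bump,
             reducible_competitor_salience = reducible_competitor_salience,
             lapse = lapse, p_nonnative = p_nonnative,
             p_attention_fail = p_attention_fail, p_random = p_random,
             lambda)
  if (any(probs < 0) || any(probs[names(probs) != "salience_bump"] > 1)) {
    stop("probability parameters must lie in [0, 1]", call. = FALSE)
  }
  if (!"default" %in% names(lambda)) {
    stop("lambda needs a 'default' entry", call. = FALSE)
  }
  if (n_per_condition < 1L) stop("n_per_condition must be >= 1",
                                 call. = FALSE)
  stopifnot(alpha_speaker >= 0, alpha_listener >= 0)
  structure(list(experiment = experiment,
                 n_per_condition = as.integer(n_per_condition),
                 alpha_speaker = alpha_speaker,
                 alpha_listener = alpha_listener,
                 noun_bias = noun_bias, salience_bump = salience_bump,
                 reducible_competitor_salience = reducible_competitor_salience,
                 lambda = lambda, lapse = lapse,
                 p_nonnative = p_nonnative,
                 p_attention_fail = p_attention_fail, p_random = p_random,
                 tasks = match.arg(tasks, c("speaker", "salience",
                                            "listener"),
                                   several.ok = TRUE),
                 condition_ids = condition_ids,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  preset: %s; tasks: %s; %s conditions x %d trials\n",
              if (x$experiment == 0L) "none" else
                paste("experiment", x$experiment),
              paste(x$tasks, collapse = "/"),
              if (is.null(x$condition_ids)) "all" else
                length(x$condition_ids),
              x$n_per_condition))
  cat(sprintf("  speaker: alpha = %g, noun bias = %g\n", x$alpha_speaker,
              x$noun_bias))
  cat(sprintf("  salience: middle bump = %g, reducible competitor = %g\n",
              x$salience_bump, x$reducible_competitor_salience))
  cat(sprintf("  listener: lambda = [%s], lapse = %g; seed = %d\n",
              paste(sprintf("%s=%g", names(x$lambda), x$lambda),
                    collapse = ", "), x$lapse, x$seed))
  invisible(x)
}

# conditions selected by a config
config_conditions <- function(config, conditions = enumerate_conditions()) {
  if (is.null(config$condition_ids)) return(conditions)
  out <- conditions[conditions$condition_id %in% config$condition_ids, ,
                    drop = FALSE]
  if (nrow(out) == 0L) stop("config selects no conditions", call. = FALSE)
  out
}

# one reproducible sub-stream per (task, condition); all values < 2^31
derive_seed <- function(seed, task, cond_index) {
  task_offset <- match(task, c("speaker", "salience", "listener")) * 100003L
  (abs(seed) %% 1000000L) * 1000L + task_offset + cond_index
}

lambda_for <- function(config, category, word_dim) {
  key <- paste(category, word_dim, sep = ".")
  if (key %in% names(config$lambda)) return(unname(config$lambda[key]))
  unname(config$lambda["default"])
}

# generative salience distribution over the three positions of an item
salience_position_probs <- function(cond, ctx, config) {
  roles <- roles_for_context(ctx, cond$category)
  base <- if (cond$category == "reducible") {
    w <- config$reducible_competitor_salience
    ifelse(roles == "competitor", w, (1 - w) / 2)
  } else {
    rep(1 / 3, 3)
  }
  base[2] <- base[2] * (1 + config$salience_bump)
  base / sum(base)
}

# Structural signature of a context: feature tokens relabeled by first
# appearance. Model probabilities depend on the context only through this
# pattern, so samplers memoize per (condition, signature).
context_signature <- function(ctx) {
  paste(paste(match(ctx$shape, unique(ctx$shape)), collapse = ""),
        paste(match(ctx$color, unique(ctx$color)), collapse = ""),
        sep = "-")
}

# vectorized context_signature over the rows of an item/trial table
item_signatures <- function(items) {
  code3 <- function(a, b, c) {
    s2 <- ifelse(b == a, 1L, 2L)
    s3 <- ifelse(c == a, 1L,
                 ifelse(c == b, s2, ifelse(b == a, 2L, 3L)))
    paste0(1L, s2, s3)
  }
  paste(code3(items$shape_left, items$shape_middle, items$shape_right),
        code3(items$color_left, items$color_middle, items$color_right),
        sep = "-")
}

memo_get <- function(memo, key, compute) {
  if (is.null(memo[[key]])) memo[[key]] <- compute()
  memo[[key]]
}

simulate_task <- function(task, conditions, config, vocab, respond_all) {
  conds <- config_conditions(config, conditions)
  out <- vector("list", nrow(conds))
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, ]
    cond_index <- match(cond$condition_id, conditions$condition_id)
    s <- derive_seed(config$seed, task, cond_index)
    items <- generate_item_set(cond, config$n_per_condition, seed = s,
                               vocab = vocab, conditions = conditions)
    n <- nrow(items)
    set.seed(s + 50000000L)
    memo <- new.env(parent = emptyenv())
    resp <- respond_all(cond, items, memo)
    # inattentive responders answer uniformly at random
    rand <- stats::runif(n) < config$p_random
    if (any(rand)) {
      if (task == "speaker") {
        for (i in which(rand)) {
          ctx <- item_context(items[i, ], vocab)
          resp$word[i] <- sample(words_for(context_object(ctx, 2L),
                                           vocab), 1L)
        }
      } else {
        resp$response[rand] <- sample(position_labels(), sum(rand),
                                      replace = TRUE)
      }
    }
    out[[ci]] <- data.frame(
      experiment = config$experiment, task = task,
      condition_id = items$condition_id, item_id = items$item_id,
      shape_left = items$shape_left, color_left = items$color_left,
      shape_middle = items$shape_middle, color_middle = items$color_middle,
      shape_right = items$shape_right, color_right = items$color_right,
      word = resp$word, response = resp$response,
      native_fluent = stats::runif(n) > config$p_nonnative,
      attention_passed = stats::runif(n) > config$p_attention_fail,
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  attr(trials, "rejects") <- trials[0, , drop = FALSE]
  class(trials) <- c("trial_data", "data.frame")
  trials
}

#' Simulate speaker-task trials
#'
#' Each simulated speaker describes the middle (target) object with one
#' word, sampled from the informative-speaker distribution at the
#' configured rationality; when the shape and color word are equally
#' informative the tie is broken by the noun bias.
#'
#' @param conditions Condition set (the full universe; the config may
#'   select a subset).
#' @param config A [synth_config()].
#' @param vocab A [vocabulary()].
#' @return A `trial_data` data frame, one row per simulated participant.
#' @export
simulate_speaker <- function(conditions = enumerate_conditions(),
                             config = synth_config(),
                             vocab = default_vocabulary()) {
  simulate_task("speaker", conditions, config, vocab,
    function(cond, items, memo) {
      n <- nrow(items)
      sigs <- item_signatures(items)
      word <- character(n)
      for (i in seq_len(n)) {
        p <- memo_get(memo, sigs[i], function() {
          ctx <- item_context(items[i, ], vocab)
          p <- unname(informative_speaker(ctx$target, ctx,
                                          config$alpha_speaker, vocab))
          if (abs(p[1] - p[2]) < 1e-9) {
            p <- c(config$noun_bias, 1 - config$noun_bias)
          }
          p
        })
        # index 1 = shape word, 2 = color word of this item's target
        W <- c(items$shape_middle[i], items$color_middle[i])
        word[i] <- W[sample.int(2L, 1L, prob = p)]
      }
      list(word = word, response = rep(NA_character_, n))
    })
}

#' Simulate salience-task trials
#'
#' Each simulated participant guesses the referent of an unintelligible
#' word: choices follow the configured salience distribution -- uniform
#' over objects apart from a relative increment for the middle position,
#' except in reducible contexts where the unique-featured competitor
#' receives its own large share.
#'
#' @inheritParams simulate_speaker
#' @return A `trial_data` data frame.
#' @export
simulate_salience <- function(conditions = enumerate_conditions(),
                              config = synth_config(),
                              vocab = default_vocabulary()) {
  simulate_task("salience", conditions, config, vocab,
    function(cond, items, memo) {
      n <- nrow(items)
      sigs <- item_signatures(items)
      pos <- character(n)
      for (i in seq_len(n)) {
        p <- memo_get(memo, sigs[i], function() {
          ctx <- item_context(items[i, ], vocab)
          salience_position_probs(cond, ctx, config)
        })
        pos[i] <- sample(position_labels(), 1L, prob = p)
      }
      list(word = rep(NA_character_, n), response = pos)
    })
}

#' Simulate listener-task trials
#'
#' Each simulated listener observes the word naming the target's feature
#' on the condition's word dimension and picks an object: with probability
#' `lapse` uniformly among the literally matching objects; otherwise from
#' the RSA posterior with probability lambda (per cell type) and from the
#' literal posterior otherwise. Both posteriors use the generative salience
#' distribution as their prior, so the simulated population is exactly the
#' mixture the estimator in [recover_lambda()] assumes.
#'
#' @inheritParams simulate_speaker
#' @return A `trial_data` data frame.
#' @export
simulate_listener <- function(conditions = enumerate_conditions(),
                              config = synth_config(),
                              vocab = default_vocabulary()) {
  simulate_task("listener", conditions, config, vocab,
    function(cond, items, memo) {
      n <- nrow(items)
      lam <- lambda_for(config, cond$category, cond$word_dim)
      sigs <- item_signatures(items)
      word <- items[[paste0(cond$word_dim, "_middle")]]
      pos <- character(n)
      for (i in seq_len(n)) {
        ps <- memo_get(memo, sigs[i], function() {
          ctx <- item_context(items[i, ], vocab)
          w <- word[i]
          prior <- salience_position_probs(cond, ctx, config)
          ext <- word_extension(w, ctx, vocab)
          list(lapse = ext / sum(ext),
               rsa = rsa_posterior(w, ctx, prior, config$alpha_listener,
                                   vocab),
               literal = literal_posterior(w, ctx, prior, vocab))
        })
        p <- if (stats::runif(1) < config$lapse) {
          ps$lapse
        } else if (stats::runif(1) < lam) {
          ps$rsa
        } else {
          ps$literal
        }
        pos[i] <- sample(position_labels(), 1L, prob = p)
      }
      list(word = word, response = pos)
    })
}

#' Simulate a full study
#'
#' Runs the per-task simulators selected by the configuration and returns
#' their trial tables together with the configuration itself (the
#' manifest).
#'
#' @inheritParams simulate_speaker
#' @return A list with one `trial_data` element per simulated task plus
#'   `config`.
#' @examples
#' sim <- simulate_experiment(synth_config(experiment = 3,
#'                                         n_per_condition = 10))
#' names(sim)
#' @export
simulate_experiment <- function(config = synth_config(),
                                conditions = enumerate_conditions(),
                                vocab = default_vocabulary()) {
  out <- list()
  if ("speaker" %in% config$tasks) {
    out$speaker <- simulate_speaker(conditions, config, vocab)
  }
  if ("salience" %in% config$tasks) {
    out$salience <- simulate_salience(conditions, config, vocab)
  }
  if ("listener" %in% config$tasks) {
    out$listener <- simulate_listener(conditions, config, vocab)
  }
  out$config <- config
  out
}

#' Estimate the pragmatic-strategy mixture weight
#'
#' Fits, by maximum likelihood over a grid, the probability lambda that a
#' listener trial follows the RSA pragmatic posterior rather than the
#' literal posterior. Only trials from the pragmatic (solvable or
#' reducible) conditions are informative -- elsewhere the two posteriors
#' coincide -- so the likelihood is evaluated on those trials. Uncertainty
#' is quantified by a bootstrap percentile interval over participants
#' (trials: the paradigm is one-shot, so each trial is a participant).
#'
#' @param trials Listener-task `trial_data` (post-exclusion).
#' @param conditions Condition set.
#' @param prior `NULL` for a uniform referent prior inside both
#'   posteriors, or a salience `choice_table` (per condition) for
#'   empirical priors.
#' @param lapse Fixed lapse rate assumed in the mixture likelihood.
#' @param alpha Speaker rationality inside the RSA posterior.
#' @param grid_step Grid resolution for lambda (<= 0.01 by default).
#' @param n_boot Bootstrap replicates for the confidence band.
#' @param conf_level Coverage of the percentile interval.
#' @param seed Seed for the bootstrap resampling.
#' @param vocab A [vocabulary()].
#' @return An object of class `lambda_fit` with the estimate, interval,
#'   profile log-likelihood and bootstrap draws. Supports `print()`,
#'   `coef()`, `confint()` and `logLik()`.
#' @examples
#' cfg <- synth_config(experiment = 3, n_per_condition = 30, seed = 2)
#' sim <- simulate_experiment(cfg)
#' fit <- recover_lambda(sim$listener, n_boot = 50, seed = 2)
#' coef(fit)
#' @export
recover_lambda <- function(trials, conditions = enumerate_conditions(),
                           prior = NULL, lapse = 0, alpha = 1,
                           grid_step = 0.01, n_boot = 200,
                           conf_level = 0.95, seed = 1,
                           vocab = default_vocabulary()) {
  stopifnot(grid_step > 0, grid_step <= 0.01 + 1e-12)
  trials <- trials[trials$task == "listener", , drop = FALSE]
  prag <- conditions$condition_id[conditions$category %in%
                                    c("solvable", "reducible")]
  trials <- trials[trials$condition_id %in% prag, , drop = FALSE]
  n <- nrow(trials)
  if (n == 0L) {
    stop("no pragmatic-condition trials: lambda is unidentifiable",
         call. = FALSE)
  }
  p_rsa <- numeric(n)
  p_lit <- numeric(n)
  m <- numeric(n)
  memo <- new.env(parent = emptyenv())
  sigs <- paste(trials$condition_id, item_signatures(trials))
  pos_all <- match(trials$response, position_labels())
  for (i in seq_len(n)) {
    ps <- memo_get(memo, sigs[i], function() {
      row <- trials[i, ]
      ctx <- item_context(row, vocab)
      cond <- find_condition(row$condition_id, conditions)
      prior_pos <- if (is.null(prior)) uniform_prior() else {
        roles <- roles_for_context(ctx, cond$category)
        pr <- empirical_prior(prior, cond, conditions)
        cond_roles <- c(cond$role_left, cond$role_middle, cond$role_right)
        check_prior(pr[match(roles, cond_roles)])
      }
      list(rsa = rsa_posterior(row$word, ctx, prior_pos, alpha, vocab),
           lit = literal_posterior(row$word, ctx, prior_pos, vocab),
           m = extension_size(row$word, ctx, vocab))
    })
    p_rsa[i] <- ps$rsa[pos_all[i]]
    p_lit[i] <- ps$lit[pos_all[i]]
    m[i] <- ps$m
  }
  grid <- seq(0, 1, by = grid_step)
  # n x length(grid) matrix of per-trial log mixture probabilities
  mix <- outer(p_rsa, grid) + outer(p_lit, 1 - grid)
  ll_terms <- log(pmax(lapse / m + (1 - lapse) * mix, 1e-12))
  loglik <- colSums(ll_terms)
  lambda_hat <- grid[which.max(loglik)]

  boot <- numeric(0)
  if (n_boot > 0L) {
    set.seed(as.integer(seed))
    boot <- vapply(seq_len(n_boot), function(b) {
      w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      grid[which.max(crossprod(w, ll_terms))]
    }, numeric(1))
  }
  a <- (1 - conf_level) / 2
  ci <- if (length(boot) > 0) {
    stats::quantile(boot, c(a, 1 - a), names = FALSE)
  } else c(NA_real_, NA_real_)
  structure(list(lambda = lambda_hat, ci = ci, conf_level = conf_level,
                 grid = grid, loglik = loglik, boot = boot,
                 n_trials = n, lapse = lapse, alpha = alpha,
                 prior = if (is.null(prior)) "uniform" else "empirical"),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pragmatic-strategy mixture weight (grid maximum likelihood)\n")
  cat(sprintf("  lambda = %.2f, %d%% bootstrap CI [%.2f, %.2f]\n",
              x$lambda, round(100 * x$conf_level), x$ci[1], x$ci[2]))
  cat(sprintf("  %d pragmatic-condition trials, %s prior, lapse = %g\n",
              x$n_trials, x$prior, x$lapse))
  invisible(x)
}

#' @export
coef.lambda_fit <- function(object, ...) {
  c(lambda = object$lambda)
}

#' @export
confint.lambda_fit <- function(object, parm = "lambda", level = NULL, ...) {
  if (!is.null(level) && abs(level - object$conf_level) > 1e-9) {
    stop("refit with the desired conf_level to change the interval",
         call. = FALSE)
  }
  out <- matrix(object$ci, nrow = 1,
                dimnames = list("lambda",
                                sprintf("%g %%",
                                        100 * c((1 - object$conf_level) / 2,
                                                1 - (1 - object$conf_level) /
                                                  2))))
  out
}

#' @export
logLik.lambda_fit <- function(object, ...) {
  structure(max(object$loglik), df = 1L, nobs = object$n_trials,
            class = "logLik")
}

#' @export
plot.lambda_fit <- function(x, ...) {
  graphics::plot(x$grid, x$loglik, type = "l", xlab = expression(lambda),
                 ylab = "log-likelihood", ...)
  graphics::abline(v = x$lambda, lty = 2)
  invisible(x)
}
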