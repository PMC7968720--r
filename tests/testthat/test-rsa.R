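test_that("RSA posterior matches the worked solvable and reducible cases", {
  # blue boot / blue mitt / green boot, word "blue", uniform prior
  post <- rsa_posterior("blue", solvable_ctx())
  expect_equal(post, c(0.6, 0.4, 0), tolerance = 1e-12)
  expect_equal(post, oracle_rsa_posterior("blue", solvable_ctx()),
               tolerance = 1e-12)

  # blue boot / blue boot / blue mitt, word "blue"
  post_r <- rsa_posterior("blue", reducible_ctx())
  expect_equal(post_r, c(8 / 21, 8 / 21, 5 / 21), tolerance = 1e-12)
  expect_equal(post_r, oracle_rsa_posterior("blue", reducible_ctx()),
               tolerance = 1e-12)

  # a uniquely identifying word wins outright whatever the prior
  expect_equal(rsa_posterior("mitt", solvable_ctx(),
                             prior = c(0.8, 0.1, 0.1), alpha = 3),
               c(0, 1, 0), tolerance = 1e-12)
})

test_that("RSA matches the exact-rational oracle on all 24 conditions", {
  conds <- enumerate_conditions()
  for (i in seq_len(nrow(conds))) {
    ctx <- refgames:::condition_context_row(conds[i, ])
    word <- conds$word[i]
    expect_equal(rsa_posterior(word, ctx),
                 oracle_rsa_posterior(word, ctx), tolerance = 1e-12,
                 label = paste("RSA posterior for", conds$condition_id[i]))
    # and under a non-uniform rational prior
    expect_equal(rsa_posterior(word, ctx, prior = c(0.2, 0.5, 0.3)),
                 oracle_rsa_posterior(word, ctx, prior_num = c(2, 5, 3)),
                 tolerance = 1e-12)
  }
})

test_that("literal listener renormalizes the prior over the extension", {
  expect_equal(literal_posterior("blue", solvable_ctx()),
               c(0.5, 0.5, 0), tolerance = 1e-12)
  # observed salience prior from the solvable conditions
  post <- literal_posterior("blue", solvable_ctx(),
                            prior = c(0.37, 0.36, 0.27))
  expect_equal(post, c(0.37, 0.36, 0) / 0.73, tolerance = 1e-12)
  expect_equal(round(post[1:2], 4), c(0.5068, 0.4932))
  # word fits all three objects: posterior equals the prior
  prior <- c(0.12, 0.19, 0.69)
  expect_equal(literal_posterior("blue", reducible_ctx(), prior), prior,
               tolerance = 1e-12)
})

test_that("alpha = 0 collapses RSA onto the literal listener", {
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    ctx <- rand_context()
    word <- rand_word(ctx)
    prior <- rand_prior()
    dev <- max(abs(rsa_posterior(word, ctx, prior, alpha = 0) -
                     literal_posterior(word, ctx, prior)))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-12)
})

test_that("posteriors are proper distributions with literal support", {
  set.seed(21)
  for (i in 1:200) {
    ctx <- rand_context()
    word <- rand_word(ctx)
    prior <- rand_prior()
    alpha <- sample(c(0, 0.5, 1, 2, 5), 1)
    post <- rsa_posterior(word, ctx, prior, alpha)
    expect_equal(sum(post), 1, tolerance = 1e-9)
    expect_true(all(post >= 0))
    ext <- vapply(1:3, function(j) {
      truth_value(word, c(shape = ctx$shape[j], color = ctx$color[j]))
    }, integer(1))
    expect_true(all(post[ext == 0] == 0))
  }
})

test_that("the pragmatic preference strengthens with speaker rationality", {
  # solvable context, uniform prior: the pragmatic referent's posterior
  # grows strictly in alpha
  ctx <- solvable_ctx()
  roles <- roles_for_context(ctx, "solvable")
  target <- which(roles == "pragmatic")
  p <- vapply(c(0, 0.5, 1, 2, 5), function(a) {
    rsa_posterior("blue", ctx, alpha = a)[target]
  }, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("ambiguous conditions are exactly where RSA adds nothing", {
  conds <- enumerate_conditions()
  for (i in which(conds$category == "ambiguous")) {
    ctx <- refgames:::condition_context_row(conds[i, ])
    word <- conds$word[i]
    expect_equal(rsa_posterior(word, ctx), literal_posterior(word, ctx),
                 tolerance = 1e-12,
                 label = paste("RSA = literal in", conds$condition_id[i]))
  }
  for (i in which(conds$category %in% c("solvable", "reducible"))) {
    ctx <- refgames:::condition_context_row(conds[i, ])
    word <- conds$word[i]
    expect_gt(max(abs(rsa_posterior(word, ctx) -
                        literal_posterior(word, ctx))), 1e-6)
  }
})

test_that("informative speaker follows the specificity rule", {
  ctx <- solvable_ctx()
  # target blue mitt: "mitt" is twice as specific as "blue"
  p <- informative_speaker(2, ctx)
  expect_equal(unname(p), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_identical(names(p), c("mitt", "blue"))
  # blue boot: shape and color word equally informative
  expect_equal(unname(informative_speaker(1, ctx)), c(0.5, 0.5),
               tolerance = 1e-12)
  # alpha = 0: uniform over the two true words
  expect_equal(unname(informative_speaker(2, ctx, alpha = 0)), c(0.5, 0.5),
               tolerance = 1e-12)
  # alpha -> large: the more specific word dominates
  expect_gt(informative_speaker(2, ctx, alpha = 50)[["mitt"]], 1 - 1e-10)
  expect_error(informative_speaker(object_spec("table", "purple"), ctx),
               "does not occur")
})

test_that("degenerate words and empty supports are rejected", {
  expect_error(rsa_posterior("purple", solvable_ctx()), "no object")
  expect_error(literal_posterior("purple", solvable_ctx()), "no object")
  expect_error(rsa_posterior("blue", solvable_ctx(),
                             prior = c(0, 0, 1)), "empty support")
  expect_error(rsa_posterior("blue", solvable_ctx(), prior = c(1, 2, 3)),
               "sum")
})

test_that("uniform and empirical priors behave as documented", {
  expect_equal(uniform_prior(), rep(1 / 3, 3))
  conds <- enumerate_conditions()
  # build a salience table for the canonical solvable condition
  cond <- conds["2s2c.b.color", ]
  tab <- data.frame(condition_id = "2s2c.b.color",
                    role = c("pragmatic", "comp.color", "comp.shape"),
                    n = 188, prop = c(0.37, 0.36, 0.27))
  prior <- empirical_prior(tab, cond, conds)
  # canonical layout: comp.color left, pragmatic middle, comp.shape right
  expect_equal(prior, c(0.36, 0.37, 0.27), tolerance = 1e-12)
  expect_error(empirical_prior(tab, "2s3c.color", conds), "no salience")
  # all-equal counts give back the uniform prior
  tab$prop <- rep(1 / 3, 3)
  expect_equal(empirical_prior(tab, cond, conds), rep(1 / 3, 3))
})
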