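conds <- enumerate_conditions()

test_that("samplers are bit-reproducible given the same config", {
  cfg <- synth_config(experiment = 3, n_per_condition = 8, seed = 42)
  expect_identical(simulate_experiment(cfg), simulate_experiment(cfg))
  other <- synth_config(experiment = 3, n_per_condition = 8, seed = 43)
  expect_false(identical(simulate_listener(config = cfg),
                         simulate_listener(config = other)))
})

test_that("generated trials round-trip through the reader with no rejects", {
  cfg <- synth_config(experiment = 1, n_per_condition = 3, seed = 5)
  sim <- simulate_experiment(cfg)
  for (task in c("speaker", "salience", "listener")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_trials(sim[[task]], path)
    back <- read_trials(path)
    expect_equal(nrow(back), nrow(sim[[task]]))
    expect_equal(nrow(attr(back, "rejects")), 0L)
    expect_equal(back$response, sim[[task]]$response)
    expect_equal(back$word, sim[[task]]$word)
  }
})

test_that("speakers are informative and noun-biased on ties", {
  cfg <- synth_config(n_per_condition = 600, seed = 10, noun_bias = 0.7,
                      alpha_speaker = 4, p_nonnative = 0,
                      p_attention_fail = 0, p_random = 0,
                      tasks = "speaker",
                      condition_ids = c("2s2c.b.color", "1s2c.ss.color"))
  trials <- simulate_speaker(conds, cfg)
  tab <- aggregate_choices(trials, "speaker", conds)
  # equal informativity (2s2c.b target): tie broken by the noun bias
  p_tie <- tab$prop_shape[tab$condition_id == "2s2c.b.color"]
  expect_equal(p_tie, 0.7, tolerance = 0.05)
  # 1s2c target has a unique shape: the shape word is twice as specific,
  # and at alpha = 4 wins 1/(1 + 2^-4) of the time
  p_inf <- tab$prop_shape[tab$condition_id == "1s2c.ss.color"]
  expect_equal(p_inf, 1 / (1 + 2^-4), tolerance = 0.05)
})

test_that("salience choosers show the middle-position bump", {
  cfg <- synth_config(n_per_condition = 3000, seed = 2,
                      salience_bump = 0.16, p_nonnative = 0,
                      p_attention_fail = 0, p_random = 0,
                      tasks = "salience", condition_ids = "3s3c.color")
  trials <- simulate_salience(conds, cfg)
  pos_share <- prop.table(table(trials$response))
  expect_equal(unname(pos_share[["middle"]] / pos_share[["left"]]), 1.16,
               tolerance = 0.08)

  flat <- synth_config(n_per_condition = 3000, seed = 2, salience_bump = 0,
                       p_nonnative = 0, p_attention_fail = 0, p_random = 0,
                       tasks = "salience", condition_ids = "3s3c.color")
  trials <- simulate_salience(conds, flat)
  expect_equal(max(abs(prop.table(table(trials$response)) - 1 / 3)), 0,
               tolerance = 0.03)
})

test_that("listener agents interpolate between literal and RSA", {
  base <- function(lam) {
    synth_config(n_per_condition = 1500, seed = 31,
                 lambda = c(default = lam), salience_bump = 0,
                 reducible_competitor_salience = 1 / 3, lapse = 0,
                 p_nonnative = 0, p_attention_fail = 0, p_random = 0,
                 tasks = "listener", condition_ids = "2s2c.b.color")
  }
  share_pragmatic <- function(trials) {
    tab <- aggregate_choices(trials, "listener", conds)
    tab$prop[tab$condition_id == "2s2c.b.color" & tab$role == "pragmatic"]
  }
  # literal agent guesses between the two literally matching objects
  expect_equal(share_pragmatic(simulate_listener(conds, base(0))), 0.5,
               tolerance = 0.04)
  # pragmatic agent follows the RSA posterior (0.6 / 0.4)
  expect_equal(share_pragmatic(simulate_listener(conds, base(1))), 0.6,
               tolerance = 0.04)
})

test_that("a salience-dominant prior overrides the pragmatic demotion", {
  # reducible context with a highly salient competitor: even the full-RSA
  # agent picks the competitor most often, because the prior dominates
  cfg <- synth_config(n_per_condition = 1200, seed = 13,
                      lambda = c(default = 1),
                      reducible_competitor_salience = 0.69,
                      salience_bump = 0, p_nonnative = 0,
                      p_attention_fail = 0, p_random = 0,
                      tasks = "listener", condition_ids = "2s3c.color")
  tab <- aggregate_choices(simulate_listener(conds, cfg), "listener", conds)
  tab <- tab[tab$condition_id == "2s3c.color", ]
  expect_gt(tab$prop[tab$role == "competitor"],
            max(tab$prop[tab$role != "competitor"]))
})

test_that("lambda is recovered from data simulated at known values", {
  neutral <- function(lam, seed) {
    synth_config(experiment = 3, n_per_condition = 250, seed = seed,
                 lambda = c(default = lam), salience_bump = 0,
                 reducible_competitor_salience = 1 / 3,
                 p_nonnative = 0, p_attention_fail = 0, p_random = 0)
  }
  for (lam in c(0, 1)) {
    sim <- simulate_listener(config = neutral(lam, 3))
    fit <- recover_lambda(sim, conds, n_boot = 40, seed = 3)
    expect_lt(abs(coef(fit) - lam), 0.15)
    ci <- confint(fit)
    expect_lte(ci[1], coef(fit))
    expect_gte(ci[2], coef(fit))
  }
  # trials outside the pragmatic conditions are uninformative
  triv <- simulate_listener(conds, synth_config(
    n_per_condition = 5, seed = 1, tasks = "listener",
    condition_ids = "1s1c.color"))
  expect_error(recover_lambda(triv, conds), "unidentifiable")
})

test_that("model fits discriminate the generating strategy over seeds", {
  for (seed in 1:5) {
    for (lam in c(0, 1)) {
      cfg <- synth_config(experiment = 3, n_per_condition = 200,
                          seed = seed, lambda = c(default = lam),
                          p_nonnative = 0, p_attention_fail = 0,
                          p_random = 0)
      ev <- run_evaluation(simulate_experiment(cfg))
      f <- ev$fits[ev$fits$slice == "pragmatic", ]
      r_rsa <- f$r[f$model == "rsa"]
      r_lit <- f$r[f$model == "literal"]
      if (lam == 1) expect_gt(r_rsa, r_lit) else expect_gte(r_lit, r_rsa)
    }
  }
})
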