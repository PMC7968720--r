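#' Evaluate the RSA and literal-listener models on a study
#'
#' End-to-end model evaluation: applies the exclusion rules to each task's
#' trials, aggregates salience choices into empirical priors and listener
#' choices into observed proportions, computes model predictions (RSA,
#' baseline literal listener, and uniform-prior RSA), and fits each model
#' per data slice -- overall with and without the literally-forced 0/1
#' cells, the pragmatic conditions, and the reducible and solvable subsets
#' -- together with the dependent-correlation comparison of RSA against the
#' literal baseline, the salience-listener correlations, the speaker-model
#' fit (when speaker trials are supplied), and pooled behavioral tables for
#' the pragmatic conditions.
#'
#' @param trials A list with elements `listener` (required), `salience`
#'   (required when `prior = "empirical"`) and optionally `speaker`, each a
#'   `trial_data` data frame (pre- or post-exclusion; exclusions are
#'   applied here and reported). The output of [simulate_experiment()] can
#'   be passed directly.
#' @param conditions Condition set.
#' @param alpha Speaker rationality inside RSA. Default 1, the basic
#'   model.
#' @param prior `"empirical"` (salience-task proportions, the default) or
#'   `"uniform"`.
#' @param vocab A [vocabulary()].
#' @return An object of class `rsa_evaluation`: a list with `fits` (one
#'   row per slice x model), `comparisons` (Hittner/Dunn-Clark z per
#'   slice), `salience_fits`, `speaker` (fit and word-share summaries, or
#'   `NULL`), `tables` (pooled solvable/reducible behavioral tables),
#'   `cells`, `exclusions`, `predictions`, `observed` and the settings.
#' @examples
#' sim <- simulate_experiment(synth_config(experiment = 3,
#'                                         n_per_condition = 20))
#' ev <- run_evaluation(sim)
#' ev$fits
#' @export
run_evaluation <- function(trials, conditions = enumerate_conditions(),
                           alpha = 1, prior = c("empirical", "uniform"),
                           vocab = default_vocabulary()) {
  prior <- match.arg(prior)
  if (is.null(trials$listener)) {
    stop("listener trials are required", call. = FALSE)
  }
  exclusions <- list()
  kept <- list()
  for (task in intersect(c("speaker", "salience", "listener"),
                         names(trials))) {
    ex <- apply_exclusions(trials[[task]], vocab)
    kept[[task]] <- ex$trials
    exclusions[[task]] <- ex$report
  }

  present <- unique(kept$listener$condition_id)
  conds <- conditions[conditions$condition_id %in% present, , drop = FALSE]

  salience_tab <- NULL
  if (!is.null(kept$salience)) {
    salience_tab <- aggregate_choices(kept$salience, "salience", conds,
                                      vocab = vocab)
  }
  if (prior == "empirical" && is.null(salience_tab)) {
    stop("empirical priors require salience trials", call. = FALSE)
  }
  listener_tab <- aggregate_choices(kept$listener, "listener", conds,
                                    vocab = vocab)
  prior_tab <- if (prior == "empirical") salience_tab else NULL
  preds <- condition_predictions(conds, prior_tab, alpha, vocab)

  cells_all <- align_cells(preds, listener_tab, drop_degenerate = FALSE)
  cells <- cells_all[!cells_all$degenerate, , drop = FALSE]

  slices <- list(
    overall_incl_degenerate = cells_all,
    overall = cells,
    pragmatic = cells[cells$category %in% c("solvable", "reducible"), ],
    reducible = cells[cells$category == "reducible", ],
    solvable = cells[cells$category == "solvable", ])

  fit_rows <- list()
  cmp_rows <- list()
  sal_rows <- list()
  for (slice in names(slices)) {
    d <- slices[[slice]]
    # degenerate slices (too few cells, or a constant vector) yield NA
    # rows rather than aborting the evaluation
    safe_fit <- function(pred) {
      tryCatch(pearson_fit(pred, d$prop), error = function(e) {
        list(r = NA_real_, r2_adj = NA_real_, t = NA_real_, p = NA_real_,
             n = nrow(d))
      })
    }
    fits <- lapply(list(literal = d$literal, rsa = d$rsa,
                        rsa_uniform = d$rsa_uniform), safe_fit)
    fit_rows[[slice]] <- do.call(rbind, lapply(names(fits), function(m) {
      f <- fits[[m]]
      data.frame(slice = slice, model = m, r = f$r, r2_adj = f$r2_adj,
                 t = f$t, p = f$p, n = f$n, stringsAsFactors = FALSE)
    }))
    cmp <- if (is.na(fits$literal$r) || is.na(fits$rsa$r)) NULL else
      tryCatch(
        compare_dependent_correlations(fits$literal$r, fits$rsa$r,
                                       stats::cor(d$literal, d$rsa),
                                       nrow(d)),
        error = function(e) NULL)
    if (!is.null(cmp)) {
      cmp_rows[[slice]] <- data.frame(
        slice = slice, r_literal = cmp$r12, r_rsa = cmp$r13,
        r_models = cmp$r23, z = cmp$z, p = cmp$p, n = cmp$n,
        stringsAsFactors = FALSE)
    }
    if (!is.null(salience_tab)) {
      sal <- merge(d[, c("condition_id", "role", "prop")],
                   salience_tab[, c("condition_id", "role", "prop")],
                   by = c("condition_id", "role"),
                   suffixes = c("_listener", "_salience"))
      if (nrow(sal) >= 3L && stats::sd(sal$prop_salience) > 0 &&
          stats::sd(sal$prop_listener) > 0) {
        f <- pearson_fit(sal$prop_salience, sal$prop_listener)
        sal_rows[[slice]] <- data.frame(
          slice = slice, r = f$r, r2_adj = f$r2_adj, t = f$t, p = f$p,
          n = f$n, stringsAsFactors = FALSE)
      }
    }
  }

  speaker <- NULL
  if (!is.null(kept$speaker)) {
    speaker <- evaluate_speaker(kept$speaker, conds, vocab)
  }

  tables <- list(
    solvable = behavioral_table(listener_tab, salience_tab, conds,
                                "solvable"),
    reducible = behavioral_table(listener_tab, salience_tab, conds,
                                 "reducible"))

  structure(list(
    fits = rbind_rows(fit_rows), comparisons = rbind_rows(cmp_rows),
    salience_fits = rbind_rows(sal_rows), speaker = speaker,
    tables = tables, cells = cells_all, exclusions = exclusions,
    predictions = preds,
    observed = list(listener = listener_tab, salience = salience_tab),
    settings = list(alpha = alpha, prior = prior,
                    n_conditions = nrow(conds))),
    class = "rsa_evaluation")
}

rbind_rows <- function(rows) {
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# speaker-task evaluation: model fit per condition plus word-share summaries
evaluate_speaker <- function(speaker_trials, conds, vocab) {
  obs <- aggregate_choices(speaker_trials, "speaker", conds, vocab = vocab)
  pred <- speaker_predictions(conds, alpha = 1, vocab = vocab)
  d <- merge(pred, obs, by = "condition_id")
  d <- d[d$n > 0L, , drop = FALSE]
  fit <- if (nrow(d) >= 3L && stats::sd(d$pred_shape) > 0) {
    pearson_fit(d$pred_shape, d$prop_shape)
  } else NULL
  equal_ids <- conds$condition_id[conds$basic_type %in%
                                    c("1s1c", "2s2c.a", "2s2c.b", "3s3c")]
  share <- function(tab) {
    tab <- tab[tab$n > 0L, , drop = FALSE]
    stats::weighted.mean(tab$prop_shape, tab$n)
  }
  list(fit = fit, table = d,
       shape_share_overall = share(obs),
       shape_share_equal_informative =
         share(obs[obs$condition_id %in% equal_ids, , drop = FALSE]))
}

# pooled behavioral table for one pragmatic category: salience row(s) plus
# listener rows per word dimension, averaging condition proportions
# weighted by their Ns
behavioral_table <- function(listener_tab, salience_tab, conds, category) {
  ids <- conds$condition_id[conds$category == category]
  if (length(ids) == 0L) return(NULL)
  pool <- function(tab, ids) {
    tab <- tab[tab$condition_id %in% ids & tab$n > 0L, , drop = FALSE]
    if (nrow(tab) == 0L) return(NULL)
    out <- lapply(split(tab, tab$role), function(g) {
      data.frame(role = g$role[1],
                 prop = stats::weighted.mean(g$prop, g$n),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    res$n <- sum(tab$n[!duplicated(tab$condition_id)])
    rownames(res) <- NULL
    res
  }
  rows <- list()
  if (category == "solvable") {
    # salience does not depend on the listener word: one pooled row
    if (!is.null(salience_tab)) {
      s <- pool(salience_tab, ids)
      if (!is.null(s)) rows[["salience"]] <- cbind(task = "salience",
                                                   word_dim = "-", s)
    }
  }
  for (wd in c("color", "shape")) {
    wids <- conds$condition_id[conds$category == category &
                                 conds$word_dim == wd]
    if (category == "reducible" && !is.null(salience_tab)) {
      # reducible contexts differ by the competitor's unique dimension,
      # which tracks the word dimension: separate salience rows
      s <- pool(salience_tab, wids)
      if (!is.null(s)) {
        rows[[paste0("salience.", wd)]] <- cbind(task = "salience",
                                                 word_dim = wd, s)
      }
    }
    l <- pool(listener_tab, wids)
    if (!is.null(l)) {
      rows[[paste0("listener.", wd)]] <- cbind(task = "listener",
                                               word_dim = wd, l)
    }
  }
  out <- rbind_rows(rows)
  if (!is.null(out)) out <- out[, c("task", "word_dim", "role", "n", "prop")]
  out
}

#' @export
print.rsa_evaluation <- function(x, digits = 2, ...) {
  cat(sprintf("Model evaluation (alpha = %g, %s prior, %d conditions)\n\n",
              x$settings$alpha, x$settings$prior,
              x$settings$n_conditions))
  f <- x$fits
  for (slice in unique(f$slice)) {
    d <- f[f$slice == slice & f$model != "rsa_uniform", , drop = FALSE]
    d <- d[order(-d$r), ]
    cmp <- x$comparisons[x$comparisons$slice == slice, , drop = FALSE]
    ranked <- nrow(cmp) == 1L && !is.na(cmp$p) && cmp$p < 0.05
    cat(sprintf("%s (n = %d cells%s)\n", slice, d$n[1],
                if (nrow(cmp) == 1L)
                  sprintf("; literal vs RSA: z = %.2f, p = %s", cmp$z,
                          format.pval(cmp$p, digits = 3)) else ""))
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  %s %-12s r = %5.2f  adj.R2 = %5.2f  t = %6.2f  p = %s\n",
                  if (ranked) as.character(i) else "-",
                  d$model[i], d$r[i], d$r2_adj[i], d$t[i],
                  format.pval(d$p[i], digits = 3)))
    }
  }
  if (!is.null(x$speaker) && !is.null(x$speaker$fit)) {
    sf <- x$speaker$fit
    cat(sprintf("\nSpeaker model: r = %.2f, adj.R2 = %.2f, t = %.2f (n = %d); shape-word share %.2f overall, %.2f where equally informative\n",
                sf$r, sf$r2_adj, sf$t, sf$n,
                x$speaker$shape_share_overall,
                x$speaker$shape_share_equal_informative))
  }
  invisible(x)
}

#' @export
summary.rsa_evaluation <- function(object, ...) {
  print(object, ...)
  cat("\nExclusions:\n")
  for (task in names(object$exclusions)) {
    r <- object$exclusions[[task]]
    cat(sprintf("  %-9s %d -> %d (non-native %d, attention %d, non-literal %d)\n",
                task, r$n_input, r$n_included, r$non_native, r$attention,
                r$non_literal))
  }
  invisible(object)
}

#' Write evaluation reports to disk
#'
#' Emits a deterministic file set: `model_fits.csv` (fits, comparisons and
#' salience-listener correlations, values rounded to two decimals in the
#' table style of published reports), `behavioral_solvable.csv` and
#' `behavioral_reducible.csv` (pooled choice proportions), `speaker.csv`
#' (when speaker trials were evaluated), and `summary.json` holding the
#' unrounded numbers plus settings and exclusion counts. Re-running the
#' same evaluation produces byte-identical files.
#'
#' @param evaluation An `rsa_evaluation` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_tables <- function(evaluation, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  round_df <- function(d) {
    num <- vapply(d, is.numeric, logical(1)) & names(d) != "n"
    d[num] <- lapply(d[num], function(v) sprintf("%.2f", v))
    d
  }
  emit <- function(d, file) {
    p <- file.path(dir, file)
    utils::write.csv(round_df(d), p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  emit(evaluation$fits, "model_fits.csv")
  if (!is.null(evaluation$comparisons)) {
    emit(evaluation$comparisons, "model_comparisons.csv")
  }
  if (!is.null(evaluation$salience_fits)) {
    emit(evaluation$salience_fits, "salience_listener.csv")
  }
  for (tab in c("solvable", "reducible")) {
    if (!is.null(evaluation$tables[[tab]])) {
      emit(evaluation$tables[[tab]], paste0("behavioral_", tab, ".csv"))
    }
  }
  if (!is.null(evaluation$speaker)) {
    emit(evaluation$speaker$table[, c("condition_id", "n", "pred_shape",
                                      "prop_shape")], "speaker.csv")
  }
  json <- file.path(dir, "summary.json")
  payload <- list(settings = evaluation$settings,
                  exclusions = evaluation$exclusions,
                  fits = evaluation$fits,
                  comparisons = evaluation$comparisons,
                  salience_fits = evaluation$salience_fits,
                  speaker = if (is.null(evaluation$speaker)) NULL else
                    list(fit = unclass(evaluation$speaker$fit),
                         shape_share_overall =
                           evaluation$speaker$shape_share_overall,
                         shape_share_equal_informative =
                           evaluation$speaker$shape_share_equal_informative),
                  tables = evaluation$tables)
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(c(paths, json))
}
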