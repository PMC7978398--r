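#' Construct a metrics table
#'
#' A per-model, per-saliency-method grid of the four explainability
#' metrics. Use this constructor to assemble a table from externally
#' reported values (e.g. a published comparison) for the summary
#' arithmetic; [compare_models()] produces the same structure by
#' computation.
#'
#' @param df A data.frame with columns `model`, `method`, `pixel`,
#'   `sectional`, `interval`, `congruence`.
#' @return An object of class `metrics_table`.
#' @export
metrics_table <- function(df) {
  need <- c("model", "method", "pixel", "sectional", "interval", "congruence")
  if (!all(need %in% names(df))) stop("metrics table needs columns: ",
                                      paste(need, collapse = ", "))
  num <- df[c("pixel", "sectional", "interval", "congruence")]
  if (any(!is.na(as.matrix(num)) & (as.matrix(num) < 0 | as.matrix(num) > 1)))
    stop("metric values must lie in [0, 1]")
  structure(as.data.frame(df)[need], class = c("metrics_table", "data.frame"))
}

#' @export
print.metrics_table <- function(x, digits = 4, ...) {
  cat("Explainability metrics (rows: saliency method; per model)\n")
  for (m in unique(x$model)) {
    cat(sprintf("\nModel: %s\n", m))
    sub <- x[x$model == m, c("method", "pixel", "sectional", "interval",
                             "congruence")]
    names(sub) <- c("Method", "Pixel", "Sect.", "Int.", "Cong.")
    print(format(sub, digits = digits), row.names = FALSE)
  }
  sl <- attr(x, "section_length")
  if (!is.null(sl))
    cat(sprintf(paste0("\nMean section length: %.1f samples (annotated) vs ",
                       "%.1f (unannotated);\nthe sectional variant scores ",
                       "sections by their maximum, so unequal lengths bias it.\n"),
                sl["annotated"], sl["unannotated"]))
  invisible(x)
}

#' Compare models via the full explainability grid
#'
#' For every model and every saliency method, computes attention maps on
#' the annotated records of `dataset` and all four explainability metrics,
#' yielding a complete model x method grid. A cell whose AUROC is
#' degenerate (single-class units) is flagged `NA` with a warning and the
#' grid is marked incomplete.
#'
#' @param models Named list of models supporting the saliency interface.
#' @param dataset A [ppg_dataset()] with annotated records.
#' @param methods Saliency methods to include.
#' @param interval_len_s Tile length for the interval variant.
#' @param ig_steps,ref_background,ref_steps,seed Passed to
#'   [attention_maps()].
#' @return A [metrics_table()] with attributes `section_length` and
#'   `complete`.
#' @export
compare_models <- function(models, dataset,
                           methods = c("reference", "integrated_gradients",
                                       "guided"),
                           interval_len_s = 5, ig_steps = 32,
                           ref_background = 8, ref_steps = 8, seed = 1) {
  if (is.null(names(models)))
    names(models) <- sprintf("model%d", seq_along(models))
  rows <- list(); complete <- TRUE; sec_len <- NULL
  for (mn in names(models)) {
    for (meth in methods) {
      maps <- attention_maps(models[[mn]], dataset, method = meth,
                             ig_steps = ig_steps,
                             ref_background = ref_background,
                             ref_steps = ref_steps, seed = seed)
      met <- tryCatch(
        explainability_metrics(dataset, maps, interval_len_s = interval_len_s),
        error = function(e) {
          warning(sprintf("cell (%s, %s) degenerate: %s", mn, meth,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(met)) {
        complete <- FALSE
        met <- list(congruence = NA_real_, pixel = NA_real_,
                    sectional = NA_real_, interval = NA_real_)
      } else sec_len <- met$section_length
      rows[[length(rows) + 1L]] <-
        data.frame(model = mn, method = meth, pixel = met$pixel,
                   sectional = met$sectional, interval = met$interval,
                   congruence = met$congruence)
    }
  }
  out <- metrics_table(do.call(rbind, rows))
  attr(out, "section_length") <- sec_len
  attr(out, "complete") <- complete
  out
}

#' Summary arithmetic over a two-model metrics grid
#'
#' Aggregates a complete grid into the headline comparison numbers:
#' the mean congruence advantage of `model_a` over `model_b` (mean over
#' saliency methods of the congruence difference), the mean Annotation
#' Classification advantage (mean over method x variant cells), the
#' per-variant means over both models and all methods, and each model's
#' mean congruence.
#'
#' @param table A [metrics_table()] containing complete rows for both
#'   models.
#' @param model_a,model_b Model names in the table.
#' @return List with `mean_congruence_diff`, `mean_ac_diff`,
#'   `per_variant_means` (named: pixel, sectional, interval) and
#'   `per_model_mean_congruence` (named by model).
#' @export
summarize_differences <- function(table, model_a, model_b) {
  pick <- function(m) {
    sub <- table[table$model == m, ]
    if (!nrow(sub) || anyNA(sub[c("pixel", "sectional", "interval",
                                  "congruence")]))
      stop("incomplete grid for model ", m)
    sub[order(sub$method), ]
  }
  a <- pick(model_a); b <- pick(model_b)
  if (!identical(a$method, b$method))
    stop("the two models cover different saliency methods")
  ac <- c("pixel", "sectional", "interval")
  both <- rbind(a, b)
  list(
    mean_congruence_diff = mean(a$congruence - b$congruence),
    mean_ac_diff = mean(as.matrix(a[ac]) - as.matrix(b[ac])),
    per_variant_means = colMeans(as.matrix(both[ac])),
    per_model_mean_congruence = stats::setNames(
      c(mean(a$congruence), mean(b$congruence)), c(model_a, model_b))
  )
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation; the p-value comes from the t transform with
#' `n - 2` degrees of freedom (via [stats::cor.test()]). Requires `n >= 3`
#' non-constant vectors.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p` and `n`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs for a correlation test")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# the explainability/performance pairs reported by the correlation study
study_pairs <- function() {
  rbind(
    data.frame(metric_1 = "Congruence", metric_2 = "Testing Accuracy",
               col_1 = "congruence", col_2 = "accuracy"),
    data.frame(metric_1 = "Sectional Classification",
               metric_2 = "Testing Accuracy", col_1 = "sectional",
               col_2 = "accuracy"),
    data.frame(metric_1 = "Interval Classification",
               metric_2 = "Testing Accuracy", col_1 = "interval",
               col_2 = "accuracy"),
    data.frame(metric_1 = "Pixel Classification",
               metric_2 = "Testing Accuracy", col_1 = "pixel",
               col_2 = "accuracy"),
    data.frame(metric_1 = "Pixel Classification", metric_2 = "NPV",
               col_1 = "pixel", col_2 = "npv"),
    data.frame(metric_1 = "Pixel Classification", metric_2 = "Specificity",
               col_1 = "pixel", col_2 = "specificity"))
}

#' Explainability-versus-performance correlation study
#'
#' Trains `length(fractions) * reps` classifiers on stratified fractions of
#' the training data (smaller fractions induce overfitting and spread the
#' test accuracy), evaluates each on the fixed test set (accuracy, NPV,
#' specificity; the artifactual class is the negative class), computes each
#' model's explainability metrics on the annotated test records, and
#' reports the Pearson correlation of every explainability/performance
#' pair, with a Bonferroni-adjusted significance column at `alpha / m`
#' (`m` = number of report rows).
#'
#' @param train_dataset,test_dataset [ppg_dataset()]s; the test set must
#'   contain annotated records.
#' @param fractions Training-set fractions to sweep.
#' @param reps Models trained per fraction.
#' @param config A [train_config()] shared by all runs.
#' @param model_args List of arguments to [build_cnn1d()] other than `n`
#'   and `seed` (e.g. `depth`, `channels`, `kernel_size`).
#' @param method Saliency method used for the explainability metrics.
#' @param interval_len_s Tile length for the interval variant.
#' @param val_fraction Per-run validation holdout fraction.
#' @param alpha Family-wise significance level before Bonferroni division.
#' @param seed Master seed; per-run seeds derive from it.
#' @return An object of class `explainability_study`: list with `records`
#'   (one row per trained model) and `report` (one row per correlation
#'   pair, with `bonferroni_alpha` and `significant` columns).
#' @export
explainability_performance_study <- function(train_dataset, test_dataset,
                                             fractions = c(0.05, 0.10, 0.20,
                                                           0.40, 0.50),
                                             reps = 5,
                                             config = train_config(),
                                             model_args = list(),
                                             method = "guided",
                                             interval_len_s = 5,
                                             val_fraction = 0.2,
                                             alpha = 0.05, seed = 1) {
  grid <- expand.grid(rep = seq_len(reps), fraction = fractions)
  run_seeds <- with_seed(seed, sample.int(2^31 - 2, nrow(grid)))
  records <- list()
  for (run in seq_len(nrow(grid))) {
    frac <- grid$fraction[run]
    run_seed <- run_seeds[run]
    rec <- tryCatch({
      sub_idx <- with_seed(run_seed, {
        unlist(lapply(unique(train_dataset$label), function(l) {
          ii <- which(train_dataset$label == l)
          ii[sample.int(length(ii), max(2L, round(length(ii) * frac)))]
        }))
      })
      sub <- train_dataset[sort(sub_idx)]
      parts <- split_dataset(sub, val_fraction = val_fraction,
                             seed = run_seed + 1L)
      cfg <- config; cfg$seed <- run_seed + 2L
      model <- do.call(build_cnn1d,
                       c(list(n = ncol(sub$x), seed = run_seed + 3L),
                         model_args))
      model <- train_cnn1d(model, parts$train, parts$val, cfg)
      perf <- evaluate_model(model, test_dataset)
      maps <- attention_maps(model, test_dataset, method = method,
                             seed = run_seed + 4L)
      met <- explainability_metrics(test_dataset, maps,
                                    interval_len_s = interval_len_s)
      n_excluded <- sum(vapply(maps, function(m) sum(m) == 0, logical(1)))
      if (n_excluded > 0)
        message(sprintf("run %d: %d record(s) had zero attention mass",
                        run, n_excluded))
      data.frame(fraction = frac, rep = grid$rep[run], seed = run_seed,
                 accuracy = perf$accuracy, npv = perf$npv,
                 specificity = perf$specificity,
                 congruence = met$congruence, pixel = met$pixel,
                 sectional = met$sectional, interval = met$interval,
                 n_train = length(sub), excluded_records = n_excluded)
    }, error = function(e) {
      warning(sprintf("run %d (fraction %.2f) failed and was excluded: %s",
                      run, frac, conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  records <- do.call(rbind, records)
  pairs <- study_pairs()
  m <- nrow(pairs)
  report <- do.call(rbind, lapply(seq_len(m), function(i) {
    x <- records[[pairs$col_1[i]]]; y <- records[[pairs$col_2[i]]]
    ok <- stats::complete.cases(x, y)
    res <- tryCatch(pearson_cor(x[ok], y[ok]),
                    error = function(e) list(r = NA_real_, p = NA_real_,
                                             n = sum(ok)))
    data.frame(metric_1 = pairs$metric_1[i], metric_2 = pairs$metric_2[i],
               r = res$r, p = res$p, n = res$n)
  }))
  report$bonferroni_alpha <- alpha / m
  report$significant <- !is.na(report$p) & report$p < report$bonferroni_alpha
  structure(list(records = records, report = report,
                 n_runs_requested = nrow(grid),
                 n_runs_completed = nrow(records), method = method),
            class = "explainability_study")
}

#' @export
print.explainability_study <- function(x, digits = 3, ...) {
  cat(sprintf("<explainability_study: %d/%d runs completed, saliency = %s>\n",
              x$n_runs_completed, x$n_runs_requested, x$method))
  rep <- x$report
  rep$r <- round(rep$r, digits); rep$p <- round(rep$p, digits)
  print(rep, row.names = FALSE)
  if (any(is.na(x$report$p)))
    cat("note: rows with n < 3 usable pairs have no p-value\n")
  invisible(x)
}

#' Write a metrics table as CSV, JSON, or a Markdown report
#'
#' @param table A [metrics_table()].
#' @param path Output file path.
#' @param format `"csv"`, `"json"`, or `"markdown"`.
#' @return Invisibly, the table.
#' @export
write_metrics_table <- function(table, path,
                                format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(as.data.frame(table), path, digits = NA,
                         dataframe = "rows")
  } else {
    lines <- c("# Explainability metrics", "",
               "| Model | Method | Pixel | Sect. | Int. | Cong. |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %.4f | %.4f | %.4f | %.4f |",
                       table$model, table$method, table$pixel,
                       table$sectional, table$interval, table$congruence))
    sl <- attr(table, "section_length")
    if (!is.null(sl))
      lines <- c(lines, "",
                 sprintf("Mean section length: %.1f samples (annotated) vs %.1f (unannotated).",
                         sl["annotated"], sl["unannotated"]))
    writeLines(lines, path)
  }
  invisible(table)
}
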