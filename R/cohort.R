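#' One-sided Welch t-test for the clinical vs non-clinical contrast
#'
#' Unpaired t-test with unequal variances (Satterthwaite degrees of
#' freedom); the alternative is that the clinical population has the higher
#' mean, so the p-value is the upper-tail probability.
#'
#' @param clinical,nonclinical Numeric feature values (e.g. per-epoch
#'   WFMR), at least two per group.
#' @return A tibble: `t`, `df`, `p`.
#' @export
welch_onesided <- function(clinical, nonclinical) {
  if (length(clinical) < 2L || length(nonclinical) < 2L) {
    abort("each group needs at least two values")
  }
  tt <- t.test(clinical, nonclinical, alternative = "greater", var.equal = FALSE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
}

.pop_levels <- c("nonclinical", "clinical")

# rpart pruned to at most `max_splits` internal split nodes
.fit_tree <- function(train, max_splits) {
  fit <- rpart::rpart(population ~ ., data = train, method = "class",
                      control = rpart::rpart.control(cp = 0, minsplit = 4,
                                                     minbucket = 2, xval = 0,
                                                     maxcompete = 0,
                                                     maxsurrogate = 0))
  cpt <- fit$cptable
  ok <- cpt[, "nsplit"] <= max_splits
  if (!all(ok)) {
    cp_cut <- max(cpt[!ok, "CP"]) + 1e-12
    fit <- rpart::prune(fit, cp = cp_cut)
  }
  fit
}

.fit_predict <- function(classifier, train, test, max_splits) {
  switch(
    classifier,
    nb = {
      fit <- e1071::naiveBayes(population ~ ., data = train)
      # threshold = 0: no density floor, far-tail points keep their class
      as.character(predict(fit, test, threshold = 0))
    },
    lr = {
      fit <- suppressWarnings(glm(population ~ ., data = train, family = binomial()))
      p <- predict(fit, test, type = "response")
      .pop_levels[1L + as.integer(p > 0.5)]
    },
    dt = {
      fit <- .fit_tree(train, max_splits)
      as.character(predict(fit, test, type = "class"))
    },
    abort(sprintf("unknown classifier '%s' (nb, lr, dt)", classifier))
  )
}

#' Leave-one-subject-out cohort classification
#'
#' All epochs of one subject form the test fold; the classifier is trained
#' on every other subject's epochs. Accuracy is the percentage of correctly
#' classified epochs over all folds. A subject counts as misclassified when
#' a majority of its epochs are misclassified (ties count as
#' misclassified). The decision tree is swept over a grid of maximum
#' internal-split counts and reports the accuracy at each value plus the
#' argmax.
#'
#' @param features A tibble with columns `subject_id`, `population` and one
#'   or more numeric feature columns (default all remaining numeric
#'   columns; restrict with `feature_cols`).
#' @param classifiers Any of `"nb"` (Gaussian naive Bayes), `"lr"`
#'   (unpenalized logistic regression), `"dt"` (decision tree).
#' @param max_splits Grid of maximum split counts for the tree (default
#'   5:30).
#' @param feature_cols Optional character vector naming the feature
#'   columns.
#' @param seed Seed fixed before fitting for any stochastic tie-breaking.
#' @return A `loso_result` list: `accuracy` (tibble: classifier, accuracy
#'   %), `subjects` (per-subject majority correctness), `dt_sweep`
#'   (accuracy per max-splits value), `n_epochs`.
#' @export
loso_classify <- function(features, classifiers = c("nb", "lr", "dt"),
                          max_splits = 5:30, feature_cols = NULL, seed = 1L) {
  stopifnot(all(c("subject_id", "population") %in% names(features)))
  bad <- setdiff(classifiers, c("nb", "lr", "dt"))
  if (length(bad)) abort(sprintf("unknown classifier '%s' (nb, lr, dt)", bad[1]))
  feature_cols <- feature_cols %||%
    setdiff(names(features)[vapply(features, is.numeric, logical(1))],
            c("epoch_id", "t_ea", "n_total"))
  if (!length(feature_cols)) abort("no numeric feature columns found")
  pops <- unique(features[c("subject_id", "population")])
  if (min(table(pops$population)) < 2L) abort("need at least 2 subjects per population")

  dat <- data.frame(population = factor(features$population, levels = .pop_levels),
                    features[feature_cols])
  sid <- features$subject_id
  set.seed(seed)

  run_loso <- function(classifier, ms) {
    pred <- character(nrow(dat))
    for (s in unique(sid)) {
      hold <- sid == s
      train <- dat[!hold, , drop = FALSE]
      if (length(unique(train$population)) < 2L) {
        abort("fold error: training fold contains a single class")
      }
      pred[hold] <- .fit_predict(classifier, train, dat[hold, , drop = FALSE], ms)
    }
    pred
  }
  acc <- function(pred) 100 * mean(pred == as.character(dat$population))

  dt_sweep <- NULL
  results <- list()
  subj_tabs <- list()
  for (cl in classifiers) {
    if (cl == "dt") {
      sweep_acc <- vapply(max_splits, function(ms) acc(run_loso("dt", ms)), numeric(1))
      dt_sweep <- tibble::tibble(max_splits = max_splits, accuracy = sweep_acc)
      best <- max_splits[which.max(sweep_acc)]
      pred <- run_loso("dt", best)
    } else {
      pred <- run_loso(cl, NA)
    }
    results[[cl]] <- tibble::tibble(classifier = cl, accuracy = acc(pred))
    correct <- pred == as.character(dat$population)
    subj_tabs[[cl]] <- tibble::tibble(subject_id = sid, correct = correct) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(classifier = cl,
                       correct = mean(.data$correct) > 0.5, .groups = "drop")
  }
  structure(list(accuracy = dplyr::bind_rows(results),
                 subjects = dplyr::bind_rows(subj_tabs),
                 dt_sweep = dt_sweep,
                 dt_best_max_splits = if (!is.null(dt_sweep)) {
                   dt_sweep$max_splits[which.max(dt_sweep$accuracy)]
                 } else NA_integer_,
                 n_epochs = nrow(dat)),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %d epochs\n", x$n_epochs))
  for (i in seq_len(nrow(x$accuracy))) {
    cat(sprintf("  %-3s accuracy %.1f%%\n", x$accuracy$classifier[i], x$accuracy$accuracy[i]))
  }
  if (!is.null(x$dt_sweep)) {
    cat(sprintf("  best max-splits for dt: %d\n", x$dt_best_max_splits))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.loso_result <- function(x, ...) x$accuracy

#' Five-number box-plot summary with outliers
#'
#' Median, quartiles (linear interpolation, type 7), whiskers at the most
#' extreme values within 1.5 IQR of the quartiles, and the outliers beyond.
#'
#' @param values Numeric vector, non-empty.
#' @return A list: `five` (named: `lower_whisker`, `q1`, `median`, `q3`,
#'   `upper_whisker`), `outliers`.
#' @export
boxplot_summary <- function(values) {
  if (!length(values)) abort("empty group")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  in_fence <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  list(five = c(lower_whisker = min(values[in_fence]), q1 = q[1],
                median = q[2], q3 = q[3], upper_whisker = max(values[in_fence])),
       outliers = sort(values[!in_fence]))
}

#' Compare the two populations on a per-epoch feature
#'
#' Bundles the one-sided Welch t-test, LOSO classification and per-group
#' box-plot summaries into one result object with [tidy()], [glance()] and
#' [autoplot()] methods.
#'
#' @param features A tibble with `subject_id`, `population` and the feature
#'   column.
#' @param feature Name of the feature column (default `"wfmr"`).
#' @param classifiers,max_splits Passed to [loso_classify()].
#' @param seed Passed to [loso_classify()].
#' @return A `cohort_result`.
#' @export
#' @examples
#' coh <- simulate_cohort(n_nonclinical = 3, n_clinical = 3, seed = 5)
#' res <- compare_cohorts(wfmr_features(coh))
#' tidy(res)
compare_cohorts <- function(features, feature = "wfmr",
                            classifiers = c("nb", "lr", "dt"),
                            max_splits = 5:30, seed = 1L) {
  stopifnot(feature %in% names(features))
  v <- features[[feature]]
  grp <- split(v, features$population)
  welch <- welch_onesided(grp[["clinical"]], grp[["nonclinical"]])
  loso <- loso_classify(features, classifiers = classifiers,
                        max_splits = max_splits, feature_cols = feature,
                        seed = seed)
  structure(list(feature = feature, welch = welch, loso = loso,
                 box = lapply(grp, boxplot_summary),
                 data = features[c("subject_id", "population", feature)]),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> feature '%s'\n", x$feature))
  cat(sprintf("  Welch one-sided: t = %.3f, df = %.1f, p = %.3g\n",
              x$welch$t, x$welch$df, x$welch$p))
  print(x$loso)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "welch_t", estimate = x$welch$t),
    tibble::tibble(term = "welch_p", estimate = x$welch$p),
    dplyr::transmute(x$loso$accuracy,
                     term = paste0("accuracy_", .data$classifier),
                     estimate = .data$accuracy)
  )
}

#' @exportS3Method generics::glance
glance.cohort_result <- function(x, ...) {
  tibble::tibble(feature = x$feature, t = x$welch$t, df = x$welch$df,
                 p = x$welch$p,
                 best_accuracy = max(x$loso$accuracy$accuracy),
                 n_epochs = x$loso$n_epochs)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cohort_result <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$population, y = .data[[object$feature]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = object$feature,
                  subtitle = sprintf("one-sided Welch p = %.3g", object$welch$p))
}
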