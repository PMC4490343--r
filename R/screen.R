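#' Well-level train/test split
#'
#' Reproduces the screening protocol's split: the condition rows of one third
#' of the wells (rounded up) go to the test set, and -- because each well has
#' about three baseline acquisitions per condition acquisition -- the baseline
#' rows of one ninth of the wells (rounded up) go to the test set, roughly
#' balancing the two classes there. All remaining rows train the classifier.
#' By default a well's baseline rows may stay in training while its condition
#' rows are tested (the protocol as described); `strict = TRUE` instead
#' forces well-level disjointness by dropping every remaining row of a test
#' well.
#'
#' @param table feature table (see [ml_table()]) with columns `well_id` and
#'   `condition`; exactly two condition labels, one of them `baseline_label`.
#' @param seed integer seed for the random well draw.
#' @param baseline_label label of the baseline class (default `"baseline"`).
#' @param strict logical; enforce well-level disjointness (default FALSE).
#' @return list with data.frames `train` and `test` (a partition of `table`
#'   unless `strict` drops rows) and the drawn well sets.
#' @export
well_split <- function(table, seed = NULL, baseline_label = "baseline",
                       strict = FALSE) {
  wells <- unique(table$well_id)
  W <- length(wells)
  if (W < 3) stop("well split undefined for fewer than 3 wells")
  labs <- unique(table$condition)
  if (length(labs) != 2 || !(baseline_label %in% labs))
    stop("table must contain exactly two labels including the baseline")
  if (!is.null(seed)) set.seed(seed)
  cond_test_wells <- sample(wells, ceiling(W / 3))
  base_test_wells <- if (strict) sample(cond_test_wells, ceiling(W / 9))
                     else sample(wells, ceiling(W / 9))
  is_base <- table$condition == baseline_label
  in_test <- (!is_base & table$well_id %in% cond_test_wells) |
             (is_base & table$well_id %in% base_test_wells)
  test <- table[in_test, , drop = FALSE]
  train <- table[!in_test, , drop = FALSE]
  if (strict)
    train <- train[!(train$well_id %in% cond_test_wells), , drop = FALSE]
  list(train = train, test = test,
       cond_test_wells = cond_test_wells, base_test_wells = base_test_wells)
}

default_svm_grid <- function() {
  list(cost = c(0.1, 1, 10, 100),
       gamma = 10^seq(-3, 1, length.out = 5))
}

feature_matrix <- function(table) {
  as.matrix(table[, paste0("p", 1:12), drop = FALSE])
}

#' Train and evaluate one RBF-SVM model
#'
#' Standardises the 12 features by the training set's mean and standard
#' deviation, tunes cost and kernel width over a coarse grid by 5-fold
#' cross-validated accuracy on the training rows, refits the best model on
#' the full training set and returns the fraction of test rows classified
#' correctly.
#'
#' @param train,test feature tables from [well_split()].
#' @param grid list with numeric vectors `cost` and `gamma`.
#' @param seed integer seed for the fold assignment.
#' @param baseline_label baseline class label.
#' @return list: `accuracy`, chosen `cost` and `gamma`, `n_train`, `n_test`.
#' @export
train_eval_once <- function(train, test, grid = default_svm_grid(),
                            seed = NULL, baseline_label = "baseline") {
  for (tb in list(train, test)) {
    if (length(unique(tb$condition)) != 2)
      stop("both labels must be present in train and test")
  }
  if (!is.null(seed)) set.seed(seed)
  Xtr <- feature_matrix(train)
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xte <- sweep(sweep(feature_matrix(test), 2, mu), 2, sdv, "/")
  ytr <- factor(train$condition == baseline_label, levels = c(FALSE, TRUE))
  yte <- factor(test$condition == baseline_label, levels = c(FALSE, TRUE))
  n <- nrow(Xtr)
  folds <- sample(rep(seq_len(5), length.out = n))
  best <- list(acc = -1, cost = NA, gamma = NA)
  for (cost in grid$cost) for (gamma in grid$gamma) {
    correct <- 0L
    for (f in seq_len(5)) {
      hold <- folds == f
      if (length(unique(ytr[!hold])) < 2) next
      fit <- e1071::svm(Xtr[!hold, , drop = FALSE], ytr[!hold],
                        kernel = "radial", cost = cost, gamma = gamma,
                        scale = FALSE)
      correct <- correct + sum(stats::predict(fit, Xtr[hold, , drop = FALSE]) ==
                                 ytr[hold])
    }
    acc <- correct / n
    if (acc > best$acc) best <- list(acc = acc, cost = cost, gamma = gamma)
  }
  fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, scale = FALSE)
  pred <- stats::predict(fit, Xte)
  list(accuracy = mean(pred == yte), cost = best$cost, gamma = best$gamma,
       cv_accuracy = best$acc, n_train = nrow(train), n_test = nrow(test))
}

#' Screening accuracy over repeated random splits
#'
#' The drug-effect index: repeats the well-level split and SVM train/evaluate
#' cycle (default 50 times) with independently drawn splits, and reports the
#' mean and standard error of the test accuracies. About 50% means the
#' classifier cannot tell condition beats from baseline beats (no detectable
#' effect); values near 1 indicate a strong, consistent effect.
#'
#' @param table feature table with exactly two labels (see [ml_table()]).
#' @param repeats number of randomized splits (default 50).
#' @param seed master seed; per-repeat seeds are derived from it, so the
#'   whole result is reproducible.
#' @param grid SVM hyperparameter grid (see [default_svm_grid()]).
#' @param baseline_label baseline class label.
#' @param strict well-level disjointness flag passed to [well_split()].
#' @return an object of class `screen_result`.
#' @export
svm_accuracy <- function(table, repeats = 50L, seed = 1L,
                         grid = default_svm_grid(),
                         baseline_label = "baseline", strict = FALSE) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * repeats)
  acc <- numeric(repeats)
  hp <- data.frame(cost = numeric(repeats), gamma = numeric(repeats))
  n_train <- integer(repeats); n_test <- integer(repeats)
  for (r in seq_len(repeats)) {
    sp <- well_split(table, seed = rep_seeds[2L * r - 1L],
                     baseline_label = baseline_label, strict = strict)
    res <- train_eval_once(sp$train, sp$test, grid = grid,
                           seed = rep_seeds[2L * r],
                           baseline_label = baseline_label)
    acc[r] <- res$accuracy
    hp$cost[r] <- res$cost; hp$gamma[r] <- res$gamma
    n_train[r] <- res$n_train; n_test[r] <- res$n_test
  }
  structure(list(
    per_repeat_accuracy = acc,
    mean_accuracy = mean(acc),
    sem_accuracy = stats::sd(acc) / sqrt(repeats),
    n_train = n_train, n_test = n_test,
    hyperparameters = hp, repeats = repeats, seed = seed
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("SVM screening accuracy: %.2f +/- %.2f %% (mean +/- SEM over %d repeats)\n",
              100 * x$mean_accuracy, 100 * x$sem_accuracy, x$repeats))
  cat(sprintf("  train/test sizes: %d-%d / %d-%d rows\n",
              min(x$n_train), max(x$n_train), min(x$n_test), max(x$n_test)))
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  out <- list(
    mean_accuracy = object$mean_accuracy,
    sem_accuracy = object$sem_accuracy,
    quartiles = stats::quantile(object$per_repeat_accuracy),
    hyperparameter_table = table(cost = object$hyperparameters$cost,
                                 gamma = signif(object$hyperparameters$gamma, 2))
  )
  class(out) <- "summary.screen_result"
  out
}

#' @export
print.summary.screen_result <- function(x, ...) {
  cat(sprintf("mean accuracy %.4f (SEM %.4f)\n", x$mean_accuracy, x$sem_accuracy))
  print(round(x$quartiles, 3))
  cat("selected hyperparameters (counts):\n")
  print(x$hyperparameter_table)
  invisible(x)
}

#' Beat feature table for a whole cohort
#'
#' Runs the profile (or flow + profile), beat segmentation and feature
#' extraction for every acquisition of a synthetic cohort and stacks the
#' per-beat rows, dropping each acquisition's last beat.
#'
#' @param cohort a cohort from [make_cohort()].
#' @param block block size in pixels for flow averaging (video fidelity).
#' @return a feature table (data.frame) ready for [svm_accuracy()] after
#'   subsetting to two labels.
#' @export
cohort_features <- function(cohort, block = 20L) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$acquisitions, function(a) {
    pr <- acquisition_profile(a, block = block)
    beats <- segment_beats(pr)
    if (nrow(beats) == 0) return(NULL)
    f <- beat_features(pr, beats)
    f$well_id <- a$well_id
    f$condition <- a$condition
    f$acquisition_index <- a$acquisition_index
    f
  })
  ml_table(do.call(rbind, rows))
}

# profile from one cohort acquisition, whatever its fidelity
acquisition_profile <- function(a, block = 20L) {
  if (inherits(a$data, "contractile_profile")) return(a$data)
  fl <- compute_flow(a$data)
  b <- min(block, dim(fl$u)[1], dim(fl$u)[2])
  profile_from_flow(block_average(fl, b))
}
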