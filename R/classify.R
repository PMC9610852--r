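#' Build a train/test split plan over an epoch-feature table
#'
#' Three evaluation protocols:
#' \describe{
#'   \item{`cv5`}{pooled, label-stratified 5-fold cross-validation over all
#'     epochs, seeded.}
#'   \item{`loso`}{leave-one-subject-out: one fold per subject.}
#'   \item{`personalized`}{per-subject out-of-time split: for each routine,
#'     epochs lying entirely within the first `train_window` seconds of the
#'     usable (post-rejection) timeline are training epochs; epochs starting at
#'     or after `train_window` are test epochs; boundary-straddling epochs are
#'     excluded, so train and test never overlap in time.}
#' }
#'
#' @param table an `epoch_features` table (see [feature_matrix()]).
#' @param scheme `"cv5"`, `"loso"` or `"personalized"`.
#' @param train_window personalized training span per routine, s (default
#'   180).
#' @param holdout_frac fraction of training epochs held out for tuning in the
#'   personalized scheme.
#' @param twin epoch length, s (used to test containment).
#' @param n_folds folds for `cv5`.
#' @param seed integer seed (fold assignment).
#' @return object of class `split_plan`.
#' @export
build_split <- function(table, scheme = c("cv5", "loso", "personalized"),
                        train_window = 180, holdout_frac = 0.5, twin = 90,
                        n_folds = 5, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(nrow(table) > 0)
  plan <- list(scheme = scheme, seed = seed, train_window = train_window,
               holdout_frac = holdout_frac, twin = twin)
  if (scheme == "cv5") {
    fold <- integer(nrow(table))
    with_seed(seed, for (lab in unique(table$label)) {
      idx <- which(table$label == lab)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    })
    plan$fold <- fold
  } else if (scheme == "loso") {
    plan$fold <- match(table$subject_id, unique(table$subject_id))
  } else {
    # usable-timeline-relative start per subject x routine
    rel <- stats::ave(table$epoch_start, table$subject_id, table$label,
                      FUN = function(s) s - min(s))
    train <- rel + twin <= train_window
    test <- rel >= train_window
    if (!any(test))
      stop("personalized split has zero test epochs; ",
           "use a smaller train_window")
    plan$train <- which(train)
    plan$test <- which(test)
  }
  structure(plan, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan:", x$scheme,
      switch(x$scheme,
             cv5 = sprintf("(%d folds)", max(x$fold)),
             loso = sprintf("(%d subjects)", max(x$fold)),
             personalized = sprintf("(%d train / %d test epochs)",
                                    length(x$train), length(x$test))), "\n")
  invisible(x)
}

# ---- model fitting ---------------------------------------------------------

# z-score by training-partition statistics only
standardize_fit <- function(x) {
  mu <- colMeans(x); s <- apply(x, 2, sd); s[s == 0 | is.na(s)] <- 1
  list(mu = mu, s = s)
}
standardize_apply <- function(x, z) sweep(sweep(x, 2, z$mu), 2, z$s, "/")

# Gaussian QDA with diagonal shrinkage, used when MASS::qda cannot invert a
# class covariance (small personalized partitions).
fit_rqda <- function(x, y, lambda = 0.3) {
  classes <- sort(unique(y))
  mods <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    S <- stats::cov(xi)
    target <- diag(mean(diag(S)) + 1e-8, ncol(x))
    Sr <- (1 - lambda) * S + lambda * target
    list(mu = colMeans(xi), Sinv = solve(Sr),
         logdet = determinant(Sr, logarithm = TRUE)$modulus,
         logprior = log(nrow(xi) / nrow(x)))
  })
  names(mods) <- classes
  structure(list(classes = classes, mods = mods), class = "rqda")
}
predict_rqda <- function(fit, x) {
  scores <- vapply(fit$mods, function(m) {
    d <- sweep(as.matrix(x), 2, m$mu)
    -0.5 * rowSums((d %*% m$Sinv) * d) - 0.5 * as.numeric(m$logdet) +
      m$logprior
  }, numeric(nrow(x)))
  fit$classes[max.col(matrix(scores, nrow = nrow(x)))]
}

fit_predict <- function(model_name, xtr, ytr, xte, k = 5, seed = 1L) {
  ytr <- factor(ytr)
  if (length(levels(ytr)) < 2)
    stop("single-class training partition (only '", levels(ytr), "')")
  switch(model_name,
    knn = as.character(class::knn(xtr, xte, ytr, k = k)),
    svm = {
      fit <- with_seed(seed, e1071::svm(xtr, ytr))
      as.character(predict(fit, xte))
    },
    qda = {
      fit <- tryCatch(MASS::qda(xtr, grouping = ytr),
                      error = function(e) fit_rqda(xtr, as.character(ytr)))
      if (inherits(fit, "rqda")) predict_rqda(fit, xte)
      else as.character(predict(fit, xte)$class)
    },
    boosted_tree = {
      yb <- as.integer(ytr == levels(ytr)[2])
      fit <- with_seed(seed, xgboost::xgboost(
        data = as.matrix(xtr), label = yb, nrounds = 100, verbose = 0,
        objective = "binary:logistic", nthread = 1))
      p <- predict(fit, as.matrix(xte))
      levels(ytr)[1 + as.integer(p > 0.5)]
    },
    bagged_tree = {
      fit <- with_seed(seed, randomForest::randomForest(
        x = xtr, y = ytr, ntree = 100, mtry = ncol(xtr)))
      as.character(predict(fit, xte))
    },
    stop("unknown model: ", model_name))
}

confusion_metrics <- function(truth, pred, positive = "R") {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = 100 * (tp + tn) / max(tp + tn + fp + fn, 1),
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Train and evaluate a classifier under a split plan
#'
#' Features are z-scored with training-partition statistics only; the model is
#' fit on the training partition and scored on the test partition (or fold by
#' fold). In the personalized scheme, each subject gets their own model;
#' the kNN neighbourhood size is tuned on a seeded 50% holdout of that
#' subject's training epochs and the model is then refit on the full training
#' split. The positive class is R (relaxed-inattention); sensitivity is the
#' recall of R epochs and specificity the recall of A epochs.
#'
#' @param table an `epoch_features` table.
#' @param plan a [build_split()] plan built on the same table.
#' @param model_name one of `"knn"`, `"svm"`, `"qda"`, `"boosted_tree"`,
#'   `"bagged_tree"`.
#' @param feature_set `"all"`, `"hrv_only"` or `"rwv_only"` (column subset
#'   applied before standardization).
#' @param k kNN neighbourhood size (fixed except in personalized tuning).
#' @param k_grid candidate k values for personalized tuning.
#' @param positive positive class label.
#' @param seed integer seed for every random element.
#' @return object of class `classifier_report`: overall metrics, confusion
#'   counts, and per-subject breakdown for `loso`/`personalized`.
#' @export
train_eval <- function(table, plan, model_name = "knn",
                       feature_set = c("all", "hrv_only", "rwv_only"),
                       k = 5, k_grid = c(1, 3, 5, 7, 9), positive = "R",
                       seed = 1L) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(plan, "split_plan"))
  cols <- switch(feature_set, all = feature_names(),
                 hrv_only = hrv_feature_names(),
                 rwv_only = rwv_feature_names())
  X <- as.matrix(table[, cols, drop = FALSE])
  y <- as.character(table$label)
  eval_split <- function(tr, te, kk = k, sd_seed = seed) {
    z <- standardize_fit(X[tr, , drop = FALSE])
    pred <- fit_predict(model_name, standardize_apply(X[tr, , drop = FALSE], z),
                        y[tr], standardize_apply(X[te, , drop = FALSE], z),
                        k = kk, seed = sd_seed)
    list(truth = y[te], pred = pred, idx = te)
  }
  per_subject <- NULL
  if (plan$scheme %in% c("cv5", "loso")) {
    outs <- lapply(sort(unique(plan$fold)), function(f) {
      te <- which(plan$fold == f); tr <- which(plan$fold != f)
      tryCatch(eval_split(tr, te, sd_seed = child_seed(seed, f)),
               error = function(e) stop("fold ", f, ": ",
                                        conditionMessage(e), call. = FALSE))
    })
    truth <- unlist(lapply(outs, `[[`, "truth"))
    pred <- unlist(lapply(outs, `[[`, "pred"))
    idx <- unlist(lapply(outs, `[[`, "idx"))
    if (plan$scheme == "loso") {
      subs <- unique(table$subject_id)
      per_subject <- do.call(rbind, lapply(seq_along(outs), function(i) {
        m <- confusion_metrics(outs[[i]]$truth, outs[[i]]$pred, positive)
        data.frame(subject_id = subs[i], accuracy = m$accuracy,
                   sensitivity = m$sensitivity, specificity = m$specificity)
      }))
    }
  } else {
    subs <- unique(table$subject_id)
    outs <- lapply(seq_along(subs), function(i) {
      s <- subs[i]
      tr <- intersect(plan$train, which(table$subject_id == s))
      te <- intersect(plan$test, which(table$subject_id == s))
      if (!length(te)) stop("subject ", s, ": zero personalized test epochs;",
                            " use a smaller train_window", call. = FALSE)
      kk <- k
      if (model_name == "knn" && length(tr) >= 4) {
        hold <- with_seed(child_seed(seed, i), {
          sample(tr, max(1, round(plan$holdout_frac * length(tr))))
        })
        fit_tr <- setdiff(tr, hold)
        if (length(unique(y[fit_tr])) == 2) {
          accs <- vapply(k_grid, function(kg) {
            o <- eval_split(fit_tr, hold, kk = min(kg, length(fit_tr)))
            mean(o$truth == o$pred)
          }, 1)
          kk <- k_grid[which.max(accs)]
        }
      }
      tryCatch(eval_split(tr, te, kk = kk, sd_seed = child_seed(seed, i)),
               error = function(e) stop("subject ", s, ": ",
                                        conditionMessage(e), call. = FALSE))
    })
    truth <- unlist(lapply(outs, `[[`, "truth"))
    pred <- unlist(lapply(outs, `[[`, "pred"))
    per_subject <- do.call(rbind, lapply(seq_along(outs), function(i) {
      m <- confusion_metrics(outs[[i]]$truth, outs[[i]]$pred, positive)
      data.frame(subject_id = subs[i], accuracy = m$accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity)
    }))
  }
  m <- confusion_metrics(truth, pred, positive)
  structure(list(scheme = plan$scheme, model = model_name,
                 feature_set = feature_set, positive = positive,
                 accuracy = m$accuracy, sensitivity = m$sensitivity,
                 specificity = m$specificity,
                 confusion = c(tp = m$tp, fn = m$fn, tn = m$tn, fp = m$fp),
                 per_subject = per_subject, n_test = length(truth),
                 seed = seed),
            class = "classifier_report")
}

#' Feature-set ablation
#'
#' Runs [train_eval()] restricted to one feature family at a time (all 43,
#' the 7 HRV-only, or the 36 RWV-only columns).
#'
#' @inheritParams train_eval
#' @return a `classifier_report` tagged with the feature set.
#' @export
ablation <- function(table, plan, feature_set = c("all", "hrv_only",
                                                  "rwv_only"),
                     model_name = "knn", ...) {
  feature_set <- match.arg(feature_set)
  train_eval(table, plan, model_name = model_name, feature_set = feature_set,
             ...)
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "classifier_report [%s, %s, %s]: positive class %s\n  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  (n = %d)\n",
    x$scheme, x$model, x$feature_set, x$positive, x$accuracy, x$sensitivity,
    x$specificity, x$n_test))
  invisible(x)
}

#' @export
summary.classifier_report <- function(object, ...) {
  print(object)
  if (!is.null(object$per_subject)) {
    cat("per-subject:\n")
    print(object$per_subject, row.names = FALSE)
  }
  invisible(object)
}

#' Cohort summary of per-subject classification reports
#'
#' Stacks per-subject accuracy/sensitivity/specificity rows and appends an
#' unweighted mean row.
#'
#' @param per_subject data frame with columns `subject_id`, `accuracy`,
#'   `sensitivity`, `specificity` (e.g. the `per_subject` field of a
#'   personalized/LOSO `classifier_report`).
#' @return data frame: the per-subject rows plus a final `Mean` row.
#' @export
report_summary <- function(per_subject) {
  stopifnot(nrow(per_subject) >= 1,
            all(c("subject_id", "accuracy", "sensitivity", "specificity")
                %in% names(per_subject)))
  mean_row <- data.frame(
    subject_id = "Mean",
    accuracy = mean(per_subject$accuracy, na.rm = TRUE),
    sensitivity = mean(per_subject$sensitivity, na.rm = TRUE),
    specificity = mean(per_subject$specificity, na.rm = TRUE))
  rbind(per_subject[, names(mean_row)], mean_row)
}
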