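# Instance-to-patient aggregation, AUROC and threshold metrics,
# calibration, and conventional machine-learning feature baselines.

#' Aggregation configuration
#'
#' @param strategy `"mean_vote"` (mean of the first `n_images` instance
#'   probabilities), `"majority_vote"` (fraction of those above 0.5) or
#'   `"mil_topk"` (mean of the `k` highest-confidence instances).
#' @param n_images Instances aggregated per decision for the voting
#'   strategies (`Inf` uses all).
#' @param k Top-k pool size for `"mil_topk"`.
#' @return An `aggregation_config` list.
#' @export
aggregation_config <- function(strategy = "mean_vote", n_images = Inf,
                               k = 5) {
  strategy <- match.arg(strategy,
                        c("mean_vote", "majority_vote", "mil_topk"))
  stopifnot(k >= 1, n_images >= 1)
  structure(list(strategy = strategy, n_images = n_images, k = k),
            class = "aggregation_config")
}

#' Build a prediction set
#'
#' @param patient_id,instance_id,probability,label Parallel vectors.
#' @return Data frame of class `prediction_set`.
#' @export
prediction_set <- function(patient_id, instance_id, probability, label) {
  stopifnot(all(probability >= 0 & probability <= 1))
  structure(data.frame(patient_id = patient_id,
                       instance_id = instance_id,
                       probability = probability, label = label,
                       stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}

#' Top-k pooling of one case's instance probabilities
#'
#' Mean of the `k` largest probabilities; `k` greater than the number of
#' instances falls back to the plain mean.
#'
#' @param probs Instance probabilities for one case.
#' @param k Pool size.
#' @return Case-level probability.
#' @export
mil_topk <- function(probs, k) {
  stopifnot(length(probs) >= 1, k >= 1)
  k <- min(k, length(probs))
  mean(sort(probs, decreasing = TRUE)[seq_len(k)])
}

#' Aggregate instance probabilities to patient level
#'
#' @param preds A [prediction_set()].
#' @param cfg An [aggregation_config()].
#' @return Data frame with one row per patient: `patient_id`,
#'   `probability`, `label`.
#' @export
aggregate_patient <- function(preds, cfg = aggregation_config()) {
  stopifnot(inherits(preds, "prediction_set"))
  ids <- unique(preds$patient_id)
  rows <- lapply(ids, function(id) {
    sub <- preds[preds$patient_id == id, ]
    p <- sub$probability
    m <- min(cfg$n_images, length(p))
    prob <- switch(cfg$strategy,
      mean_vote = mean(p[seq_len(m)]),
      majority_vote = mean(p[seq_len(m)] > 0.5),
      mil_topk = mil_topk(p, cfg$k)
    )
    data.frame(patient_id = id, probability = prob,
               label = sub$label[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random
#' positive outranks a random negative, ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration by equal-width probability bins
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param n_bins Number of equal-width bins over [0, 1].
#' @return List with `bins` (data frame: bin midpoint, mean predicted
#'   probability, observed event rate, count) and `brier` (mean squared
#'   probability error).
#' @export
calibration_bins <- function(probs, labels, n_bins = 10) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  b <- findInterval(probs, edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(i) {
    sel <- b == i
    data.frame(midpoint = (edges[i] + edges[i + 1]) / 2,
               mean_pred = if (any(sel)) mean(probs[sel]) else NA_real_,
               event_rate = if (any(sel)) mean(labels[sel]) else NA_real_,
               n = sum(sel))
  }))
  list(bins = bins, brier = mean((probs - labels)^2))
}

#' Evaluate a prediction set at image and patient level
#'
#' @param preds A [prediction_set()].
#' @param cfg An [aggregation_config()] for the patient-level
#'   aggregation.
#' @param threshold Decision threshold for sensitivity/specificity on
#'   the aggregated patient probabilities.
#' @return An `eval_report` list: `auroc_image`, `auroc_patient`,
#'   `sensitivity`, `specificity`, `accuracy`, `calibration`,
#'   `patient_probs`.
#' @export
evaluate_predictions <- function(preds, cfg = aggregation_config(),
                                 threshold = 0.5) {
  stopifnot(inherits(preds, "prediction_set"))
  pat <- aggregate_patient(preds, cfg)
  dec <- as.integer(pat$probability > threshold)
  tp <- sum(dec == 1 & pat$label == 1); fn <- sum(dec == 0 & pat$label == 1)
  tn <- sum(dec == 0 & pat$label == 0); fp <- sum(dec == 1 & pat$label == 0)
  structure(list(
    auroc_image = auroc(preds$probability, preds$label),
    auroc_patient = auroc(pat$probability, pat$label),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / nrow(pat),
    calibration = calibration_bins(pat$probability, pat$label),
    patient_probs = pat
  ), class = "eval_report")
}

#' Mean and SD of metrics across repeats
#'
#' @param reports List of `eval_report`s.
#' @return Data frame with one row per metric: `mean`, `sd`.
#' @export
summarize_repeats <- function(reports) {
  metrics <- c("auroc_image", "auroc_patient", "sensitivity",
               "specificity", "accuracy")
  vals <- sapply(metrics, function(m)
    vapply(reports, function(r) r[[m]], numeric(1)))
  vals <- matrix(vals, nrow = length(reports),
                 dimnames = list(NULL, metrics))
  data.frame(metric = metrics,
             mean = colMeans(vals),
             sd = apply(vals, 2, stats::sd),
             row.names = NULL)
}

# ---- feature selection for the ML baselines ----------------------------

# one-way F statistic per feature column (binary grouping)
f_value_scores <- function(X, y) {
  apply(X, 2, function(v) {
    m1 <- mean(v[y == 1]); m0 <- mean(v[y == 0])
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    gm <- mean(v)
    ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
    ssw <- sum((v[y == 1] - m1)^2) + sum((v[y == 0] - m0)^2)
    if (ssw < 1e-24) return(Inf)
    (ssb / 1) / (ssw / (length(v) - 2))
  })
}

# mutual information with the label after quantile binning
mutual_info_scores <- function(X, y, bins = 8) {
  apply(X, 2, function(v) {
    qs <- unique(stats::quantile(v, seq(0, 1, length.out = bins + 1),
                                 type = 7, names = FALSE))
    if (length(qs) < 2) return(0)
    b <- findInterval(v, qs, rightmost.closed = TRUE, all.inside = TRUE)
    tab <- table(b, y) / length(v)
    px <- rowSums(tab); py <- colSums(tab)
    mi <- 0
    for (i in seq_along(px)) for (j in seq_along(py)) {
      if (tab[i, j] > 0)
        mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
    }
    mi
  })
}

# recursive feature elimination on standardized logistic coefficients
rfe_select <- function(X, y, n_keep) {
  feats <- colnames(X)
  Xs <- scale(X)
  while (length(feats) > n_keep) {
    fit <- suppressWarnings(stats::glm.fit(
      cbind(1, Xs[, feats, drop = FALSE]), y,
      family = stats::binomial()))
    co <- abs(fit$coefficients[-1])
    co[is.na(co)] <- 0
    drop_n <- max(1L, floor(length(feats) * 0.2))
    drop_n <- min(drop_n, length(feats) - n_keep)
    feats <- feats[order(co)][-seq_len(drop_n)]
    feats <- feats[order(match(feats, colnames(X)))]
  }
  feats
}

#' Select features on training data
#'
#' @param X Numeric feature matrix (training rows only).
#' @param y 0/1 labels.
#' @param selector `"RFE"`, `"F_value"` or `"mutual_info"`.
#' @param n_keep Number of features to retain.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(X, y, selector = "F_value", n_keep = 10) {
  selector <- match.arg(selector, c("RFE", "F_value", "mutual_info"))
  n_keep <- min(n_keep, ncol(X))
  if (selector == "RFE") return(rfe_select(X, y, n_keep))
  sc <- switch(selector,
               F_value = f_value_scores(X, y),
               mutual_info = mutual_info_scores(X, y))
  names(sort(sc, decreasing = TRUE))[seq_len(n_keep)]
}

fit_baseline <- function(X, y, model) {
  switch(model,
    logistic = {
      df <- data.frame(X, y = y)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      function(Xn) {
        p <- stats::predict(fit, newdata = data.frame(Xn),
                            type = "response")
        pmin(pmax(unname(p), 0), 1)
      }
    },
    random_forest = {
      fit <- randomForest::randomForest(X, as.factor(y))
      function(Xn) unname(stats::predict(fit, Xn, type = "prob")[, "1"])
    },
    svm = {
      fit <- e1071::svm(X, as.factor(y), probability = TRUE)
      function(Xn) {
        pr <- attr(stats::predict(fit, Xn, probability = TRUE),
                   "probabilities")
        unname(pr[, "1"])
      }
    },
    knn = {
      force(X); force(y)
      function(Xn) {
        pred <- class::knn(X, Xn, factor(y), k = 5, prob = TRUE)
        p <- attr(pred, "prob")
        ifelse(pred == "1", p, 1 - p)
      }
    },
    stop("unknown model: ", model)
  )
}

#' Conventional machine-learning baselines on handcrafted features
#'
#' For each repeat of the split plan, zero-variance features are dropped,
#' feature selection is fit on the training patients only, a pulse-level
#' model is fit (logistic regression, random forest, SVM or k-nearest
#' neighbors with default settings), and test-set pulses are scored and
#' aggregated to patient level under the same evaluation contract as the
#' CNN.
#'
#' @param features A feature table (data frame with `patient_id`,
#'   `label` and numeric feature columns, e.g. from
#'   [cohort_feature_table()]).
#' @param selector Feature-selection method; see [select_features()].
#' @param model `"logistic"`, `"random_forest"`, `"svm"` or `"knn"`.
#' @param plan A `split_plan` over the feature table's patients.
#' @param n_keep Features retained by the selector.
#' @param agg_cfg Patient aggregation for evaluation.
#' @param threshold Decision threshold.
#' @return List with `per_repeat` (list of `eval_report`s), `summary`
#'   (mean/SD table) and `selected` (features chosen per repeat).
#' @export
ml_baselines <- function(features, selector = "F_value",
                         model = "logistic", plan, n_keep = 10,
                         agg_cfg = aggregation_config(),
                         threshold = 0.5) {
  stopifnot(inherits(plan, "split_plan"))
  meta_cols <- intersect(c("patient_id", "pulse_id", "label",
                           "dn_method"), names(features))
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                              logical(1))], meta_cols)
  X_all <- as.matrix(features[, feat_cols, drop = FALSE])
  keep_rows <- stats::complete.cases(X_all)
  features <- features[keep_rows, ]
  X_all <- X_all[keep_rows, , drop = FALSE]
  reports <- list(); selected <- list()
  for (rep_i in seq_len(plan$n_repeats)) {
    asg <- plan$assignments[[rep_i]]
    set_of <- asg$set[match(features$patient_id, asg$patient_id)]
    tr <- which(set_of %in% c("train", "val"))
    te <- which(set_of == "test")
    Xtr <- X_all[tr, , drop = FALSE]
    vars <- apply(Xtr, 2, stats::var)
    usable <- colnames(Xtr)[is.finite(vars) & vars > 1e-24]
    if (length(usable) < ncol(Xtr))
      message(ncol(Xtr) - length(usable),
              " zero-variance features dropped")
    sel <- select_features(Xtr[, usable, drop = FALSE],
                           features$label[tr], selector, n_keep)
    pred_fn <- fit_baseline(Xtr[, sel, drop = FALSE],
                            features$label[tr], model)
    probs <- pred_fn(X_all[te, sel, drop = FALSE])
    preds <- prediction_set(features$patient_id[te],
                            instance_id = seq_along(te),
                            probability = probs,
                            label = features$label[te])
    reports[[rep_i]] <- evaluate_predictions(preds, agg_cfg, threshold)
    selected[[rep_i]] <- sel
  }
  list(per_repeat = reports, summary = summarize_repeats(reports),
       selected = selected)
}

#' Paired bootstrap comparison of two models' patient-level AUROCs
#'
#' Resamples patients with replacement and compares the AUROC difference
#' to zero. No particular reference test is implemented here; this is a
#' generic surrogate, not a reproduction of any published p-value.
#'
#' @param probs_a,probs_b Patient-level probabilities from two models on
#'   the same patients.
#' @param labels 0/1 outcomes.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed.
#' @return List with `delta` (observed AUROC difference a - b) and
#'   `p_value` (two-sided bootstrap p).
#' @export
compare_models_bootstrap <- function(probs_a, probs_b, labels,
                                     n_boot = 2000, seed = 1) {
  stopifnot(length(probs_a) == length(labels),
            length(probs_b) == length(labels))
  delta <- auroc(probs_a, labels) - auroc(probs_b, labels)
  n <- length(labels)
  ds <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) == 2) break
    }
    auroc(probs_a[i], labels[i]) - auroc(probs_b[i], labels[i])
  }, numeric(1)))
  p <- 2 * min(mean(ds <= 0) + 0.5 / n_boot, mean(ds >= 0) + 0.5 / n_boot)
  list(delta = delta, p_value = min(1, p))
}
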