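auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("patient aggregation matches hand-computed voting examples", {
  ps <- prediction_set(rep("A", 3), 1:3, c(0.2, 0.4, 0.9),
                       rep(1L, 3))
  expect_equal(aggregate_patient(ps, aggregation_config("mean_vote",
                                                        n_images = 3))$probability,
               0.5)
  expect_equal(aggregate_patient(ps, aggregation_config("majority_vote",
                                                        n_images = 3))$probability,
               1 / 3)
  one <- prediction_set("B", 1, 0.73, 0L)
  expect_equal(aggregate_patient(one)$probability, 0.73)
})

test_that("top-k pooling matches the sort-based oracle", {
  expect_equal(mil_topk(c(0.9, 0.1, 0.5), 2), 0.7)
  expect_equal(mil_topk(c(0.9, 0.1, 0.5), 7), mean(c(0.9, 0.1, 0.5)))
  expect_equal(mil_topk(rep(0.42, 6), 3), 0.42)
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(sample(1:12, 1))
    k <- sample(1:15, 1)
    kk <- min(k, length(p))
    expect_equal(mil_topk(p, k),
                 mean(sort(p, decreasing = TRUE)[1:kk]))
  }
})

test_that("aggregation strategies agree with sort-based references on
           random prediction sets", {
  set.seed(22)
  for (rep in 1:10) {
    n_pat <- 6
    rows <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
      m <- sample(1:8, 1)
      data.frame(pid = sprintf("P%d", i), prob = runif(m),
                 label = i %% 2)
    }))
    ps <- prediction_set(rows$pid, seq_len(nrow(rows)), rows$prob,
                         rows$label)
    agg <- aggregate_patient(ps, aggregation_config("mil_topk", k = 3))
    for (i in seq_len(n_pat)) {
      pid <- sprintf("P%d", i)
      p <- rows$prob[rows$pid == pid]
      kk <- min(3, length(p))
      expect_equal(agg$probability[agg$patient_id == pid],
                   mean(sort(p, decreasing = TRUE)[1:kk]))
    }
  }
})

test_that("rank AUROC equals the all-pairs brute force exactly for
           small n, with ties", {
  expect_equal(auroc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(23)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_identical(auroc(scores, labels), auroc_brute(scores, labels))
  }
  expect_error(auroc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUROC of label-independent scores is near one half", {
  set.seed(24)
  scores <- runif(2000)
  labels <- sample(0:1, 2000, replace = TRUE)
  expect_lt(abs(auroc(scores, labels) - 0.5), 0.05)
})

test_that("raising positive scores never lowers AUROC", {
  set.seed(25)
  for (rep in 1:25) {
    n <- 30
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- runif(n)
    bumped <- scores + ifelse(labels == 1, runif(n, 0, 0.5), 0)
    expect_gte(auroc(bumped, labels), auroc(scores, labels))
  }
})

test_that("evaluation report: perfect predictions, calibration ordering,
           zero SD across identical repeats", {
  labs <- c(1, 1, 1, 0, 0)
  ps <- prediction_set(sprintf("P%d", 1:5), 1:5, labs, labs)
  ev <- evaluate_predictions(ps)
  expect_equal(ev$auroc_patient, 1.0)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)

  set.seed(26)
  labels <- sample(0:1, 400, replace = TRUE)
  calibrated <- ifelse(labels == 1, runif(400, 0.5, 1),
                       runif(400, 0, 0.5))
  cal <- calibration_bins(calibrated, labels)
  anti <- calibration_bins(1 - calibrated, labels)
  expect_lte(cal$brier, anti$brier)

  reports <- replicate(5, ev, simplify = FALSE)
  sm <- summarize_repeats(reports)
  expect_true(all(sm$sd == 0))
})

test_that("patient-level aggregation denoises instance scores on
           average", {
  set.seed(27)
  wins <- 0
  for (s in 1:12) {
    n_pat <- 30
    lab <- rep(c(1, 0), n_pat / 2)
    latent <- 0.8 * lab + rnorm(n_pat, 0, 0.4)
    rows <- do.call(rbind, lapply(seq_len(n_pat), function(i)
      data.frame(pid = sprintf("P%d", i), lab = lab[i],
                 prob = plogis(latent[i] + rnorm(8, 0, 1)))))
    ps <- prediction_set(rows$pid, seq_len(nrow(rows)), rows$prob,
                         rows$lab)
    ev <- evaluate_predictions(ps)
    wins <- wins + (ev$auroc_patient >= ev$auroc_image)
  }
  expect_gte(wins, 9)
})

test_that("feature selectors honour the requested count and ML baselines
           behave at the oracle and null extremes", {
  set.seed(28)
  n <- 200
  labels <- rep(c(0L, 1L), n / 2)
  X <- matrix(rnorm(n * 63), n,
              dimnames = list(NULL, paste0("f", 1:63)))
  expect_length(select_features(X, labels, "RFE", 10), 10)
  expect_length(select_features(X, labels, "F_value", 10), 10)
  expect_length(select_features(X, labels, "mutual_info", 10), 10)

  pats <- sprintf("P%03d", 1:n)
  plan <- make_splits(pats, labels, n_repeats = 2, seed = 9)
  # oracle feature: the label itself; non-numeric metadata columns such
  # as the landmark-method tag must be ignored
  oracle <- data.frame(patient_id = pats, label = labels,
                       dn_method = "local_min",
                       onefeat = labels + 0.0,
                       stringsAsFactors = FALSE)
  res <- ml_baselines(oracle, selector = "F_value", model = "logistic",
                      plan = plan, n_keep = 1)
  expect_true(all(vapply(res$per_repeat, function(r) r$auroc_patient,
                         numeric(1)) == 1))
  # pure noise: AUROC near one half
  noise <- cbind(data.frame(patient_id = pats, label = labels),
                 as.data.frame(X[, 1:10]))
  res0 <- ml_baselines(noise, selector = "F_value", model = "logistic",
                       plan = plan, n_keep = 5)
  expect_lt(abs(res0$summary$mean[res0$summary$metric ==
                                    "auroc_patient"] - 0.5), 0.2)
})

test_that("paired bootstrap model comparison returns a valid p-value", {
  set.seed(29)
  labels <- rep(c(0, 1), 30)
  pa <- plogis(labels + rnorm(60, 0, 0.8))
  pb <- runif(60)
  out <- compare_models_bootstrap(pa, pb, labels, n_boot = 300, seed = 4)
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  expect_gt(out$delta, 0)
  same <- compare_models_bootstrap(pa, pa, labels, n_boot = 100, seed = 4)
  expect_equal(same$delta, 0)
})
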