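test_that("MET table bands map activities to intensities", {
  expect_equal(met_intensity("walking"), "moderate")
  expect_equal(met_intensity("running"), "vigorous")
  expect_equal(met_intensity("lying"), "light")
  expect_equal(met_intensity("cycling"), "moderate")
  expect_equal(intensity_of_met(c(2.9, 3, 6, 6.1)),
               c("light", "moderate", "moderate", "vigorous"))
  expect_error(met_intensity("swimming"), "unknown")
})

test_that("sensor pair selection follows the fusion rules", {
  expect_equal(select_sensor_pair("light"), c("chest", "wrist"))
  expect_equal(select_sensor_pair("moderate"), c("wrist", "ankle"))
  expect_equal(select_sensor_pair("vigorous"), c("chest", "ankle"))
})

test_that("split intensity votes resolve to the more vigorous class", {
  expect_equal(activital:::vote_intensity("light", "light"), "light")
  expect_equal(activital:::vote_intensity("light", "moderate"), "moderate")
  expect_equal(activital:::vote_intensity("vigorous", "light"), "vigorous")
  expect_equal(activital:::vote_intensity("moderate", "vigorous"),
               "vigorous")
})

test_that("layer-1 gate uses exactly four magnitude features", {
  expect_length(intensity_features(rnorm(50)), 4L)
  expect_named(intensity_features(rnorm(50)),
               c("mad", "var", "rms", "iqr"))
  data <- small_har_data()
  g <- data$gate$chest
  expect_equal(ncol(g$h1), 4L)
  fit <- train_intensity_layer(g$h1, data$meta$intensity)
  acc <- mean(predict(fit, as.data.frame(g$h1), type = "class") ==
                data$meta$intensity)
  expect_gte(acc, 0.95)
  expect_error(train_intensity_layer(g$h1, rep("light", nrow(g$h1))),
               "2 intensity classes")
})

test_that("layer-2 fuses ten attributes per sensor into a 20-vector", {
  m <- matrix(rnorm(300), ncol = 3)
  expect_length(fusion_features(m), 10L)
  data <- small_har_data()
  models <- train_fusion_layer(data, num_trees = 30, seed = 1)
  expect_setequal(names(models),
                  c("light|chest+wrist", "moderate|ankle+wrist",
                    "vigorous|ankle+chest"))
  expect_equal(models[["light|chest+wrist"]]$num.independent.variables,
               20L)
  expect_setequal(models[["light|chest+wrist"]]$forest$levels,
                  c("standing", "sitting", "lying"))
})

test_that("an intensity with one activity degrades to a constant model", {
  co <- gen_cohort(2, default_profiles()[c("lying", "running")], seed = 2,
                   duration_s = 8)
  data <- build_har_dataset(co)
  models <- train_fusion_layer(data, num_trees = 30, seed = 1)
  expect_equal(models[["light|chest+wrist"]]$type, "constant")
  expect_equal(models[["light|chest+wrist"]]$label, "lying")
})

test_that("classification routes exactly the mandated sensor pair", {
  data <- small_har_data()
  model <- train_har_model(data, num_trees = 50, seed = 3)
  res <- classify_activity(model, data)
  expect_false(any(res$fallback))
  for (iv in intensity_levels()) {
    rows <- res$pair[res$intensity == iv]
    if (!length(rows)) next
    expect_equal(unique(rows),
                 paste(sort(select_sensor_pair(iv)), collapse = "+"))
  }
  expect_gte(mean(res$label == data$meta$label), 0.95)
})

test_that("a missing sensor falls back to a trained alternative pair", {
  data <- small_har_data()
  model <- train_har_model(data, num_trees = 50, seed = 3,
                           all_pairs = TRUE)
  res <- suppressMessages(
    classify_activity(model, data, available = c("chest", "wrist")))
  expect_false(any(is.na(res$label)))
  expect_equal(unique(res$pair), "chest+wrist")
  expect_true(any(res$fallback))          # moderate/vigorous rerouted
  # without fallback models the gating sensor is still required
  expect_error(classify_activity(model, data, available = "wrist"),
               "gating")
})

test_that("confusion metrics satisfy the defining identities", {
  conf <- matrix(c(9, 1, 0, 0, 9, 1, 1, 0, 9), 3, byrow = TRUE,
                 dimnames = list(letters[1:3], letters[1:3]))
  rep <- metrics_from_confusion(conf)
  expect_equal(rep$per_class$accuracy, rep$per_class$recall)
  expect_equal(rep$per_class$accuracy[1], 0.9)
  expect_equal(rep$overall_accuracy, sum(diag(conf)) / sum(conf))
  # micro-averaged recall equals overall accuracy
  expect_equal(sum(diag(conf)) / sum(conf),
               sum(rep$per_class$recall * rep$per_class$n) /
                 sum(rep$per_class$n))

  set.seed(10)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    cm <- matrix(sample(0:20, k * k, replace = TRUE), k,
                 dimnames = list(seq_len(k), seq_len(k)))
    r <- metrics_from_confusion(cm)
    expect_equal(r$per_class$accuracy, r$per_class$recall)
    pr_eq <- r$per_class$precision == r$per_class$recall
    expect_equal(r$per_class$f_measure[pr_eq],
                 r$per_class$precision[pr_eq])
    # the harmonic mean lies between precision and recall
    expect_true(all(r$per_class$f_measure >=
                      pmin(r$per_class$precision, r$per_class$recall) -
                      1e-12))
    expect_true(all(r$per_class$f_measure <=
                      pmax(r$per_class$precision, r$per_class$recall) +
                      1e-12))
  }
})

test_that("evaluation schemes partition the data correctly", {
  data <- small_har_data()
  rep_loso <- evaluate_har(data, scheme = "loso", num_trees = 50, seed = 4)
  pd <- attr(rep_loso, "predictions")
  expect_setequal(unique(pd$subject), unique(data$meta$subject))
  expect_equal(nrow(pd), nrow(data$meta))
  expect_equal(sum(rep_loso$confusion), nrow(data$meta))
  expect_gte(rep_loso$overall_accuracy, 0.9)

  rep_kf <- evaluate_har(data, scheme = "kfold", k = 3, runs = 2,
                         num_trees = 30, seed = 4)
  expect_equal(sum(rep_kf$confusion), 2L * nrow(data$meta))
  expect_gte(rep_kf$overall_accuracy, 0.9)

  one <- activital:::subset_har(data, which(data$meta$subject == "S01"))
  expect_error(evaluate_har(one, scheme = "loso"), "2 subjects")
})

test_that("a perfectly separable two-class problem scores 1 everywhere", {
  co <- gen_cohort(2, default_profiles()[c("lying", "running")], seed = 6,
                   duration_s = 16)
  data <- build_har_dataset(co)
  rep <- evaluate_har(data, scheme = "kfold", k = 2, runs = 1,
                      num_trees = 30, seed = 1)
  expect_equal(rep$overall_accuracy, 1)
  expect_true(all(rep$per_class$f_measure == 1))
})
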