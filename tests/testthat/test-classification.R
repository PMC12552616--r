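# Stratified splitting, the gaussian-per-class baseline, the forest ensemble
# and the confusion-matrix evaluation.

seven_class_events <- function(n = 300, seed = 5) {
  simulate_labeled_events(ag_fixture(), analytes = straight_chain,
                          n_per_class = n, seed = seed)
}

test_that("stratified splitting is per-class exact, disjoint and deterministic", {
  ev <- data.frame(ires_pct = stats::rnorm(300), duration = rep(0.1, 300),
                   rms_noise = rep(1, 300),
                   label = rep(c("a", "b", "c"), each = 100))
  sp <- stratified_split(ev, 0.3, seed = 4)
  expect_equal(unname(table(sp$test$label)), rep(30L, 3), ignore_attr = TRUE)
  expect_equal(nrow(sp$train) + nrow(sp$test), 300L)
  sp2 <- stratified_split(ev, 0.3, seed = 4)
  expect_identical(sp$test, sp2$test)
  expect_equal(nrow(stratified_split(ev, 0, seed = 1)$test), 0L)
  one <- ev[c(1, 101, 201, 2), ]
  one$label[4] <- "lonely"
  expect_error(stratified_split(rbind(one), 0.3), ">= 2 events")
})

test_that("widely separated classes are classified perfectly", {
  set.seed(7)
  ev <- data.frame(
    ires_pct = c(stats::rnorm(100, 98, 0.05), stats::rnorm(100, 96, 0.05)),
    duration = stats::rexp(200, 8) + 5e-4,
    rms_noise = abs(stats::rnorm(200, 1, 0.05)),
    label = rep(c("hi", "lo"), each = 100))
  sp <- stratified_split(ev, 0.3, seed = 1)
  m <- train_event_classifier(sp$train, "gaussian")
  expect_equal(evaluate_classifier(m, sp$test)$accuracy, 1)
})

test_that("the gaussian baseline equals a brute-force posterior oracle", {
  ev <- seven_class_events(n = 14, seed = 11)  # <= 100 total per oracle contract
  sp <- stratified_split(ev, 0.3, seed = 2)
  m <- train_event_classifier(sp$train, "gaussian")
  expect_identical(predict(m, sp$test),
                   brute_force_gaussian_predict(sp$train, sp$test))
})

test_that("accuracy is invariant to feature order and affine feature rescaling", {
  ev <- seven_class_events(n = 60, seed = 3)
  sp <- stratified_split(ev, 0.3, seed = 3)
  m <- train_event_classifier(sp$train, "gaussian")
  base <- predict(m, sp$test)
  # column order of the data.frame is irrelevant (features found by name)
  expect_identical(predict(m, sp$test[, rev(names(sp$test))]), base)
  # affine rescaling of one feature (duration in ms instead of s)
  tr2 <- sp$train; te2 <- sp$test
  tr2$duration <- tr2$duration * 1000
  te2$duration <- te2$duration * 1000
  m2 <- train_event_classifier(tr2, "gaussian")
  expect_identical(predict(m2, te2), base)
})

test_that("label permutation collapses accuracy to chance", {
  ev <- seven_class_events(n = 120, seed = 6)
  sp <- stratified_split(ev, 0.3, seed = 6)
  perm <- sp$train
  set.seed(123)
  perm$label <- sample(perm$label)
  m <- train_event_classifier(perm, "gaussian")
  acc <- evaluate_classifier(m, sp$test)$accuracy
  expect_lt(acc, 0.30)  # chance is 1/7
})

test_that("larger level separation never hurts the classifier", {
  make_pair <- function(delta, seed) {
    fx <- list(pore = toy_pore(),
               analytes = list(
                 lo = analyte_spec("lo", 0, 0.3, diastereomer_spec("A", 96, 8)),
                 hi = analyte_spec("hi", 0, 0.3,
                                   diastereomer_spec("A", 96 + delta, 8))))
    class(fx) <- "pore_fixture"
    ev <- simulate_labeled_events(fx, n_per_class = 400, seed = seed)
    sp <- stratified_split(ev, 0.3, seed = seed)
    evaluate_classifier(train_event_classifier(sp$train, "gaussian"), sp$test)$accuracy
  }
  for (seed in 1:3) {
    accs <- vapply(c(0.05, 0.2, 0.8), make_pair, numeric(1), seed = seed)
    expect_true(all(diff(accs) >= 0))
  }
})

test_that("chain isomers with a 0.2% level gap are harder than the straight-chain set", {
  fx <- ag_fixture()
  iso <- simulate_labeled_events(fx, c("butanal", "2-methylpropanal"),
                                 n_per_class = 2000, seed = 31)
  spi <- stratified_split(iso, 0.3, seed = 31)
  acc_iso <- evaluate_classifier(train_event_classifier(spi$train, "gaussian"),
                                 spi$test)$accuracy
  sep <- simulate_labeled_events(fx, c("butanal", "hexanal"),
                                 n_per_class = 2000, seed = 31)
  sps <- stratified_split(sep, 0.3, seed = 31)
  acc_sep <- evaluate_classifier(train_event_classifier(sps$train, "gaussian"),
                                 sps$test)$accuracy
  expect_lt(acc_iso, acc_sep)
  expect_gt(acc_iso, 0.5)
})

test_that("the forest ensemble separates a straight-chain subset", {
  ev <- simulate_labeled_events(ag_fixture(),
                                c("propanal", "pentanal", "heptanal"),
                                n_per_class = 200, seed = 9)
  sp <- stratified_split(ev, 0.3, seed = 9)
  m <- train_event_classifier(sp$train, "forest", seed = 9, num_trees = 200)
  cm <- evaluate_classifier(m, sp$test)
  expect_gte(cm$accuracy, 0.98)
  expect_equal(unname(rowSums(cm$table)), rep(60L, 3), ignore_attr = TRUE)
})

test_that("gaussian models round-trip through JSON with identical predictions", {
  ev <- seven_class_events(n = 50, seed = 13)
  sp <- stratified_split(ev, 0.3, seed = 13)
  m <- train_event_classifier(sp$train, "gaussian")
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(m, path)
  m2 <- read_classifier(path)
  expect_identical(predict(m2, sp$test), predict(m, sp$test))
})

test_that("evaluation guards its contract", {
  ev <- seven_class_events(n = 20, seed = 15)
  sp <- stratified_split(ev, 0.3, seed = 15)
  m <- train_event_classifier(sp$train, "gaussian")
  alien <- sp$test
  alien$label <- "benzaldehyde"
  expect_error(evaluate_classifier(m, alien), "not trained")
  empty <- sp$test[0, ]
  cm <- evaluate_classifier(m, empty)
  expect_true(is.na(cm$accuracy))
  expect_equal(sum(cm$table), 0L)
})
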