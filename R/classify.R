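# Event classification from the three per-event features (I_res%, duration,
# within-event RMS noise). Two model kinds: a fully specified gaussian-
# per-class baseline (equal priors, maximum posterior) and a random-forest
# ensemble. Duration and RMS are log-transformed before fitting: both are
# positive and right-skewed (durations are exponential).

event_feature_matrix <- function(events) {
  need <- c("ires_pct", "duration", "rms_noise")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    stop("events lack feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(events[need])) stop("missing feature values", call. = FALSE)
  cbind(ires_pct = events$ires_pct,
        log_duration = log(events$duration),
        log_rms = log(pmax(events$rms_noise, .Machine$double.eps)))
}

#' Stratified train/test split
#'
#' Per class, `round(n * test_fraction)` events are drawn (without
#' replacement) into the test set; the split is disjoint, exhaustive and
#' deterministic given the seed.
#'
#' @param events Data.frame with a `label` column.
#' @param test_fraction Fraction of each class held out.
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames.
#' @export
stratified_split <- function(events, test_fraction = 0.3, seed = 1L) {
  stopifnot(is.data.frame(events), !is.null(events$label),
            test_fraction >= 0, test_fraction <= 1)
  tab <- table(events$label)
  if (any(tab < 2L)) {
    stop("each class needs >= 2 events (offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "), ")", call. = FALSE)
  }
  set.seed(derive_seed(seed, "split"))
  test_idx <- integer(0)
  for (cl in names(tab)) {
    idx <- which(events$label == cl)
    n_test <- round(length(idx) * test_fraction)
    if (n_test > 0L) test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = events[setdiff(seq_len(nrow(events)), test_idx), , drop = FALSE],
       test = events[sort(test_idx), , drop = FALSE])
}

#' Train an event classifier
#'
#' `kind = "gaussian"`: fits a mean vector and full covariance per class over
#' the three (transformed) features and classifies by maximum posterior with
#' equal class priors. A singular class covariance triggers a diagonal
#' fallback with a warning. `kind = "forest"`: a random forest (via
#' \pkg{ranger}) over the same features.
#'
#' @param train Data.frame with feature columns and `label`.
#' @param kind "gaussian" or "forest".
#' @param seed Integer seed (forest bootstrap).
#' @param num_trees Trees in the forest.
#' @return An object of class `event_classifier`.
#' @export
train_event_classifier <- function(train, kind = c("gaussian", "forest"),
                                   seed = 1L, num_trees = 500L) {
  kind <- match.arg(kind)
  stopifnot(!is.null(train$label))
  classes <- sort(unique(as.character(train$label)))
  if (length(classes) < 2L) stop("need >= 2 classes to train", call. = FALSE)
  X <- event_feature_matrix(train)
  y <- as.character(train$label)
  if (kind == "gaussian") {
    params <- lapply(classes, function(cl) {
      Xi <- X[y == cl, , drop = FALSE]
      mu <- colMeans(Xi)
      S <- stats::cov(Xi)
      ok <- is.finite(determinant(S)$modulus) &&
        !inherits(try(chol(S), silent = TRUE), "try-error")
      if (!ok) {
        warning("singular covariance for class ", cl,
                "; falling back to diagonal covariance", call. = FALSE)
        S <- diag(pmax(diag(S), 1e-12), ncol(Xi))
        dimnames(S) <- list(colnames(Xi), colnames(Xi))
      }
      list(mean = mu, cov = S)
    })
    names(params) <- classes
    model <- list(kind = "gaussian", classes = classes, params = params)
  } else {
    df <- data.frame(X, label = factor(y, levels = classes))
    fit <- ranger::ranger(label ~ ., data = df, num.trees = num_trees,
                          seed = derive_seed(seed, "forest"),
                          num.threads = 1L)
    model <- list(kind = "forest", classes = classes, fit = fit)
  }
  model$meta <- list(seed = seed, n_train = nrow(train))
  structure(model, class = "event_classifier")
}

gaussian_log_density <- function(X, mu, S) {
  p <- length(mu)
  L <- chol(S)
  logdet <- 2 * sum(log(diag(L)))
  md <- stats::mahalanobis(X, mu, S)
  -0.5 * (p * log(2 * pi) + logdet + md)
}

#' @param object An `event_classifier`.
#' @param newdata Data.frame of events (feature columns required).
#' @param type "class" for labels, "logdensity" for the per-class
#'   log-densities of the gaussian baseline.
#' @param ... Unused.
#' @rdname train_event_classifier
#' @export
predict.event_classifier <- function(object, newdata, type = "class", ...) {
  X <- event_feature_matrix(newdata)
  if (object$kind == "gaussian") {
    ld <- vapply(object$classes, function(cl) {
      p <- object$params[[cl]]
      gaussian_log_density(X, p$mean, p$cov)
    }, numeric(nrow(X)))
    if (nrow(X) == 1L) ld <- matrix(ld, nrow = 1L, dimnames = list(NULL, object$classes))
    if (type == "logdensity") return(ld)
    object$classes[max.col(ld, ties.method = "first")]
  } else {
    if (type == "logdensity") stop("log-densities only for the gaussian kind",
                                   call. = FALSE)
    as.character(stats::predict(object$fit,
                                data = data.frame(X))$predictions)
  }
}

#' Evaluate a classifier on a labeled test set
#'
#' @param model An `event_classifier`.
#' @param test Data.frame with feature columns and `label` (classes must be a
#'   subset of the trained classes).
#' @return List of class `confusion_matrix`: `table` (true x predicted
#'   counts), `accuracy` (fraction correct), `per_class_recall`.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "event_classifier"), !is.null(test$label))
  if (nrow(test) == 0L) {
    tab <- table(factor(character(0), model$classes),
                 factor(character(0), model$classes))
    return(structure(list(table = tab, accuracy = NA_real_,
                          per_class_recall = stats::setNames(
                            rep(NA_real_, length(model$classes)), model$classes)),
                     class = "confusion_matrix"))
  }
  unseen <- setdiff(unique(as.character(test$label)), model$classes)
  if (length(unseen)) {
    stop("test set contains classes the model was not trained on: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  pred <- predict(model, test)
  truth <- factor(as.character(test$label), levels = model$classes)
  pred <- factor(pred, levels = model$classes)
  tab <- table(truth, pred)
  structure(list(table = tab,
                 accuracy = sum(diag(tab)) / sum(tab),
                 per_class_recall = diag(tab) / pmax(1L, rowSums(tab))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Accuracy: %.1f%% over %d events\n",
              100 * x$accuracy, sum(x$table)))
  print(x$table)
  invisible(x)
}

#' Serialize / load a gaussian baseline classifier (JSON)
#'
#' The gaussian baseline is fully described by its per-class means and
#' covariances and round-trips through JSON with identical predictions.
#' Forest models are R objects; persist those with `saveRDS()`.
#'
#' @param model A gaussian `event_classifier`.
#' @param path File path.
#' @return `path` invisibly / an `event_classifier`.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "event_classifier"))
  if (model$kind != "gaussian") {
    stop("JSON serialization supports the gaussian baseline; use saveRDS() ",
         "for forest models", call. = FALSE)
  }
  obj <- list(kind = "gaussian", classes = model$classes,
              params = lapply(model$params, function(p) {
                list(mean = as.numeric(p$mean), cov = unclass(p$cov),
                     features = colnames(p$cov))
              }),
              meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    S <- matrix(unlist(p$cov), length(p$features), length(p$features),
                dimnames = list(p$features, p$features))
    list(mean = stats::setNames(as.numeric(p$mean), p$features), cov = S)
  })
  structure(list(kind = "gaussian", classes = obj$classes, params = params,
                 meta = obj$meta),
            class = "event_classifier")
}
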