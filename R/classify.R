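#' @title Pluggable classification over sparse examples
#' @description A generalized classifier contract: adapters expose
#'   `fit(x, y, params, seed)` and `predict(model, x, examples)` with
#'   per-class confidence scores, so different back-ends (regularized
#'   multinomial logistic regression, random forests, the always-correct
#'   oracle) plug into the same pipeline. Prediction records hold the full
#'   score vector so recall adjustment can rescale the negative class after
#'   the fact.
#' @name classify
NULL

#' Construct a classifier adapter
#'
#' @param name Adapter name.
#' @param fit `function(x, y, params, seed)` returning an opaque fit; `x` is
#'   a sparse design matrix, `y` a character vector of classes.
#' @param predict_scores `function(fit, x, examples)` returning a numeric
#'   matrix of per-class scores (columns named by class).
#' @param has_confidences,has_importances,stochastic Capability flags.
#' @param importances Optional `function(fit)` returning a named numeric
#'   vector of per-feature importances.
#' @return A `classifier_adapter`.
#' @export
classifier_adapter <- function(name, fit, predict_scores,
                               has_confidences = TRUE,
                               has_importances = FALSE,
                               stochastic = FALSE,
                               importances = NULL) {
  structure(list(name = name, fit = fit, predict_scores = predict_scores,
                 has_confidences = has_confidences,
                 has_importances = has_importances,
                 stochastic = stochastic, importances = importances),
            class = "classifier_adapter")
}

#' @export
print.classifier_adapter <- function(x, ...) {
  cat(sprintf("<classifier_adapter %s>%s%s\n", x$name,
              if (x$has_importances) " +importances" else "",
              if (x$stochastic) " (stochastic)" else ""))
  invisible(x)
}

constant_fit <- function(y) {
  tab <- sort(table(y), decreasing = TRUE)
  list(kind = "constant", classes = names(tab),
       major = names(tab)[1])
}

constant_scores <- function(fit, n) {
  m <- matrix(0, nrow = n, ncol = length(fit$classes),
              dimnames = list(NULL, fit$classes))
  m[, fit$major] <- 1
  m
}

#' The always-correct oracle adapter
#'
#' Returns the annotated class of every example with confidence 1; used to
#' measure the performance impact of individual pipeline components.
#' Prediction fails on examples without a gold class.
#'
#' @return A [classifier_adapter()].
#' @export
adapter_oracle <- function() {
  classifier_adapter(
    name = "oracle",
    fit = function(x, y, params, seed) list(kind = "oracle",
                                            classes = sort(unique(y))),
    predict_scores = function(fit, x, examples) {
      if (is.null(examples) || anyNA(examples$gold)) {
        bad <- if (is.null(examples)) "<unknown>" else
          paste(utils::head(examples$id[is.na(examples$gold)], 3),
                collapse = ", ")
        stop(sprintf("oracle classifier requires gold classes; missing for %s",
                     bad), call. = FALSE)
      }
      classes <- sort(unique(c(fit$classes, examples$gold)))
      m <- matrix(0, nrow = nrow(examples), ncol = length(classes),
                  dimnames = list(NULL, classes))
      m[cbind(seq_len(nrow(examples)), match(examples$gold, classes))] <- 1
      m
    })
}

#' Sparse multinomial logistic adapter (glmnet)
#'
#' The default trainable back-end: L2-regularized multinomial logistic
#' regression on the sparse feature matrix, with class probabilities as
#' confidences. The regularization strength `lambda` is the tunable
#' hyperparameter.
#'
#' @param alpha Elastic-net mixing parameter (0 = ridge).
#' @return A [classifier_adapter()].
#' @export
adapter_glmnet <- function(alpha = 0) {
  classifier_adapter(
    name = "glmnet",
    fit = function(x, y, params, seed) {
      lambda <- params$lambda %||% 1e-3
      classes <- sort(unique(y))
      if (length(classes) < 2 || ncol(x) < 2) {
        return(constant_fit(y))
      }
      # glmnet rejects classes with fewer than two observations; duplicate
      # singleton rows so every observed class stays learnable
      tab <- table(y)
      singles <- names(tab)[tab < 2]
      if (length(singles)) {
        idx <- which(y %in% singles)
        x <- rbind(x, x[idx, , drop = FALSE])
        y <- c(y, y[idx])
      }
      set.seed(seed)
      # fit along a decreasing path down to the requested lambda: pathwise
      # warm starts converge far more reliably than a cold single-value fit
      path <- sort(unique(c(10^seq(0, -3), lambda)), decreasing = TRUE)
      path <- path[path >= lambda]
      fit <- tryCatch(
        glmnet::glmnet(x, factor(y, levels = classes),
                       family = "multinomial", alpha = alpha,
                       lambda = path, standardize = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) return(constant_fit(y))
      list(kind = "glmnet", fit = fit, classes = classes, lambda = lambda)
    },
    predict_scores = function(fit, x, examples) {
      if (fit$kind == "constant") return(constant_scores(fit, nrow(x)))
      p <- stats::predict(fit$fit, newx = x, type = "response",
                          s = fit$lambda)
      m <- p[, , 1, drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = nrow(x),
                                       dimnames = list(NULL, fit$classes))
      m
    },
    has_importances = TRUE,
    importances = function(fit) {
      if (fit$kind == "constant") return(numeric())
      co <- glmnet::coef.glmnet(fit$fit, s = fit$lambda)
      w <- Reduce(`+`, lapply(co, function(m) abs(as.numeric(m))[-1]))
      stats::setNames(w, rownames(co[[1]])[-1])
    })
}

#' Random-forest adapter (ranger)
#'
#' Probability forest with impurity-based feature importances (total
#' decrease in node impurity averaged over the trees), the back-end used for
#' feature-importance reporting.
#'
#' @param num_trees Number of trees.
#' @return A [classifier_adapter()].
#' @export
adapter_forest <- function(num_trees = 100) {
  classifier_adapter(
    name = "forest",
    fit = function(x, y, params, seed) {
      classes <- sort(unique(y))
      if (length(classes) < 2) return(constant_fit(y))
      xd <- as.matrix(x)
      colnames(xd) <- paste0("f", seq_len(ncol(xd)))
      fit <- ranger::ranger(
        x = xd, y = factor(y, levels = classes),
        num.trees = params$num_trees %||% num_trees,
        probability = TRUE, importance = "impurity", seed = seed,
        num.threads = 1)
      list(kind = "ranger", fit = fit, classes = classes,
           feature_names = colnames(x))
    },
    predict_scores = function(fit, x, examples) {
      if (fit$kind == "constant") return(constant_scores(fit, nrow(x)))
      xd <- as.matrix(x)
      colnames(xd) <- paste0("f", seq_len(ncol(xd)))
      stats::predict(fit$fit, data = xd, num.threads = 1)$predictions
    },
    has_importances = TRUE,
    stochastic = FALSE,
    importances = function(fit) {
      if (fit$kind == "constant") return(numeric())
      stats::setNames(as.numeric(fit$fit$variable.importance),
                      fit$feature_names)
    })
}

#' Train a classifier on examples
#'
#' @param adapter A [classifier_adapter()].
#' @param examples Tibble of gold-labelled examples.
#' @param params Hyperparameter list passed to the adapter.
#' @param space Optional frozen [feature_space()] (built from the examples
#'   when omitted).
#' @param seed Seed forwarded to the adapter.
#' @return A `trained_classifier` holding the fit, the frozen feature space
#'   and the class inventory.
#' @export
train_classifier <- function(adapter, examples, params = list(),
                             space = NULL, seed = 1L) {
  if (anyNA(examples$gold)) {
    stop("training requires gold classes for every example", call. = FALSE)
  }
  if (is.null(space)) space <- feature_space(examples)
  x <- examples_to_matrix(examples, space)
  fit <- adapter$fit(x, examples$gold, params, seed)
  structure(list(adapter = adapter, fit = fit, space = space,
                 params = params,
                 classes = sort(unique(examples$gold))),
            class = "trained_classifier")
}

#' Predict examples with a trained classifier
#'
#' @param model A `trained_classifier`.
#' @param examples Tibble of examples (gold classes may be absent, except
#'   for the oracle).
#' @return Prediction records: tibble `id`, `pred` (argmax class) and
#'   list-column `scores` (named per-class confidences).
#' @export
predict_classifier <- function(model, examples) {
  if (!nrow(examples)) {
    return(tibble::tibble(id = character(), pred = character(),
                          scores = list()))
  }
  x <- examples_to_matrix(examples, model$space)
  m <- model$adapter$predict_scores(model$fit, x, examples)
  if (is.null(colnames(m))) colnames(m) <- model$classes
  pred <- colnames(m)[max.col(m, ties.method = "first")]
  tibble::tibble(id = examples$id, pred = pred,
                 scores = lapply(seq_len(nrow(m)), function(r) m[r, ]))
}

#' Classify gold-labelled examples with the oracle
#'
#' @param examples Tibble of examples with gold classes.
#' @return Prediction records with the gold class at confidence 1.
#' @export
oracle_classify <- function(examples) {
  ad <- adapter_oracle()
  fit <- ad$fit(NULL, examples$gold %||% character(), list(), 1L)
  m <- ad$predict_scores(fit, NULL, examples)
  tibble::tibble(id = examples$id,
                 pred = colnames(m)[max.col(m, ties.method = "first")],
                 scores = lapply(seq_len(nrow(m)), function(r) m[r, ]))
}

#' Recall adjustment: rescale the negative-class confidence
#'
#' Multiplies the negative class score by `beta` in `[0,1]` and recomputes
#' the argmax: `beta = 1` is the identity, `beta = 0` forces every example
#' to its best positive class. The number of positive predictions is
#' non-increasing in `beta`.
#'
#' @param preds Prediction records (from [predict_classifier()]).
#' @param beta Multiplier in `[0,1]`.
#' @param neg_class Name of the negative class.
#' @return Prediction records with adjusted scores and argmax.
#' @export
adjust_recall <- function(preds, beta, neg_class = "neg") {
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) ||
      beta < 0 || beta > 1) {
    stop("beta must be a single number in [0,1]", call. = FALSE)
  }
  if (!nrow(preds)) return(preds)
  preds$scores <- lapply(preds$scores, function(s) {
    if (neg_class %in% names(s)) s[neg_class] <- s[neg_class] * beta
    s
  })
  preds$pred <- vapply(preds$scores, function(s) {
    nm <- names(s)
    # ties favour the positive class so beta = 0 always yields a positive
    ord <- order(-unlist(s), nm == neg_class)
    nm[ord[1]]
  }, character(1))
  preds
}

#' Exhaustive grid search over hyperparameters and recall adjustment
#'
#' Evaluates every combination of adapter hyperparameters and `beta` against
#' an objective on development data and returns the deterministic winner
#' (ties broken toward the largest `beta`, then the smallest regularization
#' value, then grid order).
#'
#' @param adapter A [classifier_adapter()].
#' @param train_examples,devel_examples Gold-labelled example tibbles.
#' @param param_grid List of hyperparameter lists (each passed to the
#'   adapter's `fit`).
#' @param betas Numeric vector of recall-adjustment values in `[0,1]`.
#' @param objective `function(preds, devel_examples)` returning a score to
#'   maximize; defaults to example-level micro-F over positive classes.
#' @param neg_class Negative class name for recall adjustment.
#' @param seed Seed forwarded to training.
#' @return List: `best_params`, `best_beta`, `best_score`, `results`
#'   (tibble of all grid points), `model` (refit at the winner).
#' @export
tune_parameters <- function(adapter, train_examples, devel_examples,
                            param_grid = list(list()), betas = 1,
                            objective = NULL, neg_class = "neg", seed = 1L) {
  if (!length(param_grid) || !length(betas)) {
    stop("the tuning grid must be non-empty", call. = FALSE)
  }
  if (is.null(objective)) {
    objective <- function(preds, ex) {
      example_micro_f(preds$pred, ex$gold, neg_class = neg_class)$f
    }
  }
  space <- feature_space(train_examples)
  rows <- list()
  best <- NULL
  for (pi in seq_along(param_grid)) {
    model <- train_classifier(adapter, train_examples,
                              params = param_grid[[pi]], space = space,
                              seed = seed)
    base_preds <- predict_classifier(model, devel_examples)
    reg <- param_grid[[pi]]$lambda %||% param_grid[[pi]]$reg %||% NA_real_
    for (beta in betas) {
      preds <- adjust_recall(base_preds, beta, neg_class = neg_class)
      sc <- objective(preds, devel_examples)
      rows[[length(rows) + 1]] <- tibble::tibble(
        param_index = pi, beta = beta, reg = reg, score = sc)
      cand <- list(pi = pi, beta = beta, reg = reg, score = sc, model = model)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && beta > best$beta) ||
          (sc == best$score && beta == best$beta &&
             !is.na(reg) && !is.na(best$reg) && reg < best$reg)) {
        best <- cand
      }
    }
  }
  list(best_params = param_grid[[best$pi]], best_beta = best$beta,
       best_score = best$score, results = dplyr::bind_rows(rows),
       model = best$model)
}

# example-level micro-averaged precision/recall/F over positive classes
example_micro_f <- function(pred, gold, neg_class = "neg") {
  tp <- sum(pred == gold & gold != neg_class)
  fp <- sum(pred != neg_class & pred != gold)
  fn <- sum(gold != neg_class & pred != gold)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(p = 100 * p, r = 100 * r, f = 100 * f, tp = tp, fp = fp, fn = fn)
}

#' Rank feature importances of a trained classifier
#'
#' Non-negative weights in descending order (normalized to sum to one),
#' with the reporting group of each feature.
#'
#' @param model A `trained_classifier` whose adapter declares the
#'   importance capability.
#' @return Tibble `feature`, `weight`, `group`, sorted by weight, of class
#'   `importance_report`.
#' @export
rank_feature_importances <- function(model) {
  ad <- model$adapter
  if (!isTRUE(ad$has_importances) || is.null(ad$importances)) {
    stop(sprintf("adapter '%s' does not expose feature importances", ad$name),
         call. = FALSE)
  }
  w <- ad$importances(model$fit)
  if (!length(w)) {
    return(structure(tibble::tibble(feature = character(), weight = numeric(),
                                    group = character()),
                     class = c("importance_report", "tbl_df", "tbl", "data.frame")))
  }
  if (is.null(names(w))) names(w) <- model$space$names[seq_along(w)]
  w <- pmax(w, 0)
  if (sum(w) > 0) w <- w / sum(w)
  out <- tibble::tibble(feature = names(w), weight = unname(w),
                        group = feature_group(names(w)))
  out <- out[order(-out$weight, out$feature), ]
  structure(out, class = c("importance_report", class(tibble::tibble())))
}

#' Per-group summary of an importance report
#'
#' Quartiles, interquartile whiskers and outlier counts of the per-feature
#' weights within each feature group, in the style of a box-plot table.
#'
#' @param x An `importance_report` from [rank_feature_importances()].
#' @param ... Unused.
#' @return Tibble with one row per group.
#' @export
tidy.importance_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$group),
    n = dplyr::n(),
    q1 = stats::quantile(.data$weight, 0.25),
    median = stats::median(.data$weight),
    q3 = stats::quantile(.data$weight, 0.75),
    max = max(.data$weight),
    outliers = sum(.data$weight >
                     stats::quantile(.data$weight, 0.75) +
                     1.5 * stats::IQR(.data$weight)),
    .groups = "drop")
}

#' Box plot of feature importances by group
#'
#' @param object An `importance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$group, y = .data$weight)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "normalized importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
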