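# Feature selection and classification: two-sample t-test filter, F-test
# threshold scan, forward best-first wrapper search, and a classifier
# battery evaluated with leave-one-out cross-validation.

# Vectorized per-feature two-sample statistics (equal variance, two-sided).
# Returns t, F (= t^2) and p-values; constant features get p = NA.
.feature_tests <- function(x, y) {
  x0 <- x[y == 0L, , drop = FALSE]
  x1 <- x[y == 1L, , drop = FALSE]
  n0 <- nrow(x0); n1 <- nrow(x1)
  if (n0 < 2L || n1 < 2L) stop("need at least 2 subjects per class")
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  v0 <- apply(x0, 2L, stats::var)
  v1 <- apply(x1, 2L, stats::var)
  sp2 <- ((n0 - 1L) * v0 + (n1 - 1L) * v1) / (n0 + n1 - 2L)
  tval <- (m1 - m0) / sqrt(sp2 * (1 / n0 + 1 / n1))
  tval[sp2 == 0] <- NA_real_
  p <- 2 * stats::pt(-abs(tval), df = n0 + n1 - 2L)
  data.frame(feature = colnames(x), t = tval, F = tval^2, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample t-test feature filter
#'
#' Keeps every feature whose equal-variance two-sided two-sample t-test
#' p-value is below `alpha`. Features constant across all subjects (zero
#' pooled variance) are excluded with a warning.
#'
#' @param table a `feature_table`.
#' @param alpha significance cutoff (default 0.05).
#' @return object of class `selection_result` with `method`, `selected`,
#'   `stats` (per-feature t/F/p), `alpha`.
#' @export
ttest_filter <- function(table, alpha = 0.05) {
  if (length(unique(table$y)) < 2L) stop("both classes must be present")
  st <- .feature_tests(table$x, table$y)
  if (anyNA(st$p)) {
    warning(sum(is.na(st$p)), " constant features excluded")
  }
  sel <- st$feature[!is.na(st$p) & st$p < alpha]
  structure(list(method = "ttest_filter", selected = sel, stats = st,
                 alpha = alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d features selected%s\n",
              x$method, length(x$selected),
              if (!is.null(x$accuracy)) sprintf(", LOOCV accuracy %.3f (%s)",
                                                x$accuracy, x$classifier) else ""))
  invisible(x)
}

## ---- classifier battery ----

.standardize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, `/`),
       test = sweep(sweep(test, 2L, mu), 2L, sdv, `/`))
}

# Each classifier: function(train_x, train_y, test_x) -> predicted 0/1.
# Library defaults, seeded by the caller where stochastic.
.classifiers <- list(
  svm = function(xtr, ytr, xte) {
    z <- .standardize(xtr, xte)
    fit <- e1071::svm(z$train, factor(ytr, levels = c(0, 1)), scale = FALSE)
    as.integer(as.character(stats::predict(fit, z$test)))
  },
  xgboost = function(xtr, ytr, xte) {
    fit <- xgboost::xgboost(xtr, factor(ytr, levels = c(0, 1)),
                            nrounds = 20L, nthreads = 1L, verbosity = 0)
    as.integer(stats::predict(fit, xte) >= 0.5)
  },
  knn = function(xtr, ytr, xte) {
    z <- .standardize(xtr, xte)
    as.integer(as.character(class::knn(z$train, z$test,
                                       factor(ytr, levels = c(0, 1)), k = 3L)))
  },
  dtree = function(xtr, ytr, xte) {
    d <- data.frame(y = factor(ytr, levels = c(0, 1)), xtr, check.names = FALSE)
    fit <- rpart::rpart(y ~ ., data = d,
                        control = rpart::rpart.control(minsplit = 4L, cp = 0.01))
    nd <- data.frame(xte, check.names = FALSE)
    as.integer(as.character(stats::predict(fit, nd, type = "class")))
  },
  nbayes = function(xtr, ytr, xte) {
    z <- .standardize(xtr, xte)
    fit <- e1071::naiveBayes(z$train, factor(ytr, levels = c(0, 1)))
    as.integer(as.character(stats::predict(fit, z$test)))
  },
  logistic = function(xtr, ytr, xte) {
    d <- data.frame(y = ytr, xtr, check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
    nd <- data.frame(xte, check.names = FALSE)
    as.integer(suppressWarnings(stats::predict(fit, nd, type = "response")) >= 0.5)
  },
  rf = function(xtr, ytr, xte) {
    fit <- randomForest::randomForest(xtr, factor(ytr, levels = c(0, 1)),
                                      ntree = 200L)
    as.integer(as.character(stats::predict(fit, xte)))
  }
)

#' Names of the available classifiers
#' @return character vector.
#' @export
classifier_names <- function() names(.classifiers)

#' Leave-one-out cross-validated accuracy
#'
#' Fits on n-1 subjects and predicts the held-out one, cycled over all
#' subjects. An empty feature set is scored by majority vote of the
#' training labels (the no-information baseline). Stochastic classifiers
#' are re-seeded deterministically per fold.
#'
#' @param table a `feature_table`.
#' @param features feature names to use (character; may be empty).
#' @param classifier one of [classifier_names()].
#' @param seed base seed.
#' @return list with `accuracy` and `predictions`.
#' @export
loocv_accuracy <- function(table, features, classifier = "svm", seed = 1L) {
  x <- table$x; y <- table$y
  n <- nrow(x)
  if (length(features) > 0L && !all(features %in% colnames(x))) {
    stop("unknown features: ",
         paste(setdiff(features, colnames(x)), collapse = ", "))
  }
  clf <- .classifiers[[classifier]]
  if (is.null(clf)) stop("unknown classifier: ", classifier)
  pred <- integer(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(features) == 0L) {
      tab <- tabulate(ytr + 1L, 2L)
      pred[i] <- which.max(tab) - 1L # tie -> class 0
      next
    }
    xtr <- x[-i, features, drop = FALSE]
    xte <- x[i, features, drop = FALSE]
    pred[i] <- with_seed(seed + i, clf(xtr, ytr, xte))
  }
  list(accuracy = mean(pred == y), predictions = pred)
}

#' F-test threshold scan
#'
#' Computes per-feature one-way ANOVA F-test p-values (for two classes
#' F = t^2, so the ranking matches the t-test) and iterates over a grid of
#' p-value thresholds: at each threshold the features below it are kept and
#' scored by LOOCV accuracy of `classifier`. Returns the best threshold and
#' subset; ties prefer the smaller subset, then the smaller threshold.
#'
#' @param table a `feature_table`.
#' @param classifier classifier name used for scoring.
#' @param grid p-value thresholds to scan.
#' @param seed LOOCV seed.
#' @return `selection_result` with `selected`, `threshold`, `accuracy`,
#'   `classifier`, `scan` (per-threshold accuracy trace).
#' @export
ftest_threshold_scan <- function(table, classifier = "svm",
                                 grid = seq(0.001, 0.10, by = 0.001),
                                 seed = 1L) {
  if (length(grid) == 0L) stop("threshold grid is empty")
  st <- .feature_tests(table$x, table$y)
  grid <- sort(grid)
  subsets <- lapply(grid, function(th) st$feature[!is.na(st$p) & st$p < th])
  sizes <- lengths(subsets)
  if (all(sizes == 0L)) stop("no threshold in the grid selects any feature")
  # score each distinct non-empty subset once
  keykeep <- !duplicated(vapply(subsets, paste, character(1L), collapse = "\r")) &
    sizes > 0L
  acc <- rep(NA_real_, length(grid))
  cache <- list()
  for (i in seq_along(grid)) {
    if (sizes[i] == 0L) next
    key <- paste(subsets[[i]], collapse = "\r")
    if (is.null(cache[[key]])) {
      cache[[key]] <- loocv_accuracy(table, subsets[[i]], classifier, seed)$accuracy
    }
    acc[i] <- cache[[key]]
  }
  ord <- order(-acc, sizes, grid, na.last = TRUE)
  best <- ord[1L]
  structure(list(method = "ftest_threshold_scan",
                 selected = subsets[[best]], stats = st,
                 threshold = grid[best], accuracy = acc[best],
                 classifier = classifier,
                 scan = data.frame(threshold = grid, n_features = sizes,
                                   accuracy = acc)),
            class = "selection_result")
}

#' Forward best-first subset search
#'
#' Maintains a priority queue of feature subsets keyed by LOOCV accuracy,
#' starting from the empty set. The best unexpanded subset is expanded by
#' adding each absent feature; the search stops after `max_no_improve`
#' consecutive expansions that fail to improve the incumbent (or when the
#' queue empties). Ties are broken toward smaller subsets and the fixed
#' column order of the table, so the search is deterministic.
#'
#' @param table a `feature_table`.
#' @param classifier classifier name used for scoring.
#' @param max_no_improve stopping patience (expansions).
#' @param max_subset_size optional cap on subset size.
#' @param seed LOOCV seed.
#' @return `selection_result` with `selected`, `accuracy`, `classifier`,
#'   `n_evaluated`.
#' @export
best_first_search <- function(table, classifier = "svm", max_no_improve = 5L,
                              max_subset_size = Inf, seed = 1L) {
  feats <- colnames(table$x)
  if (length(feats) == 0L) stop("table has no features")
  score <- function(subset) loocv_accuracy(table, subset, classifier, seed)$accuracy
  cache <- new.env(parent = emptyenv())
  scored <- function(subset) {
    key <- paste0("k:", paste(sort(subset), collapse = "\r"))
    if (is.null(cache[[key]])) cache[[key]] <- score(subset)
    cache[[key]]
  }
  open <- list(list(subset = character(0), acc = scored(character(0))))
  expanded <- character(0)
  incumbent <- open[[1L]]
  no_improve <- 0L
  n_eval <- 1L
  while (length(open) > 0L && no_improve < max_no_improve) {
    # best unexpanded: highest accuracy, then smallest, then insertion order
    accs <- vapply(open, `[[`, numeric(1L), "acc")
    szs <- vapply(open, function(o) length(o$subset), integer(1L))
    bi <- order(-accs, szs)[1L]
    node <- open[[bi]]
    open[[bi]] <- NULL
    key <- paste(sort(node$subset), collapse = "\r")
    if (key %in% expanded) next
    expanded <- c(expanded, key)
    improved <- FALSE
    if (length(node$subset) < max_subset_size) {
      for (f in setdiff(feats, node$subset)) {
        child <- c(node$subset, f)
        a <- scored(child)
        n_eval <- n_eval + 1L
        open[[length(open) + 1L]] <- list(subset = child, acc = a)
        if (a > incumbent$acc + 1e-12 ||
            (a == incumbent$acc && length(child) < length(incumbent$subset))) {
          if (a > incumbent$acc + 1e-12) improved <- TRUE
          incumbent <- list(subset = child, acc = a)
        }
      }
    }
    no_improve <- if (improved) 0L else no_improve + 1L
  }
  structure(list(method = "best_first_search",
                 selected = incumbent$subset, accuracy = incumbent$acc,
                 classifier = classifier, n_evaluated = n_eval),
            class = "selection_result")
}

#' Evaluate a classifier battery on a selected feature set
#'
#' Leave-one-out accuracy for each requested classifier on the selected
#' features. A classifier failure is recorded as NA (with a warning), never
#' silently dropped.
#'
#' @param table a `feature_table`.
#' @param selected feature names (or a `selection_result`).
#' @param classifiers subset of [classifier_names()].
#' @param seed LOOCV base seed.
#' @return named numeric vector of accuracies.
#' @export
evaluate_classifiers <- function(table, selected,
                                 classifiers = classifier_names(),
                                 seed = 1L) {
  if (inherits(selected, "selection_result")) selected <- selected$selected
  if (length(selected) == 0L) stop("selection is empty")
  vapply(stats::setNames(classifiers, classifiers), function(cl) {
    tryCatch(loocv_accuracy(table, selected, cl, seed)$accuracy,
             error = function(e) {
               warning(sprintf("classifier %s failed: %s", cl,
                               conditionMessage(e)))
               NA_real_
             })
  }, numeric(1L))
}

#' Selection embedded in the LOOCV loop (nested) or done once (flat)
#'
#' The flat protocol selects features on all subjects and reports LOOCV
#' accuracy on the same data — optimistically biased, but it is the common
#' protocol for small cohorts and is the default. The nested protocol
#' re-runs the selection inside every fold so the held-out subject is never
#' seen by the selector; it is the honest generalization estimate.
#'
#' @param table a `feature_table`.
#' @param select_fun function(table) -> `selection_result`.
#' @param classifier classifier name.
#' @param nested use the nested protocol.
#' @param seed LOOCV seed.
#' @return list with `accuracy`, `nested`, and (flat mode) `selection`.
#' @export
classify_with_selection <- function(table, select_fun, classifier = "svm",
                                    nested = FALSE, seed = 1L) {
  if (!nested) {
    sel <- select_fun(table)
    acc <- loocv_accuracy(table, sel$selected, classifier, seed)$accuracy
    return(list(accuracy = acc, nested = FALSE, selection = sel))
  }
  x <- table$x; y <- table$y
  n <- nrow(x)
  pred <- integer(n)
  clf <- .classifiers[[classifier]]
  for (i in seq_len(n)) {
    sub <- feature_table(x[-i, , drop = FALSE], y[-i])
    sel <- select_fun(sub)
    if (length(sel$selected) == 0L) {
      pred[i] <- which.max(tabulate(y[-i] + 1L, 2L)) - 1L
    } else {
      pred[i] <- with_seed(seed + i,
                           clf(x[-i, sel$selected, drop = FALSE], y[-i],
                               x[i, sel$selected, drop = FALSE]))
    }
  }
  list(accuracy = mean(pred == y), nested = TRUE)
}
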