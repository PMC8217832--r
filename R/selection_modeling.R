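# Feature selection and per-map logistic modeling: Pearson correlation
# filter, 10-fold cross-validated LASSO (glmnet), forward stepwise logistic
# regression with likelihood-ratio entry/removal, and ROC evaluation with a
# Youden threshold frozen on the training set.

#' Pearson correlation filter
#'
#' Iteratively removes one member of the most correlated remaining pair
#' (|r| > `threshold`): the member with the larger mean absolute correlation
#' to all currently retained features, ties broken by dropping the feature
#' later in canonical column order. Zero-variance features are removed
#' first and logged as degenerate.
#'
#' @param x data.frame or matrix of features (cases in rows).
#' @param threshold absolute Pearson cutoff (default 0.95, exclusive).
#' @return list with `kept` (column names retained), `x` (reduced table),
#'   and `log` (data.frame of removals: feature, partner, r, reason).
#' @export
correlation_filter <- function(x, threshold = 0.95) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L || nrow(x) < 3L) stop("need >= 2 features and >= 3 cases")
  log <- data.frame(feature = character(0), partner = character(0),
                    r = numeric(0), reason = character(0))
  sds <- vapply(x, stats::sd, numeric(1))
  for (f in names(x)[sds == 0 | !is.finite(sds)]) {
    log <- rbind(log, data.frame(feature = f, partner = NA, r = NA,
                                 reason = "zero variance"))
  }
  x <- x[, sds > 0 & is.finite(sds), drop = FALSE]
  repeat {
    if (ncol(x) < 2L) break
    C <- abs(stats::cor(as.matrix(x)))
    diag(C) <- 0
    if (max(C) <= threshold) break
    ij <- which(C == max(C), arr.ind = TRUE)[1, ]
    mean_abs <- (rowSums(C)) / (ncol(x) - 1L)
    # drop the pair member with the larger mean |r|; tie -> later column
    drop_j <- if (mean_abs[ij[1]] > mean_abs[ij[2]]) ij[1]
              else if (mean_abs[ij[2]] > mean_abs[ij[1]]) ij[2]
              else max(ij)
    keep_j <- setdiff(ij, drop_j)[1]
    log <- rbind(log, data.frame(feature = names(x)[drop_j],
                                 partner = names(x)[keep_j],
                                 r = stats::cor(x[[drop_j]], x[[keep_j]]),
                                 reason = "high correlation"))
    x <- x[, -drop_j, drop = FALSE]
  }
  list(kept = names(x), x = x, log = log)
}

# Deterministic stratified fold assignment.
stratified_folds <- function(labels, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' LASSO feature selection by cross-validated logistic regression
#'
#' Features are z-scored on the supplied (training) data, an L1-penalized
#' logistic path is fitted, and the penalty minimizing the mean
#' cross-validated binomial deviance over seeded stratified folds is
#' chosen; selected features are those with nonzero coefficients at that
#' penalty. Per-fold nonzero sets are recorded.
#'
#' @param x feature table (cases x features).
#' @param labels 0/1 vector.
#' @param folds number of CV folds (default 10).
#' @param seed seed for fold assignment.
#' @return list: `selected` (feature names), `lambda`, `per_fold` (list of
#'   per-fold nonzero name sets), `dropped_constant` (features unusable for
#'   z-scoring).
#' @export
lasso_select <- function(x, labels, folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  if (nrow(x) < folds) {
    stop(sprintf("n = %d < %d folds; use fewer folds", nrow(x), folds))
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  x <- x[, sds > 0 & is.finite(sds), drop = FALSE]
  xs <- scale(x)
  foldid <- stratified_folds(labels, folds, seed)
  cv <- glmnet::cv.glmnet(xs, labels, family = "binomial", alpha = 1,
                          foldid = foldid, type.measure = "deviance",
                          standardize = FALSE)
  nz_at <- function(fit, s) {
    cf <- as.matrix(stats::coef(fit, s = s))[-1, 1]
    names(cf)[cf != 0]
  }
  selected <- nz_at(cv$glmnet.fit, cv$lambda.min)
  per_fold <- lapply(seq_len(folds), function(k) {
    fit_k <- glmnet::glmnet(xs[foldid != k, , drop = FALSE],
                            labels[foldid != k], family = "binomial",
                            alpha = 1, standardize = FALSE)
    nz_at(fit_k, cv$lambda.min)
  })
  list(selected = selected, lambda = cv$lambda.min, per_fold = per_fold,
       dropped_constant = dropped)
}

# Binomial deviance of a ML logistic fit with the given feature columns.
logistic_deviance <- function(x, labels, feats) {
  if (length(feats) == 0L) {
    fit <- suppressWarnings(stats::glm(labels ~ 1, family = stats::binomial()))
  } else {
    df <- data.frame(x[, feats, drop = FALSE], .y = labels, check.names = FALSE)
    fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", feats), collapse = "+")))
    fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  }
  list(dev = fit$deviance, fit = fit)
}

#' Forward stepwise logistic regression with likelihood-ratio criteria
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' with the smallest likelihood-ratio p-value below `entry_p`, then removes
#' any included feature whose removal p-value exceeds `removal_p`, until no
#' change. The final model is a maximum-likelihood fit on raw
#' (unstandardized) features. Complete separation (diverging coefficients)
#' triggers a lightly ridge-penalized refit of the final coefficient
#' vector, flagged in the model record.
#'
#' @param x feature table (cases x features); columns are the candidates.
#' @param labels 0/1 vector.
#' @param entry_p,removal_p likelihood-ratio entry / removal thresholds
#'   (defaults 0.05 / 0.10).
#' @param map_name map identifier stored in the model spec.
#' @return a `model_spec`: `map_name`, `intercept`, `coefficients` (named),
#'   `threshold` (NA until set from a training ROC), `flags`, `steps` (log).
#' @export
forward_stepwise_logistic <- function(x, labels, entry_p = 0.05,
                                      removal_p = 0.10, map_name = "map") {
  x <- as.data.frame(x, check.names = FALSE)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  included <- character(0)
  steps <- data.frame(action = character(0), feature = character(0),
                      p = numeric(0))
  repeat {
    changed <- FALSE
    dev_cur <- logistic_deviance(x, labels, included)$dev
    cand <- setdiff(names(x), included)
    if (length(cand) > 0) {
      p_add <- vapply(cand, function(f) {
        dev_f <- logistic_deviance(x, labels, c(included, f))$dev
        stats::pchisq(pmax(dev_cur - dev_f, 0), df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (min(p_add) < entry_p) {
        f <- cand[which.min(p_add)]
        included <- c(included, f)
        steps <- rbind(steps, data.frame(action = "add", feature = f,
                                         p = min(p_add)))
        changed <- TRUE
      }
    }
    # backward pass: remove the worst included feature if above removal_p
    repeat {
      if (length(included) == 0L) break
      dev_full <- logistic_deviance(x, labels, included)$dev
      p_rm <- vapply(included, function(f) {
        dev_wo <- logistic_deviance(x, labels, setdiff(included, f))$dev
        stats::pchisq(pmax(dev_wo - dev_full, 0), df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (max(p_rm) > removal_p) {
        f <- included[which.max(p_rm)]
        included <- setdiff(included, f)
        steps <- rbind(steps, data.frame(action = "remove", feature = f,
                                         p = max(p_rm)))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  flags <- character(0)
  if (length(included) == 0L) {
    flags <- c(flags, "intercept-only")
    fit <- stats::glm(labels ~ 1, family = stats::binomial())
    cf <- stats::coef(fit)
    intercept <- unname(cf[1])
    betas <- stats::setNames(numeric(0), character(0))
  } else {
    warned <- FALSE
    fit <- withCallingHandlers(
      logistic_deviance(x, labels, included)$fit,
      warning = function(w) warned <<- TRUE)
    cf <- stats::coef(fit)
    separated <- any(!is.finite(cf)) || max(abs(cf[-1])) > 15
    if (separated) {
      flags <- c(flags, "separation-ridge-refit")
      xm <- as.matrix(x[, included, drop = FALSE])
      # glmnet needs >= 2 columns; pad with an all-zero dummy and drop it
      pad <- ncol(xm) == 1L
      if (pad) xm <- cbind(xm, .dummy = 0)
      rfit <- glmnet::glmnet(xm, labels, family = "binomial", alpha = 0,
                             lambda = 1e-2, standardize = TRUE)
      cf <- as.matrix(stats::coef(rfit))[, 1]
      if (pad) cf <- cf[seq_len(length(cf) - 1L)]
    }
    intercept <- unname(cf[1])
    betas <- cf[-1]
    names(betas) <- included
  }
  structure(list(map_name = map_name, intercept = intercept,
                 coefficients = betas, threshold = NA_real_,
                 flags = flags, steps = steps),
            class = "model_spec")
}

#' Construct a model spec from printed coefficients
#'
#' For worked examples: a linear logistic score
#' `Y = intercept + sum(coefficients * features)`.
#'
#' @param intercept scalar intercept.
#' @param coefficients named numeric vector.
#' @param threshold decision threshold on Y (default NA).
#' @param map_name map identifier.
#' @return a `model_spec`.
#' @export
model_spec <- function(intercept, coefficients, threshold = NA_real_,
                       map_name = "map") {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients))
  structure(list(map_name = map_name, intercept = intercept,
                 coefficients = coefficients, threshold = threshold,
                 flags = character(0), steps = NULL),
            class = "model_spec")
}

#' Linear predictor and class call of a fitted model
#'
#' @param model a `model_spec`.
#' @param features named numeric vector, or data.frame/matrix with the
#'   model's features as columns.
#' @return list with `Y` (linear predictor) and `call` (1 = positive iff
#'   `Y >= threshold`; NA if the threshold is unset).
#' @export
predict_model <- function(model, features) {
  need <- names(model$coefficients)
  if (is.null(dim(features))) {
    missing_f <- setdiff(need, names(features))
    if (length(missing_f) > 0) {
      stop(sprintf("missing model feature: %s", missing_f[1]))
    }
    y <- model$intercept + sum(model$coefficients * features[need])
  } else {
    missing_f <- setdiff(need, colnames(features))
    if (length(missing_f) > 0) {
      stop(sprintf("missing model feature: %s", missing_f[1]))
    }
    xm <- as.matrix(as.data.frame(features)[, need, drop = FALSE])
    y <- as.vector(model$intercept + xm %*% model$coefficients)
  }
  call <- if (is.na(model$threshold)) rep(NA_integer_, length(y))
          else as.integer(y >= model$threshold)
  list(Y = y, call = call)
}

# Mann-Whitney AUC with ties counted half.
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong standard error of the AUC.
delong_se <- function(scores, labels) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(xs, function(x) mean(psi(x, ys)), numeric(1))
  v01 <- vapply(ys, function(y) mean(psi(xs, y)), numeric(1))
  sqrt(stats::var(v10) / length(xs) + stats::var(v01) / length(ys))
}

#' ROC analysis with Youden-optimal threshold
#'
#' Empirical ROC over all observed score cut-points (call positive iff
#' `Y >= t`). AUC is the rank (Mann-Whitney) statistic, identical to the
#' trapezoid area; the 95% CI is DeLong's. The reported threshold maximizes
#' the Youden index, ties resolved toward the higher sensitivity (lower
#' threshold).
#'
#' @param scores numeric vector (higher = more positive).
#' @param labels 0/1 vector, both classes present.
#' @return a `roc_report`: `auc`, `ci` (length 2), `sensitivity`,
#'   `specificity`, `accuracy` (percent), `threshold`, `n_pos`, `n_neg`,
#'   `flags`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (length(unique(scores)) == 1L) {
    return(structure(list(auc = 0.5, ci = c(NA_real_, NA_real_),
                          sensitivity = NA_real_, specificity = NA_real_,
                          accuracy = NA_real_, threshold = NA_real_,
                          n_pos = n_pos, n_neg = n_neg,
                          flags = "constant-scores"),
                     class = "roc_report"))
  }
  auc <- auc_rank(scores, labels)
  se <- delong_se(scores, labels)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  cuts <- sort(unique(scores))
  best <- NULL
  for (t in cuts) {
    sens <- sum(scores >= t & labels == 1) / n_pos
    spec <- sum(scores < t & labels == 0) / n_neg
    j <- sens + spec - 1
    # strict improvement, or equal J with higher sensitivity
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens)) {
      best <- list(t = t, j = j, sens = sens, spec = spec)
    }
  }
  acc <- (best$sens * n_pos + best$spec * n_neg) / (n_pos + n_neg)
  structure(list(auc = auc, ci = ci,
                 sensitivity = 100 * best$sens, specificity = 100 * best$spec,
                 accuracy = 100 * acc, threshold = best$t,
                 n_pos = n_pos, n_neg = n_neg, flags = character(0)),
            class = "roc_report")
}

#' Evaluate a trained model on a test table at the frozen threshold
#'
#' AUC (and DeLong CI) come from the test scores; sensitivity, specificity
#' and accuracy are computed at the threshold determined on the training
#' set, never re-optimized.
#'
#' @param model a `model_spec` with a finite `threshold`.
#' @param x test feature table.
#' @param labels 0/1 test labels.
#' @return a `roc_report` (threshold = the frozen training threshold).
#' @export
evaluate_on_test <- function(model, x, labels) {
  if (is.na(model$threshold)) stop("model threshold is unset; train first")
  labels <- as.integer(labels)
  scores <- predict_model(model, x)$Y
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  auc <- auc_rank(scores, labels)
  se <- delong_se(scores, labels)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  sens <- sum(scores >= model$threshold & labels == 1) / n_pos
  spec <- sum(scores < model$threshold & labels == 0) / n_neg
  acc <- (sens * n_pos + spec * n_neg) / (n_pos + n_neg)
  structure(list(auc = auc, ci = ci, sensitivity = 100 * sens,
                 specificity = 100 * spec, accuracy = 100 * acc,
                 threshold = model$threshold, n_pos = n_pos, n_neg = n_neg,
                 flags = character(0)),
            class = "roc_report")
}

#' Serialize / deserialize a model spec as JSON
#'
#' Byte-deterministic for identical inputs.
#'
#' @param model a `model_spec`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_model_spec` returns the `model_spec`.
#' @export
write_model_spec <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  obj <- list(map_name = model$map_name, intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              threshold = model$threshold, flags = as.list(model$flags))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- if (length(obj$coefficients)) unlist(obj$coefficients)
        else stats::setNames(numeric(0), character(0))
  model_spec(intercept = obj$intercept, coefficients = cf,
             threshold = if (is.null(obj$threshold) || is.na(obj$threshold))
               NA_real_ else obj$threshold,
             map_name = obj$map_name)
}
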