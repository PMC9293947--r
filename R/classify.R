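# PD-vs-control discrimination from marker vectors: leave-one-subject-out
# logistic regression with a weak fixed ridge penalty (numerical stability
# under separability; plain logistic regression is the penalty -> 0 limit),
# rank-based ROC/AUC, exhaustive marker-subset search, and prevalence at a
# bounded false-positive operating point. Positive class = PD throughout.

# Ridge-penalized logistic regression by iteratively reweighted least
# squares. X: standardized design without intercept; penalty excludes the
# intercept. Returns c(intercept, coefficients).
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 50L, tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X1, w * X1) + 2 * pen, crossprod(X1, w * z))
    if (max(abs(new - beta)) < tol) { beta <- new; break }
    beta <- new
  }
  drop(beta)
}

#' Leave-one-subject-out logistic scores
#'
#' For each subject, features are z-scored with the statistics of the
#' remaining n-1 subjects, a weakly ridge-penalized logistic regression is
#' fitted on them, and the held-out subject is scored. No information from
#' the held-out subject reaches its fold's model. Deterministic.
#'
#' @param X numeric matrix or data.frame, subjects x markers.
#' @param y labels: factor/character (`PD` positive) or 0/1 vector.
#' @param subset optional column names/indices restricting the features.
#' @param lambda ridge strength on standardized features (default 1e-4).
#' @return numeric vector of n held-out PD probabilities.
#' @export
loso_scores <- function(X, y, subset = NULL, lambda = 1e-4) {
  X <- as.matrix(X)
  if (!is.null(subset)) X <- X[, subset, drop = FALSE]
  if (ncol(X) < 1L) stop("empty marker subset")
  y <- as_binary_labels(y)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 subjects")
  if (anyNA(X)) stop("complete cases required on the selected markers")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    if (length(unique(y[-i])) < 2L)
      stop("degenerate training fold: one class only")
    mu <- colMeans(X[-i, , drop = FALSE])
    s <- apply(X[-i, , drop = FALSE], 2L, sd)
    s[s == 0] <- 1
    Xtr <- sweep(sweep(X[-i, , drop = FALSE], 2L, mu), 2L, s, "/")
    beta <- ridge_logistic(Xtr, y[-i], lambda)
    xi <- (X[i, ] - mu) / s
    scores[i] <- 1 / (1 + exp(-(beta[1L] + sum(beta[-1L] * xi))))
  }
  scores
}

as_binary_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    if (!all(y %in% c("PD", "HC"))) stop("labels must be PD/HC or 0/1")
    as.integer(y == "PD")
  } else as.integer(y)
}

#' ROC metrics for classifier scores
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank tie correction;
#' accuracy, sensitivity and specificity at the fixed probability threshold
#' 0.5 with PD as the positive class.
#'
#' @param scores per-subject probabilities.
#' @param y labels (both classes must be present).
#' @param threshold probability threshold for the confusion-table metrics.
#' @return list: `auc`, `accuracy`, `sensitivity`, `specificity`.
#' @export
roc_metrics <- function(scores, y, threshold = 0.5) {
  y <- as_binary_labels(y)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- scores > threshold
  list(auc = auc,
       accuracy = mean(pred == (y == 1L)),
       sensitivity = mean(pred[y == 1L]),
       specificity = mean(!pred[y == 0L]))
}

#' Exhaustive marker-subset grid search
#'
#' Evaluates every nonempty subset of the candidate markers by pooled LOSO
#' accuracy. Ties are broken by higher AUC, then smaller subset, then
#' lexicographic order of the joined names; the search is deterministic.
#' Selection is non-nested by default (the reported scores are the selection
#' scores); the resulting accuracy is optimistic for unseen data.
#'
#' @param X subjects x markers matrix/data.frame.
#' @param y labels.
#' @param candidates candidate marker (column) names, at most 20.
#' @param lambda ridge strength for [loso_scores()].
#' @return list: `subset`, `scores`, `metrics` (from [roc_metrics()]),
#'   `evaluated` (number of subsets tried).
#' @export
subset_grid_search <- function(X, y, candidates = colnames(X), lambda = 1e-4) {
  if (!length(candidates)) stop("empty candidate list")
  if (length(candidates) > 20L) stop("exhaustive search limited to 20 candidates")
  X <- as.matrix(X)
  best <- NULL
  n_eval <- 0L
  for (k in seq_along(candidates)) {
    combs <- utils::combn(candidates, k, simplify = FALSE)
    for (sub in combs) {
      n_eval <- n_eval + 1L
      sc <- loso_scores(X, y, subset = sub, lambda = lambda)
      m <- roc_metrics(sc, y)
      key <- list(acc = m$accuracy, auc = m$auc, size = length(sub),
                  name = paste(sort(sub), collapse = "+"))
      if (is.null(best) ||
          key$acc > best$key$acc ||
          (key$acc == best$key$acc && key$auc > best$key$auc) ||
          (key$acc == best$key$acc && key$auc == best$key$auc &&
           key$size < best$key$size) ||
          (key$acc == best$key$acc && key$auc == best$key$auc &&
           key$size == best$key$size && key$name < best$key$name))
        best <- list(subset = sub, scores = sc, metrics = m, key = key)
    }
  }
  list(subset = best$subset, scores = best$scores, metrics = best$metrics,
       evaluated = n_eval)
}

#' Operating point with a bounded control false-positive rate
#'
#' Chooses the smallest score threshold whose control (HC) false-positive
#' rate is strictly under `fpr_bound`; subjects scoring above the threshold
#' are called hypomimic. Prevalence is the fraction of patients above the
#' threshold.
#'
#' @param scores per-subject probabilities.
#' @param y labels.
#' @param fpr_bound false-positive-rate bound (default 0.05).
#' @return list: `threshold`, `prevalence`, `fpr` (achieved control FPR).
#' @export
prevalence_at_fpr <- function(scores, y, fpr_bound = 0.05) {
  y <- as_binary_labels(y)
  neg <- scores[y == 0L]; pos <- scores[y == 1L]
  if (!length(neg) || !length(pos)) stop("both classes must be present")
  cand <- sort(unique(c(-Inf, scores)))
  fprs <- vapply(cand, function(th) mean(neg > th), numeric(1))
  ok <- which(fprs < fpr_bound)
  if (!length(ok)) {
    warning("false-positive bound unattainable; thresholding above max score")
    th <- max(scores)
  } else th <- cand[min(ok)]
  list(threshold = th, prevalence = mean(pos > th), fpr = mean(neg > th))
}

#' Classify a cohort from its marker table
#'
#' End-to-end discrimination: complete cases on the candidate side-averaged
#' markers, optional exhaustive subset search, pooled LOSO logistic scores,
#' ROC metrics, and the prevalence estimate at the bounded false-positive
#' operating point.
#'
#' @param markers marker table from [marker_table()].
#' @param cohort cohort table with `subject_id` and `group`.
#' @param candidates averaged marker names to consider (default: all 12).
#' @param search run the exhaustive subset search; `FALSE` uses all
#'   candidates as one subset.
#' @param lambda ridge strength.
#' @param fpr_bound bound for the prevalence operating point.
#' @return object of class `facekin_clf`.
#' @export
classify_cohort <- function(markers, cohort,
                            candidates = marker_catalogue()$marker,
                            search = FALSE, lambda = 1e-4,
                            fpr_bound = 0.05) {
  df <- merge(markers, cohort[, c("subject_id", "group")], by = "subject_id")
  cols <- paste0("avg_", candidates)
  cols <- cols[cols %in% names(df)]
  # markers absent for every subject (e.g. surface markers without frames)
  # cannot enter the model; complete-case filtering applies to the rest
  cols <- cols[vapply(cols, function(c) any(is.finite(df[[c]])), logical(1))]
  if (!length(cols)) stop("no usable candidate markers")
  keep <- complete.cases(df[, cols])
  df <- df[keep, , drop = FALSE]
  X <- as.matrix(df[, cols]); colnames(X) <- sub("^avg_", "", cols)
  y <- df$group
  if (search) {
    gs <- subset_grid_search(X, y, colnames(X), lambda)
    subset <- gs$subset; scores <- gs$scores; metrics <- gs$metrics
  } else {
    subset <- colnames(X)
    scores <- loso_scores(X, y, lambda = lambda)
    metrics <- roc_metrics(scores, y)
  }
  op <- prevalence_at_fpr(scores, y, fpr_bound)
  structure(list(subset = subset, subject_id = df$subject_id,
                 scores = scores, group = y, metrics = metrics,
                 operating_point = op, fpr_bound = fpr_bound,
                 lambda = lambda, n = nrow(df)),
            class = "facekin_clf")
}

#' @export
print.facekin_clf <- function(x, ...) {
  m <- x$metrics; op <- x$operating_point
  cat("<facekin_clf> LOSO ridge-logistic classification (PD vs HC)\n")
  cat(sprintf("  n = %d, markers: %s\n", x$n, paste(x$subset, collapse = ", ")))
  cat(sprintf("  AUC %.3f | accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%%\n",
              m$auc, 100 * m$accuracy, 100 * m$sensitivity,
              100 * m$specificity))
  cat(sprintf("  operating point (control FPR < %g%%): threshold %.3f, prevalence %.1f%%, achieved FPR %.1f%%\n",
              100 * x$fpr_bound, op$threshold, 100 * op$prevalence,
              100 * op$fpr))
  invisible(x)
}

#' @export
summary.facekin_clf <- function(object, ...) {
  print(object)
  invisible(list(metrics = object$metrics,
                 operating_point = object$operating_point,
                 subset = object$subset))
}

#' ROC curve points
#'
#' @param scores per-subject probabilities.
#' @param y labels.
#' @return `data.frame` with `threshold`, `fpr`, `tpr`, suitable for
#'   delimited-text export.
#' @export
roc_points <- function(scores, y) {
  y <- as_binary_labels(y)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  data.frame(threshold = th,
             fpr = vapply(th, function(t) mean(scores[y == 0L] > t), numeric(1)),
             tpr = vapply(th, function(t) mean(scores[y == 1L] > t), numeric(1)))
}
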