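# LOSO ridge-logistic classification, ROC metrics, subset search, and the
# bounded-FPR operating point.

make_xy <- function(n_per, shift, p_noise = 3L, seed = 1L) {
  set.seed(seed)
  X <- cbind(signal = c(rnorm(n_per), rnorm(n_per, shift)),
             matrix(rnorm(2 * n_per * p_noise), ncol = p_noise,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(X = X, y = rep(c("HC", "PD"), each = n_per))
}

test_that("a wide-margin marker separates the classes in LOSO", {
  d <- make_xy(20L, 8, seed = 2)
  sc <- loso_scores(d$X, d$y, subset = "signal")
  expect_true(all(sc[d$y == "PD"] > 0.5))
  expect_true(all(sc[d$y == "HC"] < 0.5))
  m <- roc_metrics(sc, d$y)
  expect_equal(m$auc, 1.0)
})

test_that("LOSO scores match an explicit held-out refit (no leakage)", {
  d <- make_xy(15L, 1.5, seed = 3)
  sc <- loso_scores(d$X, d$y)
  y <- as.integer(d$y == "PD")
  for (i in c(1L, 17L)) {
    mu <- colMeans(d$X[-i, ]); s <- apply(d$X[-i, ], 2, sd)
    Xtr <- sweep(sweep(d$X[-i, ], 2, mu), 2, s, "/")
    beta <- facekin:::ridge_logistic(Xtr, y[-i], 1e-4)
    xi <- (d$X[i, ] - mu) / s
    expect_equal(sc[i], unname(1 / (1 + exp(-(beta[1] + sum(beta[-1] * xi))))),
                 tolerance = 1e-12)
  }
  # changing the held-out subject's features does not change its fold model
  X2 <- d$X; X2[1L, ] <- X2[1L, ] + 100
  sc2 <- loso_scores(X2, d$y)
  mu <- colMeans(d$X[-1L, ]); s <- apply(d$X[-1L, ], 2, sd)
  beta <- facekin:::ridge_logistic(
    sweep(sweep(d$X[-1L, ], 2, mu), 2, s, "/"), y[-1L], 1e-4)
  xi <- (X2[1L, ] - mu) / s
  expect_equal(sc2[1L], unname(1 / (1 + exp(-(beta[1] + sum(beta[-1] * xi))))),
               tolerance = 1e-12)
  expect_equal(sc2[-1L] == sc[-1L], rep(FALSE, 29L))  # others retrain with i
})

test_that("permuted labels give chance-level pooled AUC", {
  set.seed(44)
  aucs <- replicate(20, {
    X <- matrix(rnorm(200 * 4), ncol = 4)
    y <- sample(rep(c("HC", "PD"), each = 100))
    roc_metrics(loso_scores(X, y), y)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("duplicated feature columns tie their weights", {
  d <- make_xy(15L, 2, p_noise = 1L, seed = 6)
  Xd <- cbind(d$X, signal2 = d$X[, "signal"])
  y <- as.integer(d$y == "PD")
  Xs <- scale(Xd)
  beta <- facekin:::ridge_logistic(Xs, y, 1e-4)
  expect_equal(unname(beta[2L]), unname(beta[4L]), tolerance = 1e-8)  # signal == signal2
  # with a vanishing penalty, duplication leaves the scores unchanged
  sc1 <- loso_scores(d$X, d$y, lambda = 1e-9)
  sc2 <- loso_scores(Xd, d$y, lambda = 1e-9)
  expect_equal(sc2, sc1, tolerance = 1e-5)
})

test_that("AUC is rank-based: invariant to increasing transforms, ties -> 0.5", {
  set.seed(5)
  sc <- runif(40); y <- rep(c("HC", "PD"), 20)
  m1 <- roc_metrics(sc, y)$auc
  m2 <- roc_metrics(qlogis(sc / 1.0001), y)$auc
  expect_equal(m1, m2)
  expect_equal(roc_metrics(rep(0.5, 40), y)$auc, 0.5)
})

test_that("ROC metrics agree with a brute-force pairwise oracle", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4)
  y <- c("PD", "PD", "PD", "HC", "HC")
  # oracle: fraction of (positive, negative) pairs correctly ordered
  pos <- scores[y == "PD"]; neg <- scores[y == "HC"]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  m <- roc_metrics(scores, y)
  expect_equal(m$auc, mean(pairs))
  expect_equal(m$auc, 1.0)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 0.5)   # the 0.6 control exceeds threshold 0.5
  expect_equal(m$accuracy, 0.8)
})

test_that("grid search enumerates 2^k - 1 subsets and recovers the signal", {
  d <- make_xy(60L, 3, p_noise = 2L, seed = 7)
  gs <- subset_grid_search(d$X, d$y)
  expect_equal(gs$evaluated, 7L)
  expect_true("signal" %in% gs$subset)
  expect_error(subset_grid_search(d$X, d$y, character()), "empty")
})

test_that("all-noise grid search stays near chance accuracy", {
  set.seed(70)
  accs <- replicate(5, {
    X <- matrix(rnorm(80 * 3), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- rep(c("HC", "PD"), each = 40)
    subset_grid_search(X, y)$metrics$accuracy
  })
  # selection optimism keeps this above 0.5 but far from separation
  expect_lt(mean(accs), 0.72)
  expect_gt(mean(accs), 0.45)
})

test_that("operating point keeps the control FPR strictly under the bound", {
  # 20 distinct control scores: even one false positive would be 5%, not
  # under it, so the threshold must exclude all controls
  set.seed(8)
  neg <- sort(runif(20)); pos <- runif(30, 0.5, 1)
  sc <- c(neg, pos); y <- rep(c("HC", "PD"), c(20, 30))
  op <- prevalence_at_fpr(sc, y, fpr_bound = 0.05)
  expect_equal(op$fpr, 0)
  expect_equal(op$prevalence, mean(pos > max(neg)))
  # perfectly separated scores
  sc2 <- c(rep(0.1, 10), rep(0.9, 10)); y2 <- rep(c("HC", "PD"), each = 10)
  op2 <- prevalence_at_fpr(sc2, y2)
  expect_equal(op2$fpr, 0)
  expect_equal(op2$prevalence, 1.0)
  # identically distributed scores: prevalence approaches the bound
  set.seed(80)
  scn <- runif(4000); yn <- rep(c("HC", "PD"), 2000)
  opn <- prevalence_at_fpr(scn, yn)
  expect_lt(opn$fpr, 0.05)
  expect_lt(abs(opn$prevalence - 0.05), 0.02)
})

test_that("classify_cohort returns a coherent report object", {
  cfg <- tiny_config(duration = 6, jitter_sd = 0.01, seed = 14)
  n <- 15L
  tab <- rbind(quick_marker_table(rep(0, n), cfg, seed_base = 300),
               quick_marker_table(rep(0.85, n), cfg, seed_base = 400))
  tab$subject_id <- sprintf("S%03d", seq_len(2L * n))
  cohort <- data.frame(subject_id = tab$subject_id,
                       group = factor(rep(c("HC", "PD"), each = n),
                                      levels = c("HC", "PD")))
  clf <- classify_cohort(tab, cohort)
  expect_s3_class(clf, "facekin_clf")
  expect_length(clf$scores, 2L * n)
  expect_true(clf$metrics$auc > 0.9)       # strong effect separates well
  expect_lt(clf$operating_point$fpr, clf$fpr_bound)
  expect_output(print(clf), "AUC")
})
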