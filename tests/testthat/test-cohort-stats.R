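fake_plane_features <- function(patient_id, label, planes, base = 1) {
  do.call(rbind, lapply(seq_len(planes), function(p) {
    df <- expand.grid(parameter = qusmap:::QUS_PARAMS,
                      stringsAsFactors = FALSE)
    df$mean <- base * p; df$contrast <- base * p + 1
    df$correlation <- 0.5; df$energy <- 0.1; df$homogeneity <- 0.6
    df$n_glcms_averaged <- 20L; df$plane_offset <- p; df$ace <- 1
    df$patient_id <- patient_id; df$label <- label
    df
  }))
}

test_that("patient aggregation is a plane average, invariant to plane order", {
  pf <- fake_plane_features("P1", "benign", 1)
  agg <- aggregate_patients(pf)
  expect_equal(agg$MBF_mean, 1)
  expect_equal(agg$SAS_contrast, 2)

  pf2 <- fake_plane_features("P2", "malignant", 2)  # plane means 1 and 2
  agg2 <- aggregate_patients(pf2)
  expect_equal(agg2$ESD_mean, 1.5)
  perm <- pf2[rev(seq_len(nrow(pf2))), ]
  expect_equal(aggregate_patients(perm)$ESD_mean, 1.5)

  # a feature missing in every plane flags the patient incomplete
  pf3 <- fake_plane_features("P3", "benign", 2)
  pf3$correlation[pf3$parameter == "SAS"] <- NA
  agg3 <- aggregate_patients(pf3)
  expect_true(agg3$incomplete)
  expect_true(is.na(agg3$SAS_correlation))
  # partially missing values are skipped, not propagated
  pf4 <- fake_plane_features("P4", "benign", 2)
  pf4$mean[pf4$parameter == "MBF" & pf4$plane_offset == 1] <- NA
  expect_equal(aggregate_patients(pf4)$MBF_mean, 2)
})

test_that("Mann-Whitney U matches exact enumeration and is symmetric", {
  res <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)            # 2 / choose(6, 3)... exact two-sided
  same <- mwu_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p, 1)
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(0.7, 4.4, 6.2)
  a <- mwu_test(x, y); b <- mwu_test(y, x)
  expect_equal(a$U + b$U, length(x) * length(y))
  expect_equal(a$p, b$p)
  expect_equal(mwu_test(1:10, (1:10) + 100)$tier, "***")
})

test_that("stepwise LDA prefers the discriminating feature and drops duplicates", {
  set.seed(101)
  n <- 40
  labels <- rep(c("benign", "malignant"), each = n / 2)
  strong <- ifelse(labels == "malignant", 3, 0) + rnorm(n, sd = 0.5)
  X <- cbind(noise1 = rnorm(n), strong = strong, noise2 = rnorm(n),
             dup = strong + rnorm(n, sd = 1e-3))
  sw <- stepwise_lda(X, labels)
  expect_equal(sw$selected[1], "strong")
  expect_false(all(c("strong", "dup") %in% sw$selected))
  # impossible entry threshold -> empty model
  sw0 <- stepwise_lda(X, labels, f_enter = Inf)
  expect_true(sw0$empty)
})

test_that("the final discriminant direction matches a reference LDA fit", {
  skip_if_not_installed("MASS")
  set.seed(202)
  n <- 60
  labels <- rep(c("benign", "malignant"), each = n / 2)
  X <- cbind(a = rnorm(n) + (labels == "malignant") * 1.5,
             b = rnorm(n) + (labels == "malignant") * 0.8,
             c = rnorm(n))
  sw <- stepwise_lda(X, labels, f_enter = 0.01, f_remove = 0.005)
  Z <- scale(X[, sw$selected, drop = FALSE])
  ld <- MASS::lda(Z, grouping = labels)
  ref <- ld$scaling[, 1]
  # recover the unstandardized discriminant direction and compare up to scale
  ng <- 2
  W <- matrix(0, ncol(Z), ncol(Z))
  for (l in unique(labels))
    W <- W + crossprod(scale(Z[labels == l, , drop = FALSE], scale = FALSE))
  b <- sw$coefficients[colnames(Z)] / sqrt(diag(W) / (nrow(Z) - ng))
  cosang <- abs(sum(b * ref)) / sqrt(sum(b^2) * sum(ref^2))
  expect_equal(cosang, 1, tolerance = 1e-8)
})

test_that("LOPO k-NN is perfect on separated clusters and honest on nulls", {
  set.seed(303)
  n <- 20
  labels <- rep(c("benign", "malignant"), each = n)
  X <- cbind(rnorm(2 * n), rnorm(2 * n)) +
    6 * cbind(labels == "malignant", labels == "malignant")
  cl <- knn_lopo(X, labels, k = 5)
  expect_equal(cl$sensitivity, 100)
  expect_equal(cl$specificity, 100)
  expect_equal(cl$accuracy, 100)
  expect_equal(cl$auc, 1)

  expect_error(knn_lopo(X, labels, k = 4), "odd")
  expect_error(knn_lopo(X, labels, k = 41), "below")
})

test_that("1-NN predicts the label of an exact duplicate", {
  X <- matrix(c(0, 0, 1, 5, 6, 7), ncol = 1)
  labels <- c("benign", "benign", "benign", "malignant", "malignant",
              "malignant")
  X[3, 1] <- 5                       # duplicate of a malignant point
  cl <- knn_lopo(X, labels, k = 1)
  expect_equal(cl$predictions$predicted[3], "malignant")
})

test_that("label-permuted LOPO accuracy matches the finite-sample null", {
  # under random labels the k neighbours of a held-out patient are a random
  # draw from 9 same-label / 10 other-label patients, so expected accuracy
  # is the hypergeometric majority probability, slightly below 50%
  set.seed(404)
  n <- 20; k <- 5
  null_acc <- sum(dhyper(3:5, 9, 10, 5) )
  accs <- replicate(200, {
    X <- matrix(rnorm(n * 2), n, 2)
    labels <- sample(rep(c("benign", "malignant"), each = n / 2))
    knn_lopo(X, labels, k = k)$accuracy / 100
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - null_acc), 2 * se + 0.01)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("LOPO predictions do not depend on patient ordering", {
  set.seed(505)
  n <- 16
  labels <- rep(c("benign", "malignant"), times = n / 2)
  X <- matrix(rnorm(n * 3), n, 3) + (labels == "malignant") * 1.2
  ids <- sprintf("P%02d", seq_len(n))
  cl1 <- knn_lopo(X, labels, k = 3, patient_ids = ids)
  perm <- sample(n)
  cl2 <- knn_lopo(X[perm, ], labels[perm], k = 3, patient_ids = ids[perm])
  m <- match(cl1$predictions$patient_id, cl2$predictions$patient_id)
  expect_equal(cl1$predictions$predicted, cl2$predictions$predicted[m])
  expect_equal(cl1$accuracy, cl2$accuracy)
})

test_that("rank-based AUC equals the trapezoidal ROC area and known cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("malignant", "malignant", "benign", "benign"))$auc, 1)
  expect_equal(roc_auc(c(0.6, 0.4, 0.6, 0.4),
                       c("malignant", "malignant", "benign", "benign"))$auc, 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 0),
                       c("malignant", "malignant", "benign", "benign"))$auc,
               0.75)
  expect_equal(roc_auc(rep(1, 6),
                       rep(c("malignant", "benign"), 3))$auc, 0.5)
  set.seed(606)
  for (i in 1:20) {
    scores <- sample(0:5, 30, replace = TRUE) / 5
    labels <- sample(c("benign", "malignant"), 30, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, r$auc_trapezoid, tolerance = 1e-12)
  }
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(707)
  scores <- rnorm(40)
  labels <- ifelse(scores + rnorm(40) > 0, "malignant", "benign")
  if (length(unique(labels)) == 2) {
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("benign", "malignant"),
      direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})
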