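# Patient-level aggregation, group comparison, stepwise LDA feature
# selection and leave-one-patient-out k-NN classification.

QUS_PARAMS <- c("MBF", "SS", "SI", "SAS", "ESD", "EAC")
QUS_FEATURES <- c("mean", "contrast", "correlation", "energy", "homogeneity")

#' Aggregate per-plane biomarkers into patient feature vectors
#'
#' Volume averaging: every biomarker (6 parameters x 5 features, plus the
#' attenuation estimate) is averaged, unweighted, over all available imaging
#' planes of a patient; per-plane missing values are skipped and counted.
#'
#' @param plane_features Data frame as produced by [mapset_features()] rows
#'   with added `patient_id` and `label` columns (one row per plane x
#'   parameter).
#' @return A data frame with one row per patient: `patient_id`, `label`, 30
#'   feature columns named `<parameter>_<feature>`, an `ACE` column, and an
#'   `incomplete` flag for patients with a feature missing in all planes.
#' @export
aggregate_patients <- function(plane_features) {
  stopifnot(all(c("patient_id", "label", "parameter") %in%
                  colnames(plane_features)))
  ids <- unique(plane_features$patient_id)
  rows <- lapply(ids, function(id) {
    sub <- plane_features[plane_features$patient_id == id, ]
    out <- list(patient_id = id, label = sub$label[1])
    incomplete <- FALSE
    for (p in QUS_PARAMS) {
      ps <- sub[sub$parameter == p, ]
      for (ft in QUS_FEATURES) {
        v <- ps[[ft]]
        nm <- paste(p, ft, sep = "_")
        if (all(is.na(v))) {
          out[[nm]] <- NA_real_
          incomplete <- TRUE
        } else out[[nm]] <- mean(v, na.rm = TRUE)
      }
    }
    ace <- unique(sub[, c("plane_offset", "ace")])$ace
    out$ACE <- mean(ace, na.rm = TRUE)
    out$incomplete <- incomplete
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

feature_columns <- function() {
  as.vector(outer(QUS_PARAMS, QUS_FEATURES, paste, sep = "_"))
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum comparison: exact for small untied samples, a
#' tie-corrected normal approximation otherwise (the engine is
#' [stats::wilcox.test()]). Reports the U statistic, the p value and the
#' significance tier (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#'
#' @param x,y Numeric vectors for the two groups.
#' @return List with `U`, `p`, and `tier`.
#' @export
mwu_test <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  if (all(c(x, y) == c(x, y)[1])) {
    return(list(U = length(x) * length(y) / 2, p = 1, tier = ""))
  }
  ties <- any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = !ties && length(x) <= 25 && length(y) <= 25,
    correct = TRUE))
  p <- wt$p.value
  tier <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(U = unname(wt$statistic), p = p, tier = tier)
}

#' Per-feature group comparison table
#'
#' @param patients [aggregate_patients()] output.
#' @param features Feature columns to test (default all 30 biomarkers).
#' @return Data frame: feature, group medians, U, p, significance tier.
#' @export
feature_stats <- function(patients, features = feature_columns()) {
  ben <- patients$label == "benign"
  rows <- lapply(features, function(ft) {
    x <- patients[[ft]][ben]; y <- patients[[ft]][!ben]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    tst <- mwu_test(x, y)
    data.frame(feature = ft, median_benign = stats::median(x),
               median_malignant = stats::median(y),
               U = tst$U, p = tst$p, tier = tst$tier)
  })
  do.call(rbind, rows)
}

# ---- stepwise linear discriminant analysis ---------------------------------

wilks_lambda <- function(X, g) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  T <- crossprod(Xc)
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in unique(g)) {
    sub <- X[g == lev, , drop = FALSE]
    sc <- scale(sub, scale = FALSE)
    W <- W + crossprod(sc)
  }
  dT <- det(T)
  if (!is.finite(dT) || abs(dT) < 1e-300) return(NA_real_)
  det(W) / dT
}

#' Stepwise LDA feature selection (Wilks' lambda criterion)
#'
#' Forward-entry / backward-removal selection for a two-class linear
#' discriminant: at each step the candidate with the largest partial F
#' enters if `F >= f_enter`, then any included feature whose partial F has
#' dropped to `<= f_remove` leaves; iteration stops at convergence. The
#' final discriminant is refit on the selected features and reported as
#' standardized coefficients (computed on z-scored features, scaled by the
#' pooled within-group standard deviations) sorted by decreasing
#' contribution.
#'
#' @param X Numeric matrix or data frame of candidate features (columns).
#' @param labels Two-level factor or character vector.
#' @param f_enter,f_remove Entry / removal partial-F thresholds.
#' @param max_steps Safety cap on selection steps.
#' @return A `qus_stepwise`: `selected` (entry order), `coefficients`
#'   (standardized, sorted by absolute value), and the per-step trace.
#' @export
stepwise_lda <- function(X, labels, f_enter = 3.84, f_remove = 2.71,
                         max_steps = 50) {
  X <- as.matrix(X)
  g <- as.character(labels)
  if (length(unique(g)) != 2) stopf("stepwise LDA needs exactly two classes")
  if (min(table(g)) < 2) stopf("need at least 2 patients per class")
  keep <- apply(X, 2, function(v) all(is.finite(v)) && stats::sd(v) > 0)
  cand_all <- colnames(X)[keep]
  Z <- scale(X[, cand_all, drop = FALSE])
  n <- nrow(Z); ngroups <- 2
  lambda_of <- function(S) if (!length(S)) 1 else
    wilks_lambda(Z[, S, drop = FALSE], g)
  partial_f <- function(S_small, S_big) {
    l0 <- lambda_of(S_small); l1 <- lambda_of(S_big)
    q <- length(S_small)
    if (!is.finite(l0) || !is.finite(l1) || l1 <= 0) return(NA_real_)
    (n - ngroups - q) / (ngroups - 1) * (l0 / l1 - 1)
  }
  selected <- character()
  trace <- list()
  for (step in seq_len(max_steps)) {
    pool <- setdiff(cand_all, selected)
    if (!length(pool)) break
    fin <- vapply(pool, function(x) partial_f(selected, c(selected, x)),
                  numeric(1))
    fin[!is.finite(fin)] <- -Inf
    best <- which.max(fin)
    entered <- NULL
    if (fin[best] >= f_enter) {
      entered <- pool[best]
      selected <- c(selected, entered)
      trace[[length(trace) + 1]] <- data.frame(
        step = step, action = "enter", feature = entered, F = fin[best])
    }
    # removal pass
    repeat {
      if (length(selected) < 2) break
      fout <- vapply(selected, function(x)
        partial_f(setdiff(selected, x), selected), numeric(1))
      fout[!is.finite(fout)] <- Inf
      worst <- which.min(fout)
      if (fout[worst] <= f_remove) {
        removed <- selected[worst]
        selected <- setdiff(selected, removed)
        trace[[length(trace) + 1]] <- data.frame(
          step = step, action = "remove", feature = removed, F = fout[worst])
      } else break
    }
    if (is.null(entered)) break
  }
  coefs <- numeric(0)
  if (length(selected)) {
    Zs <- Z[, selected, drop = FALSE]
    lev <- sort(unique(g))
    mu1 <- colMeans(Zs[g == lev[1], , drop = FALSE])
    mu2 <- colMeans(Zs[g == lev[2], , drop = FALSE])
    W <- matrix(0, length(selected), length(selected))
    for (l in lev) {
      sc <- scale(Zs[g == l, , drop = FALSE], scale = FALSE)
      W <- W + crossprod(sc)
    }
    Sw <- W / (n - ngroups)
    b <- solve(Sw, mu2 - mu1)
    coefs <- b * sqrt(diag(W) / (n - ngroups))
    names(coefs) <- selected
    coefs <- coefs[order(abs(coefs), decreasing = TRUE)]
  }
  structure(list(selected = selected, coefficients = coefs,
                 trace = if (length(trace)) do.call(rbind, trace) else NULL,
                 f_enter = f_enter, f_remove = f_remove,
                 empty = !length(selected)),
            class = "qus_stepwise")
}

#' @export
print.qus_stepwise <- function(x, ...) {
  if (x$empty) {
    cat("Stepwise LDA: no feature passed the entry threshold\n")
    return(invisible(x))
  }
  cat(sprintf("Stepwise LDA: %d features selected (F-enter %.2f, F-remove %.2f)\n",
              length(x$selected), x$f_enter, x$f_remove))
  for (nm in names(x$coefficients))
    cat(sprintf("  %-18s standardized coefficient %+.2f\n", nm,
                x$coefficients[nm]))
  invisible(x)
}

# ---- k-NN with leave-one-patient-out CV ------------------------------------

knn_vote <- function(train, test_row, labels_train, ids_train, k) {
  d <- sqrt(colSums((t(train) - test_row)^2))
  ord <- order(d, ids_train)          # distance ties broken by patient order
  nb <- ord[seq_len(k)]
  mean(labels_train[nb] == "malignant")
}

#' Leave-one-patient-out k-NN classification
#'
#' For each held-out patient the remaining patients form the training fold:
#' features are z-scored with fold statistics, stepwise feature selection
#' (when requested) is refit inside the fold so no information leaks from
#' the held-out case, and the patient is classified by the majority vote of
#' its k nearest training neighbours (Euclidean distance); the malignancy
#' score is the malignant fraction among those neighbours. With odd `k`
#' vote ties cannot occur; distance ties are broken by patient order.
#'
#' @param X Feature matrix / data frame (rows = patients).
#' @param labels `"benign"` / `"malignant"` per patient.
#' @param k Number of neighbours (odd).
#' @param select `"none"` (use all given columns) or `"stepwise"`
#'   (per-fold Wilks-lambda selection).
#' @param features Optional column subset to use (e.g. a single biomarker).
#' @param patient_ids Optional ids for reporting.
#' @param global_selection If `TRUE` with `select = "stepwise"`, features
#'   are selected once on the full cohort (the optimistic design some
#'   clinical reports imply) instead of per fold.
#' @param ... Passed to [stepwise_lda()].
#' @return A `qus_classification`: per-patient predictions and scores,
#'   sensitivity/specificity/accuracy (%, malignant positive), AUC and ROC.
#' @export
knn_lopo <- function(X, labels, k = 5, select = c("none", "stepwise"),
                     features = NULL, patient_ids = NULL,
                     global_selection = FALSE, ...) {
  select <- match.arg(select)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  labels <- as.character(labels)
  n <- nrow(X)
  if (k >= n) stopf("k must be below the number of patients")
  if (k %% 2 == 0) stopf("use an odd k so majority votes cannot tie")
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  patient_ids <- patient_ids %||% sprintf("P%03d", seq_len(n))

  global_sel <- NULL
  if (select == "stepwise" && global_selection) {
    sw <- stepwise_lda(X, labels, ...)
    if (sw$empty) stopf("global stepwise selection returned no features")
    global_sel <- sw$selected
  }

  scores <- numeric(n)
  fold_features <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(labels[tr])) < 2)
      stopf("a class is absent from the training fold for patient %s",
            patient_ids[i])
    cols <- colnames(X)
    if (select == "stepwise") {
      if (!is.null(global_sel)) cols <- global_sel
      else {
        sw <- tryCatch(stepwise_lda(X[tr, , drop = FALSE], labels[tr], ...),
                       error = function(e) list(empty = TRUE))
        cols <- if (isTRUE(sw$empty)) colnames(X) else sw$selected
      }
    }
    fold_features[[i]] <- cols
    Xtr <- X[tr, cols, drop = FALSE]
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- scale(Xtr, mu, sdv)
    zte <- (X[i, cols] - mu) / sdv
    scores[i] <- knn_vote(Ztr, zte, labels[tr], tr, k)
  }
  predicted <- ifelse(scores > 0.5, "malignant", "benign")
  tp <- sum(predicted == "malignant" & labels == "malignant")
  tn <- sum(predicted == "benign" & labels == "benign")
  fp <- sum(predicted == "malignant" & labels == "benign")
  fn <- sum(predicted == "benign" & labels == "malignant")
  roc <- roc_auc(scores, labels)
  structure(list(
    predictions = data.frame(patient_id = patient_ids, label = labels,
                             score = scores, predicted = predicted),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / n,
    auc = roc$auc, roc = roc$roc, k = k, select = select,
    fold_features = fold_features
  ), class = "qus_classification")
}

#' @export
print.qus_classification <- function(x, ...) {
  cat(sprintf(
    "LOPO k-NN (k = %d, selection: %s): sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%, AUC %.2f\n",
    x$k, x$select, x$sensitivity, x$specificity, x$accuracy, x$auc))
  invisible(x)
}

#' @export
summary.qus_classification <- function(object, ...) {
  print(object)
  cm <- table(truth = object$predictions$label,
              predicted = object$predictions$predicted)
  print(cm)
  invisible(object)
}

#' Rank-based AUC and ROC curve
#'
#' AUC as the Mann-Whitney probability that a malignant score exceeds a
#' benign one (ties counted one half), plus the ROC curve from a threshold
#' sweep over the observed scores; the trapezoidal area under that curve
#' equals the rank-based AUC.
#'
#' @param scores Malignancy scores.
#' @param labels `"benign"` / `"malignant"` per score.
#' @return List with `auc`, `auc_trapezoid`, and the `roc` data frame
#'   (threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- scores[labels == "malignant"]
  neg <- scores[labels == "benign"]
  if (!length(pos) || !length(neg)) stopf("both classes must be present")
  if (length(unique(scores)) == 1) {
    auc <- 0.5
  } else {
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    auc <- mean(cmp)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)))
  auc_trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                     utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, auc_trapezoid = auc_trap, roc = roc)
}
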