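# Group statistics and classification: one-way ANOVA with Bonferroni post hoc
# pairwise t tests, Fisher linear discriminant analysis (with optional
# diagonal shrinkage of the pooled covariance), LD1/LD2 projection, 95%
# confidence ellipses, prediction, and confusion-matrix reporting.

star_grade <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' One-way ANOVA with Bonferroni post hoc pairwise tests
#'
#' Standard one-way ANOVA F test across classes, followed by all pairwise
#' two-sample pooled-variance t tests with Bonferroni adjustment
#' `p_adj = min(1, m p)` over the `m = choose(g, 2)` pairs (adjustment is per
#' parameter, not across parameters). Star grades follow the thresholds
#' 0.05 / 0.01 / 0.001 on the adjusted p.
#'
#' @param values_by_class named list mapping class label to a numeric vector
#'   (>= 2 classes, each with >= 2 values, nonzero total variance).
#' @param parameter_name label carried into the result.
#' @return an object of class `pa_group_comparison`: `anova_F`, `anova_p`,
#'   and a `pairwise` data frame (`class_a`, `class_b`, `t`, `p_raw`, `p_adj`,
#'   `stars`).
#' @export
anova_bonferroni <- function(values_by_class, parameter_name = "parameter") {
  g <- length(values_by_class)
  if (g < 2L) stop("anova_bonferroni: need at least 2 classes")
  ns <- lengths(values_by_class)
  if (any(ns < 2L)) stop("anova_bonferroni: each class needs >= 2 values")
  labs <- names(values_by_class)
  if (is.null(labs)) stop("anova_bonferroni: classes must be named")
  all_v <- unlist(values_by_class, use.names = FALSE)
  n <- length(all_v)
  grand <- mean(all_v)
  means <- vapply(values_by_class, mean, numeric(1))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(values_by_class, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssb == 0 && ssw == 0) stop("anova_bonferroni: zero variance everywhere")
  f_stat <- if (ssw == 0) Inf else (ssb / (g - 1)) / (ssw / (n - g))
  p_anova <- if (is.infinite(f_stat)) 0 else
    stats::pf(f_stat, g - 1, n - g, lower.tail = FALSE)
  pairs <- utils::combn(labs, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    a <- values_by_class[[pairs[1, k]]]
    b <- values_by_class[[pairs[2, k]]]
    na <- length(a); nb <- length(b)
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tval <- if (se == 0) {
      if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    } else (mean(a) - mean(b)) / se
    p_raw <- if (is.infinite(tval)) 0 else
      2 * stats::pt(-abs(tval), df = na + nb - 2)
    p_adj <- min(1, m * p_raw)
    data.frame(class_a = pairs[1, k], class_b = pairs[2, k],
               t = tval, p_raw = p_raw, p_adj = p_adj,
               stars = star_grade(p_adj), stringsAsFactors = FALSE)
  })
  structure(
    list(parameter_name = parameter_name, anova_F = f_stat, anova_p = p_anova,
         pairwise = do.call(rbind, rows)),
    class = "pa_group_comparison"
  )
}

#' @export
print.pa_group_comparison <- function(x, ...) {
  cat(sprintf("<pa_group_comparison> %s: F = %.4g, p = %.3g\n",
              x$parameter_name, x$anova_F, x$anova_p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Fit a linear discriminant model
#'
#' Fisher LDA: discriminant directions are eigenvectors of
#' `W^{-1/2} B W^{-1/2}` mapped back through `W^{-1/2}`, where `W` is the
#' pooled within-class covariance and `B` the between-class scatter.
#' Internally features are standardized by their pooled within-class standard
#' deviations (the raw feature scales span many orders of magnitude), which
#' leaves LDA invariant in exact arithmetic. Optional shrinkage replaces the
#' standardized `W` by `(1 - gamma) W + gamma I` (shrinkage toward the
#' diagonal), on by default when any class has fewer than `2 p` samples.
#'
#' @param x numeric feature matrix (`n x p`, named columns) or a
#'   [pa_feature_matrix()] list.
#' @param labels class labels (ignored if `x` is a feature-matrix list).
#' @param shrinkage shrinkage intensity in `[0, 1]`, or `NULL` for the
#'   default rule (0.25 if any class is smaller than `2 p`, else 0).
#' @return an object of class `pa_lda`.
#' @export
fit_lda <- function(x, labels = NULL, shrinkage = NULL) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$x)) {
    labels <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  if (anyNA(x) || !all(is.finite(x))) stop("fit_lda: missing or non-finite feature values")
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("fit_lda: labels/feature length mismatch")
  classes <- sort(unique(labels))
  g <- length(classes)
  if (g < 2L) stop("fit_lda: need at least 2 classes")
  ncls <- table(factor(labels, levels = classes))
  if (any(ncls < 2L)) stop("fit_lda: each class needs >= 2 samples")
  p <- ncol(x)
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))
  mu <- do.call(rbind, lapply(classes, function(cl) colMeans(x[labels == cl, , drop = FALSE])))
  rownames(mu) <- classes
  Wraw <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2, mu[cl, ])
    Wraw <- Wraw + crossprod(xc)
  }
  Wraw <- Wraw / (n - g)
  scale <- sqrt(pmax(diag(Wraw), .Machine$double.eps))
  if (is.null(shrinkage)) shrinkage <- if (min(ncls) < 2L * p) 0.25 else 0
  if (shrinkage < 0 || shrinkage > 1) stop("fit_lda: shrinkage must be in [0, 1]")
  Ws <- Wraw / tcrossprod(scale)                 # standardized pooled covariance
  Wsh <- (1 - shrinkage) * Ws + shrinkage * diag(diag(Ws), p)
  ew <- eigen(Wsh, symmetric = TRUE)
  if (min(ew$values) <= .Machine$double.eps * max(ew$values)) {
    stop("fit_lda: singular pooled covariance; set a positive shrinkage")
  }
  Wih <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
  mus <- sweep(mu, 2, scale, "/")
  grand <- colSums(mus * as.numeric(ncls)) / n
  Bs <- matrix(0, p, p)
  for (k in seq_len(g)) {
    d <- mus[k, ] - grand
    Bs <- Bs + ncls[k] * tcrossprod(d)
  }
  Bs <- Bs / n
  eb <- eigen(Wih %*% Bs %*% Wih, symmetric = TRUE)
  r <- min(g - 1L, p)
  basis <- Wih %*% eb$vectors[, seq_len(r), drop = FALSE]   # standardized space
  colnames(basis) <- paste0("LD", seq_len(r))
  structure(
    list(class_labels = classes, class_means = mu, priors = as.numeric(ncls) / n,
         counts = as.numeric(ncls),
         pooled_covariance = Wsh * tcrossprod(scale),        # raw scale, shrunk
         cov_inv_std = Wih %*% Wih,                          # inverse, std scale
         feature_scale = scale, feature_names = colnames(x),
         discriminant_basis = basis, eigenvalues = eb$values[seq_len(r)],
         shrinkage = shrinkage, grand_mean = grand * scale),
    class = "pa_lda"
  )
}

#' @export
print.pa_lda <- function(x, ...) {
  cat(sprintf("<pa_lda> %d classes (%s), %d features, %d discriminants, shrinkage = %.2f\n",
              length(x$class_labels), paste(x$class_labels, collapse = ", "),
              length(x$feature_names), ncol(x$discriminant_basis), x$shrinkage))
  invisible(x)
}

check_feature_names <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    if (!identical(colnames(x), model$feature_names)) {
      if (all(model$feature_names %in% colnames(x))) {
        x <- x[, model$feature_names, drop = FALSE]
      } else {
        stop("feature-name mismatch with the fitted model")
      }
    }
  } else if (ncol(x) != length(model$feature_names)) {
    stop("feature count mismatch with the fitted model")
  }
  x
}

#' Project features onto the first two discriminants
#'
#' @param model a fitted [fit_lda()] model with >= 2 discriminants.
#' @param x feature matrix or [pa_feature_matrix()] list.
#' @return `n x 2` matrix of scores (`LD1`, `LD2`).
#' @export
transform_lda <- function(model, x) {
  stopifnot(inherits(model, "pa_lda"))
  if (is.list(x) && !is.data.frame(x) && !is.null(x$x)) x <- x$x
  x <- check_feature_names(model, x)
  if (ncol(model$discriminant_basis) < 2L) {
    stop("transform_lda: fewer than 2 discriminants available")
  }
  xs <- sweep(sweep(x, 2, model$grand_mean), 2, model$feature_scale, "/")
  scores <- xs %*% model$discriminant_basis[, 1:2, drop = FALSE]
  colnames(scores) <- c("LD1", "LD2")
  scores
}

#' Predict class labels
#'
#' Gaussian discriminant rule under the (shrunk) pooled covariance:
#' `argmax_c -0.5 (x - mu_c)' S^{-1} (x - mu_c) + log prior_c`, with
#' deterministic lexicographic tie-breaking (class labels are kept sorted).
#'
#' @param object a fitted [fit_lda()] model.
#' @param newdata feature matrix or [pa_feature_matrix()] list.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.pa_lda <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata) && !is.null(newdata$x)) newdata <- newdata$x
  x <- check_feature_names(object, newdata)
  xs <- sweep(x, 2, object$feature_scale, "/")
  mus <- sweep(object$class_means, 2, object$feature_scale, "/")
  Sinv <- object$cov_inv_std
  scores <- sapply(seq_along(object$class_labels), function(k) {
    d <- sweep(xs, 2, mus[k, ])
    -0.5 * rowSums((d %*% Sinv) * d) + log(object$priors[k])
  })
  scores <- matrix(scores, nrow = nrow(xs))
  object$class_labels[apply(scores, 1, which.max)]
}

#' Confusion matrix and accuracy
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param class_labels the admissible label set (default: sorted union of the
#'   true labels); a predicted or true label outside this set is an error.
#' @return an object of class `pa_class_report`: `confusion` (rows = true,
#'   columns = predicted), `accuracy` (percent, `100 * trace / total`),
#'   `per_class_recall` (percent).
#' @export
confusion_and_accuracy <- function(true_labels, predicted_labels,
                                   class_labels = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels) || length(true_labels) < 1L) {
    stop("confusion_and_accuracy: label vectors must have equal length >= 1")
  }
  if (is.null(class_labels)) class_labels <- sort(unique(true_labels))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_labels)
  if (length(bad)) {
    stop("confusion_and_accuracy: label(s) outside the class set: ",
         paste(bad, collapse = ", "))
  }
  cm <- table(factor(true_labels, levels = class_labels),
              factor(predicted_labels, levels = class_labels))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  total <- sum(cm)
  acc <- 100 * sum(diag(cm)) / total
  rs <- rowSums(cm)
  recall <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  structure(list(confusion = cm, accuracy = acc, per_class_recall = recall,
                 n = total),
            class = "pa_class_report")
}

#' @export
print.pa_class_report <- function(x, ...) {
  cat(sprintf("<pa_class_report> accuracy = %.1f%% on %d samples\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' 95% confidence ellipse of 2-D scores
#'
#' Center = sample mean; semi-axes = `sqrt(lambda_k * qchisq(level, 2))` from
#' the eigen-decomposition of the 2-D sample covariance; rotation = angle of
#' the leading eigenvector. A point is inside the ellipse iff its squared
#' Mahalanobis distance is below the chi-square quantile.
#'
#' @param scores `n x 2` matrix (`n >= 3`).
#' @param level confidence level (default 0.95).
#' @return an object of class `pa_ellipse`: `center`, `semi_axes`,
#'   `rotation` (radians), `level`.
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3L || ncol(scores) != 2L) {
    stop("confidence_ellipse: need an n x 2 matrix with n >= 3")
  }
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= .Machine$double.eps * max(abs(e$values), 1)) {
    stop("confidence_ellipse: degenerate covariance")
  }
  q <- stats::qchisq(level, df = 2)
  structure(
    list(center = ctr, semi_axes = sqrt(e$values * q),
         rotation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
         level = level, covariance = S),
    class = "pa_ellipse"
  )
}

#' Points-in-ellipse test
#'
#' @param ellipse a [confidence_ellipse()].
#' @param scores `n x 2` matrix.
#' @return logical vector: inside (or on) the ellipse.
#' @export
ellipse_contains <- function(ellipse, scores) {
  scores <- as.matrix(scores)
  d2 <- stats::mahalanobis(scores, ellipse$center, ellipse$covariance)
  d2 <= stats::qchisq(ellipse$level, df = 2)
}

# Extract one family's features for a list of signals; failures are logged
# and excluded (never imputed).
extract_family <- function(signals, family, ids = NULL, band = c(1e6, 2e7),
                           identify_opts = list()) {
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(signals))
  out <- vector("list", length(signals))
  n_failed <- 0L
  for (k in seq_along(signals)) {
    fv <- tryCatch(
      switch(family,
             TD = time_domain_features(signals[[k]], sample_id = ids[k]),
             FD = frequency_domain_features(signals[[k]], band = band, sample_id = ids[k]),
             ARMA = arma_features(signals[[k]], sample_id = ids[k]),
             SS = do.call(extract_ss_features,
                          c(list(signal = signals[[k]], sample_id = ids[k]),
                            identify_opts))),
      error = function(e) {
        warning(sprintf("extract_family[%s]: sample %s failed: %s",
                        family, ids[k], conditionMessage(e)))
        NULL
      })
    if (is.null(fv)) n_failed <- n_failed + 1L
    out[[k]] <- fv
  }
  attr(out, "n_failed") <- n_failed
  out
}

#' Run the multi-family classification benchmark
#'
#' Simulates a training dataset from the configuration's class table and,
#' under the default `"holdout"` split, an independent stratified test set
#' (`n_test_per_class` traces per class, 20 total for five classes). For each
#' feature family it extracts features, fits [fit_lda()] on the training set,
#' predicts the test set, and reports the confusion matrix, accuracy, LD1/LD2
#' training scores, class centroids and 95% confidence ellipses. Under
#' `"resubstitution"` the training set itself is the test set and the report
#' is flagged accordingly.
#'
#' @param config a [pa_sim_config()].
#' @param families subset of `c("TD", "FD", "ARMA", "SS")`.
#' @param split `"holdout"` or `"resubstitution"`.
#' @param n_test_per_class held-out traces per class (holdout split).
#' @param seed RNG seed for the simulated datasets (default: `config$seed`).
#' @param band FD analysis band in Hz.
#' @param identify_opts options forwarded to [identify_ss()] for the SS family.
#' @return an object of class `pa_benchmark`: per-family results
#'   (`report`, `accuracy`, `scores`, `centroids`, `ellipses`, `lda`,
#'   `n_excluded`), plus `split`, `seed`, `config`.
#' @export
run_benchmark <- function(config = pa_sim_config(),
                          families = c("TD", "FD", "ARMA", "SS"),
                          split = c("holdout", "resubstitution"),
                          n_test_per_class = 4L, seed = config$seed,
                          band = c(1e6, 2e7), identify_opts = list()) {
  split <- match.arg(split)
  families <- match.arg(families, c("TD", "FD", "ARMA", "SS"), several.ok = TRUE)
  cfg_train <- config
  cfg_train$seed <- as.integer(seed)
  train <- simulate_dataset(cfg_train)
  if (split == "holdout") {
    cfg_test <- config
    cfg_test$classes <- lapply(config$classes, function(s) {
      s$n_samples <- as.integer(n_test_per_class)
      s
    })
    cfg_test$seed <- as.integer(seed) + 1000003L
    test <- simulate_dataset(cfg_test)
  } else {
    test <- train
  }
  train_ids <- sprintf("train%03d", seq_along(train))
  test_ids <- if (split == "holdout") sprintf("test%03d", seq_along(test)) else train_ids
  res <- list()
  for (fam in families) {
    fam_res <- tryCatch({
      fv_tr <- extract_family(train, fam, ids = train_ids, band = band,
                              identify_opts = identify_opts)
      fv_te <- if (split == "holdout") {
        extract_family(test, fam, ids = test_ids, band = band,
                       identify_opts = identify_opts)
      } else fv_tr
      fm_tr <- pa_feature_matrix(fv_tr)
      fm_te <- pa_feature_matrix(fv_te)
      lda <- fit_lda(fm_tr)
      pred <- predict(lda, fm_te)
      report <- confusion_and_accuracy(fm_te$labels, pred,
                                       class_labels = lda$class_labels)
      scores <- transform_lda(lda, fm_tr)
      centroids <- transform_lda(lda, lda$class_means)
      rownames(centroids) <- lda$class_labels
      ell <- list()
      for (cl in lda$class_labels) {
        pts <- scores[fm_tr$labels == cl, , drop = FALSE]
        if (nrow(pts) >= 3L) {
          ell[[cl]] <- tryCatch(confidence_ellipse(pts), error = function(e) NULL)
        }
      }
      list(report = report, accuracy = report$accuracy,
           scores = scores, score_labels = fm_tr$labels,
           centroids = centroids, ellipses = ell, lda = lda,
           features_train = fm_tr, features_test = fm_te,
           n_excluded = attr(fv_tr, "n_failed") +
             if (split == "holdout") attr(fv_te, "n_failed") else 0L)
    }, error = function(e) {
      warning(sprintf("run_benchmark: family %s excluded: %s", fam,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(fam_res)) res[[fam]] <- fam_res
  }
  structure(list(families = res, split = split, seed = as.integer(seed),
                 n_train = length(train), n_test = length(test),
                 config = config),
            class = "pa_benchmark")
}

#' @export
print.pa_benchmark <- function(x, ...) {
  cat(sprintf("<pa_benchmark> split = %s, seed = %d, %d train / %d test\n",
              x$split, x$seed, x$n_train, x$n_test))
  for (fam in names(x$families)) {
    cat(sprintf("  %-4s accuracy = %5.1f%%\n", fam, x$families[[fam]]$accuracy))
  }
  invisible(x)
}
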