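test_that("anova_bonferroni: degenerate, arithmetic, and oracle agreement", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  gc <- anova_bonferroni(same)
  expect_equal(gc$anova_F, 0)
  expect_equal(gc$pairwise$p_adj, 1)
  expect_identical(gc$pairwise$stars, "")
  # Bonferroni arithmetic and star grades against the pooled t.test oracle
  set.seed(61)
  vals <- lapply(stats::setNames(1:5, c("HF", "HM", "A1", "A2", "L")),
                 function(k) rnorm(6, mean = k * 0.8))
  gc5 <- anova_bonferroni(vals)
  expect_equal(nrow(gc5$pairwise), 10L)
  for (r in sample(10, 4)) {
    row <- gc5$pairwise[r, ]
    tt <- t.test(vals[[row$class_a]], vals[[row$class_b]], var.equal = TRUE)
    expect_equal(row$p_raw, tt$p.value, tolerance = 1e-12)
    expect_equal(row$p_adj, min(1, 10 * tt$p.value), tolerance = 1e-12)
    expected_star <- if (row$p_adj < 0.001) "***" else if (row$p_adj < 0.01)
      "**" else if (row$p_adj < 0.05) "*" else ""
    expect_identical(row$stars, expected_star)
  }
  # ANOVA F/p against the stats::oneway.test pooled oracle
  ow <- stats::oneway.test(y ~ g,
                           data = data.frame(y = unlist(vals),
                                             g = rep(names(vals), each = 6)),
                           var.equal = TRUE)
  expect_equal(gc5$anova_F, unname(ow$statistic), tolerance = 1e-10)
  expect_equal(gc5$anova_p, unname(ow$p.value), tolerance = 1e-10)
  expect_error(anova_bonferroni(list(a = c(1, 1), b = c(1, 1))), "zero variance")
  expect_error(anova_bonferroni(list(a = 1:3)), "2 classes")
})

test_that("fit_lda separates, bounds discriminants, and is affine invariant", {
  set.seed(62)
  x1 <- matrix(rnorm(50), ncol = 1)
  x2 <- matrix(rnorm(50, mean = 10), ncol = 1)
  lab <- rep(c("a", "b"), each = 50)
  lda1 <- fit_lda(rbind(x1, x2), lab, shrinkage = 0)
  expect_equal(ncol(lda1$discriminant_basis), 1L)
  expect_identical(predict(lda1, rbind(x1, x2)), lab)
  # 5 classes x 4 features -> exactly 4 discriminants
  x <- matrix(rnorm(200), ncol = 4)
  labs5 <- rep(c("HF", "HM", "A1", "A2", "L"), each = 10)
  x <- x + model.matrix(~ 0 + labs5) %*% matrix(rnorm(20, sd = 4), 5, 4)
  colnames(x) <- paste0("f", 1:4)
  lda5 <- fit_lda(x, labs5, shrinkage = 0)
  expect_equal(ncol(lda5$discriminant_basis), 4L)
  expect_equal(sum(lda5$priors), 1)
  # predictions invariant under invertible affine maps of feature space
  base_pred <- predict(lda5, x)
  for (rep in 1:20) {
    M <- matrix(rnorm(16), 4, 4)
    while (abs(det(M)) < 0.05) M <- matrix(rnorm(16), 4, 4)
    shift <- rnorm(4)
    xt <- sweep(x %*% M, 2, shift, "+")
    colnames(xt) <- colnames(x)
    ldat <- fit_lda(xt, labs5, shrinkage = 0)
    expect_identical(predict(ldat, xt), base_pred)
  }
  expect_error(fit_lda(x[c(1, 11, 12), ], labs5[c(1, 11, 12)]), ">= 2 samples")
})

test_that("transform_lda geometry", {
  set.seed(63)
  x <- matrix(rnorm(300), ncol = 3)
  labs <- rep(c("a", "b", "c", "d"), each = 25)
  x <- x + model.matrix(~ 0 + labs) %*% matrix(rnorm(12, sd = 3), 4, 3)
  colnames(x) <- paste0("f", 1:3)
  m <- fit_lda(x, labs, shrinkage = 0)
  sc <- transform_lda(m, x)
  expect_identical(colnames(sc), c("LD1", "LD2"))
  # between-class variance along LD1 >= LD2
  ctr <- transform_lda(m, m$class_means)
  expect_gte(var(ctr[, 1]), var(ctr[, 2]))
  # class-mean feature vectors project onto the class centroids of the scores
  for (cl in m$class_labels) {
    expect_equal(ctr[which(m$class_labels == cl), ],
                 colMeans(sc[labs == cl, , drop = FALSE]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # a constant shift moves scores but not between-class geometry
  xs <- sweep(x, 2, c(5, -2, 7), "+")
  colnames(xs) <- colnames(x)
  ms <- fit_lda(xs, labs, shrinkage = 0)
  ctr2 <- transform_lda(ms, ms$class_means)
  expect_equal(as.numeric(dist(ctr2)), as.numeric(dist(ctr)), tolerance = 1e-6)
})

test_that("predict: class means, tie-breaking, held-out separation", {
  set.seed(64)
  x <- matrix(rnorm(80), ncol = 2)
  labs <- rep(c("a", "b"), each = 20)
  x[labs == "b", ] <- x[labs == "b", ] + 12
  colnames(x) <- c("f1", "f2")
  m <- fit_lda(x, labs, shrinkage = 0)
  expect_identical(predict(m, m$class_means), m$class_labels)
  # equidistant point with equal priors -> lexicographically first class
  mid <- matrix(colMeans(m$class_means), 1)
  colnames(mid) <- colnames(x)
  m_eq <- m
  m_eq$priors <- c(0.5, 0.5)
  expect_identical(predict(m_eq, mid), "a")
  # well-separated 5-class synthetic features -> held-out accuracy 100%
  mk <- function(n) {
    centers <- matrix(c(0, 0, 20, 0, 0, 20, 20, 20, 10, 40), 5, 2, byrow = TRUE)
    x <- do.call(rbind, lapply(1:5, function(k) {
      sweep(matrix(rnorm(2 * n, sd = 0.5), n, 2), 2, centers[k, ], "+")
    }))
    colnames(x) <- c("f1", "f2")
    list(x = x, labels = rep(c("A", "B", "C", "D", "E"), each = n))
  }
  tr <- mk(20); te <- mk(8)
  m5 <- fit_lda(tr$x, tr$labels)
  rep5 <- confusion_and_accuracy(te$labels, predict(m5, te$x),
                                 class_labels = m5$class_labels)
  expect_equal(rep5$accuracy, 100)
})

test_that("confusion_and_accuracy arithmetic is exact", {
  labs <- rep(c("A", "B", "C", "D", "E"), each = 4)
  pred <- labs
  pred[20] <- "A"  # 19 of 20 correct
  rep1 <- confusion_and_accuracy(labs, pred)
  expect_equal(rep1$accuracy, 95)
  expect_equal(sum(rep1$confusion), 20)
  expect_equal(unname(rowSums(rep1$confusion)), rep(4L, 5), ignore_attr = TRUE)
  perfect <- confusion_and_accuracy(labs, labs)
  expect_true(all(perfect$confusion[row(perfect$confusion) != col(perfect$confusion)] == 0))
  expect_equal(perfect$accuracy, 100)
  all_a <- confusion_and_accuracy(labs, rep("A", 20))
  expect_equal(unname(colSums(all_a$confusion)), c(20L, 0L, 0L, 0L, 0L),
               ignore_attr = TRUE)
  expect_equal(all_a$accuracy, 100 * 4 / 20)
  expect_error(confusion_and_accuracy(labs, replace(pred, 1, "Z")), "outside")
  expect_error(confusion_and_accuracy(labs, pred[-1]), "equal length")
})

test_that("confidence ellipse: closed form, equivariance, coverage", {
  set.seed(65)
  pts <- rmvnorm2(500, S = diag(c(2, 2)))
  e <- confidence_ellipse(pts)
  S <- cov(pts)
  ev <- eigen(S, symmetric = TRUE)$values
  expect_equal(sort(e$semi_axes), sort(sqrt(ev * qchisq(0.95, 2))),
               tolerance = 1e-10)
  expect_equal(e$center, colMeans(pts), ignore_attr = TRUE)
  # rotation equivariance
  pts_a <- rmvnorm2(300, S = matrix(c(3, 1, 1, 1), 2))
  e1 <- confidence_ellipse(pts_a)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e2 <- confidence_ellipse(pts_a %*% t(R))
  d <- (e2$rotation - e1$rotation - th) %% pi
  expect_true(min(d, pi - d) < 1e-6)
  # empirical coverage on 10000 Gaussian draws: 95% +- 1%
  big <- rmvnorm2(10000, mean = c(1, -2), S = matrix(c(2, 0.8, 0.8, 1), 2))
  eb <- confidence_ellipse(big)
  expect_lt(abs(mean(ellipse_contains(eb, big)) - 0.95), 0.01)
  expect_error(confidence_ellipse(pts[1:2, ]), "n >= 3")
  degen <- cbind(1:5, 2 * (1:5))
  expect_error(confidence_ellipse(degen), "degenerate")
})

test_that("run_benchmark: determinism, structure, and split handling", {
  cfg <- pa_sim_config(snr_db = 30)
  b1 <- suppressWarnings(run_benchmark(cfg, families = c("TD", "SS"), seed = 3))
  b2 <- suppressWarnings(run_benchmark(cfg, families = c("TD", "SS"), seed = 3))
  expect_identical(sapply(b1$families, `[[`, "accuracy"),
                   sapply(b2$families, `[[`, "accuracy"))
  expect_identical(b1$families$SS$report$confusion, b2$families$SS$report$confusion)
  expect_equal(b1$n_train, 35L)
  expect_equal(b1$n_test, 20L)
  expect_equal(b1$families$SS$report$n, 20L)
  expect_true(all(c("scores", "centroids", "ellipses") %in% names(b1$families$SS)))
  rs <- suppressWarnings(run_benchmark(cfg, families = "SS",
                                       split = "resubstitution", seed = 3))
  expect_identical(rs$split, "resubstitution")
  expect_equal(rs$families$SS$report$n, 35L)
})

test_that("ANOVA type-I error is near nominal on null simulations", {
  set.seed(66)
  hits <- vapply(1:1000, function(r) {
    vals <- lapply(stats::setNames(1:5, c("a", "b", "c", "d", "e")),
                   function(k) rnorm(7))
    anova_bonferroni(vals)$anova_p < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})
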