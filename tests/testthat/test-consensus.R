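test_that("feature assembly enforces node coverage and the two-positive rule", {
  withr::with_seed(20, {
    net <- random_net(10, p_edge = 0.4)
    signal <- make_signal(net, network_nodes(net)[1:2])
    scores <- score_nodes(net, signal)
    labels <- tibble::tibble(node = network_nodes(net),
                             label = c(1, 1, rep(0, 8)))
    fm <- assemble_features(scores, labels)
    expect_equal(names(fm), c("node", "propagation", "random_walk",
                              "interconnectivity", "neighborhood", "label"))
    expect_equal(nrow(fm), 10)
    expect_equal(sum(fm$label), 2)

    labels$label <- c(1, rep(0, 9))
    expect_error(assemble_features(scores, labels), "two known targets")
    # one method missing a node the others have
    holey <- scores[!(scores$node == "v01" & scores$method == "random_walk"), ]
    expect_error(assemble_features(holey, labels), "different node sets")
  })
})

test_that("stratified folds balance positives within one and partition all nodes", {
  withr::with_seed(21, {
    y <- c(rep(1, 10), rep(0, 90))
    fold <- stratified_folds(y, k = 5, seed = 123)
    expect_equal(sort(unique(fold)), 1:5)
    expect_equal(length(fold), 100)
    expect_equal(unname(table(fold[y == 1])), rep(2L, 5) |> as.integer(),
                 ignore_attr = TRUE)
    expect_equal(unname(table(fold[y == 0])), rep(18L, 5), ignore_attr = TRUE)
    # determinism under seed
    expect_identical(fold, stratified_folds(y, k = 5, seed = 123))
    # uneven positives still within one of each other
    y2 <- c(rep(1, 7), rep(0, 43))
    f2 <- stratified_folds(y2, k = 5, seed = 9)
    expect_true(all(table(f2[y2 == 1]) %in% c(1, 2)))
    expect_error(stratified_folds(c(1, 0, 1, 0), k = 5), "exceeds")
    expect_warning(stratified_folds(c(1, 1, rep(0, 20)), k = 5, seed = 1),
                   "Fewer positives")
  })
})

test_that("ridge path solver agrees with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  withr::with_seed(22, {
    x <- matrix(rnorm(150 * 4), 150, 4)
    y <- rbinom(150, 1, plogis(1.5 * x[, 1] - x[, 2]))
    for (lam in c(1e-3, 0.1, 10)) {
      own <- netprior:::ridge_logistic_path(x, y, lam)
      ref <- as.numeric(coef(glmnet::glmnet(
        x, y, family = "binomial", alpha = 0, lambda = lam,
        standardize = FALSE, thresh = 1e-14
      )))
      expect_equal(as.numeric(own), ref, tolerance = 1e-6)
    }
  })
})

test_that("tuning picks near-chance models for label-independent features", {
  withr::with_seed(23, {
    aucs <- vapply(1:20, function(i) {
      fm <- toy_feature_matrix(n = 120, n_pos = 30, strength = 0)
      m <- fit_logistic(fm)
      max(m$tuning$mean_oob_auc)
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.07)
  })
})

test_that("regularized fit handles collinear and single-class edge cases", {
  withr::with_seed(24, {
    fm <- toy_feature_matrix(n = 100, n_pos = 20)
    fm$random_walk <- fm$propagation # duplicated feature
    expect_s3_class(fit_logistic(fm), "consensus_model")
    fm0 <- fm
    fm0$label <- 0L
    expect_error(fit_logistic(fm0), "single class")
  })
})

test_that("out-of-fold prediction covers every node once and is seed-reproducible", {
  withr::with_seed(25, {
    fm <- toy_feature_matrix(n = 150, n_pos = 15)
    cv <- cross_validated_predict(fm, k = 5, seed = 99)
    expect_setequal(cv$predictions$node, fm$node)
    expect_equal(sort(cv$predictions$rank), 1:150)
    expect_equal(as.integer(table(cv$predictions$fold)), rep(30L, 5))
    cv2 <- cross_validated_predict(fm, k = 5, seed = 99)
    expect_identical(cv$predictions, cv2$predictions)
    # ranking is by descending probability with node-id tie-break
    expect_true(all(diff(cv$predictions$probability) <= 0))
  })
})

test_that("separable features give perfect out-of-fold ranking", {
  withr::with_seed(26, {
    fm <- toy_feature_matrix(n = 100, n_pos = 20, strength = 50)
    cv <- cross_validated_predict(fm, k = 5, seed = 1)
    expect_equal(cv$auc$auc, 1.0, tolerance = 0.01)
  })
})

test_that("held-out probabilities track a single informative feature", {
  withr::with_seed(27, {
    # label generated from a latent score; one feature is a strictly
    # increasing transform of that score, the rest are pure noise
    n <- 400
    latent <- rnorm(n)
    fm <- tibble::tibble(
      node = sprintf("n%03d", seq_len(n)),
      propagation = rnorm(n),
      random_walk = rnorm(n),
      interconnectivity = qlogis(plogis(latent)), # = latent, monotone
      neighborhood = rnorm(n),
      label = rbinom(n, 1, plogis(2 * latent - 1))
    )
    cv <- cross_validated_predict(fm, k = 5, seed = 5)
    ord <- match(fm$node, cv$predictions$node)
    rc <- cor(fm$interconnectivity, cv$predictions$probability[ord],
              method = "spearman")
    expect_gt(rc, 0.9)
  })
})

test_that("importance rescales fold-averaged |z| to [0, 100] with ties at 100", {
  withr::with_seed(28, {
    fm <- toy_feature_matrix(n = 250, n_pos = 50, strength = 3,
                             informative = "propagation")
    cv <- cross_validated_predict(fm, k = 5, seed = 3)
    imp <- feature_importance(cv)
    expect_setequal(imp$method, c("propagation", "random_walk",
                                  "interconnectivity", "neighborhood"))
    expect_true(all(imp$importance >= 0 & imp$importance <= 100))
    expect_equal(max(imp$importance), 100)
    expect_equal(min(imp$importance), 0)
    expect_equal(imp$method[which.max(imp$importance)], "propagation")

    # degenerate all-equal case reports all 100s
    m <- cv$models[[1]]
    m$zstats[] <- 1
    expect_equal(feature_importance(list(m))$importance, rep(100, 4))
  })
})

test_that("signal injected through one method dominates importance across seeds", {
  withr::with_seed(29, {
    hits <- 0
    for (i in 1:20) {
      fm <- toy_feature_matrix(n = 150, n_pos = 25, strength = 2.5,
                               informative = "propagation")
      imp <- feature_importance(cross_validated_predict(fm, k = 5, seed = i))
      hits <- hits + (imp$method[which.max(imp$importance)] == "propagation")
    }
    expect_gte(hits, 18)
  })
})

test_that("tidy and glance summarize a cross-validated fit", {
  withr::with_seed(30, {
    fm <- toy_feature_matrix(n = 120, n_pos = 24)
    cv <- cross_validated_predict(fm, k = 4, seed = 2)
    td <- tidy(cv)
    expect_equal(nrow(td), 4 * 5) # 4 folds x (intercept + 4 methods)
    expect_true(all(is.finite(td$estimate)))
    gl <- glance(cv)
    expect_equal(gl$n, 120L)
    expect_equal(gl$n_pos, 24L)
    expect_equal(gl$k, 4L)
    expect_true(gl$auc > 0.5)
  })
})
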