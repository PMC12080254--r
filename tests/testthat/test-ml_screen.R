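test_that("training is deterministic and validates its inputs", {
  feats <- toy_features(n = 120, seed = 3)
  y <- toy_labels(feats)
  b1 <- train_pmt_model(feats, y, seed = 9, nrounds = 40)
  b2 <- train_pmt_model(feats, y, seed = 9, nrounds = 40)
  p1 <- predict_pmt(b1, feats)
  p2 <- predict_pmt(b2, feats)
  expect_identical(p1$probability, p2$probability)

  expect_error(train_pmt_model(feats, rep(1, nrow(feats))),
               "single class")
  expect_error(train_pmt_model(feats, y[-1]), "length mismatch")
})

test_that("applicability domain distances obey Euclidean geometry", {
  # hand-built geometry: training point (3,4), query at the origin
  train <- matrix(c(3, 4), nrow = 1, dimnames = list("t1", c("a", "b")))
  bundle <- geometry_bundle(train)
  q <- data.frame(compound_id = c("q0", "qt"), a = c(0, 3), b = c(0, 4))
  ad <- applicability_domain(bundle, q)
  expect_equal(ad$distance, c(5, 0))
  expect_true(all(ad$in_domain))
  # a compound identical to a training compound always has distance 0
  feats <- toy_features(n = 60, seed = 4)
  y <- toy_labels(feats)
  b <- train_pmt_model(feats, y, seed = 1, nrounds = 30)
  ad2 <- applicability_domain(b, feats)
  expect_equal(max(abs(ad2$distance)), 0, tolerance = 1e-10)
  expect_true(all(ad2$in_domain))
})

test_that("in-domain verdicts are monotone in the threshold", {
  feats <- toy_features(n = 80, seed = 5)
  y <- toy_labels(feats)
  b <- train_pmt_model(feats, y, seed = 2, nrounds = 30)
  q <- toy_features(n = 40, seed = 99)
  ad <- applicability_domain(b, q)
  for (thr in c(0.5, 1, 2, 4)) {
    b_lo <- b; b_lo$ad_threshold <- thr
    b_hi <- b; b_hi$ad_threshold <- thr * 2
    in_lo <- applicability_domain(b_lo, q)$in_domain
    in_hi <- applicability_domain(b_hi, q)$in_domain
    expect_true(all(in_hi[in_lo]))  # widening never evicts
  }
  expect_error(applicability_domain(b, data.frame(compound_id = "x",
                                                  z1 = 1)),
               "column manifest")
})

test_that("out-of-domain compounds stay unresolved regardless of score", {
  feats <- toy_features(n = 80, seed = 6)
  y <- toy_labels(feats)
  b <- train_pmt_model(feats, y, seed = 2, nrounds = 30)
  far <- feats[1:3, ]
  far$compound_id <- c("far1", "far2", "far3")
  far[, -1] <- far[, -1] + 1000
  pred <- predict_pmt(b, far)
  expect_true(all(pred$hazard_class == "unresolved"))
  expect_true(all(pred$decided_by == "none"))
  expect_true(all(grepl("outside AD", pred$detail)))
  # in-domain rows resolve to candidate or negative
  pred2 <- predict_pmt(b, feats)
  expect_true(all(pred2$hazard_class %in% c("candidate_PMT_vPvM",
                                            "not_PMT_vPvM")))
  expect_true(all(pred2$decided_by == "ml_model"))
})

test_that("SHAP attributions satisfy additivity and flag constants", {
  feats <- toy_features(n = 100, seed = 7)
  feats$const <- 1.0
  y <- toy_labels(feats)
  b <- train_pmt_model(feats, y, seed = 3, nrounds = 50)
  ex <- explain_pmt(b, feats, interactions = TRUE)
  resid <- abs(ex$base_value + rowSums(ex$shap) - ex$margin)
  scale <- pmax(1, rowSums(abs(ex$shap)) + abs(ex$base_value))
  expect_true(all(resid / scale <= 1e-6))
  # constant feature receives zero attribution
  expect_true(all(ex$shap[, "const"] == 0))
  # interaction matrix: symmetric, row sums recover attributions
  i1 <- ex$interactions[1, , ]
  expect_equal(i1, t(i1), tolerance = 1e-6)
  expect_equal(rowSums(i1), ex$shap[1, ], tolerance = 1e-5)
})

test_that("planted monotone rules are recovered in global importance", {
  for (seed in c(21, 22)) {
    set.seed(seed)
    feats <- toy_features(n = 250, p = 8, seed = seed)
    y <- as.integer(feats$f1 < 0 & feats$f2 > -0.5)
    b <- train_pmt_model(feats, y, seed = seed, nrounds = 80)
    ex <- explain_pmt(b, feats)
    top5 <- ex$importance$feature[1:5]
    expect_true(all(c("f1", "f2") %in% top5))
    dep <- shap_dependence(ex, "f1")
    expect_lt(cor(dep$value, dep$shap, method = "spearman"), 0)
  }
})

test_that("origin contrast ranks strata separately and checks inputs", {
  feats <- toy_features(n = 90, seed = 8)
  y <- toy_labels(feats)
  b <- train_pmt_model(feats, y, seed = 4, nrounds = 30)
  ex <- explain_pmt(b, feats)
  roster <- data.frame(compound_id = feats$compound_id,
                       origin = rep(c("synthetic", "natural", "undefined"),
                                    each = 30),
                       stringsAsFactors = FALSE)
  ct <- contrast_importance_by_origin(ex, roster, k = 4)
  expect_equal(nrow(ct$synthetic), 4)
  expect_equal(length(ct$unique_to_synthetic) + length(ct$shared), 4)
  # identical strata give identical lists and empty differences
  ex_sub <- ex
  ex_sub$shap <- ex$shap[rep(1, 20), ]
  rownames(ex_sub$shap) <- feats$compound_id[1:20]
  roster_half <- data.frame(
    compound_id = feats$compound_id[1:20],
    origin = rep(c("synthetic", "natural"), 10),
    stringsAsFactors = FALSE)
  ct2 <- contrast_importance_by_origin(ex_sub, roster_half, k = 3)
  expect_equal(ct2$synthetic$feature, ct2$natural_or_undefined$feature)
  expect_length(ct2$unique_to_synthetic, 0)
  # k beyond feature count returns full ranking with warning
  expect_warning(ct3 <- contrast_importance_by_origin(ex, roster, k = 99),
                 "full ranking")
  expect_equal(nrow(ct3$synthetic), ncol(ex$shap))
  # empty stratum is an error
  roster_syn <- roster
  roster_syn$origin <- "synthetic"
  expect_error(contrast_importance_by_origin(ex, roster_syn, k = 3),
               "empty origin stratum")
})

test_that("bundle serialization round-trips predictions exactly", {
  feats <- toy_features(n = 100, seed = 9)
  y <- toy_labels(feats)
  b <- train_pmt_model(feats, y, seed = 5, nrounds = 60)
  dir <- withr::local_tempdir()
  save_model_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("model.json", "bundle.json", "training_matrix.csv")))))
  b2 <- load_model_bundle(dir)
  q <- toy_features(n = 50, seed = 10)
  expect_identical(predict_pmt(b, q)$probability,
                   predict_pmt(b2, q)$probability)
  expect_equal(applicability_domain(b, q)$distance,
               applicability_domain(b2, q)$distance)
  expect_equal(b2$ad_threshold, b$ad_threshold)
  expect_equal(b2$label_definition, b$label_definition)
})

test_that("missing descriptor values are imputed with training medians", {
  feats <- toy_features(n = 80, seed = 12)
  feats$f3[1:10] <- NaN
  y <- toy_labels(feats)
  b <- train_pmt_model(feats, y, seed = 6, nrounds = 30)
  q <- feats[1:5, ]
  q$f3 <- NaN
  pred <- predict_pmt(b, q)
  expect_true(all(is.finite(pred$probability)))
})
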