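# compact two-class table with controllable per-feature separation
make_class_table <- function(n_per_class, deltas, seed = 1,
                             sds = rep(1, length(deltas))) {
  feats <- paste0("f", seq_along(deltas))
  gp <- data.frame(feature = feats,
                   lyric_mean = rep(0, length(deltas)), lyric_sd = sds,
                   dramatic_mean = deltas, dramatic_sd = sds)
  sample_population(gp, n_per_class, seed = seed)
}

test_that("forest training basics: separability, determinism, validation", {
  tab <- make_class_table(60, deltas = c(8, 0), seed = 1)
  fit <- train_fach_forest(tab, seed = 1)
  pred <- classify_fach(fit, tab)
  expect_equal(balanced_error_rate(tab$voice_structure, pred), 0)

  fit2 <- train_fach_forest(tab, seed = 1)
  expect_identical(predict(fit, tab), predict(fit2, tab))

  one_class <- tab[tab$voice_structure == "lyric", ]
  expect_error(train_fach_forest(one_class), "single class")
})

test_that("balanced error rate follows its definition", {
  truth <- rep(c("lyric", "dramatic"), each = 10)
  expect_equal(balanced_error_rate(truth, truth), 0)
  expect_equal(balanced_error_rate(truth, rep("lyric", 20)), 50)
  # class errors 10% and 30% average to 20%
  pred <- truth
  pred[1] <- "dramatic"                      # 1/10 lyric wrong
  pred[11:13] <- "lyric"                     # 3/10 dramatic wrong
  expect_equal(balanced_error_rate(truth, pred), 20)
  expect_error(balanced_error_rate(rep("lyric", 5), rep("lyric", 5)),
               "two classes")
})

test_that("label-shuffled data yields chance-level cross-validated BER", {
  bers <- sapply(1:10, function(seed) {
    tab <- make_class_table(50, deltas = c(1.5, 0.5), seed = seed)
    set.seed(seed + 100)
    tab$voice_structure <- sample(tab$voice_structure)
    cross_validated_ber(tab, k = 5, seed = seed, num_trees = 200)$ber
  })
  expect_gt(mean(bers), 45)
  expect_lt(mean(bers), 55)
})

test_that("adding a duplicated feature leaves predictions nearly unchanged", {
  tab <- make_class_table(60, deltas = c(1.2, 0.3), seed = 2)
  test <- make_class_table(40, deltas = c(1.2, 0.3), seed = 3)
  fit <- train_fach_forest(tab, seed = 4)
  tab2 <- tab; tab2$f1_copy <- tab2$f1
  test2 <- test; test2$f1_copy <- test2$f1
  fit2 <- train_fach_forest(tab2, seed = 4)
  p1 <- predict(fit, test)
  p2 <- predict(fit2, test2)
  expect_lt(mean(abs(p1 - p2)), 0.08)
  expect_gt(stats::cor(p1, p2), 0.9)
})

test_that("impurity importance ranks separations and respects symmetry", {
  # strong feature vs pure noise: strong ranked first for every seed
  top <- sapply(1:20, function(seed) {
    tab <- make_class_table(50, deltas = c(2, 0), seed = seed)
    fit <- train_fach_forest(tab, seed = seed, num_trees = 200)
    names(feature_importance(fit))[1]
  })
  expect_true(all(top == "f1"))

  # identical class-separations: near-uniform importances
  tab <- make_class_table(150, deltas = c(1, 1, 1), seed = 5)
  fit <- train_fach_forest(tab, seed = 5)
  imp <- feature_importance(fit)
  expect_lt(max(imp) - min(imp), 0.15)
  expect_equal(sum(imp), 1)
  expect_true(all(imp >= 0))
})

test_that("SC leads the importance ranking on cohort-like populations", {
  # default baritone parameters give SC the largest standardized
  # separation; it must come out on top across seeds
  # the designed SC lead (d ~ 1.46 vs 1.28 for PHE) is modest, so in a
  # finite draw PHE sometimes realizes the larger separation; the property
  # is that whichever feature realizes the largest standardized
  # separation -- usually SC -- leads the importance ranking
  gp <- default_group_params("baritone")
  res <- t(sapply(1:10, function(seed) {
    tab <- sample_population(gp, n_per_class = 400, seed = seed)
    fit <- train_fach_forest(tab, seed = seed, num_trees = 300)
    d <- sapply(gp$feature, function(f) {
      a <- tab[[f]][tab$voice_structure == "lyric"]
      b <- tab[[f]][tab$voice_structure == "dramatic"]
      abs(mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
    })
    ds <- sort(d, decreasing = TRUE)
    c(top = names(feature_importance(fit))[1],
      widest = gp$feature[which.max(d)],
      decisive = unname(ds[1] > 1.1 * ds[2]))   # margin below which impurity
  }))                                   # importance may legitimately flip
  dec <- res[, "decisive"] == "TRUE"
  expect_true(any(dec))
  expect_true(all(res[dec, "top"] == res[dec, "widest"]))
  expect_gte(mean(res[, "widest"] == "SC"), 0.7)
})

test_that("cross-validated BER on cohort-parameter populations is stable
          and better than chance", {
  gp <- default_group_params("baritone")
  bers <- sapply(1:10, function(seed) {
    tab <- sample_population(gp, n_per_class = 150, seed = seed)
    cross_validated_ber(tab, k = 5, seed = seed, num_trees = 200)$ber
  })
  expect_true(all(bers < 50))
  expect_lt(max(bers) - min(bers), 10)    # stable within +/- 5 pp
})

test_that("attributions are additive, symmetric and directionally sensible", {
  gp <- default_group_params("baritone")
  tab <- sample_population(gp, n_per_class = 80, seed = 6)
  tab <- tab[, c("sample_id", "voice_type", "voice_structure", "PHE",
                 "SC", "VR", "VE")]
  fit <- train_fach_forest(tab, seed = 6, num_trees = 200)
  idx <- seq(1, nrow(tab), by = 4)
  att <- attribution_summary(fit, tab[idx, ], tab)

  # local accuracy on every explained sample
  resid <- rowSums(att$attributions) - (att$prediction - att$base_value)
  expect_lt(max(abs(resid)), 1e-6)

  # dramatic voices have lower SC: SC attribution anti-correlates with SC
  expect_lt(stats::cor(tab$SC[idx], att$attributions[, "SC"]), -0.8)

  # deterministic for fixed seed and table
  att2 <- attribution_summary(fit, tab[idx, ], tab)
  expect_identical(att$attributions, att2$attributions)
})

test_that("a single-feature model gives that feature every attribution", {
  tab <- make_class_table(50, deltas = 2, seed = 7)
  fit <- train_fach_forest(tab, features = "f1", seed = 7,
                           num_trees = 100)
  att <- attribution_summary(fit, tab[1:20, ], tab)
  resid <- att$attributions[, "f1"] - (att$prediction - att$base_value)
  expect_lt(max(abs(resid)), 1e-12)
})
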