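test_that("binary metrics match hand arithmetic and flag undefined ratios", {
  # hand oracle: TP=3 FP=1 FN=2 TN=4
  m <- binary_metrics(3, 1, 2, 4)
  expect_equal(m$precision, 75)
  expect_equal(m$sensitivity, 60)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 70)
  expect_equal(round(m$f_score, 1), 66.7)
  # perfect predictions
  p <- binary_metrics(5, 0, 0, 5)
  expect_true(all(unlist(p[1:5]) == 100))
  # 0/0 cases are 0 with a flag; all-zero input errors
  z <- binary_metrics(0, 0, 5, 5)
  expect_equal(z$precision, 0)
  expect_true("precision" %in% z$undefined)
  expect_error(binary_metrics(0, 0, 0, 0), "zero")
  expect_error(binary_metrics(-1, 0, 0, 2), "non-negative")
})

test_that("macro averaging equals a brute-force one-vs-rest recomputation", {
  cm <- matrix(c(50, 3, 2,
                 4, 40, 6,
                 1, 5, 44), 3, 3, byrow = TRUE,
               dimnames = list(truth = c("a", "b", "c"),
                               predicted = c("a", "b", "c")))
  rep <- macro_average(cm)
  # oracle: binarize each class by exhaustive relabeling
  total <- sum(cm)
  oracle <- sapply(1:3, function(k) {
    tp <- cm[k, k]; fn <- sum(cm[k, ]) - tp; fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    pr <- 100 * tp / (tp + fp); se <- 100 * tp / (tp + fn)
    c(precision = pr, sensitivity = se,
      specificity = 100 * tn / (tn + fp),
      accuracy = 100 * (tp + tn) / total,
      f_score = 2 * pr * se / (pr + se))
  })
  for (metric in rownames(oracle)) {
    expect_equal(rep[[metric]][1:3], unname(oracle[metric, ]), tolerance = 1e-12)
    expect_equal(rep[[metric]][4], mean(oracle[metric, ]), tolerance = 1e-12)
  }
  # diagonal matrix -> all 100
  d <- diag(c(5, 6, 7)); dimnames(d) <- list(letters[1:3], letters[1:3])
  rd <- macro_average(d)
  expect_true(all(abs(as.matrix(rd[, -1]) - 100) < 1e-12))
  # balanced symmetric binary: macro accuracy equals pooled accuracy
  b <- matrix(c(40, 10, 10, 40), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  rb <- macro_average(b)
  expect_equal(rb$accuracy[rb$class == "macro"], 100 * 80 / 100)
  # zero-support class flagged and excluded from the macro mean
  zs <- matrix(c(5, 2, 1, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  rz <- macro_average(zs)
  expect_identical(attr(rz, "zero_support_classes"), c("b", "c"))
})

test_that("metric reports satisfy the F = 2PS/(P+S) identity row by row", {
  set.seed(8)
  truth <- sample(c("A", "B", "C"), 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.7, truth, sample(c("A", "B", "C"), 300, TRUE))
  rep <- macro_average(confusion_matrix(truth, pred))
  for (i in seq_len(nrow(rep))) {
    p <- rep$precision[i]; s <- rep$sensitivity[i]
    if (p + s > 0 && rep$class[i] != "macro") {
      expect_lt(abs(rep$f_score[i] - 2 * p * s / (p + s)), 0.1)
    }
  }
  # confusion total equals the number of evaluated items
  expect_equal(sum(attr(rep, "confusion")), 300)
})

test_that("hold-out splits are stratified, disjoint, covering, and seeded", {
  items <- data.frame(class = rep(c("pos", "neg"), each = 500))
  plan <- make_holdout_split(items, seed = 3)
  expect_length(plan$train, 700)
  expect_length(plan$validation, 150)
  expect_length(plan$test, 150)
  all_idx <- c(plan$train, plan$validation, plan$test)
  expect_identical(sort(all_idx), seq_len(1000))
  # per-class sizes within 1 of exact ratios
  for (cl in c("pos", "neg")) {
    expect_lte(abs(sum(items$class[plan$train] == cl) - 350), 1)
  }
  expect_identical(make_holdout_split(items, seed = 3)$train, plan$train)
  expect_false(identical(make_holdout_split(items, seed = 4)$train, plan$train))
  expect_error(make_holdout_split(items, ratios = c(0.5, 0.2, 0.2)), "sum")
})

test_that("subject-unit splits keep all of a subject's images together", {
  items <- data.frame(subject_id = rep(sprintf("s%02d", 1:20), each = 15),
                      class = rep(c("pos", "neg"), each = 150))
  plan <- make_holdout_split(items, unit = "subject", seed = 1)
  parts <- list(plan$train, plan$validation, plan$test)
  seen <- lapply(parts, function(idx) unique(items$subject_id[idx]))
  expect_length(Reduce(intersect, seen), 0)
  expect_warning(make_holdout_split(items, unit = "image", seed = 1),
                 "straddle")
})

test_that("k-fold plans are stratified, disjoint and covering", {
  items <- data.frame(class = rep(c("a", "b"), each = 50))
  plan <- kfold_plan(items, k = 10, seed = 2)
  expect_length(plan$folds, 10)
  expect_true(all(lengths(plan$folds) == 10))
  expect_identical(sort(unlist(plan$folds)), seq_len(100))
  for (f in plan$folds) {
    expect_equal(sum(items$class[f] == "a"), 5)
  }
  expect_error(kfold_plan(items, k = 60), "k")
  # aggregate report carries mean and sd rows plus formatted strings
  rows <- data.frame(round = sprintf("fold%02d", 1:4),
                     accuracy = c(87.5, 86.9, 86.9, 85.8))
  agg <- aggregate_rounds(rows)
  expect_equal(nrow(agg), 6)
  expect_equal(agg$accuracy[agg$round == "mean"], mean(rows$accuracy))
  expect_match(attr(agg, "mean_sd")[["accuracy"]], "^86.8 ± 0.7$")
})

test_that("leave-one-site-out holds out only sites containing all classes", {
  # site layout of the emulated multi-site cohort: ASD and NC co-occur only
  # at 4 of the 8 sites
  site_tab <- list(
    NYU = c(ASD = 9, NC = 9), SBL = c(ASD = 9, NC = 9),
    SDSU = c(ASD = 9, NC = 9), Yale = c(ASD = 9, NC = 9),
    Trinity = c(NC = 0, ASD = 0, APD = 4), USM = c(`PDD-NOS` = 1),
    KKI = c(APD = 8), UM1 = c(`PDD-NOS` = 1)
  )
  rows <- list()
  for (s in names(site_tab)) {
    for (cl in names(site_tab[[s]])) {
      n <- site_tab[[s]][[cl]]
      if (n > 0) rows[[length(rows) + 1]] <- data.frame(
        site = s, class = cl)[rep(1, n), ]
    }
  }
  items <- do.call(rbind, rows)
  plan <- leave_one_site_out(items, required_classes = c("ASD", "NC"))
  expect_identical(sort(plan$eligible_sites), sort(c("NYU", "SBL", "SDSU", "Yale")))
  expect_length(plan$rounds, 4)
  for (rd in plan$rounds) {
    expect_identical(sort(c(rd$train, rd$test)), seq_len(nrow(items)))
    expect_true(all(items$site[rd$test] == rd$site))
    expect_false(rd$site %in% items$site[rd$train])
  }
  # two-site toy cohort -> 2 rounds
  toy <- data.frame(site = rep(c("P", "Q"), each = 4),
                    class = rep(c("ASD", "NC"), 4))
  expect_length(leave_one_site_out(toy)$rounds, 2)
  expect_error(leave_one_site_out(data.frame(site = "P", class = "ASD")[0, ]),
               "site|class|items")
})
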