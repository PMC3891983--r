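test_that("confusion counts conserve deaths and match brute-force recall", {
  causes <- c("A", "B", "C")
  withr::with_seed(61, {
    for (rep in 1:5) {
      true <- sample(causes, 20, replace = TRUE)
      pred <- sample(c(causes, NA), 20, replace = TRUE)
      conf <- confusion(true, pred, causes)
      expect_equal(sum(conf$TP + conf$FN), 20)        # conservation
      ss <- sensitivity_specificity(conf)
      expect_equal(unname(ss$sensitivity),
                   unname(oracle_recall(true, pred, causes)))
    }
  })
  # perfect prediction: no FN, no FP anywhere
  conf <- confusion(c("A", "B"), c("A", "B"), causes)
  expect_true(all(conf$FN == 0) && all(conf$FP == 0))
  # one wrong death: one FN (its cause) and one FP (the assigned cause)
  conf1 <- confusion("A", "B", causes)
  expect_equal(sum(conf1$FN), 1)
  expect_equal(sum(conf1$FP), 1)
  expect_error(confusion("A", "Z", causes), "outside")
})

test_that("sensitivity and specificity handle undefined denominators", {
  conf <- confusion(c("A", "A", "B"), c("A", "B", "B"), c("A", "B", "C"))
  ss <- sensitivity_specificity(conf)
  expect_equal(ss$sensitivity[ss$cause == "A"], 0.5)
  expect_true(is.na(ss$sensitivity[ss$cause == "C"]))  # absent cause
  expect_equal(ss$specificity[ss$cause == "C"], 1)
})

test_that("chance-corrected concordance follows its formula", {
  # N = 3, TP = 8, FN = 2: (0.8 - 1/3) / (1 - 1/3) = 0.7
  conf <- data.frame(cause = c("A", "B", "C"), TP = c(8, 5, 0),
                     FN = c(2, 0, 0), FP = c(0, 2, 0), TN = c(5, 8, 15))
  cc <- chance_corrected_concordance(conf)
  expect_equal(unname(cc$per_cause["A"]), 0.7)
  expect_equal(unname(cc$per_cause["B"]), 1)       # perfect sensitivity
  expect_true(is.na(cc$per_cause["C"]))            # absent cause
  expect_equal(cc$overall, mean(c(0.7, 1)))        # unweighted, NA dropped
  # sensitivity exactly 1/N sits at chance level 0
  conf2 <- data.frame(cause = c("A", "B", "C"), TP = c(1, 1, 1),
                      FN = c(2, 2, 2), FP = c(2, 2, 2), TN = c(4, 4, 4))
  expect_equal(unname(chance_corrected_concordance(conf2)$per_cause),
               rep(0, 3))
  expect_error(chance_corrected_concordance(conf[1, , drop = FALSE]),
               "2 causes")
})

test_that("kappa is 1 on identity, ~0 under independence, label-invariant", {
  labs <- rep(c("A", "B", "C"), times = c(5, 3, 2))
  expect_equal(cohens_kappa(labs, labs), 1)
  withr::with_seed(62, {
    true <- sample(c("A", "B"), 10000, replace = TRUE, prob = c(0.7, 0.3))
    pred <- sample(c("A", "B"), 10000, replace = TRUE, prob = c(0.4, 0.6))
    expect_lt(abs(cohens_kappa(true, pred)), 0.02)
    relab <- c(A = "x", B = "y")
    expect_equal(cohens_kappa(relab[true], relab[pred]),
                 cohens_kappa(true, pred))
  })
})

test_that("CSMF accuracy matches its printed identities", {
  true <- csmf(c(a = 0.5, b = 0.3, c = 0.2))
  expect_equal(csmf_accuracy(true, true), 1)
  # swapped mass: 1 - 0.4 / (2 * 0.8) = 0.75
  expect_equal(csmf_accuracy(true, csmf(c(a = 0.3, b = 0.5, c = 0.2))), 0.75)
  # all mass on the rarest cause: maximal summed error, accuracy 0
  expect_equal(csmf_accuracy(true, csmf(c(a = 0, b = 0, c = 1))), 0)
  # symmetric under simultaneous relabeling, bounded, 1 iff equal
  perm <- c(3, 1, 2)
  pred <- csmf(c(a = 0.2, b = 0.2, c = 0.6))
  expect_equal(csmf_accuracy(csmf(as.numeric(true)[perm], letters[1:3]),
                             csmf(as.numeric(pred)[perm], letters[1:3])),
               csmf_accuracy(true, pred))
  expect_lt(csmf_accuracy(true, pred), 1)
  expect_error(csmf_accuracy(csmf(c(a = 1)), csmf(c(a = 1))), "single-cause")
})

test_that("CSMF regression diagnostics recover exact lines", {
  true <- c(0.1, 0.2, 0.3, 0.4)
  r <- csmf_regression(true, true)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$rmse, 0)
  expect_equal(r$mae, 0)
  r2 <- csmf_regression(true, 0.5 * true + 0.1)
  expect_equal(r2$slope, 0.5)
  expect_equal(r2$intercept, 0.1)
  expect_equal(r2$rmse, 0, tolerance = 1e-12)
  # constant truth: regression undefined, absolute error still reported
  r3 <- csmf_regression(rep(0.2, 5), c(0.1, 0.2, 0.3, 0.2, 0.2))
  expect_true(is.na(r3$slope))
  expect_equal(r3$mae, mean(abs(c(0.1, 0.2, 0.3, 0.2, 0.2) - 0.2)))
})

test_that("split summaries bracket the median", {
  s <- summarize_splits(c(1, 2, 3, 4, 5), n_boot = 200, seed = 1)
  expect_equal(s$median, 3)
  expect_lte(s$lower, s$median)
  expect_gte(s$upper, s$median)
  sc <- summarize_splits(rep(0.4, 10), n_boot = 100, seed = 1)
  expect_equal(c(sc$lower, sc$median, sc$upper), rep(0.4, 3))
  expect_error(summarize_splits(1), "at least 2")
})

test_that("a uniform-random assigner scores at chance on CCC and kappa", {
  causes <- paste0("c", 1:10)
  stats <- withr::with_seed(63, {
    vapply(1:10, function(r) {
      true <- sample(causes, 10000, replace = TRUE)
      pred <- sample(causes, 10000, replace = TRUE)
      conf <- confusion(true, pred, causes)
      c(chance_corrected_concordance(conf)$overall,
        cohens_kappa(true, pred))
    }, numeric(2))
  })
  expect_lt(abs(mean(stats[1, ])), 0.02)
  expect_lt(abs(mean(stats[2, ])), 0.02)
})

test_that("individual and population performance move together", {
  # sweep the generator's signal strength: methods that assign deaths
  # better should also estimate compositions better
  ccc <- acc <- numeric(0)
  for (sig in c(0.2, 0.4, 0.6, 0.8)) {
    gen <- gen_dataset(n_causes = 4, n_items = 12, signal = sig,
                       base = 0.2, n = 300, seed = 64)
    ds <- gen$data
    sp <- generate_splits(ds, n_splits = 5, seed = 65)
    for (s in sp) {
      pair <- split_data(ds, s)
      a <- interva_assign(pair$test, fit_conditionals(pair$train))
      conf <- confusion(pair$test$gold_cause, a$cause, ds$causes)
      ccc <- c(ccc, chance_corrected_concordance(conf)$overall)
      truth <- csmf(as.numeric(table(factor(pair$test$gold_cause,
                                            ds$causes))) /
                      n_deaths(pair$test), ds$causes)
      acc <- c(acc, csmf_accuracy(truth, a$csmf))
    }
  }
  expect_gt(cor(ccc, acc), 0.5)
})
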