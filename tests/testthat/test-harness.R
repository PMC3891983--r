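# plugin that predicts the gold cause perfectly
oracle_method <- function() {
  va_method("oracle",
            fit = function(train) NULL,
            predict = function(model, test)
              list(cause = test$gold_cause))
}

# plugin that always predicts the first cause
constant_method <- function() {
  va_method("constant",
            fit = function(train) train$causes[1],
            predict = function(model, test)
              list(cause = rep(model, n_deaths(test))))
}

test_that("method plugins are validated at registration", {
  expect_error(va_method("", fit = identity,
                         predict = function(m, t) NULL), "id")
  expect_error(va_method("m", fit = function() 1,
                         predict = function(m, t) NULL), "fit")
  expect_error(va_method("m", fit = identity,
                         predict = function(m) NULL), "predict")
})

test_that("an oracle plugin attains perfect scores on every split", {
  ds <- gen_dataset(n_causes = 3, n_items = 9, n = 150, seed = 71)$data
  ex <- run_experiment(ds, list(oracle_method()), n_splits = 5,
                       hce = "with", seed = 1)
  ov <- ex$metrics[is.na(ex$metrics$cause), ]
  expect_true(all(ov$value[ov$metric == "ccc"] == 1))
  expect_true(all(ov$value[ov$metric == "kappa"] == 1))
  expect_true(all(ov$value[ov$metric == "csmf_accuracy"] == 1))
})

test_that("a constant assigner scores near chance under the design", {
  ds <- gen_dataset(n_causes = 5, n_items = 15, n = 1000, seed = 72)$data
  ex <- run_experiment(ds, list(constant_method()), n_splits = 30,
                       hce = "with", seed = 2)
  ov <- ex$metrics[ex$metrics$metric == "ccc" & is.na(ex$metrics$cause), ]
  # per-cause CCC is 1 for the predicted cause and -1/(N-1) for the rest;
  # the unweighted mean is 0 by construction of the chance correction
  expect_lt(abs(mean(ov$value)), 0.02)
})

test_that("experiments are deterministic and internally consistent", {
  ds <- gen_dataset(n_causes = 3, n_items = 12, n = 200, seed = 73)$data
  methods <- list(method_interva(), method_kinglu(kl_subset_size = 5,
                                                  n_subsets = 20))
  e1 <- run_experiment(ds, methods, n_splits = 3, seed = 5)
  e2 <- run_experiment(ds, methods, n_splits = 3, seed = 5)
  expect_identical(e1$metrics, e2$metrics)
  expect_identical(e1$csmf, e2$csmf)
  # direct estimation contributes no individual-level rows
  expect_false(any(e1$metrics$method == "kinglu" &
                     e1$metrics$metric %in% c("ccc", "kappa")))
  expect_true(any(e1$metrics$method == "kinglu" &
                    e1$metrics$metric == "csmf_accuracy"))
  # CSMF rows sum to 1 for every method/split/condition
  sums <- tapply(e1$csmf$estimated,
                 paste(e1$csmf$method, e1$csmf$split, e1$csmf$hce),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("with/without HCE runs share splits and drop the flagged items", {
  ds <- gen_dataset(n_causes = 3, n_items = 12, n = 200, seed = 74)$data
  seen <- new.env()
  probe <- va_method("probe",
    fit = function(train) {
      assign(paste0("items", n_items(train)), TRUE, envir = seen)
      NULL
    },
    predict = function(model, test) list(cause = test$gold_cause))
  ex <- run_experiment(ds, list(probe), n_splits = 2, seed = 3)
  expect_setequal(ls(seen),
                  paste0("items", c(12, 12 - sum(ds$items$is_hce))))
  expect_setequal(unique(ex$metrics$hce), c("with", "without"))
})

test_that("a failing method is excluded with a reason, not fatal", {
  ds <- gen_dataset(n_causes = 3, n_items = 9, n = 150, seed = 75)$data
  bomb <- va_method("bomb",
    fit = function(train) stop("boom"),
    predict = function(model, test) NULL)
  ex <- run_experiment(ds, list(bomb, oracle_method()), n_splits = 2,
                       hce = "with", seed = 4)
  expect_equal(nrow(ex$exclusions), 2)
  expect_match(ex$exclusions$reason[1], "boom")
  expect_true(all(ex$metrics$method == "oracle"))
  # a plugin assigning labels outside the cause list is likewise excluded
  alien <- va_method("alien", fit = function(train) NULL,
    predict = function(model, test)
      list(cause = rep("martian_flu", n_deaths(test))))
  ex2 <- run_experiment(ds, list(alien), n_splits = 1, hce = "with",
                        seed = 4)
  expect_match(ex2$exclusions$reason, "outside the cause list")
})

test_that("head-to-head credit is conserved and order-invariant", {
  # strict winner takes every split
  wide <- cbind(a = c(1, 1, 1), b = c(0, 0.5, 0.2))
  h <- head_to_head(wide)
  expect_equal(h$credit[h$method == "a"], 3)
  expect_equal(h$credit[h$method == "b"], 0)
  # exact tie shares the split's credit
  wide2 <- cbind(a = c(1, 0.7), b = c(1, 0.9))
  h2 <- head_to_head(wide2)
  expect_equal(h2$credit, c(0.5, 1.5))
  expect_equal(sum(h2$credit), 2)
  # registration order does not affect credit
  ds <- gen_dataset(n_causes = 3, n_items = 9, n = 150, seed = 76)$data
  e_ab <- run_experiment(ds, list(method_interva(), oracle_method()),
                         n_splits = 3, hce = "with", seed = 6)
  e_ba <- run_experiment(ds, list(oracle_method(), method_interva()),
                         n_splits = 3, hce = "with", seed = 6)
  h_ab <- head_to_head(e_ab); h_ba <- head_to_head(e_ba)
  expect_equal(h_ab[order(h_ab$method), ], h_ba[order(h_ba$method), ],
               ignore_attr = TRUE)
  expect_equal(sum(h_ab$credit), 3)
})

test_that("summaries and reports are written as tidy files", {
  ds <- gen_dataset(n_causes = 3, n_items = 9, n = 150, seed = 77)$data
  ex <- run_experiment(ds, list(method_interva()), n_splits = 4,
                       hce = "with", seed = 7)
  s <- summary(ex)
  expect_true(all(c("median", "lower", "upper") %in% names(s)))
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  reg <- csmf_regression_table(ex)
  expect_true(all(reg$rmse >= 0, na.rm = TRUE))
  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  expect_true(all(file.exists(file.path(dir,
    c("metrics.csv", "csmf.csv", "head_to_head.csv", "summary.json",
      "splits.json")))))
  back <- read.csv(file.path(dir, "metrics.csv"))
  expect_equal(nrow(back), nrow(ex$metrics))
})
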