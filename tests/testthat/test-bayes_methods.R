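test_that("fitted conditionals follow the smoothed count formula", {
  ds <- tiny_dataset()
  # 3 of 3 cause-A deaths endorse it1; smoothing 1 -> (3+1)/(3+2) = 0.8
  cond <- fit_conditionals(ds, smoothing = 1)
  expect_equal(unname(cond$P["it1", "A"]), 4 / 5)
  # 0 of 4 endorsing with smoothing 1 gives 1/6
  X <- matrix(c(0, 0, 0, 0), ncol = 1, dimnames = list(NULL, "i"))
  d4 <- va_dataset(X, va_items("i"), gold_cause = rep("A", 4),
                   causes = c("A", "B"))
  expect_error(fit_conditionals(d4), "zero deaths")   # cause B unseen
  d4$causes <- "A"
  expect_equal(unname(fit_conditionals(d4, 1)$P[1, 1]), 1 / 6)
  # unsmoothed rates are the raw fractions; smoothed ones avoid 0 and 1
  raw <- fit_conditionals(ds, smoothing = 0)
  expect_equal(unname(raw$P["it1", "A"]), 1)
  expect_true(all(cond$P > 0 & cond$P < 1))
})

test_that("joint posterior follows Bayes' rule by hand", {
  # 2 causes, one item with P = (0.8, 0.2), flat prior, death endorses
  P <- matrix(c(0.8, 0.2), 1, dimnames = list("i1", c("A", "B")))
  cond <- structure(list(P = P, causes = c("A", "B")),
                    class = "cause_profiles")
  te <- va_dataset(matrix(1L, 1, 1, dimnames = list(NULL, "i1")),
                   va_items("i1"))
  out <- interva_assign(te, cond)
  expect_equal(unname(out$posterior[1, ]), c(0.8, 0.2))
  expect_equal(out$cause, "A")
  # posterior below a high threshold -> indeterminate
  out2 <- interva_assign(te, cond, threshold = 0.9)
  expect_true(is.na(out2$cause))
  expect_equal(out2$n_indeterminate, 1)
  # an uninformative conditional matrix returns the prior
  Pu <- matrix(0.5, 1, 2, dimnames = list("i1", c("A", "B")))
  condu <- structure(list(P = Pu, causes = c("A", "B")),
                     class = "cause_profiles")
  pr <- csmf(c(A = 0.3, B = 0.7))
  outu <- interva_assign(te, condu, prior = pr)
  expect_equal(unname(outu$posterior[1, ]), c(0.3, 0.7))
})

test_that("joint posteriors match the enumeration oracle to 1e-9", {
  # all 2^10 profiles, 3 causes, random conditionals and prior
  withr::with_seed(31, {
    P <- matrix(runif(10 * 3, 0.05, 0.95), 10, 3,
                dimnames = list(paste0("i", 1:10), c("A", "B", "C")))
    pr <- as.numeric(draw_target_csmf(3))
  })
  prior <- csmf(pr, c("A", "B", "C"))
  X <- all_profiles(10)
  colnames(X) <- rownames(P)
  te <- va_dataset(X, va_items(rownames(P)))
  cond <- structure(list(P = P, causes = colnames(P)),
                    class = "cause_profiles")
  got <- interva_assign(te, cond, prior = prior)$posterior
  want <- oracle_joint_posterior(X, P, pr)
  expect_lt(max(abs(got - want)), 1e-9)
  # every determinate death's joint posterior sums to 1
  expect_true(all(abs(rowSums(got) - 1) < 1e-9))
})

test_that("one-vs-rest posteriors match the enumeration oracle to 1e-9", {
  withr::with_seed(32, {
    P <- matrix(runif(8 * 3, 0.1, 0.9), 8, 3,
                dimnames = list(paste0("i", 1:8), c("A", "B", "C")))
  })
  n_tr <- 60
  tr <- withr::with_seed(33, {
    prof <- structure(list(P = P, items = va_items(rownames(P)),
                           causes = colnames(P), provenance = "synthetic-truth"),
                      class = "cause_profiles")
    simulate_deaths(prof, csmf(c(0.5, 0.3, 0.2), colnames(P)), n_tr)
  })
  X <- all_profiles(8)
  colnames(X) <- rownames(P)
  te <- va_dataset(X, va_items(rownames(P)))
  # full item set, one draw: the subset mechanism plays no role and the
  # posterior must equal the exact one-vs-rest computation on the fitted
  # conditionals and training composition
  got <- ssp_assign(te, tr, subset_size = 8, n_draws = 1, seed = 1)
  Pfit <- fit_conditionals(tr, 1)$P
  pi_tr <- as.numeric(table(factor(tr$gold_cause, colnames(P))) / n_tr)
  want <- oracle_ovr_posterior(X, Pfit, pi_tr)
  expect_lt(max(abs(got$posterior - want)), 1e-9)
})

test_that("for two causes SSP with the full set reduces to joint Bayes", {
  gen <- gen_dataset(n_causes = 2, n_items = 8, signal = 0.6, base = 0.2,
                     n = 200, seed = 34)
  ds <- gen$data
  sp <- generate_splits(ds, n_splits = 1, seed = 1)
  pair <- split_data(ds, sp[[1]])
  pi_tr <- table(factor(pair$train$gold_cause, ds$causes)) /
    n_deaths(pair$train)
  ssp <- ssp_assign(pair$test, pair$train, subset_size = 8, n_draws = 1,
                    seed = 2)
  joint <- interva_assign(pair$test, fit_conditionals(pair$train, 1),
                          prior = csmf(as.numeric(pi_tr), ds$causes))
  expect_equal(ssp$posterior, joint$posterior, tolerance = 1e-9)
  expect_identical(ssp$cause, joint$cause)
})

test_that("SSP is deterministic under a seed and perfect when separable", {
  gen <- gen_dataset(n_causes = 3, n_items = 9, signal = 1, base = 0,
                     n = 150, seed = 35)
  ds <- gen$data
  sp <- generate_splits(ds, n_splits = 1, seed = 3)
  pair <- split_data(ds, sp[[1]])
  a1 <- ssp_assign(pair$test, pair$train, subset_size = 5, n_draws = 20,
                   seed = 9)
  a2 <- ssp_assign(pair$test, pair$train, subset_size = 5, n_draws = 20,
                   seed = 9)
  expect_identical(a1$cause, a2$cause)
  expect_equal(a1$cause, pair$test$gold_cause)
  expect_error(ssp_assign(pair$test, pair$train, subset_size = 99),
               "subset_size")
})

test_that("restricting the joint classifier's items cannot add information", {
  gen <- gen_dataset(n_causes = 4, n_items = 16, signal = 0.5, base = 0.2,
                     n = 500, seed = 36)
  ds <- gen$data
  splits <- generate_splits(ds, n_splits = 50, seed = 4)
  ccc_of <- function(frac) {
    vapply(splits, function(s) {
      pair <- split_data(ds, s)
      cond <- fit_conditionals(pair$train)
      keep <- colnames(ds$X)[seq_len(frac * n_items(ds))]
      a <- interva_assign(pair$test, cond, restricted_items = keep)
      chance_corrected_concordance(
        confusion(pair$test$gold_cause, a$cause, ds$causes))$overall
    }, numeric(1))
  }
  expect_lte(median(ccc_of(0.25)), median(ccc_of(1)))
})
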