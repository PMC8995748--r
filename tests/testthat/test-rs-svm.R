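fake_bounds <- function(c_max, c_min, n)
  structure(list(c_max = c_max, c_min = c_min, extremum_tol = 1e-9,
                 g = 1, n_voxels = n, rho_min = 0, rho_max = 1,
                 swapped = FALSE), class = "feature_bounds")

test_that("surveys respect the size bounds and are seed-deterministic", {
  b <- fake_bounds(21, 132, 64411)
  withr::with_seed(1, {
    for (i in 1:20) {
      s <- draw_survey(64411, b)
      expect_gte(s$l, 21); expect_lte(s$l, 132)
      expect_identical(length(unique(s$R)), s$l)
      expect_true(all(s$R >= 1 & s$R <= 64411))
      expect_true(all(diff(s$R) > 0))
    }
  })
  ## degenerate interval draws exactly l = c_min features
  withr::with_seed(2, {
    s5 <- draw_survey(10, fake_bounds(5, 5, 10))
    expect_identical(s5$l, 5L)
  })
  a <- withr::with_seed(3, draw_survey(100, b <- fake_bounds(3, 9, 100)))
  b2 <- withr::with_seed(3, draw_survey(100, b))
  expect_identical(a, b2)
  expect_error(draw_survey(50, fake_bounds(21, 132, 64411)),
               "C_min")
})

test_that("6:2:2 split is stratified, disjoint and exhaustive", {
  y <- rep(c(-1, 1), each = 5)
  sp <- split_dataset(10, y, seed = 4)
  expect_length(sp$train_idx, 6)
  expect_length(sp$val_idx, 2)
  expect_length(sp$test_idx, 2)
  all_idx <- c(sp$train_idx, sp$val_idx, sp$test_idx)
  expect_setequal(all_idx, 1:10)
  expect_identical(length(all_idx), 10L) # pairwise disjoint
  ## stratification: 3 per class in train, 1 per class in val/test
  expect_identical(sum(y[sp$train_idx] == -1), 3L)
  expect_identical(sum(y[sp$val_idx] == -1), 1L)
  expect_identical(sum(y[sp$test_idx] == -1), 1L)
  expect_identical(split_dataset(10, y, seed = 4), sp)
  expect_false(identical(split_dataset(10, y, seed = 5), sp))
  expect_error(split_dataset(5, rep(1, 5)), "both classes")
})

test_that("uneven class sizes assign remainders train-first", {
  y <- c(rep(-1, 7), rep(1, 9))
  sp <- split_dataset(16, y, seed = 1)
  ## class -1: 7 -> 4.2/1.4/1.4 -> 5/1/1; class +1: 9 -> 6/2/1
  expect_identical(sum(y[sp$train_idx] == -1), 5L)
  expect_identical(sum(y[sp$val_idx] == -1), 1L)
  expect_identical(sum(y[sp$test_idx] == -1), 1L)
  expect_identical(sum(y[sp$train_idx] == 1), 6L)
  expect_setequal(c(sp$train_idx, sp$val_idx, sp$test_idx), 1:16)
})

test_that("grid search maximizes validation accuracy with deterministic ties", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(c(-1, 1), each = 15)
  X[y == 1, ] <- X[y == 1, ] + 3
  tr <- c(1:10, 16:25); va <- c(11:15, 26:30)

  ## single-point grid returns that point
  g1 <- data.frame(kernel = "rbf", C = 7, gamma = 0.2)
  gs1 <- grid_search(X[tr, ], y[tr], X[va, ], y[va], grid = g1)
  expect_equal(gs1$best_params$C, 7)
  expect_equal(gs1$best_params$gamma, 0.2)

  ## default grid contains the conventional start point C=1, gamma=0.5
  dg <- default_svm_grid()
  expect_true(any(dg$C == 1 & dg$kernel == "linear"))
  expect_true(any(dg$C == 1 & !is.na(dg$gamma) & dg$gamma == 0.5))

  ## tie on well-separated data: smaller C wins
  g2 <- data.frame(kernel = "linear", C = c(10, 1), gamma = NA_real_)
  gs2 <- grid_search(X[tr, ], y[tr], X[va, ], y[va], grid = g2)
  expect_identical(
    gs2$grid$val_accuracy[1], gs2$grid$val_accuracy[2])
  expect_equal(gs2$best_params$C, 1)

  expect_error(grid_search(X[tr, ], y[tr], X[va, ], y[va],
                           grid = dg[0, ]), "non-empty")
})

test_that("the survey loop selects, reproduces, and improves with surveys", {
  co <- small_cohort(seed = 21, n = 15, dims = c(5, 5, 5),
                     n_informative = 12)
  pi <- pipeline_inputs(co, split_seed = 2)

  ## a single survey is its own best
  r1 <- run_rs_svm(pi$features, pi$bounds, pi$split, n_surveys = 1,
                   seed = 5)
  expect_identical(nrow(r1$history), 1L)
  expect_identical(r1$best$survey$R,
                   withr::with_seed(5, draw_survey(
                     ncol(pi$features$X), pi$bounds))$R)
  expect_true(r1$best$accepted)

  ## fixed seeds reproduce the whole run
  r30a <- run_rs_svm(pi$features, pi$bounds, pi$split,
                     n_surveys = 30, seed = 5)
  r30b <- run_rs_svm(pi$features, pi$bounds, pi$split,
                     n_surveys = 30, seed = 5)
  expect_identical(r30a$history, r30b$history)
  expect_identical(r30a$best$survey, r30b$best$survey)

  ## prefix property: more surveys never lower the best val accuracy
  r10 <- run_rs_svm(pi$features, pi$bounds, pi$split, n_surveys = 10,
                    seed = 5)
  expect_identical(r30a$history[1:10, ], r10$history)
  expect_gte(max(r30a$history$val_accuracy),
             max(r10$history$val_accuracy))

  ## metrics land in [0, 1]
  expect_true(all(unlist(r30a$history[, c("val_accuracy",
                                          "test_accuracy")]) >= 0))
  expect_true(all(unlist(r30a$history[, c("val_accuracy",
                                          "test_accuracy")]) <= 1))
})

test_that("selected surveys recover planted voxels (precision >= 0.5)", {
  ## derived recovery check: across 10 seeds, at least half of the
  ## best survey's columns are planted informative voxels on average
  prec <- vapply(1:10, function(s) {
    co <- generate_cohort(30, 30, c(6, 7, 6), 20, effect_size = 0.3,
                          noise_sd = 0.05, seed = s)
    pi <- pipeline_inputs(co, split_seed = s + 100)
    rs <- run_rs_svm(pi$features, pi$bounds, pi$split,
                     n_surveys = 200, seed = s + 200)
    survey_recovery(rs, co)$precision
  }, numeric(1))
  expect_gte(mean(prec), 0.5)
})

test_that("planted-voxel recall increases with effect size", {
  recall_at <- function(effect, s) {
    co <- generate_cohort(30, 30, c(6, 7, 6), 20,
                          effect_size = effect, noise_sd = 0.05,
                          seed = s)
    pi <- pipeline_inputs(co, split_seed = s + 10)
    rs <- run_rs_svm(pi$features, pi$bounds, pi$split,
                     n_surveys = 100, seed = s + 20)
    survey_recovery(rs, co)$recall
  }
  gains <- vapply(1:5, function(s)
    recall_at(0.3, s) - recall_at(0.05, s), numeric(1))
  expect_gte(mean(gains), 0)
  expect_gte(sum(gains >= 0), 4)
})
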