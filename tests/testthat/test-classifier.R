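test_that("build_training_set caps abundant species and nothing else", {
  counts <- c(japonicus = 508, vexans = 2056, geniculatus = 322, daciae = 102)
  tab <- withr::with_seed(1, tibble::tibble(
    species = rep(names(counts), counts),
    role = ifelse(rep(names(counts), counts) == "japonicus",
                  "invasive", "native"),
    year = 2011L, x = runif(sum(counts)), y = runif(sum(counts)),
    T13 = rnorm(sum(counts))
  ))
  capped <- build_training_set(tab, cap = 1000, seed = 42)
  got <- table(capped$species)
  expect_equal(got[["vexans"]], 1000)
  expect_equal(got[["japonicus"]], 508)
  expect_equal(got[["geniculatus"]], 322)
  expect_equal(got[["daciae"]], 102)
  expect_equal(sum(capped$role == "invasive"), 508)
  expect_equal(sum(capped$role == "native"), 1424)

  # identity when all species are below the cap
  expect_equal(build_training_set(tab, cap = 3000, seed = 1), tab,
               ignore_attr = TRUE)
  # deterministic under a fixed seed, different under another
  expect_identical(build_training_set(tab, 1000, 7),
                   build_training_set(tab, 1000, 7))
  expect_false(identical(build_training_set(tab, 1000, 7),
                         build_training_set(tab, 1000, 8)))

  single <- tab[tab$role == "native", ]
  expect_error(build_training_set(single, 1000, 1), "binary separator")
})

test_that("well-separated clouds are learned perfectly; training artefacts recorded", {
  tab <- two_cloud_table(20, sep = 10)
  model <- train_niche_model(tab, training_config(gamma = 0.1))
  expect_equal(weighted_f1(tab$role, predict_class(model, tab)), 1.0)
  # resubstitution confusion matrix is carried by the model
  expect_equal(model$training_confusion$tp, 20L)
  expect_equal(model$training_confusion$tn, 20L)
  expect_s3_class(tidy(model), "tbl_df")
  expect_equal(glance(model)$n_invasive, 20)

  # raw mode and probability mode agree on the separable case
  expect_identical(as.character(predict_class(model, tab, mode = "raw")),
                   as.character(predict_class(model, tab, mode = "probability")))

  # degenerate covariates are refused
  flat <- dplyr::mutate(tab, v1 = 1, v2 = 2)
  expect_error(train_niche_model(flat), "zero variance")
})

test_that("identical class distributions give chance-level hold-out skill", {
  # Monte-Carlo: balanced draws from one distribution, stratified 50/50 split
  f1s <- vapply(1:12, function(s) {
    tab <- null_table(200, seed = s)
    idx <- withr::with_seed(s + 500, sample(nrow(tab), nrow(tab) / 2))
    m <- train_niche_model(tab[idx, ], training_config(gamma = 0.5))
    weighted_f1(tab$role[-idx], predict_class(m, tab[-idx, ]))
  }, numeric(1))
  expect_lt(abs(mean(f1s, na.rm = TRUE) - 0.5), 0.1)
})

test_that("probabilities are calibrated, bounded and monotone in the decision value", {
  tab <- two_cloud_table(25, sep = 4, seed = 3)
  model <- train_niche_model(tab, training_config(gamma = 0.1))
  grid <- tibble::tibble(v1 = seq(-3, 7, length.out = 41),
                         v2 = seq(-3, 7, length.out = 41))
  p <- predict_probability(model, grid)
  d <- decision_values(model, grid)
  expect_true(all(p >= 0 & p <= 1))
  # strictly monotone: ordering by decision value equals ordering by probability
  expect_equal(order(d), order(p))
  expect_true(all(diff(p[order(d)]) >= 0))

  # probability equals the fitted sigmoid evaluated at the decision value
  A <- model$platt[["A"]]; B <- model$platt[["B"]]
  d_raw <- if (model$positive_first) d else -d
  expect_equal(p, 1 / (1 + exp(A * d_raw + B)), tolerance = 1e-8)

  # a positive-class support vector sits on the invasive side
  sv_rows <- model$fit$index[model$fit$coefs > 0]
  expect_true(all(predict_probability(model, tab[sv_rows[1], ]) > 0.5))

  # threshold semantics
  lab <- predict_class(model, grid, threshold = 0)
  expect_true(all(lab == "invasive"))
  pl <- predict_class(model, grid)
  expect_identical(unname(pl[p >= 0.5] == "invasive"),
                   rep(TRUE, sum(p >= 0.5)))

  # dimension mismatch names the expected variables
  expect_error(predict_probability(model, tibble::tibble(v1 = 1)), "v2")
})

test_that("predictions depend on raw covariate units (no silent standardization)", {
  tab <- two_cloud_table(25, sep = 2, seed = 5)
  model <- train_niche_model(tab, training_config(gamma = 0.05))
  scaled <- dplyr::mutate(tab, v1 = v1 * 10)
  p_orig <- predict_probability(model, tab)
  p_scaled <- predict_probability(model, scaled)
  expect_false(isTRUE(all.equal(p_orig, p_scaled)))

  # explicit standardization flag changes the model, not the caller's data
  m_std <- train_niche_model(tab, training_config(gamma = 0.05, standardize = TRUE))
  expect_true(all(predict_probability(m_std, tab) >= 0))
})

test_that("models survive a JSON round trip with identical predictions", {
  tab <- two_cloud_table(20, sep = 3, seed = 7)
  grid <- tibble::tibble(v1 = runif(50, -2, 5), v2 = runif(50, -2, 5))
  for (std in c(FALSE, TRUE)) {
    model <- train_niche_model(tab, training_config(gamma = 0.1, standardize = std))
    f <- withr::local_tempfile(fileext = ".json")
    write_niche_model(model, f)
    back <- read_niche_model(f)
    expect_equal(predict_probability(back, grid),
                 predict_probability(model, grid), tolerance = 1e-10)
    expect_equal(decision_values(back, grid), decision_values(model, grid),
                 tolerance = 1e-10)
    expect_identical(as.character(predict_class(back, grid)),
                     as.character(predict_class(model, grid)))
  }
})

test_that("training is deterministic and cross-checks against an independent SVM", {
  tab <- two_cloud_table(30, sep = 2, seed = 9)
  m1 <- train_niche_model(tab, training_config(gamma = 0.1, subsample_seed = 3))
  m2 <- train_niche_model(tab, training_config(gamma = 0.1, subsample_seed = 3))
  grid <- tibble::tibble(v1 = runif(30, -2, 4), v2 = runif(30, -2, 4))
  expect_identical(predict_probability(m1, grid), predict_probability(m2, grid))

  skip_if_not_installed("kernlab")
  # same kernel, same hyperparameters, independent implementation: the two
  # decision boundaries must agree on clearly classified points
  kfit <- kernlab::ksvm(as.matrix(tab[, c("v1", "v2")]),
                        factor(tab$role, levels = c("invasive", "native")),
                        kernel = "rbfdot", kpar = list(sigma = 0.1),
                        C = 1, scaled = FALSE)
  kpred <- as.character(kernlab::predict(kfit, as.matrix(grid)))
  ours <- as.character(predict_class(m1, grid, mode = "raw"))
  expect_gt(mean(kpred == ours), 0.95)
})
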