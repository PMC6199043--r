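test_that("window features concatenate scaled rows with neutral padding", {
  pr <- random_profile(L = 20L, seed = 2L)
  v <- window_features(pr, 10L, 13L)
  expect_length(v, 260L)
  expect_equal(v, as.vector(t(pr$scaled[4:16, ])))

  # pseudo-profiles are probability-valued: neutral pad is the uniform 1/20
  v1 <- window_features(pr, 1L, 13L)
  expect_equal(v1[1:120], rep(0.05, 120))
  expect_equal(v1[121:260], as.vector(t(pr$scaled[1:7, ])))

  expect_error(window_features(pr, 1L, 12L), class = "tmhkit_config_error")
  expect_error(window_features(pr, 21L, 13L), class = "tmhkit_input_error")

  # identical contexts -> identical vectors
  rec <- sequence_record("r", strrep("ACDEFGHIKL", 4))
  prr <- pseudo_profile(rec)
  expect_identical(window_features(prr, 15L, 13L),
                   window_features(prr, 25L, 13L))
})

test_that("classify matches stated closed forms", {
  model <- structure(list(
    x = matrix(c(0, 0, 10, 10), nrow = 2, byrow = TRUE),
    y = c(1L, 0L), k = 1L, alpha0 = 0.95, gamma_pos = 1, gamma_neg = 1,
    window_size = NA_integer_, feature_length = 2L),
    class = "oetknn_model")
  # single TMH neighbor at d=0: 0.95 + 0.05/2
  expect_equal(classify_oetknn(model, c(0, 0)), 0.975)
  # two neighbors, one per class, equal distance and gammas -> 0.5
  model$k <- 2L
  expect_equal(classify_oetknn(model, c(5, 5)), 0.5)
})

test_that("classify equals the exhaustive Dempster oracle (k <= 5)", {
  withr::with_seed(42, {
    for (case in 1:200) {
      n <- sample(6:15, 1); p <- sample(2:6, 1); k <- sample(1:5, 1)
      x <- matrix(rnorm(n * p), ncol = p)
      y <- c(0L, 1L, sample(c(0L, 1L), n - 2L, replace = TRUE))
      g <- runif(2, 0.1, 2)
      model <- structure(list(x = x, y = y, k = k, alpha0 = 0.95,
                              gamma_pos = g[1], gamma_neg = g[2],
                              window_size = NA_integer_, feature_length = p),
                         class = "oetknn_model")
      q <- rnorm(p)
      expect_equal(classify_oetknn(model, q),
                   oetknn_oracle(x, y, q, k, 0.95, g[1], g[2]),
                   tolerance = 1e-9)
    }
  })
})

test_that("Dempster combination is order-invariant and monotone in distance", {
  withr::with_seed(17, {
    for (case in 1:50) {
      n <- 20L; p <- 4L; k <- 7L
      x <- matrix(rnorm(n * p), ncol = p)
      y <- rep(c(0L, 1L), each = 10L)
      model <- structure(list(x = x, y = y, k = k, alpha0 = 0.9,
                              gamma_pos = 0.7, gamma_neg = 0.5,
                              window_size = NA_integer_, feature_length = p),
                         class = "oetknn_model")
      q <- rnorm(p)
      base <- classify_oetknn(model, q)
      perm <- sample(n)
      shuffled <- model
      shuffled$x <- x[perm, , drop = FALSE]; shuffled$y <- y[perm]
      expect_equal(classify_oetknn(shuffled, q), base, tolerance = 1e-12)
      expect_gte(base, 0); expect_lte(base, 1)
    }
  })
})

test_that("pulling a positive neighbor closer never decreases the propensity", {
  withr::with_seed(23, {
    for (case in 1:100) {
      k <- sample(2:6, 1)
      d2 <- runif(k, 0, 4)
      lab <- c(1L, sample(c(0L, 1L), k - 1L, replace = TRUE))
      m_far <- tmhkit:::neighbor_mass(d2, lab, 0.95, 0.8, 0.6)
      d2_near <- d2; d2_near[1] <- d2[1] * runif(1)
      m_near <- tmhkit:::neighbor_mass(d2_near, lab, 0.95, 0.8, 0.6)
      p_far <- tmhkit:::pignistic_tmh(tmhkit:::dempster_combine(m_far))
      p_near <- tmhkit:::pignistic_tmh(tmhkit:::dempster_combine(m_near))
      expect_gte(p_near, p_far - 1e-12)
    }
  })
})

test_that("duplicating references with doubled k preserves every decision", {
  # Dempster's rule is not idempotent: combining each neighbor's evidence
  # twice strengthens it, so the propensity value itself shifts away from
  # 0.5. What duplication + doubled k cannot do is flip a decision: the
  # sign of (propensity - 0.5) is invariant (brute-force 20-point check).
  cl <- gaussian_clouds(10L, p = 4L, seed = 5L)
  model <- train_oetknn(cl$x, cl$y, k = 3L, refine = FALSE)
  dup <- model
  dup$x <- rbind(cl$x, cl$x); dup$y <- c(cl$y, cl$y); dup$k <- 6L
  q <- withr::with_seed(6, matrix(rnorm(20 * 4), ncol = 4))
  p1 <- classify_oetknn(model, q)
  p2 <- classify_oetknn(dup, q)
  expect_equal(sign(p2 - 0.5), sign(p1 - 0.5))
  expect_true(all(abs(p2 - 0.5) >= abs(p1 - 0.5) - 1e-12))
})

test_that("training on separated clouds reaches low LOO error; refinement never hurts", {
  cl <- gaussian_clouds(60L, p = 8L, sep = 4, seed = 1L)
  init <- train_oetknn(cl$x, cl$y, k = 11L, refine = FALSE)
  nb <- tmhkit:::loo_neighbors(init$x, init$y, init$k)
  err_init <- tmhkit:::loo_error(nb, init$y, init$alpha0,
                                 init$gamma_pos, init$gamma_neg)
  refined <- train_oetknn(cl$x, cl$y, k = 11L, refine = TRUE)
  expect_lte(refined$loo_error, err_init)
  expect_lte(refined$loo_error, 0.05)
})

test_that("training rejects degenerate corpora", {
  x <- matrix(rnorm(40), ncol = 4)
  expect_error(train_oetknn(x, rep(1L, 10)), class = "tmhkit_training_error")
  expect_error(train_oetknn(x, rep(c(0L, 1L), 5), k = 6L),
               class = "tmhkit_training_error")
  m <- train_oetknn(x, rep(c(0L, 1L), 5), k = 2L, refine = FALSE)
  expect_error(classify_oetknn(m, rnorm(5)), class = "tmhkit_input_error")
})

test_that("multi-scale prediction averages per-window propensities", {
  corpus <- small_corpus(6L, seed = 21L)
  model <- train_tmh_model(corpus, windows = window_config(c(5L, 7L)),
                           k = 5L, max_ref = 1500L, refine = FALSE)
  pr <- pseudo_profile(corpus[[1]]$record)
  track <- predict_propensity(pr, model)
  expect_length(track$values, corpus[[1]]$record$length)
  expect_true(all(track$values >= 0 & track$values <= 1))
  w5 <- classify_oetknn(model$models[["5"]], window_feature_matrix(pr, 5L))
  w7 <- classify_oetknn(model$models[["7"]], window_feature_matrix(pr, 7L))
  expect_equal(track$values, (w5 + w7) / 2)
})

test_that("tmh model archive round-trips", {
  corpus <- small_corpus(4L, seed = 31L)
  model <- train_tmh_model(corpus, windows = window_config(c(5L, 7L)),
                           k = 3L, max_ref = 400L, refine = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tmh_model(model, path)
  back <- read_tmh_model(path)
  expect_equal(back$windows, model$windows)
  for (w in names(model$models)) {
    expect_equal(back$models[[w]]$x, model$models[[w]]$x)
    expect_equal(back$models[[w]]$gamma_pos, model$models[[w]]$gamma_pos)
  }
  pr <- pseudo_profile(corpus[[1]]$record)
  expect_equal(predict_propensity(pr, back)$values,
               predict_propensity(pr, model)$values)
})
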