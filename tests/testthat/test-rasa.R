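# Shared small synthetic RASA corpus (profiles, tracks, topologies).
rasa_fixture <- function(n = 12L, seed = 55L, noise_sd = 10) {
  corpus <- generate_membrane_protein_corpus(
    topology_generator_config(n_proteins = n, seed = seed))
  tracks <- generate_rasa_corpus(corpus, noise_sd = noise_sd,
                                 seed = seed + 1L)
  profiles <- lapply(corpus, function(e) pseudo_profile(e$record))
  list(corpus = corpus, tracks = tracks, profiles = profiles)
}

test_that("template pool: entry count, unit norms, determinism", {
  rec <- random_record("p", 20L, seed = 1L)
  pr <- pseudo_profile(rec)
  tr <- rasa_track("p", withr::with_seed(2, runif(20, 0, 100)))
  pool <- build_template_pool(list(pr), list(tr), segment_length = 15L)
  expect_equal(nrow(pool$features), 6L)  # positions 8..13
  expect_equal(sqrt(rowSums(pool$features^2)), rep(1, 6), tolerance = 1e-12)
  expect_equal(pool$rasa, tr$values[8:13])
  pool2 <- build_template_pool(list(pr), list(tr), segment_length = 15L)
  expect_identical(pool, pool2)
  expect_error(build_template_pool(list(), list()),
               class = "tmhkit_build_error")
})

test_that("template_predict: self-match similarity 1, scale invariance", {
  fx <- rasa_fixture(4L)
  pool <- build_template_pool(fx$profiles, fx$tracks)
  out <- template_predict(fx$profiles[[1]], pool,
                          rasa_fusion_config(top_t = 1L))
  L <- fx$corpus[[1]]$record$length
  # interior positions match their own stored window exactly
  interior <- 8:(L - 7)
  expect_equal(out$similarity[interior], rep(1, length(interior)),
               tolerance = 1e-9)
  expect_equal(out$track$values[interior], fx$tracks[[1]]$values[interior],
               tolerance = 1e-9)
  # truncated terminal windows: similarity 0
  expect_equal(out$similarity[1:7], rep(0, 7))

  # similarity is invariant to rescaling the query profile
  pr2 <- fx$profiles[[1]]
  pr2$scaled <- pr2$scaled * 3
  out2 <- template_predict(pr2, pool, rasa_fusion_config(top_t = 1L))
  expect_equal(out2$similarity, out$similarity, tolerance = 1e-9)

})

test_that("leave-one-protein-out templates beat the corpus-mean baseline", {
  fx <- rasa_fixture(12L)
  pool <- build_template_pool(fx$profiles, fx$tracks)
  err_tmpl <- err_base <- NULL
  for (e in 1:3) {
    loo <- template_predict(fx$profiles[[e]], pool, rasa_fusion_config(),
                            exclude_source = fx$corpus[[e]]$record$id)
    obs <- fx$tracks[[e]]$values
    base <- mean(unlist(lapply(fx$tracks[-e], `[[`, "values")))
    err_tmpl <- c(err_tmpl, abs(loo$track$values - obs))
    err_base <- c(err_base, abs(base - obs))
  }
  expect_lt(mean(err_tmpl), mean(err_base))
})

test_that("rasa feature matrix has the six-block layout", {
  fx <- rasa_fixture(2L)
  pr <- fx$profiles[[1]]
  topo <- fx$corpus[[1]]$topology
  f <- rasa_features(pr, topo, W = 9L)
  L <- fx$corpus[[1]]$record$length
  expect_equal(dim(f), c(L, 9L * 20L + 9L + 20L + 9L + 1L + 1L))
  # block 3 is one-hot on the residue
  chars <- strsplit(pr$residues, "")[[1]]
  onehot <- f[, (180L + 9L + 1L):(180L + 9L + 20L)]
  expect_equal(rowSums(onehot), rep(1, L))
  expect_equal(aa_alphabet()[apply(onehot, 1, which.max)], chars)
  # block 5 is zero outside helices
  m <- as.logical(tmhkit:::topology_mask(topo, L))
  expect_true(all(f[!m, ncol(f) - 1L] == 0))
})

test_that("kernel regression engine honors its contracts", {
  withr::with_seed(77, {
    x <- matrix(runif(200 * 5), ncol = 5)
    # noiseless linear relation into [0,100]
    y <- pmin(100, pmax(0, 20 + x %*% c(10, 20, -5, 15, 8)))
  })
  reg <- train_rasa_regressor(x, as.numeric(y), seed = 3L)
  pred <- predict(reg, x)
  expect_lt(mean(abs(pred - y)), 5)
  expect_true(all(pred >= 0 & pred <= 100))

  expect_warning(cst <- train_rasa_regressor(x[1:50, ], rep(42, 50)),
                 "constant")
  expect_equal(predict(cst, x[51:60, ]), rep(42, 10))

  reg2 <- train_rasa_regressor(x, as.numeric(y), seed = 3L)
  expect_equal(predict(reg2, x[1:5, ]), pred[1:5])
  expect_error(predict(reg, x[, 1:3]), class = "tmhkit_input_error")
})

test_that("fusion rules follow the knowledge rule", {
  tv <- rasa_track("p", c(10, 20, 30))
  rv <- rasa_track("p", c(90, 80, 70))
  hs <- fuse_rasa(tv, c(0.95, 0.2, 0.9), rv,
                  rasa_fusion_config(similarity_threshold = 0.9))
  expect_equal(hs$values, c(10, 80, 30))
  expect_equal(attr(hs, "engine"), c("template", "regression", "template"))

  all_t <- fuse_rasa(tv, rep(1, 3), rv, rasa_fusion_config())
  expect_equal(all_t$values, tv$values)
  all_r <- fuse_rasa(tv, rep(0, 3), rv, rasa_fusion_config())
  expect_equal(all_r$values, rv$values)

  bl <- fuse_rasa(tv, c(1, 0.5, 0), rv,
                  rasa_fusion_config(blend = "similarity_blend"))
  expect_equal(bl$values, c(10, 50, 70))
  expect_error(fuse_rasa(tv, c(1, 0), rv, rasa_fusion_config()),
               class = "tmhkit_input_error")
})

test_that("evaluate_rasa computes pearson and mae per contract", {
  a <- rasa_track("p", c(10, 40, 80, 20))
  expect_equal(evaluate_rasa(a, a), list(pearson_r = 1, mae = 0))
  shifted <- rasa_track("p", pmin(100, a$values + 10))
  ev <- evaluate_rasa(shifted, a)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$mae, 10)
  anti <- evaluate_rasa(rasa_track("p", c(0, 100)), rasa_track("p", c(100, 0)))
  expect_equal(anti$pearson_r, -1)
  expect_warning(ev <- evaluate_rasa(a, rasa_track("p", rep(50, 4))),
                 "constant")
  expect_true(is.na(ev$pearson_r))
  expect_equal(ev$mae, mean(abs(a$values - 50)))
})

test_that("all predictions stay within [0,100] on arbitrary inputs", {
  fx <- rasa_fixture(6L, seed = 91L, noise_sd = 25)
  pool <- build_template_pool(fx$profiles[1:4], fx$tracks[1:4])
  feats <- do.call(rbind, lapply(1:4, function(e)
    rasa_features(fx$profiles[[e]], fx$corpus[[e]]$topology)))
  reg <- train_rasa_regressor(feats,
                              unlist(lapply(fx$tracks[1:4], `[[`, "values")),
                              seed = 1L)
  for (e in 5:6) {
    tmpl <- template_predict(fx$profiles[[e]], pool)
    rg <- predict(reg, rasa_features(fx$profiles[[e]],
                                     fx$corpus[[e]]$topology))
    fused <- fuse_rasa(tmpl$track, tmpl$similarity,
                       rasa_track(fx$profiles[[e]]$record_id, rg))
    expect_true(all(fused$values >= 0 & fused$values <= 100))
    expect_true(all(tmpl$track$values >= 0 & tmpl$track$values <= 100))
  }
})
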