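test_that("signal-free alignments give zero coevolution scores", {
  msa <- msa_block(rep("ACDEFGHIKLMNPQRSTVWY", 10))
  map <- coevolution_scores(msa, coevolution_config(apc = FALSE))
  expect_true(all(map$scores[!is.na(map$scores)] == 0))
  expect_error(coevolution_scores(msa_block("ACDEF")),
               class = "tmhkit_insufficient_alignment_error")
})

test_that("coevolution engine recovers planted pairs and is row-order invariant", {
  planted <- generate_planted_contact_msa(30L, 300L, 5L, 0.9, seed = 8L)
  map <- coevolution_scores(planted$msa, record_id = "q")
  sc <- map$scores
  pl <- sc[cbind(planted$pairs$i, planted$pairs$j)]
  bg <- sc[upper.tri(sc)]
  expect_gt(mean(pl), mean(bg, na.rm = TRUE))
  map <- set_contact_truth(map, planted$pairs)
  # top-n_pairs precision at least 10x the random baseline
  n_unmasked <- sum(!is.na(sc[upper.tri(sc)]))
  expect_gte(top_k_accuracy(map, 5L), 10 * 5 / n_unmasked)

  perm <- withr::with_seed(4, sample(planted$msa$depth))
  shuffled <- msa_block(planted$msa$seqs[perm], planted$msa$ids[perm])
  map2 <- coevolution_scores(shuffled, record_id = "q")
  expect_equal(map2$scores, map$scores, tolerance = 1e-8)
})

test_that("APC annihilates product structure up to the self-pair masking", {
  withr::with_seed(2, {
    # the removal is exact only when self-pairs are included in the means;
    # excluding them leaves a residual of order 1/L that shrinks with L
    resid_frac <- vapply(c(40L, 160L), function(L) {
      a <- runif(L, 0.5, 2)
      s <- outer(a, a)
      corrected <- apc_correct(s)  # mask = diagonal only
      off <- !diag(TRUE, L)
      mean(abs(corrected[off])) / mean(abs(s[off]))
    }, numeric(1))
    expect_lt(resid_frac[1], 0.05)   # >95% of product structure removed
    expect_lt(resid_frac[2], resid_frac[1])  # residual shrinks with L
    # with the engine's separation mask the removal is still near-total
    L <- 40L
    a <- runif(L, 0.5, 2)
    s <- outer(a, a)
    mask <- abs(row(s) - col(s)) >= 5
    corr_masked <- apc_correct(s, mask)
    expect_lt(mean(abs(corr_masked[mask])), 0.05 * mean(s[mask]))
  })
})

test_that("pair features are canonical, sized 2*W*20+3, and guarded", {
  pr <- random_profile(L = 40L, seed = 9L)
  topo <- topology("rec", c(3L, 20L), c(12L, 30L))
  v1 <- pair_features(pr, topo, 5L, 25L)
  v2 <- pair_features(pr, topo, 25L, 5L)
  expect_identical(v1, v2)
  expect_length(v1, 2L * 7L * 20L + 3L)
  expect_error(pair_features(pr, topo, 5L, 10L),
               class = "tmhkit_masked_pair_error")  # same helix
  expect_error(pair_features(pr, topo, 5L, 15L),
               class = "tmhkit_masked_pair_error")  # j in a loop

  tab <- contact_pair_table(pr, topo)
  expect_true(all(tab$pairs$j - tab$pairs$i >= 5L))
  k <- which(tab$pairs$i == 5L & tab$pairs$j == 25L)
  expect_equal(unname(tab$features[k, ]), unname(v1))
})

test_that("under-sampling ensemble: diversity, mean scoring, guards", {
  withr::with_seed(31, {
    x <- rbind(matrix(rnorm(40 * 6), ncol = 6),
               matrix(rnorm(160 * 6, mean = 3), ncol = 6))
    y <- c(rep(1L, 40), rep(0L, 160))
  })
  ens <- train_contact_ensemble(x, y, n_models = 10L, k = 5L, seed = 2L)
  negsets <- lapply(ens$members, `[[`, "negatives")
  expect_gt(length(unique(vapply(negsets, paste, "", collapse = ","))), 1L)

  # far inside the positive cloud every member says ~1, so the mean does too
  q <- matrix(0, 1, 6)
  member_scores <- vapply(ens$members, function(m)
    classify_oetknn(m, sweep(q, 2, ens$feature_scale, "*")), numeric(1))
  expect_equal(predict_contact_ensemble(ens, q), mean(member_scores))
  expect_gt(predict_contact_ensemble(ens, q), 0.9)

  expect_error(train_contact_ensemble(x, rep(0L, nrow(x))),
               class = "tmhkit_training_error")

  # separable corpus: ensemble training accuracy close to member accuracy
  sc <- predict_contact_ensemble(ens, x)
  ens_acc <- mean((sc >= 0.5) == (y == 1L))
  member_acc <- vapply(ens$members, function(m) {
    xs <- sweep(x, 2, ens$feature_scale, "*")
    mean((classify_oetknn(m, xs) >= 0.5) == (y == 1L))
  }, numeric(1))
  expect_gte(ens_acc, max(member_acc) - 0.05)
})

test_that("contact ensemble archive round-trips", {
  withr::with_seed(41, {
    x <- rbind(matrix(rnorm(20 * 5), ncol = 5),
               matrix(rnorm(40 * 5, mean = 2), ncol = 5))
    y <- c(rep(1L, 20), rep(0L, 40))
  })
  ens <- train_contact_ensemble(x, y, n_models = 3L, k = 3L, seed = 7L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_ensemble(ens, path)
  back <- read_contact_ensemble(path)
  q <- withr::with_seed(42, matrix(rnorm(10 * 5), ncol = 5))
  expect_equal(predict_contact_ensemble(back, q),
               predict_contact_ensemble(ens, q))
})

test_that("rank fusion respects weights and improves shared top pairs", {
  withr::with_seed(12, {
    L <- 20L
    base <- matrix(NA_real_, L, L)
    idx <- which(upper.tri(base) & abs(row(base) - col(base)) >= 5)
    a <- base; a[idx] <- runif(length(idx))
    b <- base; b[idx] <- runif(length(idx))
    sym <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; m }
    ma <- contact_map("q", sym(a)); mb <- contact_map("q", sym(b))

    same <- fuse_contact_maps(ma, ma)
    expect_equal(order(same$scores[idx]), order(ma$scores[idx]))
    wa <- fuse_contact_maps(ma, mb, w = 1)
    expect_equal(order(wa$scores[idx]), order(ma$scores[idx]))

    mismatched <- contact_map("q", sym(b), min_separation = 6L)
    expect_error(fuse_contact_maps(ma, mismatched),
                 class = "tmhkit_input_error")
  })

  # constructed 5-pair example: the true pair ranked 1st and 3rd fuses to
  # rank <= 2
  mk <- function(scores_ij) {
    m <- matrix(NA_real_, 12, 12)
    pairs <- cbind(c(1, 1, 2, 3, 4), c(6, 8, 9, 10, 11))
    m[pairs] <- scores_ij
    m[pairs[, 2:1]] <- scores_ij
    contact_map("q", m)
  }
  f <- fuse_contact_maps(mk(c(5, 4, 3, 2, 1)), mk(c(3, 5, 4, 2, 1)), w = 0.5)
  fused_rank <- rank(-f$scores[cbind(c(1, 1, 2, 3, 4), c(6, 8, 9, 10, 11))])
  expect_lte(fused_rank[1], 2)
})

test_that("top_k_accuracy counts true contacts with lexicographic ties", {
  m <- matrix(NA_real_, 12, 12)
  pairs <- cbind(c(1, 1, 2, 3, 4, 5), c(6, 8, 9, 10, 11, 12))
  m[pairs] <- c(0.9, 0.8, 0.8, 0.5, 0.4, 0.1)
  m[pairs[, 2:1]] <- m[pairs]
  map <- contact_map("q", m)
  map <- set_contact_truth(map, data.frame(i = c(1, 2), j = c(6, 9)))
  # hand enumeration: top3 = (1,6), (1,8), (2,9) -> 2/3 true
  expect_equal(top_k_accuracy(map, 3L), 2 / 3)
  expect_equal(top_k_accuracy(map, 1L), 1)
  map0 <- set_contact_truth(map, data.frame(i = integer(), j = integer()))
  expect_equal(top_k_accuracy(map0, 3L), 0)
  expect_error(top_k_accuracy(contact_map("q", m), 3L),
               class = "tmhkit_input_error")
})

test_that("fusion dominance holds across seeds on the planted benchmark", {
  # ML engine trained once on 20 independent planted alignments at the
  # benchmark scale (L=50, depth 400, 10 planted pairs, coupling 0.9);
  # evaluated against the coevolution engine on 10 fresh alignments, all
  # maps restricted to their common scorable (inter-helix) pairs.
  topo <- dense_helix_topology(50L)
  train <- lapply(300:319, function(s)
    planted_pair_corpus(generate_planted_contact_msa(50L, 400L, 10L, 0.9,
                                                     seed = s), topo))
  ens <- train_contact_ensemble(
    do.call(rbind, lapply(train, function(t) t$tab$features)),
    unlist(lapply(train, `[[`, "lab")), seed = 5L)
  gaps <- vapply(1:10, function(rep) {
    planted <- generate_planted_contact_msa(50L, 400L, 10L, 0.9,
                                            seed = 400L + rep)
    b <- planted_pair_corpus(planted, topo)
    ml <- pairs_to_map("query", 50L, b$tab$pairs,
                       predict_contact_ensemble(ens, b$tab$features))
    co <- suppressWarnings(coevolution_scores(planted$msa,
                                              record_id = "query"))
    common <- !is.na(co$scores) & !is.na(ml$scores)
    restrict <- function(m) {
      s <- m$scores; s[!common] <- NA
      set_contact_truth(contact_map("query", s), planted$pairs)
    }
    mlr <- restrict(ml); cor <- restrict(co)
    fused <- fuse_contact_maps(cor, mlr)
    k <- max(1L, round(50 / 5))
    top_k_accuracy(fused, k) -
      max(top_k_accuracy(cor, k), top_k_accuracy(mlr, k))
  }, numeric(1))
  expect_true(all(gaps >= -0.05))
})
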