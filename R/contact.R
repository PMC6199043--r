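## contact: TMH-TMH residue contact prediction.
##
## Two engines are fused: (1) an unsupervised coevolution engine of the
## sparse-inverse-covariance (PSICOV-style) family -- sequence-weighted
## indicator covariance over the MSA, shrinkage, graphical lasso, block
## L1 norms, average product correction; (2) a supervised classifier
## ensemble built by repeated random under-sampling of the (majority)
## non-contact class, with OET-KNN base learners over dual-window pair
## features. Maps are fused by weighted rank averaging.

#' Coevolution engine configuration
#'
#' @param shrinkage_lambda shrinkage of the covariance toward its diagonal,
#'   in \[0,1\] (default 0.1).
#' @param sparsity_rho L1 penalty of the sparse inverse estimate (default
#'   0.005).
#' @param seq_weight_identity fractional-identity threshold for sequence
#'   weighting, in (0,1) (default 0.8).
#' @param apc apply the average product correction (default TRUE).
#' @param pseudocount frequency pseudocount (default 1), applied as
#'   covariance shrinkage toward the independence model so that
#'   signal-free alignments keep exactly zero covariance.
#' @param max_iter,tol stopping rule of the sparse estimator.
#' @return a `coevolution_config` list.
#' @export
coevolution_config <- function(shrinkage_lambda = 0.1, sparsity_rho = 0.005,
                               seq_weight_identity = 0.8, apc = TRUE,
                               pseudocount = 1, max_iter = 50L, tol = 1e-3) {
  if (shrinkage_lambda < 0 || shrinkage_lambda > 1 || sparsity_rho <= 0 ||
      seq_weight_identity <= 0 || seq_weight_identity >= 1 ||
      pseudocount < 0 || max_iter < 1L || tol <= 0)
    tk_stop("invalid coevolution configuration", "tmhkit_config_error")
  structure(list(shrinkage_lambda = shrinkage_lambda,
                 sparsity_rho = sparsity_rho,
                 seq_weight_identity = seq_weight_identity, apc = apc,
                 pseudocount = pseudocount, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "coevolution_config")
}

## 0/1 indicator matrix (depth x 20L) of the 20 residue states per column;
## gaps and X rows are all-zero for that column (gap dropped as the
## reference category, keeping the covariance invertible after shrinkage).
msa_indicator <- function(mat) {
  depth <- nrow(mat); L <- ncol(mat)
  X <- matrix(0, depth, 20L * L)
  code <- match(mat, AA20)  # NA for '-' and 'X'
  ok <- which(!is.na(code))
  rows <- ((ok - 1L) %% depth) + 1L
  cols <- ((ok - 1L) %/% depth)  # 0-based alignment column
  X[cbind(rows, cols * 20L + code[ok])] <- 1
  X
}

#' Sequence weights for an alignment
#'
#' Each row's weight is `1 / n_r` where `n_r` counts the rows (including
#' itself) whose fractional identity to it is at least
#' `identity_threshold`.
#'
#' @param msa an `msa_block`.
#' @param identity_threshold fractional identity threshold (default 0.8).
#' @return numeric vector of weights, one per row.
#' @export
sequence_weights <- function(msa, identity_threshold = 0.8) {
  mat <- msa_matrix(msa)
  depth <- nrow(mat); L <- ncol(mat)
  ## identity via indicator crossprod over the 22-state alphabet
  states <- c(aa_alphabet(with_x = TRUE), "-")
  code <- match(mat, states)
  X <- matrix(0, depth, length(states) * L)
  cols0 <- ((seq_along(code) - 1L) %/% depth)
  rows <- ((seq_along(code) - 1L) %% depth) + 1L
  X[cbind(rows, cols0 * length(states) + code)] <- 1
  idfrac <- tcrossprod(X) / L
  1 / rowSums(idfrac >= identity_threshold)
}

#' PSICOV-style coevolution contact scores from an MSA
#'
#' Pipeline: sequence weighting; weighted single/pair indicator
#' frequencies with a pseudocount (implemented as shrinkage of the
#' covariance toward the independence model); 20L x 20L indicator
#' covariance with the gap state as reference category; shrinkage toward
#' the diagonal; L1-penalized sparse precision estimation (graphical
#' lasso, coordinate descent); pair score = L1 norm of each 20 x 20
#' precision block; optional average product correction.
#'
#' @param msa an `msa_block` of width L.
#' @param config a [coevolution_config()].
#' @param record_id identifier for the returned map.
#' @param min_separation sequence-separation mask (default 5).
#' @return a [contact_map()]; `attr(,"converged")` reports the estimator's
#'   convergence flag.
#' @export
coevolution_scores <- function(msa, config = coevolution_config(),
                               record_id = "query", min_separation = 5L) {
  stopifnot(inherits(msa, "msa_block"))
  if (msa$depth < 2L)
    tk_stop("alignment depth must be at least 2",
            "tmhkit_insufficient_alignment_error")
  mat <- msa_matrix(msa)
  L <- ncol(mat)
  w <- sequence_weights(msa, config$seq_weight_identity)
  wn <- w / sum(w)
  neff <- sum(w)
  X <- msa_indicator(mat)
  mu <- colSums(wn * X)
  C <- crossprod(X * sqrt(wn)) - tcrossprod(mu)
  ## pseudocount as shrinkage toward independence (zero covariance)
  alpha <- config$pseudocount / (config$pseudocount + neff)
  C <- (1 - alpha) * C
  ## shrink toward the diagonal, then floor the diagonal
  lam <- config$shrinkage_lambda
  D <- diag(C)
  C <- (1 - lam) * C
  diag(C) <- D
  diag(C) <- pmax(diag(C), 1e-4)
  fit <- glasso_cd(C, config$sparsity_rho, config$max_iter, config$tol)
  if (!fit$converged)
    warning("sparse inverse covariance estimation did not fully converge; ",
            "returning best iterate")
  theta <- fit$theta
  sc <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ri <- ((i - 1L) * 20L + 1L):(i * 20L)
    for (j in (i + 1L):L) {
      rj <- ((j - 1L) * 20L + 1L):(j * 20L)
      sc[i, j] <- sc[j, i] <- sum(abs(theta[ri, rj]))
    }
  }
  sep <- abs(row(sc) - col(sc))
  mask <- sep >= min_separation
  if (config$apc) sc <- apc_correct(sc, mask)
  sc[!mask] <- NA_real_
  out <- contact_map(record_id, sc, min_separation = min_separation)
  attr(out, "converged") <- fit$converged
  out
}

#' Average product correction
#'
#' Subtracts `rowmean_i * colmean_j / grandmean` from each score, removing
#' multiplicative row/column background. Means are taken over unmasked
#' entries only; with no mask the correction exactly annihilates
#' rank-one (product-structured) score matrices.
#'
#' @param scores symmetric numeric matrix.
#' @param mask optional logical matrix of entries to use (default: all
#'   off-diagonal entries).
#' @return corrected matrix; masked entries are left as-is.
#' @export
apc_correct <- function(scores, mask = NULL) {
  L <- nrow(scores)
  if (is.null(mask)) mask <- !diag(TRUE, L)
  s <- scores
  s[!mask] <- NA_real_
  rmean <- rowMeans(s, na.rm = TRUE)
  gmean <- mean(s[mask])
  if (!is.finite(gmean) || gmean == 0) return(scores)
  corr <- outer(rmean, rmean) / gmean
  out <- scores
  out[mask] <- scores[mask] - corr[mask]
  out
}

#' Column-frequency profile of an MSA query
#'
#' Builds a profile for the alignment's query sequence (first row) from
#' the weighted per-column residue frequencies: `scaled` holds the
#' frequencies, `raw` their log-odds against the uniform background.
#' Gap/unknown columns of the query are labeled `X`.
#'
#' @param msa an `msa_block`.
#' @param pseudocount frequency pseudocount (default 1).
#' @return a profile object with `source = "msa"`.
#' @export
msa_profile <- function(msa, pseudocount = 1) {
  mat <- msa_matrix(msa)
  L <- ncol(mat)
  counts <- vapply(seq_len(L), function(j)
    tabulate(match(mat[, j], AA20), 20L), integer(20L))
  freq <- t(counts + pseudocount / 20)
  freq <- freq / rowSums(freq)
  raw <- log(freq / (1 / 20))
  query <- mat[1, ]
  query[!query %in% AA20] <- "X"
  new_profile("query", paste(query, collapse = ""), raw, freq, "msa")
}

## ---- supervised pair engine ---------------------------------------------

#' Pair feature vector for two residues in different helices
#'
#' Concatenates the two W=7 scaled-profile windows, the sequence
#' separation |i-j| (normalized by L so it shares the \[0,1\] scale of the
#' profile features, as Euclidean-distance learners require) and the two
#' within-helix relative positions in \[0,1\]. Pairs are canonically
#' ordered (i < j), so (i,j) and (j,i) produce identical vectors.
#'
#' @param profile a profile object.
#' @param topo a [topology()] over the same sequence.
#' @param i,j residue positions lying in two different helices.
#' @param W window width for the profile blocks (default 7).
#' @return numeric feature vector of length `2*W*20 + 3`.
#' @export
pair_features <- function(profile, topo, i, j, W = 7L) {
  if (i == j) tk_stop("i and j must differ", "tmhkit_masked_pair_error")
  lo <- min(i, j); hi <- max(i, j)
  L <- profile_length(profile)
  hidx <- helix_index(topo, L)
  if (is.na(hidx[lo]) || is.na(hidx[hi]) || hidx[lo] == hidx[hi])
    tk_stop("pair must lie in two different TMHs", "tmhkit_masked_pair_error")
  fm <- window_feature_matrix(profile, W)
  seg <- topo$segments
  relpos <- function(p) {
    s <- seg$start[hidx[p]]; e <- seg$end[hidx[p]]
    if (e == s) 0.5 else (p - s) / (e - s)
  }
  c(fm[lo, ], fm[hi, ], (hi - lo) / L, relpos(lo), relpos(hi))
}

#' Enumerate all scorable inter-helix pairs with their features
#'
#' @param profile a profile object.
#' @param topo a [topology()].
#' @param W window width (default 7).
#' @param min_separation minimum |i-j| (default 5).
#' @return list with `pairs` (data.frame `i`,`j`) and `features` (matrix,
#'   one row per pair).
#' @export
contact_pair_table <- function(profile, topo, W = 7L, min_separation = 5L) {
  L <- profile_length(profile)
  hidx <- helix_index(topo, L)
  fm <- window_feature_matrix(profile, W)
  seg <- topo$segments
  idx <- which(!is.na(hidx))
  cand <- expand.grid(i = idx, j = idx)
  cand <- cand[cand$j - cand$i >= min_separation, ]
  cand <- cand[hidx[cand$i] != hidx[cand$j], ]
  if (!nrow(cand))
    return(list(pairs = data.frame(i = integer(), j = integer()),
                features = matrix(0, 0, 2L * W * 20L + 3L)))
  rel <- (idx - seg$start[hidx[idx]]) /
    pmax(1L, seg$end[hidx[idx]] - seg$start[hidx[idx]])
  rel[seg$end[hidx[idx]] == seg$start[hidx[idx]]] <- 0.5
  relmap <- rep(NA_real_, L); relmap[idx] <- rel
  feats <- cbind(fm[cand$i, , drop = FALSE], fm[cand$j, , drop = FALSE],
                 (cand$j - cand$i) / L, relmap[cand$i], relmap[cand$j])
  list(pairs = data.frame(i = cand$i, j = cand$j), features = unname(feats))
}

#' Train a random-under-sampling contact classifier ensemble
#'
#' Each member is an OET-KNN model trained on all positive pairs plus an
#' independent seeded draw of negatives at `undersample_ratio` negatives
#' per positive; repeated draws create the ensemble's diversity. The
#' ensemble score is the mean member propensity. Before training, each of
#' the four semantic feature blocks (window i, window j, separation,
#' helix positions) is rescaled to unit total variance on the training
#' pool, so no single block dominates the base learners' Euclidean
#' metric; the scaler is stored with the ensemble.
#'
#' @param features matrix of pair feature vectors.
#' @param labels binary contact labels (1 = contact).
#' @param n_models ensemble size (default 10).
#' @param undersample_ratio negatives per positive (default 1).
#' @param k,alpha0 base-learner parameters (`k` is reduced if a member's
#'   reference set is too small).
#' @param seed integer seed.
#' @return a `contact_ensemble`.
#' @export
train_contact_ensemble <- function(features, labels, n_models = 10L,
                                   undersample_ratio = 1, k = 11L,
                                   alpha0 = 0.95, seed = 1L) {
  features <- as.matrix(features); labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos))
    tk_stop("no positive pairs in the training set", "tmhkit_training_error")
  if (!length(neg))
    tk_stop("no negative pairs in the training set", "tmhkit_training_error")
  n_neg <- min(length(neg), max(1L, round(undersample_ratio * length(pos))))
  fscale <- pair_block_scale(features)
  features <- sweep(features, 2, fscale, "*")
  members <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_models), function(m) {
      take <- sample(neg, n_neg)
      idx <- c(pos, take)
      k_eff <- max(1L, min(k, min(length(pos), n_neg)))
      mod <- train_oetknn(features[idx, , drop = FALSE], labels[idx],
                          k = k_eff, alpha0 = alpha0, refine = TRUE)
      mod$negatives <- take
      mod
    })
  })
  structure(list(members = members, n_models = n_models,
                 feature_length = ncol(features), feature_scale = fscale),
            class = "contact_ensemble")
}

## Per-column multiplicative weights giving each semantic block of the
## pair feature layout (window i | window j | separation | positions)
## unit total variance on the training pool.
pair_block_scale <- function(features) {
  p <- ncol(features)
  nw <- (p - 3L) %/% 2L
  blocks <- list(seq_len(nw), nw + seq_len(nw), p - 2L, c(p - 1L, p))
  v <- apply(features, 2, stats::var)
  w <- rep(1, p)
  for (bl in blocks) {
    s <- sqrt(sum(v[bl]))
    if (s > 1e-8) w[bl] <- 1 / s
  }
  w
}

#' Score pairs with a contact ensemble
#'
#' @param ensemble a `contact_ensemble`.
#' @param features matrix of pair feature vectors.
#' @return numeric vector: mean member propensity per pair.
#' @export
predict_contact_ensemble <- function(ensemble, features) {
  features <- as.matrix(features)
  if (!is.null(ensemble$feature_scale))
    features <- sweep(features, 2, ensemble$feature_scale, "*")
  preds <- vapply(ensemble$members, classify_oetknn, numeric(nrow(features)),
                  x = features)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Build a contact map from per-pair ensemble scores
#'
#' @param record_id identifier.
#' @param L sequence length.
#' @param pairs data.frame with columns `i`, `j`.
#' @param scores numeric vector aligned with `pairs`.
#' @param min_separation mask threshold (default 5).
#' @return a [contact_map()]; pairs not listed stay masked (NA).
#' @export
pairs_to_map <- function(record_id, L, pairs, scores, min_separation = 5L) {
  sc <- matrix(NA_real_, L, L)
  sc[cbind(pairs$i, pairs$j)] <- scores
  sc[cbind(pairs$j, pairs$i)] <- scores
  contact_map(record_id, sc, min_separation = min_separation)
}

#' Write a contact ensemble as a flat TSV archive
#'
#' @param ensemble a `contact_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "contact_ensemble"))
  meta <- list(
    scaler = list(feature_scale = ensemble$feature_scale),
    members = lapply(ensemble$members, function(m)
      list(k = m$k, alpha0 = m$alpha0, gamma_pos = m$gamma_pos,
           gamma_neg = m$gamma_neg, feature_length = m$feature_length)))
  rows <- lapply(seq_along(ensemble$members), function(i) {
    m <- ensemble$members[[i]]
    data.table::data.table(member = i, label = m$y,
                           matrix(sprintf("%.17g", m$x), nrow = nrow(m$x)))
  })
  con <- file(path, "w")
  writeLines(paste0("#meta\t", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                digits = NA)), con)
  close(con)
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a contact ensemble archive
#'
#' @param path archive written by [write_contact_ensemble()].
#' @return a `contact_ensemble`.
#' @export
read_contact_ensemble <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#meta\t"))
    tk_stop("malformed ensemble archive", "tmhkit_parse_error")
  all_meta <- jsonlite::fromJSON(sub("^#meta\t", "", hdr),
                                 simplifyDataFrame = FALSE)
  meta <- all_meta$members
  dt <- data.table::fread(path, sep = "\t", skip = 1L)
  members <- lapply(seq_along(meta), function(i) {
    m <- meta[[i]]
    sub <- dt[dt$member == i, ]
    feat <- as.matrix(sub[, -(1:2)])
    dimnames(feat) <- NULL
    structure(list(x = feat, y = as.integer(sub$label), k = as.integer(m$k),
                   alpha0 = m$alpha0, gamma_pos = m$gamma_pos,
                   gamma_neg = m$gamma_neg, window_size = NA_integer_,
                   feature_length = as.integer(m$feature_length)),
              class = "oetknn_model")
  })
  structure(list(members = members, n_models = length(members),
                 feature_length = meta[[1]]$feature_length,
                 feature_scale = unlist(all_meta$scaler$feature_scale)),
            class = "contact_ensemble")
}

## ---- fusion and evaluation ----------------------------------------------

rank_normalize <- function(v) {
  r <- rank(v, ties.method = "average")
  if (length(v) <= 1L) return(rep(0.5, length(v)))
  (r - 1) / (length(v) - 1)
}

#' Fuse two contact maps by weighted rank averaging
#'
#' Each map's unmasked scores are rank-normalized to \[0,1\] (average rank
#' on ties); the fused score is `w * coevolution + (1-w) * ml`.
#'
#' @param coevo,ml [contact_map()]s over the same record with identical
#'   masks of scorable pairs.
#' @param w weight on the coevolution map, in \[0,1\] (default 0.5).
#' @return a fused [contact_map()].
#' @export
fuse_contact_maps <- function(coevo, ml, w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  a <- coevo$scores; b <- ml$scores
  if (!all(dim(a) == dim(b)) || !identical(which(is.na(a)), which(is.na(b))))
    tk_stop("contact maps have mismatched masks", "tmhkit_input_error")
  idx <- which(upper.tri(a) & !is.na(a))
  fused <- matrix(NA_real_, nrow(a), ncol(a))
  fv <- w * rank_normalize(a[idx]) + (1 - w) * rank_normalize(b[idx])
  fused[idx] <- fv
  fused[lower.tri(fused)] <- t(fused)[lower.tri(fused)]
  out <- contact_map(coevo$record_id, fused,
                     min_separation = coevo$min_separation)
  out$truth <- coevo$truth
  out$tmh_mask <- coevo$tmh_mask
  out
}

#' Attach a binary truth layer to a contact map
#'
#' @param map a [contact_map()].
#' @param pairs data.frame of true contact pairs (`i`, `j`).
#' @return the map with a symmetric 0/1 `truth` matrix.
#' @export
set_contact_truth <- function(map, pairs) {
  L <- nrow(map$scores)
  tr <- matrix(0, L, L)
  if (nrow(pairs)) {
    tr[cbind(pairs$i, pairs$j)] <- 1
    tr[cbind(pairs$j, pairs$i)] <- 1
  }
  map$truth <- tr
  map
}

#' Precision of the top-k contact predictions
#'
#' Fraction of the k highest-scoring unmasked pairs whose truth layer is
#' contact; ties are broken deterministically by (i, j) lexicographic
#' order.
#'
#' @param map a [contact_map()] with a truth layer.
#' @param k number of top pairs (e.g. `L/5` rounded).
#' @return fraction in \[0,1\].
#' @export
top_k_accuracy <- function(map, k) {
  if (is.null(map$truth))
    tk_stop("contact map has no truth layer", "tmhkit_input_error")
  stopifnot(k >= 1L)
  sc <- map$scores
  idx <- which(upper.tri(sc) & !is.na(sc), arr.ind = TRUE)
  vals <- sc[which(upper.tri(sc) & !is.na(sc))]
  ord <- order(-vals, idx[, 1], idx[, 2])
  top <- head(ord, k)
  mean(map$truth[idx[top, , drop = FALSE]] == 1)
}
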