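## propensity: multi-scale sliding-window features over an evolutionary
## profile, classified per residue by an optimized evidence-theoretic
## K-nearest-neighbor (OET-KNN) model.
##
## Each of the k nearest reference vectors contributes a basic belief
## assignment with mass alpha0 * exp(-gamma_q * d^2) on its own class and
## the remainder on the full frame; the k assignments are combined by
## Dempster's rule (conflict-normalized) and reported as the pignistic
## probability of the TMH class. The "optimized" step is a leave-one-out
## coordinate search over the two per-class gamma scale parameters.

#' Multi-scale window configuration
#'
#' Two window widths (13 and 15 by default) are fused by averaging their
#' propensities, which limits the bias a single width induces on short
#' (half) and long helices.
#'
#' @param sizes odd window widths, all >= 3.
#' @return a `window_config` list.
#' @export
window_config <- function(sizes = c(13L, 15L)) {
  sizes <- as.integer(sizes)
  if (any(sizes %% 2L == 0L) || any(sizes < 3L))
    tk_stop("window sizes must be odd and >= 3", "tmhkit_config_error")
  structure(list(sizes = sizes), class = "window_config")
}

#' Sliding-window feature matrix over a profile
#'
#' Row `i` is the concatenation of the scaled profile rows
#' `i-(W-1)/2 ... i+(W-1)/2`; positions outside the sequence contribute a
#' neutral constant row, keeping the feature length fixed (required by
#' instance-based distances). The neutral value matches the profile's
#' value scale: 0.5 (the logistic image of log-odds 0) for PSSM-derived
#' profiles, the uniform frequency 1/20 for probability-valued
#' (pseudo/MSA) profiles.
#'
#' @param profile a profile object.
#' @param W odd window width.
#' @return numeric matrix of dimension L x (W*20).
#' @export
window_feature_matrix <- function(profile, W) {
  W <- as.integer(W)
  if (W %% 2L == 0L || W < 3L)
    tk_stop("window width must be odd and >= 3", "tmhkit_config_error")
  S <- profile$scaled
  L <- nrow(S)
  h <- (W - 1L) %/% 2L
  neutral <- if (profile$source == "pssm_file") 0.5 else 1 / 20
  pad <- matrix(neutral, nrow = h, ncol = 20L)
  P <- rbind(pad, S, pad)
  out <- matrix(0, nrow = L, ncol = W * 20L)
  for (o in seq_len(W))
    out[, ((o - 1L) * 20L + 1L):(o * 20L)] <- P[o:(o + L - 1L), , drop = FALSE]
  out
}

#' Window feature vector at one position
#'
#' @param profile a profile object.
#' @param i 1-based residue position.
#' @param W odd window width.
#' @return numeric vector of length `W*20`.
#' @export
window_features <- function(profile, i, W) {
  L <- profile_length(profile)
  if (i < 1L || i > L)
    tk_stop("position outside sequence", "tmhkit_input_error")
  window_feature_matrix(profile, W)[i, ]
}

## ---- Dempster-Shafer machinery ------------------------------------------

## Combine k simple mass assignments given as a k x 3 matrix with columns
## (m({TMH}), m({non}), m(Theta)); returns the combined triple. Sequential
## pairwise combination with per-step conflict normalization (equivalent to
## normalizing once at the end).
dempster_combine <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 3L)
  cur <- c(0, 0, 1)
  for (r in seq_len(nrow(m))) {
    a1 <- cur[1]; b1 <- cur[2]; c1 <- cur[3]
    a2 <- m[r, 1]; b2 <- m[r, 2]; c2 <- m[r, 3]
    conflict <- a1 * b2 + b1 * a2
    z <- 1 - conflict
    if (z <= .Machine$double.eps)
      tk_stop("total conflict in Dempster combination", "tmhkit_numeric_error")
    cur <- c(a1 * a2 + a1 * c2 + c1 * a2,
             b1 * b2 + b1 * c2 + c1 * b2,
             c1 * c2) / z
  }
  cur
}

## Pignistic probability of the TMH class from a combined mass triple.
pignistic_tmh <- function(m) m[1] + m[3] / 2

neighbor_mass <- function(d2, label, alpha0, gamma_pos, gamma_neg) {
  g <- ifelse(label == 1L, gamma_pos, gamma_neg)
  own <- alpha0 * exp(-g * d2)
  cbind(ifelse(label == 1L, own, 0),
        ifelse(label == 1L, 0, own),
        1 - own)
}

## ---- model ---------------------------------------------------------------

#' Train an evidence-theoretic K-nearest-neighbor model
#'
#' Stores the reference vectors; initializes each per-class scale gamma_q
#' to 1 / (mean squared Euclidean distance among class-q references); then
#' refines both gammas by a multiplicative coordinate search that accepts
#' only strict improvements of leave-one-out misclassification.
#'
#' @param x numeric matrix of reference feature vectors (rows).
#' @param y binary labels (1 = TMH / positive class).
#' @param k neighbor count (default 11); each class must supply at least
#'   `k` examples.
#' @param alpha0 mass ceiling in (0,1), default 0.95.
#' @param refine run the leave-one-out gamma search (default TRUE).
#' @param window_size optional width tag for multi-scale bookkeeping.
#' @return an `oetknn_model`.
#' @export
train_oetknn <- function(x, y, k = 11L, alpha0 = 0.95, refine = TRUE,
                         window_size = NA_integer_) {
  x <- as.matrix(x); y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)),
            alpha0 > 0, alpha0 < 1)
  k <- as.integer(k)
  if (length(unique(y)) < 2L)
    tk_stop("training corpus must contain both classes",
            "tmhkit_training_error")
  if (min(table(y)) < k)
    tk_stop(sprintf("need at least k=%d examples of each class", k),
            "tmhkit_training_error")
  gamma0 <- vapply(c(1L, 0L), function(q) {
    xi <- x[y == q, , drop = FALSE]
    n <- nrow(xi)
    ctr <- colMeans(xi)
    S <- sum(sweep(xi, 2, ctr)^2)
    msd <- 2 * S / (n - 1)
    if (msd <= 0) 1 else 1 / msd
  }, numeric(1))
  model <- structure(list(x = x, y = y, k = k, alpha0 = alpha0,
                          gamma_pos = gamma0[1], gamma_neg = gamma0[2],
                          window_size = as.integer(window_size),
                          feature_length = ncol(x)),
                     class = "oetknn_model")
  if (refine) model <- refine_gammas(model)
  model
}

#' @export
print.oetknn_model <- function(x, ...) {
  cat(sprintf(
    "<oetknn_model> %d refs, p=%d, k=%d, alpha0=%.2f, gammas=(%.3g, %.3g)\n",
    nrow(x$x), x$feature_length, x$k, x$alpha0, x$gamma_pos, x$gamma_neg))
  invisible(x)
}

## Leave-one-out neighbor lists (k nearest among the other references).
## Returns list(d2 = n x k matrix, lab = n x k matrix).
loo_neighbors <- function(x, y, k, chunk = 1024L) {
  n <- nrow(x)
  rs <- rowSums(x^2)
  d2m <- matrix(0, n, k); labm <- matrix(0L, n, k)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    D2 <- outer(rs[lo:hi], rs, "+") - 2 * tcrossprod(x[lo:hi, , drop = FALSE], x)
    D2[D2 < 0] <- 0
    for (r in seq_len(hi - lo + 1L)) {
      i <- lo + r - 1L
      d <- D2[r, ]; d[i] <- Inf
      ord <- order(d)[seq_len(k)]
      d2m[i, ] <- d[ord]; labm[i, ] <- y[ord]
    }
  }
  list(d2 = d2m, lab = labm)
}

## Vectorized LOO misclassification for given gammas using precomputed
## neighbor lists.
loo_error <- function(nb, y, alpha0, gamma_pos, gamma_neg) {
  n <- nrow(nb$d2); k <- ncol(nb$d2)
  mT <- rep(0, n); mN <- rep(0, n); mTh <- rep(1, n)
  for (c in seq_len(k)) {
    lab <- nb$lab[, c]; d2 <- nb$d2[, c]
    own <- alpha0 * exp(-ifelse(lab == 1L, gamma_pos, gamma_neg) * d2)
    a2 <- ifelse(lab == 1L, own, 0)
    b2 <- ifelse(lab == 1L, 0, own)
    c2 <- 1 - own
    z <- 1 - (mT * b2 + mN * a2)
    z[z < .Machine$double.eps] <- .Machine$double.eps
    newT <- (mT * a2 + mT * c2 + mTh * a2) / z
    newN <- (mN * b2 + mN * c2 + mTh * b2) / z
    mTh <- (mTh * c2) / z
    mT <- newT; mN <- newN
  }
  prop <- mT + mTh / 2
  mean((prop >= 0.5) != (y == 1L))
}

## Coordinate search over (gamma_pos, gamma_neg) on a multiplicative grid;
## accepts strict improvements only, so the refined LOO error never exceeds
## the initialization's.
refine_gammas <- function(model, factors = c(0.25, 0.5, 2, 4), rounds = 3L) {
  nb <- loo_neighbors(model$x, model$y, model$k)
  best <- c(model$gamma_pos, model$gamma_neg)
  best_err <- loo_error(nb, model$y, model$alpha0, best[1], best[2])
  for (r in seq_len(rounds)) {
    improved <- FALSE
    for (which_g in 1:2) {
      for (f in factors) {
        cand <- best
        cand[which_g] <- cand[which_g] * f
        err <- loo_error(nb, model$y, model$alpha0, cand[1], cand[2])
        if (err < best_err) {
          best <- cand; best_err <- err; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  model$gamma_pos <- best[1]
  model$gamma_neg <- best[2]
  model$loo_error <- best_err
  model
}

#' Classify feature vectors with an OET-KNN model
#'
#' For each query, the k nearest reference vectors (with all references
#' tied at the k-th distance included, which makes the output independent
#' of reference ordering) each contribute a mass assignment; the masses are
#' combined by Dempster's rule and the pignistic TMH probability is
#' returned.
#'
#' @param model an `oetknn_model`.
#' @param x a feature vector or a matrix of row vectors.
#' @param chunk internal query chunk size for the distance computation.
#' @return numeric vector of propensities in \[0,1\].
#' @export
classify_oetknn <- function(model, x, chunk = 512L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$feature_length)
    tk_stop(sprintf("feature length %d does not match model (%d)",
                    ncol(x), model$feature_length), "tmhkit_input_error")
  ref <- model$x
  rs_ref <- rowSums(ref^2)
  out <- numeric(nrow(x))
  k <- model$k
  for (lo in seq(1L, nrow(x), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(x))
    Q <- x[lo:hi, , drop = FALSE]
    D2 <- outer(rowSums(Q^2), rs_ref, "+") - 2 * tcrossprod(Q, ref)
    D2[D2 < 0] <- 0
    for (r in seq_len(hi - lo + 1L)) {
      d2 <- D2[r, ]
      kth <- sort(d2, partial = k)[k]
      idx <- which(d2 <= kth)
      m <- neighbor_mass(d2[idx], model$y[idx], model$alpha0,
                         model$gamma_pos, model$gamma_neg)
      out[lo + r - 1L] <- pignistic_tmh(dempster_combine(m))
    }
  }
  out
}

## ---- multi-scale training and prediction --------------------------------

#' Train the multi-scale TMH propensity model on a labeled corpus
#'
#' Builds window features for every residue of every protein at each
#' configured width, optionally down-samples to at most `max_ref`
#' reference vectors (stratified by class, seeded) to keep KNN queries
#' desk-scale, and trains one OET-KNN model per width.
#'
#' @param corpus list of `list(record, topology)` (profiles are built with
#'   [pseudo_profile()] unless `profiles` is supplied).
#' @param windows a [window_config()] or integer vector of odd widths.
#' @param k,alpha0 OET-KNN parameters.
#' @param max_ref reference-set cap per window model (default 20000).
#' @param seed seed for the stratified down-sampling.
#' @param profiles optional list of profile objects matching `corpus`.
#' @param refine run the gamma leave-one-out search (default TRUE).
#' @return a `tmh_model`: list of `oetknn_model`s keyed by window size.
#' @export
train_tmh_model <- function(corpus, windows = window_config(), k = 11L,
                            alpha0 = 0.95, max_ref = 20000L, seed = 1L,
                            profiles = NULL, refine = TRUE) {
  if (!inherits(windows, "window_config")) windows <- window_config(windows)
  if (is.null(profiles))
    profiles <- lapply(corpus, function(e) pseudo_profile(e$record))
  labels <- unlist(lapply(corpus, function(e)
    topology_mask(e$topology, e$record$length)))
  models <- lapply(windows$sizes, function(W) {
    feats <- do.call(rbind, lapply(profiles, window_feature_matrix, W = W))
    keep <- stratified_subsample(labels, max_ref, seed + W)
    train_oetknn(feats[keep, , drop = FALSE], labels[keep], k = k,
                 alpha0 = alpha0, refine = refine, window_size = W)
  })
  names(models) <- as.character(windows$sizes)
  structure(list(models = models, windows = windows$sizes),
            class = "tmh_model")
}

## Stratified, seeded subsample of indices preserving class proportions.
stratified_subsample <- function(y, max_n, seed) {
  n <- length(y)
  if (n <= max_n) return(seq_len(n))
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    idx <- unlist(lapply(unique(y), function(q) {
      iq <- which(y == q)
      take <- max(1L, round(max_n * length(iq) / n))
      sample(iq, min(take, length(iq)))
    }))
    sort(idx)
  })
}

#' Predict a per-residue TMH propensity track
#'
#' Classifies every residue at each configured window width and averages
#' the per-width propensities.
#'
#' @param profile a profile object.
#' @param model a `tmh_model` from [train_tmh_model()].
#' @return a [propensity_track()].
#' @export
predict_propensity <- function(profile, model) {
  stopifnot(inherits(model, "tmh_model"))
  per_w <- lapply(model$models, function(m) {
    feats <- window_feature_matrix(profile, m$window_size)
    classify_oetknn(m, feats)
  })
  propensity_track(profile$record_id, Reduce(`+`, per_w) / length(per_w))
}

## ---- model persistence (flat TSV archive) -------------------------------

#' Write a multi-scale TMH model as a flat TSV archive
#'
#' One table holds every reference vector of every window model, preceded
#' by `#`-prefixed scalar header lines. Feature columns are NA-padded to
#' the widest window.
#'
#' @param model a `tmh_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tmh_model <- function(model, path) {
  stopifnot(inherits(model, "tmh_model"))
  meta <- lapply(model$models, function(m)
    list(window = m$window_size, k = m$k, alpha0 = m$alpha0,
         gamma_pos = m$gamma_pos, gamma_neg = m$gamma_neg,
         feature_length = m$feature_length))
  pmax_len <- max(vapply(model$models, `[[`, 0L, "feature_length"))
  rows <- lapply(model$models, function(m) {
    feat <- m$x
    if (ncol(feat) < pmax_len)
      feat <- cbind(feat, matrix(NA_real_, nrow(feat), pmax_len - ncol(feat)))
    ## %.17g so the archive round-trips bit-exactly
    feat <- matrix(sprintf("%.17g", feat), nrow = nrow(feat))
    feat[feat == "NA"] <- NA_character_
    data.table::data.table(window = m$window_size, label = m$y, feat)
  })
  dt <- data.table::rbindlist(rows)
  con <- file(path, "w")
  writeLines(paste0("#meta\t", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                digits = NA)), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a multi-scale TMH model archive
#'
#' @param path archive written by [write_tmh_model()].
#' @return a `tmh_model`.
#' @export
read_tmh_model <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#meta\t"))
    tk_stop("malformed model archive", "tmhkit_parse_error")
  meta <- jsonlite::fromJSON(sub("^#meta\t", "", hdr),
                             simplifyDataFrame = FALSE)
  dt <- data.table::fread(path, sep = "\t", skip = 1L)
  models <- lapply(meta, function(m) {
    sub <- dt[dt$window == m$window, ]
    feat <- as.matrix(sub[, -(1:2)])[, seq_len(m$feature_length),
                                     drop = FALSE]
    dimnames(feat) <- NULL
    structure(list(x = feat, y = as.integer(sub$label), k = as.integer(m$k),
                   alpha0 = m$alpha0, gamma_pos = m$gamma_pos,
                   gamma_neg = m$gamma_neg,
                   window_size = as.integer(m$window),
                   feature_length = as.integer(m$feature_length)),
              class = "oetknn_model")
  })
  names(models) <- vapply(meta, function(m) as.character(m$window), "")
  structure(list(models = models,
                 windows = unname(vapply(meta, function(m)
                   as.integer(m$window), 0L))),
            class = "tmh_model")
}
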