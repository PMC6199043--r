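## rasa: per-residue relative accessible surface area (percent).
##
## Two engines: (1) a segment-template engine that looks up the most
## similar profile windows in a pool built from solved (here: synthetic)
## structures and averages their central-residue RASA; (2) a kernel
## regression engine over six sequence-feature blocks. A knowledge rule
## fuses them: where a confident template exists (similarity >= tau) the
## template wins, elsewhere the regression engine is used.

#' RASA fusion configuration
#'
#' @param similarity_threshold tau in (0,1\]: minimum mapped template
#'   similarity for the template engine to override the regression engine
#'   under the `hard_switch` rule (default 0.9).
#' @param top_t number of templates averaged per position (default 3).
#' @param blend `"hard_switch"` (default) or `"similarity_blend"`.
#' @return a `rasa_fusion_config` list.
#' @export
rasa_fusion_config <- function(similarity_threshold = 0.9, top_t = 3L,
                               blend = c("hard_switch", "similarity_blend")) {
  blend <- match.arg(blend)
  if (similarity_threshold <= 0 || similarity_threshold > 1 || top_t < 1L)
    tk_stop("invalid rasa fusion configuration", "tmhkit_config_error")
  structure(list(similarity_threshold = similarity_threshold,
                 top_t = as.integer(top_t), blend = blend),
            class = "rasa_fusion_config")
}

#' Build a segment-template pool
#'
#' One entry per residue position with a full `segment_length` window:
#' the unit-normalized flattened scaled-profile window and the central
#' residue's RASA. Truncated terminal windows are skipped.
#'
#' @param profiles list of profile objects.
#' @param tracks list of [rasa_track()]s aligned with `profiles`.
#' @param segment_length odd window length (default 15).
#' @return a `template_pool` with `features` (matrix), `rasa`, `source`.
#' @export
build_template_pool <- function(profiles, tracks, segment_length = 15L) {
  segment_length <- as.integer(segment_length)
  stopifnot(segment_length %% 2L == 1L, length(profiles) == length(tracks))
  if (!length(profiles))
    tk_stop("empty template corpus", "tmhkit_build_error")
  h <- (segment_length - 1L) %/% 2L
  feats <- list(); rasa <- list(); src <- list()
  for (e in seq_along(profiles)) {
    pr <- profiles[[e]]; tr <- tracks[[e]]
    L <- profile_length(pr)
    stopifnot(length(tr$values) == L)
    if (L < segment_length) next
    pos <- (h + 1L):(L - h)
    fm <- window_feature_matrix(pr, segment_length)[pos, , drop = FALSE]
    nrm <- sqrt(rowSums(fm^2))
    nrm[nrm == 0] <- 1
    feats[[length(feats) + 1L]] <- fm / nrm
    rasa[[length(rasa) + 1L]] <- tr$values[pos]
    src[[length(src) + 1L]] <- rep(pr$record_id, length(pos))
  }
  if (!length(feats))
    tk_stop("no protein long enough for the segment length",
            "tmhkit_build_error")
  structure(list(features = do.call(rbind, feats),
                 rasa = unlist(rasa), source = unlist(src),
                 segment_length = segment_length),
            class = "template_pool")
}

#' @export
print.template_pool <- function(x, ...) {
  cat(sprintf("<template_pool> %d segments of length %d\n",
              nrow(x$features), x$segment_length))
  invisible(x)
}

#' Segment-template RASA prediction
#'
#' Per position with a full window, the query window is unit-normalized
#' and compared with every pool entry by cosine similarity, mapped from
#' \[-1,1\] to \[0,1\] via `(s+1)/2`; the prediction is the mean central
#' RASA of the `top_t` most similar entries. Positions without a full
#' window get similarity 0 and the pool-mean RASA.
#'
#' @param profile a profile object.
#' @param pool a `template_pool`.
#' @param config a [rasa_fusion_config()].
#' @param exclude_source optional record id(s) excluded from the pool
#'   (for leave-one-protein-out evaluation).
#' @return list with `track` (a [rasa_track()]) and `similarity`
#'   (numeric vector of mapped best similarities).
#' @export
template_predict <- function(profile, pool, config = rasa_fusion_config(),
                             exclude_source = NULL) {
  stopifnot(inherits(pool, "template_pool"))
  keep <- if (is.null(exclude_source)) seq_along(pool$rasa)
          else which(!pool$source %in% exclude_source)
  if (!length(keep))
    tk_stop("template pool is empty after exclusion", "tmhkit_build_error")
  feats <- pool$features[keep, , drop = FALSE]
  rasa <- pool$rasa[keep]
  L <- profile_length(profile)
  sl <- pool$segment_length
  h <- (sl - 1L) %/% 2L
  pred <- rep(mean(rasa), L)
  sim <- rep(0, L)
  if (L >= sl) {
    pos <- (h + 1L):(L - h)
    qm <- window_feature_matrix(profile, sl)[pos, , drop = FALSE]
    nrm <- sqrt(rowSums(qm^2)); nrm[nrm == 0] <- 1
    qm <- qm / nrm
    S <- tcrossprod(qm, feats)  # cosine similarities
    tt <- min(config$top_t, ncol(S))
    for (r in seq_len(nrow(S))) {
      s <- S[r, ]
      ord <- order(s, decreasing = TRUE)[seq_len(tt)]
      pred[pos[r]] <- mean(rasa[ord])
      sim[pos[r]] <- (max(s) + 1) / 2
    }
  }
  list(track = rasa_track(profile$record_id, pmin(100, pmax(0, pred))),
       similarity = sim)
}

## ---- six-block regression features --------------------------------------

#' Six-block RASA feature matrix
#'
#' One row per residue, six concatenated blocks: (1) scaled-profile window
#' (width `W`); (2) hydropathy window (Kyte-Doolittle, `X` = 0); (3)
#' one-hot residue identity; (4) TMH propensity window (from a supplied
#' track, from the 0/1 topology membership, or zeros); (5) relative
#' position within the containing helix (0 outside); (6) normalized
#' distance to the nearer terminus.
#'
#' @param profile a profile object.
#' @param topo optional [topology()].
#' @param propensity optional [propensity_track()]; defaults to the 0/1
#'   topology membership when `topo` is given.
#' @param W odd window width for blocks 1, 2 and 4 (default 9).
#' @return numeric matrix, `L x (W*20 + W + 20 + W + 2)`.
#' @export
rasa_features <- function(profile, topo = NULL, propensity = NULL, W = 9L) {
  W <- as.integer(W)
  stopifnot(W %% 2L == 1L)
  L <- profile_length(profile)
  h <- (W - 1L) %/% 2L
  chars <- strsplit(profile$residues, "")[[1]]
  b1 <- window_feature_matrix(profile, W)
  kd <- ifelse(chars == "X", 0, KD_HYDROPATHY[match(chars, AA20)])
  padded <- c(rep(0, h), kd, rep(0, h))
  b2 <- t(vapply(seq_len(L), function(i) padded[i:(i + W - 1L)], numeric(W)))
  b3 <- matrix(0, L, 20L)
  known <- which(chars != "X")
  b3[cbind(known, match(chars[known], AA20))] <- 1
  ptrack <- if (!is.null(propensity)) propensity$values
            else if (!is.null(topo)) as.numeric(topology_mask(topo, L))
            else rep(0, L)
  padp <- c(rep(0, h), ptrack, rep(0, h))
  b4 <- t(vapply(seq_len(L), function(i) padp[i:(i + W - 1L)], numeric(W)))
  b5 <- rep(0, L)
  if (!is.null(topo)) {
    hidx <- helix_index(topo, L)
    seg <- topo$segments
    inh <- which(!is.na(hidx))
    if (length(inh)) {
      len <- pmax(1L, seg$end[hidx[inh]] - seg$start[hidx[inh]])
      b5[inh] <- (inh - seg$start[hidx[inh]]) / len
    }
  }
  b6 <- pmin(seq_len(L), rev(seq_len(L))) / L
  cbind(b1, b2, b3, b4, b5, b6)
}

## ---- kernel regression engine -------------------------------------------

#' Train the RASA kernel regression engine
#'
#' Epsilon-free radial-basis kernel ridge regression: the closest
#' deterministic stand-in for support vector regression available without
#' external solvers. Targets are centered, so a constant-target corpus
#' yields an exactly constant predictor; predictions are clamped to
#' \[0,100\]. The basis is a seeded subsample of at most `max_basis`
#' training rows; the bandwidth defaults to the median pairwise distance
#' heuristic.
#'
#' @param x feature matrix (rows = residues).
#' @param y RASA targets in \[0,100\].
#' @param lambda ridge penalty (default 1e-3).
#' @param max_basis basis-size cap (default 2000).
#' @param bandwidth RBF bandwidth sigma; `NULL` = median heuristic.
#' @param seed seed for the basis subsample.
#' @return a `rasa_krr` model.
#' @export
train_rasa_regressor <- function(x, y, lambda = 1e-3, max_basis = 2000L,
                                 bandwidth = NULL, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), length(y) >= 1L)
  if (stats::var(y) == 0)
    warning("constant-target corpus: regressor degenerates to a constant")
  idx <- withr::with_seed(as.integer(seed), {
    if (nrow(x) > max_basis) sort(sample(nrow(x), max_basis)) else seq_len(nrow(x))
  })
  xb <- x[idx, , drop = FALSE]
  yb <- y[idx]
  if (is.null(bandwidth)) {
    sub <- withr::with_seed(as.integer(seed) + 1L, {
      xb[sample(nrow(xb), min(500L, nrow(xb))), , drop = FALSE]
    })
    d <- stats::dist(sub)
    bandwidth <- stats::median(d)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  K <- rbf_kernel(xb, xb, bandwidth)
  n <- nrow(xb)
  alpha <- solve(K + diag(lambda * n, n), yb - mean(yb))
  structure(list(basis = xb, alpha = as.numeric(alpha),
                 intercept = mean(yb), bandwidth = bandwidth,
                 lambda = lambda, feature_length = ncol(xb)),
            class = "rasa_krr")
}

rbf_kernel <- function(a, b, sigma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Predict RASA with the kernel regression engine
#'
#' @param object a `rasa_krr` model.
#' @param x feature matrix.
#' @param ... unused.
#' @return numeric vector of predictions clamped to \[0,100\].
#' @export
predict.rasa_krr <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$feature_length)
    tk_stop("feature length mismatch", "tmhkit_input_error")
  K <- rbf_kernel(x, object$basis, object$bandwidth)
  pmin(100, pmax(0, object$intercept + as.numeric(K %*% object$alpha)))
}

## ---- fusion and evaluation ----------------------------------------------

#' Fuse template and regression RASA predictions
#'
#' `hard_switch`: a position uses the template value iff its mapped best
#' similarity is at least `similarity_threshold`, else the regression
#' value. `similarity_blend`: `s * template + (1-s) * regression` with `s`
#' the mapped similarity.
#'
#' @param template_track [rasa_track()] from [template_predict()].
#' @param similarity numeric vector of mapped similarities.
#' @param regression_track [rasa_track()] from the regression engine.
#' @param config a [rasa_fusion_config()].
#' @return a fused [rasa_track()]; `attr(,"engine")` records the engine
#'   used per position, `attr(,"rule")` the fusion rule and threshold.
#' @export
fuse_rasa <- function(template_track, similarity, regression_track,
                      config = rasa_fusion_config()) {
  tv <- template_track$values; rv <- regression_track$values
  if (length(tv) != length(rv) || length(tv) != length(similarity))
    tk_stop("track lengths differ", "tmhkit_input_error")
  if (config$blend == "hard_switch") {
    use_template <- similarity >= config$similarity_threshold
    vals <- ifelse(use_template, tv, rv)
    engine <- ifelse(use_template, "template", "regression")
  } else {
    vals <- similarity * tv + (1 - similarity) * rv
    engine <- rep("blend", length(tv))
  }
  out <- rasa_track(template_track$record_id, pmin(100, pmax(0, vals)))
  attr(out, "engine") <- engine
  attr(out, "rule") <- list(blend = config$blend,
                            tau = config$similarity_threshold)
  out
}

#' Evaluate a RASA prediction
#'
#' @param predicted,observed [rasa_track()]s of equal length.
#' @return list with `pearson_r` (NA with a warning when the observed
#'   track is constant) and `mae` (mean absolute error, percent).
#' @export
evaluate_rasa <- function(predicted, observed) {
  p <- predicted$values; o <- observed$values
  if (length(p) != length(o) || length(o) < 2L)
    tk_stop("tracks must have equal length >= 2", "tmhkit_input_error")
  mae <- mean(abs(p - o))
  if (stats::var(o) == 0) {
    warning("observed track is constant: correlation undefined")
    return(list(pearson_r = NA_real_, mae = mae))
  }
  r <- if (stats::var(p) == 0) 0 else stats::cor(p, o)
  list(pearson_r = r, mae = mae)
}
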