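## synthetic: seeded generators that replace structure-database-derived
## training corpora. Every generated label is the generative truth, never
## re-derived from the emitted sequence.

#' Configuration for the synthetic membrane-protein generator
#'
#' Defaults encode the stated world the generators emulate: alternating
#' loop/helix architecture, loops down to 1-2 residues, core helices of
#' 17-28 residues, plus rare irregular helices -- "half" helices of 8-12
#' residues and long helices above 35 residues.
#'
#' @param n_proteins number of proteins to generate.
#' @param loop_length_range integer interval for loop lengths (default 1-30).
#' @param tmh_length_core integer interval for regular helix lengths
#'   (default 17-28).
#' @param p_half_tmh probability that a helix is a short half-helix of 8-12
#'   residues (default 0.1).
#' @param p_long_tmh probability that a helix is a long helix of 36-45
#'   residues (default 0.05).
#' @param n_tmh_range integer interval for helices per protein (default 1-7).
#' @param seed integer seed fixing the corpus bit-exactly.
#' @return a `topology_generator_config` list.
#' @export
topology_generator_config <- function(n_proteins = 100L,
                                      loop_length_range = c(1L, 30L),
                                      tmh_length_core = c(17L, 28L),
                                      p_half_tmh = 0.1,
                                      p_long_tmh = 0.05,
                                      n_tmh_range = c(1L, 7L),
                                      seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              loop_length_range = as.integer(loop_length_range),
              tmh_length_core = as.integer(tmh_length_core),
              p_half_tmh = p_half_tmh, p_long_tmh = p_long_tmh,
              n_tmh_range = as.integer(n_tmh_range),
              seed = as.integer(seed))
  with(cfg, {
    if (n_proteins < 1L ||
        diff(loop_length_range) < 0L || loop_length_range[1] < 1L ||
        diff(tmh_length_core) < 0L || tmh_length_core[1] < 1L ||
        diff(n_tmh_range) < 0L || n_tmh_range[1] < 1L ||
        p_half_tmh < 0 || p_half_tmh > 1 || p_long_tmh < 0 ||
        p_long_tmh > 1 || p_half_tmh + p_long_tmh > 1)
      tk_stop("infeasible generator configuration", "tmhkit_config_error")
  })
  structure(cfg, class = "topology_generator_config")
}

## Emission weights: helix residues favour hydrophobic residues
## (weights ~ exp(KD/2) over the Kyte-Doolittle scale), loop residues the
## complement (~ exp(-KD/2)).
tmh_emission_probs <- function() {
  w <- exp(KD_HYDROPATHY / 2)
  w / sum(w)
}
loop_emission_probs <- function() {
  w <- exp(-KD_HYDROPATHY / 2)
  w / sum(w)
}

#' Generate a labeled synthetic membrane-protein corpus
#'
#' Proteins alternate loop and helix stretches: loop, (TMH, loop) repeated.
#' Helix residues are drawn from a hydrophobicity-weighted composition,
#' loop residues from the complementary composition, making helices
#' recoverable from local composition -- the signal a profile-window
#' classifier exploits. The returned [topology()] is the generative truth.
#'
#' @param config a [topology_generator_config()].
#' @return list of `list(record, topology)` pairs, reproducible bit-exactly
#'   from `config$seed`.
#' @export
generate_membrane_protein_corpus <- function(config = topology_generator_config()) {
  stopifnot(inherits(config, "topology_generator_config"))
  p_tmh <- tmh_emission_probs()
  p_loop <- loop_emission_probs()
  withr::with_seed(config$seed, {
    lapply(seq_len(config$n_proteins), function(pi) {
      n_tmh <- sample(config$n_tmh_range[1]:config$n_tmh_range[2], 1L)
      parts <- character(0)
      starts <- integer(0); ends <- integer(0)
      pos <- 0L
      rloop <- function() {
        n <- sample(config$loop_length_range[1]:config$loop_length_range[2], 1L)
        paste(sample(AA20, n, replace = TRUE, prob = p_loop), collapse = "")
      }
      parts <- rloop(); pos <- nchar(parts)
      for (h in seq_len(n_tmh)) {
        u <- runif(1)
        len <- if (u < config$p_half_tmh) sample(8:12, 1L)
               else if (u < config$p_half_tmh + config$p_long_tmh) sample(36:45, 1L)
               else sample(config$tmh_length_core[1]:config$tmh_length_core[2], 1L)
        helix <- paste(sample(AA20, len, replace = TRUE, prob = p_tmh),
                       collapse = "")
        starts <- c(starts, pos + 1L); ends <- c(ends, pos + len)
        pos <- pos + len
        lp <- rloop()
        parts <- paste0(parts, helix, lp)
        pos <- pos + nchar(lp)
      }
      rec <- sequence_record(sprintf("synth_%04d", pi), parts)
      list(record = rec, topology = topology(rec$id, starts, ends))
    })
  })
}

## Compatible residue states for planted covarying column pairs. The list
## mixes hydrophobic-packing and identity pairs so that planted columns are
## also compositionally shifted relative to the uniform background.
CONTACT_STATES <- matrix(c(
  "A", "V",
  "V", "A",
  "I", "L",
  "L", "I",
  "F", "W",
  "W", "F",
  "C", "C",
  "M", "M"), ncol = 2, byrow = TRUE)

#' Generate an MSA with planted covarying column pairs
#'
#' Unpaired columns are i.i.d. uniform over the 20 residues. Each planted
#' pair is drawn, per row, from a fixed 8-entry compatible-state list with
#' probability `coupling`, else independently from the background. Planted
#' pairs have sequence separation at least 5 and disjoint columns.
#'
#' @param L alignment width.
#' @param depth number of rows.
#' @param n_pairs number of planted pairs (at most `L/2`).
#' @param coupling coupling strength in \[0,1\].
#' @param seed integer seed.
#' @param gap_rate per-cell gap probability (default 0).
#' @return list with `msa` (an `msa_block`) and `pairs` (data.frame `i`,`j`
#'   with `i < j`).
#' @export
generate_planted_contact_msa <- function(L, depth, n_pairs, coupling,
                                         seed = 1L, gap_rate = 0) {
  if (n_pairs > L / 2)
    tk_stop("n_pairs exceeds L/2", "tmhkit_config_error")
  if (coupling < 0 || coupling > 1 || gap_rate < 0 || gap_rate >= 1)
    tk_stop("coupling and gap_rate must lie in [0,1]", "tmhkit_config_error")
  withr::with_seed(as.integer(seed), {
    ## sample disjoint column pairs with separation >= 5
    pairs <- matrix(integer(0), ncol = 2)
    free <- seq_len(L)
    guard <- 0L
    while (nrow(pairs) < n_pairs) {
      guard <- guard + 1L
      if (guard > 10000L)
        tk_stop("could not place planted pairs with separation >= 5",
                "tmhkit_config_error")
      ij <- sort(sample(free, 2L))
      if (ij[2] - ij[1] >= 5L) {
        pairs <- rbind(pairs, ij)
        free <- setdiff(free, ij)
      }
    }
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    mat <- matrix(sample(AA20, depth * L, replace = TRUE), nrow = depth)
    for (p in seq_len(nrow(pairs))) {
      coupled <- runif(depth) < coupling
      k <- sum(coupled)
      if (k) {
        st <- CONTACT_STATES[sample(nrow(CONTACT_STATES), k, replace = TRUE), ,
                             drop = FALSE]
        mat[coupled, pairs[p, 1]] <- st[, 1]
        mat[coupled, pairs[p, 2]] <- st[, 2]
      }
    }
    if (gap_rate > 0)
      mat[matrix(runif(length(mat)) < gap_rate, nrow = depth)] <- "-"
    msa <- msa_block(apply(mat, 1, paste, collapse = ""),
                     ids = sprintf("s%04d", seq_len(depth)))
    list(msa = msa,
         pairs = data.frame(i = pairs[, 1], j = pairs[, 2]))
  })
}

#' Generate synthetic RASA tracks for a membrane-protein corpus
#'
#' Encodes the lipid-facing/buried periodicity of transmembrane helices:
#' within a helix, `rasa_i = clamp(45 + 35 sin(2 pi i / 3.6 + phi) + eps,
#' 0, 100)` with a per-helix random phase `phi` (period 3.6 residues/turn,
#' the alpha-helix geometry) and Gaussian noise `eps`; loop residues are
#' `clamp(70 + eps', 0, 100)`.
#'
#' @param corpus list of `list(record, topology)` as returned by
#'   [generate_membrane_protein_corpus()].
#' @param noise_sd Gaussian noise standard deviation in percent (default 10).
#' @param seed integer seed.
#' @return list of [rasa_track()], one per corpus entry.
#' @export
generate_rasa_corpus <- function(corpus, noise_sd = 10, seed = 1L) {
  if (noise_sd < 0)
    tk_stop("noise_sd must be non-negative", "tmhkit_config_error")
  withr::with_seed(as.integer(seed), {
    lapply(corpus, function(entry) {
      L <- entry$record$length
      vals <- 70 + rnorm(L, sd = noise_sd)
      seg <- entry$topology$segments
      for (s in seq_len(nrow(seg))) {
        idx <- seg$start[s]:seg$end[s]
        phi <- runif(1, 0, 2 * pi)
        i_rel <- seq_along(idx)
        vals[idx] <- 45 + 35 * sin(2 * pi * i_rel / 3.6 + phi) +
          rnorm(length(idx), sd = noise_sd)
      }
      rasa_track(entry$record$id, pmin(100, pmax(0, vals)))
    })
  })
}
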