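# Programmatic fixtures shared across test files.

random_record <- function(id = "rec", L = 30L, seed = NULL, with_x = FALSE) {
  gen <- function() {
    alpha <- aa_alphabet(with_x)
    sequence_record(id, paste(sample(alpha, L, replace = TRUE),
                              collapse = ""))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

random_profile <- function(L = 30L, seed = 1L, id = "rec") {
  withr::with_seed(seed, {
    rec <- random_record(id, L)
    pr <- pseudo_profile(rec)
    pr
  })
}

# Write an integer-valued log-odds PSSM file for a record.
write_fixture_pssm <- function(record, path, seed = 1L) {
  withr::with_seed(seed, {
    L <- record$length
    raw <- matrix(sample(-8:8, L * 20, replace = TRUE), nrow = L)
    res <- strsplit(record$residues, "")[[1]]
    lines <- c("", "Last position-specific scoring matrix computed",
               paste(" ", paste(sprintf("%3s", aa_alphabet()), collapse = " ")))
    for (i in seq_len(L))
      lines <- c(lines, paste0(sprintf("%5d %s ", i, res[i]),
                               paste(sprintf("%3d", raw[i, ]), collapse = " ")))
    writeLines(lines, path)
    raw
  })
}

# Small labeled corpus for classifier tests: two seeded Gaussian clouds.
gaussian_clouds <- function(n_per_class = 60L, p = 8L, sep = 4, seed = 1L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
               matrix(rnorm(n_per_class * p, mean = sep), ncol = p))
    y <- rep(c(0L, 1L), each = n_per_class)
    list(x = x, y = y)
  })
}

# Tiny synthetic corpus + matching profiles for end-to-end tests.
small_corpus <- function(n = 10L, seed = 7L) {
  generate_membrane_protein_corpus(
    topology_generator_config(n_proteins = n, seed = seed))
}

# A topology of short helices separated by single-residue loops, so that
# almost every pair with separation >= 5 lies in two different helices.
dense_helix_topology <- function(L, record_id = "query") {
  s <- seq(1L, L, by = 6L); e <- pmin(s + 4L, L)
  keep <- e - s + 1L >= 2L
  topology(record_id, s[keep], e[keep])
}

# Features + labels for a planted-contact MSA under a given topology.
planted_pair_corpus <- function(planted, topo) {
  tab <- contact_pair_table(msa_profile(planted$msa), topo)
  lab <- as.integer(paste(tab$pairs$i, tab$pairs$j) %in%
                    paste(planted$pairs$i, planted$pairs$j))
  list(tab = tab, lab = lab)
}
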