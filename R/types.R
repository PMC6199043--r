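## Core S3 containers shared by all engines.

#' Create a sequence record
#'
#' A named amino-acid sequence over the 20 standard residues plus `X`
#' (unknown). Lower-case input is upper-cased; any other character is
#' rejected with the offending position.
#'
#' @param id free-text identifier.
#' @param residues character scalar, the amino-acid sequence.
#' @return an object of class `sequence_record` with fields `id`, `residues`
#'   and `length`.
#' @export
sequence_record <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[ \t\r\n]", "", residues))
  if (!nzchar(residues))
    tk_stop(sprintf("record '%s': empty sequence", id), "tmhkit_parse_error")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% aa_alphabet(with_x = TRUE))
  if (length(bad))
    tk_stop(sprintf("record '%s': illegal residue '%s' at position %d",
                    id, chars[bad[1]], bad[1]),
            "tmhkit_parse_error")
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (L=%d)\n", x$id, x$length))
  invisible(x)
}

## Internal Profile constructor; users obtain profiles via read_pssm(),
## pseudo_profile() or msa_profile().
new_profile <- function(record_id, residues, raw, scaled, source) {
  stopifnot(is.matrix(raw), ncol(raw) == 20L,
            is.matrix(scaled), all(dim(scaled) == dim(raw)),
            nchar(residues) == nrow(raw),
            source %in% c("pssm_file", "pseudo", "msa"))
  if (any(!is.finite(raw)))
    tk_stop("profile raw matrix contains non-finite values",
            "tmhkit_numeric_error")
  if (any(scaled < 0 | scaled > 1))
    tk_stop("profile scaled matrix outside [0,1]", "tmhkit_numeric_error")
  colnames(raw) <- colnames(scaled) <- AA20
  structure(list(record_id = record_id, residues = residues,
                 raw = raw, scaled = scaled, source = source),
            class = "tmh_profile")
}

#' @export
print.tmh_profile <- function(x, ...) {
  cat(sprintf("<tmh_profile> %s (L=%d, source=%s)\n",
              x$record_id, nrow(x$raw), x$source))
  invisible(x)
}

profile_length <- function(profile) nrow(profile$raw)

#' Create a per-residue propensity track
#'
#' @param record_id identifier of the underlying sequence.
#' @param values numeric vector in \[0,1\], one value per residue.
#' @return an object of class `propensity_track`.
#' @export
propensity_track <- function(record_id, values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (any(!is.finite(values)) || any(values < 0 | values > 1))
    tk_stop("propensity values must be finite and within [0,1]",
            "tmhkit_numeric_error")
  structure(list(record_id = record_id, values = as.numeric(values)),
            class = "propensity_track")
}

#' Create a TMH topology
#'
#' An ordered list of non-overlapping transmembrane helix intervals
#' (1-based, inclusive) over one sequence. Consecutive segments must be
#' separated by at least one loop residue.
#'
#' @param record_id identifier of the underlying sequence.
#' @param start,end integer vectors of equal length (may be empty).
#' @return an object of class `topology` with a `segments` data.frame.
#' @export
topology <- function(record_id, start = integer(), end = integer()) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end))
  if (length(start)) {
    if (any(start < 1L) || any(end < start))
      tk_stop("invalid segment coordinates", "tmhkit_input_error")
    o <- order(start)
    start <- start[o]; end <- end[o]
    if (length(start) > 1L && any(start[-1L] <= end[-length(end)] + 1L))
      tk_stop("segments must be disjoint with a gap of at least 1 residue",
              "tmhkit_input_error")
  }
  structure(list(record_id = record_id,
                 segments = data.frame(start = start, end = end)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %s: %d TMH segment(s)\n",
              x$record_id, nrow(x$segments)))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

n_segments <- function(topo) nrow(topo$segments)

## 0/1 membership vector of length L for a topology.
topology_mask <- function(topo, L) {
  m <- integer(L)
  seg <- topo$segments
  if (nrow(seg)) {
    if (max(seg$end) > L)
      tk_stop("topology extends beyond sequence length", "tmhkit_input_error")
    for (s in seq_len(nrow(seg))) m[seg$start[s]:seg$end[s]] <- 1L
  }
  m
}

#' Create a RASA track
#'
#' Per-residue relative accessible surface area in percent, clamped to
#' \[0,100\].
#'
#' @param record_id identifier of the underlying sequence.
#' @param values numeric vector, percent units.
#' @return an object of class `rasa_track`.
#' @export
rasa_track <- function(record_id, values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (any(!is.finite(values)) || any(values < 0 | values > 100))
    tk_stop("rasa values must be finite and within [0,100]",
            "tmhkit_numeric_error")
  structure(list(record_id = record_id, values = as.numeric(values)),
            class = "rasa_track")
}

#' Create a contact map
#'
#' Symmetric L x L score matrix with the diagonal and short-range pairs
#' (sequence separation below `min_separation`) masked out, plus an optional
#' binary truth layer (contact = spatial distance < 8 Angstrom in the source
#' structure) and an optional inter-helix mask derived from a [topology()].
#'
#' @param record_id identifier of the underlying sequence.
#' @param scores symmetric numeric L x L matrix; masked entries are set to NA.
#' @param truth optional symmetric binary (0/1) L x L matrix.
#' @param topo optional [topology()]; if given, the `tmh_mask` layer marks
#'   pairs whose two residues lie in different helices.
#' @param min_separation minimum |i-j| for a scorable pair (default 5).
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(record_id, scores, truth = NULL, topo = NULL,
                        min_separation = 5L) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  L <- nrow(scores)
  sep <- abs(row(scores) - col(scores))
  keep <- sep >= min_separation
  if (!isTRUE(all.equal(unname(scores[keep]), unname(t(scores)[keep]))))
    tk_stop("score matrix must be symmetric on unmasked pairs",
            "tmhkit_input_error")
  scores[!keep] <- NA_real_
  if (!is.null(truth)) {
    stopifnot(is.matrix(truth), all(dim(truth) == L),
              all(truth[!is.na(truth)] %in% c(0, 1)))
    if (!isTRUE(all.equal(unname(truth), unname(t(truth)))))
      tk_stop("truth layer must be symmetric", "tmhkit_input_error")
  }
  tmh_mask <- NULL
  if (!is.null(topo)) {
    helix_of <- helix_index(topo, L)
    tmh_mask <- outer(helix_of, helix_of,
                      function(a, b) !is.na(a) & !is.na(b) & a != b)
    tmh_mask <- tmh_mask & keep
  }
  structure(list(record_id = record_id, scores = scores, truth = truth,
                 tmh_mask = tmh_mask, min_separation = as.integer(min_separation)),
            class = "contact_map")
}

## helix index per residue (NA outside all helices)
helix_index <- function(topo, L) {
  h <- rep(NA_integer_, L)
  seg <- topo$segments
  for (s in seq_len(nrow(seg))) h[seg$start[s]:seg$end[s]] <- s
  h
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s (L=%d, truth=%s)\n", x$record_id,
              nrow(x$scores), if (is.null(x$truth)) "absent" else "present"))
  invisible(x)
}
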