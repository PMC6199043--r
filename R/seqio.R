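## seqio: every external format the toolkit touches.
##
## FASTA reading/writing is delegated to Biostrings; alphabet validation
## (with located errors) is done here because the toolkit's alphabet is
## stricter than Biostrings' extended amino-acid set. The PSI-BLAST ASCII
## PSSM dialect has no established R parser, so it is parsed here.
## All on-disk coordinates are 1-based inclusive.

#' Read protein sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return list of [sequence_record()] in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    tk_stop(sprintf("file not found: %s", path), "tmhkit_io_error")
  if (file.size(path) == 0L)
    tk_stop(sprintf("empty FASTA file: %s", path), "tmhkit_empty_input_error")
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    tk_stop(sprintf("no records in FASTA file: %s", path),
            "tmhkit_empty_input_error")
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    sequence_record(ids[i], as.character(set[[i]])))
}

#' Write sequence records to a FASTA file
#'
#' @param records list of [sequence_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "residues"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Logistic scaling of profile scores
#'
#' Maps log-odds profile values elementwise to (0,1) with the standard
#' logistic function `1/(1+exp(-x))` (slope 1, midpoint 0). Monotone, so
#' the ordering of raw scores is preserved.
#'
#' @param raw numeric matrix (or vector) of finite values.
#' @return object of the same shape with values strictly inside (0,1).
#' @export
scale_profile <- function(raw) {
  if (any(!is.finite(raw)))
    tk_stop("scale_profile: non-finite input", "tmhkit_numeric_error")
  stats::plogis(raw)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the 20-column log-odds block of the classic PSI-BLAST ASCII
#' matrix dump (`-out_ascii_pssm`): header lines, then one row per residue
#' starting with the position index and residue letter, followed by at
#' least 20 integer log-odds columns. The optional percentage block and
#' trailing statistics are ignored.
#'
#' @param path path to the PSSM file.
#' @param record optional [sequence_record()]; if given, the PSSM residue
#'   letters are cross-checked against it.
#' @return a profile object (class `tmh_profile`) with `raw` log-odds and
#'   logistic-`scaled` matrices, `source = "pssm_file"`.
#' @export
read_pssm <- function(path, record = NULL) {
  if (!file.exists(path))
    tk_stop(sprintf("file not found: %s", path), "tmhkit_io_error")
  lines <- readLines(path, warn = FALSE)
  if (!length(lines))
    tk_stop(sprintf("empty PSSM file: %s", path), "tmhkit_empty_input_error")
  raw <- NULL
  letters_seen <- character()
  expected_pos <- 1L
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(toks) < 2L) next
    if (!grepl("^[0-9]+$", toks[1]) || !grepl("^[A-ZX]$", toks[2])) next
    if (length(toks) < 22L)
      tk_stop(sprintf("PSSM line %d: expected 20 log-odds columns", ln),
              "tmhkit_parse_error")
    pos <- as.integer(toks[1])
    if (pos != expected_pos)
      tk_stop(sprintf("PSSM line %d: expected position %d, found %d",
                      ln, expected_pos, pos), "tmhkit_parse_error")
    vals <- suppressWarnings(as.numeric(toks[3:22]))
    if (any(is.na(vals)))
      tk_stop(sprintf("PSSM line %d: non-numeric log-odds cell", ln),
              "tmhkit_parse_error")
    raw <- rbind(raw, vals)
    letters_seen <- c(letters_seen, toks[2])
    expected_pos <- expected_pos + 1L
  }
  if (is.null(raw))
    tk_stop(sprintf("no PSSM rows found in %s", path), "tmhkit_parse_error")
  residues <- paste(letters_seen, collapse = "")
  if (!is.null(record) && !identical(record$residues, residues))
    tk_stop(sprintf(
      "PSSM residues disagree with record '%s' (PSSM '%s' vs FASTA '%s')",
      record$id, residues, record$residues), "tmhkit_consistency_error")
  id <- if (is.null(record)) basename(path) else record$id
  rownames(raw) <- NULL
  new_profile(id, residues, unname(raw), scale_profile(unname(raw)),
              "pssm_file")
}

#' Write a profile in PSI-BLAST ASCII PSSM layout
#'
#' Emits the 20-column log-odds block in the same dialect [read_pssm()]
#' accepts, so write/read round-trips.
#'
#' @param profile a profile object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "tmh_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste(" ", paste(sprintf("%3s", AA20), collapse = " "))), con)
  res <- strsplit(profile$residues, "")[[1]]
  for (i in seq_len(nrow(profile$raw)))
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%6.2f", profile$raw[i, ]),
                            collapse = " ")), con)
  invisible(path)
}

#' Pseudo-profile fallback for sequences without a PSSM
#'
#' When no evolutionary profile is available, row `i` is a
#' point-mass-plus-background distribution: weight `w` on the observed
#' residue and `(1-w)/19` on each of the other 19; rows for the unknown
#' residue `X` are uniform (0.05). This is a degraded mode: real profiles
#' carry homology information that a single sequence cannot.
#'
#' @param record a [sequence_record()].
#' @param w weight on the observed residue, in (0,1); default 0.9.
#' @return a profile object with `source = "pseudo"`; `raw` and `scaled`
#'   both hold the probability rows (already in \[0,1\]).
#' @export
pseudo_profile <- function(record, w = 0.9) {
  stopifnot(inherits(record, "sequence_record"), w > 0, w < 1)
  chars <- strsplit(record$residues, "")[[1]]
  L <- length(chars)
  raw <- matrix((1 - w) / 19, nrow = L, ncol = 20)
  for (i in seq_len(L)) {
    if (chars[i] == "X") raw[i, ] <- 1 / 20
    else raw[i, match(chars[i], AA20)] <- w
  }
  new_profile(record$id, record$residues, raw, raw, "pseudo")
}

#' Read a multiple sequence alignment (aligned FASTA)
#'
#' All rows must have equal length; the first row is taken as the query.
#' Rows are restricted to the 20 residues, `X` and the gap character `-`.
#'
#' @param path path to an aligned FASTA file.
#' @return an `msa_block`: list with `seqs` (character vector), `ids`,
#'   `width` and `depth`.
#' @export
read_msa <- function(path) {
  if (!file.exists(path))
    tk_stop(sprintf("file not found: %s", path), "tmhkit_io_error")
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L)
    tk_stop("alignment must contain at least 2 rows",
            "tmhkit_insufficient_alignment_error")
  seqs <- toupper(as.character(set))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    tk_stop(sprintf("unequal alignment row lengths (%s)",
                    paste(unique(widths), collapse = ", ")),
            "tmhkit_parse_error")
  ok <- paste0(c(aa_alphabet(with_x = TRUE), "-"), collapse = "")
  bad <- regexpr(sprintf("[^%s]", ok), seqs)
  if (any(bad > 0)) {
    r <- which(bad > 0)[1]
    tk_stop(sprintf("alignment row %d: illegal character at column %d",
                    r, bad[r]), "tmhkit_parse_error")
  }
  msa_block(seqs, ids = sub("\\s.*$", "", names(set)))
}

#' Construct an MSA block from character sequences
#'
#' @param seqs character vector of equal-length gapped sequences.
#' @param ids row identifiers (default `row1..rowN`).
#' @return an `msa_block` object.
#' @export
msa_block <- function(seqs, ids = paste0("row", seq_along(seqs))) {
  stopifnot(is.character(seqs), length(seqs) >= 1L,
            length(unique(nchar(seqs))) == 1L)
  seqs <- unname(seqs)
  structure(list(seqs = seqs, ids = unname(ids),
                 width = nchar(seqs[1]), depth = length(seqs)),
            class = "msa_block")
}

#' @export
print.msa_block <- function(x, ...) {
  cat(sprintf("<msa_block> depth=%d width=%d\n", x$depth, x$width))
  invisible(x)
}

#' Write an MSA block as aligned FASTA
#'
#' @param msa an `msa_block`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  seqs <- Biostrings::BStringSet(msa$seqs)
  names(seqs) <- msa$ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, ""))
}

## ---- tabular prediction output ------------------------------------------

#' Write a per-residue propensity table
#'
#' TSV with columns position, residue, propensity, smoothed, label.
#'
#' @param record a [sequence_record()].
#' @param raw_track,smooth_track [propensity_track()] objects.
#' @param topo a [topology()] supplying the 0/1 label column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_propensity_tsv <- function(record, raw_track, smooth_track, topo, path) {
  L <- record$length
  stopifnot(length(raw_track$values) == L, length(smooth_track$values) == L)
  dt <- data.table::data.table(
    position = seq_len(L),
    residue = strsplit(record$residues, "")[[1]],
    propensity = raw_track$values,
    smoothed = smooth_track$values,
    label = topology_mask(topo, L))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a per-residue propensity table written by [write_propensity_tsv()]
#'
#' @param path input path.
#' @param record_id identifier for the reconstructed tracks.
#' @return list with `raw_track`, `smooth_track`, `labels`, `residues`.
#' @export
read_propensity_tsv <- function(path, record_id = basename(path)) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("position", "residue", "propensity", "smoothed", "label")
  if (!all(need %in% names(dt)))
    tk_stop("malformed propensity table", "tmhkit_parse_error")
  list(raw_track = propensity_track(record_id, dt$propensity),
       smooth_track = propensity_track(record_id, dt$smoothed),
       labels = as.integer(dt$label),
       residues = paste(dt$residue, collapse = ""))
}

#' Write topologies as a TSV interval list
#'
#' Columns record, start, end; coordinates 1-based inclusive.
#'
#' @param topologies a [topology()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology_tsv <- function(topologies, path) {
  if (inherits(topologies, "topology")) topologies <- list(topologies)
  rows <- lapply(topologies, function(tp) {
    if (!nrow(tp$segments)) return(NULL)
    data.table::data.table(record = tp$record_id,
                           start = tp$segments$start, end = tp$segments$end)
  })
  dt <- data.table::rbindlist(rows)
  if (!nrow(dt))
    dt <- data.table::data.table(record = character(), start = integer(),
                                 end = integer())
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a topology interval list
#'
#' @param path TSV written by [write_topology_tsv()].
#' @return named list of [topology()] objects, one per record.
#' @export
read_topology_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (!all(c("record", "start", "end") %in% names(dt)))
    tk_stop("malformed topology table", "tmhkit_parse_error")
  if (!nrow(dt)) return(list())
  out <- lapply(split(dt, by = "record", sorted = FALSE), function(d)
    topology(d$record[1], d$start, d$end))
  out
}

#' Write a contact map as a three-column TSV
#'
#' Upper triangle only (`i < j`), unmasked pairs, sorted by descending
#' score.
#'
#' @param map a [contact_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(map, path) {
  sc <- map$scores
  idx <- which(upper.tri(sc) & !is.na(sc), arr.ind = TRUE)
  dt <- data.table::data.table(i = idx[, 1], j = idx[, 2],
                               score = sc[idx])
  data.table::setorder(dt, -score, i, j)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a three-column contact TSV into a contact map
#'
#' @param path TSV with columns i, j, score.
#' @param L sequence length of the reconstructed map.
#' @param record_id identifier for the map.
#' @param min_separation mask threshold, as in [contact_map()].
#' @return a [contact_map()].
#' @export
read_contact_tsv <- function(path, L, record_id = basename(path),
                             min_separation = 5L) {
  dt <- data.table::fread(path, sep = "\t")
  if (!all(c("i", "j", "score") %in% names(dt)))
    tk_stop("malformed contact table", "tmhkit_parse_error")
  sc <- matrix(NA_real_, L, L)
  if (nrow(dt)) {
    if (any(dt$i >= dt$j))
      tk_stop("contact table must contain upper-triangle pairs (i < j)",
              "tmhkit_parse_error")
    sc[cbind(dt$i, dt$j)] <- dt$score
    sc[cbind(dt$j, dt$i)] <- dt$score
  }
  contact_map(record_id, sc, min_separation = min_separation)
}

#' Write a RASA track as TSV
#'
#' Columns position, residue, rasa (percent).
#'
#' @param record a [sequence_record()].
#' @param track a [rasa_track()].
#' @param path output path.
#' @param extra optional data.frame of extra columns (e.g. engine, similarity).
#' @return `path`, invisibly.
#' @export
write_rasa_tsv <- function(record, track, path, extra = NULL) {
  stopifnot(length(track$values) == record$length)
  dt <- data.table::data.table(position = seq_len(record$length),
                               residue = strsplit(record$residues, "")[[1]],
                               rasa = track$values)
  if (!is.null(extra)) dt <- cbind(dt, extra)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a RASA TSV
#'
#' @param path TSV written by [write_rasa_tsv()].
#' @param record_id identifier for the track.
#' @return a [rasa_track()].
#' @export
read_rasa_tsv <- function(path, record_id = basename(path)) {
  dt <- data.table::fread(path, sep = "\t")
  if (!all(c("position", "rasa") %in% names(dt)))
    tk_stop("malformed rasa table", "tmhkit_parse_error")
  rasa_track(record_id, dt$rasa)
}
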