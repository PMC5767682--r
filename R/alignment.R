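#' Region-annotated pairwise alignments
#'
#' A `region_alignment` holds two gapped sequences of equal length plus
#' named column ranges (e.g. `TM1`, `TM1_TM3`, `TM`), the unit on which
#' register-shift correction and region-restricted identity operate.
#'
#' @param seq1,seq2 gapped sequences (single strings or character vectors
#'   of residues/gaps); must have equal gapped length. Gaps are `-`.
#' @param regions named list of `c(from, to)` column ranges.
#' @param labels1 optional residue labels for sequence 1 (e.g. `"P236"`);
#'   default: one-letter code plus ungapped position.
#' @return a `region_alignment`.
#' @export
region_alignment <- function(seq1, seq2, regions = list(), labels1 = NULL) {
  s1 <- split_seq(seq1); s2 <- split_seq(seq2)
  if (length(s1) != length(s2)) abort("gapped sequence lengths differ")
  n <- length(s1)
  for (r in names(regions)) {
    rg <- regions[[r]]
    if (length(rg) != 2 || rg[1] < 1 || rg[2] > n || rg[1] > rg[2]) {
      abort(paste0("region '", r, "' out of bounds"))
    }
  }
  if (is.null(labels1)) {
    pos <- cumsum(s1 != "-")
    labels1 <- ifelse(s1 == "-", NA_character_, paste0(s1, pos))
  }
  structure(list(seq1 = s1, seq2 = s2, regions = regions,
                 labels1 = labels1),
            class = "region_alignment")
}

split_seq <- function(s) {
  if (length(s) == 1) strsplit(s, "")[[1]] else as.character(s)
}

#' @export
print.region_alignment <- function(x, ...) {
  cat("<region alignment> length ", length(x$seq1), "; regions: ",
      if (length(x$regions)) paste(names(x$regions), collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Read a pairwise alignment from aligned FASTA
#'
#' @param path aligned-FASTA file with exactly two records of equal
#'   gapped length.
#' @param regions named list of column ranges (see [region_alignment()]).
#' @return a `region_alignment`.
#' @export
read_alignment <- function(path, regions = list()) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) != 2) abort("aligned FASTA must contain exactly 2 records")
  get <- function(k) {
    to <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    paste(lines[(hdr[k] + 1):to], collapse = "")
  }
  region_alignment(gsub("\\s", "", get(1)), gsub("\\s", "", get(2)),
                   regions = regions)
}

#' Correct a register shift by gap insertion
#'
#' A register shift — a systematic off-by-n assignment of residues to
#' helical density, caused e.g. by tracing one extra helix turn — is
#' corrected in the sequence-structure alignment by inserting a run of
#' gap columns in the first sequence immediately after a stated residue,
#' shifting everything downstream by `gap_length` positions. The partner
#' sequence is padded with trailing gaps to restore equal length, and
#' region annotations spanning or following the insertion point are
#' widened/shifted accordingly.
#'
#' @param alignment a `region_alignment`.
#' @param after_position residue label in sequence 1 (e.g. `"P236"`)
#'   after whose column the gap run is inserted.
#' @param gap_length number of gap columns (default 4, one helix turn).
#' @return a `region_alignment` with `gap_length` extra columns.
#' @export
apply_register_shift <- function(alignment, after_position, gap_length = 4) {
  stopifnot(gap_length >= 0)
  if (gap_length == 0) return(alignment)
  col <- match(after_position, alignment$labels1)
  if (is.na(col)) {
    abort(paste0("position '", after_position, "' not found in sequence 1"))
  }
  n <- length(alignment$seq1)
  ins <- rep("-", gap_length)
  s1 <- append(alignment$seq1, ins, after = col)
  l1 <- append(alignment$labels1, rep(NA_character_, gap_length), after = col)
  # sequence 2 keeps its residues in place up to the insertion point; its
  # tail slides on unchanged, and trailing gaps restore equal length
  s2 <- c(alignment$seq2, rep("-", gap_length))
  regions <- map(alignment$regions, function(rg) {
    c(if (rg[1] > col) rg[1] + gap_length else rg[1],
      if (rg[2] > col) rg[2] + gap_length else rg[2])
  })
  region_alignment(s1, s2, regions = regions, labels1 = l1)
}

#' Percent identity over a named region
#'
#' Identical columns divided by aligned columns within the region.
#' A column counts as aligned when at least one sequence has a residue
#' there; double-gap columns are excluded from the denominator, and a
#' residue-vs-gap column counts as aligned but not identical.
#'
#' @param alignment a `region_alignment`.
#' @param region region name, or `NULL` for the full alignment.
#' @return list with `percent` (raw), `rounded` (nearest integer, the
#'   reporting convention), `identical` and `aligned` column counts.
#' @export
percent_identity <- function(alignment, region = NULL) {
  if (is.null(region)) {
    cols <- seq_along(alignment$seq1)
  } else {
    rg <- alignment$regions[[region]]
    if (is.null(rg)) abort(paste0("unknown region '", region, "'"))
    cols <- rg[1]:rg[2]
  }
  a <- toupper(alignment$seq1[cols]); b <- toupper(alignment$seq2[cols])
  aligned <- !(a == "-" & b == "-")
  if (!any(aligned)) abort("region has no aligned columns")
  ident <- aligned & a == b & a != "-"
  pct <- 100 * sum(ident) / sum(aligned)
  list(percent = pct, rounded = round(pct),
       identical = sum(ident), aligned = sum(aligned))
}
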