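# Germline reference module: segment containers, conserved-motif anchor
# location, FASTA I/O, and V-J combination enumeration.
#
# CDR3 anchors follow the classical definition: the conserved cysteine of
# the V-segment Y[YFLI]C motif and the conserved phenylalanine/tryptophan
# of the J-segment [FW]GXGT motif. Anchor offsets are 0-based nucleotide
# offsets of the anchor codon's first base.

#' Construct a germline segment
#'
#' @param segment_id segment label, e.g. `"TRBV9"`.
#' @param segment_class one of `"V"`, `"J"`, `"C"`.
#' @param sequence nucleotide sequence (A/C/G/T, N tolerated but flagged).
#' @param anchor_offset 0-based offset of the anchor codon; located
#'   automatically via [locate_anchor()] when `NULL` (C segments have no
#'   anchor and keep `NA`).
#' @param functional logical; defaults to `TRUE` when an anchor was found
#'   (or for C segments) and the sequence is clean A/C/G/T.
#' @return an object of class `germline_segment`.
#' @export
germline_segment <- function(segment_id, segment_class, sequence,
                             anchor_offset = NULL, functional = NULL) {
  segment_class <- match.arg(segment_class, c("V", "J", "C"))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop_input("segment sequence must be non-empty")
  clean <- !grepl("[^ACGT]", sequence)
  if (!clean && grepl("[^ACGTN]", sequence))
    warning("segment ", segment_id, ": non-ACGTN characters; flagged non-functional")
  if (is.null(anchor_offset)) {
    anchor_offset <- if (segment_class == "C") NA_integer_
      else locate_anchor(sequence, segment_class)
  }
  if (is.null(functional)) {
    functional <- clean && (segment_class == "C" || !is.na(anchor_offset))
  }
  structure(
    list(segment_id = as.character(segment_id),
         segment_class = segment_class,
         sequence = sequence,
         anchor_offset = as.integer(anchor_offset),
         functional = isTRUE(functional)),
    class = "germline_segment"
  )
}

#' @export
print.germline_segment <- function(x, ...) {
  cat(sprintf("<germline_segment> %s [%s] %d nt, anchor_offset=%s, functional=%s\n",
              x$segment_id, x$segment_class, nchar(x$sequence),
              ifelse(is.na(x$anchor_offset), "NA", x$anchor_offset),
              x$functional))
  invisible(x)
}

#' Locate the conserved CDR3 anchor codon
#'
#' Scans all three forward reading frames of `sequence` for the conserved
#' motif: `Y[YFLI]C` for V segments (the anchor is the cysteine codon of
#' the 3'-most occurrence, since the motif marks the 3' end of the V
#' gene), `[FW]GXGT` for J segments (the anchor is the F/W codon of the
#' 5'-most occurrence). Reverse strands are not searched; orientation
#' handling belongs to read annotation.
#'
#' @param sequence nucleotide string, length >= 9.
#' @param segment_class `"V"` or `"J"`.
#' @return 0-based integer offset of the anchor codon, or `NA_integer_`
#'   when no frame contains the motif.
#' @examples
#' locate_anchor("TATTTTTGT", "V")        # YFC -> 6
#' locate_anchor("TTTGGCCAGGGAACC", "J")  # FGQGT -> 0
#' @export
locate_anchor <- function(sequence, segment_class) {
  segment_class <- match.arg(segment_class, c("V", "J"))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 9L) return(NA_integer_)
  pattern <- if (segment_class == "V") "Y[YFLI]C" else "[FW]G.GT"
  hits <- integer(0)
  for (frame in 0:2) {
    if (nchar(sequence) - frame < 3L) next
    aa <- translate_nt(substr(sequence, frame + 1L, nchar(sequence)))
    m <- gregexpr(pattern, aa)[[1]]
    if (m[1] == -1L) next
    for (start in as.integer(m)) {
      # nucleotide offset of the anchor codon within this frame
      anchor_aa <- if (segment_class == "V") start + 2L else start
      hits <- c(hits, frame + (anchor_aa - 1L) * 3L)
    }
  }
  if (!length(hits)) return(NA_integer_)
  if (segment_class == "V") max(hits) else min(hits)
}

#' Load germline segments from FASTA
#'
#' One segment per record; the first whitespace-delimited header token is
#' the `segment_id`. Anchors are located with [locate_anchor()]; records
#' whose anchor cannot be found (or that contain non-ACGT characters) are
#' returned flagged non-functional, not dropped.
#'
#' @param path FASTA file.
#' @param segment_class `"V"`, `"J"` or `"C"`; applied to all records.
#' @return list of [germline_segment()] objects.
#' @export
load_germline_fasta <- function(path, segment_class) {
  segment_class <- match.arg(segment_class, c("V", "J", "C"))
  if (!file.exists(path)) stop_input("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop_input("empty FASTA: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  lapply(seq_along(seqs), function(i) {
    germline_segment(ids[i], segment_class, as.character(seqs[[i]]))
  })
}

#' Write germline segments to FASTA
#'
#' Headers follow the `">TRBV9 functional=yes"` convention.
#'
#' @param segments list of `germline_segment` objects.
#' @param path output file.
#' @export
write_germline_fasta <- function(segments, path) {
  lines <- unlist(lapply(segments, function(s) {
    c(sprintf(">%s functional=%s", s$segment_id,
              if (s$functional) "yes" else "no"),
      s$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a germline library
#'
#' @param segments list of `germline_segment` objects (any mix of V/J/C).
#' @param name library label.
#' @return object of class `germline_library`.
#' @export
germline_library <- function(segments, name = "library") {
  ids <- vapply(segments, `[[`, character(1), "segment_id")
  if (anyDuplicated(ids)) stop_input("duplicate segment_id in library")
  cls <- vapply(segments, `[[`, character(1), "segment_class")
  structure(list(name = name, segments = setNames(segments, ids),
                 classes = setNames(cls, ids)),
            class = "germline_library")
}

#' @export
print.germline_library <- function(x, ...) {
  cat(sprintf("<germline_library> '%s': %d V, %d J, %d C segments\n",
              x$name, sum(x$classes == "V"), sum(x$classes == "J"),
              sum(x$classes == "C")))
  invisible(x)
}

#' Extract segments of one class from a library
#'
#' @param library a `germline_library`.
#' @param segment_class `"V"`, `"J"` or `"C"`.
#' @param functional_only keep only functional segments.
#' @return named list of `germline_segment` objects.
#' @export
library_segments <- function(library, segment_class, functional_only = FALSE) {
  keep <- library$classes == segment_class
  segs <- library$segments[keep]
  if (functional_only)
    segs <- segs[vapply(segs, `[[`, logical(1), "functional")]
  segs
}

segment_sequences <- function(segs) {
  vapply(segs, `[[`, character(1), "sequence")
}

#' Enumerate potential V-J combinations
#'
#' The Cartesian product of the library's V and J segments, optionally
#' restricted to functional segments. The size of this product is the
#' "potential combinations" denominator of V-J usage coverage.
#'
#' @param library a `germline_library`.
#' @param functional_only restrict to functional segments (default TRUE).
#' @return list with `count` and a data frame `pairs` (`v_id`, `j_id`).
#' @export
enumerate_vj_combinations <- function(library, functional_only = TRUE) {
  v <- names(library_segments(library, "V", functional_only))
  j <- names(library_segments(library, "J", functional_only))
  if (!length(v) || !length(j))
    return(list(count = 0L, pairs = data.frame(v_id = character(0),
                                               j_id = character(0))))
  pairs <- expand.grid(v_id = v, j_id = j, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  list(count = nrow(pairs), pairs = pairs)
}

#' The packaged synthetic germline library
#'
#' A small synthetic TRB-style reference (12 V, 6 J, 1 C segments)
#' shipped with the package so that no external download is needed. The
#' segments are random in their framework regions but carry proper
#' `Y[YFLI]C` / `[FW]GXGT` anchors; they are synthetic stand-ins, not
#' IMGT sequences.
#'
#' @return a `germline_library`.
#' @export
synthetic_germline_library <- function() {
  f <- system.file("extdata", "trb_germline_synthetic.fasta",
                   package = "trirep", mustWork = TRUE)
  seqs <- Biostrings::readBStringSet(f)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  cls <- ifelse(grepl("^SYNV", ids), "V", ifelse(grepl("^SYNJ", ids), "J", "C"))
  segs <- lapply(seq_along(seqs), function(i) {
    germline_segment(ids[i], cls[i], as.character(seqs[[i]]))
  })
  germline_library(segs, name = "synthetic-trb")
}
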