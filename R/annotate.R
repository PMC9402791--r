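# V/J annotation module: germline assignment by seeded gapless local
# alignment, CDR3 junction extraction by anchor projection, junction
# decomposition, and repertoire building.
#
# The aligner uses exact k-mer seeds (k = 12 by default) against the
# segment library and gapless diagonal extension (substitution-only),
# scoring match +1 / mismatch -1; the best local block per read is kept.
# Reads are canonicalized to V->J orientation before J assignment.

align_class <- function(seqs, segs, k) {
  cpp_align_best(seqs, segment_sequences(segs), as.integer(k))
}

#' Annotate merged reads against a germline library
#'
#' Assigns the best-scoring functional V and J segment to each read,
#' projects the conserved anchor codons (V cysteine, J phenylalanine/
#' tryptophan) from germline coordinates through the alignment onto the
#' read, and extracts the CDR3 junction (anchor-inclusive). Reads are
#' tried on both strands and canonicalized to V->J orientation.
#'
#' Rejection reasons: `unassigned` (no V or J hit at or above
#' `min_identity`), `no-V-anchor` / `no-J-anchor` (anchor codon not
#' covered by the alignment, or anchor residue not C / not F,W),
#' `out-of-frame` (junction length not a multiple of 3, or non-positive),
#' `stop-codon`.
#'
#' @param merged data frame from [merge_pairs()]`$merged`, or a character
#'   vector of merged sequences.
#' @param library a `germline_library`.
#' @param min_identity identity floor for the V and J aligned blocks.
#' @param k seed k-mer length.
#' @return data frame with one row per read: `read_id`, `sequence`
#'   (canonical orientation), `v_call`, `j_call`, `v_score`, `j_score`,
#'   `v_identity`, `j_identity`, `v_flank_identity`, `j_flank_identity`
#'   (aligned-block identity outside the junction), 0-based coordinates
#'   `v_block_start`, `v_anchor_start`, `j_anchor_start`, `j_block_end`,
#'   `frame_offset`, `junction`, `junction_aa`, `productive`,
#'   `reject_reason`.
#' @export
annotate_reads <- function(merged, library, min_identity = 0.85, k = 12L) {
  if (is.character(merged))
    merged <- data.frame(read_id = sprintf("s%06d", seq_along(merged)),
                         sequence = merged, stringsAsFactors = FALSE)
  vs <- library_segments(library, "V", functional_only = TRUE)
  js <- library_segments(library, "J", functional_only = TRUE)
  if (!length(vs) || !length(js))
    stop_input("library needs functional V and J segments with anchors")
  v_anch <- vapply(vs, `[[`, integer(1), "anchor_offset")
  j_anch <- vapply(js, `[[`, integer(1), "anchor_offset")

  seqs <- toupper(merged$sequence)
  u <- !duplicated(seqs)
  useq <- seqs[u]
  n <- length(useq)

  af <- align_class(useq, vs, k)
  ar <- align_class(revcomp(useq), vs, k)
  sf <- ifelse(is.na(af$score), -Inf, af$score)
  sr <- ifelse(is.na(ar$score), -Inf, ar$score)
  use_rev <- sr > sf
  canon <- ifelse(use_rev, revcomp(useq), useq)
  av <- af
  av[use_rev, ] <- ar[use_rev, ]
  aj <- align_class(canon, js, k)

  v_id <- unname(names(vs)[av$seg])
  j_id <- unname(names(js)[aj$seg])
  v_len <- av$rend - av$rstart
  j_len <- aj$rend - aj$rstart
  v_ident <- ifelse(v_len > 0, av$nmatch / v_len, 0)
  j_ident <- ifelse(j_len > 0, aj$nmatch / j_len, 0)

  va0 <- unname(av$diag + v_anch[av$seg])  # 0-based V anchor start on read
  ja0 <- unname(aj$diag + j_anch[aj$seg])  # 0-based J anchor start on read
  nc <- nchar(canon)

  assigned <- !is.na(av$seg) & !is.na(aj$seg) &
    v_ident >= min_identity & j_ident >= min_identity
  v_anchor_ok <- assigned & av$rstart <= va0 & va0 + 3L <= av$rend
  j_anchor_ok <- assigned & aj$rstart <= ja0 & ja0 + 3L <= aj$rend

  junction <- rep(NA_character_, n)
  ok <- which(v_anchor_ok & j_anchor_ok & ja0 + 3L > va0)
  junction[ok] <- substr(canon[ok], va0[ok] + 1L, ja0[ok] + 3L)
  jlen <- ifelse(is.na(junction), 0L, nchar(junction))
  in_frame <- !is.na(junction) & jlen %% 3L == 0L & jlen >= 6L
  aa <- rep(NA_character_, n)
  aa[in_frame] <- translate_nt(junction[in_frame])
  no_stop <- in_frame & !grepl("*", aa, fixed = TRUE)
  anchor_res_v <- no_stop & substr(aa, 1L, 1L) == "C"
  anchor_res_j <- no_stop & substr(aa, jlen %/% 3L, jlen %/% 3L) %in% c("F", "W")

  productive <- anchor_res_v & anchor_res_j
  reason <- rep(NA_character_, n)
  reason[!assigned] <- "unassigned"
  reason[assigned & !v_anchor_ok] <- "no-V-anchor"
  reason[assigned & v_anchor_ok & !j_anchor_ok] <- "no-J-anchor"
  reason[is.na(reason) & !productive & !in_frame] <- "out-of-frame"
  reason[is.na(reason) & !productive & in_frame & !no_stop] <- "stop-codon"
  reason[is.na(reason) & !productive & !anchor_res_v] <- "no-V-anchor"
  reason[is.na(reason) & !productive & !anchor_res_j] <- "no-J-anchor"
  aa[!productive] <- NA_character_
  junction[!(v_anchor_ok & j_anchor_ok & ja0 + 3L > va0)] <- NA_character_

  # flank identity: the full germline diagonal overlap outside the
  # junction (not the trimmed local block, so error-dense flanks remain
  # visible to the reference filter)
  vf <- cpp_block_identity(canon, segment_sequences(vs), av$seg, av$diag,
                           rep(0L, n), ifelse(is.na(va0), 0L, va0))
  jf <- cpp_block_identity(canon, segment_sequences(js), aj$seg, aj$diag,
                           ifelse(is.na(ja0), 0L, ja0 + 3L), nc)
  v_flank <- ifelse(vf$len > 0, vf$match / vf$len, 1)
  j_flank <- ifelse(jf$len > 0, jf$match / jf$len, 1)

  utab <- data.frame(
    sequence = canon, v_call = v_id, j_call = j_id,
    v_score = av$score, j_score = aj$score,
    v_identity = v_ident, j_identity = j_ident,
    v_flank_identity = v_flank, j_flank_identity = j_flank,
    v_block_start = av$rstart, v_anchor_start = va0,
    j_anchor_start = ja0, j_block_end = aj$rend,
    frame_offset = ifelse(is.na(va0), NA_integer_, va0 %% 3L),
    junction = junction, junction_aa = aa,
    productive = productive, reject_reason = reason,
    stringsAsFactors = FALSE)
  utab$v_call[!assigned] <- NA_character_
  utab$j_call[!assigned] <- NA_character_

  out <- utab[match(seqs, useq), , drop = FALSE]
  out$read_id <- merged$read_id
  rownames(out) <- NULL
  out[, c("read_id", setdiff(names(out), "read_id"))]
}

#' Assign germline V and J segments to one read
#'
#' Single-read wrapper over the batch annotator; see [annotate_reads()].
#'
#' @param read merged read sequence (either strand).
#' @param library a `germline_library`.
#' @param min_identity identity floor.
#' @return list with `v_id`, `j_id`, `v_score`, `j_score`, `v_end`,
#'   `j_start` (0-based half-open read coordinates), `frame_offset`,
#'   `productive`; or `NULL` when unassigned.
#' @export
assign_vj <- function(read, library, min_identity = 0.85) {
  a <- annotate_reads(read, library, min_identity = min_identity)
  if (is.na(a$v_call) || is.na(a$j_call)) return(NULL)
  list(v_id = a$v_call, j_id = a$j_call,
       v_score = a$v_score, j_score = a$j_score,
       v_end = a$v_anchor_start, j_start = a$j_anchor_start,
       frame_offset = a$frame_offset, productive = a$productive,
       sequence = a$sequence)
}

#' Extract the CDR3 junction from one annotated read
#'
#' @param read merged read sequence.
#' @param library a `germline_library`.
#' @param min_identity identity floor.
#' @return list with `status` (`"ok"` or a rejection reason code among
#'   `no-V-anchor`, `no-J-anchor`, `out-of-frame`, `stop-codon`,
#'   `unassigned`), and for `"ok"` also `junction_nt`, `junction_aa`,
#'   `productive`.
#' @export
extract_cdr3 <- function(read, library, min_identity = 0.85) {
  a <- annotate_reads(read, library, min_identity = min_identity)
  if (!a$productive) return(list(status = a$reject_reason))
  list(status = "ok", junction_nt = a$junction, junction_aa = a$junction_aa,
       productive = TRUE)
}

#' Decompose junctions into trims and insert length
#'
#' Greedy maximal matching from both ends: the V-attributed part is the
#' longest exact prefix match of the junction against the germline V
#' 3'-end (anchor onward), the J part the longest exact suffix match
#' against the germline J 5'-end (through the anchor codon). When the two
#' greedy matches overlap (short junctions) the tie is split toward V and
#' the insert length is 0. Germline homology inside the true insert makes
#' the recovered trims lower bounds (documented greedy bias).
#'
#' @param junction_nt character vector of junction sequences.
#' @param v_id,j_id segment calls (recycled if length 1).
#' @param library a `germline_library`.
#' @return data frame (`v_trim`, `j_trim`, `n_len`).
#' @export
decompose_junction <- function(junction_nt, v_id, j_id, library) {
  nj <- length(junction_nt)
  v_id <- rep_len(v_id, nj); j_id <- rep_len(j_id, nj)
  segs <- library$segments
  out <- data.frame(v_trim = integer(nj), j_trim = integer(nj),
                    n_len = integer(nj))
  for (i in seq_len(nj)) {
    v <- segs[[v_id[i]]]; j <- segs[[j_id[i]]]
    gv <- substr(v$sequence, v$anchor_offset + 1L, nchar(v$sequence))
    gj <- substr(j$sequence, 1L, j$anchor_offset + 3L)
    jn <- junction_nt[i]
    L <- nchar(jn)
    vm <- 0L
    while (vm < min(L, nchar(gv)) &&
           substr(jn, vm + 1L, vm + 1L) == substr(gv, vm + 1L, vm + 1L))
      vm <- vm + 1L
    jm <- 0L
    while (jm < min(L, nchar(gj)) &&
           substr(jn, L - jm, L - jm) ==
           substr(gj, nchar(gj) - jm, nchar(gj) - jm))
      jm <- jm + 1L
    if (vm + jm > L) jm <- L - vm   # tie toward V
    out$v_trim[i] <- nchar(gv) - vm
    out$j_trim[i] <- nchar(gj) - jm
    out$n_len[i] <- L - vm - jm
  }
  out
}

#' Build a clonotype repertoire from annotated reads
#'
#' Clonotypes are keyed by junction nucleotide sequence; copies are read
#' counts, V/J calls the plurality call across supporting reads (ties
#' broken lexicographically), frequencies copies over the total.
#'
#' @param annot annotation table from [annotate_reads()]; only productive
#'   rows are used.
#' @param donor_id,lineage sample metadata.
#' @return object of class `repertoire`.
#' @export
build_repertoire <- function(annot, donor_id = "donorI", lineage = "CD3") {
  acc <- annot[which(annot$productive), , drop = FALSE]
  if (!nrow(acc)) {
    cl <- data.frame(junction_nt = character(0), junction_aa = character(0),
                     v_call = character(0), j_call = character(0),
                     copies = numeric(0), frequency = numeric(0),
                     stringsAsFactors = FALSE)
    return(structure(list(donor_id = donor_id, lineage = lineage,
                          clonotypes = cl, total_reads_assigned = 0),
                     class = "repertoire"))
  }
  plurality <- function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    nm <- names(tb)[tb == tb[1]]
    sort(nm)[1]
  }
  sp <- split(seq_len(nrow(acc)), acc$junction)
  cl <- data.frame(
    junction_nt = names(sp),
    junction_aa = vapply(sp, function(i) acc$junction_aa[i[1]], character(1)),
    v_call = vapply(sp, function(i) plurality(acc$v_call[i]), character(1)),
    j_call = vapply(sp, function(i) plurality(acc$j_call[i]), character(1)),
    copies = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE)
  cl <- cl[order(-cl$copies, cl$junction_nt), , drop = FALSE]
  cl$frequency <- cl$copies / sum(cl$copies)
  rownames(cl) <- NULL
  structure(list(donor_id = donor_id, lineage = lineage, clonotypes = cl,
                 total_reads_assigned = sum(cl$copies)),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %s/%s: %d clonotypes, %s reads assigned\n",
              x$donor_id, x$lineage, nrow(x$clonotypes),
              format(x$total_reads_assigned)))
  if (nrow(x$clonotypes))
    print(head(x$clonotypes, 5L))
  invisible(x)
}

renormalize <- function(rep) {
  tot <- sum(rep$clonotypes$copies)
  rep$clonotypes$frequency <-
    if (tot > 0) rep$clonotypes$copies / tot else numeric(nrow(rep$clonotypes))
  rep$total_reads_assigned <- tot
  rep
}

#' Write / read an AIRR-rearrangement-style clonotype table
#'
#' Tab-separated with columns `sequence_id`, `v_call`, `j_call`,
#' `junction`, `junction_aa`, `productive`, `duplicate_count`,
#' `frequency` (1-based conventions as the schema requires).
#'
#' @param rep a `repertoire`.
#' @param path output file.
#' @export
write_airr <- function(rep, path) {
  cl <- rep$clonotypes
  df <- data.frame(sequence_id = sprintf("%s_%s_%06d", rep$donor_id,
                                         rep$lineage, seq_len(nrow(cl))),
                   v_call = cl$v_call, j_call = cl$j_call,
                   junction = cl$junction_nt, junction_aa = cl$junction_aa,
                   productive = rep("T", nrow(cl)),
                   duplicate_count = cl$copies, frequency = cl$frequency,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_airr
#' @param donor_id,lineage metadata to attach on read.
#' @export
read_airr <- function(path, donor_id = "donorI", lineage = "CD3") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  cl <- data.frame(junction_nt = df$junction, junction_aa = df$junction_aa,
                   v_call = df$v_call, j_call = df$j_call,
                   copies = df$duplicate_count,
                   frequency = df$frequency, stringsAsFactors = FALSE)
  structure(list(donor_id = donor_id, lineage = lineage, clonotypes = cl,
                 total_reads_assigned = sum(cl$copies)),
            class = "repertoire")
}
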