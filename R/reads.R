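# Paired-end read handling: FASTQ I/O and overlap-based merging.
# Merging uses the overlap (glocal) dialect of global alignment: end gaps
# free, internal gaps disallowed, match +1 / mismatch -1; within the
# overlap, disagreements resolve to the higher-quality base (tie: mate 1)
# and agreed bases take the max quality.

reverse_str <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

merge_status_labels <- c("merged", "no-overlap", "empty-read")

#' Merge paired-end reads by overlap alignment
#'
#' Mate 2 is reverse-complemented, all suffix(mate 1)/prefix(mate 2)
#' overlap offsets are scored, and the best-scoring overlap satisfying
#' `min_overlap` and `max_mismatch_rate` is chosen (ties: longer overlap,
#' then smaller offset). Pairs with no admissible overlap are dropped and
#' accounted in the log.
#'
#' @param reads a `read_set` (from [simulate_reads()] or
#'   [read_fastq_pairs()]).
#' @param min_overlap minimum overlap length (nt).
#' @param max_mismatch_rate maximum mismatch fraction inside the overlap.
#' @return list with `merged` (data frame: `read_id`, `sequence`,
#'   `quality`, `overlap_len`, `overlap_mismatches`) and `log` (data
#'   frame: `read_id`, `status`).
#' @export
merge_pairs <- function(reads, min_overlap = 30L, max_mismatch_rate = 0.1) {
  if (min_overlap < 5L) stop_input("min_overlap must be >= 5")
  s2rc <- revcomp(reads$seq2)
  q2r <- reverse_str(reads$qual2)
  key <- paste(reads$seq1, s2rc, reads$qual1, q2r, sep = "\r")
  u <- !duplicated(key)
  res <- cpp_merge_pairs(reads$seq1[u], s2rc[u], reads$qual1[u], q2r[u],
                         as.integer(min_overlap), max_mismatch_rate)
  idx <- match(key, key[u])
  status <- res$status[idx]
  ok <- status == 0L
  merged <- data.frame(read_id = reads$read_id[ok],
                       sequence = res$sequence[idx][ok],
                       quality = res$quality[idx][ok],
                       overlap_len = res$overlap_len[idx][ok],
                       overlap_mismatches = res$overlap_mismatches[idx][ok],
                       stringsAsFactors = FALSE)
  log <- data.frame(read_id = reads$read_id,
                    status = merge_status_labels[status + 1L],
                    stringsAsFactors = FALSE)
  list(merged = merged, log = log)
}

#' Merge one read pair
#'
#' Single-pair convenience wrapper around [merge_pairs()].
#'
#' @param seq1,seq2 mate sequences (mate 2 in sequencing orientation).
#' @param qual1,qual2 quality strings; constant Q30 assumed when omitted.
#' @inheritParams merge_pairs
#' @return list (`sequence`, `quality`, `overlap_len`,
#'   `overlap_mismatches`), or an object of class `merge_failure` with a
#'   `reason` element when no admissible overlap exists.
#' @export
merge_pair <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                       min_overlap = 30L, max_mismatch_rate = 0.1) {
  rs <- list(read_id = "pair", seq1 = seq1, seq2 = seq2,
             qual1 = qual1 %||% strrep("?", nchar(seq1)),
             qual2 = qual2 %||% strrep("?", nchar(seq2)))
  out <- merge_pairs(rs, min_overlap, max_mismatch_rate)
  if (!nrow(out$merged)) {
    return(structure(list(reason = out$log$status[1]),
                     class = "merge_failure"))
  }
  as.list(out$merged[1, c("sequence", "quality", "overlap_len",
                          "overlap_mismatches")])
}

#' Write a read set as paired FASTQ plus truth map
#'
#' Produces `<prefix>_R1.fastq`, `<prefix>_R2.fastq` and, when the read
#' set carries simulator truth, `<prefix>_truth.tsv` (tab-separated:
#' `read_id`, `parent_id`, `second_parent_id`, `junction_error`).
#'
#' @param reads a `read_set`.
#' @param prefix output path prefix.
#' @return invisibly, the file paths written.
#' @export
write_read_fastq <- function(reads, prefix) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(quals))
    # the quality mcols are written through the qualities= slot; the
    # writer's note about dropping them is expected
    withCallingHandlers(
      Biostrings::writeQualityScaledXStringSet(x, path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    path
  }
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  files <- c(write_one(reads$seq1, reads$qual1, reads$read_id, p1),
             write_one(reads$seq2, reads$qual2, reads$read_id, p2))
  if (!is.null(reads$truth) && nrow(reads$truth)) {
    pt <- paste0(prefix, "_truth.tsv")
    write.table(reads$truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, pt)
  }
  invisible(files)
}

#' Read paired FASTQ files into a read set
#'
#' Mate order must correspond between the two files.
#'
#' @param r1_path,r2_path FASTQ files (Phred+33).
#' @return a `read_set` without truth information.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  read_one <- function(path) {
    # the reader re-attaches qualities from the quality lines; its note
    # about dropped metadata columns is expected
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  f1 <- read_one(r1_path)
  f2 <- read_one(r2_path)
  if (length(f1) != length(f2))
    stop_input("mate files differ in record count")
  ids <- vapply(strsplit(names(f1), "\\s+"), `[`, character(1), 1L)
  structure(list(read_id = ids,
                 seq1 = as.character(f1), qual1 = as.character(f1@quality),
                 seq2 = as.character(f2), qual2 = as.character(f2@quality),
                 truth = NULL, model = NULL),
            class = "read_set")
}
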