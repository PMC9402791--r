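# Artifact filter cascade: five checkpoints applied in fixed order --
# sequencing-error absorption, mosaic (chimera) removal, amplification-
# performance down-weighting, reference-identity read removal, and the
# frequency threshold that discards single-copy variants. The stage
# algorithms are explicit stand-ins honoring the published five-stage
# design goal (>99% artifact detection); the original internals were
# never published.

#' Filter cascade configuration
#'
#' @param child_parent_max_hamming maximum Hamming distance for a
#'   sequencing-error child to be absorbed into a parent clonotype.
#' @param child_parent_min_ratio minimum parent/child copy ratio for
#'   absorption.
#' @param chimera_score_margin minimum alignment score of both V-block
#'   halves for a read to count as a confident two-parent mosaic.
#' @param amplification_mad_k outlier multiplier on the MAD of per-V read
#'   shares (scaled MAD, `stats::mad` default constant).
#' @param reference_min_identity identity floor for the V/J aligned
#'   blocks outside the junction.
#' @param frequency_threshold copy floor: clonotypes with copies less
#'   than or equal to this are discarded (default 1, i.e. copies must
#'   exceed 1 -- singletons go).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(child_parent_max_hamming = 1L,
                          child_parent_min_ratio = 10,
                          chimera_score_margin = 5,
                          amplification_mad_k = 5,
                          reference_min_identity = 0.9,
                          frequency_threshold = 1L) {
  stopifnot(child_parent_max_hamming >= 0, child_parent_min_ratio > 0,
            chimera_score_margin > 0, amplification_mad_k > 0,
            reference_min_identity > 0, frequency_threshold >= 0)
  structure(as.list(environment()), class = "filter_config")
}

stage_row <- function(stage, input, removed) {
  data.frame(stage = stage, input = input, removed = removed,
             retained = input - removed, stringsAsFactors = FALSE)
}

#' Sequencing-error filter (stage 1)
#'
#' Absorbs likely sequencing/PCR error children into their parents: a
#' clonotype within `child_parent_max_hamming` of a same-length clonotype
#' with the same V/J calls and at least `child_parent_min_ratio` times
#' its copies is merged into that parent (copies added, record removed).
#'
#' @param rep a `repertoire`.
#' @param cfg a [filter_config()].
#' @return list: `repertoire`, `report` (one stage row), `removed`
#'   (character vector of absorbed junctions).
#' @export
filter_sequencing_errors <- function(rep, cfg = filter_config()) {
  cl <- rep$clonotypes
  n0 <- nrow(cl)
  if (n0 > 1L) {
    grp <- paste(cl$v_call, cl$j_call, nchar(cl$junction_nt), sep = "|")
    drop <- logical(n0)
    for (g in split(seq_len(n0), grp)) {
      if (length(g) < 2L) next
      parent <- cpp_absorb_group(cl$junction_nt[g], cl$copies[g],
                                 cfg$child_parent_max_hamming,
                                 cfg$child_parent_min_ratio)
      kids <- which(parent > 0L)
      if (!length(kids)) next
      # resolve absorption chains to terminal parents
      term <- function(i) { while (parent[i] > 0L) i <- parent[i]; i }
      for (k in kids) {
        t <- term(k)
        cl$copies[g[t]] <- cl$copies[g[t]] + cl$copies[g[k]]
        drop[g[k]] <- TRUE
      }
    }
    removed <- cl$junction_nt[drop]
    cl <- cl[!drop, , drop = FALSE]
  } else removed <- character(0)
  rep$clonotypes <- cl
  rep <- renormalize(rep)
  list(repertoire = rep, report = stage_row("sequencing-error", n0,
                                            length(removed)),
       removed = removed)
}

#' Mosaic sequencing filter (stage 2)
#'
#' Detects two-parent chimeric support: a read is a mosaic when the 5'
#' and 3' halves of its V region (everything 5' of the projected V
#' anchor) best-align to different V segments, each with score at least
#' `chimera_score_margin`. A clonotype is removed when the majority of
#' its supporting reads are mosaics.
#'
#' @param rep a `repertoire`.
#' @param annot annotation table from [annotate_reads()] for the reads
#'   that built `rep`.
#' @param cfg a [filter_config()].
#' @param library the `germline_library` used for annotation.
#' @param k seed k-mer length for the half-block alignments.
#' @return list: `repertoire`, `report`, `removed`.
#' @export
filter_mosaic <- function(rep, annot, cfg = filter_config(),
                          library, k = 12L) {
  n0 <- nrow(rep$clonotypes)
  acc <- annot[which(annot$productive & annot$junction %in%
                       rep$clonotypes$junction_nt), , drop = FALSE]
  removed <- character(0)
  if (nrow(acc) && n0 > 0L) {
    u <- !duplicated(acc$sequence)
    us <- acc[u, , drop = FALSE]
    # split the whole region 5' of the V anchor (not the local alignment
    # block, which would exclude the foreign half of a splice)
    vb_to <- us$v_anchor_start
    mid <- vb_to %/% 2L
    h5 <- substr(us$sequence, 1L, mid)
    h3 <- substr(us$sequence, mid + 1L, vb_to)
    vs <- library_segments(library, "V", functional_only = TRUE)
    a5 <- align_class(h5, vs, k)
    a3 <- align_class(h3, vs, k)
    mosaic_u <- !is.na(a5$seg) & !is.na(a3$seg) & a5$seg != a3$seg &
      pmin(a5$score, a3$score) >= cfg$chimera_score_margin
    mosaic <- mosaic_u[match(acc$sequence, us$sequence)]
    frac <- tapply(mosaic, acc$junction, mean)
    removed <- names(frac)[frac > 0.5]
    keep <- !(rep$clonotypes$junction_nt %in% removed)
    rep$clonotypes <- rep$clonotypes[keep, , drop = FALSE]
    rep <- renormalize(rep)
  }
  list(repertoire = rep, report = stage_row("mosaic", n0, length(removed)),
       removed = removed)
}

#' PCR amplification performance filter (stage 3)
#'
#' Computes per-V-segment total read share; V segments whose share
#' exceeds median + `amplification_mad_k` * MAD are down-weighted: their
#' clonotypes' copies are rescaled to the median-share expectation
#' (distorted quantity, not identity -- nothing is removed here).
#' Requires at least 3 distinct V segments, otherwise a logged no-op.
#'
#' @inheritParams filter_sequencing_errors
#' @return list: `repertoire`, `report`, `flagged` (V labels), `note`.
#' @export
filter_amplification <- function(rep, cfg = filter_config()) {
  cl <- rep$clonotypes
  n0 <- nrow(cl)
  note <- NA_character_
  flagged <- character(0)
  vset <- unique(cl$v_call)
  if (length(vset) < 3L) {
    note <- "fewer than 3 V segments: amplification stage skipped"
  } else {
    share <- tapply(cl$copies, cl$v_call, sum) / sum(cl$copies)
    med <- median(share); md <- mad(share)
    flagged <- names(share)[share > med + cfg$amplification_mad_k * md]
    for (v in flagged) {
      idx <- cl$v_call == v
      cl$copies[idx] <- cl$copies[idx] * (med / share[[v]])
    }
    rep$clonotypes <- cl
    rep <- renormalize(rep)
  }
  list(repertoire = rep, report = stage_row("amplification", n0, 0L),
       flagged = flagged, note = note)
}

#' Reference sequence filter (stage 4)
#'
#' Discards reads whose V or J aligned-block identity outside the
#' junction falls below `reference_min_identity`; standalone it operates
#' on the annotation table (before repertoire building), inside the
#' cascade the discarded reads' copies are subtracted from their
#' clonotypes.
#'
#' @param annot annotation table from [annotate_reads()].
#' @param cfg a [filter_config()].
#' @return list: `annot` (retained rows), `discarded` (removed rows),
#'   `report` (read-level stage row).
#' @export
filter_reference <- function(annot, cfg = filter_config()) {
  bad <- !is.na(annot$v_call) & !is.na(annot$j_call) &
    (annot$v_flank_identity < cfg$reference_min_identity |
     annot$j_flank_identity < cfg$reference_min_identity)
  list(annot = annot[!bad, , drop = FALSE],
       discarded = annot[bad, , drop = FALSE],
       report = stage_row("reference", nrow(annot), sum(bad)))
}

#' Frequency threshold filter (stage 5)
#'
#' Removes clonotypes whose copies are less than or equal to `threshold`
#' and renormalizes. The replication default (threshold 1) discards all
#' single-copy variants.
#'
#' @param rep a `repertoire`.
#' @param threshold copy floor.
#' @return list: `repertoire`, `report`, `removed`.
#' @export
filter_frequency <- function(rep, threshold = 1L) {
  n0 <- nrow(rep$clonotypes)
  drop <- rep$clonotypes$copies <= threshold
  removed <- rep$clonotypes$junction_nt[drop]
  rep$clonotypes <- rep$clonotypes[!drop, , drop = FALSE]
  rep <- renormalize(rep)
  list(repertoire = rep, report = stage_row("frequency", n0, sum(drop)),
       removed = removed)
}

#' Run the five-checkpoint filter cascade
#'
#' Stages apply in fixed order: sequencing-error, mosaic, amplification,
#' reference, frequency. The reference stage subtracts the copies of
#' identity-failing reads from the clonotypes they support (clonotypes
#' reduced to zero are removed).
#'
#' @param rep unfiltered `repertoire` (from [build_repertoire()]).
#' @param annot annotation table for the reads that built `rep`.
#' @param cfg a [filter_config()].
#' @param library the `germline_library` used for annotation.
#' @return list: `repertoire` (filtered), `report` (object of class
#'   `filter_report`: per-stage accounting), `removed` (per-stage
#'   removed junction listings).
#' @export
run_cascade <- function(rep, annot, cfg = filter_config(), library) {
  removed <- list()
  s1 <- filter_sequencing_errors(rep, cfg)
  removed$`sequencing-error` <- s1$removed
  s2 <- filter_mosaic(s1$repertoire, annot, cfg, library)
  removed$mosaic <- s2$removed
  s3 <- filter_amplification(s2$repertoire, cfg)
  r4 <- filter_reference(annot, cfg)
  rep4 <- s3$repertoire
  n4 <- nrow(rep4$clonotypes)
  if (nrow(r4$discarded)) {
    lost <- table(r4$discarded$junction[r4$discarded$productive])
    idx <- match(names(lost), rep4$clonotypes$junction_nt)
    hit <- !is.na(idx)
    rep4$clonotypes$copies[idx[hit]] <-
      pmax(0, rep4$clonotypes$copies[idx[hit]] - as.numeric(lost)[hit])
  }
  gone4 <- rep4$clonotypes$copies <= 0
  removed$reference <- rep4$clonotypes$junction_nt[gone4]
  rep4$clonotypes <- rep4$clonotypes[!gone4, , drop = FALSE]
  rep4 <- renormalize(rep4)
  s5 <- filter_frequency(rep4, cfg$frequency_threshold)
  removed$frequency <- s5$removed
  report <- rbind(s1$report, s2$report, s3$report,
                  stage_row("reference", n4, sum(gone4)), s5$report)
  class(report) <- c("filter_report", "data.frame")
  list(repertoire = s5$repertoire, report = report, removed = removed)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> clonotype accounting per cascade stage\n")
  print.data.frame(x)
  invisible(x)
}
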