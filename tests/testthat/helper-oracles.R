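# Independent oracle implementations used to cross-check the package's
# aligners and set analyses. Deliberately written in a different style
# from the implementation (plain character vectors, exhaustive scans).

fixture_library <- function() synthetic_germline_library()

chars <- function(s) strsplit(s, "")[[1]]

# exhaustive all-offset overlap merge oracle (mate 2 already revcomp'd);
# same scoring contract: match +1 / mismatch -1, free end gaps, no
# internal gaps, ties -> longer overlap then smaller offset
oracle_merge <- function(r1, r2rc, min_overlap, max_mm_rate) {
  a <- chars(r1); b <- chars(r2rc)
  L1 <- length(a); L2 <- length(b)
  best <- NULL
  for (d in seq(-(L2 - min_overlap), L1 - min_overlap)) {
    from <- max(1, d + 1); to <- min(L1, d + L2)
    ov <- to - from + 1
    if (ov < min_overlap) next
    bpos <- (from:to) - d
    mm <- sum(a[from:to] != b[bpos])
    if (mm / ov > max_mm_rate) next
    score <- ov - 2 * mm
    cand <- list(score = score, ov = ov, d = d, mm = mm)
    if (is.null(best) || score > best$score ||
        (score == best$score && (ov > best$ov ||
                                 (ov == best$ov && d < best$d))))
      best <- cand
  }
  if (is.null(best)) return(NULL)
  d <- best$d
  left <- if (d > 0) a[1:d] else if (d < 0) b[1:(-d)] else character(0)
  from <- max(1, d + 1); to <- min(L1, d + L2)
  mid <- a[from:to]  # constant qualities in tests: ties resolve to mate 1
  right <- if (d + L2 > L1) b[(L1 - d + 1):L2]
           else if (to < L1) a[(to + 1):L1] else character(0)
  list(sequence = paste(c(left, mid, right), collapse = ""),
       overlap_len = best$ov, overlap_mismatches = best$mm, offset = d)
}

# brute-force conserved-motif scan over all three frames, codon by codon
oracle_anchor <- function(nt, cls) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(nt)
  hits <- integer(0)
  for (off in 0:(n - 9)) {
    aa <- vapply(0:4, function(k) {
      cod <- substr(nt, off + 3 * k + 1, off + 3 * k + 3)
      if (nchar(cod) < 3) NA_character_ else unname(code[cod])
    }, character(1))
    if (cls == "V") {
      if (!is.na(aa[1]) && !is.na(aa[2]) && !is.na(aa[3]) &&
          aa[1] == "Y" && aa[2] %in% c("Y", "F", "L", "I") && aa[3] == "C")
        hits <- c(hits, off + 6L)
    } else {
      if (!anyNA(aa) && aa[1] %in% c("F", "W") && aa[2] == "G" &&
          aa[4] == "G" && aa[5] == "T")
        hits <- c(hits, off)
    }
  }
  if (!length(hits)) return(NA_integer_)
  if (cls == "V") max(hits) else min(hits)
}

# naive percentage set-statistics used against the comparison module
naive_pct_shared <- function(a, b) {
  if (!length(a)) return(0)
  100 * length(a[a %in% b]) / length(a)
}
naive_exclusive <- function(sets) {
  lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    keep <- vapply(s, function(x)
      !any(vapply(sets[-i], function(o) x %in% o, logical(1))), logical(1))
    s[keep]
  })
}

# a tiny deterministic observed-repertoire container for set/stats tests
toy_repertoire <- function(junctions, copies = NULL, v = "SYNV1", j = "SYNJ1",
                           donor = "d", lineage = "CD3") {
  n <- length(junctions)
  copies <- copies %||% rep(2, n)
  cl <- data.frame(junction_nt = junctions,
                   junction_aa = translate_nt(junctions),
                   v_call = rep_len(v, n), j_call = rep_len(j, n),
                   copies = copies, frequency = copies / sum(copies),
                   stringsAsFactors = FALSE)
  structure(list(donor_id = donor, lineage = lineage, clonotypes = cl,
                 total_reads_assigned = sum(copies)),
            class = "repertoire")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared end-to-end helper: simulate -> merge -> annotate -> build
run_sim_pipeline <- function(true_rep, n_reads, model, seed,
                             lib = fixture_library(),
                             cfg = filter_config()) {
  rs <- simulate_reads(true_rep, n_reads, model, seed = seed)
  mg <- merge_pairs(rs, model$min_overlap %||% 30L)
  ann <- annotate_reads(mg$merged, lib)
  rep0 <- build_repertoire(ann)
  casc <- run_cascade(rep0, ann, cfg, lib)
  list(reads = rs, merged = mg, annot = ann, unfiltered = rep0,
       filtered = casc$repertoire, cascade = casc)
}
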