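lib <- fixture_library()
segs <- lib$segments

test_that("V/J assignment recovers constructed segment composition", {
  v3 <- segs[["SYNV3"]]$sequence
  j2 <- segs[["SYNJ2"]]$sequence
  read <- paste0(substr(v3, 1, nchar(v3) - 4), "GGCAT", substr(j2, 3, nchar(j2)))
  a <- assign_vj(read, lib)
  expect_identical(a$v_id, "SYNV3")
  expect_identical(a$j_id, "SYNJ2")
  # exhaustive oracle: best segment by pairwise local alignment
  pa_best <- function(read, class) {
    ss <- segment_sequences(library_segments(lib, class, functional_only = TRUE))
    sc <- vapply(ss, function(s) Biostrings::pairwiseAlignment(
      read, s, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
      gapOpening = 100, gapExtension = 100, scoreOnly = TRUE), numeric(1))
    names(ss)[which.max(sc)]
  }
  expect_identical(a$v_id, pa_best(read, "V"))
  expect_identical(a$j_id, pa_best(read, "J"))

  # random non-germline read: unassigned
  set.seed(5)
  junk <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  expect_null(assign_vj(junk, lib))

  # strand symmetry: annotation identical after canonicalization
  b <- assign_vj(revcomp(read), lib)
  expect_identical(b$sequence, a$sequence)
  expect_identical(b[c("v_id", "j_id", "v_score", "j_score")],
                   a[c("v_id", "j_id", "v_score", "j_score")])
})

test_that("CDR3 extraction equals simulator truth at zero noise", {
  tr <- simulate_repertoire(lib, 300, seed = 71)
  rs <- simulate_reads(tr, 6000, noise_free_model(), seed = 72)
  mg <- merge_pairs(rs)
  ann <- annotate_reads(mg$merged, lib)
  expect_true(all(ann$productive))
  truth_j <- setNames(tr$clonotypes$junction_nt, tr$clonotypes$clone_id)
  expect_identical(ann$junction,
                   unname(truth_j[rs$truth$parent_id[match(ann$read_id,
                                                           rs$read_id)]]))
  # anchor-residue audit on every extracted junction
  expect_true(all(substr(ann$junction_aa, 1, 1) == "C"))
  last <- nchar(ann$junction_aa)
  expect_true(all(substr(ann$junction_aa, last, last) %in% c("F", "W")))
})

test_that("rejection reasons are typed and forced by construction", {
  tr <- simulate_repertoire(lib, 1, seed = 73)
  cl <- tr$clonotypes
  full <- cl$full_nt
  # in-frame TAA in the junction interior -> stop-codon
  jl <- nchar(cl$junction_nt)
  mid_codon <- 61L + 3L * (jl %/% 6L)  # in-frame position inside the junction
  stopped <- full
  substr(stopped, mid_codon, mid_codon + 2L) <- "TAA"
  r <- extract_cdr3(stopped, lib)
  expect_identical(r$status, "stop-codon")
  # single-base deletion in the insert region breaks the frame (the two
  # anchor codons themselves stay intact)
  v3 <- segs[[cl$v_id]]$sequence
  del_pos <- 75L - cl$v_trim + 2L
  broken <- paste0(substr(full, 1, del_pos - 1),
                   substr(full, del_pos + 1, nchar(full)))
  rb <- extract_cdr3(broken, lib)
  expect_identical(rb$status, "out-of-frame")
  # trimming through the V cysteine -> no V anchor
  j <- segs[[cl$j_id]]$sequence
  noanchor <- paste0(substr(v3, 1, 58), cl$n_region, j)
  rn <- extract_cdr3(noanchor, lib)
  expect_identical(rn$status, "no-V-anchor")
})

test_that("junction decomposition is exact for homology-free inserts and
           conservatively greedy otherwise", {
  v <- segs[["SYNV5"]]; j <- segs[["SYNJ3"]]
  gv <- substr(v$sequence, v$anchor_offset + 1, nchar(v$sequence))  # 15 nt
  gj <- substr(j$sequence, 1, j$anchor_offset + 3)                  #  9 nt
  build_junction <- function(v_trim, j_trim, n) {
    paste0(substr(gv, 1, nchar(gv) - v_trim), n,
           substr(gj, j_trim + 1, nchar(gj)))
  }
  other_than <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  # homology-free insert: first base differs from the next germline V
  # base, last base from the preceding germline J base
  n5 <- paste0(other_than(substr(gv, nchar(gv) - 2, nchar(gv) - 2)), "AC",
               "G", other_than(substr(gj, 2, 2)))
  jn <- build_junction(3, 2, n5)
  d <- decompose_junction(jn, "SYNV5", "SYNJ3", lib)
  expect_identical(unlist(d), c(v_trim = 3L, j_trim = 2L, n_len = 5L))

  # untrimmed, empty insert
  d0 <- decompose_junction(build_junction(0, 0, ""), "SYNV5", "SYNJ3", lib)
  expect_identical(unlist(d0), c(v_trim = 0L, j_trim = 0L, n_len = 0L))

  # insert starting with the base the trimmed V would have: greedy
  # matching attributes it to V, so recovered v_trim <= true v_trim
  hom <- substr(gv, nchar(gv) - 2, nchar(gv) - 2)
  n_hom <- paste0(hom, "A", other_than(substr(gj, 2, 2)))
  dh <- decompose_junction(build_junction(3, 2, n_hom), "SYNV5", "SYNJ3", lib)
  expect_lte(dh$v_trim, 3L)

  # randomized exactness under enforced homology-freedom
  set.seed(9)
  for (case in 1:20) {
    vt <- sample(0:6, 1); jt <- sample(0:4, 1); nl <- sample(2:8, 1)
    nxt_v <- substr(gv, nchar(gv) - vt + 1, nchar(gv) - vt + 1)
    prev_j <- substr(gj, jt, jt)
    n <- c(other_than(nxt_v),
           sample(c("A", "C", "G", "T"), max(nl - 2, 0), TRUE),
           other_than(prev_j))[1:nl]
    n <- paste(n, collapse = "")
    dd <- decompose_junction(build_junction(vt, jt, n), "SYNV5", "SYNJ3", lib)
    expect_identical(unlist(dd),
                     c(v_trim = vt, j_trim = jt, n_len = nl),
                     info = paste("case", case))
  }
})

test_that("repertoire building aggregates copies, frequencies and plurality calls", {
  ann <- data.frame(
    read_id = sprintf("r%d", 1:8),
    sequence = "x",
    v_call = c("SYNV2", "SYNV2", "SYNV1", "SYNV2", "SYNV9",
               "SYNV1", "SYNV9", "SYNV3"),
    j_call = "SYNJ1",
    junction = c(rep("TGTAAATTT", 5), rep("TGTCCCTTT", 3)),
    junction_aa = c(rep("CKF", 5), rep("CPF", 3)),
    productive = TRUE, stringsAsFactors = FALSE)
  rep <- build_repertoire(ann)
  expect_identical(nrow(rep$clonotypes), 2L)
  expect_equal(sort(rep$clonotypes$frequency), c(0.375, 0.625))
  expect_identical(rep$total_reads_assigned, 8L)
  expect_equal(sum(rep$clonotypes$frequency), 1, tolerance = 1e-9)
  cl <- rep$clonotypes
  expect_identical(cl$v_call[cl$junction_nt == "TGTAAATTT"], "SYNV2")
  # 1-1-1 tie within the second junction: lexicographically first call
  expect_identical(cl$v_call[cl$junction_nt == "TGTCCCTTT"], "SYNV1")

  empty <- build_repertoire(ann[0, ])
  expect_identical(nrow(empty$clonotypes), 0L)
  expect_identical(empty$total_reads_assigned, 0)
})

test_that("noise without filtering creates false clonotypes (cascade premise)", {
  tr <- simulate_repertoire(lib, 200, seed = 81)
  rs <- simulate_reads(tr, 3e4, error_model(pcr_error_rate = 0,
                                            chimera_rate = 0), seed = 82)
  mg <- merge_pairs(rs)
  ann <- annotate_reads(mg$merged, lib)
  rep0 <- build_repertoire(ann)
  truth <- tr$clonotypes$junction_nt
  obs <- rep0$clonotypes$junction_nt
  expect_equal(mean(truth %in% obs), 1)           # recall 1 at this depth
  expect_lt(mean(obs %in% truth), 1)              # precision < 1: errors
})
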