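lib <- fixture_library()

mutate1 <- function(junction) {
  # one substitution in the junction interior, keeping anchors intact
  p <- nchar(junction) %/% 2
  b <- substr(junction, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  substr(junction, p, p) <- alt
  junction
}

test_that("sequencing-error filter absorbs low-copy Hamming-1 children", {
  parent_j <- "TGTAAACCCGGGTTT"
  child_j <- mutate1(parent_j)
  rep <- toy_repertoire(c(parent_j, child_j), copies = c(1000, 5))
  out <- filter_sequencing_errors(rep)
  expect_identical(nrow(out$repertoire$clonotypes), 1L)
  expect_identical(out$repertoire$clonotypes$junction_nt, parent_j)
  expect_equal(out$repertoire$clonotypes$copies, 1005)
  expect_identical(out$removed, child_j)
  expect_equal(sum(out$repertoire$clonotypes$frequency), 1, tolerance = 1e-9)

  # equal copies: ratio unmet, nothing absorbed
  tie <- toy_repertoire(c(parent_j, child_j), copies = c(500, 500))
  out2 <- filter_sequencing_errors(tie)
  expect_identical(nrow(out2$repertoire$clonotypes), 2L)

  # different V call blocks absorption
  vdiff <- toy_repertoire(c(parent_j, child_j), copies = c(1000, 5),
                          v = c("SYNV1", "SYNV2"))
  out3 <- filter_sequencing_errors(vdiff)
  expect_identical(nrow(out3$repertoire$clonotypes), 2L)
})

test_that("sequencing-error stage removes most error-derived variants in a
           truth-checked simulation", {
  tr <- simulate_repertoire(lib, 150, seed = 91)
  rs <- simulate_reads(tr, 3e4, error_model(pcr_error_rate = 0,
                                            chimera_rate = 0), seed = 92)
  mg <- merge_pairs(rs)
  ann <- annotate_reads(mg$merged, lib)
  rep0 <- build_repertoire(ann)
  err <- setdiff(rep0$clonotypes$junction_nt, tr$clonotypes$junction_nt)
  out <- filter_sequencing_errors(rep0)
  left <- intersect(err, out$repertoire$clonotypes$junction_nt)
  expect_gt(1 - length(left) / length(err), 0.5)
  # no true clonotype was absorbed
  expect_true(all(tr$clonotypes$junction_nt %in%
                    out$repertoire$clonotypes$junction_nt))
})

test_that("mosaic filter removes majority-chimeric clonotypes and nothing else", {
  tr <- simulate_repertoire(lib, 2, seed = 95)
  # force every read to be a two-parent splice
  all_chim <- error_model(seq_error_rate = 0, pcr_error_rate = 0,
                          chimera_rate = 1)
  rs <- simulate_reads(tr, 400, all_chim, seed = 96)
  mg <- merge_pairs(rs)
  ann <- annotate_reads(mg$merged, lib)
  rep0 <- build_repertoire(ann)
  out <- filter_mosaic(rep0, ann, filter_config(), lib)
  # both true junctions are supported purely by mid-V splices: removed
  # (splices inside the junction itself leave no V-block signature and
  # are handled by the frequency stage instead)
  expect_true(all(tr$clonotypes$junction_nt %in% out$removed))

  # chimera-free reads: stage removes nothing
  rs2 <- simulate_reads(tr, 400, noise_free_model(), seed = 97)
  mg2 <- merge_pairs(rs2)
  ann2 <- annotate_reads(mg2$merged, lib)
  rep2 <- build_repertoire(ann2)
  out2 <- filter_mosaic(rep2, ann2, filter_config(), lib)
  expect_identical(out2$repertoire$clonotypes, rep2$clonotypes)
  expect_length(out2$removed, 0)
})

test_that("amplification filter flags and rescales outlier V shares", {
  # uniform shares: no flags, output equals input
  uni <- toy_repertoire(sprintf("TGTAAACCCGGGTT%s", c("T", "C", "A", "G")),
                        copies = c(10, 10, 10, 10),
                        v = c("SYNV1", "SYNV2", "SYNV3", "SYNV4"))
  out <- filter_amplification(uni)
  expect_identical(out$repertoire$clonotypes$copies, uni$clonotypes$copies)
  expect_length(out$flagged, 0)

  # one V at ~50x the median share
  jx <- vapply(1:9, function(i) paste0("TGTAAA", strrep("C", i), "GGGTTT"),
               character(1))
  rep <- toy_repertoire(jx, copies = c(rep(10, 8), 4000),
                        v = c(sprintf("SYNV%d", 1:8), "SYNV9"))
  out2 <- filter_amplification(rep, filter_config(amplification_mad_k = 5))
  share <- tapply(rep$clonotypes$copies, rep$clonotypes$v_call, sum) /
    sum(rep$clonotypes$copies)
  expect_identical(out2$flagged,
                   names(share)[share > median(share) + 5 * mad(share)])
  expect_true("SYNV9" %in% out2$flagged)
  # direct recomputation of the rescaling
  expect_equal(out2$repertoire$clonotypes$copies[9],
               4000 * (median(share) / share[["SYNV9"]]))

  # fewer than 3 V segments: logged no-op
  two <- toy_repertoire(jx[1:2], copies = c(10, 4000),
                        v = c("SYNV1", "SYNV2"))
  out3 <- filter_amplification(two)
  expect_identical(out3$repertoire$clonotypes$copies, two$clonotypes$copies)
  expect_match(out3$note, "skipped")
})

test_that("reference filter discards reads by flank identity, matching a
           direct recomputation", {
  tr <- simulate_repertoire(lib, 60, seed = 101)
  rs <- simulate_reads(tr, 2000, noise_free_model(), seed = 102)
  mg <- merge_pairs(rs)
  ann <- annotate_reads(mg$merged, lib)
  out <- filter_reference(ann)
  expect_identical(nrow(out$discarded), 0L)

  # inject 10 substitutions into the V flank of one read: 50/60 < 0.9
  s <- ann$sequence[1]
  pos <- seq(2, 29, 3)
  for (p in pos) {
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
  }
  ann2 <- annotate_reads(data.frame(read_id = "mut", sequence = s,
                                    stringsAsFactors = FALSE), lib,
                         min_identity = 0.7)
  expect_lt(ann2$v_flank_identity, 0.9)
  out2 <- filter_reference(ann2)
  expect_identical(nrow(out2$discarded), 1L)

  # discard count equals an independent per-read identity recomputation
  noisy <- simulate_reads(tr, 5000, error_model(seq_error_rate = 5e-3),
                          seed = 103)
  annn <- annotate_reads(merge_pairs(noisy)$merged, lib)
  cfg <- filter_config(reference_min_identity = 0.97)
  outn <- filter_reference(annn, cfg)
  direct <- sum(!is.na(annn$v_call) & !is.na(annn$j_call) &
                  (annn$v_flank_identity < 0.97 | annn$j_flank_identity < 0.97))
  expect_identical(nrow(outn$discarded), direct)
})

test_that("frequency filter drops clonotypes at or below the copy floor", {
  rep <- toy_repertoire(sprintf("TGTAAACCCGGGTT%s", c("T", "C", "A", "G")),
                        copies = c(5, 3, 1, 1))
  out <- filter_frequency(rep, 1)
  expect_identical(nrow(out$repertoire$clonotypes), 2L)
  expect_true(all(out$repertoire$clonotypes$copies > 1))
  expect_equal(sum(out$repertoire$clonotypes$frequency), 1, tolerance = 1e-9)

  ident <- filter_frequency(rep, 0)
  expect_identical(ident$repertoire$clonotypes, rep$clonotypes)

  # direct-scan oracle on a simulated repertoire
  tr <- simulate_repertoire(lib, 300, seed = 104)
  rs <- simulate_reads(tr, 8000, error_model(), seed = 105)
  rep0 <- build_repertoire(annotate_reads(merge_pairs(rs)$merged, lib))
  o <- filter_frequency(rep0, 1)
  expect_setequal(o$repertoire$clonotypes$junction_nt,
                  rep0$clonotypes$junction_nt[rep0$clonotypes$copies >= 2])
})

test_that("the cascade applies stages in fixed order, never grows the
           repertoire, and is idempotent on its own output", {
  tr <- simulate_repertoire(lib, 150, seed = 111)
  rs <- simulate_reads(tr, 1e4, error_model(), seed = 112)
  ann <- annotate_reads(merge_pairs(rs)$merged, lib)
  rep0 <- build_repertoire(ann)
  casc <- run_cascade(rep0, ann, filter_config(), lib)
  expect_identical(casc$report$stage,
                   c("sequencing-error", "mosaic", "amplification",
                     "reference", "frequency"))
  expect_true(all(casc$report$input == casc$report$removed +
                    casc$report$retained))
  # each stage starts from the previous stage's survivors and never grows
  expect_identical(casc$report$input[-1], casc$report$retained[-5])
  expect_true(all(casc$report$retained <= casc$report$input))
  expect_true(all(casc$repertoire$clonotypes$copies > 1))

  # idempotence of absorbing/threshold stages on the cascade's own output
  again_seq <- filter_sequencing_errors(casc$repertoire)
  expect_identical(again_seq$repertoire$clonotypes$junction_nt,
                   casc$repertoire$clonotypes$junction_nt)
  again_freq <- filter_frequency(casc$repertoire, 1)
  expect_identical(again_freq$repertoire$clonotypes,
                   casc$repertoire$clonotypes)

  # an all-clean zero-noise input passes through unchanged
  rs0 <- simulate_reads(tr, 2e4, noise_free_model(), seed = 113)
  ann0 <- annotate_reads(merge_pairs(rs0)$merged, lib)
  rep00 <- build_repertoire(ann0)
  c0 <- run_cascade(rep00, ann0, filter_config(), lib)
  expect_identical(c0$repertoire$clonotypes$junction_nt,
                   rep00$clonotypes$junction_nt)
})
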