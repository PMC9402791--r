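lib <- fixture_library()

rand_junctions <- function(n, len = 12) {
  unique(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1)))
}

test_that("pairwise overlap percentages are per-side and exact", {
  a <- toy_repertoire(c("TGTAAATTT", "TGTCCCTTT", "TGTGGGTTT"))
  expect_equal(pairwise_overlap(a, a)$pctA, 100)
  b <- toy_repertoire(c("TGTTTTTTT"))
  o <- pairwise_overlap(a, b)
  expect_identical(o$n_shared, 0L)
  expect_equal(o$pctA, 0); expect_equal(o$pctB, 0)

  # designed sharing: 10 of 100 junctions shared
  reps <- lapply(1:2, function(i)
    simulate_repertoire(lib, 100, donor_id = paste0("d", i), seed = 130 + i))
  pw <- matrix(c(0L, 10L, 10L, 0L), 2, 2)
  sh <- share_clonotypes(reps, pairwise = pw, seed = 3)
  o2 <- pairwise_overlap(sh[[1]], sh[[2]])
  expect_identical(o2$n_shared, 10L)
  expect_equal(o2$pctA, 10.0)
})

test_that("exclusive variants follow the one-sample-only definition", {
  r1 <- toy_repertoire(c("TGTAAATTT", "TGTCCCTTT"))
  r2 <- toy_repertoire(c("TGTGGGTTT"))
  ex <- exclusive_variants(list(s1 = r1, s2 = r2))
  expect_setequal(ex$s1, c("TGTAAATTT", "TGTCCCTTT"))
  expect_setequal(ex$s2, "TGTGGGTTT")

  r3 <- toy_repertoire(c("TGTAAATTT", "TGTTTTTTT"))  # shares one with r1
  ex2 <- exclusive_variants(list(s1 = r1, s2 = r2, s3 = r3))
  expect_false("TGTAAATTT" %in% ex2$s1)
  expect_false("TGTAAATTT" %in% ex2$s3)

  # set identity: |A| = |exclusive_A| + |shared with >= 1 other|
  sets <- list(s1 = junctions(r1), s2 = junctions(r2), s3 = junctions(r3))
  for (nm in names(sets)) {
    shared_n <- sum(vapply(sets[[nm]], function(x)
      any(vapply(sets[names(sets) != nm], function(o) x %in% o, logical(1))),
      logical(1)))
    expect_identical(length(sets[[nm]]),
                     length(ex2[[nm]]) + shared_n)
  }
})

test_that("trilineage common pools and containment", {
  a <- toy_repertoire(c("AAAA", "CCCC", "GGGG"))  # junction identity only
  expect_equal(trilineage_common(a, a, a)$fraction, 100)
  d <- toy_repertoire(c("TTTT"))
  expect_length(trilineage_common(a, a, d)$common, 0)

  reps <- lapply(1:3, function(i)
    simulate_repertoire(lib, 150, lineage = c("CD15", "CD14", "CD3")[i],
                        seed = 140 + i))
  pw <- matrix(6L, 3, 3); diag(pw) <- 0L
  sh <- share_clonotypes(reps, pairwise = pw, common = 4L, seed = 5)
  tc <- trilineage_common(sh[[1]], sh[[2]], sh[[3]])
  expect_length(tc$common, 4)
  un <- length(unique(c(junctions(sh[[1]]), junctions(sh[[2]]),
                        junctions(sh[[3]]))))
  expect_equal(tc$fraction, 100 * 4 / un)
  # the common pool is contained in every pairwise shared set
  for (i in 1:2) for (j in (i + 1):3) {
    expect_true(all(tc$common %in%
                      pairwise_overlap(sh[[i]], sh[[j]])$shared))
  }
})

test_that("public/private partitions across donors", {
  donors <- lapply(1:5, function(i)
    simulate_repertoire(lib, 80, donor_id = paste0("d", i), seed = 150 + i))
  pw <- matrix(1L, 5, 5); diag(pw) <- 0L
  sh <- share_clonotypes(donors, pairwise = pw, common = 1L, seed = 9)
  names(sh) <- sprintf("d%d", 1:5)
  pp <- public_private(sh)
  expect_length(pp$public, 1)  # exactly the one variant implanted everywhere
  expect_true(all(pp$private_pct <= 100 & pp$private_pct >= 0))

  # fully disjoint donors: empty public set, 100% private
  dis <- lapply(1:3, function(i)
    simulate_repertoire(lib, 40, donor_id = paste0("x", i), seed = 160 + i))
  names(dis) <- sprintf("x%d", 1:3)
  pd <- public_private(dis)
  expect_length(pd$public, 0)
  expect_equal(unname(pd$private_pct), rep(100, 3))
})

test_that("turnover between states matches the designed replacement", {
  before <- toy_repertoire(c("AAAA", "CCCC", "GGGG", "TTTT"))
  expect_equal(turnover(before, before)$retained_pct, 100)
  after_dis <- toy_repertoire(c("ACGT", "TGCA"))
  t0 <- turnover(before, after_dis)
  expect_equal(t0$retained_pct, 0)
  expect_setequal(t0$lost, junctions(before))
  expect_error(turnover(before, toy_repertoire(character(0),
                                               copies = numeric(0))),
               "empty after")

  # designed differentiation: keep 10 of 100 clones, add 40 new ones
  mono <- simulate_repertoire(lib, 100, lineage = "CD14", seed = 171)
  fresh <- simulate_repertoire(lib, 40, lineage = "M1", seed = 172)
  kept <- mono$clonotypes$junction_nt[1:10]
  m1 <- toy_repertoire(c(kept, fresh$clonotypes$junction_nt))
  tv <- turnover(mono, m1)
  expect_equal(tv$retained_pct, 100 * 10 / 50)
  expect_length(tv$gained, 40)
})

test_that("comparison percentages match a naive independent implementation", {
  set.seed(19)
  for (case in 1:12) {
    sizes <- sample(5:200, 3, replace = TRUE)
    pool <- rand_junctions(260, 9)
    sets <- lapply(sizes, function(s) sample(pool, s))
    reps <- lapply(sets, toy_repertoire)
    names(reps) <- c("A", "B", "C")
    o <- pairwise_overlap(reps$A, reps$B)
    expect_equal(o$pctA, naive_pct_shared(sets[[1]], sets[[2]]))
    expect_equal(o$pctB, naive_pct_shared(sets[[2]], sets[[1]]))
    ex <- exclusive_variants(reps)
    nex <- naive_exclusive(sets)
    for (i in 1:3) expect_setequal(ex[[i]], nex[[i]])
    sr <- sharing_report(reps)
    expect_identical(sr$shared_counts["A", "B"],
                     length(intersect(sets[[1]], sets[[2]])))
    expect_true(isSymmetric(sr$shared_counts))
  }
})
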