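# Multi-repertoire set analyses: interlineage sharing, exclusive
# variants, trilineage-common pools, public/private partitions and
# before/after turnover. All comparisons are presence/absence on
# junction identity (nucleotide by default, amino acid by flag);
# frequencies play no role in sharing counts.

#' Junction set of a repertoire
#'
#' @param rep a `repertoire` or `true_repertoire`.
#' @param level `"nt"` or `"aa"`.
#' @return character vector of unique junctions.
#' @export
junctions <- function(rep, level = c("nt", "aa")) {
  level <- match.arg(level)
  cl <- rep$clonotypes
  if (level == "nt") unique(cl$junction_nt) else unique(cl$junction_aa)
}

#' Pairwise repertoire overlap
#'
#' @param repA,repB repertoires.
#' @param level junction identity level, `"nt"` or `"aa"`.
#' @return list: `shared` (junction set), `n_shared`, `pctA`, `pctB`
#'   (per-side percentages of each repertoire's own size; 0 for an empty
#'   repertoire).
#' @export
pairwise_overlap <- function(repA, repB, level = "nt") {
  a <- junctions(repA, level); b <- junctions(repB, level)
  shared <- intersect(a, b)
  list(shared = shared, n_shared = length(shared),
       pctA = if (length(a)) 100 * length(shared) / length(a) else 0,
       pctB = if (length(b)) 100 * length(shared) / length(b) else 0)
}

#' Exclusive variants per sample
#'
#' A junction is exclusive to a sample iff it appears in no other sample
#' of the grouping (one individual AND one lineage).
#'
#' @param reps named list of repertoires (>= 2).
#' @param level junction identity level.
#' @return named list of exclusive junction sets.
#' @export
exclusive_variants <- function(reps, level = "nt") {
  if (length(reps) < 2L) stop_input("need at least two samples")
  sets <- lapply(reps, junctions, level = level)
  all_j <- unlist(sets, use.names = FALSE)
  multi <- unique(all_j[duplicated(all_j)])
  lapply(sets, function(s) setdiff(s, multi))
}

#' Trilineage common pool
#'
#' Junctions simultaneously present in all three lineage repertoires of
#' one donor, as a percentage of the combined (union) pool.
#'
#' @param repN,repM,repT the three repertoires (e.g. neutrophil,
#'   monocyte, T cell).
#' @param level junction identity level.
#' @return list: `common` (junction set), `fraction` (percent of the
#'   union).
#' @export
trilineage_common <- function(repN, repM, repT, level = "nt") {
  a <- junctions(repN, level); b <- junctions(repM, level)
  cc <- junctions(repT, level)
  common <- intersect(intersect(a, b), cc)
  pool <- union(union(a, b), cc)
  list(common = common,
       fraction = if (length(pool)) 100 * length(common) / length(pool) else 0)
}

#' Public and private variants across donors
#'
#' Public variants are shared by all donors of a lineage; a donor's
#' private variants appear in no other donor.
#'
#' @param reps named list of repertoires, one per donor (>= 2).
#' @param level junction identity level.
#' @return list: `public` (junction set), `private` (per-donor sets),
#'   `private_pct` (per-donor private percentage of own size),
#'   `public_pct` (per-donor public percentage of own size).
#' @export
public_private <- function(reps, level = "nt") {
  if (length(reps) < 2L) stop_input("need at least two donors")
  sets <- lapply(reps, junctions, level = level)
  public <- Reduce(intersect, sets)
  priv <- lapply(seq_along(sets), function(i) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    setdiff(sets[[i]], others)
  })
  names(priv) <- names(sets)
  pct <- function(part) vapply(seq_along(sets), function(i) {
    n <- length(sets[[i]])
    if (n) 100 * length(part[[i]]) / n else 0
  }, numeric(1))
  pub_per <- lapply(seq_along(sets), function(i) public)
  list(public = public, private = priv,
       private_pct = setNames(pct(priv), names(sets)),
       public_pct = setNames(pct(pub_per), names(sets)))
}

#' Repertoire turnover between two states
#'
#' E.g. monocytes before and M1 macrophages after differentiation.
#'
#' @param rep_before,rep_after repertoires of the same donor/lineage at
#'   two states.
#' @param level junction identity level.
#' @return list: `retained_pct` (percent of the after-state also present
#'   before), `lost` (before-only set), `gained` (after-only set).
#' @export
turnover <- function(rep_before, rep_after, level = "nt") {
  b <- junctions(rep_before, level); a <- junctions(rep_after, level)
  if (!length(a)) stop_input("empty after-state: retained percentage undefined")
  list(retained_pct = 100 * length(intersect(b, a)) / length(a),
       lost = setdiff(b, a), gained = setdiff(a, b))
}

#' Multi-sample sharing report
#'
#' Pairwise shared-variant counts and per-side percentages over a set of
#' samples, with exclusive-variant counts per sample.
#'
#' @param reps named list of repertoires.
#' @param level junction identity level.
#' @return object of class `sharing_report`: `samples`, `n_variants`,
#'   `shared_counts` (symmetric matrix), `shared_pct` (row sample's
#'   perspective: percent of row sample's variants shared with the
#'   column sample), `exclusive` (sets), `exclusive_counts`.
#' @export
sharing_report <- function(reps, level = "nt") {
  n <- length(reps)
  labels <- names(reps) %||% sprintf("sample%d", seq_len(n))
  sets <- lapply(reps, junctions, level = level)
  sizes <- vapply(sets, length, integer(1))
  cnt <- matrix(0L, n, n, dimnames = list(labels, labels))
  pct <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { cnt[i, j] <- sizes[i]; pct[i, j] <- 100; next }
    s <- length(intersect(sets[[i]], sets[[j]]))
    cnt[i, j] <- s
    pct[i, j] <- if (sizes[i]) 100 * s / sizes[i] else 0
  }
  excl <- if (n >= 2L) exclusive_variants(reps, level) else sets
  structure(list(samples = labels, n_variants = setNames(sizes, labels),
                 shared_counts = cnt, shared_pct = pct,
                 exclusive = excl,
                 exclusive_counts = vapply(excl, length, integer(1)),
                 level = level),
            class = "sharing_report")
}

#' @export
print.sharing_report <- function(x, ...) {
  cat(sprintf("<sharing_report> %d samples (%s level)\n",
              length(x$samples), x$level))
  cat("shared variant counts:\n")
  print(x$shared_counts)
  invisible(x)
}
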