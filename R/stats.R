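# Per-repertoire diversity and composition statistics: unique-variant
# counts, V-J usage and coverage, CDR3 length spectra with a continuous
# Gaussianity score (the computational analog of spectratyping), junction
# trim/insert profiles, and mean +/- SD summaries.

# accept observed repertoires (v_call/frequency) and simulator truth
# (v_id/abundance) interchangeably
normalize_clonotypes <- function(cl) {
  if (is.null(cl$v_call) && !is.null(cl$v_id)) {
    cl$v_call <- cl$v_id; cl$j_call <- cl$j_id
  }
  if (is.null(cl$frequency) && !is.null(cl$abundance))
    cl$frequency <- cl$abundance
  cl
}

#' Count unique CDR3 variants
#'
#' @param rep a `repertoire` (or `true_repertoire`).
#' @param level `"nt"` (junction nucleotide, the uniqueness default) or
#'   `"aa"` (synonymous collapse).
#' @return integer count.
#' @export
count_unique <- function(rep, level = c("nt", "aa")) {
  level <- match.arg(level)
  cl <- rep$clonotypes
  if (!nrow(cl)) return(0L)
  if (level == "nt") length(unique(cl$junction_nt))
  else length(unique(cl$junction_aa))
}

#' V-J usage matrix
#'
#' Summed clonotype frequency per (V, J) pair; total mass 1 for a
#' non-empty repertoire.
#'
#' @param rep a `repertoire` (or `true_repertoire`).
#' @param library optional `germline_library` fixing the label order (all
#'   functional segments appear even with zero mass).
#' @return numeric matrix (V rows, J columns) of class `usage_matrix`.
#' @export
vj_usage <- function(rep, library = NULL) {
  cl <- normalize_clonotypes(rep$clonotypes)
  if (is.null(library)) {
    v_labels <- sort(unique(cl$v_call)); j_labels <- sort(unique(cl$j_call))
  } else {
    v_labels <- names(library_segments(library, "V", functional_only = TRUE))
    j_labels <- names(library_segments(library, "J", functional_only = TRUE))
  }
  m <- matrix(0, length(v_labels), length(j_labels),
              dimnames = list(v_labels, j_labels))
  if (nrow(cl)) {
    agg <- tapply(cl$frequency, list(cl$v_call, cl$j_call), sum)
    for (v in rownames(agg)) for (j in colnames(agg)) {
      if (!is.na(agg[v, j]) && v %in% v_labels && j %in% j_labels)
        m[v, j] <- agg[v, j]
    }
  }
  structure(m, class = c("usage_matrix", "matrix", "array"))
}

#' V-J combination coverage
#'
#' Observed distinct (V, J) combinations as a percentage of the library's
#' potential functional combinations, rounded to one decimal.
#'
#' @param usage a `usage_matrix` from [vj_usage()].
#' @param library a `germline_library` supplying the potential count.
#' @return list: `observed`, `potential`, `percentage`.
#' @export
vj_coverage <- function(usage, library) {
  potential <- enumerate_vj_combinations(library, functional_only = TRUE)$count
  observed <- sum(usage > 0)
  list(observed = observed, potential = potential,
       percentage = coverage_percentage(observed, potential))
}

#' @rdname vj_coverage
#' @param observed,potential combination counts; the potential count is a
#'   property of the reference catalog, not a constant.
#' @export
coverage_percentage <- function(observed, potential) {
  if (potential == 0) stop_input("potential combination count is zero")
  round(100 * observed / potential, 1)
}

#' Continuous Gaussianity score
#'
#' 1 minus the sup distance between the (weighted) empirical CDF of the
#' values and a normal CDF with matched mean and variance -- a discrete
#' KS-style statistic in `[0, 1]`, reported as a continuous score rather
#' than a hypothesis test. A degenerate single-valued input scores 0.
#'
#' @param values numeric vector (e.g. CDR3 lengths, insert lengths).
#' @param weights optional non-negative weights (clonotype frequencies).
#' @return numeric scalar in `[0, 1]`.
#' @export
gaussianity_score <- function(values, weights = NULL) {
  if (!length(values)) return(NA_real_)
  if (is.null(weights)) weights <- rep(1, length(values))
  w <- weights / sum(weights)
  o <- order(values)
  x <- values[o]; w <- w[o]
  agg <- tapply(w, x, sum)
  xs <- as.numeric(names(agg))
  if (length(xs) < 2L) return(0)  # degenerate single-length spectrum
  m <- sum(xs * agg)
  s <- sqrt(sum(agg * (xs - m)^2))
  if (s == 0) return(0)
  Fobs <- cumsum(agg)
  # continuity correction for lattice-valued data: compare the
  # right-continuous empirical CDF at the midpoint between support points
  delta <- min(diff(xs)) / 2
  D <- max(abs(Fobs - stats::pnorm(xs + delta, m, s)))
  1 - D
}

#' CDR3 length spectrum
#'
#' Clonotype-frequency mass per amino acid CDR3 length, with a
#' Gaussianity score (1 minus the sup distance between the observed
#' length CDF and a matched-moment normal CDF).
#'
#' @param rep a `repertoire`.
#' @return object of class `length_spectrum`: `lengths`, `mass`,
#'   `gaussianity_score`.
#' @export
length_spectrum <- function(rep) {
  cl <- normalize_clonotypes(rep$clonotypes)
  if (!nrow(cl)) stop_input("empty repertoire has no length spectrum")
  len <- nchar(cl$junction_nt) %/% 3L
  agg <- tapply(cl$frequency, len, sum)
  structure(list(lengths = as.integer(names(agg)),
                 mass = as.numeric(agg) / sum(agg),
                 gaussianity_score = gaussianity_score(len, cl$frequency)),
            class = "length_spectrum")
}

#' @export
print.length_spectrum <- function(x, ...) {
  cat(sprintf("<length_spectrum> %d lengths (aa), gaussianity %.3f\n",
              length(x$lengths), x$gaussianity_score))
  invisible(x)
}

#' Trim and insert profiles
#'
#' Frequency-weighted histograms of V-end trimming, J-end trimming and
#' nontemplated insert length across a repertoire's junction
#' decompositions, plus the Gaussianity score of the insert lengths.
#'
#' @param decomp data frame from [decompose_junction()].
#' @param weights clonotype frequencies (uniform when `NULL`).
#' @return list of named histograms `v_trim`, `j_trim`, `n_len` (masses
#'   summing to 1 each) and `n_len_gaussianity`.
#' @export
trim_insert_profiles <- function(decomp, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(decomp))
  w <- weights / sum(weights)
  hist1 <- function(v) {
    agg <- tapply(w, v, sum)
    setNames(as.numeric(agg), names(agg))
  }
  list(v_trim = hist1(decomp$v_trim),
       j_trim = hist1(decomp$j_trim),
       n_len = hist1(decomp$n_len),
       n_len_gaussianity = gaussianity_score(decomp$n_len, weights))
}

#' Mean +/- SD summary
#'
#' @param values numeric vector, length >= 1.
#' @param sd_convention `"population"` (n divisor; the replication
#'   default) or `"sample"` (n-1 divisor).
#' @return list: `n`, `mean`, `sd`, `min`, `max`, `sd_convention`.
#' @export
summarize_values <- function(values, sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  n <- length(values)
  if (n < 1L) stop_input("summarize_values needs at least one value")
  m <- mean(values)
  s <- if (n == 1L) 0 else {
    ss <- sum((values - m)^2)
    if (sd_convention == "population") sqrt(ss / n) else sqrt(ss / (n - 1))
  }
  list(n = n, mean = m, sd = s, min = min(values), max = max(values),
       sd_convention = sd_convention)
}
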