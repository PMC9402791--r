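# Synthetic-data module: ground-truth repertoires and paired-end amplicon
# reads with the statistical structure the downstream analysis assumes --
# clonal abundance skew, junction diversity, PCR/sequencing substitution
# errors with clonal expansion of early PCR errors, chimeric reads, and
# designed cross-sample clonotype sharing.

#' Amplicon error model
#'
#' Substitution-only noise model for the simulated ARM-PCR + short-read
#' assay. PCR errors are compounded over `pcr_cycles` with clonal
#' expansion of early errors (an error arising at cycle c is inherited by
#' a final read with probability 2^-c); sequencing errors are independent
#' per base per mate. Chimeric reads splice two parent templates at a
#' uniform V-region breakpoint.
#'
#' @param seq_error_rate per-base sequencing substitution probability.
#' @param pcr_error_rate per-base per-cycle PCR substitution probability.
#' @param pcr_cycles number of PCR cycles.
#' @param chimera_rate fraction of reads formed from two parent templates.
#' @param read_length mate length in nt.
#' @param min_overlap minimum mate overlap the read geometry must allow.
#' @param seed optional default seed carried by the model.
#' @return object of class `error_model`.
#' @export
error_model <- function(seq_error_rate = 1e-3, pcr_error_rate = 1e-4,
                        pcr_cycles = 20L, chimera_rate = 0.005,
                        read_length = 100L, min_overlap = 30L, seed = NULL) {
  rates <- c(seq_error_rate, pcr_error_rate, chimera_rate)
  if (any(rates < 0 | rates > 1)) stop_input("error rates must be in [0, 1]")
  if (read_length < 2L * min_overlap / 2L)  # read must span half the overlap
    stop_input("read_length too short for the configured overlap")
  structure(list(seq_error_rate = seq_error_rate,
                 pcr_error_rate = pcr_error_rate,
                 pcr_cycles = as.integer(pcr_cycles),
                 chimera_rate = chimera_rate,
                 read_length = as.integer(read_length),
                 min_overlap = as.integer(min_overlap),
                 seed = seed),
            class = "error_model")
}

#' Zero-noise error model
#'
#' Convenience constructor: all error and chimera rates zero.
#' @param ... overrides passed to [error_model()].
#' @export
noise_free_model <- function(...) {
  error_model(seq_error_rate = 0, pcr_error_rate = 0, chimera_rate = 0, ...)
}

#' Gaussian / bimodal samplers for inserted-nucleotide lengths
#'
#' Return a function drawing `k` integer N/D-region lengths. The Gaussian
#' sampler emulates the bell-shaped insert profiles seen in mononuclear
#' cells; the bimodal one the non-Gaussian profiles seen in neutrophils.
#'
#' @param mean,sd Gaussian parameters (nt).
#' @param mean1,mean2 the two modes of the bimodal sampler.
#' @param max upper truncation (keeps amplicons within read-pair span).
#' @return function(k) -> integer vector.
#' @export
gaussian_n_len <- function(mean = 12, sd = 3, max = 24) {
  force(mean); force(sd); force(max)
  function(k) pmax(0L, pmin(as.integer(max), as.integer(round(rnorm(k, mean, sd)))))
}

#' @rdname gaussian_n_len
#' @export
bimodal_n_len <- function(mean1 = 4, mean2 = 18, sd = 1.5, max = 24) {
  force(mean1); force(mean2); force(sd); force(max)
  function(k) {
    m <- ifelse(runif(k) < 0.5, mean1, mean2)
    pmax(0L, pmin(as.integer(max), as.integer(round(rnorm(k, m, sd)))))
  }
}

#' Simulate a ground-truth repertoire
#'
#' Draws `n_clonotypes` distinct productive rearrangements from the
#' germline library: uniform functional V/J choice, uniform end trimming
#' up to the configured maxima, nontemplated/D-derived insert lengths
#' from `n_len_sampler`, random insert bases, and Zipf-like power-law
#' abundances (frequency of rank r proportional to r^-`abundance_shape`).
#'
#' @param library a `germline_library`.
#' @param n_clonotypes number of distinct clonotypes.
#' @param abundance_shape power-law exponent of the rank-frequency law.
#' @param trim_max_v,trim_max_j maximum nucleotides trimmed from the V 3'
#'   and J 5' coding ends.
#' @param n_len_sampler function(k) -> integer insert lengths; see
#'   [gaussian_n_len()].
#' @param productive_only keep only in-frame, stop-free junctions with
#'   intact anchors (rejection sampling).
#' @param donor_id,lineage sample metadata.
#' @param seed RNG seed; identical seed + parameters give bit-identical
#'   output.
#' @return object of class `true_repertoire` with a `clonotypes` data
#'   frame (`clone_id`, `v_id`, `j_id`, `v_trim`, `j_trim`, `n_region`,
#'   `n_len`, `full_nt`, `junction_nt`, `junction_aa`, `productive`,
#'   `abundance`).
#' @export
simulate_repertoire <- function(library, n_clonotypes, abundance_shape = 1,
                                trim_max_v = 9L, trim_max_j = 6L,
                                n_len_sampler = gaussian_n_len(),
                                productive_only = TRUE,
                                donor_id = "donorI", lineage = "CD3",
                                seed = 1L) {
  if (n_clonotypes < 0) stop_input("n_clonotypes must be >= 0")
  vs <- library_segments(library, "V", functional_only = TRUE)
  js <- library_segments(library, "J", functional_only = TRUE)
  cs <- library_segments(library, "C")
  if (n_clonotypes > 0 && (!length(vs) || !length(js)))
    stop_input("library needs at least one functional V and J segment")
  c_seq <- if (length(cs)) cs[[1]]$sequence else ""
  empty <- data.frame(clone_id = character(0), v_id = character(0),
                      j_id = character(0), v_trim = integer(0),
                      j_trim = integer(0), n_region = character(0),
                      n_len = integer(0), full_nt = character(0),
                      junction_nt = character(0), junction_aa = character(0),
                      productive = logical(0), abundance = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_clonotypes == 0) {
    return(structure(list(donor_id = donor_id, lineage = lineage,
                          seed = seed, clonotypes = empty),
                     class = "true_repertoire"))
  }
  v_seq <- segment_sequences(vs); j_seq <- segment_sequences(js)
  v_anchor <- vapply(vs, `[[`, integer(1), "anchor_offset")
  j_anchor <- vapply(js, `[[`, integer(1), "anchor_offset")

  with_seed(seed, {
    got <- empty
    seen <- character(0)
    attempts <- 0L
    max_attempts <- 60L * n_clonotypes + 1000L
    while (nrow(got) < n_clonotypes) {
      need <- n_clonotypes - nrow(got)
      k <- max(need * 2L, 16L)
      attempts <- attempts + k
      if (attempts > max_attempts)
        stop_input("junction space exhausted: cannot realize ", n_clonotypes,
                   " distinct clonotypes under the trim/insert limits")
      vi <- sample.int(length(v_seq), k, replace = TRUE)
      ji <- sample.int(length(j_seq), k, replace = TRUE)
      vt <- sample.int(trim_max_v + 1L, k, replace = TRUE) - 1L
      jt <- sample.int(trim_max_j + 1L, k, replace = TRUE) - 1L
      nl <- n_len_sampler(k)
      nreg <- vapply(nl, function(m)
        paste(sample(DNA_BASES, m, replace = TRUE), collapse = ""), character(1))
      vlen <- nchar(v_seq)[vi]; jlen <- nchar(j_seq)[ji]
      v_part <- substr(v_seq[vi], 1L, vlen - vt)
      j_part <- substr(j_seq[ji], jt + 1L, jlen)
      full <- paste0(v_part, nreg, j_part, c_seq)
      anchors_ok <- (vt <= vlen - v_anchor[vi] - 3L) & (jt <= j_anchor[ji])
      jn_len <- (vlen - v_anchor[vi] - vt) + nl + (j_anchor[ji] + 3L - jt)
      junction <- ifelse(anchors_ok,
                         substr(full, v_anchor[vi] + 1L, v_anchor[vi] + jn_len),
                         NA_character_)
      aa <- ifelse(is.na(junction) | jn_len %% 3L != 0L, NA_character_,
                   translate_nt(ifelse(is.na(junction), "", junction)))
      productive <- anchors_ok & jn_len %% 3L == 0L &
        !is.na(aa) & !grepl("*", aa, fixed = TRUE)
      keep <- if (productive_only) productive else rep(TRUE, k)
      keep <- keep & !is.na(junction) & !duplicated(junction) &
        !(junction %in% seen)
      if (!any(keep)) next
      idx <- which(keep)[seq_len(min(need, sum(keep)))]
      seen <- c(seen, junction[idx])
      got <- rbind(got, data.frame(
        clone_id = "",
        v_id = names(v_seq)[vi[idx]], j_id = names(j_seq)[ji[idx]],
        v_trim = vt[idx], j_trim = jt[idx],
        n_region = nreg[idx], n_len = nl[idx],
        full_nt = full[idx], junction_nt = junction[idx],
        junction_aa = aa[idx], productive = productive[idx],
        abundance = 0, stringsAsFactors = FALSE))
    }
    got$clone_id <- sprintf("c%05d", seq_len(nrow(got)))
    r <- seq_len(nrow(got))
    w <- r^(-abundance_shape)
    got$abundance <- w / sum(w)
    rownames(got) <- NULL
    structure(list(donor_id = donor_id, lineage = lineage, seed = seed,
                   clonotypes = got),
              class = "true_repertoire")
  })
}

#' @export
print.true_repertoire <- function(x, ...) {
  cat(sprintf("<true_repertoire> %s/%s: %d clonotypes (seed %s)\n",
              x$donor_id, x$lineage, nrow(x$clonotypes),
              format(x$seed)))
  invisible(x)
}

#' Implant designed clonotype sharing across repertoires
#'
#' Rewrites selected clonotypes so that each pair of repertoires shares
#' exactly the designed number of junction sequences and all repertoires
#' share exactly `common` junctions (the pairwise targets are totals and
#' therefore must be >= `common`). Implanted clonotypes keep the
#' recipient's abundance, so abundances still sum to 1.
#'
#' @param repertoires list of `true_repertoire` objects.
#' @param pairwise symmetric integer matrix of designed pairwise shared
#'   counts (diagonal ignored); `NULL` means all zero.
#' @param common number of junctions shared by every repertoire.
#' @param seed RNG seed for slot selection.
#' @return list of modified `true_repertoire` objects.
#' @export
share_clonotypes <- function(repertoires, pairwise = NULL, common = 0L,
                             seed = 1L) {
  n <- length(repertoires)
  if (n < 2L) stop_input("need at least two repertoires")
  sizes <- vapply(repertoires, function(r) nrow(r$clonotypes), integer(1))
  if (is.null(pairwise)) pairwise <- matrix(0L, n, n)
  pairwise <- as.matrix(pairwise)
  if (!all(dim(pairwise) == c(n, n)) || !isTRUE(all.equal(pairwise, t(pairwise))))
    stop_input("pairwise must be a symmetric ", n, "x", n, " matrix")
  if (common > 0 && any(pairwise[upper.tri(pairwise)] < common))
    stop_input("infeasible design: common exceeds a pairwise target")
  need <- vapply(seq_len(n), function(i) {
    extra <- sum(pmax(pairwise[i, -i] - common, 0L))
    as.integer(common + extra)
  }, integer(1))
  if (any(need > sizes))
    stop_input("infeasible design: repertoire too small for its sharing load")

  with_seed(seed, {
    id_cols <- c("v_id", "j_id", "v_trim", "j_trim", "n_region", "n_len",
                 "full_nt", "junction_nt", "junction_aa", "productive")
    touched <- lapply(sizes, function(s) logical(s))
    pick <- function(i, k) {
      free <- which(!touched[[i]])
      sel <- if (length(free) == 1L) free else sample(free, k)
      touched[[i]][sel] <<- TRUE
      sel
    }
    implant <- function(group, k) {
      if (k <= 0L) return(invisible())
      donor_rep <- group[1L]
      donors <- pick(donor_rep, k)
      for (r in group[-1L]) {
        slots <- pick(r, k)
        repertoires[[r]]$clonotypes[slots, id_cols] <<-
          repertoires[[donor_rep]]$clonotypes[donors, id_cols]
      }
    }
    implant(seq_len(n), as.integer(common))
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      implant(c(i, j), as.integer(pairwise[i, j] - common))
    }
    # verify the construction produced exactly the designed intersections
    juncs <- lapply(repertoires, function(r) r$clonotypes$junction_nt)
    if (any(vapply(juncs, anyDuplicated, integer(1)) > 0L))
      stop_input("sharing design produced a duplicate junction (retry with another seed)")
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      got <- length(intersect(juncs[[i]], juncs[[j]]))
      if (got != pairwise[i, j])
        stop_input("sharing construction check failed for pair (", i, ",", j, ")")
    }
    repertoires
  })
}

#' Mix two ground-truth repertoires
#'
#' Emulates the cell-titration control: abundances are rescaled to
#' `(1 - minor_fraction) * major + minor_fraction * minor` and the
#' clonotype lists merged (junctions present in both are summed).
#'
#' @param major,minor `true_repertoire` objects.
#' @param minor_fraction proportion in `[0, 1]`.
#' @return a `true_repertoire` (metadata from `major`).
#' @export
mix_repertoires <- function(major, minor, minor_fraction) {
  if (minor_fraction < 0 || minor_fraction > 1)
    stop_input("minor_fraction must be in [0, 1]")
  a <- major$clonotypes; b <- minor$clonotypes
  a$abundance <- a$abundance * (1 - minor_fraction)
  b$abundance <- b$abundance * minor_fraction
  both <- rbind(a, b)
  both <- both[both$abundance > 0, , drop = FALSE]
  if (anyDuplicated(both$junction_nt)) {
    agg <- tapply(both$abundance, both$junction_nt, sum)
    both <- both[!duplicated(both$junction_nt), , drop = FALSE]
    both$abundance <- as.numeric(agg[both$junction_nt])
  }
  both$abundance <- both$abundance / sum(both$abundance)
  rownames(both) <- NULL
  structure(list(donor_id = major$donor_id, lineage = major$lineage,
                 seed = major$seed, clonotypes = both,
                 minor_fraction = minor_fraction),
            class = "true_repertoire")
}

#' Simulate paired-end amplicon reads
#'
#' Reads are sampled from clonotypes proportionally to abundance. PCR
#' errors are applied to the per-read template before sequencing errors:
#' mutation events from the first `min(8, pcr_cycles)` cycles are
#' generated explicitly per clonotype and inherited by each final read
#' with probability 2^-cycle (clonally expanded artifacts); the remaining
#' cycles act as an independent per-read per-base rate. A fraction
#' `chimera_rate` of reads splice a second parent template at a uniform
#' V-region breakpoint. Each mate is `read_length` nt from the two
#' amplicon ends, so every pair covers the junction with at least the
#' configured overlap.
#'
#' @param repertoire a `true_repertoire`.
#' @param n_reads number of read pairs.
#' @param model an [error_model()].
#' @param seed RNG seed (defaults to the model's seed, then 1).
#' @return object of class `read_set`: `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`, and a `truth` data frame (`read_id`, `parent_id`,
#'   `second_parent_id`, `junction_error`).
#' @export
simulate_reads <- function(repertoire, n_reads, model = error_model(),
                           seed = NULL) {
  seed <- seed %||% model$seed %||% 1L
  cl <- repertoire$clonotypes
  if (n_reads > 0 && nrow(cl) == 0) stop_input("empty repertoire")
  rl <- model$read_length
  if (n_reads == 0) {
    return(structure(list(read_id = character(0), seq1 = character(0),
                          qual1 = character(0), seq2 = character(0),
                          qual2 = character(0),
                          truth = data.frame(read_id = character(0),
                                             parent_id = character(0),
                                             second_parent_id = character(0),
                                             junction_error = logical(0),
                                             stringsAsFactors = FALSE),
                          model = model),
                     class = "read_set"))
  }
  amp0 <- cl$full_nt
  L0 <- nchar(amp0)
  jlen0 <- nchar(cl$junction_nt)
  v_anchor_1b <- 61L  # junction start on the amplicon (fixed library geometry)

  with_seed(seed, {
    parent <- sample.int(nrow(cl), n_reads, replace = TRUE, prob = cl$abundance)
    chim <- runif(n_reads) < model$chimera_rate & nrow(cl) > 1L
    parent2 <- rep(NA_integer_, n_reads)
    if (any(chim)) {
      idx <- which(chim)
      p2 <- sample.int(nrow(cl), length(idx), replace = TRUE, prob = cl$abundance)
      same <- p2 == parent[idx]
      while (any(same)) {
        p2[same] <- sample.int(nrow(cl), sum(same), replace = TRUE,
                               prob = cl$abundance)
        same <- p2 == parent[idx]
      }
      parent2[idx] <- p2
    }
    bp <- rep(NA_integer_, n_reads)
    if (any(chim)) bp[chim] <- sample(16:70, sum(chim), replace = TRUE)

    tmpl <- ifelse(chim, parent2, parent)     # template supplying junction + J/C side
    amps <- amp0[tmpl]
    if (any(chim)) {
      i <- which(chim)
      amps[i] <- paste0(substr(amp0[parent[i]], 1L, bp[i]),
                        substr(amp0[parent2[i]], bp[i] + 1L, L0[parent2[i]]))
    }
    Lamp <- L0[tmpl]
    jend <- v_anchor_1b - 1L + jlen0[tmpl]
    junction_error <- chim & bp >= v_anchor_1b

    # --- PCR errors ------------------------------------------------------
    sub_read <- integer(0); sub_pos <- integer(0); sub_alt <- character(0)
    p <- model$pcr_error_rate
    cyc <- model$pcr_cycles
    if (p > 0 && cyc > 0) {
      c_split <- min(8L, cyc)
      reads_by_clone <- split(which(!chim), parent[!chim])
      for (ci in names(reads_by_clone)) {
        rids <- reads_by_clone[[ci]]
        Lc <- L0[as.integer(ci)]
        for (cc in seq_len(c_split)) {
          n_ev <- rpois(1L, 2^(cc - 1L) * Lc * p)
          if (n_ev == 0L) next
          for (ev in seq_len(n_ev)) {
            pos <- sample.int(Lc, 1L)
            carriers <- rids[runif(length(rids)) < 2^(-cc)]
            if (!length(carriers)) next
            ref <- substr(amp0[as.integer(ci)], pos, pos)
            alt <- sample(setdiff(DNA_BASES, ref), 1L)
            sub_read <- c(sub_read, carriers)
            sub_pos <- c(sub_pos, rep(pos, length(carriers)))
            sub_alt <- c(sub_alt, rep(alt, length(carriers)))
          }
        }
      }
      p_late <- 1 - (1 - p)^(cyc - c_split)
      if (p_late > 0) {
        n_err <- rbinom(n_reads, Lamp, p_late)
        hot <- which(n_err > 0L)
        for (i in hot) {
          pos <- sample.int(Lamp[i], n_err[i])
          ref <- substring(amps[i], pos, pos)
          alt <- random_bases(length(pos), not = ref)
          sub_read <- c(sub_read, rep(i, length(pos)))
          sub_pos <- c(sub_pos, pos)
          sub_alt <- c(sub_alt, alt)
        }
      }
      if (length(sub_read)) {
        junction_error[unique(sub_read[sub_pos >= v_anchor_1b &
                                       sub_pos <= jend[sub_read]])] <- TRUE
        f <- factor(sub_read)
        amps[as.integer(levels(f))] <- cpp_apply_subs(
          amps[as.integer(levels(f))], split(sub_pos, f), split(sub_alt, f))
      }
    }

    # --- read extraction + sequencing errors -----------------------------
    r1 <- substr(amps, 1L, rl)
    r2 <- revcomp(substring(amps, Lamp - rl + 1L, Lamp))
    e <- model$seq_error_rate
    if (e > 0) {
      for (mate in 1:2) {
        n_err <- rbinom(n_reads, rl, e)
        hot <- which(n_err > 0L)
        if (!length(hot)) next
        pos_l <- lapply(hot, function(i) sample.int(rl, n_err[i]))
        seqs <- if (mate == 1L) r1[hot] else r2[hot]
        alt_l <- lapply(seq_along(hot), function(k) {
          ref <- substring(seqs[k], pos_l[[k]], pos_l[[k]])
          random_bases(length(ref), not = ref)
        })
        mut <- cpp_apply_subs(seqs, pos_l, alt_l)
        # junction hit check in amplicon coordinates
        for (k in seq_along(hot)) {
          i <- hot[k]
          ap <- if (mate == 1L) pos_l[[k]] else Lamp[i] - pos_l[[k]] + 1L
          if (any(ap >= v_anchor_1b & ap <= jend[i])) junction_error[i] <- TRUE
        }
        if (mate == 1L) r1[hot] <- mut else r2[hot] <- mut
      }
    }
    ids <- sprintf("r%06d", seq_len(n_reads))
    qual <- strrep("?", rl)  # constant Q30-equivalent
    structure(list(read_id = ids, seq1 = r1, qual1 = rep(qual, n_reads),
                   seq2 = r2, qual2 = rep(qual, n_reads),
                   truth = data.frame(
                     read_id = ids,
                     parent_id = cl$clone_id[parent],
                     second_parent_id = ifelse(chim, cl$clone_id[parent2],
                                               NA_character_),
                     junction_error = junction_error,
                     stringsAsFactors = FALSE),
                   model = model),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d read pairs (%d flagged junction errors, %d chimeric)\n",
              length(x$read_id), sum(x$truth$junction_error),
              sum(!is.na(x$truth$second_parent_id))))
  invisible(x)
}
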