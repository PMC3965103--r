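# Five-criteria evaluation and the verdict logic: a read pattern either
# supports canonical Drosha/Dicer processing, refutes it, or is too sparse
# to judge; structure-only failures are a fourth, flagged outcome.

#' Evaluate the five high-confidence criteria on one locus
#'
#' \describe{
#'   \item{c1 read depth}{at least \code{min_reads_per_arm} no-mismatch
#'     reads assigned to each of the two possible mature products, counts
#'     summed across datasets.}
#'   \item{c2 overhang}{both 3' overhangs of the most-abundant-read duplex
#'     defined and within \code{[overhang_min, overhang_max]} nt. The
#'     annotated-pair geometry is recorded alongside in the metrics.}
#'   \item{c3 5' homogeneity}{at least \code{min_modal5p_fraction} of each
#'     arm's reads share the modal 5' start.}
#'   \item{c4 energy}{folding free energy strictly below
#'     \code{max_energy_per_nt} kcal/mol/nt.}
#'   \item{c5 mature pairing}{at least \code{min_mature_paired_fraction}
#'     of mature bases paired in the structure.}
#' }
#'
#' @param hp [hairpin()] with structure and mfe set.
#' @param matures mature loci covering both arms (one may be an inferred
#'   star).
#' @param stack aggregated [build_stack()] result.
#' @param th thresholds.
#' @param geometry optional precomputed duplex geometry for c2; computed
#'   from the most abundant reads when NULL.
#' @return object of class \code{"criteria_result"}.
#' @export
evaluate_criteria <- function(hp, matures, stack, th = thresholds(),
                              geometry = NULL) {
  stopifnot(inherits(hp, "hairpin"), inherits(stack, "read_stack"))
  if (is.null(hp$structure)) {
    stop(sprintf("hairpin '%s' has no structure; fold it or supply one",
                 hp$id), call. = FALSE)
  }
  pt <- pair_table(hp$structure)
  L <- nchar(hp$sequence)
  arms <- vapply(matures, `[[`, "", "arm")
  m5 <- if ("5p" %in% arms) matures[[match("5p", arms)]] else NULL
  m3 <- if ("3p" %in% arms) matures[[match("3p", arms)]] else NULL

  # criterion 2 geometry from the most abundant read on each arm
  notes <- character(0)
  if (is.null(geometry)) {
    geometry <- list(overhang_5p = NA_integer_, overhang_3p = NA_integer_,
                     derived_from = "most_abundant_reads")
    top5 <- stack$most_abundant[["5p"]]
    top3 <- stack$most_abundant[["3p"]]
    if (!is.null(top5) && !is.null(top3)) {
      r5 <- mature_locus("top5", hp$id, top5$start,
                         top5$start + nchar(top5$sequence) - 1L, "5p",
                         "annotated", hairpin_length = L,
                         len_min = 1L, len_max = L)
      r3 <- mature_locus("top3", hp$id, top3$start,
                         top3$start + nchar(top3$sequence) - 1L, "3p",
                         "annotated", hairpin_length = L,
                         len_min = 1L, len_max = L)
      geometry <- duplex_overhangs(r5, r3, pt, th$overhang_walk_limit,
                                   "most_abundant_reads")
    } else {
      notes <- c(notes, "duplex geometry undefined: reads missing on one arm")
    }
  }
  ann_geom <- list(overhang_5p = NA_integer_, overhang_3p = NA_integer_)
  if (!is.null(m5) && !is.null(m3)) {
    ann_geom <- duplex_overhangs(m5, m3, pt, th$overhang_walk_limit,
                                 "annotated_pair")
  }
  epn <- if (is.null(hp$mfe)) NA_real_ else energy_per_nt(hp$mfe, L)
  if (is.null(hp$mfe)) notes <- c(notes, "no folding energy available")
  metrics <- list(
    reads_5p = stack$per_arm_total[["5p"]],
    reads_3p = stack$per_arm_total[["3p"]],
    overhang_5p = geometry$overhang_5p,
    overhang_3p = geometry$overhang_3p,
    geometry_source = geometry$derived_from,
    annotated_overhang_5p = ann_geom$overhang_5p,
    annotated_overhang_3p = ann_geom$overhang_3p,
    modal5p_fraction_5p = stack$modal5p_fraction[["5p"]],
    modal5p_fraction_3p = stack$modal5p_fraction[["3p"]],
    mfe = if (is.null(hp$mfe)) NA_real_ else hp$mfe,
    energy_per_nt = epn,
    mature_paired_fraction = mature_paired_fraction(matures, pt),
    multi_hit = isTRUE(stack$any_multi_hit))
  booleans <- criteria_from_metrics(metrics, th)
  if (booleans[["c1"]] && (is.na(metrics$overhang_5p) ||
                           is.na(metrics$overhang_3p))) {
    notes <- c(notes, "overhang undefined despite sufficient reads")
  }
  cr <- criteria_result(booleans, metrics)
  attr(cr, "notes") <- notes
  cr
}

#' Turn a criteria result into a confidence verdict
#'
#' \code{HIGH_CONFIDENCE} iff all five criteria hold. Otherwise the locus
#' is judged in the order insufficiency before inconsistency:
#' \code{INSUFFICIENT_EVIDENCE} when read depth (c1) fails,
#' \code{PATTERN_INCONSISTENT} when reads are plentiful but the overhang
#' or 5'-homogeneity pattern (c2/c3) contradicts canonical processing, and
#' \code{STRUCTURE_FAIL} when only the structure criteria (c4/c5) fail —
#' an explicitly flagged extension beyond the three read-pattern
#' assertions, since a well-read locus on a badly folding precursor fits
#' none of them.
#'
#' @param criteria a \code{"criteria_result"}.
#' @param stack the read stack (for notes).
#' @param th thresholds.
#' @param multiloop was the hairpin structure branched?
#' @return a \code{"confidence_call"}.
#' @export
classify <- function(criteria, stack, th = thresholds(), multiloop = FALSE) {
  b <- criteria_booleans(criteria)
  verdict <- if (all(b)) "HIGH_CONFIDENCE"
             else if (!b[["c1"]]) "INSUFFICIENT_EVIDENCE"
             else if (!b[["c2"]] || !b[["c3"]]) "PATTERN_INCONSISTENT"
             else "STRUCTURE_FAIL"
  notes <- attr(criteria, "notes")
  if (is.null(notes)) notes <- character(0)
  if (multiloop) {
    notes <- c(notes, "branched (multiloop) hairpin structure")
    if (verdict == "HIGH_CONFIDENCE") {
      # conservative: a branched precursor never enters the HC set
      verdict <- "STRUCTURE_FAIL"
      notes <- c(notes, "demoted: multiloop structure blocks high confidence")
    }
  }
  confidence_call(stack$hairpin_id, verdict, criteria, notes)
}

#' Analyze one locus end to end
#'
#' Resolves the structure (given, else folded), locates the loop, infers
#' the star partner when only one arm is annotated, maps and aggregates
#' the reads, evaluates the criteria and classifies.
#'
#' @param hp [hairpin()].
#' @param matures annotated mature loci on \code{hp} (one or two).
#' @param read_sets list of read data.frames (one per dataset).
#' @param th thresholds.
#' @param refold force de novo folding even when a structure was supplied.
#' @param per_dataset evaluate the read-depth criterion per dataset (some
#'   single dataset must reach the depth threshold on both arms) instead
#'   of on counts summed across datasets. Summed counts are the default
#'   and the convention used in locus displays; this mode is stricter.
#' @return list (a locus bundle) with \code{hairpin}, \code{matures}
#'   (annotated + inferred), \code{stack}, \code{partition}, \code{call}.
#' @export
analyze_locus <- function(hp, matures, read_sets, th = thresholds(),
                          refold = FALSE, per_dataset = FALSE) {
  if (is.null(hp$structure) || refold) {
    f <- fold(hp$sequence)
    hp$structure <- f$structure
    hp$mfe <- f$mfe
    structure_source <- "folded"
  } else {
    structure_source <- "given"
  }
  pt <- pair_table(hp$structure)
  partition <- find_loop(pt)
  arms <- vapply(matures, `[[`, "", "arm")
  notes <- character(0)
  if (!all(c("5p", "3p") %in% arms) && length(matures) >= 1L) {
    star <- infer_star(matures[[1L]], pt, nchar(hp$sequence))
    if (!is.null(star)) {
      matures <- c(matures, list(star))
    } else {
      notes <- c(notes, "star inference failed: no paired base in mature")
    }
  }
  alns <- lapply(read_sets, function(rs) map_reads_exact(rs, hp, th))
  stacks <- lapply(alns, build_stack, matures = matures,
                   partition = partition, hairpin_id = hp$id, th = th)
  stack <- if (length(stacks) == 1L) stacks[[1L]]
           else aggregate_stacks(stacks, matures, partition, th)
  criteria <- evaluate_criteria(hp, matures, stack, th)
  criteria$metrics$structure_source <- structure_source
  if (per_dataset && criteria$c1_read_depth) {
    # stricter reading: the depth threshold must be met by both arms
    # within at least one single dataset
    per_ds_ok <- any(vapply(stacks, function(s)
      s$per_arm_total[["5p"]] >= th$min_reads_per_arm &&
      s$per_arm_total[["3p"]] >= th$min_reads_per_arm, NA))
    if (!per_ds_ok) {
      criteria$c1_read_depth <- FALSE
      attr(criteria, "notes") <- c(attr(criteria, "notes"),
        "read depth met only on summed counts (per-dataset mode)")
    }
  }
  call <- classify(criteria, stack, th, multiloop = partition$multiloop)
  call$notes <- unique(c(call$notes, notes))
  list(hairpin = hp, matures = matures, stack = stack,
       partition = partition, call = call)
}

#' Classify a batch of loci
#'
#' Applies the criteria to each locus bundle independently; per-locus
#' errors are recorded and the batch continues. Verdict tallies are
#' attached as an attribute.
#'
#' @param loci list of bundles, each with elements \code{hairpin},
#'   \code{matures}, \code{read_sets}.
#' @param th thresholds.
#' @param overrides optional data.frame of manual promotions/demotions
#'   with columns \code{locus_id}, \code{forced_verdict}, \code{reason};
#'   matching calls get verdict \code{MANUAL} semantics: the forced
#'   verdict with the reason recorded in notes.
#' @param per_dataset see [analyze_locus()].
#' @return list of \code{"confidence_call"}s with attributes
#'   \code{tallies} (named verdict counts) and \code{failures}.
#' @export
classify_batch <- function(loci, th = thresholds(), overrides = NULL,
                           per_dataset = FALSE) {
  calls <- list()
  failures <- character(0)
  for (bundle in loci) {
    res <- tryCatch(
      analyze_locus(bundle$hairpin, bundle$matures, bundle$read_sets, th,
                    per_dataset = per_dataset),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", bundle$hairpin$id,
                                      conditionMessage(res)))
      next
    }
    calls[[length(calls) + 1L]] <- res$call
  }
  if (!is.null(overrides) && nrow(overrides)) {
    for (k in seq_along(calls)) {
      i <- match(calls[[k]]$hairpin_id, overrides$locus_id)
      if (!is.na(i)) {
        calls[[k]]$notes <- c(calls[[k]]$notes,
                              sprintf("MANUAL override from %s: %s",
                                      calls[[k]]$verdict,
                                      overrides$reason[i]))
        calls[[k]]$verdict <- overrides$forced_verdict[i]
      }
    }
  }
  tallies <- table(factor(vapply(calls, `[[`, "", "verdict"),
                          levels = VERDICTS))
  attr(calls, "tallies") <- tallies
  attr(calls, "failures") <- failures
  calls
}
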