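# Shared domain types: hairpin, mature locus, thresholds, criteria result,
# confidence call. All coordinates are 1-based inclusive on the hairpin.

#' @importFrom stats setNames
NULL

VERDICTS <- c("HIGH_CONFIDENCE", "INSUFFICIENT_EVIDENCE",
              "PATTERN_INCONSISTENT", "STRUCTURE_FAIL", "MANUAL")
ARMS <- c("5p", "3p", "loop", "unassigned")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Any residual character outside A/C/G/U
#' is an error: the classifier's exact-matching semantics are undefined for
#' ambiguity codes or gaps.
#'
#' @param x character vector of sequences.
#' @param context string naming the offending input in error messages.
#' @return character vector over A/C/G/U.
#' @export
normalize_rna <- function(x, context = "sequence") {
  x <- chartr("tT", "uU", x)
  x <- toupper(x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGU]", "", x[bad][1L]), "")))
    stop(sprintf("illegal character(s) '%s' in %s (expected A/C/G/U or T)",
                 paste(ch, collapse = ""), context), call. = FALSE)
  }
  x
}

#' Hairpin precursor
#'
#' A pre-miRNA stem-loop sequence, optionally carrying a predicted secondary
#' structure (dot-bracket, same length) and its minimum folding free energy.
#'
#' @param id locus identifier (miRBase-style, e.g. \code{"dme-mir-100"}).
#' @param sequence precursor sequence; DNA is accepted and normalized to RNA.
#' @param structure optional dot-bracket string of equal length with balanced
#'   brackets.
#' @param mfe optional folding free energy of \code{structure} in kcal/mol.
#' @param min_length shortest admissible precursor (default 40 nt); genuine
#'   pre-miRNAs are ~60-120 nt and shorter input is almost always truncation.
#' @return an object of class \code{"hairpin"}.
#' @export
hairpin <- function(id, sequence, structure = NULL, mfe = NULL,
                    min_length = 40L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_rna(sequence, sprintf("hairpin '%s'", id))
  if (nchar(sequence) < min_length) {
    stop(sprintf("hairpin '%s' is %d nt, below the minimum of %d",
                 id, nchar(sequence), min_length), call. = FALSE)
  }
  if (!is.null(structure)) {
    if (nchar(structure) != nchar(sequence)) {
      stop(sprintf("hairpin '%s': structure length %d != sequence length %d",
                   id, nchar(structure), nchar(sequence)), call. = FALSE)
    }
    pair_table(structure)  # validates balance and character set
  }
  if (!is.null(mfe)) stopifnot(is.numeric(mfe), length(mfe) == 1L)
  structure(list(id = id, sequence = sequence, structure = structure,
                 mfe = mfe, species_prefix = species_prefix(id)),
            class = "hairpin")
}

# miRBase ids carry a three-letter organism prefix ("dme-mir-100" -> "dme").
species_prefix <- function(id) {
  m <- regmatches(id, regexpr("^[a-z]{3}(?=-)", id, perl = TRUE))
  if (length(m)) m else NA_character_
}

#' Mature microRNA locus on a hairpin
#'
#' Coordinates of a mature product (or an inferred star partner) on its
#' hairpin, 1-based inclusive, with the arm of origin following the
#' -5p/-3p naming convention for products of the 5' and 3' arms.
#'
#' @param id mature identifier.
#' @param hairpin_id id of the parent hairpin.
#' @param start,end 1-based inclusive coordinates on the hairpin.
#' @param arm \code{"5p"} or \code{"3p"}.
#' @param provenance \code{"annotated"} for curated coordinates,
#'   \code{"inferred_star"} for a structure-derived duplex partner.
#' @param hairpin_length if supplied, bounds are checked against it.
#' @param len_min,len_max admissible mature length range (default 16-30 nt).
#' @return an object of class \code{"mature_locus"}.
#' @export
mature_locus <- function(id, hairpin_id, start, end, arm,
                         provenance = c("annotated", "inferred_star"),
                         hairpin_length = NULL,
                         len_min = 16L, len_max = 30L) {
  provenance <- match.arg(provenance)
  arm <- match.arg(arm, c("5p", "3p"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start) {
    stop(sprintf("mature '%s': invalid interval [%d, %d]", id, start, end),
         call. = FALSE)
  }
  if (!is.null(hairpin_length) && end > hairpin_length) {
    stop(sprintf("mature '%s' extends past hairpin end (%d > %d)",
                 id, end, hairpin_length), call. = FALSE)
  }
  len <- end - start + 1L
  if (len < len_min || len > len_max) {
    stop(sprintf("mature '%s' is %d nt, outside [%d, %d]",
                 id, len, len_min, len_max), call. = FALSE)
  }
  structure(list(id = id, hairpin_id = hairpin_id, start = start, end = end,
                 arm = arm, provenance = provenance),
            class = "mature_locus")
}

#' Classification thresholds
#'
#' The five high-confidence criteria constants plus mapping-side knobs.
#' Defaults are the published values: at least 10 no-mismatch reads per
#' mature, duplex 3' overhangs of 0-4 nt, at least 50% of each arm's reads
#' sharing the modal 5' end, folding free energy strictly below
#' -0.2 kcal/mol/nt, and at least 60% of mature bases paired.
#'
#' @param min_reads_per_arm minimum summed read count per mature (criterion
#'   is inclusive: exactly this many passes).
#' @param overhang_min,overhang_max admissible 3' overhang range in nt,
#'   inclusive at both ends.
#' @param min_modal5p_fraction minimum fraction of an arm's reads sharing
#'   the modal 5' start (inclusive).
#' @param max_energy_per_nt energy threshold in kcal/mol/nt; the criterion
#'   is a strict less-than, so exactly this value fails.
#' @param min_mature_paired_fraction minimum fraction of mature bases paired
#'   (inclusive).
#' @param read_len_min,read_len_max read lengths admitted to mapping.
#' @param mature_overlap_fraction fraction of a read's length that must
#'   overlap a mature locus for the read to count toward that arm.
#' @param overhang_walk_limit how far (nt) to walk inward over unpaired
#'   bases when anchoring overhang computation on imperfect duplex ends.
#' @return an object of class \code{"mirstack_thresholds"}.
#' @seealso [read_thresholds()], [write_thresholds()]
#' @export
thresholds <- function(min_reads_per_arm = 10L,
                       overhang_min = 0L,
                       overhang_max = 4L,
                       min_modal5p_fraction = 0.5,
                       max_energy_per_nt = -0.2,
                       min_mature_paired_fraction = 0.6,
                       read_len_min = 16L,
                       read_len_max = 30L,
                       mature_overlap_fraction = 0.5,
                       overhang_walk_limit = 5L) {
  th <- list(min_reads_per_arm = as.integer(min_reads_per_arm),
             overhang_min = as.integer(overhang_min),
             overhang_max = as.integer(overhang_max),
             min_modal5p_fraction = as.numeric(min_modal5p_fraction),
             max_energy_per_nt = as.numeric(max_energy_per_nt),
             min_mature_paired_fraction = as.numeric(min_mature_paired_fraction),
             read_len_min = as.integer(read_len_min),
             read_len_max = as.integer(read_len_max),
             mature_overlap_fraction = as.numeric(mature_overlap_fraction),
             overhang_walk_limit = as.integer(overhang_walk_limit))
  stopifnot(th$min_reads_per_arm >= 0L,
            th$overhang_min <= th$overhang_max,
            th$min_modal5p_fraction >= 0, th$min_modal5p_fraction <= 1,
            th$min_mature_paired_fraction >= 0,
            th$min_mature_paired_fraction <= 1,
            th$read_len_min >= 1L, th$read_len_min <= th$read_len_max,
            th$mature_overlap_fraction > 0, th$mature_overlap_fraction <= 1,
            th$overhang_walk_limit >= 0L)
  class(th) <- "mirstack_thresholds"
  th
}

#' Read thresholds from a YAML config file
#'
#' Keys are named exactly as the arguments of [thresholds()]; missing keys
#' take their defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a \code{"mirstack_thresholds"} object.
#' @export
read_thresholds <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(thresholds))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop(sprintf("unknown threshold key(s) in '%s': %s",
                 path, paste(extra, collapse = ", ")), call. = FALSE)
  }
  do.call(thresholds, vals)
}

#' Write thresholds to a YAML config file
#'
#' @param th a \code{"mirstack_thresholds"} object.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_thresholds <- function(th, path) {
  stopifnot(inherits(th, "mirstack_thresholds"))
  # format doubles ourselves: full round-trip precision (17 significant
  # digits survives IEEE-754 read-back bit-exactly)
  vals <- lapply(unclass(th), function(v)
    if (is.double(v)) format(v, digits = 17L) else v)
  writeLines(sprintf("%s: %s", names(vals),
                     vapply(vals, as.character, "")), path)
  invisible(path)
}

#' Evaluate the five criteria booleans from raw metrics
#'
#' Pure function from a metrics record to the criteria booleans, used both
#' by the classifier and to re-derive stored booleans when auditing reports.
#' Undefined metrics (NA) fail the corresponding criterion.
#'
#' @param metrics list with elements \code{reads_5p}, \code{reads_3p},
#'   \code{overhang_5p}, \code{overhang_3p}, \code{modal5p_fraction_5p},
#'   \code{modal5p_fraction_3p}, \code{energy_per_nt},
#'   \code{mature_paired_fraction}.
#' @param th thresholds.
#' @return named logical vector \code{c1..c5}.
#' @export
criteria_from_metrics <- function(metrics, th = thresholds()) {
  ge <- function(x, t) !is.na(x) & x >= t
  within <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi
  c(c1 = unname(ge(metrics$reads_5p, th$min_reads_per_arm) &
                ge(metrics$reads_3p, th$min_reads_per_arm)),
    c2 = unname(within(metrics$overhang_5p, th$overhang_min, th$overhang_max) &
                within(metrics$overhang_3p, th$overhang_min, th$overhang_max)),
    c3 = unname(ge(metrics$modal5p_fraction_5p, th$min_modal5p_fraction) &
                ge(metrics$modal5p_fraction_3p, th$min_modal5p_fraction)),
    c4 = unname(!is.na(metrics$energy_per_nt) &
                metrics$energy_per_nt < th$max_energy_per_nt),
    c5 = unname(ge(metrics$mature_paired_fraction,
                   th$min_mature_paired_fraction)))
}

criteria_result <- function(booleans, metrics) {
  stopifnot(identical(names(booleans), c("c1", "c2", "c3", "c4", "c5")))
  structure(list(c1_read_depth = booleans[["c1"]],
                 c2_overhang = booleans[["c2"]],
                 c3_five_prime_homogeneity = booleans[["c3"]],
                 c4_energy = booleans[["c4"]],
                 c5_mature_pairing = booleans[["c5"]],
                 metrics = metrics),
            class = "criteria_result")
}

criteria_booleans <- function(cr) {
  c(c1 = cr$c1_read_depth, c2 = cr$c2_overhang,
    c3 = cr$c3_five_prime_homogeneity, c4 = cr$c4_energy,
    c5 = cr$c5_mature_pairing)
}

confidence_call <- function(hairpin_id, verdict, criteria, notes = character()) {
  verdict <- match.arg(verdict, VERDICTS)
  structure(list(hairpin_id = hairpin_id, verdict = verdict,
                 criteria = criteria, notes = notes),
            class = "confidence_call")
}

#' @export
print.confidence_call <- function(x, ...) {
  b <- criteria_booleans(x$criteria)
  cat(sprintf("<confidence_call> %s: %s [%s]\n", x$hairpin_id, x$verdict,
              paste(names(b)[b], collapse = " ")))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("<hairpin> %s (%d nt%s%s)\n", x$id, nchar(x$sequence),
              if (!is.null(x$structure)) ", structured" else "",
              if (!is.null(x$mfe)) sprintf(", %.2f kcal/mol", x$mfe) else ""))
  invisible(x)
}
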