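# Secondary-structure geometry: dot-bracket pair tables, terminal-loop
# location, star-sequence inference, duplex 3' overhangs, pairing fraction
# and folding free energy per nucleotide.

#' Build a base-pair table from dot-bracket notation
#'
#' Stack-based matching of \code{"("} with \code{")"}; \code{"."} is
#' unpaired. The result is symmetric: \code{pt[pt[i]] == i} for every
#' paired base \code{i} (1-based).
#'
#' @param structure dot-bracket string (nested pairs only, no pseudoknots).
#' @return integer vector \code{pt} with \code{pt[i]} the partner of base
#'   \code{i}, or \code{NA} if unpaired.
#' @export
pair_table <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  ch <- strsplit(structure, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad)) {
    stop(sprintf("invalid character(s) '%s' in dot-bracket string",
                 paste(bad, collapse = "")), call. = FALSE)
  }
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) {
        stop(sprintf("unbalanced dot-bracket: unmatched ')' at position %d", i),
             call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i
      pt[i] <- j
    }
  }
  if (length(stack)) {
    stop(sprintf("unbalanced dot-bracket: unmatched '(' at position %d",
                 stack[length(stack)]), call. = FALSE)
  }
  pt
}

# Immediate child pairs of the region (i+1, j-1): outermost pairs nested
# directly under (i, j). With i = 0, j = L+1 this lists top-level stems.
child_pairs <- function(pt, i, j) {
  kids <- list()
  k <- i + 1L
  while (k < j) {
    if (!is.na(pt[k]) && pt[k] > k) {
      kids[[length(kids) + 1L]] <- c(k, pt[k])
      k <- pt[k] + 1L
    } else {
      k <- k + 1L
    }
  }
  kids
}

n_pairs_within <- function(pt, i, j) {
  idx <- seq.int(i, j)
  sum(!is.na(pt[idx]) & pt[idx] > idx)
}

#' Locate the terminal loop and arm regions of a hairpin
#'
#' Descends the structure from its outermost pair to the innermost pair;
#' the enclosed unpaired interval is the terminal loop, and the flanking
#' regions are the 5' and 3' arms. Branched structures (more than one stem
#' at any level) are resolved toward the branch containing the most base
#' pairs and flagged \code{multiloop}; ties break to the 5'-most branch.
#'
#' @param pt pair table from [pair_table()].
#' @return list with \code{loop_start}, \code{loop_end} (1-based inclusive
#'   bounds of the loop), \code{five_p_end}, \code{three_p_start} (the arms
#'   are \code{[1, five_p_end]} and \code{[three_p_start, length]}), and
#'   logical \code{multiloop}.
#' @export
find_loop <- function(pt) {
  if (all(is.na(pt))) {
    stop("structure contains no base pair; cannot locate a terminal loop",
         call. = FALSE)
  }
  multiloop <- FALSE
  i <- 0L
  j <- length(pt) + 1L
  repeat {
    kids <- child_pairs(pt, i, j)
    if (!length(kids)) break
    if (length(kids) > 1L) {
      multiloop <- TRUE
      npair <- vapply(kids, function(k) n_pairs_within(pt, k[1], k[2]), 0L)
      kids <- kids[which.max(npair)]  # which.max ties -> first (5'-most)
    }
    i <- kids[[1L]][1L]
    j <- kids[[1L]][2L]
  }
  # (i, j) is now the innermost pair enclosing the terminal loop
  list(loop_start = i + 1L, loop_end = j - 1L,
       five_p_end = i, three_p_start = j,
       multiloop = multiloop)
}

#' Fold an RNA sequence with the delegated thermodynamic engine
#'
#' Delegates minimum-free-energy folding to \code{RNAfold} (ViennaRNA),
#' which must be on the \code{PATH}. Default temperature and parameter set
#' of the installed engine are used and its version string is returned so
#' reports can record the engine identity.
#'
#' @param sequence RNA (or DNA) string.
#' @return list with \code{structure} (dot-bracket), \code{mfe} (kcal/mol)
#'   and \code{engine} (version string).
#' @export
fold <- function(sequence) {
  sequence <- normalize_rna(sequence, "sequence to fold")
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop(paste("RNAfold not found on PATH; install ViennaRNA or supply",
               "precomputed dot-bracket structures via read_dotbracket()"),
         call. = FALSE)
  }
  out <- suppressWarnings(
    system2(exe, c("--noPS"), input = sequence, stdout = TRUE, stderr = TRUE))
  # last line: "((..))... ( -12.30)" ; mfe may abut the paren: "(-12.30)"
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$",
                                line))[[1L]]
  if (length(m) != 3L) {
    stop(sprintf("could not parse RNAfold output line: '%s'", line),
         call. = FALSE)
  }
  ver <- tryCatch(system2(exe, "--version", stdout = TRUE)[1L],
                  error = function(e) "RNAfold (version unknown)")
  list(structure = m[2L], mfe = as.numeric(m[3L]), engine = ver)
}

#' Folding free energy per nucleotide
#'
#' @param mfe minimum free energy in kcal/mol.
#' @param length sequence length in nt (> 0).
#' @return energy density in kcal/mol/nt.
#' @export
energy_per_nt <- function(mfe, length) {
  if (any(length <= 0)) stop("length must be positive", call. = FALSE)
  mfe / length
}

# Walk from position `from` in direction `dir` (+1L/-1L) to the nearest
# paired base, at most `limit` steps; NA if none found in range.
walk_to_paired <- function(pt, from, dir, limit = 5L) {
  pos <- from
  steps <- 0L
  n <- length(pt)
  while (steps <= limit && pos >= 1L && pos <= n) {
    if (!is.na(pt[pos])) return(pos)
    pos <- pos + dir
    steps <- steps + 1L
  }
  NA_integer_
}

#' Infer the star sequence of an annotated mature
#'
#' Constructs the duplex partner implied by canonical Drosha/Dicer
#' processing: products pair with a 2-nt 3' overhang at both duplex ends.
#' The star's 5' end is the structure partner of the base 2 nt inside the
#' mature's 3' end, and its 3' end lies 2 nt beyond the partner of the
#' mature's 5' end. Unpaired bases at either anchor are bridged by walking
#' inward to the nearest paired base.
#'
#' @param mature a [mature_locus()].
#' @param pt pair table of the parent hairpin.
#' @param hairpin_length length of the hairpin, used to clamp the result.
#' @return a \code{"mature_locus"} on the opposite arm with provenance
#'   \code{"inferred_star"}, or \code{NULL} when no base of the mature is
#'   paired (inference impossible).
#' @export
infer_star <- function(mature, pt, hairpin_length = length(pt)) {
  if (!any(!is.na(pt[mature$start:mature$end]))) return(NULL)
  # anchor near the mature 3' end: base 2 nt inside, walked 5'-ward
  a3 <- walk_to_paired(pt, max(mature$start, mature$end - 2L), -1L,
                       limit = mature$end - mature$start)
  # anchor at the mature 5' end, walked 3'-ward
  a5 <- walk_to_paired(pt, mature$start, +1L,
                       limit = mature$end - mature$start)
  if (is.na(a3) || is.na(a5)) return(NULL)
  star_start <- pt[a3]
  star_end <- min(pt[a5] + 2L, hairpin_length)
  if (star_start > star_end) return(NULL)
  len <- star_end - star_start + 1L
  mature_locus(id = paste0(mature$id, "*"),
               hairpin_id = mature$hairpin_id,
               start = star_start, end = star_end,
               arm = if (mature$arm == "5p") "3p" else "5p",
               provenance = "inferred_star",
               hairpin_length = hairpin_length,
               len_min = max(10L, len), len_max = max(40L, len))
}

#' Duplex 3' overhangs between a 5p and a 3p product
#'
#' For each product, the 3' overhang is the number of its 3'-terminal
#' bases protruding past the paired end of the partner product: positive
#' for a 3' overhang, 0 for a blunt end, negative for a recessed 3' end.
#' The canonical Drosha/Dicer signature is a 2-nt overhang at both ends.
#' Unpaired bases at a product's 5' end are bridged by walking 3'-ward to
#' the nearest paired base (at most \code{walk_limit} nt); the walked
#' distance folds into the overhang arithmetic.
#'
#' @param m5 mature locus on the 5p arm.
#' @param m3 mature locus on the 3p arm.
#' @param pt pair table of the hairpin.
#' @param walk_limit maximum inward walk over unpaired 5'-end bases.
#' @param derived_from provenance label carried in the result.
#' @return list with integer \code{overhang_5p} and \code{overhang_3p}
#'   (NA when no paired anchor exists within the walk limit) and
#'   \code{derived_from}.
#' @export
duplex_overhangs <- function(m5, m3, pt, walk_limit = 5L,
                             derived_from = c("annotated_pair",
                                              "most_abundant_reads")) {
  derived_from <- match.arg(derived_from)
  stopifnot(m5$arm == "5p", m3$arm == "3p")
  p3 <- walk_to_paired(pt, m3$start, +1L, walk_limit)  # anchor on 3p product
  p5 <- walk_to_paired(pt, m5$start, +1L, walk_limit)  # anchor on 5p product
  o5 <- if (is.na(p3)) NA_integer_ else m5$end - pt[p3]
  o3 <- if (is.na(p5)) NA_integer_ else m3$end - pt[p5]
  list(overhang_5p = o5, overhang_3p = o3, derived_from = derived_from)
}

#' Fraction of mature bases paired in the hairpin structure
#'
#' Counts paired bases over the union of the mature intervals, so
#' overlapping annotations are not double-counted.
#'
#' @param matures list of [mature_locus()] objects (at least one).
#' @param pt pair table.
#' @return fraction in [0, 1].
#' @export
mature_paired_fraction <- function(matures, pt) {
  if (!length(matures)) stop("at least one mature locus required", call. = FALSE)
  idx <- sort(unique(unlist(lapply(matures, function(m) m$start:m$end))))
  idx <- idx[idx >= 1L & idx <= length(pt)]
  if (!length(idx)) stop("mature intervals fall outside the hairpin",
                         call. = FALSE)
  sum(!is.na(pt[idx])) / length(idx)
}
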