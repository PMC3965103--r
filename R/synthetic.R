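# Seeded synthetic loci with exactly controlled properties: perfect-stem
# hairpins with constructed ground-truth structures, matures placed to
# realize requested duplex overhangs, and read stacks with controlled
# depth and 5'-end homogeneity. Used for validation; none of it attempts
# to model sequencing error, adapters or expression dynamics.

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

# run expr under a locus-local seed without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

reverse_complement_rna <- function(x) {
  paste(rev(RNA_COMPLEMENT[strsplit(x, "")[[1L]]]), collapse = "")
}

#' Specification for one synthetic locus
#'
#' @param arm_len stem arm length in nt (>= 18).
#' @param loop_len terminal loop length in nt (>= 3); the loop is poly-A
#'   so it stays unpaired under any reasonable folding model.
#' @param gc_fraction GC content of the 5' arm.
#' @param overhang_5p,overhang_3p requested duplex 3' overhangs in nt.
#' @param reads_5p,reads_3p read counts per arm.
#' @param modal_fraction_5p,modal_fraction_3p fraction of each arm's reads
#'   sharing the mature 5' start; the remainder is spread over non-zero
#'   offsets.
#' @param offset_noise maximum |5' offset| of non-modal reads in nt.
#' @param mature_len mature product length in nt.
#' @param mature5_start start of the 5p mature on the hairpin.
#' @param seed integer seed; identical specs give byte-identical loci.
#' @return object of class \code{"locus_spec"}.
#' @export
locus_spec <- function(arm_len = 35L, loop_len = 6L, gc_fraction = 0.8,
                       overhang_5p = 2L, overhang_3p = 2L,
                       reads_5p = 100L, reads_3p = 100L,
                       modal_fraction_5p = 0.9, modal_fraction_3p = 0.9,
                       offset_noise = 2L, mature_len = 22L,
                       mature5_start = 9L, seed = 1L) {
  spec <- list(arm_len = as.integer(arm_len), loop_len = as.integer(loop_len),
               gc_fraction = gc_fraction,
               overhang_5p = as.integer(overhang_5p),
               overhang_3p = as.integer(overhang_3p),
               reads_5p = as.integer(reads_5p),
               reads_3p = as.integer(reads_3p),
               modal_fraction_5p = modal_fraction_5p,
               modal_fraction_3p = modal_fraction_3p,
               offset_noise = as.integer(offset_noise),
               mature_len = as.integer(mature_len),
               mature5_start = as.integer(mature5_start),
               seed = as.integer(seed))
  stopifnot(spec$arm_len >= 18L, spec$loop_len >= 3L,
            spec$gc_fraction >= 0, spec$gc_fraction <= 1,
            spec$modal_fraction_5p >= 0, spec$modal_fraction_5p <= 1,
            spec$modal_fraction_3p >= 0, spec$modal_fraction_3p <= 1,
            spec$offset_noise >= 1L, spec$mature_len >= 16L,
            spec$mature5_start >= 1L)
  class(spec) <- "locus_spec"
  spec
}

# Nominal stacking-style energy assigned to a constructed (not folded)
# ground-truth structure: -3.4 kcal/mol per GC pair, -2.0 per AU pair.
# A bookkeeping value for the synthetic fixtures, not a thermodynamic
# prediction.
nominal_mfe <- function(sequence, structure) {
  pt <- pair_table(structure)
  ch <- strsplit(sequence, "")[[1L]]
  e <- 0
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (is.na(j) || j < i) next
    pair <- paste(sort(c(ch[i], ch[j])), collapse = "")
    e <- e - switch(pair, CG = 3.4, AU = 2.0, GU = 1.5, 0)
  }
  e
}

#' Construct a synthetic hairpin with known structure
#'
#' The 3' arm is the reverse complement of the (seeded, GC-controlled)
#' 5' arm, joined by a poly-A loop, so the ground-truth structure — a
#' perfect stem around an unpaired loop — is constructed, never folded.
#' Matures are placed so the annotated duplex realizes the requested 3'
#' overhangs exactly; a spec whose overhangs cannot fit inside the arms
#' is an error.
#'
#' @param spec a [locus_spec()].
#' @param id hairpin identifier (default derived from the seed).
#' @return list with \code{hairpin} (structure and nominal mfe set) and
#'   \code{matures} (5p and 3p [mature_locus()]).
#' @export
make_hairpin <- function(spec, id = sprintf("syn-mir-%d", spec$seed)) {
  stopifnot(inherits(spec, "locus_spec"))
  L <- 2L * spec$arm_len + spec$loop_len
  s5 <- spec$mature5_start
  e5 <- s5 + spec$mature_len - 1L
  s3 <- L + 1L - e5 + spec$overhang_5p
  e3 <- L + 1L - s5 + spec$overhang_3p
  if (e5 > spec$arm_len) {
    stop("5p mature extends into the loop; increase arm_len", call. = FALSE)
  }
  if (s3 < spec$arm_len + spec$loop_len + 1L || e3 > L || s3 > e3) {
    stop(sprintf("requested overhangs (%d, %d) do not fit inside the 3p arm",
                 spec$overhang_5p, spec$overhang_3p), call. = FALSE)
  }
  arm5 <- with_preserved_rng(spec$seed, {
    n_gc <- round(spec$gc_fraction * spec$arm_len)
    bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
               sample(c("A", "U"), spec$arm_len - n_gc, replace = TRUE))
    paste(sample(bases), collapse = "")
  })
  seqn <- paste0(arm5, strrep("A", spec$loop_len),
                 reverse_complement_rna(arm5))
  db <- paste0(strrep("(", spec$arm_len), strrep(".", spec$loop_len),
               strrep(")", spec$arm_len))
  hp <- hairpin(id, seqn, structure = db, mfe = nominal_mfe(seqn, db))
  m5 <- mature_locus(paste0(id, "-5p"), id, s5, e5, "5p", "annotated",
                     hairpin_length = L)
  m3 <- mature_locus(paste0(id, "-3p"), id, s3, e3, "3p", "annotated",
                     hairpin_length = L,
                     len_min = min(16L, e3 - s3 + 1L),
                     len_max = max(30L, e3 - s3 + 1L))
  list(hairpin = hp, matures = list(m5, m3))
}

# reads for one arm: modal reads start exactly at the mature 5' end;
# the remainder is spread round-robin over distinct non-zero offsets in
# [-offset_noise, +offset_noise], so no single off-modal start outweighs
# the modal start whenever modal_fraction >= 0.5.
arm_reads <- function(hp, m, n, modal_fraction, offset_noise, tag) {
  if (n <= 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  len <- m$end - m$start + 1L
  L <- nchar(hp$sequence)
  n_modal <- as.integer(ceiling(modal_fraction * n))
  offsets <- setdiff(seq.int(-offset_noise, offset_noise), 0L)
  offsets <- offsets[m$start + offsets >= 1L &
                     m$start + offsets + len - 1L <= L]
  if (!length(offsets) && n_modal < n) {
    stop("offset_noise pushes every non-modal read outside the hairpin",
         call. = FALSE)
  }
  counts <- integer(length(offsets))
  k <- n - n_modal
  if (k > 0L) {
    counts <- tabulate(rep_len(seq_along(offsets), k), length(offsets))
  }
  starts <- c(if (n_modal > 0L) m$start, (m$start + offsets)[counts > 0L])
  cnts <- c(if (n_modal > 0L) n_modal, counts[counts > 0L])
  data.frame(id = sprintf("%s_r%d_x%d", tag, seq_along(starts), cnts),
             sequence = substring(hp$sequence, starts, starts + len - 1L),
             count = cnts, stringsAsFactors = FALSE)
}

#' Generate a synthetic read set for a locus
#'
#' Emits collapsed read records (id, sequence, count) for both arms. All
#' reads are exact substrings of the hairpin, so they survive exact
#' mapping unchanged; modal reads start exactly at each mature 5' end
#' with count \code{ceiling(modal_fraction * n)}.
#'
#' @param spec the [locus_spec()].
#' @param bundle result of [make_hairpin()] for the same spec.
#' @return data.frame of read records (columns \code{id}, \code{sequence},
#'   \code{count}).
#' @export
make_read_stack <- function(spec, bundle) {
  m5 <- bundle$matures[[1L]]
  m3 <- bundle$matures[[2L]]
  rbind(arm_reads(bundle$hairpin, m5, spec$reads_5p, spec$modal_fraction_5p,
                  spec$offset_noise, paste0(bundle$hairpin$id, "_5p")),
        arm_reads(bundle$hairpin, m3, spec$reads_3p, spec$modal_fraction_3p,
                  spec$offset_noise, paste0(bundle$hairpin$id, "_3p")))
}

#' Generate a complete synthetic locus for one of the three archetypes
#'
#' \code{SUPPORTED} emulates a locus whose reads map to both matures and
#' pair with the canonical 2-nt 3' overhang; \code{ONE_ARM_ONLY} a locus
#' with reads on a single arm; \code{BAD_OVERHANG} a well-read locus
#' whose products pair with a 7-nt overhang, inconsistent with canonical
#' processing.
#'
#' @param archetype \code{"SUPPORTED"}, \code{"ONE_ARM_ONLY"} or
#'   \code{"BAD_OVERHANG"}.
#' @param seed integer seed.
#' @return locus bundle with \code{hairpin}, \code{matures},
#'   \code{read_sets} (list of one read data.frame), \code{spec},
#'   \code{expected_verdict}.
#' @export
make_case <- function(archetype = c("SUPPORTED", "ONE_ARM_ONLY",
                                    "BAD_OVERHANG"), seed = 1L) {
  archetype <- match.arg(archetype)
  spec <- switch(archetype,
    SUPPORTED = locus_spec(seed = seed),
    ONE_ARM_ONLY = locus_spec(reads_3p = 0L, seed = seed),
    BAD_OVERHANG = locus_spec(overhang_5p = 7L, overhang_3p = 7L,
                              seed = seed))
  bundle <- make_hairpin(spec)
  reads <- make_read_stack(spec, bundle)
  expected <- switch(archetype,
    SUPPORTED = "HIGH_CONFIDENCE",
    ONE_ARM_ONLY = "INSUFFICIENT_EVIDENCE",
    BAD_OVERHANG = "PATTERN_INCONSISTENT")
  list(hairpin = bundle$hairpin, matures = bundle$matures,
       read_sets = list(reads), spec = spec, expected_verdict = expected)
}

#' Write a synthetic fixture directory
#'
#' Emits hairpin FASTA (seed recorded in the description), a mature
#' linkage table and FASTA, one collapsed-read FASTA (suffix_xN dialect)
#' per pseudo-dataset, and a ground-truth verdict TSV.
#'
#' @param cases list of bundles from [make_case()].
#' @param dir output directory (created if needed).
#' @param n_datasets number of pseudo-datasets to split reads across.
#' @return \code{dir}, invisibly.
#' @export
write_fixture_dir <- function(cases, dir, n_datasets = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hp_lines <- character(0)
  mat_lines <- character(0)
  link <- character(0)
  truth <- c("locus_id\texpected_verdict")
  ds_lines <- rep(list(character(0)), n_datasets)
  for (cs in cases) {
    hp <- cs$hairpin
    hp_lines <- c(hp_lines, sprintf(">%s seed=%d", hp$id, cs$spec$seed),
                  hp$sequence)
    for (m in cs$matures) {
      mat_lines <- c(mat_lines, sprintf(">%s", m$id),
                     substring(hp$sequence, m$start, m$end))
      link <- c(link, sprintf("%s\t%s", m$id, hp$id))
    }
    truth <- c(truth, sprintf("%s\t%s", hp$id, cs$expected_verdict))
    reads <- cs$read_sets[[1L]]
    for (k in seq_len(nrow(reads))) {
      ds <- 1L + (k - 1L) %% n_datasets
      ds_lines[[ds]] <- c(ds_lines[[ds]],
                          sprintf(">%s_x%d", sub("_x[0-9]+$", "",
                                                 reads$id[k]),
                                  reads$count[k]),
                          reads$sequence[k])
    }
  }
  writeLines(hp_lines, file.path(dir, "hairpins.fa"))
  writeLines(mat_lines, file.path(dir, "matures.fa"))
  writeLines(c("mature_id\thairpin_id", link),
             file.path(dir, "mature_links.tsv"))
  writeLines(truth, file.path(dir, "truth.tsv"))
  for (ds in seq_len(n_datasets)) {
    writeLines(ds_lines[[ds]], file.path(dir, sprintf("reads_ds%d.fa", ds)))
  }
  invisible(dir)
}
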