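# Exact (no-mismatch) mapping of reads onto hairpins, arm assignment and
# cross-dataset aggregation into per-locus read stacks.

#' Map reads exactly onto a hairpin
#'
#' Every occurrence of a read as an exact, sense-strand substring of the
#' hairpin yields one alignment (no mismatches; small RNA protocols are
#' stranded). A read occurring at several positions in the hairpin gives
#' one alignment per site, each carrying the full count and flagged
#' \code{multi_hit}. Reads with no occurrence are dropped silently, reads
#' outside the admissible length range are skipped and tallied.
#'
#' @param reads data.frame with columns \code{sequence}, \code{count}
#'   (e.g. from [read_reads()]); identical sequences may repeat.
#' @param hp a [hairpin()].
#' @param th thresholds (read length range).
#' @return data.frame of alignments with columns \code{sequence},
#'   \code{start} (1-based), \code{count}, \code{multi_hit}; attribute
#'   \code{n_length_filtered} records skipped reads.
#' @export
map_reads_exact <- function(reads, hp, th = thresholds()) {
  stopifnot(inherits(hp, "hairpin"))
  empty <- data.frame(sequence = character(0), start = integer(0),
                      count = integer(0), multi_hit = logical(0))
  if (!nrow(reads)) return(`attr<-`(empty, "n_length_filtered", 0L))
  len <- nchar(reads$sequence)
  keep <- len >= th$read_len_min & len <= th$read_len_max
  n_filtered <- sum(reads$count[!keep])
  reads <- reads[keep, , drop = FALSE]
  rows <- vector("list", nrow(reads))
  for (k in seq_len(nrow(reads))) {
    hits <- find_all_starts(reads$sequence[k], hp$sequence)
    if (!length(hits)) next
    rows[[k]] <- data.frame(sequence = reads$sequence[k],
                            start = hits,
                            count = reads$count[k],
                            multi_hit = length(hits) > 1L)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, NA)])
  if (is.null(out)) out <- empty
  attr(out, "n_length_filtered") <- n_filtered
  out
}

# all (possibly overlapping) 1-based start positions of `pattern` in `x`
find_all_starts <- function(pattern, x) {
  hits <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(pattern, substr(x, from, nchar(x)), fixed = TRUE)
    if (m == -1L) break
    pos <- from + as.integer(m) - 1L
    hits <- c(hits, pos)
    from <- pos + 1L
  }
  hits
}

#' Assign an alignment to a hairpin arm
#'
#' A read counts toward the 5p or 3p arm when it overlaps that arm's
#' mature locus by at least \code{mature_overlap_fraction} of the read's
#' length (tolerant of templated 3' trimming and tailing). A read covering
#' the entire terminal loop is \code{"loop"}; anything else is
#' \code{"unassigned"}. When both matures qualify, the larger overlap
#' wins; ties go to the 5p arm.
#'
#' @param start,width alignment start (1-based) and length on the hairpin.
#' @param matures list of mature loci (annotated or inferred).
#' @param partition loop/arm partition from [find_loop()].
#' @param th thresholds.
#' @return one of \code{"5p"}, \code{"3p"}, \code{"loop"},
#'   \code{"unassigned"}.
#' @export
assign_arm <- function(start, width, matures, partition, th = thresholds()) {
  if (is.null(partition)) {
    stop("arm partition required; compute it with find_loop()", call. = FALSE)
  }
  end <- start + width - 1L
  best_arm <- NA_character_
  best_ov <- -1L
  for (m in matures) {
    ov <- max(0L, min(end, m$end) - max(start, m$start) + 1L)
    if (ov >= th$mature_overlap_fraction * width &&
        (ov > best_ov || (ov == best_ov && m$arm == "5p"))) {
      best_ov <- ov
      best_arm <- m$arm
    }
  }
  if (!is.na(best_arm)) return(best_arm)
  if (start <= partition$loop_start && end >= partition$loop_end) {
    return("loop")  # spans the entire terminal loop
  }
  "unassigned"
}

#' Build a read stack from alignments
#'
#' Merges identical (sequence, start) alignments by summing counts, then
#' derives per-arm totals, the modal 5'-start fraction and the most
#' abundant read per arm. The modal 5' start is the position carrying the
#' greatest summed count; ties break to the smaller start. The most
#' abundant read ties break to smaller start, then lexicographically
#' smaller sequence.
#'
#' @param alignments data.frame from [map_reads_exact()] (one hairpin).
#' @param matures mature loci used for arm assignment.
#' @param partition loop partition from [find_loop()].
#' @param hairpin_id locus id recorded in the stack.
#' @param th thresholds.
#' @return object of class \code{"read_stack"}: list with \code{hairpin_id},
#'   \code{reads} (merged alignment frame with \code{arm}),
#'   \code{per_arm_total}, \code{modal_start}, \code{modal5p_fraction},
#'   \code{most_abundant} (per-arm single-row frames), \code{any_multi_hit}.
#' @export
build_stack <- function(alignments, matures, partition, hairpin_id,
                        th = thresholds()) {
  if (nrow(alignments)) {
    key <- paste(alignments$sequence, alignments$start, sep = "\r")
    agg <- rowsum(alignments$count, key, reorder = FALSE)
    mh <- tapply(alignments$multi_hit, key, any)[rownames(agg)]
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    reads <- data.frame(sequence = vapply(parts, `[`, "", 1L),
                        start = as.integer(vapply(parts, `[`, "", 2L)),
                        count = as.integer(agg[, 1L]),
                        multi_hit = as.logical(mh),
                        stringsAsFactors = FALSE)
    reads$arm <- vapply(seq_len(nrow(reads)), function(k)
      assign_arm(reads$start[k], nchar(reads$sequence[k]), matures,
                 partition, th), "")
    reads <- reads[order(reads$start, reads$sequence), , drop = FALSE]
    rownames(reads) <- NULL
  } else {
    reads <- data.frame(sequence = character(0), start = integer(0),
                        count = integer(0), multi_hit = logical(0),
                        arm = character(0), stringsAsFactors = FALSE)
  }
  per_arm_total <- vapply(ARMS, function(a)
    sum(reads$count[reads$arm == a]), 0)
  modal_start <- setNames(rep(NA_integer_, length(ARMS)), ARMS)
  modal_fraction <- setNames(rep(NA_real_, length(ARMS)), ARMS)
  most_abundant <- setNames(vector("list", length(ARMS)), ARMS)
  for (a in c("5p", "3p")) {
    sub <- reads[reads$arm == a, , drop = FALSE]
    if (!nrow(sub)) next
    by_start <- rowsum(sub$count, sub$start)
    starts <- as.integer(rownames(by_start))
    best <- which(by_start[, 1L] == max(by_start[, 1L]))
    modal_start[a] <- min(starts[best])
    modal_fraction[a] <- by_start[as.character(modal_start[a]), 1L] /
      per_arm_total[a]
    top <- sub[sub$count == max(sub$count), , drop = FALSE]
    top <- top[order(top$start, top$sequence), , drop = FALSE]
    most_abundant[[a]] <- top[1L, , drop = FALSE]
  }
  structure(list(hairpin_id = hairpin_id, reads = reads,
                 per_arm_total = per_arm_total,
                 modal_start = modal_start,
                 modal5p_fraction = modal_fraction,
                 most_abundant = most_abundant,
                 any_multi_hit = any(reads$multi_hit)),
            class = "read_stack")
}

#' Aggregate read stacks from several datasets
#'
#' Counts are summed per (sequence, start) across datasets — the summed
#' display convention — and all derived statistics are recomputed on the
#' summed stack, so aggregation is invariant under input order and equals
#' mapping the concatenation of all read sets at once.
#'
#' @param stacks list of \code{"read_stack"} objects for one hairpin.
#' @param matures,partition,th as in [build_stack()].
#' @return a single aggregated \code{"read_stack"}.
#' @export
aggregate_stacks <- function(stacks, matures, partition, th = thresholds()) {
  stopifnot(length(stacks) >= 1L)
  ids <- unique(vapply(stacks, `[[`, "", "hairpin_id"))
  if (length(ids) != 1L) {
    stop(sprintf("stacks reference different hairpins: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  all_reads <- do.call(rbind, lapply(stacks, function(s)
    s$reads[, c("sequence", "start", "count", "multi_hit")]))
  build_stack(all_reads, matures, partition, ids, th)
}

#' @export
print.read_stack <- function(x, ...) {
  cat(sprintf("<read_stack> %s: %d distinct reads (5p %d, 3p %d, loop %d, unassigned %d)\n",
              x$hairpin_id, nrow(x$reads),
              x$per_arm_total[["5p"]], x$per_arm_total[["3p"]],
              x$per_arm_total[["loop"]], x$per_arm_total[["unassigned"]]))
  invisible(x)
}
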