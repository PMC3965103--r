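# On-disk formats: FASTA/FASTQ reads (plain or collapsed-count headers),
# hairpin/mature FASTA, RNAfold-style dot-bracket text, TSV and GFF3
# reports. Sequence parsing goes through Biostrings; gzip input is handled
# transparently by it.

#' Read a FASTA file with RNA normalization
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @param alphabet_policy \code{"strict"} errors on characters outside
#'   A/C/G/U/T; \code{"skip"} drops offending records with a warning.
#' @return data.frame with columns \code{id}, \code{description},
#'   \code{sequence}, in file order.
#' @export
read_fasta <- function(path, alphabet_policy = c("strict", "skip")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop(sprintf("malformed FASTA '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  if (length(set) && any(Biostrings::width(set) == 0L)) {
    stop(sprintf("malformed FASTA '%s': empty sequence record", path),
         call. = FALSE)
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(set)
  if (alphabet_policy == "skip") {
    norm <- chartr("tT", "uU", toupper(seqs))
    keep <- !grepl("[^ACGU]", norm)
    if (!all(keep)) {
      warning(sprintf("%d record(s) with non-ACGUT characters skipped in %s",
                      sum(!keep), path), call. = FALSE)
    }
    id <- id[keep]; description <- description[keep]; seqs <- norm[keep]
  } else {
    seqs <- normalize_rna(seqs, sprintf("FASTA file '%s'", path))
  }
  data.frame(id = id, description = description, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Parse a collapsed-FASTA header into id and read count
#'
#' Collapsed small-RNA FASTA encodes the number of identical reads in the
#' header. Two common dialects are supported, plus \code{"none"} for
#' uncollapsed data (count 1). Dialects are never auto-detected.
#'
#' @param header header string (without the leading \code{">"}).
#' @param dialect \code{"suffix_xN"} (\code{seq42_x117}),
#'   \code{"count_field"} (\code{seq42-117}), or \code{"none"}.
#' @return list with \code{id} and integer \code{count}.
#' @export
parse_collapsed_header <- function(header,
                                   dialect = c("suffix_xN", "count_field",
                                               "none")) {
  dialect <- match.arg(dialect)
  header <- sub("\\s.*$", "", header)
  if (dialect == "none") return(list(id = header, count = 1L))
  pat <- if (dialect == "suffix_xN") "^(.*)_x([^_]+)$" else "^(.*)-([^-]+)$"
  m <- regmatches(header, regexec(pat, header))[[1L]]
  if (length(m) != 3L) {
    stop(sprintf("header '%s' does not match dialect '%s'", header, dialect),
         call. = FALSE)
  }
  if (!grepl("^[0-9]+$", m[3L])) {
    stop(sprintf("non-numeric count '%s' in header '%s'", m[3L], header),
         call. = FALSE)
  }
  count <- as.integer(m[3L])
  if (is.na(count) || count < 1L) {
    stop(sprintf("count in header '%s' must be a positive integer", header),
         call. = FALSE)
  }
  list(id = m[2L], count = count)
}

#' Read a small-RNA read set
#'
#' Accepts plain FASTA, collapsed FASTA (counts in headers), or FASTQ
#' (qualities read and discarded; the classification criteria use only
#' counts and positions).
#'
#' @param path input file, optionally gzipped.
#' @param format \code{"fasta"} or \code{"fastq"}.
#' @param dialect collapsed-header dialect, see [parse_collapsed_header()].
#' @return data.frame with columns \code{id}, \code{sequence},
#'   \code{count} (class \code{"read_records"}).
#' @export
read_reads <- function(path, format = c("fasta", "fastq"),
                       dialect = c("none", "suffix_xN", "count_field")) {
  format <- match.arg(format)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = format),
                  error = function(e) {
                    stop(sprintf("malformed %s '%s': %s", toupper(format),
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  headers <- if (is.null(names(set))) {
    sprintf("read%d", seq_along(set))
  } else names(set)
  parsed <- lapply(headers, parse_collapsed_header, dialect = dialect)
  out <- data.frame(id = vapply(parsed, `[[`, "", "id"),
                    sequence = normalize_rna(as.character(set),
                                             sprintf("reads file '%s'", path)),
                    count = vapply(parsed, `[[`, 1L, "count"),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_records", class(out))
  out
}

#' Read precomputed secondary structures (RNAfold-style text)
#'
#' Parses the folding engine's three-line blocks: a FASTA-style header, the
#' sequence, and the dot-bracket structure with an optional trailing
#' energy in parentheses, e.g. \code{"((((...)))) (-12.30)"}. A missing
#' energy suffix leaves \code{mfe} as NA (not an error); unbalanced
#' brackets or a structure/sequence length mismatch are errors.
#'
#' @param path structure file.
#' @return data.frame with columns \code{id}, \code{sequence},
#'   \code{structure}, \code{mfe}.
#' @export
read_dotbracket <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) {
    stop(sprintf("'%s': no FASTA-style headers found", path), call. = FALSE)
  }
  recs <- lapply(seq_along(hdr), function(k) {
    from <- hdr[k]
    to <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 3L) {
      stop(sprintf("'%s', line %d: record needs header, sequence and structure",
                   path, from), call. = FALSE)
    }
    id <- sub("\\s.*$", "", sub("^>", "", block[1L]))
    seq <- normalize_rna(trimws(block[2L]), sprintf("'%s' record '%s'",
                                                    path, id))
    sline <- trimws(block[3L])
    m <- regmatches(sline,
                    regexec("^([.()]+)(?:\\s*\\(\\s*(-?[0-9.]+)\\s*\\))?$",
                            sline))[[1L]]
    if (!length(m)) {
      stop(sprintf("'%s', line %d: cannot parse structure line", path,
                   from + 2L), call. = FALSE)
    }
    db <- m[2L]
    mfe <- if (nzchar(m[3L])) as.numeric(m[3L]) else NA_real_
    if (nchar(db) != nchar(seq)) {
      stop(sprintf("'%s' record '%s': structure length %d != sequence length %d",
                   path, id, nchar(db), nchar(seq)), call. = FALSE)
    }
    pair_table(db)  # errors on unbalanced brackets
    data.frame(id = id, sequence = seq, structure = db, mfe = mfe,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Link mature sequences to hairpins
#'
#' Mature FASTA records do not carry coordinates, so linkage is resolved
#' either from an explicit two-column table (mature id, hairpin id) or by
#' exact substring search of the mature within every hairpin. A mature
#' matching a hairpin at more than one position (or, without a table,
#' matching several hairpins) is ambiguous and raises an error.
#'
#' @param matures data.frame from [read_fasta()] of mature sequences.
#' @param hairpins named list of [hairpin()] objects.
#' @param link optional data.frame with columns \code{mature_id},
#'   \code{hairpin_id}.
#' @param th thresholds (mature length bounds).
#' @return list of [mature_locus()] objects.
#' @export
link_matures <- function(matures, hairpins, link = NULL, th = thresholds()) {
  out <- list()
  for (k in seq_len(nrow(matures))) {
    mid <- matures$id[k]
    mseq <- matures$sequence[k]
    if (!is.null(link)) {
      hid <- link$hairpin_id[match(mid, link$mature_id)]
      if (is.na(hid) || is.null(hairpins[[hid]])) {
        stop(sprintf("mature '%s': no hairpin link or unknown hairpin '%s'",
                     mid, hid), call. = FALSE)
      }
      cand <- hid
    } else {
      cand <- names(hairpins)[vapply(hairpins, function(h)
        grepl(mseq, h$sequence, fixed = TRUE), NA)]
      if (length(cand) == 0L) {
        stop(sprintf("mature '%s' not found in any hairpin", mid),
             call. = FALSE)
      }
      if (length(cand) > 1L) {
        stop(sprintf("mature '%s' matches %d hairpins (%s); supply a link table",
                     mid, length(cand), paste(cand, collapse = ", ")),
             call. = FALSE)
      }
    }
    h <- hairpins[[cand]]
    hits <- find_all_starts(mseq, h$sequence)  # overlap-aware
    if (!length(hits)) {
      hits <- -1L
    }
    if (hits[1L] == -1L) {
      stop(sprintf("mature '%s' is not a substring of hairpin '%s'",
                   mid, cand), call. = FALSE)
    }
    if (length(hits) > 1L) {
      stop(sprintf("mature '%s' matches hairpin '%s' at %d positions; supply coordinates",
                   mid, cand, length(hits)), call. = FALSE)
    }
    start <- as.integer(hits[1L])
    end <- start + nchar(mseq) - 1L
    # arm from name suffix if present, else by position relative to midpoint;
    # structure_analysis re-checks against the located loop downstream
    arm <- if (grepl("-5p$", mid)) "5p"
           else if (grepl("-3p$", mid)) "3p"
           else if ((start + end) / 2 <= nchar(h$sequence) / 2) "5p" else "3p"
    out[[length(out) + 1L]] <- mature_locus(
      mid, cand, start, end, arm, "annotated",
      hairpin_length = nchar(h$sequence),
      len_min = th$read_len_min, len_max = th$read_len_max)
  }
  out
}

report_columns <- c("locus_id", "verdict",
                    "c1_read_depth", "c2_overhang",
                    "c3_five_prime_homogeneity", "c4_energy",
                    "c5_mature_pairing",
                    "reads_5p", "reads_3p",
                    "modal5p_fraction_5p", "modal5p_fraction_3p",
                    "overhang_5p", "overhang_3p",
                    "annotated_overhang_5p", "annotated_overhang_3p",
                    "mfe", "energy_per_nt", "mature_paired_fraction",
                    "structure_source", "multi_hit", "notes")

calls_to_frame <- function(calls) {
  if (!length(calls)) {
    df <- as.data.frame(setNames(rep(list(character(0)),
                                     length(report_columns)),
                                 report_columns))
    return(df)
  }
  rows <- lapply(calls, function(cl) {
    m <- cl$criteria$metrics
    num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
    data.frame(
      locus_id = cl$hairpin_id,
      verdict = cl$verdict,
      c1_read_depth = cl$criteria$c1_read_depth,
      c2_overhang = cl$criteria$c2_overhang,
      c3_five_prime_homogeneity = cl$criteria$c3_five_prime_homogeneity,
      c4_energy = cl$criteria$c4_energy,
      c5_mature_pairing = cl$criteria$c5_mature_pairing,
      reads_5p = num(m$reads_5p), reads_3p = num(m$reads_3p),
      modal5p_fraction_5p = num(m$modal5p_fraction_5p),
      modal5p_fraction_3p = num(m$modal5p_fraction_3p),
      overhang_5p = num(m$overhang_5p), overhang_3p = num(m$overhang_3p),
      annotated_overhang_5p = num(m$annotated_overhang_5p),
      annotated_overhang_3p = num(m$annotated_overhang_3p),
      mfe = num(m$mfe), energy_per_nt = num(m$energy_per_nt),
      mature_paired_fraction = num(m$mature_paired_fraction),
      structure_source = if (is.null(m$structure_source)) NA_character_
                         else m$structure_source,
      multi_hit = isTRUE(m$multi_hit),
      notes = paste(cl$notes, collapse = "; "),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a classification report
#'
#' TSV: one row per locus with verdict, the five criteria booleans and all
#' raw metrics. GFF3: one row per locus with 1-based inclusive coordinates
#' and a \code{high_confidence=true/false} attribute.
#'
#' @param calls list of confidence calls from [classify()] /
#'   [classify_batch()].
#' @param path output file.
#' @param format \code{"tsv"} or \code{"gff3"}.
#' @param loci optional named list of locus bundles (used by GFF3 for
#'   hairpin lengths and mature features).
#' @return \code{path}, invisibly.
#' @export
write_report <- function(calls, path, format = c("tsv", "gff3"),
                         loci = NULL) {
  format <- match.arg(format)
  df <- calls_to_frame(calls)
  if (format == "tsv") {
    num_cols <- vapply(df, is.numeric, NA)
    df[num_cols] <- lapply(df[num_cols], function(x)
      ifelse(is.na(x), NA, formatC(x, digits = 6L, format = "f")))
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop(sprintf("cannot write report to '%s'", path), call. = FALSE)
  } else {
    lines <- "##gff-version 3"
    for (cl in calls) {
      hc <- tolower(as.character(cl$verdict %in%
                                   c("HIGH_CONFIDENCE", "MANUAL")))
      len <- NA_integer_
      if (!is.null(loci) && !is.null(loci[[cl$hairpin_id]])) {
        len <- nchar(loci[[cl$hairpin_id]]$hairpin$sequence)
      }
      attrs <- sprintf("ID=%s;verdict=%s;high_confidence=%s",
                       cl$hairpin_id, cl$verdict, hc)
      lines <- c(lines, paste(cl$hairpin_id, "mirstack",
                              "miRNA_primary_transcript",
                              1L, ifelse(is.na(len), 1L, len),
                              ".", "+", ".", attrs, sep = "\t"))
      if (!is.null(loci) && !is.null(loci[[cl$hairpin_id]])) {
        for (m in loci[[cl$hairpin_id]]$matures) {
          mattrs <- sprintf("ID=%s;Parent=%s;arm=%s;provenance=%s",
                            m$id, cl$hairpin_id, m$arm, m$provenance)
          lines <- c(lines, paste(cl$hairpin_id, "mirstack", "miRNA",
                                  m$start, m$end, ".", "+", ".", mattrs,
                                  sep = "\t"))
        }
      }
    }
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("cannot write report to '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path report TSV.
#' @return data.frame with the documented report columns.
#' @export
read_report <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(structure_source = "character",
                                   notes = "character"))
}
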