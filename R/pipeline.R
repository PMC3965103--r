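# End-to-end runs over files on disk, plus per-species summaries. The
# command-line wrapper in inst/cli/mirstack.R is a thin shell over these.

#' Assemble a run configuration
#'
#' @param hairpins path to hairpin FASTA.
#' @param matures path to mature FASTA.
#' @param reads named character vector of read-set paths; names are the
#'   dataset labels used in the log.
#' @param mature_links optional TSV (\code{mature_id}, \code{hairpin_id}).
#' @param structures optional RNAfold-style dot-bracket file.
#' @param overrides optional TSV (\code{locus_id}, \code{forced_verdict},
#'   \code{reason}) of manual promotions/demotions.
#' @param out_dir output directory.
#' @param th thresholds.
#' @param read_format \code{"fasta"} or \code{"fastq"}.
#' @param dialect collapsed-header dialect for the read files.
#' @param refold refold even when structures are supplied.
#' @param per_dataset_mode evaluate read depth per dataset, see
#'   [analyze_locus()].
#' @param report_format \code{"tsv"} or \code{"gff3"} (TSV is always
#'   written; GFF3 additionally when selected).
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(hairpins, matures, reads, mature_links = NULL,
                       structures = NULL, overrides = NULL,
                       out_dir = ".", th = thresholds(),
                       read_format = "fasta", dialect = "none",
                       refold = FALSE, report_format = "tsv",
                       per_dataset_mode = FALSE) {
  cfg <- list(hairpins = hairpins, matures = matures, reads = reads,
              mature_links = mature_links, structures = structures,
              overrides = overrides, out_dir = out_dir, th = th,
              read_format = read_format, dialect = dialect,
              refold = refold, report_format = report_format,
              per_dataset_mode = per_dataset_mode)
  required <- c(hairpins, matures, unname(reads), mature_links, structures,
                overrides)
  missing <- required[!file.exists(required)]
  if (length(missing)) {
    stop(sprintf("input file(s) not found: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full classification pipeline
#'
#' Reads all inputs, analyzes every hairpin, and writes into
#' \code{out_dir}: \code{report.tsv} (full report), optionally
#' \code{report.gff3}, \code{high_confidence.tsv} and
#' \code{high_confidence.fa} (the high-confidence subset, including
#' manual promotions), and \code{run_log.txt} (thresholds, structure
#' source, folding engine, tallies; the timestamp lives only here so the
#' report itself is byte-stable across reruns).
#'
#' @param cfg a [run_config()].
#' @return list of confidence calls (with tallies attribute), invisibly.
#' @export
run_classify <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$th
  hp_df <- read_fasta(cfg$hairpins)
  structs <- if (!is.null(cfg$structures)) read_dotbracket(cfg$structures)
  hairpins <- list()
  for (k in seq_len(nrow(hp_df))) {
    st <- mfe <- NULL
    if (!is.null(structs)) {
      i <- match(hp_df$id[k], structs$id)
      if (!is.na(i)) {
        st <- structs$structure[i]
        if (!is.na(structs$mfe[i])) mfe <- structs$mfe[i]
      }
    }
    hairpins[[hp_df$id[k]]] <- hairpin(hp_df$id[k], hp_df$sequence[k],
                                       structure = st, mfe = mfe)
  }
  mat_df <- read_fasta(cfg$matures)
  link <- if (!is.null(cfg$mature_links)) {
    utils::read.delim(cfg$mature_links, stringsAsFactors = FALSE)
  }
  matures <- link_matures(mat_df, hairpins, link, th)
  read_sets <- lapply(cfg$reads, read_reads, format = cfg$read_format,
                      dialect = cfg$dialect)
  overrides <- if (!is.null(cfg$overrides)) {
    utils::read.delim(cfg$overrides, stringsAsFactors = FALSE)
  }
  loci <- lapply(hairpins, function(hp) {
    mine <- Filter(function(m) m$hairpin_id == hp$id, matures)
    list(hairpin = hp, matures = mine, read_sets = read_sets)
  })
  calls <- classify_batch(loci, th, overrides,
                          per_dataset = isTRUE(cfg$per_dataset_mode))
  tallies <- attr(calls, "tallies")

  write_report(calls, file.path(cfg$out_dir, "report.tsv"), "tsv")
  if (cfg$report_format == "gff3") {
    bundles <- lapply(loci, function(b) list(hairpin = b$hairpin,
                                             matures = b$matures))
    write_report(calls, file.path(cfg$out_dir, "report.gff3"), "gff3",
                 loci = bundles)
  }
  hc <- Filter(function(cl)
    cl$verdict %in% c("HIGH_CONFIDENCE", "MANUAL"), calls)
  write_report(hc, file.path(cfg$out_dir, "high_confidence.tsv"), "tsv")
  fa <- unlist(lapply(hc, function(cl)
    c(sprintf(">%s %s", cl$hairpin_id, cl$verdict),
      hairpins[[cl$hairpin_id]]$sequence)))
  writeLines(if (is.null(fa)) character(0) else fa,
             file.path(cfg$out_dir, "high_confidence.fa"))

  engine <- if (any(vapply(hairpins, function(h) is.null(h$structure), NA)) ||
                cfg$refold) {
    tryCatch(fold("GGGGAAAACCCC")$engine, error = function(e) "unavailable")
  } else "not used (structures supplied)"
  log_lines <- c(
    sprintf("mirstack run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("hairpins: %d; matures: %d; datasets: %d",
            length(hairpins), length(matures), length(cfg$reads)),
    sprintf("folding engine: %s", engine),
    "thresholds:",
    sprintf("  %s: %s", names(unclass(th)),
            vapply(unclass(th), format, "")),
    "verdict tallies:",
    sprintf("  %s: %d", names(tallies), as.integer(tallies)),
    if (length(attr(calls, "failures"))) {
      c("failures:", paste0("  ", attr(calls, "failures")))
    })
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(calls)
}

#' Summarize a report per species
#'
#' Groups loci by the three-letter organism prefix of their ids
#' (\code{"dme-"}, \code{"hsa-"}, ...); ids without a recognizable prefix
#' are grouped under \code{"unknown"}.
#'
#' @param report_path path to a TSV report from [run_classify()] /
#'   [write_report()].
#' @return data.frame with columns \code{species}, \code{n},
#'   \code{n_high_confidence}, \code{fraction_high_confidence}.
#' @export
run_summarize <- function(report_path) {
  rep <- read_report(report_path)
  if (!nrow(rep)) {
    return(data.frame(species = character(0), n = integer(0),
                      n_high_confidence = integer(0),
                      fraction_high_confidence = numeric(0)))
  }
  sp <- vapply(rep$locus_id, function(id) {
    p <- species_prefix(id)
    if (is.na(p)) "unknown" else p
  }, "")
  hc <- rep$verdict %in% c("HIGH_CONFIDENCE", "MANUAL")
  out <- do.call(rbind, lapply(split(seq_along(sp), sp), function(idx) {
    data.frame(species = sp[idx[1L]], n = length(idx),
               n_high_confidence = sum(hc[idx]),
               fraction_high_confidence = sum(hc[idx]) / length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}
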