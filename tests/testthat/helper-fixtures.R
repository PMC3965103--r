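# Shared test helpers: tiny independent oracles and fixture writers.
# Oracles are deliberately naive (linear scans, recursion) and share no
# code with the implementation paths they check.

rand_rna <- function(n, gc = 0.5) {
  p <- c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
  paste(sample(c("G", "C", "A", "U"), n, replace = TRUE, prob = p),
        collapse = "")
}

# brute-force all-offsets exact substring scan (mapping oracle)
naive_substring_starts <- function(pattern, x) {
  np <- nchar(pattern)
  hits <- integer(0)
  for (s in seq_len(nchar(x) - np + 1L)) {
    if (substr(x, s, s + np - 1L) == pattern) hits <- c(hits, s)
  }
  hits
}

# recursive-descent dot-bracket matcher (pair-table oracle)
recursive_pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1L]]
  pt <- rep(NA_integer_, length(ch))
  match_from <- function(i, stop_at) {
    while (i <= stop_at) {
      if (ch[i] == "(") {
        # find the matching ')' by depth counting, then recurse inside
        depth <- 1L
        j <- i
        while (depth > 0L) {
          j <- j + 1L
          if (ch[j] == "(") depth <- depth + 1L
          if (ch[j] == ")") depth <- depth - 1L
        }
        pt[i] <<- j
        pt[j] <<- i
        match_from(i + 1L, j - 1L)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  match_from(1L, length(ch))
  pt
}

# random valid dot-bracket string built from an explicit recursive grammar
rand_dotbracket <- function(n_items = 8L, depth = 0L) {
  out <- character(0)
  for (k in seq_len(n_items)) {
    if (depth < 4L && runif(1) < 0.4) {
      inner <- rand_dotbracket(sample(0:4, 1L), depth + 1L)
      out <- c(out, "(", inner, ")")
    } else {
      out <- c(out, ".")
    }
  }
  paste(out, collapse = "")
}

# write a temporary FASTA file from id/sequence vectors
write_tmp_fasta <- function(ids, seqs, descriptions = NULL) {
  path <- tempfile(fileext = ".fa")
  hdr <- if (is.null(descriptions)) paste0(">", ids)
         else paste0(">", ids, " ", descriptions)
  writeLines(as.vector(rbind(hdr, seqs)), path)
  path
}

# a deterministic ideal locus bundle used across tests
ideal_case <- function(seed = 1L, ...) {
  spec <- locus_spec(seed = seed, ...)
  bundle <- make_hairpin(spec)
  reads <- make_read_stack(spec, bundle)
  list(spec = spec, hairpin = bundle$hairpin, matures = bundle$matures,
       reads = reads)
}
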