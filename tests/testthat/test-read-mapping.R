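test_that("exact mapping equals a naive all-offsets scan", {
  set.seed(21)
  th <- thresholds()
  for (k in 1:25) {
    hp <- hairpin(sprintf("syn-mir-%d", k), rand_rna(80))
    reads <- data.frame(
      sequence = vapply(1:20, function(i) {
        if (runif(1) < 0.6) {  # mostly genuine substrings
          s <- sample(1:(80 - 21), 1)
          substr(hp$sequence, s, s + 20L)
        } else rand_rna(21)
      }, ""),
      count = sample(1:50, 20, replace = TRUE))
    alns <- map_reads_exact(reads, hp, th)
    expected <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i) {
      hits <- naive_substring_starts(reads$sequence[i], hp$sequence)
      if (!length(hits)) return(NULL)
      data.frame(sequence = reads$sequence[i], start = hits,
                 count = reads$count[i], multi_hit = length(hits) > 1)
    }))
    if (is.null(expected)) {
      expect_identical(nrow(alns), 0L)
    } else {
      o1 <- order(alns$sequence, alns$start)
      o2 <- order(expected$sequence, expected$start)
      expect_equal(alns[o1, ], expected[o2, ], ignore_attr = TRUE)
    }
  }
})

test_that("multi-hit reads align at every occurrence with full count", {
  hp <- hairpin("syn-mir-1",
                paste0("GCGCGCGCGCUAUAUACGCG", strrep("A", 6),
                       "CGCGUAUAUAGCGCGCGCGC"))
  th <- thresholds(read_len_min = 2L)
  reads <- data.frame(sequence = "UAUAUA", count = 5L)
  alns <- map_reads_exact(reads, hp, th)
  expect_identical(alns$start,
                   naive_substring_starts("UAUAUA", hp$sequence))
  expect_true(all(alns$multi_hit))
  expect_true(all(alns$count == 5L))
})

test_that("length-filtered reads are tallied, not silently lost", {
  hp <- hairpin("syn-mir-1", strrep("ACGU", 15))
  reads <- data.frame(sequence = c("ACGUACGUACGUACGUACGU", "ACGU"),
                      count = c(3L, 9L))
  alns <- map_reads_exact(reads, hp)
  expect_identical(attr(alns, "n_length_filtered"), 9L)
  expect_true(all(nchar(alns$sequence) >= 16))
})

test_that("arm assignment follows overlap and loop-spanning rules", {
  cs <- ideal_case(seed = 31)
  pt <- pair_table(cs$hairpin$structure)
  part <- find_loop(pt)
  m5 <- cs$matures[[1]]; m3 <- cs$matures[[2]]
  th <- thresholds()
  expect_identical(assign_arm(m5$start, m5$end - m5$start + 1L,
                              cs$matures, part, th), "5p")
  expect_identical(assign_arm(m3$start, m3$end - m3$start + 1L,
                              cs$matures, part, th), "3p")
  # read covering the entire loop, far from both matures
  loop_read_start <- part$loop_start - 2L
  loop_read_w <- (part$loop_end - loop_read_start + 1L) + 2L
  expect_identical(assign_arm(loop_read_start, loop_read_w,
                              cs$matures, part, th), "loop")
  expect_error(assign_arm(1L, 20L, cs$matures, NULL, th), "partition")

  # randomized reads vs an independent interval-overlap reimplementation
  set.seed(32)
  L <- nchar(cs$hairpin$sequence)
  for (k in 1:300) {
    w <- sample(16:26, 1)
    s <- sample(1:(L - w + 1L), 1)
    got <- assign_arm(s, w, cs$matures, part, th)
    e <- s + w - 1L
    ov5 <- max(0L, min(e, m5$end) - max(s, m5$start) + 1L)
    ov3 <- max(0L, min(e, m3$end) - max(s, m3$start) + 1L)
    want <- if (ov5 >= w / 2 && ov5 >= ov3) "5p"
            else if (ov3 >= w / 2) "3p"
            else if (s <= part$loop_start && e >= part$loop_end) "loop"
            else "unassigned"
    expect_identical(got, want)
  }
})

test_that("stacks merge duplicates and compute modal fractions correctly", {
  cs <- ideal_case(seed = 33)
  pt <- pair_table(cs$hairpin$structure)
  part <- find_loop(pt)
  m5 <- cs$matures[[1]]
  seq1 <- substr(cs$hairpin$sequence, m5$start, m5$end)
  alns <- data.frame(sequence = c(seq1, seq1),
                     start = c(m5$start, m5$start),
                     count = c(3L, 7L), multi_hit = FALSE)
  stack <- build_stack(alns, cs$matures, part, cs$hairpin$id)
  expect_identical(nrow(stack$reads), 1L)
  expect_identical(stack$reads$count, 10L)
  expect_identical(stack$modal5p_fraction[["5p"]], 1)

  # starts {s: 60, s+1: 40} -> modal fraction 0.6
  seq2 <- substr(cs$hairpin$sequence, m5$start + 1L, m5$end + 1L)
  alns2 <- data.frame(sequence = c(seq1, seq2),
                      start = c(m5$start, m5$start + 1L),
                      count = c(60L, 40L), multi_hit = FALSE)
  stack2 <- build_stack(alns2, cs$matures, part, cs$hairpin$id)
  expect_equal(stack2$modal5p_fraction[["5p"]], 0.6)
  expect_identical(stack2$modal_start[["5p"]], m5$start)
})

test_that("modal fraction equals a brute-force maximum over start sums", {
  set.seed(34)
  cs <- ideal_case(seed = 34)
  pt <- pair_table(cs$hairpin$structure)
  part <- find_loop(pt)
  m5 <- cs$matures[[1]]
  for (k in 1:50) {
    n <- sample(3:12, 1)
    offs <- sample(-3:3, n, replace = TRUE)
    starts <- m5$start + offs
    alns <- data.frame(sequence = substring(cs$hairpin$sequence, starts,
                                            starts + 21L),
                       start = starts,
                       count = sample(1:20, n, replace = TRUE),
                       multi_hit = FALSE)
    stack <- build_stack(alns, cs$matures, part, cs$hairpin$id)
    sums <- tapply(alns$count, alns$start, sum)
    arm_total <- sum(alns$count)  # all fall on the 5p mature at these offsets
    expect_equal(stack$modal5p_fraction[["5p"]], max(sums) / arm_total)
    best <- as.integer(names(sums)[sums == max(sums)])
    expect_identical(stack$modal_start[["5p"]], min(best))
  }
})

test_that("aggregation conserves counts, ignores order and matches one-shot mapping", {
  set.seed(35)
  cs <- ideal_case(seed = 35)
  hp <- cs$hairpin
  pt <- pair_table(hp$structure)
  part <- find_loop(pt)
  th <- thresholds()
  for (k in 1:10) {
    n_sets <- sample(2:4, 1)
    sets <- lapply(seq_len(n_sets), function(i) {
      spec <- locus_spec(seed = 35L, reads_5p = sample(5:40, 1),
                         reads_3p = sample(5:40, 1),
                         modal_fraction_5p = runif(1, 0.3, 1),
                         modal_fraction_3p = runif(1, 0.3, 1))
      make_read_stack(spec, list(hairpin = hp, matures = cs$matures))
    })
    stacks <- lapply(sets, function(rs)
      build_stack(map_reads_exact(rs, hp, th), cs$matures, part, hp$id, th))
    agg <- aggregate_stacks(stacks, cs$matures, part, th)
    # conservation
    expect_identical(sum(agg$reads$count),
                     sum(vapply(stacks, function(s) sum(s$reads$count), 0L)))
    # order invariance
    perm <- aggregate_stacks(stacks[sample(n_sets)], cs$matures, part, th)
    expect_equal(agg, perm)
    # equals mapping the concatenation at once
    oneshot <- build_stack(map_reads_exact(do.call(rbind, sets), hp, th),
                           cs$matures, part, hp$id, th)
    expect_equal(agg, oneshot)
  }
  expect_error(aggregate_stacks(list(stacks[[1]],
                                     `[[<-`(stacks[[1]], "hairpin_id", "x")),
                                cs$matures, part, th), "different hairpins")
})

test_that("adding reads at the modal start never decreases the modal fraction", {
  set.seed(36)
  cs <- ideal_case(seed = 36)
  pt <- pair_table(cs$hairpin$structure)
  part <- find_loop(pt)
  th <- thresholds()
  base <- build_stack(map_reads_exact(cs$reads, cs$hairpin, th),
                      cs$matures, part, cs$hairpin$id, th)
  for (k in 1:100) {
    add <- sample(1:30, 1)
    top <- base$most_abundant[["5p"]]
    extra <- rbind(base$reads[, c("sequence", "start", "count", "multi_hit")],
                   data.frame(sequence = top$sequence, start = top$start,
                              count = add, multi_hit = FALSE))
    grown <- build_stack(extra, cs$matures, part, cs$hairpin$id, th)
    expect_gte(grown$modal5p_fraction[["5p"]],
               base$modal5p_fraction[["5p"]])
  }
})
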