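# Helper: run the full per-locus path on a synthetic case and return the
# bundle (stack, criteria, call).
analyze_case <- function(cs, th = thresholds()) {
  analyze_locus(cs$hairpin, cs$matures, cs$read_sets, th)
}

test_that("an ideal locus satisfies all five criteria", {
  cs <- make_case("SUPPORTED", seed = 61)
  res <- analyze_case(cs)
  b <- mirstack:::criteria_booleans(res$call$criteria)
  expect_true(all(b))
  expect_identical(res$call$verdict, "HIGH_CONFIDENCE")
  m <- res$call$criteria$metrics
  expect_identical(m$overhang_5p, 2L)
  expect_identical(m$overhang_3p, 2L)
  expect_identical(m$geometry_source, "most_abundant_reads")
})

test_that("nine reads on one arm fail only the read-depth criterion", {
  spec <- locus_spec(reads_3p = 9L, seed = 62)
  bundle <- make_hairpin(spec)
  reads <- make_read_stack(spec, bundle)
  res <- analyze_locus(bundle$hairpin, bundle$matures, list(reads))
  b <- mirstack:::criteria_booleans(res$call$criteria)
  expect_false(b[["c1"]])
  expect_true(all(b[c("c2", "c3", "c4", "c5")]))
  expect_identical(res$call$verdict, "INSUFFICIENT_EVIDENCE")
  # ten reads pass
  spec10 <- locus_spec(reads_3p = 10L, seed = 62)
  res10 <- analyze_locus(bundle$hairpin, bundle$matures,
                         list(make_read_stack(spec10, bundle)))
  expect_true(res10$call$criteria$c1_read_depth)
})

test_that("criteria booleans equal a straight-line re-evaluation on random loci", {
  set.seed(63)
  th <- thresholds()
  for (k in 1:150) {
    spec <- locus_spec(
      reads_5p = sample(0:25, 1), reads_3p = sample(0:25, 1),
      overhang_5p = sample(0:6, 1), overhang_3p = sample(0:6, 1),
      modal_fraction_5p = runif(1, 0.2, 1),
      modal_fraction_3p = runif(1, 0.2, 1),
      gc_fraction = runif(1, 0.3, 1), seed = 1000L + k)
    bundle <- make_hairpin(spec)
    reads <- make_read_stack(spec, bundle)
    res <- analyze_locus(bundle$hairpin, bundle$matures, list(reads), th)
    b <- mirstack:::criteria_booleans(res$call$criteria)
    m <- res$call$criteria$metrics
    expect_identical(b[["c1"]],
                     m$reads_5p >= th$min_reads_per_arm &&
                     m$reads_3p >= th$min_reads_per_arm)
    expect_identical(b[["c2"]],
                     !is.na(m$overhang_5p) && !is.na(m$overhang_3p) &&
                     m$overhang_5p >= th$overhang_min &&
                     m$overhang_5p <= th$overhang_max &&
                     m$overhang_3p >= th$overhang_min &&
                     m$overhang_3p <= th$overhang_max)
    expect_identical(b[["c3"]],
                     !is.na(m$modal5p_fraction_5p) &&
                     !is.na(m$modal5p_fraction_3p) &&
                     m$modal5p_fraction_5p >= th$min_modal5p_fraction &&
                     m$modal5p_fraction_3p >= th$min_modal5p_fraction)
    expect_identical(b[["c4"]], m$energy_per_nt < th$max_energy_per_nt)
    expect_identical(b[["c5"]],
                     m$mature_paired_fraction >= th$min_mature_paired_fraction)
    # verdict is the documented function of the booleans
    want <- if (all(b)) "HIGH_CONFIDENCE"
            else if (!b[["c1"]]) "INSUFFICIENT_EVIDENCE"
            else if (!b[["c2"]] || !b[["c3"]]) "PATTERN_INCONSISTENT"
            else "STRUCTURE_FAIL"
    expect_identical(res$call$verdict, want)
  }
})

test_that("verdicts partition: exactly one outcome per boolean combination", {
  for (mask in 0:31) {
    b <- c(c1 = bitwAnd(mask, 1L) > 0, c2 = bitwAnd(mask, 2L) > 0,
           c3 = bitwAnd(mask, 4L) > 0, c4 = bitwAnd(mask, 8L) > 0,
           c5 = bitwAnd(mask, 16L) > 0)
    cr <- mirstack:::criteria_result(b, list())
    stack <- structure(list(hairpin_id = "x"), class = "read_stack")
    v <- classify(cr, stack)$verdict
    matches <- c(all(b),
                 !b[["c1"]],
                 b[["c1"]] && (!b[["c2"]] || !b[["c3"]]),
                 b[["c1"]] && b[["c2"]] && b[["c3"]] &&
                   (!b[["c4"]] || !b[["c5"]]))
    expect_identical(sum(matches), 1L)
    expect_identical(v, c("HIGH_CONFIDENCE", "INSUFFICIENT_EVIDENCE",
                          "PATTERN_INCONSISTENT", "STRUCTURE_FAIL")[matches])
  }
})

test_that("a well-read locus on a badly pairing precursor is a structure failure", {
  cs <- make_case("SUPPORTED", seed = 64)
  # keep reads, but unpair the central 14 bp of the stem (and partners):
  # duplex-end anchors stay paired so the overhang criterion still holds,
  # while the mature pairing fraction drops to 16/44
  hp <- cs$hairpin
  db <- strsplit(hp$structure, "")[[1]]
  pt0 <- pair_table(hp$structure)
  db[c(13:26, pt0[13:26])] <- "."
  hp$structure <- paste(db, collapse = "")
  res <- analyze_locus(hp, cs$matures, cs$read_sets)
  expect_false(res$call$criteria$c5_mature_pairing)
  expect_identical(res$call$verdict, "STRUCTURE_FAIL")
  # likewise a weak folding energy with everything else intact
  hp2 <- cs$hairpin
  hp2$mfe <- -0.1 * nchar(hp2$sequence)
  res2 <- analyze_locus(hp2, cs$matures, cs$read_sets)
  expect_false(res2$call$criteria$c4_energy)
  expect_identical(res2$call$verdict, "STRUCTURE_FAIL")
})

test_that("duplicating the most abundant reads never demotes a high-confidence call", {
  set.seed(65)
  for (k in 1:20) {
    cs <- make_case("SUPPORTED", seed = 600L + k)
    res <- analyze_case(cs)
    expect_identical(res$call$verdict, "HIGH_CONFIDENCE")
    boosted <- cs$read_sets[[1]]
    for (a in c("5p", "3p")) {
      top <- res$stack$most_abundant[[a]]
      boosted <- rbind(boosted,
                       data.frame(id = paste0("boost_", a),
                                  sequence = top$sequence,
                                  count = sample(1:200, 1)))
    }
    res2 <- analyze_locus(cs$hairpin, cs$matures, list(boosted))
    expect_identical(res2$call$verdict, "HIGH_CONFIDENCE")
  }
})

test_that("boosting reads can rescue insufficiency but preserves statelessness", {
  cs <- make_case("ONE_ARM_ONLY", seed = 66)
  res <- analyze_case(cs)
  expect_identical(res$call$verdict, "INSUFFICIENT_EVIDENCE")
  # add canonical reads on the silent arm: verdict moves to HIGH_CONFIDENCE
  m3 <- cs$matures[[2]]
  rescue <- rbind(cs$read_sets[[1]],
                  data.frame(id = "rescue_x20",
                             sequence = substr(cs$hairpin$sequence,
                                               m3$start, m3$end),
                             count = 20L))
  res2 <- analyze_locus(cs$hairpin, cs$matures, list(rescue))
  expect_identical(res2$call$verdict, "HIGH_CONFIDENCE")
})

test_that("batch classification tallies verdicts and survives bad loci", {
  cases <- c(lapply(1:4, function(s) make_case("SUPPORTED", s)),
             lapply(5:7, function(s) make_case("ONE_ARM_ONLY", s)),
             lapply(8:9, function(s) make_case("BAD_OVERHANG", s)))
  # one structure-fail locus: supported reads, weak energy
  sf <- make_case("SUPPORTED", 10)
  sf$hairpin$mfe <- -5
  cases <- c(cases, list(sf))
  calls <- classify_batch(cases)
  t <- attr(calls, "tallies")
  expect_identical(as.integer(t[c("HIGH_CONFIDENCE", "INSUFFICIENT_EVIDENCE",
                                  "PATTERN_INCONSISTENT", "STRUCTURE_FAIL")]),
                   c(4L, 3L, 2L, 1L))
  # permuting the batch yields the identical multiset of calls
  calls_perm <- classify_batch(rev(cases))
  expect_identical(sort(vapply(calls, `[[`, "", "verdict")),
                   sort(vapply(calls_perm, `[[`, "", "verdict")))
  # empty input
  empty <- classify_batch(list())
  expect_identical(length(empty), 0L)
  expect_identical(sum(attr(empty, "tallies")), 0L)
  # a failing locus is recorded, the batch continues
  broken <- cases
  broken[[1]]$hairpin$structure <- NULL
  broken[[1]]$hairpin$sequence <- strrep("A", 60)  # unfoldable: no loop
  calls2 <- classify_batch(broken)
  expect_identical(length(calls2), length(cases) - 1L)
  expect_match(attr(calls2, "failures"), "syn-mir-1")
})

test_that("manual overrides promote loci and record the prior verdict", {
  cs <- make_case("ONE_ARM_ONLY", seed = 67)
  ov <- data.frame(locus_id = cs$hairpin$id, forced_verdict = "MANUAL",
                   reason = "extensively studied locus")
  calls <- classify_batch(list(cs), overrides = ov)
  expect_identical(calls[[1]]$verdict, "MANUAL")
  expect_match(calls[[1]]$notes[length(calls[[1]]$notes)],
               "MANUAL override from INSUFFICIENT_EVIDENCE")
})

test_that("per-dataset mode requires the depth threshold within one dataset", {
  spec <- locus_spec(reads_5p = 12L, reads_3p = 12L, modal_fraction_5p = 1,
                     modal_fraction_3p = 1, seed = 68)
  bundle <- make_hairpin(spec)
  reads <- make_read_stack(spec, bundle)
  # split each arm's stack 6/6 across two datasets: summed counts pass,
  # no single dataset reaches 10 on any arm
  half <- reads; half$count <- 6L
  res_sum <- analyze_locus(bundle$hairpin, bundle$matures, list(half, half))
  expect_identical(res_sum$call$verdict, "HIGH_CONFIDENCE")
  res_ds <- analyze_locus(bundle$hairpin, bundle$matures, list(half, half),
                          per_dataset = TRUE)
  expect_identical(res_ds$call$verdict, "INSUFFICIENT_EVIDENCE")
  expect_match(paste(res_ds$call$notes, collapse = " "), "per-dataset")
  # a dataset that alone meets the threshold keeps the verdict
  res_ok <- analyze_locus(bundle$hairpin, bundle$matures,
                          list(reads, half), per_dataset = TRUE)
  expect_identical(res_ok$call$verdict, "HIGH_CONFIDENCE")
})
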