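test_that("marker genotyping follows the depth band rules", {
  ev <- noiseless_evidence(as_genotype(tiny_genome()))
  md <- ev$marker_depths$chrI
  md$depth_A <- 25; md$depth_B <- 25
  ev$marker_depths$chrI <- md
  mc <- call_markers(ev)
  expect_true(all(mc$state[mc$chrom == "chrI"] == "HET"))

  md$depth_A <- 50; md$depth_B <- 0
  ev$marker_depths$chrI <- md
  mc <- call_markers(ev)
  expect_true(all(mc$state[mc$chrom == "chrI"] == "HOM_A"))

  md$depth_A <- 2; md$depth_B <- 1
  ev$marker_depths$chrI <- md
  mc <- call_markers(ev, min_depth = 10)
  expect_true(all(mc$state[mc$chrom == "chrI"] == "NOCALL"))
})

test_that("segmentation places boundaries midway between flanking markers", {
  chroms <- data.frame(name = "chrI", length = 30000)
  mc <- fake_calls(rep("HET", 200))
  segs <- segment_states(mc, chroms)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$state, "HET")
  expect_equal(c(segs$start, segs$end), c(0, 30000))

  mc <- fake_calls(c(rep("HET", 100), rep("HOM_A", 100)))
  segs <- segment_states(mc, chroms)
  expect_equal(nrow(segs), 2)
  # markers at 100*i bp: change between marker 100 (10000) and 101 (10100)
  expect_equal(segs$end[1], 10050)
  expect_equal(segs$start[2], 10050)
  expect_true(segs$terminal[1] && segs$terminal[2])
})

test_that("isolated miscalls are smoothed away, short runs merged", {
  chroms <- data.frame(name = "chrI", length = 30000)
  states <- rep("HET", 200)
  states[c(50, 120)] <- "HOM_B"              # isolated flips
  segs <- segment_states(fake_calls(states), chroms)
  expect_equal(nrow(segs), 1)
  states[90:92] <- "HOM_A"                   # run of 3 < min_segment_markers
  segs <- segment_states(fake_calls(states), chroms, min_segment_markers = 5)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$state, "HET")
})

test_that("breakpoint refinement snaps by distance, support, then coordinate", {
  jn <- data.frame(chrom1 = "chrI", pos1 = 10000, side1 = "left",
                   chrom2 = "chrII", pos2 = 99999, side2 = "right",
                   support = 12)
  r <- refine_breakpoint(10050, "chrI", jn, window = 1000)
  expect_equal(r$pos, 10000)
  expect_false(r$approximate)

  r <- refine_breakpoint(50000, "chrI", jn, window = 1000)
  expect_equal(r$pos, 50000)
  expect_true(r$approximate)

  jn2 <- rbind(jn, data.frame(chrom1 = "chrI", pos1 = 10100, side1 = "left",
                              chrom2 = "chrII", pos2 = 5, side2 = "right",
                              support = 30))
  expect_equal(refine_breakpoint(10049, "chrI", jn2, window = 1000)$pos,
               10000)      # nearer wins over higher support
  jn3 <- jn2; jn3$pos1[2] <- 10098          # equidistant from 10049
  expect_equal(refine_breakpoint(10049, "chrI", jn3, window = 1000)$pos,
               10098)      # tie broken by support
  jn3$support[2] <- 12
  expect_equal(refine_breakpoint(10049, "chrI", jn3, window = 1000)$pos,
               10000)      # then by lower coordinate
  expect_error(refine_breakpoint(1, "chrI", jn, window = 0))
})

test_that("terminal reciprocal LOH is BIR, interstitial is sGC", {
  g <- tiny_genome()
  gt <- plant_events(g, list(
    rearrangement_event("BIR", "chrI", "B", breakpoint = 60000),
    rearrangement_event("SGC", "chrII", "A", interval = c(40000, 60000))))
  cl <- call_events(noiseless_evidence(gt))
  ev <- cl$events
  bir <- ev[ev$kind == "BIR", ]
  expect_equal(bir$chrom, "chrI")
  expect_equal(bir$homolog, "B")
  expect_equal(bir$donor_homolog, "A")
  expect_gt(bir$coverage_ratio, 0.95)
  sgc <- ev[ev$kind == "SGC", ]
  expect_equal(sgc$chrom, "chrII")
  expect_equal(sgc$homolog, "A")
  # classification consistency: BIR terminal, sGC interstitial by rule
  expect_true(bir$end == 120000 || bir$start == 0)
  expect_true(sgc$start > 0 && sgc$end < 100000)
})

test_that("aneuploidy is read from chromosome-wide homolog coverage", {
  g <- tiny_genome()
  gt <- plant_events(g, list(
    rearrangement_event("ANEUPLOIDY_LOSS", "chrII", "B"),
    rearrangement_event("ANEUPLOIDY_GAIN", "chrIII", "A")))
  aneu <- detect_aneuploidy(noiseless_evidence(gt))
  expect_equal(nrow(aneu), 2)
  expect_equal(aneu$kind[aneu$chrom == "chrII"], "ANEUPLOIDY_LOSS")
  expect_equal(aneu$homolog[aneu$chrom == "chrII"], "B")
  expect_equal(aneu$kind[aneu$chrom == "chrIII"], "ANEUPLOIDY_GAIN")
  # copy-neutral whole-chromosome LOH must not masquerade as aneuploidy
  gt2 <- plant_events(g, rearrangement_event("BIR", "chrI", "B",
                                             breakpoint = 1000))
  expect_equal(nrow(detect_aneuploidy(noiseless_evidence(gt2))), 0)
})

test_that("circularization needs both terminal losses and the joining junction", {
  g <- tiny_genome()
  x <- taqmap:::snap_to_site(g, "chrI", 20000)   # anchor at TCGA sites
  y <- taqmap:::snap_to_site(g, "chrI", 90000)
  gt <- plant_events(g, rearrangement_event("CIRCULARIZATION", "chrI", "B",
                                            breakpoints = c(x, y)))
  ev <- noiseless_evidence(gt)
  circ <- detect_circularization(ev, sites = g$sites)
  expect_equal(circ$events$kind, "CIRCULARIZATION")
  expect_equal(circ$events$start, x)
  expect_equal(circ$events$end, y)
  expect_equal(circ$events$site_dist_start, 0)   # anchored at TCGA sites

  # same coverage pattern, junction removed -> two terminal deletions
  ev$junctions <- ev$junctions[0, ]
  circ2 <- detect_circularization(ev, sites = g$sites)
  expect_equal(sort(circ2$events$kind), c("DELETION", "DELETION"))
  expect_false("CIRCULARIZATION" %in% circ2$events$kind)
})

test_that("deletion keeps its bridging junction, TL links another locus", {
  g <- tiny_genome()
  gt <- plant_events(g, list(
    rearrangement_event("DELETION", "chrII", "A", interval = c(40000, 60000)),
    rearrangement_event("TL", "chrIII", "A", breakpoint = 50000,
                        partner_chrom = "chrI", partner_pos = 80000)))
  cl <- call_events(noiseless_evidence(gt))
  del <- cl$events[cl$events$kind == "DELETION", ]
  expect_equal(nrow(del), 1)
  expect_equal(c(del$start, del$end), c(40000, 60000))
  expect_false(del$approximate)                  # snapped to the junction
  tl <- cl$events[cl$events$kind == "TL", ]
  expect_equal(nrow(tl), 1)
  expect_setequal(c(tl$chrom, tl$partner_chrom), c("chrIII", "chrI"))
})

test_that("noiseless caller output matches the truth set exactly", {
  g <- tiny_genome()
  gt <- plant_events(g, list(
    rearrangement_event("BIR", "chrI", "B", breakpoint = 60000),
    rearrangement_event("SGC", "chrII", "A", interval = c(30000, 45000)),
    rearrangement_event("ANEUPLOIDY_LOSS", "chrIII", "B")))
  cl <- call_events(noiseless_evidence(gt), sites = g$sites)
  m <- match_events(gt, cl$events, tol_markers = 1)
  expect_true(all(m$matched))
  expect_equal(m$n_extra, 0)
})

test_that("an unrearranged genome yields no events", {
  g <- tiny_genome()
  cl <- call_events(noiseless_evidence(as_genotype(g)))
  expect_equal(nrow(cl$events), 0)
})
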