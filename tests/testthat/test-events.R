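test_that("BIR converts marker states from the breakpoint to the chosen end", {
  g <- tiny_genome()
  p <- 60000
  gt <- plant_events(g, rearrangement_event("BIR", "chrI", "B",
                                            breakpoint = p, end = "right"))
  pos <- g$markers$chrI$pos
  expect_true(all(gt$states$chrI$B[pos >= p] == "A"))
  expect_true(all(gt$states$chrI$B[pos < p] == "B"))
  expect_identical(gt$states$chrI$A, rep("A", length(pos)))  # donor untouched
  expect_identical(gt$states$chrII$B, rep("B", nrow(g$markers$chrII)))

  gt_l <- plant_events(g, rearrangement_event("BIR", "chrI", "A",
                                              breakpoint = p, end = "left"))
  expect_true(all(gt_l$states$chrI$A[pos < p] == "B"))
  expect_true(all(gt_l$states$chrI$A[pos >= p] == "A"))
})

test_that("an empty event list is the identity", {
  g <- tiny_genome()
  gt0 <- as_genotype(g)
  gt <- plant_events(g, list())
  expect_identical(gt$states, gt0$states)
  expect_identical(gt$cn, gt0$cn)
  expect_equal(length(gt$truth), 0)
})

test_that("sGC converts only its interstitial interval", {
  g <- tiny_genome()
  gt <- plant_events(g, rearrangement_event("SGC", "chrII", "A",
                                            interval = c(30000, 45000)))
  pos <- g$markers$chrII$pos
  inside <- pos >= 30000 & pos < 45000
  expect_true(all(gt$states$chrII$A[inside] == "B"))
  expect_true(all(gt$states$chrII$A[!inside] == "A"))
  expect_error(plant_events(g, rearrangement_event(
    "SGC", "chrII", "A", interval = c(0, 45000))), "interstitial")
})

test_that("circularization zeroes copy number outside its arc and records the junction", {
  g <- tiny_genome()
  x <- 20000; y <- 90000
  gt <- plant_events(g, rearrangement_event("CIRCULARIZATION", "chrI", "B",
                                            breakpoints = c(x, y)))
  tr <- gt$cn$chrI$B
  expect_equal(taqmap:::cn_at(tr, c(0, x - 1, x, y - 1, y, 119999)),
               c(0, 0, 1, 1, 0, 0))
  expect_equal(nrow(gt$junctions), 1)
  expect_equal(gt$junctions$pos1, x)
  expect_equal(gt$junctions$side1, "right")
  expect_equal(gt$junctions$pos2, y)
  expect_equal(gt$junctions$side2, "left")
  expect_error(plant_events(g, rearrangement_event(
    "CIRCULARIZATION", "chrI", "B", breakpoints = c(0, y))), "interior")
})

test_that("aneuploidy sets homolog copy number chromosome-wide", {
  g <- tiny_genome()
  gt <- plant_events(g, list(
    rearrangement_event("ANEUPLOIDY_LOSS", "chrI", "B"),
    rearrangement_event("ANEUPLOIDY_GAIN", "chrII", "A")))
  expect_equal(gt$cn$chrI$B$cn, 0)
  expect_equal(gt$cn$chrI$A$cn, 1)
  expect_equal(gt$cn$chrII$A$cn, 2)
})

test_that("deletion zeroes its interval and bridges it with a junction", {
  g <- tiny_genome()
  gt <- plant_events(g, rearrangement_event("DELETION", "chrIII", "A",
                                            interval = c(40000, 60000)))
  expect_equal(taqmap:::cn_at(gt$cn$chrIII$A, c(39999, 40000, 59999, 60000)),
               c(1, 0, 0, 1))
  expect_equal(gt$junctions$side1, "left")
  expect_equal(gt$junctions$side2, "right")
})

test_that("reciprocal TL records two junctions and leaves marker states alone", {
  g <- tiny_genome()
  gt <- plant_events(g, rearrangement_event(
    "TL", "chrI", "A", breakpoint = 50000,
    partner_chrom = "chrII", partner_pos = 70000))
  expect_equal(nrow(gt$junctions), 2)
  expect_identical(gt$states, as_genotype(g)$states)
  expect_error(rearrangement_event("TL", "chrI", "A", breakpoint = 5,
                                   partner_chrom = "chrI", partner_pos = 5),
               "distinct")
})

test_that("contradictory overlapping events are rejected naming the pair", {
  g <- tiny_genome()
  evs <- list(
    rearrangement_event("BIR", "chrI", "B", breakpoint = 50000, end = "right"),
    rearrangement_event("SGC", "chrI", "B", interval = c(60000, 70000)))
  expect_error(plant_events(g, evs), "BIR.*SGC|SGC.*BIR")
  # same footprints on different homologs are fine for plant_events
  evs[[2]]$homolog <- "A"
  expect_silent(plant_events(g, evs))
  expect_error(plant_events(g, rearrangement_event(
    "BIR", "chrI", "B", breakpoint = 2e6)), "bounds")
})

test_that("truth set retains every planted event exactly once", {
  g <- tiny_genome()
  evs <- list(
    rearrangement_event("BIR", "chrI", "B", breakpoint = 60000),
    rearrangement_event("SGC", "chrII", "A", interval = c(30000, 45000)),
    rearrangement_event("ANEUPLOIDY_LOSS", "chrIII", "B"))
  gt <- plant_events(g, evs)
  expect_equal(length(gt$truth), 3)
  expect_identical(lapply(gt$truth, `[[`, "kind"),
                   lapply(evs, `[[`, "kind"))
  td <- truth_events_df(gt)
  expect_equal(nrow(td), 3)
  expect_equal(td$kind, c("BIR", "SGC", "ANEUPLOIDY_LOSS"))
})

test_that("planting is invertible: re-converting restores ancestral states", {
  g <- tiny_genome()
  gt <- plant_events(g, rearrangement_event("BIR", "chrI", "B",
                                            breakpoint = 60000))
  # the inverse description: convert the same tract back to B alleles
  pos <- g$markers$chrI$pos
  gt$states$chrI$B[pos >= 60000] <- "B"
  expect_identical(gt$states, as_genotype(g)$states)
})
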