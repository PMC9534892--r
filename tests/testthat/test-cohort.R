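test_that("a vacuous selection threshold accepts every draw", {
  g <- tiny_genome()
  co <- simulate_taq_cohort(g, n_mutants = 5, selection_threshold = 1.01,
                            seed = 2)
  expect_equal(co$n_draws, 5)
  expect_equal(co$acceptance_rate, 1)
})

test_that("an unreachable threshold fails explicitly at the draw cap", {
  g <- tiny_genome()
  expect_error(
    simulate_taq_cohort(g, n_mutants = 2, events_per_mutant = 0,
                        selection_threshold = 0.2, max_draws = 25, seed = 4),
    "unreachable")
})

test_that("every accepted mutant disrupts at least one causal locus", {
  g <- tiny_genome()
  m <- default_phenotype_model(g)
  co <- simulate_taq_cohort(g, m, n_mutants = 30, selection_threshold = 0.2,
                            seed = 8)
  # oracle: direct genotype inspection of the three loci in the truth sets
  disrupted <- vapply(co$mutants, function(gt) {
    str_pos <- mean(m$structural$interval)
    reps <- vapply(c("A", "B"), function(h) {
      cn <- taqmap:::cn_at(gt$cn[[m$structural$chrom]][[h]], str_pos)
      if (cn >= 1)
        m$structural$repeat_units[[taqmap:::state_at(gt, m$structural$chrom,
                                                     h, str_pos)]]
      else 0
    }, 0)
    act <- any(vapply(c("A", "B"), function(h) {
      cn <- taqmap:::cn_at(gt$cn[[m$activator$chrom]][[h]], m$activator$pos)
      cn >= 1 && isTRUE(m$activator$functional[[
        taqmap:::state_at(gt, m$activator$chrom, h, m$activator$pos)]])
    }, TRUE))
    dose <- sum(vapply(c("A", "B"), function(h) {
      cn <- taqmap:::cn_at(gt$cn[[m$repressor$chrom]][[h]], m$repressor$pos)
      if (cn >= 1 && isTRUE(m$repressor$functional[[
        taqmap:::state_at(gt, m$repressor$chrom, h, m$repressor$pos)]])) cn
      else 0
    }, 0))
    max(reps) < 18 || !act || dose >= 2
  }, TRUE)
  expect_equal(mean(disrupted), 1.0)
})

test_that("selection lowers the mean phenotype relative to unselected draws", {
  g <- tiny_genome()
  co <- simulate_taq_cohort(g, n_mutants = 60, selection_threshold = 0.2,
                            seed = 10)
  expect_gte(length(co$draw_scores), 100)
  expect_lt(mean(co$scores), mean(co$draw_scores))
})

test_that("every break-derived breakpoint sits on a recognition site", {
  g <- tiny_genome()
  co <- simulate_taq_cohort(g, n_mutants = 10, selection_threshold = 1.01,
                            seed = 12)
  for (gt in co$mutants) for (ev in gt$truth) {
    pts <- switch(ev$kind,
                  BIR = ev$breakpoint,
                  SGC = ev$interval,
                  DELETION = ev$interval,
                  CIRCULARIZATION = ev$breakpoints,
                  TL = c(ev$breakpoint), NULL)
    for (p in pts) expect_true(p %in% g$sites[[ev$chrom]])
    if (ev$kind == "TL")
      expect_true(ev$partner_pos %in% g$sites[[ev$partner_chrom]])
  }
})

test_that("cohorts are reproducible from the root seed", {
  g <- tiny_genome()
  c1 <- simulate_taq_cohort(g, n_mutants = 5, selection_threshold = 1.01,
                            seed = 14)
  c2 <- simulate_taq_cohort(g, n_mutants = 5, selection_threshold = 1.01,
                            seed = 14)
  expect_identical(lapply(c1$mutants, `[[`, "truth"),
                   lapply(c2$mutants, `[[`, "truth"))
  e1 <- simulate_cohort_evidence(c1, seed = 3)
  e2 <- simulate_cohort_evidence(c2, seed = 3)
  expect_identical(e1[[1]]$marker_depths, e2[[1]]$marker_depths)
})
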