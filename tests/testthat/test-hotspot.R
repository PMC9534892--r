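test_that("windowed homozygosity counts markers correctly", {
  chroms <- data.frame(name = "chrI", length = 30000)
  mc <- fake_calls(c(rep("HET", 10), rep("HOM_A", 12),
                     rep("HOM_B", 7), rep("HET", 3)), spacing = 1)
  # put markers into distinct windows by position
  mc$pos <- c(seq(0, 9), seq(10000, 10011), seq(20000, 20009))
  ws <- window_homozygosity(mc, chroms, window_size = 10000)
  expect_equal(ws$hom_fraction, c(0, 1, 0.7))
  expect_equal(ws$n_hom, c(0, 12, 7))
  expect_equal(ws$hom_het_odds, c(0, NA, 7 / 3))
  # conservation: window counts sum to chromosome-wide marker counts
  expect_equal(sum(ws$n_hom) + sum(ws$n_het), nrow(mc))
  expect_error(window_homozygosity(mc, chroms, window_size = 500))
})

test_that("NOCALL markers count toward neither class", {
  chroms <- data.frame(name = "chrI", length = 10000)
  mc <- fake_calls(c(rep("HOM_A", 5), rep("NOCALL", 20)), spacing = 10)
  ws <- window_homozygosity(mc, chroms, window_size = 10000)
  expect_equal(ws$n_hom, 5)
  expect_equal(ws$n_het, 0)
  expect_equal(ws$hom_fraction, 1)
})

test_that("cohort aggregation counts LOH mutants per window", {
  chroms <- data.frame(name = "chrI", length = 30000)
  het <- window_homozygosity(fake_calls(rep("HET", 120), spacing = 249),
                             chroms, 10000)
  loh <- window_homozygosity(fake_calls(c(rep("HOM_A", 41), rep("HET", 79)),
                                        spacing = 249), chroms, 10000)
  agg <- aggregate_cohort(list(loh))
  expect_equal(agg$k, c(1, 0, 0))
  agg0 <- aggregate_cohort(list(het, het))
  expect_equal(agg0$k, c(0, 0, 0))
  # permutation invariance over mutant order
  a1 <- aggregate_cohort(list(loh, het, loh))
  a2 <- aggregate_cohort(list(het, loh, loh))
  expect_equal(a1$k, a2$k)
  # mismatched tilings rejected
  other <- window_homozygosity(fake_calls(rep("HET", 120), spacing = 249),
                               chroms, 15000)
  expect_error(aggregate_cohort(list(het, other)), "tiling")
})

test_that("LOH segments covering half a window count toward it", {
  chroms <- data.frame(name = "chrI", length = 30000)
  het <- window_homozygosity(fake_calls(rep("HET", 120), spacing = 249),
                             chroms, 10000)
  segs <- data.frame(chrom = "chrI", start = 14000, end = 26000,
                     state = "HOM_B")
  agg <- aggregate_cohort(list(het), segments = list(segs))
  expect_equal(agg$k, c(0, 1, 1))   # covers 60% of w2, 60% of w3
})

test_that("binomial hotspot test matches an explicit summation oracle", {
  agg <- data.frame(chrom = "chrI", start = (0:49) * 10000,
                    end = (1:50) * 10000, k = c(25, rep(3, 49)), M = 30)
  rep <- test_hotspots(agg, alpha = 0.05, p0 = 0.1)
  # oracle: direct tail sum of the binomial pmf
  tail_oracle <- sum(vapply(25:30, function(i)
    choose(30, i) * 0.1^i * 0.9^(30 - i), 0))
  expect_equal(rep$windows$p[1], tail_oracle, tolerance = 1e-12)
  expect_true(rep$windows$hotspot[1])
  expect_false(any(rep$windows$hotspot[-1]))
  expect_equal(nrow(rep$hotspots), 1)

  # k = 0 everywhere: nothing to call, degenerate background noted
  agg0 <- agg; agg0$k <- 0
  rep0 <- test_hotspots(agg0)
  expect_true(rep0$degenerate)
  expect_equal(nrow(rep0$hotspots), 0)
})

test_that("q-values are monotone in p-values and adjacent hotspots merge", {
  agg <- data.frame(chrom = "chrI", start = (0:39) * 10000,
                    end = (1:40) * 10000,
                    k = c(20, 22, rep(2, 38)), M = 30)
  rep <- test_hotspots(agg, p0 = 0.08)
  o <- order(rep$windows$p)
  expect_true(all(diff(rep$windows$q[o]) >= -1e-12))
  expect_equal(nrow(rep$hotspots), 1)           # two adjacent windows merged
  expect_equal(rep$hotspots$start, 0)
  expect_equal(rep$hotspots$end, 20000)
})

test_that("aneuploidy frequency tabulates per chromosome, homolog and type", {
  chroms <- data.frame(name = c("chrI", "chrII"), length = c(1e5, 1e5))
  empty <- aneuploidy_frequency(list(), chroms)
  expect_true(all(empty$count == 0))
  ev <- data.frame(kind = c("ANEUPLOIDY_LOSS", "ANEUPLOIDY_LOSS",
                            "ANEUPLOIDY_GAIN"),
                   chrom = c("chrI", "chrI", "chrII"),
                   homolog = c("B", "B", "A"))
  tab <- aneuploidy_frequency(list(ev[1:2, ], ev[3, ]), chroms)
  expect_equal(tab$count[tab$chrom == "chrI" & tab$homolog == "B" &
                           tab$type == "loss"], 2)
  expect_equal(tab$count[tab$chrom == "chrII" & tab$homolog == "A" &
                           tab$type == "gain"], 1)
  expect_equal(sum(tab$count), 3)
})

test_that("candidate genes are the hotspot-overlapping ones, ranked", {
  rep <- test_hotspots(data.frame(chrom = "chrI", start = (0:19) * 10000,
                                  end = (1:20) * 10000,
                                  k = c(rep(1, 10), 25, rep(1, 9)), M = 30),
                       p0 = 0.05)
  ann <- data.frame(gene = c("HIT", "MISS"), chrom = "chrI",
                    start = c(104000, 50000), end = c(106000, 52000))
  cand <- candidate_genes(rep, ann)
  expect_equal(cand$gene, "HIT")
  expect_equal(cand$overlap_fraction, 1)
  # gene desert
  cand2 <- candidate_genes(rep, ann[2, , drop = FALSE])
  expect_equal(nrow(cand2), 0)
  expect_warning(candidate_genes(rep, ann[0, , drop = FALSE]), "empty")
})
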