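passing_record <- function(...) {
  rec <- list(DP = 20, MQM = 40, QUAL = 200, AO = 15, SAF = 5, SAR = 10,
              RPR = 3, RPL = 5, AF = 1.0)
  utils::modifyList(rec, list(...))
}

test_that("the nine-clause chain passes a clean record and is strict at bounds", {
  expect_true(apply_filter_chain(passing_record())$pass)    # QUAL/AO ~ 13.3

  # every printed inequality is strict: boundary values fail their clause
  boundary <- list(DP = 15, MQM = 30, QUAL = 100, SAF = 0, SAR = 0,
                   RPR = 1, RPL = 1)
  for (f in names(boundary)) {
    r <- apply_filter_chain(do.call(passing_record,
                                    setNames(list(boundary[[f]]), f)))
    expect_false(r$pass)
    expect_true(f %in% r$failed_clauses ||
                  (f == "QUAL" && "QUAL" %in% r$failed_clauses))
  }
})

test_that("single-clause failures are named", {
  r <- apply_filter_chain(passing_record(DP = 15))
  expect_identical(r$failed_clauses, "DP")
  r <- apply_filter_chain(passing_record(AF = 0.5))
  expect_identical(r$failed_clauses, "AF")
  r <- apply_filter_chain(passing_record(QUAL = 120))  # QUAL/AO = 8 < 10
  expect_identical(r$failed_clauses, "QUAL/AO")
  # AF equality absorbs float round-trip
  expect_true(apply_filter_chain(passing_record(AF = 1 - 1e-12))$pass)
})

test_that("AO = 0 fails QUAL/AO by definition without dividing", {
  r <- apply_filter_chain(passing_record(AO = 0, SAF = 0, SAR = 0,
                                         RPR = 0, RPL = 0))
  expect_false(r$pass)
  expect_true("QUAL/AO" %in% r$failed_clauses)
})

test_that("malformed records are rejected naming the missing field", {
  rec <- passing_record(); rec$MQM <- NULL
  expect_error(apply_filter_chain(rec), "MQM")
})

test_that("raising QUAL never flips a pass into a fail", {
  set.seed(31)
  for (i in 1:50) {
    rec <- passing_record(DP = sample(10:40, 1), MQM = runif(1, 20, 50),
                          QUAL = runif(1, 50, 300),
                          AF = sample(c(1, 0.5), 1))
    p1 <- apply_filter_chain(rec)$pass
    rec$QUAL <- rec$QUAL + runif(1, 0, 500)
    p2 <- apply_filter_chain(rec)$pass
    expect_false(p1 && !p2)
  }
})

test_that("filtering is a pure per-record predicate", {
  set.seed(7)
  recs <- do.call(rbind, lapply(1:20, function(i)
    as.data.frame(passing_record(DP = sample(10:30, 1),
                                 QUAL = runif(1, 50, 300)))))
  out <- filter_variants(recs)
  perm <- sample.int(nrow(recs))
  out2 <- filter_variants(recs[perm, ])
  expect_identical(out$pass[perm], out2$pass)
  expect_identical(out$failed_clauses[perm], out2$failed_clauses)
})

test_that("variant_record enforces its internal consistency", {
  expect_error(variant_record(DP = 20, MQM = 40, QUAL = 200, AO = 10,
                              SAF = 5, SAR = 4, RPR = 5, RPL = 5, AF = 1),
               "SAF")
  expect_error(variant_record(DP = 5, MQM = 40, QUAL = 200, AO = 10,
                              SAF = 5, SAR = 5, RPR = 5, RPL = 5, AF = 1),
               "DP")
  rec <- variant_record(DP = 20, MQM = 40, QUAL = 200, AO = 10, SAF = 5,
                        SAR = 5, RPR = 5, RPL = 5, AF = 1)
  expect_true(apply_filter_chain(rec)$pass)
})

test_that("VCF records round-trip with multi-allelic decomposition", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrI,length=100000>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="depth">',
    '##INFO=<ID=MQM,Number=A,Type=Float,Description="mq">',
    '##INFO=<ID=AO,Number=A,Type=Integer,Description="alt obs">',
    '##INFO=<ID=SAF,Number=A,Type=Integer,Description="f">',
    '##INFO=<ID=SAR,Number=A,Type=Integer,Description="r">',
    '##INFO=<ID=RPR,Number=A,Type=Float,Description="pr">',
    '##INFO=<ID=RPL,Number=A,Type=Float,Description="pl">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="af">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chrI\t1\t.\tA\tG\t500\t.\t",
           "DP=40;MQM=55;AO=38;SAF=20;SAR=18;RPR=19;RPL=19;AF=1"),
    paste0("chrI\t777\t.\tC\tT,G\t200\t.\t",
           "DP=60;MQM=50,40;AO=30,20;SAF=15,10;SAR=15,10;RPR=14,9;",
           "RPL=16,11;AF=0.5,0.33"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  tab <- read_variant_table(path)
  expect_equal(nrow(tab), 3)                     # multi-allelic decomposed
  expect_equal(tab$pos[1], 1)                    # VCF pos 1 stays 1-based here
  expect_equal(tab$alt, c("G", "T", "G"))
  expect_equal(tab$AO, c(38, 30, 20))
  expect_equal(tab$MQM, c(55, 50, 40))
  out <- filter_variants(tab)
  expect_equal(out$pass, c(TRUE, FALSE, FALSE))
  audit <- withr::local_tempfile(fileext = ".tsv")
  write_filter_audit(out, audit)
  back <- read.table(audit, header = TRUE, sep = "\t")
  expect_equal(back$pass, out$pass)
})
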