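test_that("signal table writer/reader round-trips and sorts to map order", {
  set.seed(10)
  m <- tiny_map(2L, 8L)
  s <- signal_sample("NA12878",
                     lrr = round(rnorm(16, 0, 0.2), 4),
                     baf = round(runif(16), 4),
                     genotype = sample(c("AA", "AB", "BB", "NC"), 16, TRUE))
  f <- withr::local_tempfile(fileext = ".txt")
  write_signal_table(m, s, f)
  back <- read_signal_table(f)
  expect_equal(back$markers, m)
  expect_equal(back$sample$lrr, s$lrr)
  expect_equal(back$sample$baf, s$baf)
  expect_equal(back$sample$genotype, s$genotype)
  expect_equal(back$sample$sample_id, "NA12878")

  # shuffled rows come back in (chrom, position) order with values attached
  lines <- readLines(f)
  shuf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(lines[1], sample(lines[-1])), shuf)
  back2 <- read_signal_table(shuf)
  expect_equal(back2$markers, m)
  expect_equal(back2$sample$lrr, s$lrr)
})

test_that("unparseable signal fields become missing; structural faults error", {
  m <- tiny_map(1L, 3L)
  s <- signal_sample("s1", lrr = c(0.1, 0.2, 0.3), baf = c(0.5, 0.5, 0.5))
  f <- withr::local_tempfile()
  write_signal_table(m, s, f)
  lines <- readLines(f)
  parts <- strsplit(lines[3], "\t")[[1]]
  parts[5] <- "NaN"
  lines[3] <- paste(parts, collapse = "\t")
  writeLines(lines, f)
  back <- read_signal_table(f)
  expect_true(is.na(back$sample$baf[2]))
  expect_equal(back$sample$baf[-2], c(0.5, 0.5))
  expect_equal(back$sample$lrr, s$lrr)

  # missing required column
  bad <- withr::local_tempfile()
  writeLines(sub("\tPosition", "\tPos", readLines(f)[1]), bad)
  expect_error(read_signal_table(bad), "Position")
  # duplicate marker id
  dup <- withr::local_tempfile()
  l <- readLines(f); l[4] <- l[3]
  writeLines(l, dup)
  expect_error(read_signal_table(dup), "duplicate")
  # non-integer position
  ni <- withr::local_tempfile()
  l <- readLines(f)
  p <- strsplit(l[2], "\t")[[1]]; p[3] <- "12.5"
  l[2] <- paste(p, collapse = "\t")
  writeLines(l, ni)
  expect_error(read_signal_table(ni), "non-integer")
})

test_that("empty marker map writes a header-only table", {
  m <- tiny_map(1L, 1L)[0, ]
  s <- signal_sample("s1", lrr = numeric(), baf = numeric())
  f <- withr::local_tempfile()
  write_signal_table(m, s, f)
  expect_length(readLines(f), 1L)
})

test_that("rawcnv reader parses the dialect, commas and all", {
  f <- withr::local_tempfile()
  writeLines(paste("chr2:110852875-110983320 numsnp=66 length=130,446",
                   "state2,cn=1 sampleA startsnp=rs1 endsnp=rs2 conf=123.4"),
             f)
  calls <- read_cnv_calls(f)
  expect_equal(calls$chrom, "2")
  expect_equal(calls$start, 110852875)
  expect_equal(calls$end, 110983320)
  expect_equal(calls$cn, 1L)
  expect_equal(calls$n_snps, 66L)
  expect_equal(calls$confidence, 123.4)
  expect_equal(calls$sample_id, "sampleA")

  # missing conf -> 0; explicit sample_id overrides the file's
  writeLines("chr3:1000-2000 numsnp=12 length=1,001 state5,cn=3 x startsnp=a endsnp=b", f)
  c2 <- read_cnv_calls(f, sample_id = "s9")
  expect_equal(c2$confidence, 0)
  expect_equal(c2$sample_id, "s9")
  expect_equal(c2$cn, 3L)

  writeLines(character(), f)
  expect_equal(nrow(read_cnv_calls(f)), 0L)

  writeLines("chr1:5-10 numsnp=3 length=6 state3,cn=2 s startsnp=a endsnp=b conf=9", f)
  expect_error(read_cnv_calls(f), "cn=2")
  writeLines("chr1:5--10 numsnp=3 length=6 state2,cn=1 s startsnp=a endsnp=b conf=9", f)
  expect_error(read_cnv_calls(f), "malformed region")
})

test_that("rawcnv writer round-trips through the reader", {
  set.seed(11)
  calls <- mk_calls(chrom = c("1", "2", "10"), start = c(100, 5000, 7e6),
                    end = c(1100, 250000, 9e6), cn = c(1L, 3L, 0L),
                    n_snps = c(15L, 40L, 120L), confidence = c(51.5, 200, 12.25))
  f <- withr::local_tempfile()
  write_cnv_calls(calls, f)
  back <- read_cnv_calls(f, caller = "test")
  expect_equal(back, calls)
})

test_that("disorder database reader validates rows", {
  f <- withr::local_tempfile()
  writeLines(c("name\tchrom\tstart\tend\tdirection\texpected_cn",
               "Joubert syndrome 4\t2\t110852875\t110983320\tdel\t1",
               "overlap A\t5\t100\t900\tdup\t",
               "overlap B\t5\t500\t1500\tdup\t"), f)
  db <- read_disorder_db(f)
  expect_equal(nrow(db), 3L)
  expect_equal(db$name[1], "Joubert syndrome 4")
  expect_equal(db$start[1], 110852875)
  expect_equal(db$end[1], 110983320)
  expect_equal(db$expected_cn[1], 1L)
  # overlapping regions are both kept
  expect_equal(sum(db$chrom == "5"), 2L)

  writeLines(c("name\tchrom\tstart\tend\tdirection", "bad\t1\t500\t100\tdel"), f)
  expect_error(read_disorder_db(f), "end < start")
  writeLines(c("name\tchrom\tstart\tend\tdirection", "bad\t1\t100\t500\tgain"), f)
  expect_error(read_disorder_db(f), "del")
})

test_that("BED export shifts to 0-based half-open and clips scores", {
  calls <- mk_calls(chrom = "2", start = 110852875, end = 110983320, cn = 1L,
                    confidence = 2000)
  f <- withr::local_tempfile()
  write_calls_bed(calls, f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.numeric(fields[2]), 110852874)  # start - 1
  expect_equal(as.numeric(fields[3]), 110983320)  # end unchanged
  expect_equal(fields[4], "cn=1")
  expect_equal(as.numeric(fields[5]), 1000)       # clipped

  # shifting back recovers the 1-based inclusive interval
  expect_equal(as.numeric(fields[2]) + 1, calls$start)
  expect_equal(as.numeric(fields[3]), calls$end)

  write_calls_bed(calls[0, ], f)
  expect_length(readLines(f), 0L)
})

test_that("PFB table round-trips", {
  m <- tiny_map(1L, 5L)
  pfb <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  f <- withr::local_tempfile()
  write_pfb_table(m, pfb, f)
  expect_equal(unname(read_pfb_table(f)), pfb)
  expect_equal(names(read_pfb_table(f)), m$marker)
})

test_that("reference model archive round-trips exactly", {
  fx <- small_reference()
  d <- withr::local_tempdir()
  write_reference(fx$model, file.path(d, "ref"))
  back <- read_reference(file.path(d, "ref"))
  expect_equal(back$k, fx$model$k)
  expect_equal(back$centroids, fx$model$centroids)
  expect_equal(back$marker_mean, fx$model$marker_mean)
  expect_equal(back$marker_sd, fx$model$marker_sd)
  expect_equal(back$ref_features, fx$model$ref_features)
  expect_equal(back$labels, fx$model$labels)
  expect_equal(back$scheme$informative, fx$model$scheme$informative)
  expect_equal(back$markers, fx$model$markers)
  # a read-back model corrects a sample identically
  s <- fx$cohort$samples[[5]]
  expect_equal(correct_sample(s, back)$mlrr, correct_sample(s, fx$model)$mlrr)
})
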