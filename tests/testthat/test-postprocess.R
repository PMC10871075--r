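test_that("gap merging: strict 200 kb rule, direction-restricted", {
  a <- mk_calls(chrom = c("1", "1"), start = c(1000000, 1250001),
                end = c(1100000, 1350000), cn = c(1L, 1L),
                n_snps = c(12L, 15L), confidence = c(60, 70))
  merged <- merge_adjacent_calls(a)  # gap 150,000 < 200,000
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 1000000)
  expect_equal(merged$end, 1350000)
  expect_equal(merged$n_snps, 27L)
  expect_equal(merged$confidence, 130)
  expect_equal(merged$cn, 1L)

  # gap exactly 200,000 stays split
  b <- mk_calls(chrom = c("1", "1"), start = c(1000000, 1300001),
                end = c(1100000, 1400000), cn = c(1L, 1L))
  expect_equal(b$start[2] - b$end[1] - 1, 200000)
  expect_equal(nrow(merge_adjacent_calls(b)), 2L)

  # deletion and duplication never merge
  d <- mk_calls(chrom = c("1", "1"), start = c(1000000, 1110001),
                end = c(1100000, 1200000), cn = c(1L, 3L))
  expect_equal(nrow(merge_adjacent_calls(d)), 2L)

  # merged copy number comes from the longer constituent
  e <- mk_calls(chrom = c("1", "1"), start = c(1000000, 1150000),
                end = c(1100000, 1600000), cn = c(0L, 1L))
  expect_equal(merge_adjacent_calls(e)$cn, 1L)

  mixed <- rbind(a, mk_calls(chrom = "1", start = 1, end = 10, cn = 1L,
                             sample_id = "other"))
  expect_error(merge_adjacent_calls(mixed), "one sample")
})

test_that("merging is idempotent on randomized call sets", {
  set.seed(70)
  for (rep in 1:15) {
    n <- sample(2:12, 1)
    st <- sort(sample.int(5e6, n))
    calls <- mk_calls(chrom = sample(c("1", "2"), n, TRUE), start = st,
                      end = st + sample.int(3e5, n), cn = sample(c(0L, 1L, 3L, 4L), n, TRUE),
                      n_snps = sample(11:50, n, TRUE), confidence = runif(n, 0, 200))
    m1 <- merge_adjacent_calls(calls)
    m2 <- merge_adjacent_calls(m1)
    expect_equal(m1, m2)
  }
})

test_that("filters are strict at the printed thresholds and monotone", {
  base <- function(n_snps = 20L, len = 100000, conf = 100) {
    mk_calls(chrom = "1", start = 1e6, end = 1e6 + len - 1, cn = 1L,
             n_snps = n_snps, confidence = conf)
  }
  expect_equal(nrow(filter_calls(base(n_snps = 10L))), 0L)   # exactly 10 removed
  expect_equal(nrow(filter_calls(base(n_snps = 11L))), 1L)
  expect_equal(nrow(filter_calls(base(len = 50000))), 0L)    # exactly 50 kb removed
  expect_equal(nrow(filter_calls(base(len = 50001))), 1L)
  expect_equal(nrow(filter_calls(base(conf = 50))), 0L)      # exactly 50 removed
  expect_equal(nrow(filter_calls(base(conf = 50.01))), 1L)

  set.seed(71)
  for (rep in 1:10) {
    n <- 20
    st <- sort(sample.int(5e6, n))
    calls <- mk_calls(chrom = "1", start = st, end = st + sample.int(2e5, n),
                      cn = sample(c(1L, 3L), n, TRUE),
                      n_snps = sample(5:30, n, TRUE), confidence = runif(n, 0, 150))
    f1 <- filter_calls(calls)
    # output is a subset of the input
    expect_true(all(f1$start %in% calls$start))
    # raising any threshold never adds a call
    expect_lte(nrow(filter_calls(calls, min_snps = 15)), nrow(f1))
    expect_lte(nrow(filter_calls(calls, min_length = 80000)), nrow(f1))
    expect_lte(nrow(filter_calls(calls, min_conf = 80)), nrow(f1))
  }
})

test_that("callset union keeps unique calls and collapses overlaps", {
  a <- mk_calls(chrom = "1", start = 1e6, end = 2e6, cn = 1L, confidence = 60,
                caller = "A")
  b <- mk_calls(chrom = "1", start = 1.5e6, end = 2.5e6, cn = 1L,
                confidence = 90, caller = "B")
  u <- combine_callsets(a, b)
  expect_equal(nrow(u), 1L)
  expect_equal(u$start, 1e6)
  expect_equal(u$end, 2.5e6)
  expect_equal(u$confidence, 90)  # max, not sum
  expect_equal(u$caller, "both")

  # a call present in only one set survives untouched
  c_only <- mk_calls(chrom = "5", start = 1e6, end = 1.2e6, cn = 3L, caller = "A")
  u2 <- combine_callsets(rbind(a, c_only), b)
  expect_true(any(u2$chrom == "5" & u2$caller == "A"))

  # identical call in both callers -> single "both" call
  u3 <- combine_callsets(a, transform(a, caller = "B"))
  expect_equal(nrow(u3), 1L)
  expect_equal(u3$caller, "both")

  # empty union X = X
  expect_equal(combine_callsets(a[0, ], b), b)

  # opposite directions stay separate even when overlapping
  dup <- mk_calls(chrom = "1", start = 1.2e6, end = 1.8e6, cn = 3L, caller = "B")
  u4 <- combine_callsets(a, dup)
  expect_equal(nrow(u4), 2L)
})

test_that("callset union is commutative and covers the union of base pairs", {
  set.seed(72)
  for (rep in 1:10) {
    mk_rand <- function(tag) {
      n <- sample(1:6, 1)
      st <- sort(sample.int(4e6, n))
      mk_calls(chrom = "1", start = st, end = st + sample.int(5e5, n),
               cn = sample(c(1L, 3L), n, TRUE), confidence = runif(n, 0, 100),
               caller = tag)
    }
    a <- mk_rand("A"); b <- mk_rand("B")
    u1 <- combine_callsets(a, b)
    u2 <- combine_callsets(b, a)
    cols <- c("chrom", "start", "end", "cn", "n_snps", "confidence")
    expect_equal(u1[cols], u2[cols])
    for (dir in c("del", "dup")) {
      sel_in <- ifelse(rbind(a, b)$cn < 2, "del", "dup") == dir
      sel_out <- ifelse(u1$cn < 2, "del", "dup") == dir
      pool <- rbind(a, b)[sel_in, ]
      if (nrow(pool)) {
        expect_equal(wavecnv:::interval_union_length(u1$start[sel_out], u1$end[sel_out]),
                     wavecnv:::interval_union_length(pool$start, pool$end))
      }
    }
  }
})

test_that("detected_fraction is the overlap-union over the region length", {
  region <- data.frame(name = "r", chrom = "1", start = 100001, end = 200000,
                       direction = "del", expected_cn = NA_integer_)
  exact <- mk_calls(chrom = "1", start = 100001, end = 200000, cn = 1L)
  expect_equal(detected_fraction(exact, region), 1)
  expect_equal(detected_fraction(exact[0, ], region), 0)
  half <- mk_calls(chrom = "1", start = 150001, end = 200000, cn = 1L)
  expect_equal(detected_fraction(half, region), 0.5)
  # direction mismatch contributes nothing
  dup <- mk_calls(chrom = "1", start = 100001, end = 200000, cn = 3L)
  expect_equal(detected_fraction(dup, region), 0)
  # overlapping calls count shared bases once
  two <- mk_calls(chrom = "1", start = c(100001, 130001), end = c(150000, 160000),
                  cn = c(1L, 1L))
  expect_equal(detected_fraction(two, region), 0.6)
})

test_that("detected_fraction agrees with a base-pair-marking oracle", {
  set.seed(73)
  for (rep in 1:25) {
    region <- data.frame(name = "r", chrom = "1", start = 51, end = 150,
                         direction = "del", expected_cn = NA_integer_)
    n <- sample(1:5, 1)
    st <- sample.int(200, n)
    calls <- mk_calls(chrom = "1", start = st, end = pmin(st + sample.int(60, n), 250),
                      cn = 1L)
    got <- detected_fraction(calls, region)
    s <- pmax(calls$start, region$start); e <- pmin(calls$end, region$end)
    keep <- s <= e
    want <- if (any(keep)) union_len_brute(s[keep], e[keep], 250) / 100 else 0
    expect_equal(got, want)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("disorder matching: direction, expected copy number, verdicts", {
  db <- data.frame(name = c("Joubert syndrome 4", "toy dup"),
                   chrom = c("2", "3"), start = c(110852875, 1e6),
                   end = c(110983320, 2e6), direction = c("del", "dup"),
                   expected_cn = c(1L, NA_integer_), stringsAsFactors = FALSE)
  call <- mk_calls(chrom = "2", start = 110852875, end = 110983320, cn = 1L,
                   n_snps = 66L, confidence = 123.4)
  res <- match_disorders(call, db)
  expect_equal(res$status, c("detected", "normal"))
  expect_equal(res$detected_fraction[1], 1.0)
  expect_equal(res$n_matched_calls, c(1L, 0L))

  # homozygous deletion does not match an expected_cn = 1 disorder
  hom <- mk_calls(chrom = "2", start = 110852875, end = 110983320, cn = 0L)
  expect_equal(match_disorders(hom, db)$status[1], "normal")

  # a dup overlapping a del region reports normal
  dup <- mk_calls(chrom = "2", start = 110852875, end = 110983320, cn = 3L)
  expect_equal(match_disorders(dup, db)$status[1], "normal")

  # no calls: every disorder is normal
  none <- match_disorders(call[0, ], db, sample_id = "s0")
  expect_equal(none$status, c("normal", "normal"))
  expect_equal(none$sample_id, c("s0", "s0"))
  expect_error(match_disorders(call, db, min_fraction = 0), "> 0")
})
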