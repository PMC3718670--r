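test_that("phred_to_prob follows the Phred definition and rejects bad input", {
  expect_equal(phred_to_prob(10), 0.9)
  expect_equal(phred_to_prob(20), 0.99)
  expect_equal(phred_to_prob(0), 0)
  expect_error(phred_to_prob(-1), "non-negative")
})

test_that("parse_pileup_line decodes the base-string grammar", {
  rec <- parse_pileup_line("chr1\t100\tA\t3\t..T\tII#\t]]]")
  expect_s3_class(rec, "pileup_record")
  expect_equal(rec$pos, 100L)
  expect_equal(rec$reads$base, c("A", "A", "T"))
  expect_equal(rec$reads$base_qual, c(40L, 40L, 2L))
  expect_equal(rec$reads$map_qual, c(60L, 60L, 60L))

  # depth-0 line with empty trailing fields
  rec0 <- parse_pileup_line("chr1\t5\tG\t0\t\t")
  expect_equal(nrow(rec0$reads), 0L)

  # '^]' consumed as read start; default mapping quality assigned
  rec2 <- parse_pileup_line("chr1\t7\tC\t2\t^].a\tI5", default_mq = 30L)
  expect_equal(rec2$reads$base, c("C", "A"))
  expect_equal(rec2$reads$base_qual, c(40L, 20L))
  expect_equal(rec2$reads$map_qual, c(30L, 30L))

  # '$', indel runs and '*' placeholders are consumed; '*' read dropped
  rec3 <- parse_pileup_line("chr1\t9\tT\t4\t.$.+2AC,*\tIIII\tFFFF")
  expect_equal(rec3$reads$base, c("T", "T", "T"))

  expect_error(parse_pileup_line("chr1\tx\tA\t1\t.\tI", line_num = 3),
               "line 3")
  expect_error(parse_pileup_line("chr1\t1\tA\t3\t...\tII", line_num = 8),
               "mismatch.*line 8")
  expect_error(parse_pileup_line("chr1\t1"), "columns")
})

test_that("reduce_to_observation applies filters and the top-2 allele rule", {
  mk <- function(bases, bq = 40L, mq = 60L)
    structure(list(chrom = "c", pos = 1L, ref = "A",
                   reads = data.frame(base = bases,
                                      base_qual = rep_len(bq, length(bases)),
                                      map_qual = rep_len(mq, length(bases)),
                                      stringsAsFactors = FALSE)),
              class = "pileup_record")
  # third allele (G) dropped entirely, not counted as mismatch
  ob <- reduce_to_observation(mk(c("A", "A", "A", "T", "T", "G")),
                              filter_config(0L, 0L, 0L))
  expect_equal(ob$L, 5L)
  expect_equal(ob$P, 3L)
  expect_equal(ob$alt, "T")

  # everything below the base-quality threshold -> absent
  expect_null(reduce_to_observation(mk(c("A", "T"), bq = 10L),
                                    filter_config(0L, 20L, 0L)))

  # single non-reference allele: all mismatch
  ob2 <- reduce_to_observation(mk(c("T", "T", "T", "T")),
                               filter_config(0L, 0L, 0L))
  expect_equal(ob2$L, 4L)
  expect_equal(ob2$P, 0L)

  # reference N -> site skipped
  rec_n <- mk("A"); rec_n$ref <- "N"
  expect_null(reduce_to_observation(rec_n, filter_config(0L, 0L, 0L)))
})

test_that("raising thresholds never increases retained coverage", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    rec <- structure(list(chrom = "c", pos = 1L, ref = "A",
                          reads = data.frame(
                            base = sample(c("A", "C", "G", "T"), n, TRUE),
                            base_qual = sample(0:40, n, TRUE),
                            map_qual = sample(0:60, n, TRUE),
                            stringsAsFactors = FALSE)),
                     class = "pileup_record")
    L <- sapply(c(0L, 10L, 20L, 30L), function(bq) {
      ob <- reduce_to_observation(rec, filter_config(0L, bq, 0L))
      if (is.null(ob)) 0L else ob$L
    })
    expect_true(all(diff(L) <= 0))
    Lm <- sapply(c(0L, 20L, 40L), function(mq) {
      ob <- reduce_to_observation(rec, filter_config(mq, 0L, 0L))
      if (is.null(ob)) 0L else ob$L
    })
    expect_true(all(diff(Lm) <= 0))
  }
})

test_that("read_pileup streams sites in order and skips empty sites", {
  f <- withr::local_tempfile(fileext = ".pileup")
  writeLines(c("chr1\t10\tA\t2\t..\tII\t]]",
               "chr1\t11\tC\t0\t\t",
               "chr1\t15\tG\t1\tT\tI\t]",
               "chr2\t3\tT\t1\t,\tI\t]"), f)
  obs <- read_pileup(f, filter_config(0L, 0L, 0L))
  expect_equal(length(obs), 3L)
  expect_equal(obs$sites$pos, c(10L, 15L, 3L))
  expect_equal(obs$sites$P, c(2L, 0L, 1L))
  expect_equal(obs$chain, c(1L, 1L, 2L))   # chains break at chromosomes

  writeLines(c("chr1\t10\tA\t1\t.\tI\t]",
               "chr1\t9\tA\t1\t.\tI\t]"), f)
  expect_error(read_pileup(f, filter_config(0L, 0L, 0L)), "sorted")
  writeLines(character(0), f)
  expect_error(read_pileup(f, filter_config(0L, 0L, 0L)), "empty")
})

test_that("bulk decoding agrees with the per-record reference path", {
  set.seed(23)
  f <- withr::local_tempfile(fileext = ".pileup")
  lines <- character(0)
  for (pos in 1:40) {
    n <- sample(1:8, 1)
    bases <- sample(c(".", ",", "A", "C", "g", "t", "N"), n, TRUE,
                    prob = c(4, 2, 1, 1, 1, 1, 0.5))
    bq <- sample(2:40, n, TRUE); mq <- sample(0:60, n, TRUE)
    lines <- c(lines, sprintf("chr1\t%d\tA\t%d\t%s\t%s\t%s", pos, n,
                              paste0(bases, collapse = ""),
                              intToUtf8(bq + 33L), intToUtf8(mq + 33L)))
  }
  writeLines(lines, f)
  filt <- filter_config(10L, 5L, 0L)
  obs <- read_pileup(f, filt)
  ref <- lapply(seq_along(lines), function(k)
    reduce_to_observation(parse_pileup_line(lines[k], line_num = k), filt))
  ref <- ref[!vapply(ref, is.null, logical(1))]
  expect_equal(obs$sites$pos, vapply(ref, `[[`, integer(1), "pos"))
  expect_equal(obs$sites$L, vapply(ref, `[[`, integer(1), "L"))
  expect_equal(obs$sites$P, vapply(ref, function(o) as.integer(o$P), integer(1)))
  expect_equal(obs$sites$alt, vapply(ref, `[[`, character(1), "alt"))
  expect_equal(obs$match, unlist(lapply(ref, `[[`, "match")))
  expect_equal(obs$r, unlist(lapply(ref, `[[`, "r")))
  expect_equal(obs$q, unlist(lapply(ref, `[[`, "q")))
})

test_that("maq dialect and 6-column input with default mapping quality work", {
  f <- withr::local_tempfile(fileext = ".pileup")
  writeLines(c("chr1\t1\tA\t2\t@..\tII", "chr1\t2\tC\t1\t@T\tI"), f)
  obs <- read_pileup(f, filter_config(0L, 0L, 0L), dialect = "maq",
                     default_mq = 25L)
  expect_equal(obs$sites$L, c(2L, 1L))
  expect_equal(unique(obs$r), phred_to_prob(25L))
})

test_that("P stored always equals the number of matching reads", {
  set.seed(5)
  for (rep in 1:10) {
    obs <- random_obs(sample(1:30, 1))
    P_from_match <- as.integer(rowsum(as.numeric(obs$match),
                                      obs$site_of_read)[, 1])
    expect_equal(obs$sites$P, P_from_match)
  }
})
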