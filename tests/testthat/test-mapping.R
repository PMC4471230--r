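test_that("adapter trimming truncates, strips Ns and drops short reads", {
  adapter <- "AGATCGGAAGAGC"
  set.seed(1)
  body35 <- paste(sample(c("A", "C", "G", "T"), 35, TRUE), collapse = "")
  clean <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  clean <- gsub("AGATCGGA", "AGATCGGT", clean) # no accidental adapter seed
  reads <- make_reads(c(
    clean,                                       # untouched
    paste0(body35, substr(adapter, 1, 25)),      # full-adapter read
    paste0(body35, substr(adapter, 1, 9)),       # partial adapter at 3' end
    paste0(substr(body35, 1, 25), "NNNNN"),      # trailing Ns
    paste0(substr(body35, 1, 18), substr(adapter, 1, 10)) # too short after
  ))
  out <- trim_reads(reads, adapter, min_len = 20, seed_len = 8)
  expect_equal(out$seq[out$read_id == "r001"], clean)
  expect_equal(out$seq[out$read_id == "r002"], body35)
  expect_equal(out$seq[out$read_id == "r003"], body35)
  expect_equal(out$seq[out$read_id == "r004"], substr(body35, 1, 25))
  expect_false("r005" %in% out$read_id)
})

test_that("fraction-mode edit distance follows the Poisson tail rule", {
  fr <- edit_schedule("fraction", 0.1)
  expect_true(all(max_edit_distance(20:26, fr) == 1L))
  expect_true(all(max_edit_distance(88:101, fr) == 4L))
  expect_equal(max_edit_distance(55, fr), 2L)
  expect_equal(max_edit_distance(56, fr), 3L)
  # non-decreasing in read length
  meds <- max_edit_distance(20:101, fr)
  expect_true(all(diff(meds) >= 0))
  expect_true(all(max_edit_distance(c(20, 60, 101),
                                    edit_schedule("absolute", 2)) == 2L))
  expect_true(all(max_edit_distance(c(20, 101),
                                    edit_schedule("perfect")) == 0L))
})

test_that("mapping equals brute-force doubled-reference search", {
  g <- rand_genome(250, 30)
  set.seed(31)
  reads <- character(0)
  for (i in 1:12) {
    len <- sample(20:60, 1)
    start <- sample(250, 1)
    s <- cs_subseq(g, start, len)
    b <- strsplit(s, "")[[1]]
    nmut <- sample(0:4, 1)
    if (nmut > 0) {
      at <- sample(len, nmut)
      b[at] <- vapply(b[at], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    }
    s <- paste(b, collapse = "")
    if (i %% 2 == 0) s <- rc_chr(s)
    reads <- c(reads, s)
  }
  reads <- make_reads(reads)
  for (sched in list(edit_schedule("perfect"), edit_schedule("absolute", 2),
                     edit_schedule("fraction", 0.1))) {
    rec <- map_reads(reads, g, sched)
    for (i in seq_len(nrow(reads))) {
      bound <- max_edit_distance(nchar(reads$seq[i]), sched)
      oracle <- brute_map(reads$seq[i], g, bound)
      mine <- rec[rec$read_id == reads$read_id[i], ]
      mine <- mine[order(mine$strand, mine$start), ]
      if (is.null(oracle) || nrow(oracle) == 0) {
        expect_equal(nrow(mine), 0L)
      } else {
        oracle <- oracle[order(oracle$strand, oracle$start), ]
        expect_equal(mine$start, oracle$start)
        expect_equal(mine$strand, oracle$strand)
        expect_equal(mine$mismatches, oracle$mismatches)
      }
    }
  }
})

test_that("reads spanning the circular origin map with wrap-around", {
  g <- rand_genome(100, 32)
  read <- paste0(substr(g$seq, 91, 100), substr(g$seq, 1, 15))
  rec <- map_reads(make_reads(read), g, edit_schedule("perfect"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$start, 91L)
  expect_equal(rec$end, 115L) # wraps: reduce modulo 100 for genome coords
  oracle <- brute_map(read, g, 0)
  expect_equal(rec$start, oracle$start)
  # on a linear genome the same read does not map
  glin <- circ_seq(g$seq, id = "lin", circular = FALSE)
  expect_equal(nrow(map_reads(make_reads(read), glin,
                              edit_schedule("perfect"))), 0L)
})

test_that("relaxing the schedule never loses an alignment", {
  g <- rand_genome(300, 33)
  set.seed(34)
  reads <- make_reads(vapply(1:8, function(i) {
    s <- cs_subseq(g, sample(300, 1), 30)
    b <- strsplit(s, "")[[1]]
    at <- sample(30, 2)
    b[at] <- vapply(b[at], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(b, collapse = "")
  }, character(1)))
  strict <- map_reads(reads, g, edit_schedule("absolute", 1))
  loose <- map_reads(reads, g, edit_schedule("absolute", 3))
  key <- function(r) paste(r$read_id, r$start, r$strand)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("reverse-complementing a read flips the strand, not the interval", {
  g <- rand_genome(200, 35)
  read <- cs_subseq(g, 50, 30)
  fwd <- map_reads(make_reads(read), g, edit_schedule("perfect"))
  rev <- map_reads(make_reads(rc_chr(read)), g, edit_schedule("perfect"))
  expect_equal(fwd$start, rev$start)
  expect_equal(fwd$end, rev$end)
  expect_setequal(c(fwd$strand, rev$strand), c("+", "-"))
})

test_that("the mapq proxy separates unique from repeated placements", {
  unit <- paste(rep(c("ACGTT", "GGCTA"), 5), collapse = "") # 50 nt
  g <- circ_seq(paste0(unit, "CCCCCAAAAATTTTTGGGGGCATCATCAT", unit),
                id = "rep", circular = FALSE)
  rep_read <- substr(unit, 1, 30)
  uniq_read <- "CCCCCAAAAATTTTTGGGGGCATCATCAT"
  rec <- map_reads(make_reads(c(rep_read, uniq_read)), g,
                   edit_schedule("perfect"))
  expect_true(all(rec$mapq[rec$read_id == "r001"] == 0L))
  expect_equal(rec$mapq[rec$read_id == "r002"], 37L)
})

test_that("N symbols always count as mismatches and bad symbols fail", {
  g <- circ_seq("ACGTACGTACGTACGTACGTNCGTACGTACGT", id = "withN",
                circular = FALSE)
  read <- substr(g$seq, 13, 32) # covers the N; read N vs ref N mismatches
  expect_equal(nrow(map_reads(make_reads(read), g,
                              edit_schedule("perfect"))), 0L)
  rec_n <- map_reads(make_reads(read), g, edit_schedule("absolute", 2))
  expect_true(all(rec_n$mismatches[rec_n$start == 13] == 1L))
  read_ok <- gsub("N", "A", read)
  rec <- map_reads(make_reads(read_ok), g, edit_schedule("absolute", 2))
  expect_true(all(rec$mismatches[rec$start == 13] >= 1L))
  expect_error(map_reads(make_reads("ACGTACGTXACGTACGTACG"), g,
                         edit_schedule("perfect")), "outside ACGTN")
})

test_that("duplicate flagging matches brute-force distinct keys", {
  rec <- tibble::tibble(
    read_id = sprintf("r%02d", 1:4), ref_id = "x",
    start = c(10L, 10L, 10L, 20L), end = c(40L, 40L, 40L, 50L),
    strand = c("+", "+", "-", "+"), length = 31L,
    mismatches = 0L, mapq = 37L, duplicate = FALSE)
  out <- deduplicate(rec)
  expect_equal(sum(!out$duplicate), 3L) # same interval opposite strand kept
  set.seed(36)
  rnd <- tibble::tibble(
    read_id = sprintf("r%02d", 1:50), ref_id = "x",
    start = sample(1:10, 50, TRUE), end = 0L,
    strand = sample(c("+", "-"), 50, TRUE),
    length = sample(3:5, 50, TRUE), mismatches = 0L, mapq = 37L,
    duplicate = FALSE)
  rnd$end <- rnd$start + rnd$length - 1L
  out <- deduplicate(rnd)
  brute <- nrow(unique(as.data.frame(
    rnd[, c("ref_id", "start", "end", "strand")])))
  expect_equal(sum(!out$duplicate), brute)
})
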