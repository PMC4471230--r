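test_that("plant_variants identity case leaves the genome untouched", {
  g <- rand_genome(500, 1)
  out <- plant_variants(g, 0, 0, list(), seed = 1)
  expect_identical(out$genome$seq, g$seq)
  expect_equal(nrow(out$truth), 0L)
})

test_that("plant_variants plants exactly the requested event profile", {
  g <- rand_genome(2000, 2)
  out <- plant_variants(g, 105, 6, list(c("ins", 1), c("del", 2)), seed = 1)
  tr <- out$truth
  expect_equal(nrow(tr), 113L)
  expect_equal(sum(tr$ts_tv %in% "t"), 105L)
  expect_equal(sum(tr$ts_tv %in% "v"), 6L)
  expect_equal(sort(tr$kind[tr$kind != "substitution"]),
               c("deletion", "insertion"))
  expect_false(is.unsorted(tr$position))
  expect_equal(nchar(out$genome$seq), 2000L - 1L)
  # every substitution is recoverable by direct comparison
  subs <- tr[tr$kind == "substitution", ]
  ref_b <- strsplit(g$seq, "")[[1]]
  expect_identical(ref_b[subs$position], subs$base_a)
})

test_that("plant_variants refuses impossible requests", {
  g <- rand_genome(60, 3)
  expect_error(plant_variants(g, 500, 0, list(), seed = 1),
               "exceed available positions")
})

test_that("planted variants round-trip exactly through the aligner", {
  g <- rand_genome(400, 4)
  out <- plant_variants(g, 6, 2, list(c("ins", 1), c("del", 2)), seed = 5)
  d <- pairwise_differences(g, out$genome)
  expect_equal(nrow(d), nrow(out$truth))
  expect_equal(d$position, out$truth$position)
  expect_equal(d$kind, out$truth$kind)
  expect_equal(d$base_b, out$truth$base_b)
  expect_equal(d$ts_tv, out$truth$ts_tv)
  # and the independent DP oracle agrees
  od <- oracle_diffs(g$seq, out$genome$seq)
  expect_equal(od$position, out$truth$position)
  expect_equal(od$kind, out$truth$kind)
})

test_that("noise-free simulated reads are exact genome substrings", {
  g <- rand_genome(300, 5)
  sim <- simulate_reads(g, 50, fragment_model(),
                        damage_model(0, 0, 0.5, 0), seed = 6)
  hay <- paste0(g$seq, g$seq)
  ok <- vapply(sim$reads$seq, function(s)
    grepl(s, hay, fixed = TRUE) || grepl(rc_chr(s), hay, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
  expect_true(all(nchar(sim$reads$seq) >= 20 & nchar(sim$reads$seq) <= 101))
  expect_equal(nrow(sim$truth), 50L)
})

test_that("simulated terminal damage matches the planted rate", {
  g <- rand_genome(800, 7)
  dmg <- damage_model(delta5 = 0.3, delta3 = 0, decay = 0.5, seq_error = 0)
  sim <- simulate_reads(g, 10000, fragment_model(), dmg, seed = 8)
  # fraction of reads whose source base at 5' offset 0 is C that read T
  frag0 <- vapply(seq_len(nrow(sim$truth)), function(i) {
    w <- cs_subseq(g, sim$truth$start[i], sim$truth$length[i])
    if (sim$truth$strand[i] == "-") w <- rc_chr(w)
    substr(w, 1, 1)
  }, character(1))
  is_c <- frag0 == "C"
  read0 <- substr(sim$reads$seq, 1, 1)
  p_hat <- mean(read0[is_c] == "T")
  se <- sqrt(0.3 * 0.7 / sum(is_c))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("read simulation is deterministic under a fixed seed", {
  g <- rand_genome(300, 9)
  a <- simulate_reads(g, 40, fragment_model(), damage_model(), seed = 10)
  b <- simulate_reads(g, 40, fragment_model(), damage_model(), seed = 10)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_reads_fastq(a$reads, f1); write_reads_fastq(b$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("contaminant mixing follows the requested proportions", {
  g1 <- rand_genome(300, 11, id = "src1")
  g2 <- rand_genome(300, 12, id = "src2")
  g3 <- rand_genome(300, 13, id = "src3")
  mk <- function(g, n, s) simulate_reads(g, n, fragment_model(),
                                         damage_model(0, 0, 0.5, 0), seed = s)
  s1 <- mk(g1, 9000, 14); s2 <- mk(g2, 9000, 15); s3 <- mk(g3, 9000, 16)
  mx <- mix_contaminants(
    list(list(reads = s1$reads, label = "a"),
         list(reads = s2$reads, label = "b"),
         list(reads = s3$reads, label = "c")),
    proportions = c(0.8, 0.15, 0.05), n_total = 10000, seed = 17)
  expect_equal(nrow(mx$reads), 10000L)
  cnt <- setNames(mx$counts$n, mx$counts$label)
  props <- c(a = 0.8, b = 0.15, c = 0.05)
  for (lbl in names(props)) {
    sd_l <- sqrt(10000 * props[lbl] * (1 - props[lbl]))
    expect_lt(abs(cnt[lbl] - 10000 * props[lbl]), 3 * sd_l)
  }
  # degenerate weight passes the first set through unchanged
  mx1 <- mix_contaminants(list(list(reads = s1$reads, label = "a"),
                               list(reads = s2$reads, label = "b")),
                          proportions = c(1, 0), seed = 18,
                          n_total = nrow(s1$reads))
  expect_identical(mx1$reads$seq, s1$reads$seq)
  # determinism
  mxa <- mix_contaminants(list(list(reads = s1$reads, label = "a"),
                               list(reads = s2$reads, label = "b")),
                          proportions = c(0.5, 0.5), seed = 19)
  mxb <- mix_contaminants(list(list(reads = s1$reads, label = "a"),
                               list(reads = s2$reads, label = "b")),
                          proportions = c(0.5, 0.5), seed = 19)
  expect_identical(mxa$reads, mxb$reads)
  # empty set with positive weight fails loudly
  empty <- s1$reads[0, ]
  expect_error(mix_contaminants(list(list(reads = empty, label = "x"),
                                     list(reads = s2$reads, label = "b")),
                                proportions = c(0.5, 0.5), seed = 20),
               "empty read set")
})

test_that("damage profiles are strand-symmetric when delta5 equals delta3", {
  g <- rand_genome(600, 21)
  dmg <- damage_model(delta5 = 0.3, delta3 = 0.3, decay = 0.5, seq_error = 0)
  sim <- simulate_reads(g, 4000, fragment_model(), dmg, seed = 22)
  rec <- tibble::tibble(read_id = sim$truth$read_id, ref_id = g$id,
                        start = sim$truth$start,
                        end = sim$truth$start + sim$truth$length - 1L,
                        strand = sim$truth$strand,
                        length = sim$truth$length, mismatches = 0L,
                        mapq = 37L, duplicate = FALSE)
  prof <- damage_profile(rec, sim$reads, g, K = 5)
  f5 <- prof$frequency[prof$sub == "C>T" & prof$end == "5p"]
  f3 <- prof$frequency[prof$sub == "G>A" & prof$end == "3p"]
  expect_true(all(abs(f5 - f3) < 0.05))
})
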