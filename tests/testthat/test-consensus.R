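pile_row <- function(pos, base, strand = "+", d5 = 15L, d3 = 15L,
                     source = "read", id = "r") {
  tibble::tibble(pos = pos, base = base, strand = strand, d5 = d5, d3 = d3,
                 source = source, evidence_id = id)
}

test_that("pileup columns tally evidence exactly", {
  g <- rand_genome(120, 40, circular = FALSE)
  # empty records -> empty pileup
  rec0 <- map_reads(make_reads(character(0)), g)
  expect_equal(nrow(build_pileup(rec0, make_reads(character(0)),
                                 consensus_policy(), 120)), 0L)
  # one perfect 30-nt read starting at 11 covers columns 11..40
  read <- substr(g$seq, 11, 40)
  rec <- deduplicate(map_reads(make_reads(read), g, edit_schedule("perfect")))
  pile <- build_pileup(rec, make_reads(read), consensus_policy(), 120)
  expect_equal(sort(unique(pile$pos)), 11:40)
  expect_equal(nrow(pile), 30L)
  expect_identical(pile$base[order(pile$pos)],
                   strsplit(read, "")[[1]])
  # staggered overlapping reads match a naive per-position tally
  reads <- make_reads(c(substr(g$seq, 1, 40), substr(g$seq, 21, 70),
                        rc_chr(substr(g$seq, 31, 90))))
  rec <- deduplicate(map_reads(reads, g, edit_schedule("perfect")))
  pile <- build_pileup(rec, reads, consensus_policy(), 120)
  naive <- table(c(1:40, 21:70, 31:90))
  got <- table(pile$pos)
  expect_equal(as.integer(got[names(naive)]), as.integer(naive))
})

test_that("column calling implements the evidence and damage rules", {
  pol <- consensus_policy()
  call1 <- function(p) call_columns(p, 1L, pol)[1, ]
  # two concordant evidences -> called
  c2 <- call1(pile_row(c(1L, 1L), c("G", "G"), id = c("a", "b")))
  expect_equal(c2$status, "called"); expect_equal(c2$base, "G")
  # single evidence
  expect_equal(call1(pile_row(1L, "G"))$status, "single_evidence")
  # zero coverage
  expect_equal(call_columns(pile_row(integer(0), character(0)), 1L,
                            pol)$status, "zero_coverage")
  # 6 G + 3 A, all A within 2 nt of their reads' 3' ends -> damage
  p <- dplyr::bind_rows(
    pile_row(rep(1L, 6), rep("G", 6), id = letters[1:6]),
    pile_row(rep(1L, 3), rep("A", 3), d3 = c(0L, 1L, 2L),
             id = letters[7:9]))
  cd <- call1(p)
  expect_equal(cd$status, "resolved_damage"); expect_equal(cd$base, "G")
  # 6 C + 3 T with the T mid-read -> flagged (33% > 25%, no damage excuse)
  p <- dplyr::bind_rows(
    pile_row(rep(1L, 6), rep("C", 6), id = letters[1:6]),
    pile_row(rep(1L, 3), rep("T", 3), d5 = 15L, d3 = 15L,
             id = letters[7:9]))
  expect_equal(call1(p)$status, "flagged_discordant")
  # the mirrored case: C majority, T minority at the reads' 5' ends
  p <- dplyr::bind_rows(
    pile_row(rep(1L, 6), rep("C", 6), id = letters[1:6]),
    pile_row(rep(1L, 3), rep("T", 3), d5 = c(0L, 0L, 1L),
             id = letters[7:9]))
  expect_equal(call1(p)$status, "resolved_damage")
  # a minus-strand read showing A on the forward frame is its own 5' C>T
  p <- dplyr::bind_rows(
    pile_row(rep(1L, 6), rep("G", 6), id = letters[1:6]),
    pile_row(rep(1L, 3), rep("A", 3), strand = "-", d5 = 0L, d3 = 15L,
             id = letters[7:9]))
  expect_equal(call1(p)$status, "resolved_damage")
  # PCR evidence can never be excused as damage
  p <- dplyr::bind_rows(
    pile_row(rep(1L, 4), rep("G", 4), id = letters[1:4]),
    pile_row(rep(1L, 2), rep("A", 2), d3 = 0L, source = c("read", "pcr"),
             id = c("x", "pcrA")))
  expect_equal(call1(p)$status, "flagged_discordant")
  # exact tie -> no consensus
  p <- pile_row(rep(1L, 4), c("A", "A", "G", "G"), id = letters[1:4])
  expect_equal(call1(p)$status, "flagged_discordant")
  # minority at 25% or less -> plain call
  p <- dplyr::bind_rows(
    pile_row(rep(1L, 6), rep("C", 6), id = letters[1:6]),
    pile_row(rep(1L, 2), rep("T", 2), id = c("g", "h")))
  expect_equal(call1(p)$status, "called")
})

test_that("adding concordant evidence never downgrades a call", {
  pol <- consensus_policy()
  base_piles <- list(
    pile_row(c(1L, 1L), c("G", "G"), id = c("a", "b")),
    dplyr::bind_rows(pile_row(rep(1L, 6), rep("G", 6), id = letters[1:6]),
                     pile_row(rep(1L, 3), rep("A", 3), d3 = 0L,
                              id = letters[7:9])))
  rank <- c(zero_coverage = 0, single_evidence = 1, flagged_discordant = 1,
            resolved_damage = 2, called = 2)
  for (p in base_piles) {
    before <- call_columns(p, 1L, pol)[1, ]
    for (extra in 1:3) {
      p <- dplyr::bind_rows(p, pile_row(1L, before$base,
                                        id = paste0("new", extra)))
      after <- call_columns(p, 1L, pol)[1, ]
      expect_gte(rank[after$status], rank[before$status])
      expect_equal(after$base, before$base)
      before <- after
    }
  }
})

test_that("clean deep coverage reconstructs the planted genome exactly", {
  g <- rand_genome(1500, 41)
  pv <- plant_variants(g, 12, 3, seed = 42)
  sim <- simulate_reads(pv$genome, 1200, fragment_model(),
                        damage_model(0, 0, 0.5, 0), seed = 43)
  asm <- assemble(sim$reads, g)
  expect_identical(asm$consensus$seq, pv$genome$seq)
  expect_equal(length(asm$gaps), 0L)
  expect_true(verify_fixed_point(sim$reads, asm$consensus)$fixed_point)
})

test_that("heavy terminal damage never enters the consensus", {
  g <- rand_genome(1500, 44)
  pv <- plant_variants(g, 12, 3, seed = 45)
  sim <- simulate_reads(pv$genome, 1200, fragment_model(),
                        damage_model(0.3, 0.3, 0.5, 0), seed = 46)
  asm <- assemble(sim$reads, g)
  expect_identical(asm$consensus$seq, pv$genome$seq)
})

test_that("an empty read set yields zero coverage everywhere", {
  g <- rand_genome(200, 47)
  asm <- assemble(make_reads(character(0)), g)
  expect_equal(asm$gaps, 1:200)
  expect_true(all(asm$calls$status == "zero_coverage"))
  fx <- verify_fixed_point(make_reads(character(0)), asm$consensus)
  expect_true(fx$fixed_point) # vacuously: nothing is called
  expect_equal(nrow(fx$discrepancies), 0L)
})

test_that("a coverage hole is reported and closed by spanning PCR evidence", {
  g <- rand_genome(600, 48, circular = FALSE)
  pv <- plant_variants(g, 5, 0, seed = 49)
  truthg <- pv$genome
  hole <- 301:340
  # deterministic >= 2x tiling of everything except the hole
  tile <- function(a, b) {
    st40 <- unique(c(seq(a, b - 39, by = 10), b - 39))
    st41 <- unique(c(seq(a, b - 40, by = 10), b - 40))
    c(substring(truthg$seq, st40, st40 + 39),
      substring(truthg$seq, st41, st41 + 40))
  }
  reads <- make_reads(c(tile(1, 300), tile(341, 600)))
  asm <- assemble(reads, g)
  expect_equal(asm$gaps, hole)
  # one read spanning the hole is not enough evidence on its own ...
  spanning <- substr(truthg$seq, 291, 350)
  reads2 <- make_reads(c(reads$seq, spanning))
  asm1 <- assemble(reads2, g)
  expect_equal(length(asm1$gaps), 0L)
  expect_true(all(hole %in% asm1$single_evidence))
  # ... but together with a spanning PCR consensus the hole is called
  pcr <- design_pcr_evidence(truthg, asm$gaps, flank = 30)
  asm2 <- integrate_pcr_evidence(asm1, pcr)
  expect_equal(length(asm2$gaps), 0L)
  expect_equal(length(asm2$single_evidence), 0L)
  expect_identical(asm2$consensus$seq, truthg$seq)
})

test_that("fixed-point verification detects a corrupted consensus base", {
  g <- rand_genome(800, 51)
  sim <- simulate_reads(g, 700, fragment_model(),
                        damage_model(0, 0, 0.5, 0), seed = 52)
  asm <- assemble(sim$reads, g)
  expect_true(verify_fixed_point(sim$reads, asm$consensus)$fixed_point)
  bad <- asm$consensus
  b <- strsplit(bad$seq, "")[[1]]
  b[400] <- setdiff(c("A", "C", "G", "T"), b[400])[1]
  bad$seq <- paste(b, collapse = "")
  fx <- verify_fixed_point(sim$reads, bad)
  expect_false(fx$fixed_point)
  expect_true(400 %in% fx$discrepancies$pos)
})

test_that("coverage accounting is conservative", {
  g <- rand_genome(1000, 53, circular = FALSE)
  read <- substr(g$seq, 101, 200)
  asm <- assemble(make_reads(read), g)
  cov <- coverage_stats(asm)
  expect_equal(cov$mean_fold_coverage, 100 / 1000)
  expect_equal(sum(cov$depth), cov$total_evidence_bases)
  expect_equal(cov$n_unique_reads, 1L)
  # partition: statuses cover all positions exactly once
  expect_equal(sort(c(asm$gaps, asm$single_evidence, asm$no_consensus,
                      asm$calls$pos[asm$calls$status %in%
                                      c("called", "resolved_damage")])),
               1:1000)
})
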