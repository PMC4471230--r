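test_that("pairwise comparison of identical genomes is empty", {
  g <- rand_genome(300, 90)
  d <- pairwise_differences(g, g)
  expect_equal(nrow(d), 0L)
})

test_that("a single substitution is typed as transition or transversion", {
  g <- rand_genome(200, 91, circular = FALSE)
  b <- strsplit(g$seq, "")[[1]]
  b[77] <- c(A = "G", G = "A", C = "T", T = "C")[[b[77]]]
  d <- pairwise_differences(g, circ_seq(paste(b, collapse = ""), id = "m"))
  expect_equal(nrow(d), 1L)
  expect_equal(d$position, 77L)
  expect_equal(d$ts_tv, "t")
  b[77] <- setdiff(c("A", "C"), b[77])[1] # force a transversion somewhere
  b[50] <- switch(b[50], A = "T", T = "A", C = "G", G = "C")
  d2 <- pairwise_differences(g, circ_seq(paste(b, collapse = ""), id = "m"))
  expect_true("v" %in% d2$ts_tv)
})

test_that("substitutions and indel runs match the exhaustive DP oracle", {
  for (seed in 92:94) {
    g <- rand_genome(300, seed, circular = FALSE)
    out <- plant_variants(g, 2, 0, list(c("del", 2)), seed = seed + 10)
    d <- pairwise_differences(g, out$genome)
    od <- oracle_diffs(g$seq, out$genome$seq)
    expect_equal(nrow(d), 3L)
    expect_equal(d$position, od$position)
    expect_equal(d$kind, od$kind)
    expect_equal(d$base_a, od$base_a)
    expect_equal(d$base_b, od$base_b)
  }
})

test_that("swapping the genomes maps insertions to deletions", {
  g <- rand_genome(400, 95)
  out <- plant_variants(g, 3, 1, list(c("ins", 1), c("del", 2)), seed = 96)
  ab <- pairwise_differences(g, out$genome)
  ba <- pairwise_differences(out$genome, g)
  expect_equal(sum(ab$kind == "insertion"), sum(ba$kind == "deletion"))
  expect_equal(sum(ab$kind == "deletion"), sum(ba$kind == "insertion"))
  expect_equal(nrow(ab), nrow(ba))
  # counting identity: ts + tv + indels = total
  expect_equal(sum(ab$ts_tv %in% "t") + sum(ab$ts_tv %in% "v") +
                 sum(ab$kind != "substitution"), nrow(ab))
})

test_that("degenerate alignments are refused", {
  a <- circ_seq(strrep("ACGT", 50), id = "a", circular = FALSE)
  b <- circ_seq(strrep("TGCA", 50), id = "b", circular = FALSE)
  expect_error(pairwise_differences(a, b, min_identity = 0.9), "degenerate")
})

codon_fixture <- function() {
  # + strand CDS at 11..40 (10 codons), - strand CDS at 61..90,
  # D-loop at 101..140
  set.seed(97)
  pre <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
  cds_p <- "ATGATTCATCCAGTAGAACTTACCGGATAA"
  mid <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  cds_m_sense <- "ATGCTAGAAATTTGGCGCACTGTCCCCTAA"
  post <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
  dloop <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  seqs <- paste0(pre, cds_p, mid, rc_chr(cds_m_sense), post, dloop)
  feats <- tibble::tibble(
    name = c("cdsP", "cdsM", "D-loop"),
    type = c("CDS", "CDS", "D-loop"),
    start = c(11L, 61L, 101L), end = c(40L, 90L, 140L),
    strand = c("+", "-", "+"))
  circ_seq(seqs, id = "fix", circular = FALSE, features = feats)
}

test_that("feature, codon and amino-acid classification is strand aware", {
  g <- codon_fixture()
  b <- strsplit(g$seq, "")[[1]]
  # pos 19 = codon 3 position 3 of cdsP: CAT -> CAC, His silent
  stopifnot(substr(g$seq, 17, 19) == "CAT")
  mut <- b; mut[19] <- "C"
  # D-loop substitution
  mut[110] <- setdiff(c("A", "C", "G", "T"), mut[110])[1]
  # minus-strand CDS: genomic 61..90 is revcomp of cds_m_sense; sense codon 2
  # = CTA (Leu, codons read from genomic position 90 downward); genomic
  # position of sense-codon-2 position 1 is 87
  mut[87] <- comp_base("T") # sense CTA -> TTA, Leu -> Leu silent
  d <- pairwise_differences(g, circ_seq(paste(mut, collapse = ""), id = "m"))
  d <- classify_against_annotation(d, g)
  r1 <- d[d$position == 19, ]
  expect_equal(r1$feature, "cdsP")
  expect_equal(r1$codon_position, 3L)
  expect_equal(r1$effect, "silent")
  r2 <- d[d$position == 110, ]
  expect_equal(r2$feature, "D-loop")
  expect_true(is.na(r2$codon_position))
  r3 <- d[d$position == 87, ]
  expect_equal(r3$feature, "cdsM")
  expect_equal(r3$codon_position, 1L)
  expect_equal(r3$effect, "silent")
  expect_equal(r3$aa_a, "L")
  # a missense change on the minus strand, hand translated:
  # sense codon 3 = GAA (Glu), position 2 genomic = 83; sense G A A ->
  # G G A (Gly) via A->G at sense position 2 = genomic complement
  mut2 <- b
  mut2[83] <- comp_base("G")
  d2 <- classify_against_annotation(
    pairwise_differences(g, circ_seq(paste(mut2, collapse = ""), id = "m")),
    g)
  expect_equal(d2$effect, "missense")
  expect_equal(d2$aa_a, "E")
  expect_equal(d2$aa_b, "G")
})

test_that("panel-specific polymorphisms are those no panel genome carries", {
  g <- rand_genome(800, 98)
  out <- plant_variants(g, 10, 0, seed = 99)
  d <- pairwise_differences(g, out$genome)
  expect_equal(nrow(d), 10L)
  # empty panel retains everything; the target itself shares everything
  expect_equal(nrow(specific_polymorphisms(d, g, list())), 10L)
  expect_equal(nrow(specific_polymorphisms(d, g, list(out$genome))), 0L)
  # a panel genome carrying 3 of the 10 planted alleles
  b <- strsplit(g$seq, "")[[1]]
  pick <- out$truth[1:3, ]
  b[pick$position] <- pick$base_b
  panel <- circ_seq(paste(b, collapse = ""), id = "p1")
  sp <- specific_polymorphisms(d, g, list(panel))
  expect_equal(nrow(sp), 7L)
  expect_false(any(pick$position %in% sp$position))
})

test_that("region rate ratios follow the count arithmetic", {
  feats <- tibble::tibble(name = "D-loop", type = "D-loop",
                          start = 1L, end = 910L, strand = "+")
  mk_diffs <- function(pos) {
    tibble::tibble(position = pos, kind = "substitution", base_a = "A",
                   base_b = "G", context_a = "", context_b = "",
                   ts_tv = "t")
  }
  # the worked arithmetic: 25 in 910 nt vs 89 in the 15,408-nt remainder
  set.seed(100)
  d <- mk_diffs(c(sample(1:910, 25), sample(911:16318, 89)))
  rr <- region_rate_ratio(d, feats, "D-loop", 16318L)
  expect_equal(rr$n_in, 25L); expect_equal(rr$n_out, 89L)
  expect_equal(rr$ratio, (25 / 910) / (89 / 15408), tolerance = 1e-12)
  expect_equal(round(rr$ratio, 1), 4.8)
  # uniform density -> ratio near 1; doubling the inside count doubles it
  du <- mk_diffs(seq(10, 16310, by = 163))
  ru <- region_rate_ratio(du, feats, "D-loop", 16318L)
  expect_lt(abs(ru$ratio - 1), 0.25)
  d2 <- mk_diffs(c(d$position, sample(setdiff(1:910, d$position), 25)))
  r2 <- region_rate_ratio(d2, feats, "D-loop", 16318L)
  expect_equal(r2$ratio / rr$ratio, 2, tolerance = 1e-12)
  # no outside differences -> undefined
  expect_true(is.na(region_rate_ratio(mk_diffs(5:10), feats, "D-loop",
                                      16318L)$ratio))
  expect_error(region_rate_ratio(d, feats, "tRNA-Phe", 16318L),
               "not present")
})
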