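NON_STOP_CODONS <- {
  b <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "AGA", "AGG"))
}

# gene layout of the synthetic mitogenome: a realistic mammalian gene
# order and sizes summing, with the three intergenic spacers, to 16,318 nt
synthetic_layout <- function() {
  tibble::tribble(
    ~name,       ~type,    ~len,  ~strand, ~spacer_before,
    "tRNA-Phe",  "tRNA",     69L, "+", 0L,
    "rRNA-12S",  "rRNA",    955L, "+", 0L,
    "tRNA-Val",  "tRNA",     67L, "+", 0L,
    "rRNA-16S",  "rRNA",   1519L, "+", 0L,
    "tRNA-Leu1", "tRNA",     75L, "+", 0L,
    "ND1",       "CDS",     957L, "+", 0L,
    "tRNA-Ile",  "tRNA",     69L, "+", 0L,
    "tRNA-Gln",  "tRNA",     72L, "-", 0L,
    "tRNA-Met",  "tRNA",     69L, "+", 0L,
    "ND2",       "CDS",    1044L, "+", 0L,
    "tRNA-Trp",  "tRNA",     69L, "+", 0L,
    "tRNA-Ala",  "tRNA",     69L, "-", 0L,
    "tRNA-Asn",  "tRNA",     73L, "-", 0L,
    "tRNA-Cys",  "tRNA",     67L, "-", 0L,
    "tRNA-Tyr",  "tRNA",     69L, "-", 0L,
    "COX1",      "CDS",    1545L, "+", 3L,
    "tRNA-Ser2", "tRNA",     69L, "-", 0L,
    "tRNA-Asp",  "tRNA",     68L, "+", 0L,
    "COX2",      "CDS",     684L, "+", 0L,
    "tRNA-Lys",  "tRNA",     70L, "+", 0L,
    "ATP8",      "CDS",     201L, "+", 0L,
    "ATP6",      "CDS",     681L, "+", 0L,
    "COX3",      "CDS",     784L, "+", 0L,
    "tRNA-Gly",  "tRNA",     69L, "+", 0L,
    "ND3",       "CDS",     346L, "+", 0L,
    "tRNA-Arg",  "tRNA",     69L, "+", 0L,
    "ND4L",      "CDS",     297L, "+", 0L,
    "ND4",       "CDS",    1378L, "+", 0L,
    "tRNA-His",  "tRNA",     69L, "+", 0L,
    "tRNA-Ser1", "tRNA",     60L, "+", 0L,
    "tRNA-Leu2", "tRNA",     71L, "+", 0L,
    "ND5",       "CDS",    1821L, "+", 0L,
    "ND6",       "CDS",     528L, "-", 0L,
    "tRNA-Glu",  "tRNA",     69L, "-", 0L,
    "CYTB",      "CDS",    1140L, "+", 4L,
    "tRNA-Thr",  "tRNA",     70L, "+", 0L,
    "tRNA-Pro",  "tRNA",     66L, "-", 3L,
    "D-loop",    "D-loop",  910L, "+", 0L
  )
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cds <- function(len, start_codon = "ATG") {
  rem <- len %% 3L
  stop_part <- switch(as.character(rem), "0" = "TAA", "1" = "T", "2" = "TA")
  n_body <- (len - 3L - nchar(stop_part)) / 3L
  body <- paste(sample(NON_STOP_CODONS, n_body, replace = TRUE),
                collapse = "")
  paste0(start_codon, body, stop_part)
}

#' Generate a synthetic annotated mitochondrial reference genome
#'
#' Builds a 16,318-bp circular genome with the full mammalian
#' mitochondrial gene complement — 13 protein-coding genes (one on the
#' minus strand), 22 tRNAs, 2 rRNAs and a 910-nt control region (D-loop) —
#' whose coding sequences all carry admissible start codons, complete or
#' incomplete terminal stops, and no internal stops under the vertebrate
#' mitochondrial genetic code. The sequence is random otherwise; it is a
#' synthetic stand-in with the structural properties the pipeline needs,
#' not a copy of any deposited genome.
#'
#' @param seed Integer seed.
#' @param id Sequence id.
#' @return An annotated [circ_seq()] of length 16,318.
#' @export
synthetic_mitogenome <- function(seed = 101L, id = "synthMito") {
  set.seed(as.integer(seed))
  layout <- synthetic_layout()
  segs <- character(nrow(layout))
  pos <- 1L
  starts <- integer(nrow(layout)); ends <- integer(nrow(layout))
  spacers <- character(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    spacers[i] <- if (layout$spacer_before[i] > 0L)
      random_bases(layout$spacer_before[i]) else ""
    pos <- pos + layout$spacer_before[i]
    s <- if (layout$type[i] == "CDS") {
      cds <- random_cds(layout$len[i])
      if (layout$strand[i] == "-") revcomp(cds) else cds
    } else {
      random_bases(layout$len[i])
    }
    segs[i] <- s
    starts[i] <- pos
    ends[i] <- pos + layout$len[i] - 1L
    pos <- pos + layout$len[i]
  }
  seq <- paste0(paste0(spacers, segs), collapse = "")
  # pin the tail of tRNA-Ser1 and the head of its neighbour to a context
  # in which a terminal 2-bp deletion aligns unambiguously
  iser <- which(layout$name == "tRNA-Ser1")
  e <- ends[iser]
  substr(seq, e - 2L, e + 1L) <- "ACGT"
  features <- tibble::tibble(name = layout$name, type = layout$type,
                             start = starts, end = ends,
                             strand = layout$strand)
  circ_seq(seq, id = id, circular = TRUE, features = features)
}

# positions (1-based) of internal body codons of every CDS:
# tibble(codon_start_genomic, strand, codon, cds_name); excludes the start
# codon and the (possibly incomplete) terminal stop
cds_body_codons <- function(genome) {
  feats <- genome$features[genome$features$type == "CDS", ]
  out <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    len <- f$end - f$start + 1L
    n_full <- len %/% 3L
    usable <- n_full - 1L - (if (len %% 3L == 0L) 1L else 0L)
    if (usable < 1L) next
    k <- seq_len(usable) # codon indices 2..usable+1 in reading order
    if (f$strand == "+") {
      cstart <- f$start + 3L * k
      codon <- substring(genome$seq, cstart, cstart + 2L)
    } else {
      chi <- f$end - 3L * k
      cstart <- chi - 2L
      codon <- revcomp(substring(genome$seq, cstart, chi))
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      cds = f$name, strand = f$strand, codon_start = cstart, codon = codon)
  }
  dplyr::bind_rows(out)
}

# genomic position of reading-frame codon position cp (1..3) for a codon
# whose genomic start is cstart
codon_pos_to_genomic <- function(cstart, strand, cp) {
  if (strand == "+") cstart + cp - 1L else cstart + 3L - cp
}

apply_ts_at <- function(bases, gpos, strand) {
  # transition at reading-frame level equals transition at genomic level
  old <- bases[gpos]
  bases[gpos] <- TRANSITION[[old]]
  bases
}

#' Plant the study-profile variant set into a synthetic reference
#'
#' Produces an "ancient" genome differing from the reference by a fixed
#' composition of events chosen to emulate an ancient-vs-modern bovine
#' mitogenome comparison: 105 transitions and 6 transversions, of which 24
#' substitutions plus a 1-bp insertion fall in the D-loop (25 control-region
#' differences in total), 73 substitutions in protein-coding genes at codon
#' positions 1/2/3 in the proportions 16/3/54 with exactly 11 amino-acid
#' changes, 14 substitutions in tRNA/rRNA/intergenic territory, and a 2-bp
#' deletion at the end of the tRNA-Ser1 gene. A 20-event subset is marked
#' `shared` for panel construction (9 in coding genes, 4 of them
#' amino-acid-changing), leaving 93 ancient-specific polymorphisms of which
#' 64 (69%) are in coding genes with 7 amino-acid changes.
#'
#' @param ref A [synthetic_mitogenome()].
#' @param seed Integer seed.
#' @param indels Plant the two indels (`TRUE`) or substitutions only.
#' @return A list: `genome` (the ancient [circ_seq()]), `truth` (tibble
#'   `position`, `kind`, `base_a`, `base_b`, `ts_tv`, `region`,
#'   `codon_position`, `effect`, `shared`), and `profile` (the planted
#'   composition as a named list).
#' @export
plant_study_profile <- function(ref, seed = 7L, indels = TRUE) {
  stopifnot(inherits(ref, "circ_seq"), !is.null(ref$features))
  set.seed(as.integer(seed))
  bases <- strsplit(ref$seq, "")[[1]]
  feats <- ref$features
  n <- length(bases)

  region_of <- function(pos) {
    f <- feature_at(pos, feats)
    if (is.null(f)) c("intergenic", "intergenic") else c(f$name, f$type)
  }
  dloop <- feats[feats$name == "D-loop", ]
  ser1 <- feats[feats$name == "tRNA-Ser1", ]
  taken <- integer(0)
  too_close <- function(p, r = 5L) any(abs(taken - p) <= r)
  claim <- function(p) taken <<- c(taken, p)

  pick_from <- function(pool, k) {
    out <- integer(0)
    pool <- sample(pool)
    for (p in pool) {
      if (length(out) == k) break
      if (!too_close(p)) { claim(p); out <- c(out, p) }
    }
    if (length(out) < k) stop("not enough well-spaced positions", call. = FALSE)
    out
  }

  truth <- list()
  add_sub <- function(pos, new_base, ts_tv, region, cp, effect, shared) {
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      position = pos, kind = "substitution", base_a = bases[pos],
      base_b = new_base, ts_tv = ts_tv, region = region,
      codon_position = cp, effect = effect, shared = shared)
    bases[pos] <<- new_base
  }

  # --- D-loop: 23 transitions + 1 transversion
  dpool <- (dloop$start + 5L):(dloop$end - 5L)
  dts <- pick_from(dpool, 23L)
  for (p in dts) add_sub(p, TRANSITION[[bases[p]]], "t", "D-loop", NA_integer_,
                         NA_character_, FALSE)
  dtv <- pick_from(dpool, 1L)
  tvb <- sample(setdiff(c("A", "C", "G", "T"),
                        c(bases[dtv], TRANSITION[[bases[dtv]]])), 1L)
  add_sub(dtv, tvb, "v", "D-loop", NA_integer_, NA_character_, FALSE)

  # --- CDS substitutions (all transitions)
  codons <- cds_body_codons(ref)
  gc2 <- Biostrings::getGeneticCode(MITO_CODE_ID)
  ts_codon <- function(codon, cp) {
    old <- substr(codon, cp, cp)
    new <- codon
    substr(new, cp, cp) <- TRANSITION[[old]]
    new
  }
  codon_ok <- function(crow, cp) {
    g <- codon_pos_to_genomic(crow$codon_start, crow$strand, cp)
    !too_close(g)
  }
  pick_codon_sites <- function(filter_fun, cp, k) {
    idx <- sample(nrow(codons))
    out <- list()
    for (i in idx) {
      if (length(out) == k) break
      crow <- codons[i, ]
      alt <- ts_codon(crow$codon, cp)
      if (!filter_fun(crow$codon, alt)) next
      if (!codon_ok(crow, cp)) next
      g <- codon_pos_to_genomic(crow$codon_start, crow$strand, cp)
      claim(g)
      out[[length(out) + 1L]] <- list(row = crow, gpos = g, alt = alt)
    }
    if (length(out) < k) stop("not enough codon sites", call. = FALSE)
    out
  }
  aa <- function(c) unname(gc2[c])
  silent1 <- pick_codon_sites(function(old, new)
    old %in% c("CTA", "TTA") && new %in% c("CTA", "TTA"), 1L, 8L)
  nonsyn1 <- pick_codon_sites(function(old, new)
    aa(old) != aa(new) && aa(new) != "*", 1L, 8L)
  nonsyn2 <- pick_codon_sites(function(old, new)
    aa(old) != aa(new) && aa(new) != "*", 2L, 3L)
  silent3 <- pick_codon_sites(function(old, new) aa(old) == aa(new), 3L, 54L)
  emit_cds <- function(sites, cp, effect) {
    for (s in sites) {
      # genomic new base: transition preserves strand complementation
      add_sub(s$gpos, TRANSITION[[bases[s$gpos]]], "t", s$row$cds, cp,
              effect, FALSE)
    }
  }
  emit_cds(silent1, 1L, "silent")
  emit_cds(nonsyn1, 1L, "missense")
  emit_cds(nonsyn2, 2L, "missense")
  emit_cds(silent3, 3L, "silent")

  # --- other territory (tRNA, rRNA, intergenic): 9 ts + 5 tv
  other_pool <- setdiff(seq(6L, n - 6L), unlist(lapply(
    seq_len(nrow(feats)), function(i)
      if (feats$type[i] %in% c("CDS", "D-loop"))
        feats$start[i]:feats$end[i] else integer(0))))
  # keep clear of the deletion site at the tRNA-Ser1 tail
  other_pool <- setdiff(other_pool, (ser1$end - 8L):(ser1$end + 8L))
  ots <- pick_from(other_pool, 9L)
  for (p in ots) add_sub(p, TRANSITION[[bases[p]]], "t",
                         region_of(p)[2], NA_integer_, NA_character_, FALSE)
  otv <- pick_from(other_pool, 5L)
  for (p in otv) {
    tvb <- sample(setdiff(c("A", "C", "G", "T"),
                          c(bases[p], TRANSITION[[bases[p]]])), 1L)
    add_sub(p, tvb, "v", region_of(p)[2], NA_integer_, NA_character_, FALSE)
  }

  truth <- dplyr::bind_rows(truth)

  # --- shared subset for panel construction: 9 CDS (4 aa-changing,
  # 5 silent third-position), 5 D-loop, 6 other
  cds_aa <- which(truth$effect == "missense")
  cds_silent3 <- which(truth$effect == "silent" & truth$codon_position == 3L)
  dl <- which(truth$region == "D-loop")
  oth <- which(!(truth$region %in% c("D-loop")) & is.na(truth$codon_position))
  shared_idx <- c(sample(cds_aa, 4L), sample(cds_silent3, 5L),
                  sample(dl, 5L), sample(oth, 6L))
  truth$shared[shared_idx] <- TRUE

  # --- indels
  seq_chr <- paste(bases, collapse = "")
  if (indels) {
    # 1-bp insertion mid-D-loop, base chosen so the gap cannot slide
    repeat {
      ip <- sample((dloop$start + 20L):(dloop$end - 20L), 1L)
      if (!too_close(ip, r = 7L)) break
    }
    claim(ip)
    ins_base <- sample(setdiff(c("A", "C", "G", "T"),
                               c(bases[ip], bases[ip + 1L])), 1L)
    # 2-bp deletion at the end of tRNA-Ser1 (context pinned by the
    # generator to ACG|T so the deletion of CG is unambiguous)
    dp <- ser1$end - 1L
    del_seq <- substr(seq_chr, dp, dp + 1L)
    truth <- dplyr::bind_rows(truth,
      tibble::tibble(position = ip, kind = "insertion", base_a = "-",
                     base_b = ins_base, ts_tv = NA_character_,
                     region = "D-loop", codon_position = NA_integer_,
                     effect = NA_character_, shared = FALSE),
      tibble::tibble(position = dp, kind = "deletion", base_a = del_seq,
                     base_b = "-", ts_tv = NA_character_,
                     region = "tRNA", codon_position = NA_integer_,
                     effect = NA_character_, shared = FALSE))
    # apply right-to-left
    if (ip > dp) {
      seq_chr <- paste0(substr(seq_chr, 1L, ip), ins_base,
                        substr(seq_chr, ip + 1L, nchar(seq_chr)))
      seq_chr <- paste0(substr(seq_chr, 1L, dp - 1L),
                        substr(seq_chr, dp + 2L, nchar(seq_chr)))
    } else {
      seq_chr <- paste0(substr(seq_chr, 1L, dp - 1L),
                        substr(seq_chr, dp + 2L, nchar(seq_chr)))
      seq_chr <- paste0(substr(seq_chr, 1L, ip), ins_base,
                        substr(seq_chr, ip + 1L, nchar(seq_chr)))
    }
  }
  truth <- dplyr::arrange(truth, .data$position)
  list(genome = circ_seq(seq_chr, id = paste0(ref$id, "_ancient"),
                         circular = TRUE),
       truth = truth,
       profile = list(n_transitions = sum(truth$ts_tv %in% "t"),
                      n_transversions = sum(truth$ts_tv %in% "v"),
                      n_indels = sum(truth$kind != "substitution"),
                      n_shared = sum(truth$shared)))
}

#' Build a panel of modern-like genomes sharing a subset of alleles
#'
#' Each panel genome carries every `shared` substitution of the planted
#' truth plus a few private substitutions of its own, so that the
#' ancient-specific polymorphism count over the panel equals the number of
#' non-shared events.
#'
#' @param ref The reference [circ_seq()] the truth positions refer to.
#' @param truth Truth tibble from [plant_study_profile()].
#' @param n_panel Number of panel genomes.
#' @param n_private Private substitutions per panel genome.
#' @param seed Integer seed.
#' @return A list of [circ_seq()] genomes.
#' @export
build_shared_panel <- function(ref, truth, n_panel = 3L, n_private = 5L,
                               seed = 11L) {
  set.seed(as.integer(seed))
  shared <- truth[truth$shared & truth$kind == "substitution", ]
  n <- nchar(ref$seq)
  forbidden <- unique(unlist(lapply(truth$position, function(p)
    (p - 5L):(p + 5L))))
  pool <- setdiff(seq(6L, n - 6L), forbidden)
  lapply(seq_len(n_panel), function(k) {
    bases <- strsplit(ref$seq, "")[[1]]
    bases[shared$position] <- shared$base_b
    priv <- sample(pool, n_private)
    pool <<- setdiff(pool, unlist(lapply(priv, function(p) (p - 5L):(p + 5L))))
    for (p in priv) bases[p] <- TRANSITION[[bases[p]]]
    circ_seq(paste(bases, collapse = ""),
             id = sprintf("%s_panel%d", ref$id, k), circular = TRUE)
  })
}

#' Simulate a divergent mitogenome panel for phylogenetic placement
#'
#' Generates an alignment (substitution-only, so all sequences stay equal
#' length) emulating the placement problem for an ancient genome. `base`
#' is the common ancestor of the ingroup: the modern clade shares
#' `modern_stem` derived substitutions plus a few private ones per
#' sequence, while the ancient sequence carries only private
#' substitutions — so it attaches below the modern clade. The two
#' outgroups descend from an ancestor `outgroup_stem` substitutions away
#' from `base`, which creates the internal edge separating the ingroup
#' (ancient + moderns) from the outgroups. Substitutions are
#' transition-biased (9:1).
#'
#' @param base A [circ_seq()] used as the ingroup ancestral sequence.
#' @param n_modern Number of modern-clade sequences.
#' @param modern_stem Substitutions shared by the whole modern clade.
#' @param modern_private Private substitutions per modern sequence.
#' @param ancient_private Private substitutions of the ancient sequence.
#' @param outgroup_stem Substitutions on the stem leading to the outgroup
#'   ancestor.
#' @param outgroup_private Private substitutions of each outgroup.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences (`ancient`,
#'   `modern1..n`, `outgroup1`, `outgroup2`).
#' @export
simulate_mito_panel <- function(base, n_modern = 5L, modern_stem = 40L,
                                modern_private = 6L, ancient_private = 30L,
                                outgroup_stem = 120L,
                                outgroup_private = c(60L, 140L), seed = 5L) {
  set.seed(as.integer(seed))
  root <- base$seq
  n <- nchar(root)
  mutate_subs <- function(seq, k) {
    b <- strsplit(seq, "")[[1]]
    pos <- sample.int(n, k)
    for (p in pos) {
      b[p] <- if (stats::runif(1) < 0.9) TRANSITION[[b[p]]]
        else sample(setdiff(c("A", "C", "G", "T"),
                            c(b[p], TRANSITION[[b[p]]])), 1L)
    }
    paste(b, collapse = "")
  }
  modern_anc <- mutate_subs(root, modern_stem)
  outgroup_anc <- mutate_subs(root, outgroup_stem)
  c(stats::setNames(mutate_subs(root, ancient_private), "ancient"),
    stats::setNames(
      vapply(seq_len(n_modern), function(i)
        mutate_subs(modern_anc, modern_private), character(1)),
      sprintf("modern%d", seq_len(n_modern))),
    stats::setNames(mutate_subs(outgroup_anc, outgroup_private[1]),
                    "outgroup1"),
    stats::setNames(mutate_subs(outgroup_anc, outgroup_private[2]),
                    "outgroup2"))
}

positions_to_intervals <- function(pos, flank = 0L, L = NULL) {
  if (length(pos) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  pos <- sort(unique(pos))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  out <- tibble::tibble(
    start = pos[brk[-length(brk)] + 1L] - flank,
    end = pos[brk[-1L]] + flank)
  out$start <- pmax(out$start, 1L)
  if (!is.null(L)) out$end <- pmin(out$end, L)
  out
}

#' Design PCR consensus evidence spanning problem intervals
#'
#' Emulates the targeted PCR stage of an ancient-genome assembly: for each
#' interval needing verification (gaps, single-read or discordant
#' positions), extracts the true sequence with flanking anchors from the
#' genome the reads were simulated from, as the consensus of a sequenced
#' amplicon would provide it.
#'
#' @param truth_genome The [circ_seq()] the reads originate from.
#' @param positions Integer positions needing support (merged into
#'   intervals internally).
#' @param flank Anchor length added on each side (nt).
#' @return A tibble (`read_id`, `seq`) of PCR consensus sequences.
#' @export
design_pcr_evidence <- function(truth_genome, positions, flank = 20L) {
  L <- nchar(truth_genome$seq)
  iv <- positions_to_intervals(positions, flank = flank, L = L)
  if (nrow(iv) == 0L) {
    return(tibble::tibble(read_id = character(0), seq = character(0)))
  }
  tibble::tibble(
    read_id = sprintf("pcr_%d_%d", iv$start, iv$end),
    seq = vapply(seq_len(nrow(iv)), function(i)
      cs_subseq(truth_genome, iv$start[i], iv$end[i] - iv$start[i] + 1L),
      character(1)))
}
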