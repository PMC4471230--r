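#' Consensus-calling policy
#'
#' A called position requires at least `min_evidence` concordant unique
#' evidences (unique Illumina reads passing the `min_mapq` filter, or PCR
#' consensus sequences, each counting as one evidence unit and exempt from
#' the mapping-quality filter). When more than `discordance_threshold` of
#' the evidence disagrees with the majority base the position is flagged —
#' unless every minority observation is explainable as terminal deamination
#' (a G-in-consensus read as A within `damage_window` nt of the supporting
#' read's 3' end, or the strand-mirrored C-read-as-T case at the 5' end),
#' in which case the majority base is accepted with status
#' `resolved_damage`.
#'
#' @param min_evidence Minimum concordant evidence count for a call.
#' @param min_mapq Minimum mapping quality for read evidence.
#' @param discordance_threshold Minority fraction above which a position is
#'   flagged.
#' @param damage_window Number of terminal nt within which a mismatch can be
#'   attributed to deamination.
#' @return A `consensus_policy` list.
#' @export
consensus_policy <- function(min_evidence = 2L, min_mapq = 25L,
                             discordance_threshold = 0.25,
                             damage_window = 10L) {
  stopifnot(min_evidence >= 1L, min_mapq >= 0L,
            discordance_threshold >= 0, discordance_threshold <= 1,
            damage_window >= 0L)
  structure(list(min_evidence = as.integer(min_evidence),
                 min_mapq = as.integer(min_mapq),
                 discordance_threshold = discordance_threshold,
                 damage_window = as.integer(damage_window)),
            class = "consensus_policy")
}

#' Build a per-position evidence pileup
#'
#' Expands deduplicated alignment records into one row per aligned base.
#' Only non-duplicate records with `mapq >= policy$min_mapq` contribute.
#' Bases are recorded on the reference forward strand; `d5`/`d3` are the
#' 0-based distances of the column from the supporting read's own 5' and 3'
#' ends (in read orientation), which is what the damage-resolution rule
#' consumes.
#'
#' @param records Alignment tibble (one reference frame, deduplicated).
#' @param reads Read tibble (`read_id`, `seq`).
#' @param policy A [consensus_policy()].
#' @param ref_len Reference length (positions are reduced modulo this).
#' @return A tibble: `pos`, `base`, `strand`, `d5`, `d3`, `source`,
#'   `evidence_id`.
#' @export
build_pileup <- function(records, reads, policy = consensus_policy(),
                         ref_len) {
  stopifnot(length(unique(records$ref_id)) <= 1L)
  reads <- as_read_tbl(reads)
  recs <- records[!records$duplicate & records$mapq >= policy$min_mapq, ]
  if (nrow(recs) > 0L && any(recs$start < 1L | recs$start > ref_len)) {
    stop("record start outside the reference frame", call. = FALSE)
  }
  if (nrow(recs) == 0L) {
    return(tibble::tibble(pos = integer(0), base = character(0),
                          strand = character(0), d5 = integer(0),
                          d3 = integer(0), source = character(0),
                          evidence_id = character(0)))
  }
  seq_of <- stats::setNames(reads$seq, reads$read_id)
  n_tot <- sum(recs$length)
  pos <- integer(n_tot); base <- character(n_tot)
  strand <- character(n_tot); d5 <- integer(n_tot); d3 <- integer(n_tot)
  eid <- character(n_tot)
  at <- 0L
  for (i in seq_len(nrow(recs))) {
    m <- recs$length[i]
    j <- seq_len(m)
    p <- ((recs$start[i] - 1L + j - 1L) %% ref_len) + 1L
    rb <- strsplit(seq_of[[recs$read_id[i]]], "")[[1]]
    if (recs$strand[i] == "+") {
      b <- rb
      dd5 <- j - 1L; dd3 <- m - j
    } else {
      # read position m - j + 1 sits at reference offset j - 1
      b <- comp_base(rb[m - j + 1L])
      dd5 <- m - j; dd3 <- j - 1L
    }
    idx <- at + j
    pos[idx] <- p; base[idx] <- b; strand[idx] <- recs$strand[i]
    d5[idx] <- dd5; d3[idx] <- dd3; eid[idx] <- recs$read_id[i]
    at <- at + m
  }
  tibble::tibble(pos = pos, base = base, strand = strand, d5 = d5, d3 = d3,
                 source = "read", evidence_id = eid)
}

pcr_pileup <- function(placements, seqs, ref_len) {
  # each PCR consensus sequence contributes one evidence unit per position
  if (is.null(placements) || nrow(placements) == 0L) {
    return(tibble::tibble(pos = integer(0), base = character(0),
                          strand = character(0), d5 = integer(0),
                          d3 = integer(0), source = character(0),
                          evidence_id = character(0)))
  }
  seq_of <- stats::setNames(seqs$seq, seqs$read_id)
  pieces <- lapply(seq_len(nrow(placements)), function(i) {
    r <- placements[i, ]
    m <- r$length
    j <- seq_len(m)
    p <- ((r$start - 1L + j - 1L) %% ref_len) + 1L
    rb <- strsplit(seq_of[[r$read_id]], "")[[1]]
    b <- if (r$strand == "+") rb else comp_base(rb[m - j + 1L])
    tibble::tibble(pos = p, base = b, strand = r$strand,
                   d5 = NA_integer_, d3 = NA_integer_, source = "pcr",
                   evidence_id = r$read_id)
  })
  dplyr::bind_rows(pieces)
}

#' Call the consensus at every position of a pileup
#'
#' @param pileup Pileup tibble from [build_pileup()] (PCR rows may be bound
#'   on).
#' @param ref_len Reference length (number of columns to call).
#' @param policy A [consensus_policy()].
#' @return A tibble with one row per position `1..ref_len`: `pos`, `base`
#'   (`NA` when nothing is called), `status` (`called`, `zero_coverage`,
#'   `single_evidence`, `flagged_discordant`, `resolved_damage`), `depth`,
#'   `n_major`, `n_minor`.
#' @export
call_columns <- function(pileup, ref_len, policy = consensus_policy()) {
  status <- rep("zero_coverage", ref_len)
  base <- rep(NA_character_, ref_len)
  depth <- integer(ref_len); n_major <- integer(ref_len)
  if (nrow(pileup) > 0L) {
    cnt <- dplyr::count(pileup, .data$pos, .data$base, name = "n")
    tot <- dplyr::count(pileup, .data$pos, name = "depth")
    depth[tot$pos] <- tot$depth
    # top and runner-up counts per position
    cnt <- dplyr::arrange(cnt, .data$pos, dplyr::desc(.data$n), .data$base)
    top <- cnt[!duplicated(cnt$pos), ]
    second <- cnt[duplicated(cnt$pos), ]
    second <- second[!duplicated(second$pos), ]
    sec_n <- integer(ref_len); sec_n[second$pos] <- second$n
    n_major[top$pos] <- top$n
    maj <- rep(NA_character_, ref_len); maj[top$pos] <- top$base

    status[depth == 1L] <- "single_evidence"
    multi <- depth >= 2L
    tie <- multi & (n_major == sec_n | n_major < policy$min_evidence)
    minor_frac <- ifelse(depth > 0L, (depth - n_major) / depth, 0)
    discordant <- multi & !tie & minor_frac > policy$discordance_threshold
    clean <- multi & !tie & !discordant
    status[tie] <- "flagged_discordant"
    status[clean] <- "called"
    base[clean] <- maj[clean]
    for (p in which(discordant)) {
      obs <- pileup[pileup$pos == p & pileup$base != maj[p], ]
      if (all(damage_explainable(obs, maj[p], policy$damage_window))) {
        status[p] <- "resolved_damage"
        base[p] <- maj[p]
      } else {
        status[p] <- "flagged_discordant"
      }
    }
  }
  tibble::tibble(pos = seq_len(ref_len), base = base, status = status,
                 depth = depth, n_major = n_major,
                 n_minor = depth - n_major)
}

# Is every observation in `obs` (rows of a pileup at one column, bases on
# the reference forward strand) explainable as terminal deamination given
# majority base `maj`? Orient consensus and observed base to the read's own
# strand, then test the two canonical patterns.
damage_explainable <- function(obs, maj, window) {
  if (nrow(obs) == 0L) return(logical(0))
  vapply(seq_len(nrow(obs)), function(i) {
    if (obs$source[i] != "read") return(FALSE)
    ref_rs <- if (obs$strand[i] == "+") maj else comp_base(maj)
    obs_rs <- if (obs$strand[i] == "+") obs$base[i] else comp_base(obs$base[i])
    (ref_rs == "C" && obs_rs == "T" && obs$d5[i] < window) ||
      (ref_rs == "G" && obs_rs == "A" && obs$d3[i] < window)
  }, logical(1))
}

#' Iterative reference-guided consensus assembly
#'
#' The assembly proceeds in three rounds. Round 1 maps the reads to the
#' reference under an absolute two-mismatch schedule, collapses duplicates,
#' and calls a provisional consensus (positions without a call keep the
#' reference base so the coordinate frame stays stable). Round 2 remaps all
#' reads to the provisional consensus under the length-scaled fraction
#' schedule (`n = 0.1`) and re-calls. Round 3 integrates each PCR consensus
#' sequence as a single evidence unit over its placement interval and makes
#' the final calls. Positions still without coverage form the gap list;
#' single-evidence and flagged positions form the verification list.
#'
#' @param reads Read tibble (`read_id`, `seq`), already adapter-trimmed.
#' @param ref Reference [circ_seq()].
#' @param pcr_sequences Optional tibble (`read_id`, `seq`) of PCR consensus
#'   sequences; placed on the provisional consensus by ungapped mapping.
#' @param policy A [consensus_policy()].
#' @return A `mito_assembly` object: list with `consensus` ([circ_seq()],
#'   reference frame, uncalled positions fall back to the provisional
#'   base), `calls` (final per-position tibble), `gaps`,
#'   `single_evidence`, `no_consensus` (integer position vectors),
#'   `records` (final deduplicated alignments), `rounds` (per-round
#'   statistics), `policy`.
#' @export
assemble <- function(reads, ref, pcr_sequences = NULL,
                     policy = consensus_policy()) {
  reads <- as_read_tbl(reads)
  L <- nchar(ref$seq)
  rounds <- list()

  # round 1: absolute n = 2 against the external reference
  rec1 <- deduplicate(map_reads(reads, ref, edit_schedule("absolute", 2)))
  pile1 <- build_pileup(rec1, reads, policy, L)
  calls1 <- call_columns(pile1, L, policy)
  ref_bases <- strsplit(ref$seq, "")[[1]]
  prov_bases <- ifelse(is.na(calls1$base), ref_bases, calls1$base)
  provisional <- circ_seq(paste(prov_bases, collapse = ""),
                          id = paste0(ref$id, "_provisional"),
                          circular = ref$circular)
  rounds$round1 <- round_stats(rec1, calls1)

  # round 2: fraction n = 0.1 against the provisional consensus
  sched2 <- edit_schedule("fraction", 0.1)
  rec2 <- deduplicate(map_reads(reads, provisional, sched2))
  pile2 <- build_pileup(rec2, reads, policy, L)
  calls2 <- call_columns(pile2, L, policy)
  rounds$round2 <- round_stats(rec2, calls2)

  # round 3: PCR consensus sequences as single evidence units
  result <- structure(list(
    consensus = NULL, calls = NULL, gaps = NULL, single_evidence = NULL,
    no_consensus = NULL, records = rec2, pcr_placements = NULL,
    pileup = pile2, pileup_reads = pile2, provisional = provisional,
    provisional_bases = prov_bases, ref_id = ref$id,
    circular = ref$circular, rounds = rounds, policy = policy
  ), class = "mito_assembly")
  integrate_pcr_evidence(result, pcr_sequences)
}

#' Integrate PCR consensus evidence into an assembly (round 3)
#'
#' Places each PCR consensus sequence on the provisional consensus by
#' ungapped mapping (best placement; ambiguous sequences are dropped with
#' a warning), adds one evidence unit per covered position, and re-calls
#' every column. Running [assemble()] with `pcr_sequences` is equivalent;
#' this entry point lets a pipeline design PCR evidence from a first
#' assembly's problem positions and integrate it without remapping the
#' reads.
#'
#' @param assembly A `mito_assembly` from [assemble()].
#' @param pcr_sequences Tibble (`read_id`, `seq`) of PCR consensus
#'   sequences, or `NULL`.
#' @return An updated `mito_assembly`.
#' @export
integrate_pcr_evidence <- function(assembly, pcr_sequences = NULL) {
  stopifnot(inherits(assembly, "mito_assembly"))
  L <- length(assembly$provisional)
  policy <- assembly$policy
  pcr_place <- NULL
  if (!is.null(pcr_sequences) && nrow(pcr_sequences) > 0L) {
    pcr_sequences <- as_read_tbl(pcr_sequences)
    pm <- map_reads(pcr_sequences, assembly$provisional,
                    edit_schedule("fraction", 0.1))
    pm <- pm[pm$mismatches == stats::ave(pm$mismatches, pm$read_id,
                                         FUN = min), ]
    dup_ids <- unique(pm$read_id[duplicated(pm$read_id)])
    if (length(dup_ids) > 0L) {
      warning("ambiguously placed PCR sequences dropped: ",
              paste(dup_ids, collapse = ", "))
      pm <- pm[!pm$read_id %in% dup_ids, ]
    }
    pcr_place <- pm
  }
  pile3 <- dplyr::bind_rows(assembly$pileup_reads,
                            pcr_pileup(pcr_place, pcr_sequences, L))
  calls3 <- call_columns(pile3, L, policy)
  assembly$rounds$round3 <- round_stats(assembly$records, calls3)
  final_bases <- ifelse(calls3$status %in% c("called", "resolved_damage"),
                        calls3$base, assembly$provisional_bases)
  assembly$consensus <- circ_seq(paste(final_bases, collapse = ""),
                                 id = paste0(assembly$ref_id, "_consensus"),
                                 circular = assembly$circular)
  assembly$calls <- calls3
  assembly$gaps <- calls3$pos[calls3$status == "zero_coverage"]
  assembly$single_evidence <- calls3$pos[calls3$status == "single_evidence"]
  assembly$no_consensus <- calls3$pos[calls3$status == "flagged_discordant"]
  assembly$pcr_placements <- pcr_place
  assembly$pileup <- pile3
  assembly
}

round_stats <- function(records, calls) {
  list(
    n_unique_reads = length(unique(
      records$read_id[!records$duplicate & records$mapq >= 0L])),
    n_unique_placements = sum(!records$duplicate),
    n_called = sum(calls$status %in% c("called", "resolved_damage")),
    n_zero_coverage = sum(calls$status == "zero_coverage"),
    n_single_evidence = sum(calls$status == "single_evidence"),
    n_flagged = sum(calls$status == "flagged_discordant"),
    n_resolved_damage = sum(calls$status == "resolved_damage")
  )
}

#' @export
print.mito_assembly <- function(x, ...) {
  st <- x$rounds$round3
  cat(sprintf(paste0(
    "<mito_assembly> %s nt consensus (%s)\n",
    "  called: %d  resolved_damage: %d  gaps: %d  single: %d  flagged: %d\n"),
    format(length(x$consensus), big.mark = ","),
    if (x$consensus$circular) "circular" else "linear",
    st$n_called - st$n_resolved_damage, st$n_resolved_damage,
    st$n_zero_coverage, st$n_single_evidence, st$n_flagged))
  invisible(x)
}

#' Fixed-point verification of an assembled consensus
#'
#' Remaps the reads to the final consensus under the fraction schedule and
#' re-calls every position; the assembly is at a fixed point when every
#' newly called base equals the consensus base.
#'
#' @param reads Read tibble.
#' @param consensus Consensus [circ_seq()].
#' @param policy A [consensus_policy()].
#' @param pcr_sequences Optional PCR evidence carried into the re-call.
#' @return A list: `fixed_point` (logical), `discrepancies` (tibble `pos`,
#'   `consensus_base`, `recalled_base`), `calls` (the re-called tibble).
#' @export
verify_fixed_point <- function(reads, consensus,
                               policy = consensus_policy(),
                               pcr_sequences = NULL) {
  reads <- as_read_tbl(reads)
  L <- nchar(consensus$seq)
  sched <- edit_schedule("fraction", 0.1)
  rec <- deduplicate(map_reads(reads, consensus, sched))
  pile <- build_pileup(rec, reads, policy, L)
  if (!is.null(pcr_sequences) && nrow(pcr_sequences) > 0L) {
    pcr_sequences <- as_read_tbl(pcr_sequences)
    pm <- map_reads(pcr_sequences, consensus, sched)
    pm <- pm[pm$mismatches == stats::ave(pm$mismatches, pm$read_id,
                                         FUN = min), ]
    pm <- pm[!pm$read_id %in% pm$read_id[duplicated(pm$read_id)], ]
    pile <- dplyr::bind_rows(pile, pcr_pileup(pm, pcr_sequences, L))
  }
  calls <- call_columns(pile, L, policy)
  cb <- strsplit(consensus$seq, "")[[1]]
  called <- calls$status %in% c("called", "resolved_damage")
  bad <- which(called & calls$base != cb)
  list(fixed_point = length(bad) == 0L,
       discrepancies = tibble::tibble(pos = bad, consensus_base = cb[bad],
                                      recalled_base = calls$base[bad]),
       calls = calls)
}

#' Coverage summary for an assembly
#'
#' Mean fold coverage counts every evidence base (unique read bases passing
#' the quality filter plus PCR bases) over the consensus length.
#'
#' @param result A `mito_assembly` from [assemble()].
#' @return A list: `mean_fold_coverage`, `depth` (per-position vector),
#'   `n_unique_reads`, `n_pcr_fragments`, `total_evidence_bases`.
#' @export
coverage_stats <- function(result) {
  stopifnot(inherits(result, "mito_assembly"))
  L <- length(result$consensus)
  depth <- integer(L)
  tab <- dplyr::count(result$pileup, .data$pos, name = "n")
  depth[tab$pos] <- tab$n
  total <- nrow(result$pileup)
  list(mean_fold_coverage = total / L,
       depth = depth,
       n_unique_reads = length(unique(
         result$pileup$evidence_id[result$pileup$source == "read"])),
       n_pcr_fragments = length(unique(
         result$pileup$evidence_id[result$pileup$source == "pcr"])),
       total_evidence_bases = total)
}
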