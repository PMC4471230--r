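# Substitution matrix over ACGTN: match +1, mismatch -1, N mismatches
# everything (including N). Affine gaps: open 4, extend 1, free end gaps —
# any sensible scheme agrees on >90%-identity organellar genomes.
diff_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
}

align_global <- function(a_seq, b_seq) {
  # Fast path for the common case of two equal-length, high-identity
  # genomes (substitutions only): the optimal alignment is gapless.
  # Guard against a hidden frame shift (compensating indel pair), which
  # would show up as a dense run of mismatches.
  if (nchar(a_seq) == nchar(b_seq)) {
    av <- strsplit(a_seq, "")[[1]]
    bv <- strsplit(b_seq, "")[[1]]
    mm <- av != bv
    n <- length(mm)
    if (mean(mm) < 0.05) {
      w <- 30L
      dense <- if (n > w) {
        cs <- cumsum(mm)
        max(cs[(w + 1L):n] - cs[1:(n - w)])
      } else sum(mm)
      if (dense < 15L) return(list(a = av, b = bv))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a_seq), Biostrings::DNAString(b_seq),
    type = "overlap", substitutionMatrix = diff_submat(),
    gapOpening = 4, gapExtension = 1)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  # "overlap" clips unaligned overhangs; restore them as end gaps so the
  # alignment spans both sequences completely
  pad <- function(al_a, al_b, a_seq, b_seq) {
    sa <- Biostrings::start(Biostrings::pattern(pa))
    ea <- Biostrings::end(Biostrings::pattern(pa))
    sb <- Biostrings::start(Biostrings::subject(pa))
    eb <- Biostrings::end(Biostrings::subject(pa))
    pre_a <- substr(a_seq, 1L, sa - 1L); pre_b <- substr(b_seq, 1L, sb - 1L)
    suf_a <- substr(a_seq, ea + 1L, nchar(a_seq))
    suf_b <- substr(b_seq, eb + 1L, nchar(b_seq))
    list(
      a = paste0(pre_a, strrep("-", nchar(pre_b)), al_a,
                 suf_a, strrep("-", nchar(suf_b))),
      b = paste0(strrep("-", nchar(pre_a)), pre_b, al_b,
                 strrep("-", nchar(suf_a)), suf_b))
  }
  p <- pad(al_a, al_b, a_seq, b_seq)
  left_normalise_gaps(p$a, p$b)
}

# Shift every gap run as far left as score neutrality allows, so gap
# placement is deterministic and insensitive to aligner tie-breaking.
# A run of gaps in `g` spanning columns i..j slides one column left when
# the column to its left is a match (g[i-1] == s[i-1], both bases) and the
# partner base at the run's right edge equals that matched base
# (s[j] == s[i-1]) — the homopolymer/tandem ambiguity case.
left_normalise_gaps <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  shift_left <- function(g, s) {
    n <- length(g)
    i <- 1L
    while (i <= n) {
      if (g[i] == "-") {
        j <- i
        while (j < n && g[j + 1L] == "-") j <- j + 1L
        while (i > 1L && g[i - 1L] != "-" && s[i - 1L] != "-" &&
                 g[i - 1L] == s[i - 1L] && s[j] == s[i - 1L]) {
          g[j] <- g[i - 1L]
          g[i - 1L] <- "-"
          i <- i - 1L
          j <- j - 1L
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    g
  }
  av <- shift_left(av, bv)
  bv <- shift_left(bv, av)
  list(a = av, b = bv)
}

#' Pairwise differences between two genomes of the same locus
#'
#' Globally aligns the two sequences (affine gaps, free ends) and emits one
#' record per substitution and per contiguous indel run, with positions on
#' genome `a`'s coordinate frame. `kind` names the event in `b` relative to
#' `a`: an `insertion` is bases present only in `b` (positioned at the `a`
#' base immediately to its left), a `deletion` is bases of `a` missing from
#' `b` (positioned at the first missing base).
#'
#' @param a,b [circ_seq()] objects (or character scalars) of the same locus.
#' @param min_identity Abort when the aligned identity falls below this
#'   (degenerate alignment guard, default 0.5).
#' @return A `mito_diffs` tibble: `position`, `kind`, `base_a`, `base_b`,
#'   `context_a`, `context_b` (5-nt windows centred on the event),
#'   `ts_tv` (`"t"`/`"v"`/`NA`).
#' @export
pairwise_differences <- function(a, b, min_identity = 0.5) {
  if (is.character(a)) a <- circ_seq(a, id = "a")
  if (is.character(b)) b <- circ_seq(b, id = "b")
  al <- align_global(a$seq, b$seq)
  av <- al$a; bv <- al$b
  ncol_al <- length(av)
  aligned_cols <- av != "-" & bv != "-"
  # identity over the longer genome, so a tiny high-identity overlap in an
  # otherwise unalignable pair still counts as degenerate
  ident <- sum(av == bv & aligned_cols) /
    max(nchar(a$seq), nchar(b$seq))
  if (ident < min_identity) {
    stop(sprintf("alignment degenerate: identity %.2f < %.2f", ident,
                 min_identity), call. = FALSE)
  }
  apos <- cumsum(av != "-")
  ctx <- function(pos) {
    lo <- max(pos - 2L, 1L); hi <- min(pos + 2L, nchar(a$seq))
    substr(a$seq, lo, hi)
  }
  ctx_b <- function(bpos) {
    lo <- max(bpos - 2L, 1L); hi <- min(bpos + 2L, nchar(b$seq))
    substr(b$seq, lo, hi)
  }
  bpos_v <- cumsum(bv != "-")
  recs <- list()
  i <- 1L
  while (i <= ncol_al) {
    if (av[i] != "-" && bv[i] != "-") {
      if (av[i] != bv[i]) {
        ts <- if (all(c(av[i], bv[i]) %in% c("A", "C", "G", "T")))
          (if (is_transition(av[i], bv[i])) "t" else "v") else NA_character_
        recs[[length(recs) + 1L]] <- tibble::tibble(
          position = apos[i], kind = "substitution",
          base_a = av[i], base_b = bv[i],
          context_a = ctx(apos[i]), context_b = ctx_b(bpos_v[i]),
          ts_tv = ts)
      }
      i <- i + 1L
    } else if (av[i] == "-") {
      j <- i
      while (j < ncol_al && av[j + 1L] == "-") j <- j + 1L
      recs[[length(recs) + 1L]] <- tibble::tibble(
        position = apos[i], kind = "insertion", base_a = "-",
        base_b = paste(bv[i:j], collapse = ""),
        context_a = ctx(max(apos[i], 1L)), context_b = ctx_b(bpos_v[i]),
        ts_tv = NA_character_)
      i <- j + 1L
    } else {
      j <- i
      while (j < ncol_al && bv[j + 1L] == "-") j <- j + 1L
      recs[[length(recs) + 1L]] <- tibble::tibble(
        position = apos[i], kind = "deletion",
        base_a = paste(av[i:j], collapse = ""), base_b = "-",
        context_a = ctx(apos[i]), context_b = ctx_b(max(bpos_v[i], 1L)),
        ts_tv = NA_character_)
      i <- j + 1L
    }
  }
  out <- if (length(recs) == 0L) {
    tibble::tibble(position = integer(0), kind = character(0),
                   base_a = character(0), base_b = character(0),
                   context_a = character(0), context_b = character(0),
                   ts_tv = character(0))
  } else {
    dplyr::arrange(dplyr::bind_rows(recs), .data$position)
  }
  class(out) <- c("mito_diffs", class(out))
  out
}

MITO_CODE_ID <- "2" # NCBI vertebrate mitochondrial genetic code

translate_codon <- function(codon) {
  gc <- Biostrings::getGeneticCode(MITO_CODE_ID)
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  unname(gc[codon])
}

feature_at <- function(pos, features) {
  hit <- features[features$start <= pos & features$end >= pos, ]
  if (nrow(hit) == 0L) return(NULL)
  prec <- c(CDS = 1L, tRNA = 2L, rRNA = 2L, `D-loop` = 3L)
  hit$rank <- prec[hit$type]
  hit[order(hit$rank), ][1L, ]
}

#' Annotate difference records with feature context and coding effect
#'
#' Fills in, for each record, the overlapping feature (precedence
#' CDS > tRNA/rRNA > D-loop > intergenic), the strand, the codon position
#' (CDS only, frame and strand aware) and the amino-acid effect under the
#' vertebrate mitochondrial genetic code.
#'
#' @param diffs A `mito_diffs` tibble with positions on `genome`'s frame.
#' @param genome The [circ_seq()] the positions refer to (genome `a` of the
#'   comparison).
#' @param features Feature tibble (defaults to `genome$features`).
#' @return The diffs tibble with added columns `feature`, `feature_type`,
#'   `strand`, `codon_position`, `aa_a`, `aa_b`, `effect`
#'   (`silent`/`missense`/`nonsense`/`NA`).
#' @export
classify_against_annotation <- function(diffs, genome,
                                        features = genome$features) {
  stopifnot(!is.null(features))
  n <- nrow(diffs)
  feature <- rep(NA_character_, n); ftype <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  codon_position <- rep(NA_integer_, n)
  aa_a <- rep(NA_character_, n); aa_b <- rep(NA_character_, n)
  effect <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pos <- diffs$position[i]
    if (pos < 1L || pos > nchar(genome$seq)) {
      stop("difference position outside the genome", call. = FALSE)
    }
    f <- feature_at(pos, features)
    if (is.null(f)) { feature[i] <- "intergenic"; ftype[i] <- "intergenic"; next }
    feature[i] <- f$name; ftype[i] <- f$type; strand[i] <- f$strand
    if (f$type != "CDS" || diffs$kind[i] != "substitution") next
    if (f$strand == "+") {
      idx <- pos - f$start              # 0-based from reading start
      cp <- idx %% 3L
      lo <- pos - cp
      codon <- substr(genome$seq, lo, lo + 2L)
      alt <- codon
      substr(alt, cp + 1L, cp + 1L) <- diffs$base_b[i]
    } else {
      idx <- f$end - pos
      cp <- idx %% 3L
      hi <- pos + cp
      codon <- revcomp(substr(genome$seq, hi - 2L, hi))
      alt <- codon
      substr(alt, cp + 1L, cp + 1L) <- comp_base(diffs$base_b[i])
    }
    codon_position[i] <- cp + 1L
    if (nchar(codon) == 3L) {
      aa_a[i] <- translate_codon(codon)
      aa_b[i] <- translate_codon(alt)
      effect[i] <- if (is.na(aa_a[i]) || is.na(aa_b[i])) NA_character_
        else if (aa_a[i] == aa_b[i]) "silent"
        else if (aa_b[i] == "*") "nonsense"
        else "missense"
    }
  }
  diffs$feature <- feature
  diffs$feature_type <- ftype
  diffs$strand <- strand
  diffs$codon_position <- codon_position
  diffs$aa_a <- aa_a
  diffs$aa_b <- aa_b
  diffs$effect <- effect
  diffs
}

#' Polymorphisms specific to the target genome
#'
#' Given the differences of a target genome against a reference frame
#' (`diffs = pairwise_differences(frame, target)`), retains the records
#' whose target allele is carried by none of the panel genomes at the
#' homologous position. Each panel genome is aligned to the same frame, so
#' a record is shared when the panel comparison contains an identical
#' event (same position, kind and target allele).
#'
#' @param target_diffs A `mito_diffs` tibble on the frame genome's
#'   coordinates.
#' @param frame The frame [circ_seq()] (genome `a` of the comparison).
#' @param panel List of panel [circ_seq()] genomes.
#' @return The subset of `target_diffs` specific to the target.
#' @export
specific_polymorphisms <- function(target_diffs, frame, panel) {
  if (length(panel) == 0L) return(target_diffs)
  key <- function(d) paste(d$position, d$kind, d$base_b, sep = "\r")
  shared <- rep(FALSE, nrow(target_diffs))
  tk <- key(target_diffs)
  for (g in panel) {
    pd <- pairwise_differences(frame, g)
    shared <- shared | tk %in% key(pd)
  }
  target_diffs[!shared, ]
}

#' Substitution-rate ratio of a region versus the rest of the genome
#'
#' `(count_in / length_in) / (count_out / length_out)`, the summary used to
#' show the fast-evolving control region (D-loop) against the genome
#' background.
#'
#' @param diffs A `mito_diffs` tibble (classified or not).
#' @param features Feature tibble defining the region.
#' @param region_name Feature `name` (all its segments pooled).
#' @param genome_len Genome length the positions live on.
#' @return A list: `ratio` (`NA` when no differences fall outside the
#'   region), `n_in`, `n_out`, `len_in`, `len_out`.
#' @export
region_rate_ratio <- function(diffs, features, region_name, genome_len) {
  seg <- features[features$name == region_name, ]
  if (nrow(seg) == 0L) stop("region not present in annotation", call. = FALSE)
  in_region <- rep(FALSE, nrow(diffs))
  for (i in seq_len(nrow(seg))) {
    in_region <- in_region |
      (diffs$position >= seg$start[i] & diffs$position <= seg$end[i])
  }
  len_in <- sum(seg$end - seg$start + 1L)
  len_out <- genome_len - len_in
  n_in <- sum(in_region); n_out <- sum(!in_region)
  ratio <- if (n_out == 0L) NA_real_ else (n_in / len_in) / (n_out / len_out)
  list(ratio = ratio, n_in = n_in, n_out = n_out,
       len_in = len_in, len_out = len_out)
}

#' Write difference records as TSV
#'
#' Column layout mirrors the field's polymorphism tables: Position, Strand,
#' codon position, the two alleles, the two 5-nt contexts, and the type
#' ("t" transition, "v" transversion, "i"/"d" indels).
#'
#' @param diffs A (classified) `mito_diffs` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diffs_tsv <- function(diffs, path) {
  type <- dplyr::case_when(
    diffs$kind == "insertion" ~ "i",
    diffs$kind == "deletion" ~ "d",
    TRUE ~ diffs$ts_tv)
  out <- data.frame(
    Position = diffs$position,
    Strand = if ("strand" %in% names(diffs)) diffs$strand else NA,
    Position_codon = if ("codon_position" %in% names(diffs))
      diffs$codon_position else NA,
    Base_a = diffs$base_a, Base_b = diffs$base_b,
    Sequence_a = diffs$context_a, Sequence_b = diffs$context_b,
    Type = type)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
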