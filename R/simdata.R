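#' Terminal deamination damage model
#'
#' Post-mortem cytosine deamination is read as C->T near the 5' end of a
#' fragment and, after end repair of the complementary strand, as G->A near
#' the 3' end. The per-position rate decays geometrically with the offset
#' from the end: rate at offset `k` is `delta * decay^k`. Sequencing error is
#' a uniform per-base substitution applied after damage.
#'
#' @param delta5 Probability of C->T at the 5'-terminal position.
#' @param delta3 Probability of G->A at the 3'-terminal position.
#' @param decay Per-position geometric decay factor, in (0, 1).
#' @param seq_error Per-base uniform sequencing-error probability.
#' @return A `damage_model` list.
#' @export
damage_model <- function(delta5 = 0.3, delta3 = 0.3, decay = 0.5,
                         seq_error = 0.001) {
  stopifnot(delta5 >= 0, delta5 <= 1, delta3 >= 0, delta3 <= 1,
            decay > 0, decay < 1, seq_error >= 0, seq_error <= 1)
  structure(list(delta5 = delta5, delta3 = delta3, decay = decay,
                 seq_error = seq_error), class = "damage_model")
}

#' Fragment-length model for ancient DNA reads
#'
#' Ancient DNA is heavily fragmented: most molecules are short, with a long
#' right tail up to the sequencing read length. The default is a discretised
#' truncated geometric distribution over `[min_len, max_len]` favouring
#' short fragments; `rate` controls how fast the weight falls off. The
#' default `rate = 0.034` puts the mean fragment length at 43.3 nt, the
#' mean unique-read length the emulated study conditions imply.
#'
#' @param min_len Minimum fragment length (nt).
#' @param max_len Maximum fragment length (nt, the sequencing read length).
#' @param rate Geometric decay rate of the default length weights.
#' @param length_weights Optional explicit weights over
#'   `min_len:max_len` (normalised internally).
#' @return A `fragment_model` list with a normalised `length_weights` vector.
#' @export
fragment_model <- function(min_len = 20L, max_len = 101L, rate = 0.034,
                           length_weights = NULL) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  lens <- min_len:max_len
  if (is.null(length_weights)) {
    length_weights <- (1 - rate)^(lens - min_len)
  }
  stopifnot(length(length_weights) == length(lens), all(length_weights >= 0),
            sum(length_weights) > 0)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 lengths = lens,
                 length_weights = length_weights / sum(length_weights)),
            class = "fragment_model")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(a, b) unname(TRANSITION[a]) == b

#' Plant substitutions and indels into a genome
#'
#' Creates a mutated copy of `ref` differing by exactly the requested events,
#' together with a ground-truth difference table on the `ref` coordinate
#' frame (the same frame [pairwise_differences()] reports on, so the two are
#' directly comparable). Event positions are drawn without collision and are
#' kept at least 3 nt apart; indels are resampled until their local sequence
#' context makes the alignment gap placement unambiguous, so the round trip
#' through the pairwise aligner is exact.
#'
#' @param ref A [circ_seq()].
#' @param n_transitions,n_transversions Substitution counts to plant.
#' @param indels List of `(kind, length)` pairs, e.g.
#'   `list(c("ins", 1), c("del", 2))`; `"ins"` inserts bases into the mutant,
#'   `"del"` removes bases from it.
#' @param seed Integer seed; the operation is fully deterministic given it.
#' @param positions Optional integer vector of admissible positions
#'   (defaults to the whole genome minus a 5-nt margin at each end).
#' @return A list with `genome` (the mutated [circ_seq()]) and `truth`, a
#'   tibble with columns `position`, `kind`, `base_a` (ref allele),
#'   `base_b` (mutant allele), `ts_tv`, sorted by position.
#' @export
plant_variants <- function(ref, n_transitions, n_transversions,
                           indels = list(), seed = 1L, positions = NULL) {
  stopifnot(inherits(ref, "circ_seq"), n_transitions >= 0,
            n_transversions >= 0)
  n <- nchar(ref$seq)
  indel_len <- if (length(indels) == 0L) 0L else
    sum(vapply(indels, function(e) as.integer(e[[2]]), integer(1)))
  if (n <= indel_len) stop("genome shorter than total planted indel length",
                           call. = FALSE)
  set.seed(as.integer(seed))

  bases <- strsplit(ref$seq, "")[[1]]
  n_events <- n_transitions + n_transversions + length(indels)
  if (is.null(positions)) positions <- seq(6L, n - 6L)
  # keep events >= 3 nt apart so 5-nt contexts are clean and gaps cannot
  # slide into a neighbouring event
  avail <- positions
  pick_pos <- function(avail) {
    if (length(avail) == 0L)
      stop("requested events exceed available positions", call. = FALSE)
    p <- if (length(avail) == 1L) avail else sample(avail, 1L)
    p
  }
  drop_near <- function(avail, p, r = 4L) avail[abs(avail - p) > r]

  truth <- list()
  # substitutions
  n_sub <- n_transitions + n_transversions
  sub_kind <- c(rep("t", n_transitions), rep("v", n_transversions))
  if (n_sub > 0L) sub_kind <- sample(sub_kind)
  for (i in seq_len(n_sub)) {
    p <- pick_pos(avail); avail <- drop_near(avail, p)
    old_b <- bases[p]
    new_b <- if (sub_kind[i] == "t") TRANSITION[[old_b]] else {
      tv <- setdiff(c("A", "C", "G", "T"), c(old_b, TRANSITION[[old_b]]))
      sample(tv, 1L)
    }
    bases[p] <- new_b
    truth[[length(truth) + 1L]] <- tibble::tibble(
      position = p, kind = "substitution", base_a = old_b, base_b = new_b,
      ts_tv = sub_kind[i])
  }
  # indels: plan on the ref frame, apply afterwards from right to left
  indel_plan <- list()
  for (e in indels) {
    kind <- match.arg(e[[1]], c("ins", "del"))
    len <- as.integer(e[[2]])
    stopifnot(len >= 1L)
    repeat {
      p <- pick_pos(avail)
      if (kind == "ins") {
        # insertion after ref position p; choose bases so the run cannot
        # slide: first inserted base != bases[p], last != bases[p+1]
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        ins[1] <- sample(setdiff(c("A", "C", "G", "T"),
                                 c(bases[p], bases[p + 1L])), 1L)
        ins[len] <- sample(setdiff(c("A", "C", "G", "T"),
                                   c(bases[p], bases[p + 1L])), 1L)
        ok <- TRUE
        if (ok) {
          avail <- drop_near(avail, p)
          indel_plan[[length(indel_plan) + 1L]] <-
            list(kind = "ins", pos = p, seq = paste(ins, collapse = ""))
          truth[[length(truth) + 1L]] <- tibble::tibble(
            position = p, kind = "insertion", base_a = "-",
            base_b = paste(ins, collapse = ""), ts_tv = NA_character_)
          break
        }
      } else {
        # delete ref positions p..p+len-1; unambiguous iff the deleted run
        # is not extendable left or right by identical flanking bases
        del <- bases[p:(p + len - 1L)]
        if (bases[p - 1L] != del[len] && bases[p + len] != del[1L] &&
              bases[p - 1L] != del[1L] && bases[p + len] != del[len]) {
          avail <- drop_near(avail, p, r = 4L + len)
          indel_plan[[length(indel_plan) + 1L]] <-
            list(kind = "del", pos = p, len = len)
          truth[[length(truth) + 1L]] <- tibble::tibble(
            position = p, kind = "deletion",
            base_a = paste(del, collapse = ""), base_b = "-",
            ts_tv = NA_character_)
          break
        }
        avail <- drop_near(avail, p) # unusable context, resample
      }
    }
  }
  # apply indels right-to-left so earlier coordinates stay valid
  if (length(indel_plan) > 0L) {
    ord <- order(vapply(indel_plan, function(x) x$pos, numeric(1)),
                 decreasing = TRUE)
    seq_chr <- paste(bases, collapse = "")
    for (ip in indel_plan[ord]) {
      if (ip$kind == "ins") {
        seq_chr <- paste0(substr(seq_chr, 1L, ip$pos), ip$seq,
                          substr(seq_chr, ip$pos + 1L, nchar(seq_chr)))
      } else {
        seq_chr <- paste0(substr(seq_chr, 1L, ip$pos - 1L),
                          substr(seq_chr, ip$pos + ip$len, nchar(seq_chr)))
      }
    }
  } else {
    seq_chr <- paste(bases, collapse = "")
  }
  truth <- if (length(truth) == 0L) {
    tibble::tibble(position = integer(0), kind = character(0),
                   base_a = character(0), base_b = character(0),
                   ts_tv = character(0))
  } else {
    dplyr::arrange(dplyr::bind_rows(truth), .data$position)
  }
  list(genome = circ_seq(seq_chr, id = paste0(ref$id, "_mut"),
                         circular = ref$circular, features = NULL),
       truth = truth)
}

#' Simulate ancient DNA reads from a genome
#'
#' Fragments are sampled uniformly over the genome (wrapping across the
#' origin when circular), on either strand with equal probability, with
#' lengths drawn from `frag`. Damage is applied on the read strand after
#' fragmentation: C->T at 5' offsets and G->A at 3' offsets, each
#' Bernoulli(`delta * decay^k`), then uniform sequencing error.
#'
#' @param genome A [circ_seq()].
#' @param n_reads Number of reads to simulate.
#' @param frag A [fragment_model()].
#' @param dmg A [damage_model()].
#' @param seed Integer seed.
#' @param prefix Read-id prefix.
#' @return A list with `reads` (tibble `read_id`, `seq`) and `truth`
#'   (tibble `read_id`, `source`, `start`, `strand`, `length`,
#'   `damage_offsets`: comma-separated 0-based read offsets that were
#'   deaminated, `""` if none).
#' @export
simulate_reads <- function(genome, n_reads, frag = fragment_model(),
                           dmg = damage_model(), seed = 1L,
                           prefix = genome$id) {
  stopifnot(inherits(genome, "circ_seq"), n_reads >= 0)
  set.seed(as.integer(seed))
  n <- nchar(genome$seq)
  if (n_reads == 0L) {
    return(list(
      reads = tibble::tibble(read_id = character(0), seq = character(0)),
      truth = tibble::tibble(read_id = character(0), source = character(0),
                             start = integer(0), strand = character(0),
                             length = integer(0),
                             damage_offsets = character(0))))
  }
  lens <- sample(frag$lengths, n_reads, replace = TRUE,
                 prob = frag$length_weights)
  lens <- pmin(lens, n)
  starts <- if (genome$circular) sample.int(n, n_reads, replace = TRUE)
            else vapply(lens, function(l) sample.int(n - l + 1L, 1L),
                        integer(1))
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  raw_frag <- vapply(seq_len(n_reads),
                     function(i) cs_subseq(genome, starts[i], lens[i]),
                     character(1))
  seqs <- ifelse(strands == "-", revcomp(raw_frag), raw_frag)

  dmg_off <- character(n_reads)
  if (dmg$delta5 > 0 || dmg$delta3 > 0 || dmg$seq_error > 0) {
    for (i in seq_len(n_reads)) {
      b <- strsplit(seqs[i], "")[[1]]
      m <- length(b)
      hit <- integer(0)
      if (dmg$delta5 > 0) {
        k5 <- which(b == "C") - 1L
        p5 <- dmg$delta5 * dmg$decay^k5
        h5 <- k5[stats::runif(length(k5)) < p5]
        if (length(h5) > 0L) { b[h5 + 1L] <- "T"; hit <- c(hit, h5) }
      }
      if (dmg$delta3 > 0) {
        idx <- which(b == "G")
        k3 <- m - idx
        p3 <- dmg$delta3 * dmg$decay^k3
        h <- idx[stats::runif(length(idx)) < p3]
        if (length(h) > 0L) { b[h] <- "A"; hit <- c(hit, h - 1L) }
      }
      if (dmg$seq_error > 0) {
        err <- which(stats::runif(m) < dmg$seq_error)
        for (j in err) b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1L)
      }
      seqs[i] <- paste(b, collapse = "")
      dmg_off[i] <- paste(sort(unique(hit)), collapse = ",")
    }
  }
  ids <- sprintf("%s_r%06d", prefix, seq_len(n_reads))
  list(reads = tibble::tibble(read_id = ids, seq = seqs),
       truth = tibble::tibble(read_id = ids, source = genome$id,
                              start = starts, strand = strands,
                              length = lens, damage_offsets = dmg_off))
}

#' Mix read sets in given proportions
#'
#' Emulates a contaminated ancient extract: the output draws a
#' multinomial(`n_total`, `proportions`) number of reads from each labelled
#' set. A set contributing all of its reads is passed through unchanged (in
#' order); otherwise reads are drawn without replacement when possible, with
#' replacement when a set is smaller than its requested count.
#'
#' @param readsets List of lists `list(reads = <tibble>, label = <chr>)`
#'   (a `truth` element, if present, is subset alongside).
#' @param proportions Numeric simplex weights, one per set.
#' @param n_total Total output size (default: sum of input sizes).
#' @param seed Integer seed.
#' @return A list with `reads` (tibble `read_id`, `seq`, `label`) and
#'   `counts` (tibble `label`, `n`).
#' @export
mix_contaminants <- function(readsets, proportions,
                             n_total = NULL, seed = 1L) {
  stopifnot(length(readsets) == length(proportions), all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1", call. = FALSE)
  sizes <- vapply(readsets, function(s) nrow(s$reads), integer(1))
  if (any(sizes == 0L & proportions > 0))
    stop("empty read set with positive weight", call. = FALSE)
  if (is.null(n_total)) n_total <- sum(sizes)
  set.seed(as.integer(seed))
  counts <- as.integer(stats::rmultinom(1L, n_total, proportions))
  pieces <- lapply(seq_along(readsets), function(i) {
    k <- counts[i]
    if (k == 0L) return(NULL)
    rs <- readsets[[i]]$reads
    idx <- if (k == nrow(rs)) seq_len(k)
           else sample.int(nrow(rs), k, replace = k > nrow(rs))
    out <- rs[idx, ]
    out$label <- readsets[[i]]$label
    out
  })
  reads <- dplyr::bind_rows(pieces)
  list(reads = reads,
       counts = dplyr::count(reads, .data$label, name = "n"))
}

#' Write a simulation truth table as TSV
#'
#' @param truth Truth tibble from [simulate_reads()] or [plant_variants()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
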