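#' Edit-distance schedule for ungapped read mapping
#'
#' Three modes mirror the mapper settings used throughout the workflow:
#' `"absolute"` allows a constant number of mismatches per read (the
#' first-pass assembly setting, `n = 2`); `"fraction"` allows a maximum that
#' grows with read length following the classical short-read-aligner rule
#' (smallest `k >= 0` such that `P(X > k) < n` for
#' `X ~ Poisson(0.02 * read_len)`, 2% base-error); `"perfect"` allows none
#' (the competitive species screen). Gapped alignment is never allowed.
#'
#' @param mode One of `"absolute"`, `"fraction"`, `"perfect"`.
#' @param n The mismatch count (absolute) or fraction (fraction mode).
#' @return An `edit_schedule` list.
#' @export
edit_schedule <- function(mode = c("absolute", "fraction", "perfect"),
                          n = 2) {
  mode <- match.arg(mode)
  if (mode == "absolute") stopifnot(n >= 0, n == as.integer(n))
  if (mode == "fraction") stopifnot(n > 0, n < 1)
  structure(list(mode = mode, n = n, gap_open_allowed = FALSE),
            class = "edit_schedule")
}

#' Maximum mismatch count for a read length under a schedule
#'
#' @param read_len Read length(s), nt.
#' @param sched An [edit_schedule()].
#' @return Integer vector of mismatch bounds.
#' @export
max_edit_distance <- function(read_len, sched) {
  stopifnot(all(read_len >= 1L))
  switch(sched$mode,
    perfect  = rep(0L, length(read_len)),
    absolute = rep(as.integer(sched$n), length(read_len)),
    fraction = vapply(read_len, function(m) {
      lambda <- 0.02 * m
      k <- 0L
      while (stats::ppois(k, lambda, lower.tail = FALSE) >= sched$n) {
        k <- k + 1L
      }
      k
    }, integer(1))
  )
}

# byte encoding in which N never matches anything (including another N):
# reference N -> 0x01, read N -> 0x02
encode_ref <- function(seq) {
  r <- charToRaw(seq)
  r[r == charToRaw("N")] <- as.raw(1L)
  r
}
encode_read <- function(seq) {
  if (grepl("[^ACGTN]", seq)) {
    stop("read contains symbols outside ACGTN", call. = FALSE)
  }
  r <- charToRaw(seq)
  r[r == charToRaw("N")] <- as.raw(2L)
  r
}

# mismatch counts of `q` against every window of `r` starting at 1..n_starts
scan_hamming <- function(r, q, n_starts) {
  m <- length(q)
  mm <- integer(n_starts)
  for (j in seq_len(m)) {
    mm <- mm + (r[j:(j + n_starts - 1L)] != q[j])
  }
  mm
}

prep_ref_index <- function(genomes) {
  if (inherits(genomes, "circ_seq")) genomes <- list(genomes)
  lapply(genomes, function(g) {
    L <- nchar(g$seq)
    doubled <- if (g$circular) paste0(g$seq, g$seq) else g$seq
    list(id = g$id, len = L, circular = g$circular, hay = doubled,
         enc = encode_ref(doubled))
  })
}

# Seed-and-verify search: any placement of an m-nt read with at most
# `bound` mismatches must contain an exact occurrence of at least one of
# `bound + 1` disjoint read segments (pigeonhole), so exact segment hits
# enumerate a complete candidate set, each then verified by Hamming count.
# Segments containing N are skipped: a zero-mismatch segment can never
# contain N (N always mismatches), so completeness is preserved.
seed_candidates <- function(seq, m, bound, ref) {
  n_starts <- if (ref$circular) ref$len else ref$len - m + 1L
  if (n_starts < 1L) return(integer(0))
  k <- bound + 1L
  cuts <- floor(seq(0L, m, length.out = k + 1L))
  cand <- integer(0)
  for (s in seq_len(k)) {
    lo <- cuts[s] + 1L; hi <- cuts[s + 1L]
    if (hi < lo) next
    seg <- substr(seq, lo, hi)
    if (grepl("N", seg, fixed = TRUE)) next
    hits <- gregexpr(seg, ref$hay, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    cand <- c(cand, as.integer(hits) - (lo - 1L))
  }
  if (length(cand) == 0L) return(integer(0))
  if (ref$circular) cand <- ((cand - 1L) %% ref$len) + 1L
  cand <- sort(unique(cand))
  cand[cand >= 1L & cand <= n_starts]
}

hamming_at <- function(ref_enc, q_enc, starts) {
  m <- length(q_enc)
  vapply(starts, function(s)
    sum(ref_enc[s:(s + m - 1L)] != q_enc), integer(1))
}

#' Map reads to one or more circular reference genomes
#'
#' Ungapped alignment: every placement on either strand whose Hamming
#' distance is within the schedule's bound for the read's length is
#' returned, with circular wrap-around implemented by scanning the doubled
#' sequence and reducing start positions modulo the genome length. `N` in a
#' read or a reference always counts as a mismatch.
#'
#' The mapping-quality proxy reproduces the operative "confidently unique"
#' distinction used by the consensus rule: `mapq = 37` when exactly one
#' placement attains the minimum mismatch count and no other placement is
#' within one mismatch of it; `25` when the best is unique but a placement
#' exists at best+1; `0` when the best count is tied. Non-best placements
#' carry `mapq = 0`.
#'
#' @param reads Tibble with `read_id`, `seq`, or a named character vector.
#' @param genomes A [circ_seq()] or list of them.
#' @param sched An [edit_schedule()].
#' @return A tibble of alignment records: `read_id`, `ref_id`, `start`,
#'   `end` (1-based inclusive on the forward strand; `end` may exceed the
#'   genome length for wrapping alignments, reduce modulo length), `strand`,
#'   `length`, `mismatches`, `mapq`, `duplicate` (all `FALSE`; see
#'   [deduplicate()]).
#' @export
map_reads <- function(reads, genomes, sched = edit_schedule("absolute", 2)) {
  reads <- as_read_tbl(reads)
  idx <- prep_ref_index(genomes)
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    out[[i]] <- map_one(reads$read_id[i], reads$seq[i], idx, sched)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(tibble::tibble(read_id = character(0), ref_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), length = integer(0),
                          mismatches = integer(0), mapq = integer(0),
                          duplicate = logical(0)))
  }
  grab <- function(f, mode) vapply(out, function(h) h[[f]], mode)
  n_each <- vapply(out, function(h) length(h$start), integer(1))
  tibble::tibble(
    read_id = rep(grab("read_id", character(1)), n_each),
    ref_id = unlist(lapply(out, `[[`, "ref_id")),
    start = unlist(lapply(out, `[[`, "start")),
    end = unlist(lapply(out, `[[`, "end")),
    strand = unlist(lapply(out, `[[`, "strand")),
    length = rep(grab("length", integer(1)), n_each),
    mismatches = unlist(lapply(out, `[[`, "mismatches")),
    mapq = unlist(lapply(out, `[[`, "mapq")),
    duplicate = FALSE)
}

as_read_tbl <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
    reads <- tibble::tibble(read_id = ids, seq = unname(reads))
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  reads
}

map_one <- function(read_id, seq, idx, sched) {
  m <- nchar(seq)
  bound <- max_edit_distance(m, sched)
  seq_rev <- revcomp(seq)
  q_fwd <- encode_read(seq)
  q_rev <- encode_read(seq_rev)
  ref_id <- character(0); start <- integer(0); strand <- character(0)
  mism <- integer(0)
  for (ref in idx) {
    if (m > ref$len) next  # alignments longer than the genome are rejected
    for (st in c("+", "-")) {
      q <- if (st == "+") q_fwd else q_rev
      s <- if (st == "+") seq else seq_rev
      cand <- seed_candidates(s, m, bound, ref)
      if (length(cand) == 0L) next
      mm <- hamming_at(ref$enc, q, cand)
      keep <- mm <= bound
      if (any(keep)) {
        k <- sum(keep)
        ref_id <- c(ref_id, rep(ref$id, k))
        start <- c(start, cand[keep])
        strand <- c(strand, rep(st, k))
        mism <- c(mism, mm[keep])
      }
    }
  }
  if (length(start) == 0L) return(NULL)
  best <- min(mism)
  n_best <- sum(mism == best)
  read_mapq <- if (n_best > 1L) 0L
               else if (any(mism == best + 1L)) 25L
               else 37L
  list(read_id = read_id, ref_id = ref_id, start = start,
       end = start + m - 1L, strand = strand, length = m,
       mismatches = mism, mapq = ifelse(mism == best, read_mapq, 0L))
}

#' Flag PCR-duplicate placements
#'
#' Among records sharing the same `(ref_id, start, end, strand)` key, all
#' but the first are flagged as duplicates; opposite-strand placements of
#' the same interval are distinct molecules and kept.
#'
#' @param records Alignment tibble from [map_reads()].
#' @return The same tibble with the `duplicate` flag set.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$ref_id, records$start, records$end, records$strand,
               sep = "\r")
  records$duplicate <- duplicated(key)
  records
}

#' Trim adapters and trailing Ns, drop short reads
#'
#' Each read is truncated at the leftmost position where it matches a
#' prefix of the adapter of at least `seed_len` nt extending either over the
#' full adapter or to the read's 3' end; trailing runs of `N` are then
#' removed, and reads shorter than `min_len` are discarded.
#'
#' @param reads Tibble with `read_id`, `seq`.
#' @param adapter Adapter sequence (5'->3' as it appears at the read 3' end).
#' @param min_len Minimum retained read length (nt).
#' @param seed_len Minimum adapter-prefix match length.
#' @return The trimmed read tibble.
#' @export
trim_reads <- function(reads, adapter, min_len = 20L, seed_len = 8L) {
  stopifnot(nchar(adapter) >= 1L, min_len >= 1L)
  reads <- as_read_tbl(reads)
  la <- nchar(adapter)
  trim_one <- function(s) {
    n <- nchar(s)
    cut <- n + 1L
    if (la >= seed_len) {
      full <- regexpr(adapter, s, fixed = TRUE)
      if (full > 0L) cut <- as.integer(full)
      # partial adapter running off the read's 3' end
      p_lo <- max(n - la + 2L, 1L)
      p_hi <- n - seed_len + 1L
      if (p_hi >= p_lo) {
        for (p in p_lo:p_hi) {
          if (p >= cut) break
          k <- n - p + 1L
          if (substr(s, p, n) == substr(adapter, 1L, k)) { cut <- p; break }
        }
      }
    }
    s <- substr(s, 1L, cut - 1L)
    sub("N+$", "", s)
  }
  reads$seq <- vapply(reads$seq, trim_one, character(1), USE.NAMES = FALSE)
  reads[nchar(reads$seq) >= min_len, ]
}

#' Write alignment records as SAM
#'
#' Minimal single-end dialect: `@HD`/`@SQ` header, FLAG bits 0x10 (reverse
#' strand) and 0x400 (duplicate), ungapped CIGAR, `NM` tag. Wrapping
#' alignments are written at their doubled-frame position reduced modulo
#' the reference length (POS stays within the reference).
#'
#' @param records Alignment tibble.
#' @param reads Read tibble (`read_id`, `seq`) supplying SEQ fields.
#' @param genomes The reference [circ_seq()] list used for the header.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, reads, genomes, path) {
  if (inherits(genomes, "circ_seq")) genomes <- list(genomes)
  reads <- as_read_tbl(reads)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(genomes, function(g)
             sprintf("@SQ\tSN:%s\tLN:%d", g$id, nchar(g$seq)), character(1)))
  seq_of <- stats::setNames(reads$seq, reads$read_id)
  len_of <- stats::setNames(
    vapply(genomes, function(g) nchar(g$seq), integer(1)),
    vapply(genomes, function(g) g$id, character(1)))
  body <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    flag <- 0L
    if (r$strand == "-") flag <- flag + 16L
    if (isTRUE(r$duplicate)) flag <- flag + 1024L
    s <- seq_of[[r$read_id]]
    if (r$strand == "-") s <- revcomp(s)
    pos <- ((r$start - 1L) %% len_of[[r$ref_id]]) + 1L
    body[i] <- paste(r$read_id, flag, r$ref_id, pos, r$mapq,
                     paste0(r$length, "M"), "*", 0L, 0L, s,
                     strrep("I", r$length), paste0("NM:i:", r$mismatches),
                     sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
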