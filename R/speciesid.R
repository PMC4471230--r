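# fast perfect-match test: does `seq` (or its reverse complement) occur in
# the (doubled, for circular) reference? This is the mapping module's
# "perfect" schedule specialised to presence/absence.
has_perfect_match <- function(seqs, genome) {
  hay <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq
  fwd <- vapply(seqs, function(s) grepl(s, hay, fixed = TRUE), logical(1),
                USE.NAMES = FALSE)
  rev <- vapply(revcomp(seqs), function(s) grepl(s, hay, fixed = TRUE),
                logical(1), USE.NAMES = FALSE)
  fwd | rev
}

#' Competitive species assignment of a read set
#'
#' Screens the reads against every candidate reference under the strictest
#' condition — a perfect ungapped match of minimum length `min_len` on
#' either strand — and counts, per genome, the reads with at least one such
#' placement. The pairwise overlap matrix counts reads matching both
#' genomes of a pair; reads of an ancient extract that match a related
#' species almost always fall in windows where that species is locally
#' identical to the true source. The assigned label is the genome with the
#' maximal count, flagged ambiguous when the runner-up exceeds half the
#' maximum.
#'
#' @param reads Read tibble (`read_id`, `seq`) or named character vector.
#' @param genomes List of candidate [circ_seq()] references (>= 2).
#' @param min_len Minimum read length for the screen (nt, default 30).
#' @return A `competitive_report`: list with `counts` (tibble `genome`,
#'   `n_reads`), `overlap` (named matrix), `label`, `ambiguous`,
#'   `threshold`, and `hits` (logical read-by-genome matrix).
#' @export
competitive_counts <- function(reads, genomes, min_len = 30L) {
  if (inherits(genomes, "circ_seq")) genomes <- list(genomes)
  if (length(genomes) < 2L) stop("need at least two candidate genomes",
                                 call. = FALSE)
  reads <- as_read_tbl(reads)
  reads <- reads[nchar(reads$seq) >= min_len, ]
  ids <- vapply(genomes, function(g) g$id, character(1))
  hits <- matrix(FALSE, nrow = nrow(reads), ncol = length(genomes),
                 dimnames = list(reads$read_id, ids))
  for (k in seq_along(genomes)) {
    if (nrow(reads) > 0L) hits[, k] <- has_perfect_match(reads$seq, genomes[[k]])
  }
  counts <- colSums(hits)
  overlap <- t(hits) %*% hits
  label <- NA_character_; ambiguous <- TRUE
  if (any(counts > 0)) {
    ord <- order(counts, decreasing = TRUE)
    label <- ids[ord[1]]
    runner <- if (length(counts) > 1L) counts[ord[2]] else 0
    ambiguous <- runner > 0.5 * counts[ord[1]]
  }
  structure(list(
    counts = tibble::tibble(genome = ids, n_reads = as.integer(counts)),
    overlap = overlap, label = label, ambiguous = ambiguous,
    threshold = as.integer(min_len), hits = hits
  ), class = "competitive_report")
}

#' @export
print.competitive_report <- function(x, ...) {
  cat(sprintf("<competitive_report> label: %s%s (min length %d nt)\n",
              x$label, if (x$ambiguous) " [ambiguous]" else "",
              x$threshold))
  print(x$counts)
  invisible(x)
}

#' Classify a cloned PCR sequence against labelled amplicons
#'
#' Ungapped Hamming comparison of a primer-trimmed clone against each
#' reference amplicon of the same length; the label with the minimum
#' distance wins, ties are reported as ambiguous.
#'
#' @param clone Clone sequence (character scalar).
#' @param amplicons Named character vector of reference amplicon sequences.
#' @return A list: `label` (`"ambiguous"` on a tie), `distances` (named
#'   integer vector).
#' @export
classify_clone <- function(clone, amplicons) {
  stopifnot(length(clone) == 1L, length(amplicons) >= 1L,
            !is.null(names(amplicons)))
  if (any(nchar(amplicons) != nchar(clone))) {
    stop("clone and amplicons must be the same length (ungapped comparison)",
         call. = FALSE)
  }
  cb <- strsplit(clone, "")[[1]]
  d <- vapply(amplicons,
              function(a) sum(strsplit(a, "")[[1]] != cb), integer(1))
  best <- which(d == min(d))
  list(label = if (length(best) > 1L) "ambiguous" else names(d)[best],
       distances = d)
}

#' Primer pair
#'
#' @param forward,reverse Primer sequences, both given 5'->3'; the reverse
#'   primer is matched as its reverse complement on the forward strand.
#' @param max_mismatch Mismatch tolerance per primer site.
#' @return A `primer_pair` list.
#' @export
primer_pair <- function(forward, reverse, max_mismatch = 1L) {
  stopifnot(nchar(forward) >= 10L, nchar(reverse) >= 10L, max_mismatch >= 0L)
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

# all start positions (1..L, circular wrap) where `pat` matches within
# `max_mm` mismatches on the forward strand of `genome`
match_sites <- function(pat, genome, max_mm) {
  L <- nchar(genome$seq)
  m <- nchar(pat)
  hay <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq
  n_starts <- if (genome$circular) L else L - m + 1L
  if (n_starts < 1L) return(integer(0))
  mm <- scan_hamming(encode_ref(hay), encode_read(pat), n_starts)
  which(mm <= max_mm)
}

#' In-silico PCR: locate the amplicon a primer pair produces
#'
#' Finds forward-primer sites on the forward strand and reverse-primer
#' sites (as reverse complement) downstream, allowing up to
#' `primers$max_mismatch` mismatches per site; fails distinctly when no
#' product or multiple products are possible.
#'
#' @param genome A [circ_seq()].
#' @param primers A [primer_pair()].
#' @param max_product Longest product considered (nt, default 2000).
#' @return A list: `start`, `end` (1-based product bounds including
#'   primers; `end` may exceed the genome length for wrapping products),
#'   `insert` (sequence between, excluding, the primers), `product_length`.
#' @export
locate_amplicon <- function(genome, primers, max_product = 2000L) {
  stopifnot(inherits(primers, "primer_pair"))
  L <- nchar(genome$seq)
  f_sites <- match_sites(primers$forward, genome, primers$max_mismatch)
  r_sites <- match_sites(revcomp(primers$reverse), genome,
                         primers$max_mismatch)
  lf <- nchar(primers$forward); lr <- nchar(primers$reverse)
  products <- list()
  for (f in f_sites) {
    for (r in r_sites) {
      r_adj <- if (genome$circular && r < f) r + L else r
      p_len <- r_adj + lr - f
      if (r_adj > f && p_len <= max_product) {
        products[[length(products) + 1L]] <-
          list(start = f, end = r_adj + lr - 1L, product_length = p_len,
               insert_start = f + lf, insert_len = r_adj - f - lf)
      }
    }
  }
  if (length(products) == 0L) {
    stop("no product: primer sites absent or not convergent", call. = FALSE)
  }
  if (length(products) > 1L) {
    stop("multiple products: ", length(products),
         " primer-site combinations", call. = FALSE)
  }
  p <- products[[1]]
  insert <- if (p$insert_len > 0L)
    cs_subseq(genome, ((p$insert_start - 1L) %% L) + 1L, p$insert_len)
  else ""
  list(start = p$start, end = p$end, insert = insert,
       product_length = p$product_length)
}

#' Fold coverage of a target from total aligned bases
#'
#' @param total_aligned_bases Sum of aligned read lengths (nt).
#' @param target_len Target sequence length (nt).
#' @param copies Copy number of the target in the genome (default 1); the
#'   per-copy depth `depth / copies` converts a multi-copy read depth to a
#'   single-copy estimate.
#' @return A list: `depth` (= bases / (len * copies) scaled to the target
#'   as a whole, i.e. bases/len), `per_copy` (= depth / copies).
#' @export
fold_coverage <- function(total_aligned_bases, target_len, copies = 1L) {
  stopifnot(target_len > 0, copies >= 1L, total_aligned_bases >= 0)
  depth <- total_aligned_bases / target_len
  list(depth = depth, per_copy = depth / copies)
}

#' @rdname fold_coverage
#' @param depth A read depth measured over all copies of a multi-copy
#'   target.
#' @export
per_copy_depth <- function(depth, copies) {
  stopifnot(copies >= 1L)
  depth / copies
}

#' Read a primer table (TSV: name, forward, reverse)
#'
#' @param path TSV file with columns `name`, `forward`, `reverse`.
#' @param max_mismatch Mismatch tolerance applied to every pair.
#' @return A named list of [primer_pair()] objects.
#' @export
read_primer_tsv <- function(path, max_mismatch = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "forward", "reverse") %in% names(tab)))
  stats::setNames(
    lapply(seq_len(nrow(tab)), function(i)
      primer_pair(tab$forward[i], tab$reverse[i], max_mismatch)),
    tab$name)
}
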