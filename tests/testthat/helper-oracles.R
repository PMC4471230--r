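# Independent oracles, deliberately naive: plain-R sliding-window search,
# a small Gotoh DP aligner, and fixture builders. None of these share code
# with the package internals they check.

rand_genome <- function(n, seed, id = "toy", circular = TRUE) {
  set.seed(seed)
  circ_seq(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = ""), id = id, circular = circular)
}

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# brute-force ungapped search: every window of the doubled sequence, both
# strands, character-by-character comparison with N always mismatching
brute_map <- function(read, genome, bound) {
  L <- nchar(genome$seq)
  m <- nchar(read)
  hay <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq
  n_starts <- if (genome$circular) L else L - m + 1L
  out <- list()
  if (m > L || n_starts < 1) return(data.frame())
  for (strand in c("+", "-")) {
    q <- strsplit(if (strand == "+") read else rc_chr(read), "")[[1]]
    for (s in seq_len(n_starts)) {
      w <- strsplit(substr(hay, s, s + m - 1L), "")[[1]]
      mm <- sum(w != q | w == "N" | q == "N")
      if (mm <= bound) {
        out[[length(out) + 1L]] <- data.frame(start = s, strand = strand,
                                              mismatches = mm)
      }
    }
  }
  do.call(rbind, out)
}

# Gotoh global alignment with free end gaps: match +1, mismatch -1,
# gap open -4 (first gap base costs -5), extend -1. Returns the aligned
# strings. Traceback prefers diagonal, then gap-in-b, then gap-in-a.
oracle_align <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # end in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  X[(2):(n + 1), 1] <- 0  # free end gaps
  Y[1, (2):(m + 1)] <- 0
  go <- -4; ge <- -1
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + go + ge, X[i - 1, j] + ge)
      Y[i, j] <- max(M[i, j - 1] + go + ge, Y[i, j - 1] + ge)
    }
  }
  # free end gaps: best cell on last row/column
  ends <- rbind(
    cbind(n + 1, seq_len(m + 1)),
    cbind(seq_len(n + 1), m + 1))
  sc <- apply(ends, 1, function(ij) max(M[ij[1], ij[2]], X[ij[1], ij[2]],
                                        Y[ij[1], ij[2]]))
  bi <- ends[which.max(sc), 1]; bj <- ends[which.max(sc), 2]
  out_a <- character(0); out_b <- character(0)
  # unaligned tails
  ta <- if (bi <= n) av[bi:n] else character(0)
  tb <- if (bj <= m) bv[bj:m] else character(0)
  i <- bi; j <- bj
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  while (i > 1 || j > 1) {
    if ((i == 1 || j == 1) ||
          (state == "M" && M[i, j] == 0 && i + j == 2)) break
    if (state == "M" && i > 1 && j > 1) {
      s <- if (av[i - 1] == bv[j - 1]) 1 else -1
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state_next <- c("M", "X", "Y")[which.max(prev)]
      out_a <- c(av[i - 1], out_a); out_b <- c(bv[j - 1], out_b)
      i <- i - 1; j <- j - 1; state <- state_next
    } else if (state == "X" && i > 1) {
      from_open <- M[i - 1, j] + (-4) + (-1)
      out_a <- c(av[i - 1], out_a); out_b <- c("-", out_b)
      state <- if (X[i, j] == from_open) "M" else "X"
      i <- i - 1
    } else if (state == "Y" && j > 1) {
      from_open <- M[i, j - 1] + (-4) + (-1)
      out_a <- c("-", out_a); out_b <- c(bv[j - 1], out_b)
      state <- if (Y[i, j] == from_open) "M" else "Y"
      j <- j - 1
    } else break
  }
  # unaligned heads
  ha <- if (i > 1) av[1:(i - 1)] else character(0)
  hb <- if (j > 1) bv[1:(j - 1)] else character(0)
  list(
    a = paste(c(ha, rep("-", length(hb)), out_a, ta,
                rep("-", length(tb))), collapse = ""),
    b = paste(c(rep("-", length(ha)), hb, out_b,
                rep("-", length(ta)), tb), collapse = ""))
}

# difference records read off an oracle alignment (positions on a's frame)
oracle_diffs <- function(a, b) {
  al <- oracle_align(a, b)
  av <- strsplit(al$a, "")[[1]]; bv <- strsplit(al$b, "")[[1]]
  apos <- cumsum(av != "-")
  recs <- list()
  i <- 1
  while (i <= length(av)) {
    if (av[i] != "-" && bv[i] != "-") {
      if (av[i] != bv[i]) {
        recs[[length(recs) + 1]] <- data.frame(
          position = apos[i], kind = "substitution",
          base_a = av[i], base_b = bv[i])
      }
      i <- i + 1
    } else if (av[i] == "-") {
      j <- i
      while (j < length(av) && av[j + 1] == "-") j <- j + 1
      recs[[length(recs) + 1]] <- data.frame(
        position = apos[i], kind = "insertion", base_a = "-",
        base_b = paste(bv[i:j], collapse = ""))
      i <- j + 1
    } else {
      j <- i
      while (j < length(av) && bv[j + 1] == "-") j <- j + 1
      recs[[length(recs) + 1]] <- data.frame(
        position = apos[i], kind = "deletion",
        base_a = paste(av[i:j], collapse = ""), base_b = "-")
      i <- j + 1
    }
  }
  do.call(rbind, recs)
}

make_reads <- function(seqs) {
  tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)), seq = seqs)
}
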