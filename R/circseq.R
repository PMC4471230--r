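#' Circular (or linear) nucleotide sequence with optional feature annotation
#'
#' `circ_seq()` is the light container every coordinate in this package
#' refers to: a single uppercase nucleotide string, a circularity flag and an
#' optional feature table. Mitochondrial genomes are circular; PCR amplicons
#' and nuclear fragments are linear.
#'
#' @param seq Character scalar of nucleotides (case-insensitive; stored
#'   uppercase). Only `A`, `C`, `G`, `T`, `N` are allowed.
#' @param id Sequence identifier.
#' @param circular Logical; wrap-around coordinates permitted when `TRUE`.
#' @param features Optional feature table: a tibble with columns `name`,
#'   `type` (one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"D-loop"`), `start`, `end`
#'   (1-based inclusive), `strand` (`"+"`/`"-"`).
#' @return An object of class `circ_seq`.
#' @export
circ_seq <- function(seq, id = "seq", circular = TRUE, features = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains symbols outside ACGTN", call. = FALSE)
  }
  if (!is.null(features)) features <- validate_features(features, nchar(seq))
  structure(
    list(id = as.character(id), seq = seq, circular = isTRUE(circular),
         features = features),
    class = "circ_seq"
  )
}

validate_features <- function(features, genome_len) {
  features <- tibble::as_tibble(features)
  needed <- c("name", "type", "start", "end", "strand")
  missing <- setdiff(needed, names(features))
  if (length(missing) > 0L) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(features$start < 1L | features$end > genome_len |
            features$start > features$end)) {
    stop("feature coordinates outside [1, genome length]", call. = FALSE)
  }
  features
}

#' @export
print.circ_seq <- function(x, ...) {
  cat(sprintf("<circ_seq> %s: %s nt, %s%s\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) "circular" else "linear",
              if (is.null(x$features)) "" else
                sprintf(", %d features", nrow(x$features))))
  invisible(x)
}

#' @export
length.circ_seq <- function(x) nchar(x$seq)

#' Extract a (possibly wrapping) subsequence
#'
#' 1-based inclusive coordinates. On a circular sequence the window may wrap
#' past the end; on a linear one wrapping is an error.
#'
#' @param x A [circ_seq()].
#' @param start 1-based start position.
#' @param len Window length.
#' @return Character scalar.
#' @export
cs_subseq <- function(x, start, len) {
  n <- nchar(x$seq)
  stopifnot(start >= 1L, start <= n, len >= 1L)
  end <- start + len - 1L
  if (end <= n) return(substr(x$seq, start, end))
  if (!x$circular) stop("window extends past the end of a linear sequence",
                        call. = FALSE)
  if (len > n) stop("window longer than the sequence", call. = FALSE)
  paste0(substr(x$seq, start, n), substr(x$seq, 1L, end - n))
}

#' Reverse complement
#'
#' Vectorised over a character vector of ACGTN strings.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(chartr("ACGTN", "TGCAN", x),
         function(s) rawToChar(rev(charToRaw(s))),
         character(1), USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Read genomes from a FASTA file
#'
#' @param path FASTA file.
#' @param circular Circularity flag applied to every record.
#' @return A list of [circ_seq()] objects, named by record id.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    circ_seq(as.character(ss[[i]]), id = names(ss)[i], circular = circular)
  })
  stats::setNames(out, names(ss))
}

#' Write genomes to a FASTA file
#'
#' @param genomes A `circ_seq` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "circ_seq")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$seq, character(1)))
  names(ss) <- vapply(genomes, function(g) g$id, character(1))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a read set from FASTA/FASTQ
#'
#' Qualities are discarded: the downstream consensus machinery is
#' quality-agnostic (evidence is counted per unique placement).
#'
#' @param path Input file.
#' @param format `"fastq"` or `"fasta"` (guessed from the extension by default).
#' @return A tibble with columns `read_id`, `seq`.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format)
  tibble::tibble(read_id = names(ss), seq = as.character(ss))
}

#' Write reads as FASTQ (Sanger Phred+33)
#'
#' Base qualities are written as constant Phred 37; they carry no
#' information downstream.
#'
#' @param reads Tibble with `read_id`, `seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq),
                 function(n) strrep(rawToChar(as.raw(37L + 33L)), n),
                 character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Feature table IO (TSV)
#'
#' Plain tab-separated feature tables with columns `name`, `type`, `start`,
#' `end`, `strand` and optionally `intergenic_nt` (negative values denote
#' overlap with the previous feature).
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_feature_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_feature_tsv
#' @param features Feature tibble to write.
#' @export
write_feature_tsv <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
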