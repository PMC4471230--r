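#' Transfer feature annotations onto a new genome through global alignment
#'
#' Aligns the annotated reference to the target and maps each feature
#' boundary through the alignment. A boundary falling in a target gap snaps
#' to the nearest aligned target position — starts snap rightwards, ends
#' leftwards — so a feature is never extended into unaligned territory. A
#' feature whose span is entirely deleted in the target is reported with
#' `NA` coordinates and `status = "deleted"` rather than silently dropped.
#'
#' @param target [circ_seq()] to annotate.
#' @param annotated_ref [circ_seq()] carrying a feature table.
#' @param features Feature tibble (defaults to `annotated_ref$features`).
#' @return Feature tibble on target coordinates with added columns
#'   `ref_start`, `ref_end`, `length_changed`, `status`
#'   (`"lifted"`/`"deleted"`) and recomputed `intergenic_nt` (signed gap to
#'   the previous feature; negative = overlap).
#' @export
lift_annotations <- function(target, annotated_ref,
                             features = annotated_ref$features) {
  stopifnot(!is.null(features))
  al <- align_global(annotated_ref$seq, target$seq)
  rv <- al$a; tv <- al$b
  rpos <- cumsum(rv != "-")
  tpos <- cumsum(tv != "-")
  # map: for each reference position, the aligned target position (NA in gaps)
  map <- rep(NA_integer_, nchar(annotated_ref$seq))
  both <- rv != "-" & tv != "-"
  map[rpos[both]] <- tpos[both]

  n <- nrow(features)
  new_start <- integer(n); new_end <- integer(n)
  status <- character(n)
  for (i in seq_len(n)) {
    s <- features$start[i]; e <- features$end[i]
    # start snaps right, end snaps left, within the feature's own span
    cand_s <- map[s:e]; cand_e <- map[e:s]
    ns <- cand_s[!is.na(cand_s)][1]
    ne <- cand_e[!is.na(cand_e)][1]
    if (is.na(ns) || is.na(ne) || ns > ne) {
      new_start[i] <- NA_integer_; new_end[i] <- NA_integer_
      status[i] <- "deleted"
    } else {
      new_start[i] <- ns; new_end[i] <- ne
      status[i] <- "lifted"
    }
  }
  out <- features
  out$ref_start <- features$start
  out$ref_end <- features$end
  out$start <- new_start
  out$end <- new_end
  out$length_changed <- !is.na(new_start) &
    (new_end - new_start) != (out$ref_end - out$ref_start)
  out$status <- status
  # signed intergenic distance to the previous lifted feature
  out$intergenic_nt <- NA_integer_
  prev_end <- NA_integer_
  ord <- order(out$ref_start)
  for (i in ord) {
    if (is.na(out$start[i])) next
    if (!is.na(prev_end)) out$intergenic_nt[i] <- out$start[i] - prev_end - 1L
    prev_end <- out$end[i]
  }
  out
}

MITO_START_CODONS <- c("ATG", "ATA", "ATT", "GTG")
MITO_STOP_CODONS <- c("TAA", "TAG", "AGA", "AGG")

extract_feature_seq <- function(feature, genome) {
  len <- feature$end - feature$start + 1L
  s <- cs_subseq(genome, feature$start, len)
  if (feature$strand == "-") s <- revcomp(s)
  s
}

#' Validate a coding sequence under the vertebrate mitochondrial code
#'
#' Checks an admissible start codon (`ATG`/`ATA`/`ATT`/`GTG`), a complete
#' terminal stop (`TAA`/`TAG`/`AGA`/`AGG`) or an incomplete one (`T`/`TA`,
#' completed by polyadenylation of the transcript — flagged, not failed),
#' and the absence of internal stop codons. Mitochondrial CDS routinely end
#' on incomplete stops; `AGA`/`AGG` are stops in this code, not arginine.
#'
#' @param feature One row of a feature tibble with `type == "CDS"`.
#' @param genome The [circ_seq()] carrying the CDS.
#' @param start_codons,stop_codons Admissible sets (mammalian conventions
#'   by default).
#' @return A one-row tibble: `name`, `pass`, `start_ok`, `stop_ok`,
#'   `incomplete_stop`, `n_internal_stops`, `reason`.
#' @export
validate_cds <- function(feature, genome,
                         start_codons = MITO_START_CODONS,
                         stop_codons = MITO_STOP_CODONS) {
  stopifnot(feature$type == "CDS")
  if (feature$end > nchar(genome$seq) && !genome$circular) {
    stop("feature out of bounds", call. = FALSE)
  }
  s <- extract_feature_seq(feature, genome)
  n <- nchar(s)
  reasons <- character(0)
  start_ok <- substr(s, 1L, 3L) %in% start_codons
  if (!start_ok) reasons <- c(reasons, sprintf("start codon %s not admissible",
                                               substr(s, 1L, 3L)))
  rem <- n %% 3L
  incomplete <- FALSE
  if (rem == 0L) {
    term <- substr(s, n - 2L, n)
    stop_ok <- term %in% stop_codons
    n_codons_body <- n / 3L - 1L # exclude terminal stop from internal scan
    if (!stop_ok) {
      n_codons_body <- n / 3L    # no terminal stop: scan everything
      reasons <- c(reasons, sprintf("terminal codon %s is not a stop", term))
    }
  } else if (rem == 1L && substr(s, n, n) == "T") {
    stop_ok <- TRUE; incomplete <- TRUE
    n_codons_body <- (n - 1L) / 3L
  } else if (rem == 2L && substr(s, n - 1L, n) == "TA") {
    stop_ok <- TRUE; incomplete <- TRUE
    n_codons_body <- (n - 2L) / 3L
  } else {
    stop_ok <- FALSE
    n_codons_body <- floor(n / 3L)
    reasons <- c(reasons, "length not a codon multiple and trailing bases are
                 not an incomplete stop (T/TA)")
  }
  internal <- 0L
  if (n_codons_body >= 2L) {
    starts <- seq(4L, by = 3L, length.out = n_codons_body - 1L)
    codons <- substring(s, starts, starts + 2L)
    internal <- sum(codons %in% MITO_STOP_CODONS)
    if (internal > 0L) reasons <- c(reasons,
                                    sprintf("%d internal stop codon(s)",
                                            internal))
  }
  tibble::tibble(name = feature$name,
                 pass = start_ok && stop_ok && internal == 0L,
                 start_ok = start_ok, stop_ok = stop_ok,
                 incomplete_stop = incomplete,
                 n_internal_stops = internal,
                 reason = if (length(reasons) == 0L) NA_character_
                          else paste(reasons, collapse = "; "))
}

#' Validate every CDS of a feature table
#'
#' @param features Feature tibble.
#' @param genome The carrying [circ_seq()].
#' @inheritParams validate_cds
#' @return A tibble with one row per CDS (see [validate_cds()]).
#' @export
validate_all_cds <- function(features, genome,
                             start_codons = MITO_START_CODONS,
                             stop_codons = MITO_STOP_CODONS) {
  cds <- features[features$type == "CDS", ]
  dplyr::bind_rows(lapply(seq_len(nrow(cds)), function(i)
    validate_cds(cds[i, ], genome, start_codons, stop_codons)))
}

#' Count features by type
#'
#' A complete vertebrate mitochondrial genome carries 13 protein-coding
#' genes, 22 tRNAs, 2 rRNAs and the control region (D-loop). Wrap-around
#' features split into two table rows are counted once (by distinct name).
#'
#' @param features Feature tibble.
#' @return A tibble `type`, `n`.
#' @export
genome_content_summary <- function(features) {
  if (nrow(features) == 0L) {
    return(tibble::tibble(type = c("CDS", "tRNA", "rRNA", "D-loop"),
                          n = 0L))
  }
  d <- dplyr::distinct(features, .data$name, .data$type)
  out <- dplyr::count(d, .data$type, name = "n")
  missing <- setdiff(c("CDS", "tRNA", "rRNA", "D-loop"), out$type)
  dplyr::bind_rows(out, tibble::tibble(type = missing, n = 0L))
}
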