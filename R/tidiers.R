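#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an assembly into its per-position call table
#'
#' @param x A `mito_assembly` from [assemble()].
#' @param ... Unused.
#' @return A tibble with one row per consensus position (`pos`, `base`,
#'   `status`, `depth`, `n_major`, `n_minor`).
#' @method tidy mito_assembly
#' @export
tidy.mito_assembly <- function(x, ...) x$calls

#' One-row assembly summary
#'
#' @param x A `mito_assembly` from [assemble()].
#' @param ... Unused.
#' @return A one-row tibble: consensus length, call-status counts, unique
#'   read and PCR fragment counts, mean fold coverage.
#' @method glance mito_assembly
#' @export
glance.mito_assembly <- function(x, ...) {
  cov <- coverage_stats(x)
  st <- x$rounds$round3
  tibble::tibble(
    consensus_length = length(x$consensus),
    n_called = st$n_called,
    n_resolved_damage = st$n_resolved_damage,
    n_zero_coverage = st$n_zero_coverage,
    n_single_evidence = st$n_single_evidence,
    n_flagged = st$n_flagged,
    n_unique_reads = cov$n_unique_reads,
    n_pcr_fragments = cov$n_pcr_fragments,
    mean_fold_coverage = cov$mean_fold_coverage)
}

#' Tidy a damage profile (drops the attribute payload)
#'
#' @param x A [damage_profile()].
#' @param ... Unused.
#' @return The profile as a plain tibble.
#' @method tidy damage_profile
#' @export
tidy.damage_profile <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "damage_profile")
  out
}

#' One-row damage-profile summary
#'
#' @param x A [damage_profile()].
#' @param ... Unused.
#' @return A one-row tibble: totals, identity, and the terminal C>T / G>A
#'   frequencies.
#' @method glance damage_profile
#' @export
glance.damage_profile <- function(x, ...) {
  t5 <- x$frequency[x$sub == "C>T" & x$end == "5p" & x$offset == 0L]
  t3 <- x$frequency[x$sub == "G>A" & x$end == "3p" & x$offset == 0L]
  tibble::tibble(
    total_mismatches = attr(x, "total_mismatches"),
    total_aligned_bases = attr(x, "total_aligned_bases"),
    percent_identity = profile_identity(x),
    ct_5p_terminal = t5,
    ga_3p_terminal = t3)
}
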