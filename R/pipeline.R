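#' Pipeline configuration
#'
#' Bundles every stage parameter with defaults equal to the workflow's
#' canonical settings: 20-nt minimum read length after trimming, 30-nt
#' minimum for the perfect-match species screen, mapping quality >= 25 and
#' >= 2 concordant evidences for a consensus call, 25% discordance
#' threshold, absolute-2 then fraction-0.1 mapping schedules. In
#' `mode = "simulate"` the reference, reads, PCR evidence, candidate
#' genomes and placement panel are all generated from the synthetic study
#' generator under `seed`; in `mode = "files"` they are read from the
#' given paths.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param seed Global integer seed.
#' @param n_reads Number of simulated reads.
#' @param frag A [fragment_model()].
#' @param dmg A [damage_model()].
#' @param min_len Minimum read length (nt).
#' @param species_min_len Minimum read length for the species screen (nt).
#' @param adapter Adapter sequence trimmed from file-based reads.
#' @param policy A [consensus_policy()].
#' @param bootstrap_reps Bootstrap replicates for the placement stage
#'   (0 disables the stage's support values).
#' @param ref_fasta,reads_fastq,candidate_fastas,pcr_fasta,annotation_tsv
#'   Input paths for `mode = "files"` (candidates optional).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            seed = 1L,
                            n_reads = 3851L,
                            frag = fragment_model(),
                            dmg = damage_model(),
                            min_len = 20L,
                            species_min_len = 30L,
                            adapter = "AGATCGGAAGAGC",
                            policy = consensus_policy(),
                            bootstrap_reps = 200L,
                            ref_fasta = NULL, reads_fastq = NULL,
                            candidate_fastas = NULL, pcr_fasta = NULL,
                            annotation_tsv = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, seed = as.integer(seed),
                 n_reads = as.integer(n_reads), frag = frag, dmg = dmg,
                 min_len = as.integer(min_len),
                 species_min_len = as.integer(species_min_len),
                 adapter = adapter, policy = policy,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 ref_fasta = ref_fasta, reads_fastq = reads_fastq,
                 candidate_fastas = candidate_fastas,
                 pcr_fasta = pcr_fasta, annotation_tsv = annotation_tsv),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration (JSON)
#'
#' @param config A [pipeline_config()].
#' @param path JSON file.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- unclass(config)
  flat$frag <- unclass(config$frag)
  flat$dmg <- unclass(config$dmg)
  flat$policy <- unclass(config$policy)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    mode = x$mode, seed = x$seed, n_reads = x$n_reads,
    frag = fragment_model(x$frag$min_len, x$frag$max_len,
                          length_weights = x$frag$length_weights),
    dmg = damage_model(x$dmg$delta5, x$dmg$delta3, x$dmg$decay,
                       x$dmg$seq_error),
    min_len = x$min_len, species_min_len = x$species_min_len,
    adapter = x$adapter,
    policy = consensus_policy(x$policy$min_evidence, x$policy$min_mapq,
                              x$policy$discordance_threshold,
                              x$policy$damage_window),
    bootstrap_reps = x$bootstrap_reps,
    ref_fasta = x$ref_fasta, reads_fastq = x$reads_fastq,
    candidate_fastas = x$candidate_fastas, pcr_fasta = x$pcr_fasta,
    annotation_tsv = x$annotation_tsv)
}

mutate_relative <- function(ref, n_subs, id, seed) {
  set.seed(as.integer(seed))
  b <- strsplit(ref$seq, "")[[1]]
  pos <- sample.int(length(b), n_subs)
  for (p in pos) {
    b[p] <- if (stats::runif(1) < 0.9) TRANSITION[[b[p]]]
      else sample(setdiff(c("A", "C", "G", "T"),
                          c(b[p], TRANSITION[[b[p]]])), 1L)
  }
  circ_seq(paste(b, collapse = ""), id = id, circular = ref$circular)
}

#' Run the full reconstruction workflow
#'
#' Simulate (or load) ancient reads; screen them competitively against the
#' candidate references; assemble the mitogenome iteratively against the
#' best-matching reference; design and integrate PCR evidence for problem
#' positions; verify the consensus fixed point; profile terminal damage;
#' compare the consensus to the reference and classify every difference;
#' lift the annotation onto the consensus and validate all coding
#' sequences; and place the consensus phylogenetically. All artifacts are
#' written under `out_dir`; the machine-readable summary is returned and
#' saved as JSON.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return The summary list (invisibly), also serialised to
#'   `summary.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  log_msg <- function(...) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  # --- inputs
  if (config$mode == "simulate") {
    log_msg("simulating study data (seed %d)", seed)
    ref <- synthetic_mitogenome(seed = seed)
    planted <- plant_study_profile(ref, seed = seed + 1L, indels = FALSE)
    source_genome <- planted$genome
    sim <- simulate_reads(source_genome, config$n_reads, config$frag,
                          config$dmg, seed = seed + 2L)
    reads <- sim$reads
    # relatives at ~4% / ~5% divergence (sister species), one distant
    # genome (~9%) playing the contamination-screen role
    candidates <- list(ref,
                       mutate_relative(ref, 650L, "relativeA", seed + 3L),
                       mutate_relative(ref, 800L, "relativeB", seed + 4L),
                       mutate_relative(ref, 1500L, "distant", seed + 5L))
    annotation <- ref$features
  } else {
    log_msg("loading inputs")
    ref <- read_genome_fasta(config$ref_fasta)[[1]]
    reads <- read_reads(config$reads_fastq)
    reads <- trim_reads(reads, config$adapter, config$min_len)
    candidates <- if (is.null(config$candidate_fastas)) list(ref) else
      c(list(ref), unlist(lapply(config$candidate_fastas, read_genome_fasta),
                          recursive = FALSE))
    annotation <- if (!is.null(config$annotation_tsv))
      read_feature_tsv(config$annotation_tsv) else ref$features
    ref$features <- annotation
  }
  reads <- reads[nchar(reads$seq) >= config$min_len, ]
  if (nrow(reads) == 0L) {
    stop("assembly aborted: no reads of length >= ", config$min_len,
         " available (every position would have zero coverage)",
         call. = FALSE)
  }
  summary <- list(seed = seed, n_reads_in = nrow(reads))

  # --- competitive species screen
  if (length(candidates) >= 2L) {
    log_msg("competitive species screen over %d genomes", length(candidates))
    screen <- competitive_counts(reads, candidates,
                                 min_len = config$species_min_len)
    summary$species <- list(
      label = screen$label, ambiguous = screen$ambiguous,
      counts = stats::setNames(as.list(screen$counts$n_reads),
                               screen$counts$genome))
    if (!is.null(out_dir)) {
      utils::write.table(screen$counts, file.path(out_dir, "species.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- iterative assembly + PCR evidence
  log_msg("assembling against %s", ref$id)
  asm <- assemble(reads, ref, pcr_sequences = NULL, policy = config$policy)
  problem <- sort(unique(c(asm$gaps, asm$single_evidence, asm$no_consensus)))
  summary$assembly_pre_pcr <- list(
    n_gap = length(asm$gaps), n_single = length(asm$single_evidence),
    n_no_consensus = length(asm$no_consensus))
  pcr <- NULL
  if (config$mode == "simulate" && length(problem) > 0L) {
    log_msg("designing PCR evidence for %d problem positions",
            length(problem))
    pcr <- design_pcr_evidence(source_genome, problem, flank = 25L)
  } else if (!is.null(config$pcr_fasta)) {
    pcr <- read_reads(config$pcr_fasta, format = "fasta")
  }
  if (!is.null(pcr) && nrow(pcr) > 0L) {
    asm <- integrate_pcr_evidence(asm, pcr)
  }
  cov <- coverage_stats(asm)
  fx <- verify_fixed_point(reads, asm$consensus, config$policy,
                           pcr_sequences = pcr)
  summary$assembly <- list(
    consensus_length = length(asm$consensus),
    n_gap = length(asm$gaps), n_single = length(asm$single_evidence),
    n_no_consensus = length(asm$no_consensus),
    n_resolved_damage = asm$rounds$round3$n_resolved_damage,
    n_unique_reads = cov$n_unique_reads,
    n_pcr_fragments = cov$n_pcr_fragments,
    mean_fold_coverage = cov$mean_fold_coverage,
    fixed_point = fx$fixed_point)
  if (config$mode == "simulate") {
    summary$assembly$n_consensus_errors <-
      sum(strsplit(asm$consensus$seq, "")[[1]] !=
            strsplit(source_genome$seq, "")[[1]])
  }

  # --- damage profile
  log_msg("profiling terminal misincorporations")
  prof <- damage_profile(asm$records, reads, asm$consensus, K = 10L)
  summary$damage <- list(
    total_mismatches = attr(prof, "total_mismatches"),
    total_aligned_bases = attr(prof, "total_aligned_bases"),
    percent_identity = profile_identity(prof))

  # --- genome comparison
  log_msg("classifying differences against %s", ref$id)
  diffs <- pairwise_differences(ref, asm$consensus)
  diffs <- classify_against_annotation(diffs, ref, annotation)
  dl <- region_rate_ratio(diffs, annotation, "D-loop", length(ref))
  summary$differences <- list(
    n_total = nrow(diffs),
    n_transitions = sum(diffs$ts_tv %in% "t"),
    n_transversions = sum(diffs$ts_tv %in% "v"),
    n_indels = sum(diffs$kind != "substitution"),
    n_dloop = dl$n_in, dloop_rate_ratio = dl$ratio,
    n_cds = sum(diffs$feature_type %in% "CDS"),
    codon_positions = as.list(table(factor(diffs$codon_position,
                                           levels = 1:3))),
    n_aa_changes = sum(diffs$effect %in% c("missense", "nonsense")))

  # --- annotation lift-over and CDS validation
  log_msg("lifting annotation and validating coding sequences")
  lifted <- lift_annotations(asm$consensus, ref, annotation)
  asm$consensus$features <- lifted[!is.na(lifted$start),
                                   c("name", "type", "start", "end",
                                     "strand")]
  cds_ok <- validate_all_cds(asm$consensus$features, asm$consensus)
  content <- genome_content_summary(asm$consensus$features)
  summary$annotation <- list(
    content = stats::setNames(as.list(content$n), content$type),
    n_cds_pass = sum(cds_ok$pass), n_cds = nrow(cds_ok))

  # --- phylogenetic placement
  log_msg("phylogenetic placement (%d bootstrap replicates)",
          config$bootstrap_reps)
  panel <- simulate_mito_panel(ref, seed = seed + 6L)
  panel["ancient"] <- asm$consensus$seq
  tree <- bootstrap_support(panel, n_reps = config$bootstrap_reps,
                            seed = seed + 7L)
  modern <- grep("^modern", names(panel), value = TRUE)
  summary$phylo <- list(
    # basal placement: the modern clade holds together without the
    # ancient genome, and ancient + moderns form a clade against the
    # outgroups (ancient is sister to, not inside, the modern clade)
    modern_clade_monophyletic = tips_form_clade(tree, modern),
    ancient_basal = tips_form_clade(tree, modern) &&
      tips_form_clade(tree, c("ancient", modern)),
    modern_clade_support = clade_support(tree, modern),
    bison_clade_support = clade_support(tree, c("ancient", modern)))

  # --- artifacts
  if (!is.null(out_dir)) {
    write_genome_fasta(asm$consensus, file.path(out_dir, "consensus.fasta"))
    utils::write.table(asm$calls, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gaps_iv <- positions_to_intervals(problem)
    utils::write.table(
      data.frame(chrom = asm$consensus$id, start = gaps_iv$start - 1L,
                 end = gaps_iv$end),
      file.path(out_dir, "verification.bed"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_damage_tsv(prof, file.path(out_dir, "damage.tsv"))
    write_diffs_tsv(diffs, file.path(out_dir, "differences.tsv"))
    write_feature_tsv(lifted, file.path(out_dir, "features.tsv"))
    ape::write.tree(tree, file.path(out_dir, "placement.nwk"))
    sam_rec <- asm$records
    sam_rec$ref_id <- asm$consensus$id # provisional and final share a frame
    write_sam(sam_rec, reads, list(asm$consensus),
              file.path(out_dir, "alignments.sam"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  log_msg("done")
  invisible(summary)
}
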