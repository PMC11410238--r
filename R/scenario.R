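# Study-level simulation scenario: a reference lineage plus two sister
# lineages that split recently from a common stem, echoing the design of a
# species-delineation study (sister pair ~7% diverged from the reference
# species, ~1% from each other, with introgression tracts, shared and
# private rearrangements, crosses and growth curves).

#' Configuration for the simulated delineation study
#'
#' Defaults define the package's standard study conditions: four 50-kb
#' chromosomes; stem branches at 3.25% per-site divergence and sister
#' branches at 0.5%, so the sister lineages land near 7% pairwise divergence
#' from the reference and ~1% from each other; three strains per lineage at
#' 0.2% within-lineage divergence; three donor tracts (7/5/3 kb); one shared
#' reciprocal translocation plus private rearrangements in lineage A; 30x
#' coverage; crosses and logistic growth curves per strain and condition.
#'
#' @param seed top-level integer seed; fully determines every output.
#' @param n_chromosomes,chrom_length,gc_content ancestor genome shape.
#' @param stem_divergence,split_divergence,sample_divergence per-branch
#'   substitution fractions (stem: ancestor to reference / to the sister
#'   stem; split: sister stem to each sister lineage; sample: lineage founder
#'   to each strain).
#' @param n_samples_per_lineage strains sampled per lineage.
#' @param introgression_tracts data.frame (`chrom`, `start`, `length`) of
#'   donor tracts implanted into the first lineage-A strain.
#' @param sv_events_shared,sv_events_a [sv_spec()] lists applied to both
#'   sister assemblies / to lineage A only.
#' @param mean_coverage,coverage_window read-coverage simulation.
#' @param cross_v0,cross_alpha,cross_n_spores viability model (see
#'   [simulate_cross()]).
#' @param growth_duration,growth_step,growth_noise_sd,growth_replicates
#'   growth-curve simulation.
#' @param conditions condition labels for phenotyping.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chrom_length = 50000L,
                       gc_content = 0.38,
                       stem_divergence = 0.0325,
                       split_divergence = 0.005,
                       sample_divergence = 0.002,
                       n_samples_per_lineage = 3L,
                       introgression_tracts = NULL,
                       sv_events_shared = NULL,
                       sv_events_a = NULL,
                       mean_coverage = 30,
                       coverage_window = 1000L,
                       cross_v0 = 95,
                       cross_alpha = 40,
                       cross_n_spores = 96L,
                       growth_duration = 48,
                       growth_step = 0.5,
                       growth_noise_sd = 0.01,
                       growth_replicates = 3L,
                       conditions = c("YNB_glucose", "glycerol", "glucose_NaCl",
                                      "maltose", "fructose", "sucrose",
                                      "galactose", "glucose_ethanol5")) {
  for (d in c(stem_divergence, split_divergence, sample_divergence))
    if (d < 0 || d > 0.25) stop_bad("divergences must lie in [0, 0.25]")
  if (!.is_count(chrom_length) || chrom_length <= 0 ||
      !.is_count(n_chromosomes) || n_chromosomes < 1)
    stop_bad("genome dimensions must be positive integers")
  if (!.is_count(n_samples_per_lineage) || n_samples_per_lineage < 2)
    stop_bad("need >= 2 samples per lineage (population statistics)")
  chroms <- paste0("chr", as.character(utils::as.roman(seq_len(n_chromosomes))))
  if (is.null(introgression_tracts)) {
    # 7/5/3 kb donor tracts on the first three chromosomes (or fewer)
    pick <- utils::head(chroms, 3L)
    sizes <- c(7000L, 5000L, 3000L)[seq_along(pick)]
    starts <- pmin(c(10000L, 20000L, 5000L)[seq_along(pick)],
                   chrom_length - sizes - 1L)
    introgression_tracts <- data.frame(chrom = pick, start = starts,
                                       length = sizes, donor = "reference",
                                       stringsAsFactors = FALSE)
  }
  for (ch in unique(introgression_tracts$chrom)) {
    tc <- introgression_tracts[introgression_tracts$chrom == ch, ]
    if (.intervals_overlap(tc$start, tc$length))
      stop_bad("introgression tracts overlap on %s", ch)
  }
  if (is.null(sv_events_shared) && n_chromosomes >= 4L) {
    sv_events_shared <- list(
      sv_spec("reciprocal_translocation", chrom_a = chroms[2L],
              chrom_b = chroms[4L], pos_a = as.integer(0.8 * chrom_length),
              pos_b = as.integer(0.7 * chrom_length)))
  }
  if (is.null(sv_events_a) && n_chromosomes >= 4L) {
    sv_events_a <- list(
      sv_spec("nonreciprocal_translocation", chrom_a = chroms[1L],
              chrom_b = chroms[2L], pos_a = as.integer(0.2 * chrom_length),
              size = as.integer(0.08 * chrom_length)),
      sv_spec("nonreciprocal_translocation", chrom_a = chroms[3L],
              chrom_b = chroms[1L], pos_a = as.integer(0.6 * chrom_length),
              size = as.integer(0.12 * chrom_length)),
      sv_spec("inversion", chrom_a = chroms[3L],
              pos_a = as.integer(0.2 * chrom_length),
              size = as.integer(0.2 * chrom_length)),
      sv_spec("deletion", chrom_a = chroms[4L],
              pos_a = as.integer(0.1 * chrom_length),
              size = as.integer(0.06 * chrom_length)))
  }
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chrom_length = as.integer(chrom_length),
                 gc_content = gc_content,
                 stem_divergence = stem_divergence,
                 split_divergence = split_divergence,
                 sample_divergence = sample_divergence,
                 n_samples_per_lineage = as.integer(n_samples_per_lineage),
                 introgression_tracts = introgression_tracts,
                 sv_events_shared = sv_events_shared %||% list(),
                 sv_events_a = sv_events_a %||% list(),
                 mean_coverage = mean_coverage,
                 coverage_window = as.integer(coverage_window),
                 cross_v0 = cross_v0, cross_alpha = cross_alpha,
                 cross_n_spores = as.integer(cross_n_spores),
                 growth_duration = growth_duration, growth_step = growth_step,
                 growth_noise_sd = growth_noise_sd,
                 growth_replicates = as.integer(growth_replicates),
                 conditions = conditions),
            class = "sim_config")
}

# deterministic gene tiling used as a stand-in annotation (synthetic; the
# simulator has no gene model)
.tile_genes <- function(genome, gene_length = 1200L, spacing = 800L) {
  rows <- lapply(names(genome), function(ch) {
    L <- nchar(genome[[ch]])
    starts <- seq.int(500L, L - gene_length, by = gene_length + spacing)
    if (length(starts) == 0L) return(NULL)
    data.frame(chrom = ch, start = starts + 1L, # 1-based inclusive
               end = starts + gene_length,
               id = sprintf("gene_%s_%03d", ch, seq_along(starts)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a gene table as GFF3
#'
#' @param genes data.frame `chrom`, `start`, `end` (1-based inclusive), `id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  writeLines(c("##gff-version 3",
               sprintf("%s\tintertaxon\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$chrom, genes$start, genes$end, genes$id)), path)
  invisible(path)
}

# multiplicative carrying-capacity effects per lineage x condition; the two
# sister lineages are handicapped on maltose/ethanol (and lineage B also on
# galactose), giving the phenotype module real group structure to find
.lineage_condition_effects <- function(conditions) {
  eff <- matrix(1, nrow = 3L, ncol = length(conditions),
                dimnames = list(c("REF", "A", "B"), conditions))
  if ("maltose" %in% conditions) eff[c("A", "B"), "maltose"] <- c(0.55, 0.50)
  if ("glucose_ethanol5" %in% conditions)
    eff[c("A", "B"), "glucose_ethanol5"] <- c(0.60, 0.60)
  if ("galactose" %in% conditions) eff["B", "galactose"] <- 0.60
  if ("glycerol" %in% conditions) eff[c("A", "B"), "glycerol"] <- c(0.90, 0.85)
  eff
}

#' Simulate a complete delineation study
#'
#' Generates the ancestor, the reference lineage and two sister lineages,
#' per-lineage strain samples, introgression tracts (reference donor into the
#' first lineage-A strain), rearranged "assembly" genomes, a coverage table,
#' a multi-sample variant table, tetrad crosses and growth curves — each with
#' its truth set.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study` with components `config`, `ancestor`,
#'   `founders`, `samples`, `populations`, `variants`, `introgression`,
#'   `assemblies`, `sv_truth`, `coverage`, `crosses`, `growth`, `genes`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  anc <- generate_ancestor(config$chrom_length, config$n_chromosomes,
                           config$gc_content, seed = seed)
  ref <- evolve_lineage(anc, config$stem_divergence,
                        seed = derive_seed(seed, "stem", 1L))$genome
  stem <- evolve_lineage(anc, config$stem_divergence,
                         seed = derive_seed(seed, "stem", 2L))$genome
  lin_a <- evolve_lineage(stem, config$split_divergence,
                          seed = derive_seed(seed, "split", 1L))$genome
  lin_b <- evolve_lineage(stem, config$split_divergence,
                          seed = derive_seed(seed, "split", 2L))$genome
  founders <- list(REF = ref, A = lin_a, B = lin_b)
  samples <- list(); populations <- character(0)
  for (lin in names(founders)) {
    for (i in seq_len(config$n_samples_per_lineage)) {
      nm <- sprintf("%s_%d", lin, i)
      samples[[nm]] <- evolve_lineage(
        founders[[lin]], config$sample_divergence,
        seed = derive_seed(seed, paste0("sample_", lin), i))$genome
      populations[nm] <- lin
    }
  }
  # introgression from the reference species into the first lineage-A strain
  intro <- implant_introgression(samples[["A_1"]], ref,
                                 config$introgression_tracts)
  samples[["A_1"]] <- intro$genome
  # rearranged assemblies: shared events in both sisters, private ones in A
  asm_a <- apply_svs(samples[["A_1"]],
                     c(config$sv_events_shared, config$sv_events_a))
  asm_b <- apply_svs(samples[["B_1"]], config$sv_events_shared)
  coverage <- simulate_coverage(samples[["A_1"]], config$mean_coverage,
                                config$coverage_window,
                                seed = derive_seed(seed, "coverage"))
  variants <- variant_table_from_genomes(samples, ref, populations,
                                         L = genome_length(ref))
  # crosses: representatives of each pair + within-lineage controls; the
  # sisters are heterozygous for the shared reciprocal translocation only
  # against the reference
  n_rt_shared <- sum(vapply(config$sv_events_shared, function(e)
    e$kind == "reciprocal_translocation", logical(1)))
  pair_div <- c(REF.A = genome_divergence(ref, lin_a),
                REF.B = genome_divergence(ref, lin_b),
                A.B = genome_divergence(lin_a, lin_b))
  cross_specs <- data.frame(
    parent_a = c("REF_1", "REF_1", "A_1", "REF_1", "A_1", "B_1"),
    parent_b = c("A_1", "B_1", "B_1", "REF_2", "A_2", "B_2"),
    divergence = c(pair_div[["REF.A"]], pair_div[["REF.B"]],
                   pair_div[["A.B"]],
                   rep(2 * config$sample_divergence, 3L)),
    n_het_rt = c(n_rt_shared, n_rt_shared, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  crosses <- do.call(rbind, lapply(seq_len(nrow(cross_specs)), function(i)
    simulate_cross(cross_specs$divergence[i], cross_specs$n_het_rt[i],
                   v0 = config$cross_v0, alpha = config$cross_alpha,
                   n_spores = config$cross_n_spores,
                   seed = derive_seed(seed, "cross", i),
                   parent_a = cross_specs$parent_a[i],
                   parent_b = cross_specs$parent_b[i])))
  # growth curves
  eff <- .lineage_condition_effects(config$conditions)
  growth <- list()
  ord <- 0L
  for (nm in names(samples)) {
    lin <- populations[[nm]]
    strain_k <- withr::with_seed(derive_seed(seed, "strainK", match(nm, names(samples))),
                                 exp(stats::rnorm(1L, 0, 0.03)))
    for (cond in config$conditions) {
      for (rep_i in seq_len(config$growth_replicates)) {
        ord <- ord + 1L
        K <- 1.0 * eff[lin, cond] * strain_k
        curve <- simulate_growth(K = K, r = 0.35, N0 = 0.05,
                                 duration = config$growth_duration,
                                 step = config$growth_step,
                                 noise_sd = config$growth_noise_sd,
                                 seed = derive_seed(seed, "growth", ord))
        curve$strain <- nm; curve$lineage <- lin
        curve$condition <- cond; curve$replicate <- rep_i
        growth[[ord]] <- curve
      }
    }
  }
  growth <- do.call(rbind, growth)[, c("strain", "lineage", "condition",
                                       "replicate", "time_h", "od")]
  structure(list(config = config, ancestor = anc, founders = founders,
                 samples = samples, populations = populations,
                 variants = variants, introgression = intro$truth,
                 assemblies = list(A = asm_a$genome, B = asm_b$genome),
                 sv_truth = list(A = asm_a$truth, B = asm_b$truth),
                 coverage = coverage, crosses = crosses, growth = growth,
                 genes = .tile_genes(ref), pair_divergence = pair_div),
            class = "sim_study")
}

#' Write the simulated dataset to disk
#'
#' Emits FASTA genomes, a multi-sample VCF, the coverage TSV, crosses and
#' growth CSVs, the synthetic gene annotation (GFF3) and the truth sets
#' (BED intervals, SV JSON) under `outdir`.
#'
#' @param study a [simulate_study()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulated_dataset <- function(study, outdir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  for (nm in names(study$samples))
    write_genome_fasta(study$samples[[nm]],
                       file.path(outdir, sprintf("lineage_%s.fasta", nm)))
  for (nm in names(study$assemblies))
    write_genome_fasta(study$assemblies[[nm]],
                       file.path(outdir, sprintf("assembly_%s.fasta", nm)))
  write_variants(study$variants, file.path(outdir, "variants.vcf"),
                 contig_lengths = chrom_lengths(study$founders$REF))
  utils::write.table(study$coverage, file.path(outdir, "coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(study$crosses, file.path(outdir, "crosses.csv"),
                   row.names = FALSE)
  utils::write.csv(study$growth, file.path(outdir, "growth.csv"),
                   row.names = FALSE)
  write_gff3(study$genes, file.path(outdir, "annotation.gff3"))
  tr <- study$introgression
  write_bed(data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                       name = tr$donor),
            file.path(outdir, "truth", "introgressions.bed"))
  jsonlite::write_json(study$sv_truth,
                       file.path(outdir, "truth", "sv_events.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(outdir)
}
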