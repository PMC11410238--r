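# Integration of ANI, divergence, reproductive-isolation, SV, introgression
# and phenotype evidence into a per-lineage-pair delineation verdict, plus
# the end-to-end pipeline on simulated data.
#
# The combination rule is a decision table, not a composite score: the
# delineation argument rests on threshold crossings (identity below the
# species band, hybrid viability far below the intraspecies range), so the
# report exposes which criterion fired, with the thresholds used. Phenotype
# separation only corroborates; it never flips a genomic + reproductive
# verdict.

.verdict_one <- function(zone, vclass) {
  if (zone == "distinct") {
    if (is.na(vclass)) return(c("distinct-species-candidate",
                                "genomic evidence only"))
    if (vclass == "reproductively isolated")
      return(c("distinct-species-candidate", ""))
    return(c("ambiguous", "ANI distinct but crosses not isolated"))
  }
  if (zone == "conspecific") {
    if (!is.na(vclass) && vclass == "reproductively isolated")
      return(c("ambiguous", "ANI conspecific but crosses isolated"))
    return(c("conspecific", ""))
  }
  # ambiguous ANI zone is never upgraded by other evidence
  if (is.na(vclass)) return(c("ambiguous", "reproductive data required"))
  c("ambiguous", sprintf("ANI in the delineation band; crosses: %s", vclass))
}

#' Combine per-pair evidence into a delineation verdict
#'
#' @param evidence data.frame with one row per lineage pair: `lineage_a`,
#'   `lineage_b`, `oani` (percent, required), and optionally
#'   `divergence_percent`, `viability` (percent), `sv_count`,
#'   `introgression_kb`, `phenotype_separated` (logical). Missing evidence
#'   downgrades certainty; it is never fabricated.
#' @param ani_band lower/upper OANI thresholds in percent.
#' @param viability_thresholds isolated-below / compatible-above percent.
#' @return object of class `delineation_report`: list with `pairs` (the
#'   evidence plus `zone`, `viability_class`, `verdict`, `note`,
#'   `rationale`) and `thresholds`.
#' @export
integrate_evidence <- function(evidence, ani_band = c(95, 96),
                               viability_thresholds = c(20, 50)) {
  need <- c("lineage_a", "lineage_b", "oani")
  if (!is.data.frame(evidence) || !all(need %in% names(evidence)))
    stop_bad("evidence must carry lineage_a, lineage_b, oani")
  if (anyDuplicated(evidence[, c("lineage_a", "lineage_b")]))
    stop_bad("duplicated lineage pair in evidence")
  for (col in c("divergence_percent", "viability", "sv_count",
                "introgression_kb", "phenotype_separated"))
    if (is.null(evidence[[col]])) evidence[[col]] <- NA
  ev <- evidence
  ev$zone <- classify_ani(ev$oani, ani_band[1L], ani_band[2L])
  ev$viability_class <- ifelse(
    is.na(ev$viability), NA_character_,
    isolation_class(ev$viability, viability_thresholds[1L],
                    viability_thresholds[2L]))
  vd <- t(vapply(seq_len(nrow(ev)), function(i)
    .verdict_one(ev$zone[i], ev$viability_class[i]), character(2)))
  ev$verdict <- vd[, 1L]
  ev$note <- vd[, 2L]
  ev$rationale <- vapply(seq_len(nrow(ev)), function(i) {
    parts <- c(sprintf("OANI %.2f%% -> %s (band %g-%g%%)", ev$oani[i],
                       ev$zone[i], ani_band[1L], ani_band[2L]))
    if (!is.na(ev$divergence_percent[i]))
      parts <- c(parts, sprintf("pairwise divergence %.2f%%",
                                ev$divergence_percent[i]))
    parts <- c(parts, if (is.na(ev$viability[i]))
      "spore viability: no data" else
        sprintf("spore viability %.1f%% -> %s (thresholds %g/%g%%)",
                ev$viability[i], ev$viability_class[i],
                viability_thresholds[1L], viability_thresholds[2L]))
    if (!is.na(ev$sv_count[i]))
      parts <- c(parts, sprintf("%d structural variant(s) > 1 kb",
                                ev$sv_count[i]))
    if (!is.na(ev$introgression_kb[i]))
      parts <- c(parts, sprintf("%.1f kb introgressed", ev$introgression_kb[i]))
    if (!is.na(ev$phenotype_separated[i]))
      parts <- c(parts, sprintf("phenotype clusters %s (corroborating only)",
                                if (isTRUE(ev$phenotype_separated[i]))
                                  "separated" else "not separated"))
    paste(parts, collapse = "; ")
  }, character(1))
  structure(list(pairs = ev,
                 thresholds = list(ani_band_percent = ani_band,
                                   viability_percent = viability_thresholds)),
            class = "delineation_report")
}

#' @export
print.delineation_report <- function(x, ...) {
  cat("<delineation_report>\n")
  for (i in seq_len(nrow(x$pairs))) {
    p <- x$pairs[i, ]
    cat(sprintf("  %s vs %s: %s%s\n", p$lineage_a, p$lineage_b, p$verdict,
                if (nzchar(p$note)) sprintf(" [%s]", p$note) else ""))
    cat(sprintf("    %s\n", p$rationale))
  }
  invisible(x)
}

.report_json <- function(report) {
  jsonlite::toJSON(list(pairs = report$pairs,
                        thresholds = report$thresholds,
                        units = list(oani = "percent",
                                     divergence_percent = "percent",
                                     viability = "percent",
                                     introgression_kb = "kilobases",
                                     sv_count = "events > 1 kb")),
                   dataframe = "rows", auto_unbox = TRUE, digits = 10,
                   pretty = TRUE, na = "null")
}

#' Run the full delineation pipeline on a simulated study
#'
#' Executes every stage in dependency order on a [simulate_study()] dataset:
#' OANI between lineage founders, population statistics and divergence
#' times, introgression scan on the introgressed strain, structural-variant
#' calling on the rearranged assemblies via the anchor aligner, cross
#' statistics with the viability-identity regression, growth-curve
#' phenotyping, and the integrated verdict. All stage outputs plus
#' `report.json` / `report.txt` are written under `outdir`; reruns with the
#' same config are byte-identical.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @param quiet suppress stage messages.
#' @return the `delineation_report`, invisibly; its attribute `"stages"`
#'   holds all intermediate results.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("intertaxon_"),
                         quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    say("[%s] running", name)
    tryCatch(expr, error = function(e)
      stop_bad("stage %s failed: %s", name, conditionMessage(e)))
  }
  study <- stage("simulate", simulate_study(config))
  stage("write", write_simulated_dataset(study, outdir))

  pairs <- list(c("REF", "A"), c("REF", "B"), c("A", "B"))
  ani <- stage("ani", lapply(pairs, function(p)
    compute_oani(study$founders[[p[1L]]], study$founders[[p[2L]]])))
  names(ani) <- vapply(pairs, paste, character(1), collapse = ".")

  pg <- stage("popgen", {
    vt <- study$variants
    list(diversity = lapply(stats::setNames(nm = names(study$founders)),
                            function(lin) nucleotide_diversity(vt, lin)),
         fst = list(A.B = hudson_fst(vt, "A", "B"),
                    REF.A = hudson_fst(vt, "REF", "A"),
                    REF.B = hudson_fst(vt, "REF", "B")),
         divtime = lapply(study$pair_divergence, generations_since_divergence))
  })

  intro <- stage("introgress", {
    vars <- genome_diff_positions(study$founders$REF, study$samples[["A_1"]])
    scan_introgressions(vars, study$coverage)
  })

  sv <- stage("sv", {
    genes <- study$genes
    per_asm <- lapply(names(study$assemblies), function(nm) {
      blocks <- genome_alignment_blocks(study$founders$REF,
                                        study$assemblies[[nm]])
      calls <- pair_reciprocal(call_svs(blocks))
      filt <- filter_svs(calls, min_size = 1000L)
      gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end),
                                   type = "gene")
      list(blocks = blocks, svs = annotate_genes(filt, gr),
           summary = summarize_svs(filt))
    })
    names(per_asm) <- names(study$assemblies)
    ab_blocks <- genome_alignment_blocks(study$assemblies$A,
                                         study$assemblies$B)
    ab <- filter_svs(pair_reciprocal(call_svs(ab_blocks)), min_size = 1000L)
    c(per_asm, list(A.B = list(blocks = ab_blocks, svs = ab,
                               summary = summarize_svs(ab))))
  })

  crosses <- stage("cross", {
    cr <- spore_viability(study$crosses$viable, study$crosses$dissected,
                          study$crosses$parent_a, study$crosses$parent_b)
    cr$identity <- 100 * (1 - study$crosses$divergence)
    cr$class <- isolation_class(cr$viability)
    list(records = cr,
         regression = fit_viability_regression(
           data.frame(identity = cr$identity, viability = cr$viability)))
  })

  pheno <- stage("phenotype", {
    gr <- study$growth
    key <- interaction(gr$strain, gr$condition, gr$replicate, drop = TRUE)
    fits <- lapply(split(gr, key), function(d)
      fit_logistic_growth(d$time_h, d$od))
    auc_tab <- do.call(rbind, lapply(names(fits), function(k) {
      d <- gr[key == k, ][1L, ]
      f <- fits[[k]]
      data.frame(strain = d$strain, lineage = d$lineage,
                 condition = d$condition, replicate = d$replicate,
                 auc = if (f$converged) f$auc_fit else f$auc_empirical,
                 converged = f$converged, stringsAsFactors = FALSE)
    }))
    m <- build_phenotype_matrix(auc_tab)
    z <- zscore_columns(m)
    cl <- cluster_phenotypes(z)
    lineage_of <- study$populations[rownames(z)]
    an <- anova_by_condition(z, groups = lineage_of)
    list(auc = auc_tab, matrix = m, zmatrix = z, cluster = cl, anova = an)
  })

  say("[report] integrating evidence")
  lineage_of <- study$populations
  majority_side <- function(lin) {
    side <- pheno$cluster$top_split[names(lineage_of)[lineage_of == lin]]
    as.integer(names(which.max(table(side))))
  }
  viab_of <- function(a, b) {
    r <- crosses$records
    hit <- (sub("_.*", "", r$parent_a) == a & sub("_.*", "", r$parent_b) == b) |
      (sub("_.*", "", r$parent_a) == b & sub("_.*", "", r$parent_b) == a)
    if (!any(hit)) NA_real_ else mean(r$viability[hit])
  }
  evidence <- do.call(rbind, lapply(pairs, function(p) {
    key <- paste(p, collapse = ".")
    data.frame(
      lineage_a = p[1L], lineage_b = p[2L],
      oani = ani[[key]]$oani,
      divergence_percent = 100 * study$pair_divergence[[key]],
      viability = viab_of(p[1L], p[2L]),
      sv_count = sv[[if (key %in% names(sv)) key else p[2L]]]$summary$n_total,
      introgression_kb = if (key == "REF.A")
        sum(intro$tracts$length) / 1000 else NA_real_,
      phenotype_separated = majority_side(p[1L]) != majority_side(p[2L]),
      stringsAsFactors = FALSE)
  }))
  report <- integrate_evidence(evidence)
  writeLines(.report_json(report), file.path(outdir, "report.json"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(outdir, "report.txt"))
  for (nm in names(sv))
    utils::write.table(sv[[nm]]$svs,
                       file.path(outdir, sprintf("svs_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(data.frame(chrom = intro$tracts$chrom, start = intro$tracts$start,
                       end = intro$tracts$end),
            file.path(outdir, "introgression_tracts.bed"))
  say("[done] %s", outdir)
  attr(report, "stages") <- list(study = study, ani = ani, popgen = pg,
                                 introgression = intro, sv = sv,
                                 crosses = crosses, phenotype = pheno)
  invisible(report)
}
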