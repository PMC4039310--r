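## End-to-end pipeline orchestration on simulated inputs: every stage
## writes its tabular outputs before the next starts, all randomness comes
## from the sim_config seed, and reruns with the same configuration give
## byte-identical tables.

.fmt_num <- function(x) {
  ## fixed significant-digit formatting keeps TSV output byte-stable
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

.write_stage_table <- function(x, path) {
  num <- vapply(x, is.double, TRUE)
  x[num] <- lapply(x[num], .fmt_num)
  write_table_file(x, path)
}

#' Run the full simulated pipeline
#'
#' Executes, in order: TAP simulation and network assembly; phosphosite
#' simulation, perturbation scoring and PPI-based extension; viability
#' screen simulation, normalization, hit calling, core-network
#' intersection and mutant-specificity testing; drug-table simulation,
#' affinity filtering, bipartite network construction and diffusion
#' ranking; and median-effect fitting with combination-index calculation.
#' Each stage's outputs are written to `outdir` before the next stage
#' starts; a failure stops the run with a stage-scoped error, leaving
#' prior outputs intact.
#'
#' @param config a [sim_config()]
#' @param outdir output directory (created if needed)
#' @param phospho_threshold score cutoff for perturbed sites
#' @param alpha decay of the diffusion kernel
#' @return data.frame run manifest (stage, outputs, status, seconds),
#'   invisibly; also written as `run_manifest.tsv`
#' @export
run_pipeline <- function(config, outdir, phospho_threshold = 0.1,
                         alpha = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = name, status = "ok",
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    res
  }
  p <- function(...) file.path(outdir, ...)

  tap <- stage("simulate_tap", {
    x <- simulate_tap(config)
    .write_stage_table(x$evidence, p("tap_evidence.tsv"))
    .write_stage_table(x$manifest, p("tap_manifest.tsv"))
    write_truth_json(x$truth, p("tap_truth.json"))
    x
  })
  net <- stage("tap_build", {
    res <- tap_pipeline(tap$evidence, tap$manifest)
    write_network(res$network, p("network.graphml"), "graphml")
    write_network(res$network, p("network.sif"), "sif")
    for (nm in names(res$pulldowns))
      .write_stage_table(res$pulldowns[[nm]],
                         p(paste0("pulldown_", nm, ".tsv")))
    res$network
  })
  ph <- stage("simulate_phospho",
              simulate_phospho(config, tap_proteins = net$nodes$protein))
  stage("phospho_tables", {
    .write_stage_table(ph$counts, p("phospho_counts.tsv"))
    write_ppi_tsv(ph$ppi, p("ppi_reference.tsv"))
    write_truth_json(ph$truth, p("phospho_truth.json"))
  })
  sites <- stage("phospho_score", {
    s <- call_significant_sites(ph$counts, threshold = phospho_threshold)
    .write_stage_table(s, p("phospho_sites.tsv"))
    s
  })
  net_ext <- stage("phospho_extend", {
    nx <- extend_network(net, sites, ph$ppi)
    write_network(nx, p("network_extended.graphml"), "graphml")
    nx
  })
  scr <- stage("simulate_screen", {
    x <- simulate_screen(config)
    .write_stage_table(x$screen$readings, p("screen_readings.tsv"))
    .write_stage_table(x$screen$meta, p("screen_meta.tsv"))
    write_truth_json(x$truth, p("screen_truth.json"))
    x
  })
  screen_res <- stage("screen_analysis", {
    ns <- normalize_screen(scr$screen)
    hits <- call_hits(ns)
    .write_stage_table(hits, p("screen_hits.tsv"))
    mut_lines <- ns$meta$cell_line[ns$meta$group == "mutant"]
    core <- core_network(hit_sets(hits)[mut_lines])
    writeLines(core, p("core_genes.txt"))
    spec <- specificity_test(ns)
    .write_stage_table(spec, p("screen_specificity.tsv"))
    viability_heatmap(ns, tsv = p("viability_heatmap.tsv"))
    list(core = core, spec = spec, normalized = ns)
  })
  drugs <- stage("simulate_drugs", {
    x <- simulate_drug_tables(config, core_proteins = config$core_genes)
    .write_stage_table(x$drug_targets, p("drug_targets.tsv"))
    .write_stage_table(x$kinase_screen, p("kinase_screen.tsv"))
    .write_stage_table(x$dose_response, p("dose_response.tsv"))
    write_truth_json(x$truth, p("drug_truth.json"))
    x
  })
  stage("drug_network", {
    filt <- filter_records(drugs$drug_targets)
    .write_stage_table(filt, p("drug_targets_filtered.tsv"))
    dn <- build_drug_network(filt, config$core_genes)
    .write_stage_table(dn$proteins, p("drug_network_proteins.tsv"))
    .write_stage_table(dn$edges, p("drug_network_edges.tsv"))
    ## EGFR-specific diffusion: rank compounds over the TAP network using
    ## the simulated kinase screen (kinase ids live on core genes, so map
    ## them onto the first baits of the TAP network for the demo ranking)
    kin <- unique(drugs$kinase_screen$kinase)
    baits <- net$nodes$protein[net$nodes$role == "bait"]
    map <- setNames(baits[seq_len(min(length(kin), length(baits)))],
                    kin[seq_len(min(length(kin), length(baits)))])
    ks <- drugs$kinase_screen[drugs$kinase_screen$kinase %in% names(map), ]
    ks$kinase <- unname(map[ks$kinase])
    rk <- diffusion_rank(net_ext, ks, alpha = alpha, targets = baits)
    .write_stage_table(rk, p("diffusion_ranking.tsv"))
    rk
  })
  stage("synergy", {
    dr <- drugs$dose_response
    ids <- unique(dr$drug_id)
    fits <- lapply(ids, function(d)
      fit_median_effect(dr$dose[dr$drug_id == d], dr$fa[dr$drug_id == d],
                        drug_id = d))
    names(fits) <- ids
    ft <- data.frame(drug_id = ids,
                     Dm = vapply(fits, `[[`, 0, "Dm"),
                     m = vapply(fits, `[[`, 0, "m"),
                     r = vapply(fits, `[[`, 0, "r"))
    .write_stage_table(ft, p("median_effect_fits.tsv"))
    if (length(ids) >= 2) {
      ## demo combination of the first two agents at a 1:1 ratio, with the
      ## combination curve constructed at the additive expectation
      f1 <- fits[[1]]; f2 <- fits[[2]]
      fa <- c(0.2, 0.35, 0.5, 0.65, 0.8)
      total <- 1 / (0.5 / dose_at_effect(f1, fa) +
                    0.5 / dose_at_effect(f2, fa))
      fc <- fit_median_effect(total, fa, drug_id = paste(ids[1], ids[2],
                                                         sep = "+"))
      ci <- combination_index(f1, f2, fc, ratio = c(1, 1))
      ci$pair_id <- fc$drug_id
      .write_stage_table(ci, p("combination_index.tsv"))
    }
  })
  man <- do.call(rbind, manifest)
  ## durations vary between runs; the persisted manifest records stage
  ## order and status only, keeping outputs byte-comparable
  write_table_file(man[, c("stage", "status")], p("run_manifest.tsv"))
  invisible(man)
}
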