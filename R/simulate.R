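## Synthetic-data generators with planted ground truth.
##
## Every pipeline input can be simulated from one sim_config. Each generator
## draws from its own RNG sub-stream of the global seed (stream ids below),
## so the same configuration always reproduces the same tables and adding a
## generator never changes another's output.

.STREAM_TAP <- 1L
.STREAM_PHOSPHO <- 2L
.STREAM_SCREEN <- 3L
.STREAM_DRUG <- 4L

.draw_counts <- function(n, lambda, overdispersion) {
  if (is.null(overdispersion)) rpois(n, lambda)
  else rnbinom(n, size = overdispersion, mu = lambda)
}

#' Simulate TAP-MS peptide evidence with planted interactions
#'
#' Generates a peptide-evidence table and pulldown manifest over a planted
#' bait-prey interactome with a shared contaminant background. Each bait is
#' purified in `n_replicates` replicate runs and pulls down the bait itself,
#' its planted prey and the background proteins; GFP-like control pulldowns
#' contain only background proteins. A configurable fraction of each bait's
#' prey carries no protein-specific peptide (all peptides shared with a
#' retained paralog in the same pulldown), exercising protein-group
#' discarding downstream.
#'
#' @param config a [sim_config()]
#' @return list with `evidence` (run_id, peptide_id, protein_ids
#'   (";"-separated), spectral_count, phospho_state), `manifest` (run_id,
#'   bait_id, cell_line, replicate, is_control) and `truth` with
#'   `true_edges`, `true_background`, `shared_only_prey`.
#' @export
simulate_tap <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_baits < 1) stop("configuration error: need at least one bait")
  if (config$n_replicates < 1)
    stop("configuration error: need at least one control pulldown")
  with_stream(config$seed, .STREAM_TAP, {
    baits <- sprintf("BAIT%02d", seq_len(config$n_baits))
    n_prey_tot <- config$n_baits * config$n_prey_per_bait
    prey <- sprintf("G%04d", seq_len(n_prey_tot))
    prey_of <- split(prey, rep(baits, each = config$n_prey_per_bait))
    background <- if (config$n_background > 0)
      sprintf("BG%03d", seq_len(config$n_background)) else character()

    ## choose shared-only prey per bait and pair each with a retained paralog
    shared_only <- character()
    partner <- character()
    n_sh <- round(config$shared_peptide_fraction * config$n_prey_per_bait)
    for (b in baits) {
      p <- prey_of[[b]]
      if (n_sh > 0 && length(p) > n_sh) {
        sh <- sort(sample(p, n_sh))
        keep <- setdiff(p, sh)
        shared_only <- c(shared_only, sh)
        partner <- c(partner, sample(keep, n_sh, replace = TRUE))
      }
    }
    names(partner) <- shared_only

    ## peptide catalog: 3 specific peptides per retained protein, 2 shared
    ## peptides per shared-only prey (mapping to prey + paralog)
    retained <- c(baits, setdiff(prey, shared_only), background)
    pep <- data.frame(
      peptide_id = paste0(rep(retained, each = 3), "_p", 1:3),
      protein_ids = rep(retained, each = 3),
      owner = rep(retained, each = 3),
      stringsAsFactors = FALSE)
    if (length(shared_only)) {
      shp <- data.frame(
        peptide_id = paste0(rep(shared_only, each = 2), "_s", 1:2),
        protein_ids = paste(rep(shared_only, each = 2),
                            rep(partner[shared_only], each = 2), sep = ";"),
        owner = rep(shared_only, each = 2),
        stringsAsFactors = FALSE)
      pep <- rbind(pep, shp)
    }
    ## abundance factors: bait >> prey > background
    fac <- setNames(rep(1, length(c(baits, prey, background))),
                    c(baits, prey, background))
    fac[baits] <- 3
    fac[background] <- 0.6

    manifest <- NULL
    evidence <- NULL
    runs <- list()
    for (b in baits) for (r in seq_len(config$n_replicates))
      runs[[paste0("run_", b, "_r", r)]] <-
        list(bait = b, rep = r, ctrl = FALSE,
             proteins = c(b, prey_of[[b]], background))
    for (r in seq_len(config$n_replicates))
      runs[[paste0("run_CONTROL_r", r)]] <-
        list(bait = "CONTROL", rep = r, ctrl = TRUE, proteins = background)

    ev <- vector("list", length(runs))
    for (i in seq_along(runs)) {
      run <- runs[[i]]
      present <- pep[pep$owner %in% run$proteins, , drop = FALSE]
      if (nrow(present) == 0) { ev[[i]] <- NULL; next }
      lambda <- config$count_mean * fac[present$owner]
      counts <- .draw_counts(nrow(present), lambda, config$overdispersion)
      keep <- counts > 0
      if (!any(keep)) { ev[[i]] <- NULL; next }
      ev[[i]] <- data.frame(run_id = names(runs)[i],
                            peptide_id = present$peptide_id[keep],
                            protein_ids = present$protein_ids[keep],
                            spectral_count = counts[keep],
                            phospho_state = 0L,
                            stringsAsFactors = FALSE)
    }
    evidence <- do.call(rbind, ev)
    rownames(evidence) <- NULL
    manifest <- data.frame(
      run_id = names(runs),
      bait_id = vapply(runs, `[[`, "", "bait"),
      cell_line = "LC1",
      replicate = vapply(runs, function(x) as.integer(x$rep), 1L),
      is_control = vapply(runs, `[[`, TRUE, "ctrl"),
      stringsAsFactors = FALSE)
    rownames(manifest) <- NULL

    truth <- .new_truth(
      true_edges = data.frame(bait = rep(baits,
                                         each = config$n_prey_per_bait),
                              prey = prey, stringsAsFactors = FALSE),
      true_background = background,
      shared_only_prey = shared_only)
    list(evidence = evidence, manifest = manifest, truth = truth)
  })
}

#' Simulate phosphosite spectral counts and a PPI reference
#'
#' Per site, four pooled spectral counts are drawn (treated/control x
#' phosphorylated/non-phosphorylated). Null sites share one Poisson mean
#' across conditions; at perturbed sites the treated phosphorylated mean is
#' divided by `phospho_effect_fold` with a compensating increase of the
#' treated non-phosphorylated mean (the drug suppresses phosphorylation,
#' the peptide itself remains).
#'
#' The accompanying PPI reference contains planted extension edges linking
#' roughly half of the perturbed non-TAP phosphoproteins to TAP proteins,
#' plus random background edges that never connect a non-perturbed external
#' phosphoprotein to a TAP protein (so the planted extension set is exact).
#'
#' @param config a [sim_config()]
#' @param tap_proteins optional character vector of proteins present in the
#'   TAP network; a fraction of sites is placed on these, the rest on
#'   external phosphoproteins.
#' @return list with `counts` (a phospho count table), `ppi` (a
#'   [ppi_reference()]) and `truth` with `true_perturbed_sites` (keys
#'   `"protein|site"`) and `true_extension_proteins`.
#' @export
simulate_phospho <- function(config, tap_proteins = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$phospho_effect_fold <= 0)
    stop("configuration error: phospho_effect_fold must be positive")
  with_stream(config$seed, .STREAM_PHOSPHO, {
    n <- config$phospho_n_sites
    n_prot <- ceiling(n / 2)
    prot_idx <- rep(seq_len(n_prot), each = 2)[seq_len(n)]
    n_on_tap <- if (length(tap_proteins))
      min(length(tap_proteins), round(0.4 * n_prot)) else 0L
    prot_pool <- c(if (n_on_tap > 0) sort(sample(tap_proteins, n_on_tap)),
                   sprintf("PY%03d", seq_len(n_prot - n_on_tap)))
    proteins <- prot_pool[prot_idx]
    sites <- paste0("Y", 100 + 17 * seq_len(n))

    n_pert <- floor(config$phospho_frac_perturbed * n)
    pert_idx <- if (n_pert > 0) sort(sample(seq_len(n), n_pert)) else integer()
    mu <- config$count_mean
    fold <- config$phospho_effect_fold
    mu_tp <- rep(mu, n); mu_tn <- rep(mu, n)
    mu_tp[pert_idx] <- mu / fold
    mu_tn[pert_idx] <- mu + (mu - mu / fold)
    counts <- data.frame(
      protein_id = proteins,
      site = sites,
      n_treated_phos = rpois(n, mu_tp),
      n_control_phos = rpois(n, mu),
      n_treated_nonphos = rpois(n, mu_tn),
      n_control_nonphos = rpois(n, mu),
      n_runs_treated = config$n_replicates,
      n_runs_control = config$n_replicates,
      stringsAsFactors = FALSE)

    ## PPI: planted extension edges + background edges
    external <- setdiff(unique(proteins), tap_proteins)
    pert_prot <- unique(proteins[pert_idx])
    pert_ext <- intersect(external, pert_prot)
    null_ext <- setdiff(external, pert_prot)
    linked <- if (length(pert_ext) && length(tap_proteins))
      sort(sample(pert_ext, ceiling(length(pert_ext) / 2))) else character()
    ea <- linked
    eb <- if (length(linked)) sample(tap_proteins, length(linked),
                                     replace = TRUE) else character()
    generic <- sprintf("N%04d", seq_len(config$ppi_n_nodes))
    pool <- c(generic, external, tap_proteins)
    n_pairs <- choose(length(pool), 2)
    n_bg <- round(config$ppi_edge_prob * n_pairs)
    if (n_bg > 0) {
      i <- sample(length(pool), n_bg, replace = TRUE)
      j <- sample(length(pool), n_bg, replace = TRUE)
      ok <- i != j
      a <- pool[pmin(i, j)[ok]]; b <- pool[pmax(i, j)[ok]]
      ## background must not create extension paths for non-planted external
      ## proteins (keeps true_extension_proteins exact by construction)
      forbid <- (a %in% tap_proteins & b %in% external) |
                (b %in% tap_proteins & a %in% external)
      ea <- c(ea, a[!forbid]); eb <- c(eb, b[!forbid])
    }
    ppi <- ppi_reference(ea, eb, source = "simulated")

    truth <- .new_truth(
      true_perturbed_sites = paste(proteins[pert_idx], sites[pert_idx],
                                   sep = "|"),
      true_extension_proteins = linked,
      true_null_external = null_ext)
    list(counts = counts, ppi = ppi, truth = truth)
  })
}

#' Simulate an RNAi viability screen with a planted core gene set
#'
#' Mutant-labelled lines have mean viability `core_effect` for core genes;
#' wild-type lines and non-core genes sit at 1.0 (fraction of control).
#' Optional `general_genes` are depleted in every line (non-differential).
#' Replicate noise is multiplicative log-normal with coefficient of
#' variation `replicate_cv`; non-targeting control wells are included per
#' line at the same plate signal.
#'
#' @param config a [sim_config()]
#' @return list with `screen` (a `viability_screen`: `readings` data.frame
#'   with cell_line, gene, replicate, readout, is_control; `meta` with
#'   cell_line, group, resistance; `readout_kind`) and `truth` with
#'   `true_core_genes`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_replicates < 2)
    stop("configuration error: need >= 2 replicates for hit testing")
  with_stream(config$seed, .STREAM_SCREEN, {
    n_mut <- config$screen_n_mutant
    n_wt <- config$screen_n_lines - n_mut
    lines <- c(sprintf("MUT%02d", seq_len(n_mut)),
               sprintf("WT%02d", seq_len(n_wt)))
    groups <- c(rep("mutant", n_mut), rep("wild-type", n_wt))
    n_fill <- config$screen_n_genes - length(config$core_genes) -
      length(config$general_genes)
    genes <- c(config$core_genes, config$general_genes,
               if (n_fill > 0) sprintf("GEN%03d", seq_len(n_fill)))
    base_signal <- 2000
    rows <- vector("list", length(lines))
    for (li in seq_along(lines)) {
      mean_v <- rep(1, length(genes))
      if (groups[li] == "mutant")
        mean_v[genes %in% config$core_genes] <- config$core_effect
      mean_v[genes %in% config$general_genes] <- config$general_effect
      nrep <- config$n_replicates
      g <- rep(genes, each = nrep)
      mv <- rep(mean_v, each = nrep)
      noise <- .lognormal_noise(length(g), config$replicate_cv)
      ctrl_noise <- .lognormal_noise(nrep, config$replicate_cv)
      rows[[li]] <- data.frame(
        cell_line = lines[li],
        gene = c(g, rep("NON_TARGETING", nrep)),
        replicate = c(rep(seq_len(nrep), times = length(genes)),
                      seq_len(nrep)),
        readout = base_signal * c(mv * noise, ctrl_noise),
        is_control = c(rep(FALSE, length(g)), rep(TRUE, nrep)),
        stringsAsFactors = FALSE)
    }
    screen <- structure(list(
      readings = do.call(rbind, rows),
      meta = data.frame(cell_line = lines, group = groups,
                        resistance = "sensitive", stringsAsFactors = FALSE),
      readout_kind = "viability"), class = "viability_screen")
    rownames(screen$readings) <- NULL
    truth <- .new_truth(true_core_genes = config$core_genes)
    list(screen = screen, truth = truth)
  })
}

#' @export
print.viability_screen <- function(x, ...) {
  cat("viability_screen:", nrow(x$meta), "cell lines,",
      length(setdiff(unique(x$readings$gene), "NON_TARGETING")), "genes,",
      "readout:", x$readout_kind,
      if (isTRUE(attr(x, "normalized"))) "(normalized)" else "(raw)", "\n")
  invisible(x)
}

#' Simulate drug-target affinity tables, a kinase screen and dose-response
#' curves
#'
#' Affinities are log-normal in nM across four source databases. Planted
#' allele-specific rows bind the first core protein with allele tag "T790M"
#' below the 100 nM filter cutoff. Dose-response fractions follow the
#' median-effect equation `fa = 1 / (1 + (Dm/D)^m)` with optional
#' logit-scale noise.
#'
#' @param config a [sim_config()]
#' @param core_proteins proteins of the core network to draw targets from;
#'   defaults to `config$core_genes`.
#' @return list with `drug_targets` (compound_id, target_protein, allele,
#'   affinity_type, value_nM, source), `kinase_screen` (compound_id, kinase,
#'   value: percent inhibition), `dose_response` (drug_id, dose, fa) and
#'   `truth` with `true_allele_binders` and `true_dose_params`.
#' @export
simulate_drug_tables <- function(config, core_proteins = config$core_genes) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$dose_response_params) == 0)
    stop("configuration error: dose_response_params must be non-empty")
  with_stream(config$seed, .STREAM_DRUG, {
    sources <- c("competition_assay", "kinase_assay", "bindingdb", "drugbank")
    cmpds <- sprintf("CPD%03d", seq_len(config$drug_n_compounds))
    mu <- config$affinity_lognormal_params[1]
    sg <- config$affinity_lognormal_params[2]
    rows <- vector("list", length(cmpds))
    for (i in seq_along(cmpds)) {
      k <- sample(1:3, 1)
      tg <- sample(core_proteins, min(k, length(core_proteins)))
      src <- sample(sources, length(tg), replace = TRUE)
      typ <- ifelse(src == "bindingdb",
                    sample(c("Ki", "Kd", "IC50", "EC50"), length(tg),
                           replace = TRUE), "Kd")
      rows[[i]] <- data.frame(compound_id = cmpds[i], target_protein = tg,
                              allele = "", affinity_type = typ,
                              value_nM = rlnorm(length(tg), mu, sg),
                              source = src, stringsAsFactors = FALSE)
    }
    drug_targets <- do.call(rbind, rows)
    ## planted allele-specific binders of the gatekeeper-mutant kinase
    allele_target <- if ("EGFR" %in% core_proteins) "EGFR" else
      core_proteins[1]
    nb <- config$n_allele_binders
    if (nb > 0) {
      ab <- data.frame(
        compound_id = sprintf("CPDA%02d", seq_len(nb)),
        target_protein = allele_target,
        allele = "T790M",
        affinity_type = "Kd",
        value_nM = runif(nb, 1, 90),
        source = "competition_assay",
        stringsAsFactors = FALSE)
      drug_targets <- rbind(drug_targets, ab)
    } else ab <- NULL
    rownames(drug_targets) <- NULL

    kinases <- core_proteins[seq_len(min(5, length(core_proteins)))]
    kinase_screen <- expand.grid(compound_id = cmpds, kinase = kinases,
                                 KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE)
    kinase_screen$value <- round(runif(nrow(kinase_screen), 0, 100), 1)

    dr_rows <- list()
    for (drug in names(config$dose_response_params)) {
      p <- config$dose_response_params[[drug]]
      Dm <- p[[1]]; m <- p[[2]]
      D <- Dm * 2^seq(-4, 3)
      fa <- 1 / (1 + (Dm / D)^m)
      if (config$dose_noise_cv > 0)
        fa <- plogis(qlogis(fa) + rnorm(length(fa), 0, config$dose_noise_cv))
      dr_rows[[drug]] <- data.frame(drug_id = drug, dose = D, fa = fa,
                                    stringsAsFactors = FALSE)
    }
    dose_response <- do.call(rbind, dr_rows)
    rownames(dose_response) <- NULL

    truth <- .new_truth(
      true_allele_binders = if (is.null(ab))
        data.frame(compound = character(), protein = character(),
                   allele = character()) else
        data.frame(compound = ab$compound_id, protein = ab$target_protein,
                   allele = ab$allele, stringsAsFactors = FALSE),
      true_dose_params = config$dose_response_params)
    list(drug_targets = drug_targets, kinase_screen = kinase_screen,
         dose_response = dose_response, truth = truth)
  })
}
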