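## Simulation configuration and planted ground truth.

#' Simulation configuration
#'
#' One configuration object drives every synthetic-data generator. Defaults
#' describe a desk-scale world shaped like a mutant-EGFR TAP-MS /
#' phosphoproteomics / RNAi study: a handful of bait pulldowns with shared
#' contaminant background, a few hundred tyrosine phosphosites of which a
#' minority respond to kinase-inhibitor treatment, a panel of mutant and
#' wild-type cell lines screened in triplicate against ~100 genes with a
#' 14-gene planted core, and drug-target tables with a few allele-specific
#' binders.
#'
#' @param seed integer; the single global seed. Generators draw from
#'   deterministic sub-streams so identical configurations give
#'   byte-identical outputs.
#' @param n_baits number of bait pulldowns.
#' @param n_prey_per_bait planted prey per bait.
#' @param n_background shared non-specific (contaminant) proteins present in
#'   every pulldown including controls.
#' @param shared_peptide_fraction fraction of each bait's prey constructed
#'   without any protein-specific peptide (every peptide shared with a
#'   retained paralog); protein grouping must discard exactly these.
#' @param count_mean mean spectral count per peptide (Poisson).
#' @param overdispersion optional negative-binomial size parameter; `NULL`
#'   (default) keeps pure Poisson counts.
#' @param n_replicates replicate runs per pulldown and wells per screen
#'   condition.
#' @param phospho_n_sites number of simulated phosphosites.
#' @param phospho_effect_fold fold suppression of treated phosphorylated
#'   counts at perturbed sites (treatment inhibits phosphorylation).
#' @param phospho_frac_perturbed fraction of sites planted as perturbed.
#' @param ppi_n_nodes size of the generic PPI background node pool.
#' @param ppi_edge_prob background PPI edge probability.
#' @param screen_n_lines number of screened cell lines.
#' @param screen_n_mutant number of mutant-labelled lines (first lines);
#'   must not exceed `screen_n_lines`.
#' @param screen_n_genes total genes in the screen library.
#' @param core_genes identifiers of planted core genes (differentially
#'   essential in mutant lines); must fit inside `screen_n_genes`.
#' @param core_effect mean viability (fraction of control) of core genes in
#'   mutant lines; must be < 0.5 so planted genes satisfy the >50%
#'   inhibition rule in expectation.
#' @param general_genes optional genes essential in every line (emulating
#'   chaperones and broadly required kinases); not differential.
#' @param general_effect mean viability for `general_genes` in all lines.
#' @param replicate_cv coefficient of variation of multiplicative
#'   (log-normal) replicate noise.
#' @param drug_n_compounds number of simulated compounds.
#' @param affinity_lognormal_params `c(meanlog, sdlog)` of affinity values
#'   in nM.
#' @param n_allele_binders planted compounds binding the first core protein
#'   with allele tag "T790M" below the 100 nM cutoff.
#' @param dose_response_params named list `drug -> c(Dm, m)` of median-effect
#'   parameters (Dm: median-effect dose, m: slope).
#' @param dose_noise_cv coefficient of variation of logit-scale noise on
#'   simulated fraction-affected values (0 = exact curves).
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_baits = 8,
                       n_prey_per_bait = 25,
                       n_background = 60,
                       shared_peptide_fraction = 0.1,
                       count_mean = 20,
                       overdispersion = NULL,
                       n_replicates = 3,
                       phospho_n_sites = 368,
                       phospho_effect_fold = 10,
                       phospho_frac_perturbed = 66 / 368,
                       ppi_n_nodes = 300,
                       ppi_edge_prob = 0.01,
                       screen_n_lines = 17,
                       screen_n_mutant = 5,
                       screen_n_genes = 102,
                       core_genes = sprintf("CORE%02d", 1:14),
                       core_effect = 0.3,
                       general_genes = character(),
                       general_effect = 0.4,
                       replicate_cv = 0.05,
                       drug_n_compounds = 50,
                       affinity_lognormal_params = c(log(50), 1.5),
                       n_allele_binders = 2,
                       dose_response_params = list(
                         erlotinib = c(Dm = 1, m = 1),
                         midostaurin = c(Dm = 2, m = 1.5)),
                       dose_noise_cv = 0) {
  cfg <- as.list(environment())
  prop <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!is.numeric(seed) || length(seed) != 1)
    stop("seed must be a single integer")
  if (n_baits < 1) stop("at least one bait is required")
  if (!prop(shared_peptide_fraction))
    stop("shared_peptide_fraction must be a proportion in [0,1]")
  if (!prop(phospho_frac_perturbed))
    stop("phospho_frac_perturbed must be a proportion in [0,1]")
  if (!prop(ppi_edge_prob)) stop("ppi_edge_prob must be a proportion in [0,1]")
  if (count_mean <= 0) stop("count_mean must be positive")
  if (phospho_effect_fold <= 0) stop("phospho_effect_fold must be positive")
  if (phospho_n_sites < 1) stop("phospho_n_sites must be >= 1")
  if (screen_n_mutant > screen_n_lines)
    stop("screen_n_mutant must not exceed screen_n_lines")
  if (!prop(core_effect) || core_effect >= 0.5)
    stop("core_effect must be in [0, 0.5) so planted core genes exceed 50% ",
         "inhibition in expectation")
  if (replicate_cv < 0) stop("replicate_cv must be non-negative")
  if (length(core_genes) + length(general_genes) > screen_n_genes)
    stop("core_genes and general_genes must fit within screen_n_genes")
  if (length(dose_response_params) == 0)
    stop("dose_response_params must be non-empty")
  for (p in cfg$dose_response_params)
    if (any(p <= 0)) stop("dose-response Dm and m must be positive")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (seed ", x$seed, "): ",
      x$n_baits, " baits x ", x$n_prey_per_bait, " prey, ",
      x$phospho_n_sites, " phosphosites, ",
      x$screen_n_lines, " cell lines (", x$screen_n_mutant, " mutant), ",
      x$drug_n_compounds, " compounds\n", sep = "")
  invisible(x)
}

#' Alias table for readable demos
#'
#' Maps the first synthetic bait/gene identifiers to familiar protein
#' names from EGFR signalling. Cosmetic only: no pipeline logic depends on
#' these names.
#'
#' @return data.frame with columns `synthetic`, `alias`
#' @export
demo_aliases <- function() {
  data.frame(
    synthetic = c(sprintf("BAIT%02d", 1:7), sprintf("CORE%02d", 1:5)),
    alias = c("EGFR", "GRB2", "SHC1", "ERBB2", "ERBB3", "CDC37", "GRP78",
              "EGFR", "GRB2", "SHC1", "ARHG5", "MK12"),
    stringsAsFactors = FALSE)
}

## Ground truth ---------------------------------------------------------------

.new_truth <- function(...) {
  structure(list(...), class = "oncoint_truth")
}

#' @export
print.oncoint_truth <- function(x, ...) {
  cat("planted ground truth:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    n <- if (is.data.frame(v)) nrow(v) else length(v)
    cat("  ", nm, ": ", n, " entr", if (n == 1) "y" else "ies", "\n", sep = "")
  }
  invisible(x)
}

#' Serialize ground truth to JSON
#'
#' @param truth an `oncoint_truth`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
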