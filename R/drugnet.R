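## Drug-target filtering, allele matching, bipartite drug network
## construction, and compound ranking by network diffusion of kinase-screen
## values.

#' Filter drug-target records by source-specific affinity cutoffs
#'
#' Keeps competition-assay and kinase-assay `Kd` records with value
#' < 100 nM, BindingDB `Ki`/`Kd`/`IC50`/`EC50` records with value < 10 nM
#' (strict inequalities), and DrugBank records by presence (no comparable
#' affinity; tagged low confidence). Percent-inhibition records are never
#' passed by the filter (they feed [diffusion_rank()] instead). Records
#' with an unknown source are skipped with one warning.
#'
#' @param records data.frame with columns compound_id, target_protein,
#'   allele, affinity_type, value_nM, source
#' @param kd_cutoff_nM cutoff for the two assay databases (default 100)
#' @param bindingdb_cutoff_nM cutoff for BindingDB (default 10)
#' @return the filtered records, with a `low_confidence` column (TRUE for
#'   DrugBank rows)
#' @export
filter_records <- function(records, kd_cutoff_nM = 100,
                           bindingdb_cutoff_nM = 10) {
  if (any(records$value_nM < 0, na.rm = TRUE))
    stop("affinity values must be non-negative")
  known <- c("competition_assay", "kinase_assay", "bindingdb", "drugbank")
  bad <- !(records$source %in% known)
  if (any(bad))
    warning(sum(bad), " record(s) with unknown source skipped: ",
            paste(unique(records$source[bad]), collapse = ", "))
  r <- records[!bad, , drop = FALSE]
  keep <- logical(nrow(r))
  assay <- r$source %in% c("competition_assay", "kinase_assay")
  keep[assay] <- r$affinity_type[assay] == "Kd" &
    r$value_nM[assay] < kd_cutoff_nM
  bdb <- r$source == "bindingdb"
  keep[bdb] <- r$affinity_type[bdb] %in% c("Ki", "Kd", "IC50", "EC50") &
    r$value_nM[bdb] < bindingdb_cutoff_nM
  keep[r$source == "drugbank"] <- TRUE
  keep[r$affinity_type == "percent_inhibition"] <- FALSE
  out <- r[keep, , drop = FALSE]
  out$low_confidence <- out$source == "drugbank"
  rownames(out) <- NULL
  out
}

#' Select records matching a target protein and allele
#'
#' A wild-type query (empty or `NA` allele) matches only records without
#' an allele tag; an allele query (e.g. `"T790M"`) matches only records
#' carrying exactly that tag.
#'
#' @param records drug-target records
#' @param protein target protein identifier
#' @param allele variant tag, or `""`/`NA` for wild type
#' @return the matching records
#' @export
allele_match <- function(records, protein, allele = "") {
  al <- records$allele
  al[is.na(al)] <- ""
  if (is.na(allele)) allele <- ""
  out <- records[records$target_protein == protein & al == allele, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the bipartite drug-protein network over core proteins
#'
#' @param records filtered drug-target records (see [filter_records()])
#' @param core_proteins protein identifiers of the core network
#' @param specific optional character vector of core proteins tagged as
#'   mutant-specific (others are tagged general)
#' @return list with `edges` (compound_id, target_protein, value_nM,
#'   source), `proteins` (protein, specificity, n_compounds, pct_compounds:
#'   distinct linked compounds as a percentage of all distinct compounds;
#'   percentages need not sum to 100 because compounds are multi-target),
#'   `compounds` (distinct compound identifiers)
#' @export
build_drug_network <- function(records, core_proteins,
                               specific = character()) {
  e <- records[records$target_protein %in% core_proteins, , drop = FALSE]
  e <- e[!duplicated(paste(e$compound_id, e$target_protein)), , drop = FALSE]
  compounds <- sort(unique(e$compound_id))
  n_tot <- length(compounds)
  per <- vapply(core_proteins, function(p)
    length(unique(e$compound_id[e$target_protein == p])), integer(1))
  proteins <- data.frame(
    protein = core_proteins,
    specificity = ifelse(core_proteins %in% specific, "specific", "general"),
    n_compounds = per,
    pct_compounds = if (n_tot > 0) 100 * per / n_tot else 0,
    stringsAsFactors = FALSE)
  rownames(proteins) <- NULL
  e <- e[order(e$compound_id, e$target_protein),
         intersect(c("compound_id", "target_protein", "value_nM", "source"),
                   names(e)), drop = FALSE]
  rownames(e) <- NULL
  list(edges = e, proteins = proteins, compounds = compounds)
}

#' Rank compounds against kinases by network diffusion of screening values
#'
#' The score of compound `c` against kinase `k` diffuses the compound's
#' measured screening values (e.g. percent inhibition) over the
#' EGFR-specific interaction network with an exponential-decay
#' shortest-path kernel:
#' `score(c, k) = sum over measured kinases k' of value(c, k') *
#' alpha^d(k, k')`, where `d` is the unweighted shortest-path distance and
#' unreachable pairs contribute 0 (`alpha^Inf = 0`). A distance-0
#' contribution carries weight 1, so a kinase's own measurement is
#' recovered undamped. This kernel is a reconstruction: the simplest model
#' in which a compound scores highly against a kinase when it strongly
#' inhibits that kinase's close network neighbours.
#'
#' @param net an [interactome()] (or igraph graph) restricted to the
#'   profiled kinases and their connecting proteins
#' @param screening data.frame with columns compound_id, kinase, value;
#'   kinases absent from the network contribute nothing
#' @param alpha decay per network step, in (0, 1); default 0.5
#' @param targets kinases to score (default: all network nodes)
#' @return data.frame with compound_id, target, score; ordered by compound
#'   then score descending
#' @export
diffusion_rank <- function(net, screening, alpha = 0.5, targets = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  g <- if (inherits(net, "interactome")) as_igraph(net) else net
  nodes <- igraph::V(g)$name
  if (is.null(targets)) targets <- nodes
  stopifnot(all(targets %in% nodes))
  meas <- screening[screening$kinase %in% nodes, , drop = FALSE]
  if (nrow(meas) == 0) {
    res <- expand.grid(compound_id = sort(unique(screening$compound_id)),
                       target = targets, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    res$score <- 0
    return(res[order(res$compound_id, res$target), , drop = FALSE])
  }
  d <- igraph::distances(g, v = targets,
                         to = unique(meas$kinase), mode = "all")
  w <- alpha^d  # alpha^Inf == 0: unreachable measurements contribute nothing
  out <- lapply(sort(unique(screening$compound_id)), function(cmp) {
    mc <- meas[meas$compound_id == cmp, , drop = FALSE]
    v <- setNames(rep(0, ncol(w)), colnames(w))
    if (nrow(mc)) {
      agg <- vapply(split(mc$value, mc$kinase), mean, numeric(1))
      v[names(agg)] <- agg
    }
    data.frame(compound_id = cmp, target = targets,
               score = as.numeric(w %*% v), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$compound_id, -res$score, res$target), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select candidate compound-target pairs above a score percentile
#'
#' @param scores output of [diffusion_rank()]
#' @param percentile keep pairs at or above this score quantile
#'   (default 0.95, i.e. top 5%)
#' @return the selected rows
#' @export
top_candidates <- function(scores, percentile = 0.95) {
  cut <- stats::quantile(scores$score, percentile, names = FALSE)
  out <- scores[scores$score >= cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}
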