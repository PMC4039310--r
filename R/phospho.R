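## Phosphosite perturbation scoring and PPI-based network extension.
##
## Per site and per state (phosphorylated / non-phosphorylated), treated vs
## control spectral counts are tested with a 1-degree-of-freedom Pearson
## goodness-of-fit statistic; the two state P-values are multiplied and a
## product cutoff (default 0.1) selects perturbed sites. Significant
## phosphoproteins absent from the TAP network are attached through
## reference protein-protein interactions.

.state_pvalue <- function(obs, expected_frac, yates = FALSE) {
  tot <- sum(obs)
  if (tot == 0) return(list(stat = 0, p = 1))
  e <- tot * expected_frac
  dev <- abs(obs - e)
  if (yates) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / e)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Score phosphosite perturbation from spectral counts
#'
#' For each state the observed (treated, control) counts are compared to
#' expected counts allocated by `allocation`: `"runs"` (default) splits the
#' state total proportionally to the number of runs per condition (equal
#' runs gives a 50/50 split); `"load"` splits proportionally to each
#' condition's total spectral load across both states. The per-state
#' statistic is Pearson's sum((O-E)^2/E) with 1 df; a state with zero total
#' count gets P = 1 (no evidence). The site score is the product of the two
#' state P-values.
#'
#' @param n_treated_phos,n_control_phos spectra containing the
#'   phosphorylated site, treated / control
#' @param n_treated_nonphos,n_control_nonphos spectra covering the site
#'   unphosphorylated, treated / control
#' @param n_runs_treated,n_runs_control runs pooled per condition
#' @param allocation expected-count allocation rule
#' @param yates apply a continuity correction (off by default)
#' @return list with `p_phos`, `p_nonphos`, `score`, `chisq_phos`,
#'   `chisq_nonphos`
#' @export
site_perturbation_score <- function(n_treated_phos, n_control_phos,
                                    n_treated_nonphos, n_control_nonphos,
                                    n_runs_treated = 1, n_runs_control = 1,
                                    allocation = c("runs", "load"),
                                    yates = FALSE) {
  allocation <- match.arg(allocation)
  counts <- c(n_treated_phos, n_control_phos,
              n_treated_nonphos, n_control_nonphos)
  if (any(counts < 0)) stop("spectral counts must be non-negative")
  if (allocation == "runs") {
    frac <- c(n_runs_treated, n_runs_control) /
      (n_runs_treated + n_runs_control)
  } else {
    load_t <- n_treated_phos + n_treated_nonphos
    load_c <- n_control_phos + n_control_nonphos
    frac <- if (load_t + load_c == 0) c(0.5, 0.5) else
      c(load_t, load_c) / (load_t + load_c)
  }
  ph <- .state_pvalue(c(n_treated_phos, n_control_phos), frac, yates)
  np <- .state_pvalue(c(n_treated_nonphos, n_control_nonphos), frac, yates)
  list(p_phos = ph$p, p_nonphos = np$p, score = ph$p * np$p,
       chisq_phos = ph$stat, chisq_nonphos = np$stat)
}

#' Call significantly perturbed phosphosites
#'
#' Scores every row of a phospho count table and flags sites whose
#' P-value product is at or below `threshold` (inclusive boundary). The
#' raw product cutoff is used without multiple-testing correction;
#' `adjust = "BH"` optionally applies Benjamini-Hochberg to the scores
#' before thresholding.
#'
#' @param counts data.frame with columns protein_id, site, n_treated_phos,
#'   n_control_phos, n_treated_nonphos, n_control_nonphos and optionally
#'   n_runs_treated, n_runs_control
#' @param threshold score cutoff in (0, 1]
#' @param adjust `"none"` (default) or `"BH"`
#' @inheritParams site_perturbation_score
#' @return data.frame with protein_id, site, p_phos, p_nonphos, score,
#'   significant; ordered by score ascending, ties by (protein, site)
#' @export
call_significant_sites <- function(counts, threshold = 0.1,
                                   allocation = c("runs", "load"),
                                   yates = FALSE, adjust = c("none", "BH")) {
  allocation <- match.arg(allocation)
  adjust <- match.arg(adjust)
  stopifnot(threshold > 0, threshold <= 1)
  rt <- if ("n_runs_treated" %in% names(counts)) counts$n_runs_treated else 1
  rc <- if ("n_runs_control" %in% names(counts)) counts$n_runs_control else 1
  rt <- rep_len(rt, nrow(counts)); rc <- rep_len(rc, nrow(counts))
  res <- vapply(seq_len(nrow(counts)), function(i) {
    s <- site_perturbation_score(counts$n_treated_phos[i],
                                 counts$n_control_phos[i],
                                 counts$n_treated_nonphos[i],
                                 counts$n_control_nonphos[i],
                                 rt[i], rc[i], allocation, yates)
    c(s$p_phos, s$p_nonphos, s$score)
  }, numeric(3))
  out <- data.frame(protein_id = counts$protein_id, site = counts$site,
                    p_phos = res[1, ], p_nonphos = res[2, ],
                    score = res[3, ], stringsAsFactors = FALSE)
  crit <- if (adjust == "BH") stats::p.adjust(out$score, "BH") else out$score
  out$significant <- crit <= threshold
  out <- out[order(out$score, out$protein_id, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend a TAP network with perturbed phosphoproteins
#'
#' Significant sites on proteins already in the network become node
#' annotations (appended to the `sites` field). Significant proteins not in
#' the network are added with role `pY-added` and one database-evidence
#' edge to every TAP-network protein they interact with in the PPI
#' reference; proteins with no PPI link to any network protein are not
#' added. No node or edge is ever removed.
#'
#' @param net an [interactome()]
#' @param sites result of [call_significant_sites()]; only rows with
#'   `significant == TRUE` are used
#' @param ppi a [ppi_reference()]
#' @return the extended [interactome()]
#' @export
extend_network <- function(net, sites, ppi) {
  stopifnot(inherits(net, "interactome"))
  sig <- sites[sites$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(net)
  tap_prot <- net$nodes$protein
  nodes <- net$nodes
  edges <- net$edges
  add_sites <- function(existing, new) {
    s <- sort(unique(c(new, Filter(nzchar, strsplit(existing, ";")[[1]]))))
    paste(s, collapse = ";")
  }
  for (p in unique(sig$protein_id)) {
    psites <- sig$site[sig$protein_id == p]
    if (p %in% tap_prot) {
      i <- match(p, nodes$protein)
      nodes$sites[i] <- add_sites(nodes$sites[i], psites)
    } else {
      partners <- intersect(ppi_neighbors(ppi, p), tap_prot)
      if (length(partners) == 0) next
      nodes <- rbind(nodes, data.frame(protein = p, role = "pY-added",
                                       sites = add_sites("", psites),
                                       stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(from = p, to = partners,
                                       evidence = "database",
                                       support = NA_real_,
                                       stringsAsFactors = FALSE))
    }
  }
  interactome(nodes, edges)
}
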