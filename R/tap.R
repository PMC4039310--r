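## TAP-MS network assembly: isoform collapsing, protein grouping by shared
## peptides, control (GFP) subtraction, and bait-prey network construction.

.split_ids <- function(x) strsplit(x, ";", fixed = TRUE)

#' Collapse protein isoforms in a peptide-evidence table
#'
#' Strips numeric isoform suffixes (UniProt style, e.g. `P04637-2`) from
#' every protein identifier and merges rows that become identical, summing
#' spectral counts per (run, peptide, protein set).
#'
#' @param evidence data.frame with columns run_id, peptide_id, protein_ids
#'   (";"-separated), spectral_count (and optionally phospho_state)
#' @param delimiter isoform suffix delimiter (default `"-"`); only a
#'   trailing `<delimiter><digits>` is removed, so identifiers containing
#'   the delimiter elsewhere are untouched
#' @return the collapsed evidence table
#' @export
collapse_isoforms <- function(evidence, delimiter = "-") {
  if (nrow(evidence) == 0) return(evidence)
  if (any(evidence$spectral_count < 0)) stop("negative spectral counts")
  pat <- paste0("\\Q", delimiter, "\\E[0-9]+$")
  stripped <- lapply(.split_ids(evidence$protein_ids), function(ids)
    sort(unique(sub(pat, "", ids, perl = TRUE))))
  key_prot <- vapply(stripped, paste, "", collapse = ";")
  key <- paste(evidence$run_id, evidence$peptide_id, key_prot, sep = "\r")
  agg <- rowsum(evidence$spectral_count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- evidence[first, , drop = FALSE]
  out$protein_ids <- key_prot[first]
  out$spectral_count <- as.integer(agg[match(key[first], rownames(agg)), 1])
  rownames(out) <- NULL
  out
}

#' Group proteins by shared peptides and discard non-specific proteins
#'
#' Evidence from all replicate runs of one pulldown is pooled; proteins
#' with identical peptide sets are merged into one group named after the
#' lexicographically smallest member. A peptide is specific to a group when
#' it maps only to members of that group. Groups without any specific
#' peptide, and groups with fewer than `min_peptides` distinct peptides,
#' are discarded.
#'
#' @param evidence pooled peptide-evidence data.frame (see
#'   [collapse_isoforms()] for columns)
#' @param min_peptides minimum distinct peptides per retained group
#'   (default 2)
#' @return data.frame of class `protein_groups` with columns group_id,
#'   members (";"), specific_peptides (";"), n_peptides,
#'   total_spectral_count; sorted by total count descending, ties by
#'   group_id
#' @export
group_proteins <- function(evidence, min_peptides = 2) {
  empty <- data.frame(group_id = character(), members = character(),
                      specific_peptides = character(),
                      n_peptides = integer(),
                      total_spectral_count = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("protein_groups", "data.frame")
  if (is.null(evidence) || nrow(evidence) == 0) return(empty)

  prot_lists <- .split_ids(evidence$protein_ids)
  long <- data.frame(
    peptide = rep(evidence$peptide_id, lengths(prot_lists)),
    protein = unlist(prot_lists),
    count = rep(evidence$spectral_count, lengths(prot_lists)),
    stringsAsFactors = FALSE)
  ## peptide -> full protein set (pooled over runs)
  pep_prot <- lapply(split(long$protein, long$peptide),
                     function(p) sort(unique(p)))
  ## protein -> peptide set
  prot_pep <- lapply(split(long$peptide, long$protein),
                     function(p) sort(unique(p)))
  ## per-peptide pooled count (each spectral-count row counted once)
  pep_count <- vapply(split(evidence$spectral_count, evidence$peptide_id),
                      sum, numeric(1))

  ## merge proteins with identical peptide sets
  sig <- vapply(prot_pep, paste, "", collapse = "\r")
  groups <- split(names(prot_pep), sig)
  out <- lapply(groups, function(members) {
    members <- sort(members)
    peps <- prot_pep[[members[1]]]
    specific <- peps[vapply(pep_prot[peps],
                            function(s) all(s %in% members), TRUE)]
    if (length(specific) == 0 || length(peps) < min_peptides) return(NULL)
    data.frame(group_id = members[1],
               members = paste(members, collapse = ";"),
               specific_peptides = paste(specific, collapse = ";"),
               n_peptides = length(peps),
               total_spectral_count = as.integer(sum(pep_count[peps])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out <- out[order(-out$total_spectral_count, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_groups", "data.frame")
  out
}

.group_members <- function(groups) {
  if (is.null(groups) || nrow(groups) == 0) return(character())
  unique(unlist(.split_ids(groups$members)))
}

#' Remove non-specific binders seen in control pulldowns
#'
#' Any protein appearing (as a group member) in the union of the control
#' pulldowns is removed from every bait pulldown; a bait group is dropped
#' when any of its members matches a control protein. Removal is by
#' identity, so isoforms must be collapsed before grouping.
#'
#' @param bait_groups a `protein_groups` data.frame or a named list of them
#'   (one per bait pulldown)
#' @param control_groups a `protein_groups` data.frame or list of them
#'   (control pulldowns to pool)
#' @return same shape as `bait_groups`, filtered
#' @export
subtract_background <- function(bait_groups, control_groups) {
  single <- is.data.frame(bait_groups)
  if (single) bait_groups <- list(bait_groups)
  if (is.data.frame(control_groups)) control_groups <- list(control_groups)
  ctrl <- unique(unlist(lapply(control_groups, .group_members)))
  res <- lapply(bait_groups, function(g) {
    if (is.null(g) || nrow(g) == 0) return(g)
    hit <- vapply(.split_ids(g$members),
                  function(m) any(m %in% ctrl), TRUE)
    out <- g[!hit, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  if (single) res[[1]] else res
}

#' Build the bait-prey interaction network
#'
#' One node per bait and per retained prey group (prey nodes take the
#' group's representative identifier); a prey also used as a bait keeps the
#' bait role. One TAP edge per (bait, prey) with support summed over that
#' bait's pulldowns (replicate runs are pooled at grouping time; multiple
#' cell lines sum here). Self-retrievals (the bait appearing among a prey
#' group's members) are dropped.
#'
#' @param pulldowns named list of background-subtracted `protein_groups`,
#'   one per bait pulldown
#' @param baits bait identifier per list entry (default `names(pulldowns)`;
#'   duplicated names merge cell lines)
#' @return an [interactome()]
#' @export
build_network <- function(pulldowns, baits = names(pulldowns)) {
  if (length(pulldowns) == 0) return(interactome())
  stopifnot(length(baits) == length(pulldowns))
  edges <- list()
  for (i in seq_along(pulldowns)) {
    g <- pulldowns[[i]]
    if (is.null(g) || nrow(g) == 0) next
    self <- vapply(.split_ids(g$members), function(m) baits[i] %in% m, TRUE)
    g <- g[!self, , drop = FALSE]
    if (nrow(g) == 0) next
    edges[[length(edges) + 1L]] <- data.frame(
      from = baits[i], to = g$group_id,
      support = g$total_spectral_count, stringsAsFactors = FALSE)
  }
  ubaits <- unique(baits)
  if (length(edges) == 0) {
    nodes <- data.frame(protein = ubaits, role = "bait",
                        stringsAsFactors = FALSE)
    return(interactome(nodes))
  }
  e <- do.call(rbind, edges)
  key <- paste(e$from, e$to, sep = "\r")
  supp <- rowsum(e$support, key, reorder = FALSE)
  first <- !duplicated(key)
  e <- e[first, , drop = FALSE]
  e$support <- as.numeric(supp[match(key[first], rownames(supp)), 1])
  e$evidence <- "TAP"
  prey <- setdiff(unique(e$to), ubaits)
  nodes <- data.frame(protein = c(ubaits, prey),
                      role = c(rep("bait", length(ubaits)),
                               rep("prey", length(prey))),
                      stringsAsFactors = FALSE)
  interactome(nodes, e[, c("from", "to", "evidence", "support")])
}

#' Filter network nodes by functional annotation
#'
#' @param net an [interactome()]
#' @param annotation data.frame with columns `protein` and `category`
#'   (one row per protein-category pair)
#' @param categories category labels to keep
#' @return character vector of node identifiers with at least one matching
#'   annotation, in network node order. Category labels absent from the
#'   annotation table trigger a warning and match nothing.
#' @export
annotation_filter <- function(net, annotation, categories) {
  stopifnot(inherits(net, "interactome"))
  if (length(categories) == 0) return(character())
  unknown <- setdiff(categories, unique(annotation$category))
  if (length(unknown))
    warning("unknown annotation categories: ",
            paste(unknown, collapse = ", "))
  keep <- unique(annotation$protein[annotation$category %in% categories])
  net$nodes$protein[net$nodes$protein %in% keep]
}

#' Run the full TAP assembly on evidence and manifest tables
#'
#' Collapses isoforms, pools replicate runs per pulldown (bait x cell
#' line), groups proteins, subtracts the control union (global by default,
#' per cell line with `per_line_controls = TRUE`) and builds the network.
#'
#' @param evidence peptide-evidence data.frame
#' @param manifest pulldown manifest (run_id, bait_id, cell_line,
#'   replicate, is_control)
#' @param min_peptides passed to [group_proteins()]
#' @param per_line_controls subtract only same-cell-line controls
#' @param delimiter isoform delimiter
#' @return list with `network` (an [interactome()]) and `pulldowns` (the
#'   filtered per-pulldown `protein_groups`)
#' @export
tap_pipeline <- function(evidence, manifest, min_peptides = 2,
                         per_line_controls = FALSE, delimiter = "-") {
  stopifnot(all(evidence$run_id %in% manifest$run_id))
  if (!any(manifest$is_control))
    stop("at least one control pulldown is required")
  ev <- collapse_isoforms(evidence, delimiter = delimiter)
  info <- manifest[match(ev$run_id, manifest$run_id), ]
  pd_key <- paste(info$bait_id, info$cell_line, sep = "\r")
  is_ctrl <- info$is_control
  bait_keys <- sort(unique(pd_key[!is_ctrl]))
  ctrl_keys <- sort(unique(pd_key[is_ctrl]))
  grp <- function(keys, ctrl) lapply(keys, function(k)
    group_proteins(ev[pd_key == k & is_ctrl == ctrl, , drop = FALSE],
                   min_peptides = min_peptides))
  bait_groups <- grp(bait_keys, FALSE)
  ctrl_groups <- grp(ctrl_keys, TRUE)
  names(bait_groups) <- bait_keys
  names(ctrl_groups) <- ctrl_keys
  if (per_line_controls) {
    line_of <- function(k) sub("^.*\r", "", k)
    filtered <- lapply(bait_keys, function(k)
      subtract_background(bait_groups[[k]],
                          ctrl_groups[line_of(ctrl_keys) == line_of(k)]))
  } else {
    filtered <- subtract_background(bait_groups, ctrl_groups)
  }
  baits <- sub("\r.*$", "", bait_keys)
  list(network = build_network(filtered, baits = baits),
       pulldowns = setNames(filtered, paste(baits,
                                            sub("^.*\r", "", bait_keys),
                                            sep = ".")))
}
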