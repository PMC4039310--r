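# Small in-code fixtures and independent oracles used across test files.

# Build a peptide-evidence table from a compact spec:
#   rows: list of c(run, peptide, "P1;P2", count)
make_evidence <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(run_id = r[[1]], peptide_id = r[[2]], protein_ids = r[[3]],
               spectral_count = as.integer(r[[4]]), phospho_state = 0L,
               stringsAsFactors = FALSE)))
}

# Build a tiny viability screen. `values` is a named list
# line -> list(gene -> replicate vector); `controls` line -> vector.
make_screen <- function(values, controls, groups = NULL) {
  rows <- list()
  for (line in names(values)) {
    for (g in names(values[[line]])) {
      v <- values[[line]][[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = line, gene = g, replicate = seq_along(v), readout = v,
        is_control = FALSE, stringsAsFactors = FALSE)
    }
    cv <- controls[[line]]
    rows[[length(rows) + 1L]] <- data.frame(
      cell_line = line, gene = "NON_TARGETING", replicate = seq_along(cv),
      readout = cv, is_control = TRUE, stringsAsFactors = FALSE)
  }
  if (is.null(groups))
    groups <- setNames(rep("mutant", length(values)), names(values))
  meta <- data.frame(cell_line = names(values),
                     group = unname(groups[names(values)]),
                     stringsAsFactors = FALSE)
  viability_screen(do.call(rbind, rows), meta)
}

# Independent brute-force 1-df Pearson statistic for a 2-cell state
# (treated, control) against a 50/50 expected split.
brute_chisq <- function(t, c) {
  tot <- t + c
  if (tot == 0) return(0)
  e <- tot / 2
  (t - e)^2 / e + (c - e)^2 / e
}

# Independent two-sided rank-sum p by exhaustive enumeration of all
# choose(n1+n2, n1) group assignments of the pooled observations.
enum_ranksum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(r), n1)
  Wp <- colSums(matrix(r[idx], nrow = n1))
  eps <- sqrt(.Machine$double.eps)
  min(1, 2 * min(mean(Wp <= W + eps), mean(Wp >= W - eps)))
}

# Independent all-pairs unweighted shortest paths by hand-coded BFS over
# an edge list (data.frame from/to), for graphs small enough to enumerate.
bfs_distances <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character()
      for (u in frontier) for (v in adj[[u]])
        if (is.infinite(d[s, v])) { d[s, v] <- d[s, u] + 1; nxt <- c(nxt, v) }
      frontier <- unique(nxt)
    }
  }
  d
}
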