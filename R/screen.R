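## RNAi screen analysis: normalization to non-targeting controls, hit
## calling (>50% inhibition + t-test), multi-line core network, resistant
## pair comparisons, and mutant-vs-wild-type rank-sum specificity.

#' Construct a viability screen object
#'
#' @param readings data.frame with columns cell_line, gene, replicate,
#'   readout, is_control (control rows are non-targeting wells)
#' @param meta data.frame with columns cell_line, group (`"mutant"` /
#'   `"wild-type"`) and optionally resistance
#' @param readout_kind `"viability"`, `"pERK"` or `"pAKT"`
#' @return a `viability_screen`
#' @export
viability_screen <- function(readings, meta,
                             readout_kind = c("viability", "pERK", "pAKT")) {
  readout_kind <- match.arg(readout_kind)
  stopifnot(all(c("cell_line", "gene", "replicate", "readout",
                  "is_control") %in% names(readings)),
            all(c("cell_line", "group") %in% names(meta)))
  if (!all(readings$cell_line %in% meta$cell_line))
    stop("readings reference cell lines absent from metadata")
  if (!"resistance" %in% names(meta)) meta$resistance <- "sensitive"
  structure(list(readings = readings, meta = meta,
                 readout_kind = readout_kind),
            class = "viability_screen")
}

#' Normalize a screen to its non-targeting controls
#'
#' Every reading of a cell line (controls included) is divided by that
#' line's control-well mean, so controls normalize to mean 1. The
#' operation is idempotent.
#'
#' @param screen a [viability_screen()]
#' @return the normalized screen (attribute `normalized` set)
#' @export
normalize_screen <- function(screen) {
  stopifnot(inherits(screen, "viability_screen"))
  r <- screen$readings
  for (line in unique(r$cell_line)) {
    ctrl <- r$readout[r$cell_line == line & r$is_control]
    if (length(ctrl) == 0)
      stop("configuration error: no control wells for cell line ", line)
    cm <- mean(ctrl)
    if (!is.finite(cm) || cm <= 0)
      stop("non-positive control mean for cell line ", line)
    r$readout[r$cell_line == line] <- r$readout[r$cell_line == line] / cm
  }
  screen$readings <- r
  attr(screen, "normalized") <- TRUE
  screen
}

## Equal-variance two-sample t-test p-value, robust to degenerate
## zero-variance inputs (identical values -> p = 1; separated constants
## -> p = 0).
.t_pvalue <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  t.test(x, y, var.equal = TRUE)$p.value
}

#' Call viability hits per cell line and gene
#'
#' A gene is a hit in a line when inhibition of viability exceeds
#' `inhibition_threshold` (default >50%) and a Student's t-test P-value is
#' below `alpha` (default 0.05, strict). The default test compares the
#' gene's normalized replicates against the line's normalized control
#' replicates (equal-variance two-sample); `mode = "one-sample"` tests
#' against 1.0 instead.
#'
#' @param screen a normalized [viability_screen()]
#' @param inhibition_threshold minimum inhibition (1 - mean viability)
#' @param alpha t-test significance level
#' @param mode `"two-sample"` (default) or `"one-sample"`
#' @return data.frame with cell_line, gene, mean_viability, inhibition,
#'   p_value, is_hit. Genes with fewer than 2 replicates are skipped with
#'   one warning.
#' @export
call_hits <- function(screen, inhibition_threshold = 0.5, alpha = 0.05,
                      mode = c("two-sample", "one-sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(screen, "viability_screen"))
  if (!isTRUE(attr(screen, "normalized")))
    screen <- normalize_screen(screen)
  r <- screen$readings
  out <- list()
  skipped <- 0L
  for (line in unique(r$cell_line)) {
    rl <- r[r$cell_line == line, ]
    ctrl <- rl$readout[rl$is_control]
    genes <- sort(unique(rl$gene[!rl$is_control]))
    for (g in genes) {
      v <- rl$readout[rl$gene == g & !rl$is_control]
      if (length(v) < 2) { skipped <- skipped + 1L; next }
      p <- if (mode == "two-sample") .t_pvalue(v, ctrl) else
        if (stats::sd(v) == 0) {
          if (isTRUE(all.equal(mean(v), 1))) 1 else 0
        } else t.test(v, mu = 1)$p.value
      mv <- mean(v)
      out[[length(out) + 1L]] <- data.frame(
        cell_line = line, gene = g, mean_viability = mv,
        inhibition = 1 - mv, p_value = p,
        is_hit = (1 - mv) > inhibition_threshold && p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(skipped, " gene(s) skipped with fewer than 2 replicates")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-line hit gene sets from a hit table
#'
#' @param hits output of [call_hits()]
#' @return named list of sorted hit-gene vectors, one per cell line
#' @export
hit_sets <- function(hits) {
  lapply(split(hits, hits$cell_line),
         function(h) sort(h$gene[h$is_hit]))
}

#' Core network: genes hit in every cell line
#'
#' @param sets list (>= 2) of per-line hit gene sets
#' @return sorted character vector, the exact intersection
#' @export
core_network <- function(sets) {
  if (length(sets) < 2) stop("core network needs at least 2 cell lines")
  sort(Reduce(intersect, sets))
}

#' Overlap partition of a sensitive/resistant hit-set pair
#'
#' @param parent_hits,resistant_hits hit gene sets
#' @return list with `shared`, `parent_only`, `resistant_only`: three
#'   disjoint sorted sets partitioning the union
#' @export
pair_overlap <- function(parent_hits, resistant_hits) {
  list(shared = sort(intersect(parent_hits, resistant_hits)),
       parent_only = sort(setdiff(parent_hits, resistant_hits)),
       resistant_only = sort(setdiff(resistant_hits, parent_hits)))
}

#' Genes with stronger knockdown effect in a resistant line
#'
#' Reconstruction of the "more effect in resistant cells" comparison:
#' reports genes whose resistant-line mean viability is below the parent
#' mean by more than `min_delta` with a directional two-sample t-test
#' P-value below `alpha`.
#'
#' @param screen a normalized [viability_screen()]
#' @param parent,resistant cell line identifiers
#' @param alpha significance level
#' @param min_delta minimum viability difference (fraction of control)
#' @return data.frame with gene, parent_mean, resistant_mean, delta,
#'   p_value for the reported genes (possibly 0 rows)
#' @export
resistant_gain <- function(screen, parent, resistant, alpha = 0.05,
                           min_delta = 0.15) {
  stopifnot(inherits(screen, "viability_screen"))
  if (!isTRUE(attr(screen, "normalized")))
    screen <- normalize_screen(screen)
  r <- screen$readings[!screen$readings$is_control, ]
  genes <- sort(intersect(r$gene[r$cell_line == parent],
                          r$gene[r$cell_line == resistant]))
  out <- list()
  for (g in genes) {
    vp <- r$readout[r$cell_line == parent & r$gene == g]
    vr <- r$readout[r$cell_line == resistant & r$gene == g]
    if (length(vp) < 2 || length(vr) < 2) next
    if (mean(vr) >= mean(vp) - min_delta) next
    p <- .t_pvalue(vr, vp)
    if (is.na(p) || p >= alpha) next
    out[[length(out) + 1L]] <- data.frame(
      gene = g, parent_mean = mean(vp), resistant_mean = mean(vr),
      delta = mean(vp) - mean(vr), p_value = p, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), parent_mean = numeric(),
               resistant_mean = numeric(), delta = numeric(),
               p_value = numeric())
  rownames(res) <- NULL
  res
}

## Two-sided Wilcoxon rank-sum p-value. Exact (classical null distribution
## via pwilcox) when both groups are <= exact_max and the data are free of
## ties; exact by permutation enumeration for small tied samples; normal
## approximation with tie correction otherwise (no continuity correction).
.ranksum_p <- function(x, y, exact_max = 10, enum_max = 12) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    return(min(1, p))
  }
  if (ties && n1 + n2 <= enum_max) {
    idx <- combn(n1 + n2, n1)
    Wp <- colSums(matrix(r[idx], nrow = n1))
    eps <- sqrt(.Machine$double.eps)
    p <- 2 * min(mean(Wp <= W + eps), mean(Wp >= W - eps))
    return(min(1, p))
  }
  n <- n1 + n2
  t <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Two-sided Wilcoxon rank-sum P-value
#'
#' Exact via the classical null distribution when both groups have at most
#' `exact_max` observations and no ties; exact by permutation enumeration
#' for tied samples of combined size at most `enum_max`; otherwise a
#' normal approximation with tie correction. The two-sided P-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))` for the observed rank sum `w`.
#'
#' @param x,y numeric samples
#' @param exact_max,enum_max mode-switch sizes
#' @return the P-value
#' @export
ranksum_pvalue <- function(x, y, exact_max = 10, enum_max = 12) {
  .ranksum_p(x, y, exact_max = exact_max, enum_max = enum_max)
}

#' Mutant-vs-wild-type specificity test across a cell line panel
#'
#' Per gene, the per-line summaries (replicate mean viabilities) of the
#' mutant-labelled lines are compared with those of the wild-type lines by
#' a two-sided Wilcoxon rank-sum test: exact when both groups have at most
#' 10 lines (permutation-exact under ties), normal approximation with tie
#' correction otherwise. Tier labels: `"##"` for P < 0.01, `"#"` for
#' P < 0.05, `""` otherwise.
#'
#' @param screen a normalized [viability_screen()]; groups are taken from
#'   `screen$meta$group`
#' @return data.frame with gene, p_value, tier, lower_in_mutant
#' @export
specificity_test <- function(screen) {
  stopifnot(inherits(screen, "viability_screen"))
  if (!isTRUE(attr(screen, "normalized")))
    screen <- normalize_screen(screen)
  meta <- screen$meta
  mut <- meta$cell_line[meta$group == "mutant"]
  wt <- meta$cell_line[meta$group == "wild-type"]
  if (length(mut) < 2 || length(wt) < 2)
    stop("each group needs at least 2 cell lines")
  r <- screen$readings[!screen$readings$is_control, ]
  means <- stats::aggregate(readout ~ cell_line + gene, data = r, FUN = mean)
  genes <- sort(unique(means$gene))
  out <- lapply(genes, function(g) {
    mg <- means[means$gene == g, ]
    x <- mg$readout[mg$cell_line %in% mut]
    y <- mg$readout[mg$cell_line %in% wt]
    p <- .ranksum_p(x, y)
    data.frame(gene = g, p_value = p,
               tier = if (p < 0.01) "##" else if (p < 0.05) "#" else "",
               lower_in_mutant = mean(x) < mean(y),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman concordance between replicate screen days
#'
#' @param screen_day1,screen_day2 [viability_screen()] objects sharing
#'   (cell line, gene) keys
#' @return Spearman rank correlation of per-(line, gene) mean viabilities
#'   (average-rank tie handling)
#' @export
replicate_concordance <- function(screen_day1, screen_day2) {
  summarize <- function(s) {
    r <- s$readings[!s$readings$is_control, ]
    m <- stats::aggregate(readout ~ cell_line + gene, data = r, FUN = mean)
    setNames(m$readout, paste(m$cell_line, m$gene, sep = "\r"))
  }
  a <- summarize(screen_day1)
  b <- summarize(screen_day2)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3)
    stop("need at least 3 shared (cell line, gene) keys")
  cor(a[shared], b[shared], method = "spearman")
}

#' Gene-by-line matrix of mean viabilities
#'
#' @param screen a normalized [viability_screen()]
#' @param gene_order,line_order optional row/column orders (defaults:
#'   sorted)
#' @param tsv,png optional output paths; the PNG is a simple heat image
#' @return numeric matrix (genes x lines), invisibly returned after
#'   optional writing
#' @export
viability_heatmap <- function(screen, gene_order = NULL, line_order = NULL,
                              tsv = NULL, png = NULL) {
  stopifnot(inherits(screen, "viability_screen"))
  if (!isTRUE(attr(screen, "normalized")))
    screen <- normalize_screen(screen)
  r <- screen$readings[!screen$readings$is_control, ]
  m <- stats::aggregate(readout ~ gene + cell_line, data = r, FUN = mean)
  genes <- if (is.null(gene_order)) sort(unique(m$gene)) else gene_order
  lines <- if (is.null(line_order)) sort(unique(m$cell_line)) else line_order
  mat <- matrix(NA_real_, length(genes), length(lines),
                dimnames = list(genes, lines))
  mat[cbind(match(m$gene, genes), match(m$cell_line, lines))] <- m$readout
  if (!is.null(tsv))
    write_table_file(data.frame(gene = rownames(mat), mat,
                                check.names = FALSE), tsv)
  if (!is.null(png)) {
    grDevices::png(png, width = 640, height = 480)
    graphics::image(t(mat[rev(seq_len(nrow(mat))), , drop = FALSE]),
                    axes = FALSE, main = "mean viability")
    grDevices::dev.off()
  }
  invisible(mat)
}
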