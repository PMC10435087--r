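#' Average DNA-damage signal over genomic regions
#'
#' Base-pair-weighted mean of a piecewise-constant signal track over each
#' region (a gene span, or the union of a gene's CDS intervals): the sum of
#' `value x overlap width` divided by the region's total width, with
#' uncovered bases contributing zero. For a piecewise-constant track this
#' equals the scaled-region mean, and it is invariant to region length for
#' a constant track.
#'
#' @param track a `signal_track` data frame (see [read_bedgraph()]).
#' @param regions data frame with columns `region_id`, `chrom`, `start`,
#'   `end` (0-based half-open); multiple rows per `region_id` form a union.
#' @return data frame with columns `region_id`, `enrichment`, `width`.
#' @export
region_enrichment <- function(track, regions) {
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)))
  if (any(regions$end <= regions$start))
    stop("zero- or negative-width region")
  tr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end))
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  ov <- GenomicRanges::findOverlaps(rg, tr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  ow <- GenomicRanges::width(IRanges::pintersect(rg[qh], tr[sh]))
  signal <- numeric(nrow(regions))
  if (length(qh)) {
    contrib <- tapply(ow * track$value[sh], qh, sum)
    signal[as.integer(names(contrib))] <- as.numeric(contrib)
  }
  piece_w <- regions$end - regions$start
  ids <- unique(regions$region_id)
  tot_sig <- tapply(signal, regions$region_id, sum)[ids]
  tot_w <- tapply(piece_w, regions$region_id, sum)[ids]
  data.frame(region_id = ids,
             enrichment = as.numeric(tot_sig) / as.numeric(tot_w),
             width = as.numeric(tot_w),
             stringsAsFactors = FALSE)
}

#' Per-gene damage enrichment for each gene set
#'
#' Convenience wrapper: computes [region_enrichment()] over gene spans
#' (`level = "gene"`) or merged CDS unions (`level = "cds"`) and labels
#' each gene with the sets it belongs to (one output row per membership).
#'
#' @param track a `signal_track`.
#' @param genes a `gene_models` data frame.
#' @param sets named list of gene-symbol vectors.
#' @param level `"gene"` or `"cds"`.
#' @return data frame with columns `gene_id`, `gene_set`, `level`,
#'   `enrichment`.
#' @export
damage_by_set <- function(track, genes, sets, level = c("gene", "cds")) {
  level <- match.arg(level)
  if (level == "cds") genes <- genes[genes$cds_length > 0L, , drop = FALSE]
  regions <- if (level == "gene") {
    data.frame(region_id = genes$gene_id, chrom = genes$chrom,
               start = genes$start, end = genes$end,
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      m <- genes$cds_intervals[[i]]
      data.frame(region_id = genes$gene_id[i], chrom = genes$chrom[i],
                 start = m[, "start"], end = m[, "end"],
                 stringsAsFactors = FALSE)
    }))
  }
  enr <- region_enrichment(track, regions)
  sym2id <- stats::setNames(genes$gene_id, genes$symbol)
  rows <- lapply(names(sets), function(nm) {
    ids <- unname(sym2id[sets[[nm]]])
    ids <- ids[!is.na(ids)]
    j <- match(ids, enr$region_id)
    j <- j[!is.na(j)]
    if (!length(j)) return(NULL)
    data.frame(gene_id = enr$region_id[j], gene_set = nm, level = level,
               enrichment = enr$enrichment[j], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_group_list <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$enrichment, groups$gene_set)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, as.numeric)
}

#' One-way ANOVA across gene sets
#'
#' Classical equal-variance between/within decomposition; p-value from the
#' F distribution with (k - 1, N - k) degrees of freedom.
#'
#' @param groups named list of numeric vectors, or a data frame with
#'   columns `gene_set` and `enrichment`.
#' @return list with `statistic` (F), `df`, `p.value`.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df = unname(ft$parameter),
       p.value = unname(ft$p.value))
}

#' Pairwise contrasts after one-way ANOVA, FDR-adjusted
#'
#' All pairwise two-sample comparisons using the pooled ANOVA error
#' variance (model-based contrasts, N - k degrees of freedom), adjusted by
#' the Benjamini-Hochberg step-up procedure.
#'
#' @inheritParams one_way_anova
#' @return data frame with columns `group1`, `group2`, `t`, `p_value`,
#'   `p_adjusted`.
#' @export
pairwise_contrasts_fdr <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                          numeric(1)))
  sp2 <- ss_within / (N - k)
  pairs <- utils::combn(names(groups), 2L)
  tstat <- pval <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt(sp2 * (1 / ni[[a]] + 1 / ni[[b]]))
    tstat[j] <- if (se == 0) 0 else (means[[a]] - means[[b]]) / se
    pval[j] <- if (se == 0) 1 else 2 * stats::pt(-abs(tstat[j]), df = N - k)
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], t = tstat,
             p_value = pval,
             p_adjusted = stats::p.adjust(pval, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test across gene sets
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees
#' of freedom (via [stats::kruskal.test()]). Used for damage enrichment at
#' CDS level, where the values are not normally distributed.
#'
#' @inheritParams one_way_anova
#' @return list with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    stop("all values tied; Kruskal-Wallis statistic undefined")
  g <- factor(rep(names(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic),
       df = unname(kt$parameter),
       p.value = unname(kt$p.value))
}

#' Dunn's post-hoc test of pairwise mean-rank differences
#'
#' For each pair of groups, `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) *
#' (1/ni + 1/nj))` where `Ri` are mean ranks over the pooled sample and
#' `T = sum(t^3 - t) / (12 (N - 1))` corrects for ties. Two-sided normal
#' p-values, Benjamini-Hochberg adjusted by default (Bonferroni or none
#' selectable).
#'
#' @inheritParams one_way_anova
#' @param adjust `"BH"` (default), `"bonferroni"`, or `"none"`.
#' @return data frame with columns `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunns_test <- function(groups, adjust = c("BH", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- as_group_list(groups)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    stop("all values tied; Dunn's test undefined")
  g <- rep(names(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, g, mean)
  ni <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2L)
  z <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt(v0 * (1 / ni[[a]] + 1 / ni[[b]]))
    z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / se
  }
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
             p_value = p, p_adjusted = stats::p.adjust(p, method = adjust),
             stringsAsFactors = FALSE)
}

#' Boxplot of damage enrichment by gene set
#'
#' Panels are ordered left to right from highest to lowest mean enrichment;
#' red diamonds mark the means.
#'
#' @param damage data frame from [damage_by_set()].
#' @param ... passed to [graphics::boxplot()].
#' @return the ordered set names, invisibly.
#' @export
plot_damage_by_set <- function(damage, ...) {
  means <- tapply(damage$enrichment, damage$gene_set, mean)
  ord <- names(sort(means, decreasing = TRUE))
  damage$gene_set <- factor(damage$gene_set, levels = ord)
  graphics::boxplot(enrichment ~ gene_set, data = damage, las = 2,
                    ylab = "mean signal per region", ...)
  graphics::points(seq_along(ord), means[ord], pch = 18, col = "red",
                   cex = 1.4)
  invisible(ord)
}
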