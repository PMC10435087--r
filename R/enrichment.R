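#' Sample random gene sets from a gene universe
#'
#' Each set contains exactly `set_size` distinct genes drawn uniformly
#' without replacement; sets are drawn independently of one another, so a
#' gene may recur across sets. These random sets define the empirical null
#' against which disease gene sets are compared.
#'
#' @param universe character vector of candidate gene ids (typically every
#'   gene in the annotation).
#' @param n_sets number of sets (default 1000).
#' @param set_size genes per set (default 300).
#' @param seed RNG seed; identical seeds reproduce identical sets.
#' @return list of character vectors of length `set_size`.
#' @export
sample_null_sets <- function(universe, n_sets = 1000L, set_size = 300L,
                             seed = NULL) {
  universe <- unique(as.character(universe))
  if (length(universe) < set_size)
    stop("gene universe (", length(universe),
         ") smaller than set_size (", set_size, ")")
  with_seed(seed,
            replicate(n_sets, sample(universe, set_size), simplify = FALSE))
}

#' Expected per-gene-per-subclone mutation rate from random gene sets
#'
#' For each random set, the rate is the total mutation count in the set's
#' genes among the class's subclones divided by (set size x number of
#' subclones in the class); the null expectation `p0` is the arithmetic
#' mean of those per-set rates.
#'
#' @param counts a `mutation_counts` data frame from [assign_mutations()].
#' @param null_sets list of gene-id sets from [sample_null_sets()].
#' @param class exposure class name.
#' @param manifest a [subclone_manifest()].
#' @param gene_ids full gene universe (zero-count genes included).
#' @param level `"gene"` or `"cds"` counts.
#' @return object of class `null_model`: list with `exposure_class`,
#'   `n_sets`, `set_size`, `per_set_rates`, `p0`, `n_subclones`, `level`.
#' @export
null_rate <- function(counts, null_sets, class, manifest, gene_ids,
                      level = c("gene", "cds")) {
  level <- match.arg(level)
  manifest <- subclone_manifest(manifest)
  ns <- n_subclones(manifest, class)
  set_size <- length(null_sets[[1L]])
  tot <- gene_class_totals(counts, manifest, class, gene_ids, level)
  per_set <- vapply(null_sets, function(s) sum(tot[s]) / (length(s) * ns),
                    numeric(1))
  structure(list(exposure_class = class, n_sets = length(null_sets),
                 set_size = set_size, per_set_rates = per_set,
                 p0 = mean(per_set), n_subclones = ns, level = level),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("Random gene-set null model\n")
  cat("  exposure class:", x$exposure_class, " level:", x$level, "\n")
  cat(sprintf("  %d sets of %d genes over %d subclones\n",
              x$n_sets, x$set_size, x$n_subclones))
  cat(sprintf("  expected rate p0 = %.6g mutations/gene/subclone\n", x$p0))
  invisible(x)
}

#' Exact binomial test of gene-set mutation enrichment
#'
#' Tests whether `observed` mutations among `n_trials` gene-by-subclone
#' opportunities are compatible with the null per-gene-per-subclone rate
#' `p0`. The default two-sided p-value uses the minimum-likelihood rule: it
#' sums the probabilities of all outcomes whose point probability does not
#' exceed that of the observed outcome (within relative tolerance 1 + 1e-7);
#' `method = "central"` doubles the smaller tail instead. Because genes can
#' contribute multiple mutations, `observed` can in principle exceed
#' `n_trials`; in that case the binomial cannot represent the data and the
#' test falls back to an exact Poisson test with mean `p0 * n_trials`, with
#' a warning.
#'
#' @param observed non-negative mutation count.
#' @param n_trials number of trials (genes x subclones).
#' @param p0 null success probability in `[0, 1]`.
#' @param method `"minlik"` (default) or `"central"`.
#' @return two-sided p-value.
#' @export
binomial_enrichment <- function(observed, n_trials, p0,
                                method = c("minlik", "central")) {
  method <- match.arg(method)
  if (length(observed) != 1L || observed < 0 || observed != round(observed))
    stop("observed must be a single non-negative integer")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (is.na(p0) || p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (observed > n_trials) {
    warning("observed (", observed, ") exceeds n_trials (", n_trials,
            "); falling back to an exact Poisson test")
    return(poisson_exact_p(observed, p0 * n_trials, method))
  }
  if (method == "central") {
    lower <- stats::pbinom(observed, n_trials, p0)
    upper <- stats::pbinom(observed - 1, n_trials, p0, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }
  d <- stats::dbinom(0:n_trials, n_trials, p0)
  min(1, sum(d[d <= d[observed + 1L] * (1 + 1e-7)]))
}

# Exact Poisson two-sided p (same tail rules as binomial_enrichment).
poisson_exact_p <- function(observed, mu, method = c("minlik", "central")) {
  method <- match.arg(method)
  if (mu == 0) return(if (observed == 0) 1 else 0)
  if (method == "central") {
    lower <- stats::ppois(observed, mu)
    upper <- stats::ppois(observed - 1, mu, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }
  hi <- max(observed, stats::qpois(1 - 1e-12, mu)) + 10L
  d <- stats::dpois(0:hi, mu)
  min(1, sum(d[d <= d[observed + 1L] * (1 + 1e-7)]))
}

#' Monte-Carlo empirical-null enrichment test
#'
#' Two-tailed p-value from size-matched random gene sets: the proportion of
#' null sets mutated at least as much, or at most as much, as the disease
#' set - whichever is smaller - multiplied by two (ties count in both
#' tails, no pseudo-count, truncated at 1). When the observed total lies
#' outside the whole null sample the p-value is 0 and is flagged as below
#' the `2/N` resolution of the null.
#'
#' @param observed observed total mutation count in the disease set.
#' @param null_totals totals from random sets matched to the disease set's
#'   gene count.
#' @return p-value with attribute `below_resolution` (logical).
#' @export
montecarlo_enrichment <- function(observed, null_totals) {
  if (!length(null_totals)) stop("empty Monte-Carlo null")
  upper <- mean(null_totals >= observed)
  lower <- mean(null_totals <= observed)
  p <- min(1, 2 * min(upper, lower))
  structure(p, below_resolution = p < 2 / length(null_totals))
}

#' Table-wide Bonferroni significance flags
#'
#' @param p vector of p-values.
#' @param m number of cells in the results table (classes x gene sets).
#' @param alpha family-wise level (default 0.05).
#' @return logical vector: `p < alpha / m`.
#' @export
bonferroni_significant <- function(p, m, alpha = 0.05) {
  if (m < 1L) stop("m must be >= 1")
  p < alpha / m
}

#' Mutation burden of random gene sets across set sizes
#'
#' Draws `n_sets` random sets at each size and reports the mean mutations
#' per subclone and per gene per subclone. Per-subclone burden grows
#' linearly with set size (slope = the per-gene rate) while the per-gene
#' rate stays flat, which is why the null need not be size-matched.
#'
#' @param counts a `mutation_counts` data frame.
#' @param universe gene-id universe to sample from.
#' @param class exposure class name.
#' @param manifest a [subclone_manifest()].
#' @param sizes set sizes (default 10 to 300 in steps of 10).
#' @param n_sets random sets per size (default 1000).
#' @param seed RNG seed.
#' @param level `"gene"` or `"cds"`.
#' @return data frame of class `setsize_sweep`: `set_size`,
#'   `mean_mutations_per_subclone`, `mean_mutations_per_gene_per_subclone`,
#'   `se_per_subclone`, `se_per_gene_per_subclone`.
#' @export
setsize_sweep <- function(counts, universe, class, manifest,
                          sizes = seq(10L, 300L, by = 10L), n_sets = 1000L,
                          seed = NULL, level = c("gene", "cds")) {
  level <- match.arg(level)
  manifest <- subclone_manifest(manifest)
  ns <- n_subclones(manifest, class)
  universe <- unique(as.character(universe))
  sizes <- sort(unique(as.integer(sizes)))
  tot <- gene_class_totals(counts, manifest, class, universe, level)
  rows <- with_seed(seed, lapply(sizes, function(sz) {
    totals <- vapply(seq_len(n_sets),
                     function(i) sum(tot[sample(universe, sz)]), numeric(1))
    per_sub <- totals / ns
    per_gene_sub <- per_sub / sz
    data.frame(set_size = sz,
               mean_mutations_per_subclone = mean(per_sub),
               mean_mutations_per_gene_per_subclone = mean(per_gene_sub),
               se_per_subclone = stats::sd(per_sub) / sqrt(n_sets),
               se_per_gene_per_subclone = stats::sd(per_gene_sub) /
                 sqrt(n_sets))
  }))
  out <- do.call(rbind, rows)
  class(out) <- c("setsize_sweep", "data.frame")
  out
}

#' Stratify a gene set into length quartiles
#'
#' Genes are ranked by length (longest first, ties broken by symbol order)
#' and split into four lists at the empirical quartiles; when the size is
#' not divisible by four the longer quartiles take the remainder, so list
#' sizes differ by at most one. `Q1` holds the longest genes.
#'
#' @param members character vector of gene symbols/ids.
#' @param lengths named numeric vector of gene lengths covering `members`.
#' @return named list of four character vectors (`Q1` longest ... `Q4`
#'   shortest).
#' @export
quartile_stratify <- function(members, lengths) {
  members <- unique(as.character(members))
  if (any(!members %in% names(lengths)))
    stop("lengths missing for some members")
  len <- lengths[members]
  ord <- members[order(-len, members)]
  n <- length(ord)
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- rep(base, 4L) + c(rep(1L, extra), rep(0L, 4L - extra))
  idx <- cumsum(sizes)
  starts <- c(1L, idx[-4L] + 1L)
  out <- lapply(1:4, function(q)
    if (sizes[q] > 0L) ord[starts[q]:idx[q]] else character(0))
  names(out) <- paste0("Q", 1:4)
  out
}

#' Observed-vs-expected mutation burden of disease gene sets
#'
#' The headline analysis: for every disease gene set and exposure class,
#' compares the observed mutation count with the expectation from the
#' random gene-set null (`p0 x n_genes x n_subclones`) using a two-sided
#' exact binomial test, with table-wide Bonferroni correction over all
#' cells. Optionally adds a Monte-Carlo empirical-null p-value from random
#' sets size-matched to each disease set.
#'
#' @param counts a `mutation_counts` data frame from [assign_mutations()].
#' @param genes a `gene_models` data frame (defines the gene universe and
#'   the symbol-to-id map).
#' @param sets named list of gene-symbol vectors (see [read_gene_sets()]).
#' @param manifest a [subclone_manifest()].
#' @param classes exposure classes to test (default: all in the manifest).
#' @param level `"gene"` or `"cds"`; at CDS level the universe is
#'   restricted to genes with coding sequence.
#' @param n_sets,set_size random-null dimensions (defaults 1000 x 300).
#' @param seed RNG seed for all resampling.
#' @param alpha nominal level (default 0.05).
#' @param monte_carlo if `TRUE`, also compute Monte-Carlo p-values.
#' @param tail_method binomial tail rule, see [binomial_enrichment()].
#' @return object of class `mutaset_enrichment`: list with `table` (one row
#'   per set x class), `null_models`, `m` (Bonferroni divisor), `level`,
#'   `alpha`, `n_sets`, `set_size`, `seed`, `dropped_symbols`.
#' @export
enrich_gene_sets <- function(counts, genes, sets, manifest, classes = NULL,
                             level = c("gene", "cds"), n_sets = 1000L,
                             set_size = 300L, seed = NULL, alpha = 0.05,
                             monte_carlo = FALSE,
                             tail_method = c("minlik", "central")) {
  level <- match.arg(level)
  tail_method <- match.arg(tail_method)
  manifest <- subclone_manifest(manifest)
  classes <- classes %||% unique(manifest$exposure_class)
  keep <- if (level == "cds") genes$cds_length > 0L else rep(TRUE, nrow(genes))
  universe <- genes$gene_id[keep]
  sym2id <- stats::setNames(genes$gene_id, genes$symbol)

  member_ids <- lapply(sets, function(s) {
    ids <- sym2id[s]
    ids <- unname(ids[!is.na(ids)])
    intersect(ids, universe)
  })
  dropped <- mapply(function(s, ids) length(unique(s)) - length(ids),
                    sets, member_ids)
  empty <- vapply(member_ids, length, 1L) == 0L
  if (any(empty))
    stop("gene set(s) with no members in the annotation: ",
         paste(names(sets)[empty], collapse = ", "))

  null_sets <- sample_null_sets(universe, n_sets, set_size,
                                seed = child_seed(seed, 1L))
  null_models <- lapply(classes, function(cl)
    null_rate(counts, null_sets, cl, manifest, universe, level))
  names(null_models) <- classes

  mc_nulls <- NULL
  if (monte_carlo) {
    mc_nulls <- lapply(seq_along(member_ids), function(i)
      sample_null_sets(universe, n_sets, length(member_ids[[i]]),
                       seed = child_seed(seed, 100L + i)))
    names(mc_nulls) <- names(sets)
  }

  rows <- list()
  for (cl in classes) {
    nm <- null_models[[cl]]
    tot <- gene_class_totals(counts, manifest, cl, universe, level)
    for (i in seq_along(member_ids)) {
      ids <- member_ids[[i]]
      n_genes <- length(ids)
      observed <- sum(tot[ids])
      n_trials <- n_genes * nm$n_subclones
      expected <- nm$p0 * n_trials
      p_b <- binomial_enrichment(observed, n_trials, nm$p0,
                                 method = tail_method)
      p_mc <- NA_real_
      mc_floor <- NA
      if (monte_carlo) {
        null_totals <- vapply(mc_nulls[[i]], function(s) sum(tot[s]),
                              numeric(1))
        pm <- montecarlo_enrichment(observed, null_totals)
        p_mc <- as.numeric(pm)
        mc_floor <- attr(pm, "below_resolution")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_set = names(sets)[i], exposure_class = cl,
        n_genes = n_genes, n_subclones = nm$n_subclones,
        observed = observed, expected = expected,
        obs_minus_exp = observed - expected,
        rate_per_gene_per_subclone = observed / n_trials,
        p_binomial = p_b, p_montecarlo = p_mc,
        mc_below_resolution = mc_floor,
        direction = if (observed > expected) "more" else "less",
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  m <- length(classes) * length(sets)
  tab$significant_nominal <- tab$p_binomial < alpha
  tab$significant_bonferroni <- bonferroni_significant(tab$p_binomial, m,
                                                       alpha)
  rownames(tab) <- NULL
  structure(list(table = tab, null_models = null_models, m = m,
                 level = level, alpha = alpha, n_sets = n_sets,
                 set_size = set_size, seed = seed,
                 tail_method = tail_method,
                 dropped_symbols = dropped,
                 call = match.call()),
            class = "mutaset_enrichment")
}

#' @export
print.mutaset_enrichment <- function(x, ...) {
  cat("Gene-set mutation enrichment (", x$level, " level)\n", sep = "")
  cat(sprintf("  null: %d random sets of %d genes; Bonferroni over m = %d cells\n",
              x$n_sets, x$set_size, x$m))
  tab <- x$table
  mark <- ifelse(tab$significant_bonferroni, "**",
                 ifelse(tab$significant_nominal,
                        ifelse(tab$direction == "more", "*", "†"), ""))
  show <- data.frame(set = tab$gene_set, class = tab$exposure_class,
                     obs = tab$observed,
                     exp = round(tab$expected, 2),
                     `obs-exp` = round(tab$obs_minus_exp, 2),
                     p = signif(tab$p_binomial, 3), sig = mark,
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mutaset_enrichment <- function(object, ...) {
  tab <- object$table
  out <- list(
    n_cells = nrow(tab),
    n_nominal = sum(tab$significant_nominal),
    n_bonferroni = sum(tab$significant_bonferroni),
    n_more = sum(tab$direction == "more"),
    p0 = vapply(object$null_models, function(nm) nm$p0, numeric(1)),
    level = object$level
  )
  class(out) <- "summary.mutaset_enrichment"
  out
}

#' @export
print.summary.mutaset_enrichment <- function(x, ...) {
  cat("Enrichment summary (", x$level, " level): ", x$n_cells, " cells; ",
      x$n_nominal, " nominal, ", x$n_bonferroni,
      " Bonferroni-significant; ", x$n_more, " in the 'more' direction\n",
      sep = "")
  cat("Null p0 by class:\n")
  print(signif(x$p0, 4))
  invisible(x)
}

#' Heatmap of observed-minus-expected mutation burden
#'
#' Cells are colored by observed minus expected counts; `*` marks nominal
#' significance in the "more" direction, `**` Bonferroni significance, and
#' a dagger nominal significance in the "less" direction.
#'
#' @param x a `mutaset_enrichment` object.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.mutaset_enrichment <- function(x, ...) {
  tab <- x$table
  sets <- unique(tab$gene_set)
  classes <- unique(tab$exposure_class)
  z <- matrix(NA_real_, length(sets), length(classes),
              dimnames = list(sets, classes))
  for (i in seq_len(nrow(tab)))
    z[tab$gene_set[i], tab$exposure_class[i]] <- tab$obs_minus_exp[i]
  lim <- max(abs(z), 1e-9)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(51)
  op <- graphics::par(mar = c(6, 8, 3, 2))
  on.exit(graphics::par(op))
  graphics::image(seq_along(classes), seq_along(sets), t(z),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "", ylab = "",
                  main = paste0("Observed - expected mutations (",
                                x$level, " level)"), ...)
  graphics::axis(1, seq_along(classes), classes, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_along(sets), sets, las = 2, cex.axis = 0.8)
  for (i in seq_len(nrow(tab))) {
    xi <- match(tab$exposure_class[i], classes)
    yi <- match(tab$gene_set[i], sets)
    lab <- if (tab$significant_bonferroni[i]) "**"
           else if (tab$significant_nominal[i] && tab$direction[i] == "more") "*"
           else if (tab$significant_nominal[i]) "†" else ""
    if (nzchar(lab)) graphics::text(xi, yi, lab, cex = 1.1)
  }
  invisible(x)
}

#' Plot the random-set size sweep
#'
#' @param x a `setsize_sweep` data frame.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.setsize_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$set_size, x$mean_mutations_per_subclone, type = "b",
                 xlab = "random set size", ylab = "mutations per subclone",
                 ...)
  graphics::plot(x$set_size, x$mean_mutations_per_gene_per_subclone,
                 type = "b", xlab = "random set size",
                 ylab = "mutations per gene per subclone", ...)
  invisible(x)
}
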