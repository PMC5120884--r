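#' Median-of-ratios size factors
#'
#' Per-sample scaling constants equalizing sequencing depth: for sample j,
#' the median over genes of `count[g, j] / geomean_g`, where `geomean_g` is
#' the geometric mean of gene g across samples, taken over genes whose
#' geometric mean is positive (i.e. genes with no zero count).
#'
#' @param counts Non-negative genes x samples matrix.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  zero_sample <- colSums(counts) == 0
  if (any(zero_sample))
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[zero_sample], collapse = ", "))
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stopf("no gene has nonzero counts in every sample")
  sf <- apply(counts, 2, function(cj)
    exp(stats::median(log(cj[use]) - log_geo[use])))
  names(sf) <- colnames(counts)
  sf
}

#' Per-gene negative-binomial Wald test between two groups
#'
#' Normalizes counts by size factors, pools a per-gene method-of-moments
#' dispersion across the two groups, shrinks it towards the median
#' dispersion of expressed genes (weight `shrink`; per-gene moment
#' estimates are extremely noisy at sorted-cell replicate numbers, and
#' sharing information across genes is what makes small-sample count
#' testing workable), and tests the log-ratio of group means with a Wald
#' statistic referred to a moderated t distribution with
#' `n1 + n2 - 2 + prior_df` degrees of freedom — the added prior degrees
#' of freedom reflect the information borrowed by the shrinkage, in the
#' spirit of empirical-Bayes moderated statistics.
#'
#' The variance model is `var = mu + dispersion * mu^2`; per group the
#' variance of the group mean is that quantity over the replicate count and
#' the delta method gives the variance of the log mean. Genes with zero
#' counts everywhere get `p = 1` and are flagged.
#'
#' @param counts Genes x samples matrix.
#' @param groups Factor/character of length `ncol(counts)` with exactly two
#'   levels; each group needs >= 2 samples.
#' @param sf Size factors; computed with [size_factors()] when `NULL`.
#' @param pseudocount Added to normalized group means before taking logs
#'   (stabilizes genes observed in one group only).
#' @param shrink Weight of the across-gene median dispersion in the
#'   shrunken per-gene dispersion, in `[0, 1]` (default 0.8).
#' @param prior_df Prior degrees of freedom added to the residual degrees
#'   of freedom of the t reference (default 25).
#' @return data.frame: `gene`, `mean1`, `mean2` (normalized group means,
#'   group order = factor levels), `log_ratio`, `stat`, `p` (two-sided, in
#'   (0, 1]), `all_zero`.
#' @export
nb_test <- function(counts, groups, sf = NULL, pseudocount = 0.5,
                    shrink = 0.8, prior_df = 25) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("groups must have exactly two levels")
  n_per <- table(groups)
  if (any(n_per < 2L)) stopf("each group needs >= 2 samples")
  sf <- sf %||% size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  # pooled within-group variance and mean -> method-of-moments dispersion
  vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mp <- (n1 * m1 + n2 * m2) / (n1 + n2)
  disp <- pmax((vp - mp) / mp^2, 0)
  disp[!is.finite(disp)] <- 0
  if (shrink > 0) {
    expressed <- mp > 5
    med <- if (any(expressed)) stats::median(disp[expressed]) else 0
    disp <- (1 - shrink) * disp + shrink * med
  }
  m1p <- m1 + pseudocount
  m2p <- m2 + pseudocount
  log_ratio <- log(m1p) - log(m2p)
  # delta method: Var(log mean_i) ~ (mu_i + disp mu_i^2) / (n_i mu_i^2)
  se2 <- (m1p + disp * m1p^2) / (n1 * m1p^2) +
    (m2p + disp * m2p^2) / (n2 * m2p^2)
  stat <- log_ratio / sqrt(se2)
  p <- 2 * stats::pt(-abs(stat), df = n1 + n2 - 2 + prior_df)
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- 1
  stat[all_zero] <- 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             mean1 = m1, mean2 = m2, log_ratio = log_ratio, stat = stat,
             p = p, all_zero = all_zero, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), clipped to 1 and
#' monotone along the sorted p values.
#'
#' @param p Numeric vector in `[0, 1]`.
#' @return Adjusted q values, same length/order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold change of mean GFP+ over mean AllCells counts
#'
#' @param mean_gfp,mean_all Non-negative mean counts (vectorized).
#' @return `mean_gfp / mean_all`; `Inf` when only the reference mean is
#'   zero, `NA` when the reference is zero-or-negative with a warning-free
#'   flagged result.
#' @export
fold_change <- function(mean_gfp, mean_all) {
  fc <- ifelse(mean_all > 0, mean_gfp / mean_all,
               ifelse(mean_gfp > 0, Inf, NA_real_))
  fc
}

#' Enrichment call from q values and mean counts
#'
#' A transcript is significantly enriched in the GFP+ fraction iff its
#' FDR-adjusted p value is below `q_threshold` (strict) and the ratio of
#' mean GFP+ counts to mean AllCells counts exceeds `ratio_threshold`.
#' When the AllCells mean is zero and the GFP+ mean positive, the ratio is
#' infinite and the call reduces to the q criterion.
#'
#' @param q FDR-adjusted p values.
#' @param mean_gfp,mean_all Mean counts per gene.
#' @param q_threshold Default 0.05 (strict `<`).
#' @param ratio_threshold Default 1 (strict `>`).
#' @param ratio_mode `"plain"` (default; mean ratio > threshold) or
#'   `"log2"` (ratio of log2-transformed means > threshold).
#' @return Logical vector of enrichment flags.
#' @export
call_enrichment <- function(q, mean_gfp, mean_all, q_threshold = 0.05,
                            ratio_threshold = 1,
                            ratio_mode = c("plain", "log2")) {
  ratio_mode <- match.arg(ratio_mode)
  ratio <- if (ratio_mode == "plain") {
    fold_change(mean_gfp, mean_all)
  } else {
    ifelse(mean_all > 1 & mean_gfp > 0,
           log2(mean_gfp) / log2(mean_all), NA_real_)
  }
  q < q_threshold & !is.na(ratio) & ratio > ratio_threshold |
    (q < q_threshold & is.infinite(ratio))
}

#' Subtractive set arithmetic over two enriched gene sets
#'
#' Categorizes each gene of the universe as `shared` (enriched in both
#' genotypes), `wt_only`, `mut_only`, or `none`; the symmetric difference
#' (`wt_only` + `mut_only`) is the preferentially enriched set whose
#' wild-type-only part nominates transcripts of the cell type missing in
#' the mutant.
#'
#' @param enriched_wt,enriched_mut Character vectors of enriched gene ids.
#' @param universe Optional character vector of all gene ids (defaults to
#'   the union of the two sets).
#' @return list: `category` (named character per universe gene), `counts`
#'   (named integer: wt, mut, shared, wt_only, mut_only, preferential).
#' @export
subtract_sets <- function(enriched_wt, enriched_mut, universe = NULL) {
  universe <- universe %||% union(enriched_wt, enriched_mut)
  in_wt <- universe %in% enriched_wt
  in_mut <- universe %in% enriched_mut
  category <- ifelse(in_wt & in_mut, "shared",
                     ifelse(in_wt, "wt_only",
                            ifelse(in_mut, "mut_only", "none")))
  names(category) <- universe
  counts <- c(wt = sum(in_wt), mut = sum(in_mut),
              shared = sum(in_wt & in_mut),
              wt_only = sum(in_wt & !in_mut),
              mut_only = sum(!in_wt & in_mut),
              preferential = sum(xor(in_wt, in_mut)))
  list(category = category, counts = counts)
}

#' Run the GFP+ vs AllCells enrichment pipeline for one genotype
#'
#' Size factors, NB differential test (GFP+ vs AllCells), BH-FDR,
#' normalized group means, fold changes and enrichment flags.
#'
#' @param counts Genes x samples matrix for one genotype.
#' @param meta data.frame with `sample` and `fraction`
#'   (`"GFP+"`/`"AllCells"`) columns matching `colnames(counts)`.
#' @param q_threshold,ratio_threshold,ratio_mode Passed to
#'   [call_enrichment()].
#' @return data.frame per gene: `gene`, `mean_gfp`, `mean_all`,
#'   `fold_change`, `p`, `q`, `enriched`.
#' @export
enrich_genotype <- function(counts, meta, q_threshold = 0.05,
                            ratio_threshold = 1, ratio_mode = "plain") {
  stopifnot(all(colnames(counts) == meta$sample))
  groups <- factor(meta$fraction, levels = c("GFP+", "AllCells"))
  res <- nb_test(counts, groups)
  q <- bh_fdr(res$p)
  fc <- fold_change(res$mean1, res$mean2)
  data.frame(gene = res$gene, mean_gfp = res$mean1, mean_all = res$mean2,
             fold_change = fc, p = res$p, q = q,
             enriched = call_enrichment(q, res$mean1, res$mean2,
                                        q_threshold, ratio_threshold,
                                        ratio_mode),
             stringsAsFactors = FALSE)
}

#' Full subtractive enrichment pipeline across two genotypes
#'
#' Runs [enrich_genotype()] on the wild-type and mutant designs and
#' categorizes every gene by [subtract_sets()].
#'
#' @param wt,mut Each a list with `counts` and `meta` (as produced by
#'   [simulate_counts()] or read from TSV).
#' @param ... Passed to [enrich_genotype()].
#' @return list: `wt`, `mut` (per-genotype result tables), `category`
#'   (per-gene), `counts` (Venn counts as in [subtract_sets()]).
#' @export
run_enrichment <- function(wt, mut, ...) {
  res_wt <- enrich_genotype(wt$counts, wt$meta, ...)
  res_mut <- enrich_genotype(mut$counts, mut$meta, ...)
  universe <- union(res_wt$gene, res_mut$gene)
  sets <- subtract_sets(res_wt$gene[res_wt$enriched],
                        res_mut$gene[res_mut$enriched], universe)
  list(wt = res_wt, mut = res_mut, category = sets$category,
       counts = sets$counts)
}

#' Validate an enrichment result against marker gene lists
#'
#' Positive markers (known transcripts of the sorted cell types) are
#' expected enriched; negative markers (non-target tissues) are expected
#' not enriched. Unknown ids are listed as unresolved, not fatal.
#'
#' @param result Per-gene table from [enrich_genotype()] (needs `gene` and
#'   `enriched`).
#' @param positive,negative Character vectors of marker gene ids.
#' @return list: `markers` (data.frame: gene, role, status), `n_pos_pass`,
#'   `n_neg_pass`, `unresolved`, `pass` (all resolvable markers behave as
#'   expected).
#' @export
validate_markers <- function(result, positive = character(0),
                             negative = character(0)) {
  status_of <- function(ids, role) {
    if (!length(ids)) return(NULL)
    hit <- match(ids, result$gene)
    data.frame(gene = ids, role = role,
               status = ifelse(is.na(hit), "unresolved",
                               ifelse(result$enriched[hit], "enriched",
                                      "not_enriched")),
               stringsAsFactors = FALSE)
  }
  markers <- rbind(status_of(positive, "positive"),
                   status_of(negative, "negative"))
  if (is.null(markers))
    return(list(markers = data.frame(gene = character(0),
                                     role = character(0),
                                     status = character(0)),
                n_pos_pass = 0L, n_neg_pass = 0L,
                unresolved = character(0), pass = TRUE))
  n_pos_pass <- sum(markers$role == "positive" &
                      markers$status == "enriched")
  n_neg_pass <- sum(markers$role == "negative" &
                      markers$status == "not_enriched")
  unresolved <- markers$gene[markers$status == "unresolved"]
  resolved <- markers[markers$status != "unresolved", , drop = FALSE]
  pass <- all(ifelse(resolved$role == "positive",
                     resolved$status == "enriched",
                     resolved$status == "not_enriched"))
  list(markers = markers, n_pos_pass = n_pos_pass,
       n_neg_pass = n_neg_pass, unresolved = unresolved, pass = pass)
}
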