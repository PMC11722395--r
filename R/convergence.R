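# Cross-experiment differential-expression convergence: expression
# filtering, Benjamini-Hochberg FDR, sign-concordant overlap, and the
# hypergeometric (Fisher exact) convergence statistic.

check_de_table <- function(tab, label) {
  need <- c("gene", "baseMean", "log2FoldChange", "pvalue")
  if (!all(need %in% names(tab)))
    stop(label, " must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene)) stop("duplicate gene ids in ", label)
  if (any(tab$baseMean < 0, na.rm = TRUE)) stop("negative baseMean in ", label)
  bad_p <- !is.na(tab$pvalue) & (tab$pvalue <= 0 | tab$pvalue > 1)
  if (any(bad_p)) stop("p-values outside (0, 1] in ", label)
  tab
}

#' Expression-filtered gene universe
#'
#' The background for the convergence test: genes whose baseMean (mean
#' normalized count) reaches `min_basemean` in BOTH experiments — a gene
#' below the floor in either experiment is excluded.
#'
#' @param table_a,table_b DE result tables (columns gene, baseMean,
#'   log2FoldChange, pvalue).
#' @param min_basemean Expression floor (default 100).
#' @return Character vector of gene ids.
#' @export
filter_basemean <- function(table_a, table_b, min_basemean = 100) {
  table_a <- check_de_table(table_a, "table_a")
  table_b <- check_de_table(table_b, "table_b")
  common <- intersect(table_a$gene, table_b$gene)
  bm_a <- table_a$baseMean[match(common, table_a$gene)]
  bm_b <- table_b$baseMean[match(common, table_b$gene)]
  universe <- common[!is.na(bm_a) & !is.na(bm_b) &
                     bm_a >= min_basemean & bm_b >= min_basemean]
  if (length(universe) == 0)
    stop("no genes pass the baseMean filter at ", min_basemean)
  universe
}

#' Benjamini-Hochberg FDR adjustment with a strict significance call
#'
#' Standard step-up BH adjustment (monotone, capped at 1) over the
#' supplied p-values; a gene is significant iff its adjusted p is
#' strictly below `alpha`.
#'
#' @param pvalues Numeric vector in (0, 1]; names are gene ids.
#' @param alpha FDR level (default 0.1).
#' @return List: `padj` (same order/names as input), `significant`
#'   (logical vector).
#' @export
bh_fdr <- function(pvalues, alpha = 0.1) {
  padj <- stats::p.adjust(pvalues, method = "BH")
  list(padj = padj, significant = !is.na(padj) & padj < alpha)
}

#' Sign-concordant overlap of two significant gene sets
#'
#' Partitions the genes significant in both experiments by direction of
#' effect. Genes with a log2 fold change of exactly 0 cannot be assigned
#' a direction; they are flagged and excluded from the concordance
#' counts (but still count toward the total overlap).
#'
#' @param sig_a,sig_b Data frames with columns `gene` and
#'   `log2FoldChange` for the significant genes of each experiment.
#' @return List: `overlap` (gene ids), `k`, `concordant`, `discordant`,
#'   `unsigned` (zero-fold-change genes), `table` (per-gene directions).
#' @export
concordant_overlap <- function(sig_a, sig_b) {
  genes <- intersect(sig_a$gene, sig_b$gene)
  la <- sig_a$log2FoldChange[match(genes, sig_a$gene)]
  lb <- sig_b$log2FoldChange[match(genes, sig_b$gene)]
  signed <- la != 0 & lb != 0
  tab <- data.frame(gene = genes, log2FC_a = la, log2FC_b = lb,
                    direction = ifelse(!signed, "unsigned",
                               ifelse(sign(la) == sign(lb),
                                      "concordant", "discordant")))
  list(overlap = genes, k = length(genes),
       concordant = sum(tab$direction == "concordant"),
       discordant = sum(tab$direction == "discordant"),
       unsigned = sum(tab$direction == "unsigned"),
       table = tab)
}

#' Hypergeometric overlap (Fisher exact) test
#'
#' Upper-tail probability of observing an overlap of at least `k` genes
#' between lists of sizes `n_a` and `n_b` drawn from a universe of `N`
#' genes: P(X >= k) for X ~ Hypergeometric(N, n_a, n_b). Evaluated via
#' the survival function of the hypergeometric distribution, which works
#' in log space internally and is stable down to the smallest
#' double-precision tail probabilities.
#'
#' @param n_a,n_b Significant-list sizes.
#' @param k Observed overlap.
#' @param N Universe size.
#' @return Upper-tail p-value; 1 when k = 0.
#' @export
overlap_fisher <- function(n_a, n_b, k, N) {
  if (k > min(n_a, n_b) || n_a > N || n_b > N || k < 0)
    stop("inconsistent overlap counts: k = ", k, ", n_a = ", n_a,
         ", n_b = ", n_b, ", N = ", N)
  if (k == 0) return(1)
  stats::phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
}

#' Full cross-experiment convergence analysis
#'
#' Filters both tables to the shared expressed universe, applies BH FDR
#' within the universe per experiment, intersects the significant sets,
#' classifies directions, and computes the Fisher convergence p-value on
#' the total overlap (all-direction; a sign-stratified variant applies
#' the test to the concordant count only).
#'
#' @param table_a,table_b DE result tables.
#' @param min_basemean Expression floor.
#' @param alpha FDR level (significant iff adjusted p < alpha).
#' @param sign_stratified Apply the Fisher test to the concordant count
#'   instead of the total overlap.
#' @return List: `N`, `n_a`, `n_b`, `k`, `concordant`, `discordant`,
#'   `fisher_p`, `overlap_table` (gene, both log2FCs and FDRs,
#'   direction).
#' @export
run_convergence <- function(table_a, table_b, min_basemean = 100,
                            alpha = 0.1, sign_stratified = FALSE) {
  universe <- filter_basemean(table_a, table_b, min_basemean)
  sub <- function(tab) tab[match(universe, tab$gene), ]
  ta <- sub(check_de_table(table_a, "table_a"))
  tb <- sub(check_de_table(table_b, "table_b"))
  fa <- bh_fdr(stats::setNames(ta$pvalue, ta$gene), alpha)
  fb <- bh_fdr(stats::setNames(tb$pvalue, tb$gene), alpha)
  sig_a <- ta[fa$significant, c("gene", "log2FoldChange")]
  sig_b <- tb[fb$significant, c("gene", "log2FoldChange")]
  ov <- concordant_overlap(sig_a, sig_b)
  k_test <- if (sign_stratified) ov$concordant else ov$k
  p <- overlap_fisher(nrow(sig_a), nrow(sig_b), k_test, length(universe))
  tab <- ov$table
  tab$padj_a <- fa$padj[match(tab$gene, names(fa$padj))]
  tab$padj_b <- fb$padj[match(tab$gene, names(fb$padj))]
  list(N = length(universe), n_a = nrow(sig_a), n_b = nrow(sig_b),
       k = ov$k, concordant = ov$concordant, discordant = ov$discordant,
       fisher_p = p, sign_stratified = sign_stratified,
       overlap_table = tab)
}
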