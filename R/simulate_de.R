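#' Specify a two-experiment differential-expression simulation
#'
#' Emulates the outputs of two independent crispant-versus-control
#' RNA-seq experiments (3 replicates per condition, each replicate a
#' pool of larvae): negative-binomial counts with a shared set of truly
#' differential genes plus experiment-specific DE genes. Shared genes
#' have the same direction of effect in both experiments by construction.
#'
#' The per-gene p-value is a deliberate simplification of a DESeq2 fit:
#' a two-sided two-sample Student t-test on log2(count + 1). Library
#' sizes are equal by construction so baseMean is the plain mean count.
#'
#' @param n_genes Total genes.
#' @param n_shared_de Genes differential in both experiments.
#' @param n_unique_de Genes differential in only one experiment (each).
#' @param lfc_mean,lfc_sd Magnitude distribution of log2 fold changes
#'   (drawn as `lfc_mean + |N(0, lfc_sd)|`, random sign).
#' @param mu_meanlog,mu_sdlog Log-normal distribution of baseline NB
#'   means (some genes fall below the baseMean filter by design).
#' @param dispersion NB dispersion (size = 1/dispersion); must be > 0.
#' @param n_reps Replicates per condition (default 3).
#' @param seed RNG seed.
#' @return A `de_gen_spec` list.
#' @export
de_gen_spec <- function(n_genes = 4000L, n_shared_de = 40L,
                        n_unique_de = 60L,
                        lfc_mean = 2, lfc_sd = 0.5,
                        mu_meanlog = log(200), mu_sdlog = 1.2,
                        dispersion = 0.05, n_reps = 3L, seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be strictly positive")
  if (n_shared_de + 2L * n_unique_de > n_genes)
    stop("more DE genes than genes")
  if (n_reps < 2L) stop("need at least 2 replicates per condition")
  structure(list(n_genes = as.integer(n_genes),
                 n_shared_de = as.integer(n_shared_de),
                 n_unique_de = as.integer(n_unique_de),
                 lfc_mean = lfc_mean, lfc_sd = lfc_sd,
                 mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
                 dispersion = dispersion, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "de_gen_spec")
}

#' Simulate the two-experiment DE tables
#'
#' @param spec A [de_gen_spec()].
#' @return List: `table_a`, `table_b` (columns gene, baseMean,
#'   log2FoldChange, pvalue), `truth` (gene, de_a, de_b, sign — sign of
#'   the implanted effect, 0 for non-DE genes), and the raw count
#'   matrices `counts_a`, `counts_b` (controls then crispants).
#' @export
make_de_tables <- function(spec = de_gen_spec()) {
  set.seed(spec$seed)
  n <- spec$n_genes
  genes <- sprintf("gene%05d", seq_len(n))
  mu <- stats::rlnorm(n, spec$mu_meanlog, spec$mu_sdlog)
  shared <- seq_len(spec$n_shared_de)
  uniq_a <- spec$n_shared_de + seq_len(spec$n_unique_de)
  uniq_b <- spec$n_shared_de + spec$n_unique_de + seq_len(spec$n_unique_de)
  signs <- integer(n)
  de_idx <- c(shared, uniq_a, uniq_b)
  signs[de_idx] <- sample(c(-1L, 1L), length(de_idx), replace = TRUE)
  lfc <- numeric(n)
  lfc[de_idx] <- (spec$lfc_mean + abs(stats::rnorm(length(de_idx),
                                                   0, spec$lfc_sd))) *
                 signs[de_idx]
  sim_experiment <- function(de_rows) {
    eff <- numeric(n)
    eff[de_rows] <- lfc[de_rows]
    size <- 1 / spec$dispersion
    ctrl <- matrix(stats::rnbinom(n * spec$n_reps, mu = mu, size = size),
                   n, spec$n_reps)
    crisp <- matrix(stats::rnbinom(n * spec$n_reps, mu = mu * 2^eff,
                                   size = size),
                    n, spec$n_reps)
    la <- log2(ctrl + 1); lb <- log2(crisp + 1)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
    sp2 <- (va + vb) / 2   # equal group sizes
    se <- sqrt(sp2 * 2 / spec$n_reps)
    tt <- (mb - ma) / se
    df <- 2 * spec$n_reps - 2
    p <- 2 * stats::pt(-abs(tt), df)
    p[se == 0] <- 1
    list(table = data.frame(gene = genes,
                            baseMean = rowMeans(cbind(ctrl, crisp)),
                            log2FoldChange = mb - ma,
                            pvalue = pmax(p, .Machine$double.xmin)),
         counts = cbind(ctrl, crisp))
  }
  ea <- sim_experiment(c(shared, uniq_a))
  eb <- sim_experiment(c(shared, uniq_b))
  truth <- data.frame(gene = genes,
                      de_a = seq_len(n) %in% c(shared, uniq_a),
                      de_b = seq_len(n) %in% c(shared, uniq_b),
                      sign = signs)
  list(table_a = ea$table, table_b = eb$table, truth = truth,
       counts_a = ea$counts, counts_b = eb$counts)
}
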