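# Shared in-code fixtures; everything is generated, nothing on disk.

toy_expr <- function(values, n_feat = nrow(values), n_samp = ncol(values)) {
  expression_matrix(values,
                    feature_ids = sprintf("f%02d", seq_len(n_feat)),
                    gene_symbols = sprintf("g%02d", seq_len(n_feat)),
                    sample_ids = sprintf("s%02d", seq_len(n_samp)))
}

# Small, fast default scenario used across module tests.
desk_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 400L, n_signature = 30L, n_datasets = 3L,
         pairs_per_dataset = 10L, cohort_size = 150L,
         n_tumor_score_genes = 20L, seed = 11L),
    list(...))
  do.call(syn_config, args)
}

# Two separated Gaussian classes over a handful of genes.
two_class_expr <- function(n_per_class = 10, n_genes = 20, shift = 2,
                           n_informative = 5, seed = 3) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * 2 * n_per_class), n_genes)
  v[seq_len(n_informative), seq_len(n_per_class) + n_per_class] <-
    v[seq_len(n_informative), seq_len(n_per_class) + n_per_class] + shift
  list(expr = toy_expr(v),
       labels = rep(c("QT", "HIR"), each = n_per_class))
}
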