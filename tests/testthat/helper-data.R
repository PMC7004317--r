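# Build an expression table + metadata pair from a plain matrix.
make_expr <- function(mat, genes = sprintf("G%d", seq_len(nrow(mat))),
                      conditions) {
  samples <- sprintf("S%02d", seq_len(ncol(mat)))
  expr <- tibble::as_tibble(as.data.frame(mat))
  names(expr) <- samples
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes), expr)
  list(expr = expr,
       meta = tibble::tibble(sample_id = samples, condition = conditions))
}

# Eight unreported SSG candidates of the bundled adipose tables.
unreported_ssgs <- function() {
  st <- adipose_ssg_status()
  st$gene[st$role == "unreported"]
}
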