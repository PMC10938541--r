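# Shared test fixtures, built in code.

# a repertoire from a named count vector (names = CDR3s)
make_rep <- function(counts, sample_id = "S1", group = "UNKNOWN",
                     v_gene = NULL, j_gene = NULL) {
  n <- length(counts)
  repertoire(sample_id,
             data.frame(cdr3_aa = names(counts),
                        v_gene = if (is.null(v_gene)) rep("TRBV2", n) else v_gene,
                        j_gene = if (is.null(j_gene)) rep("TRBJ1-1", n) else j_gene,
                        chain = "TRB",
                        count = unname(counts),
                        stringsAsFactors = FALSE),
             group)
}

# small, fast synthetic spec for unit tests (not the study-scale defaults)
small_spec <- function(n_case = 10, n_control = 12, seed = 1,
                       implanted = topdown_signature_clones(freq_case = 5e-3),
                       n_undersized = 0, ...) {
  synthetic_spec(n_case = n_case, n_control = n_control,
                 umis_range = c(1500, 5000), background_pool_size = 1500,
                 implanted = implanted, n_undersized = n_undersized,
                 undersized_umis = 100, seed = seed, ...)
}

# a small cohort matrix with a given number of separating features:
# `signal` features have case frequencies shifted up
toy_matrix <- function(n_case = 10, n_control = 10, n_noise = 5,
                       n_signal = 2, shift = 1, seed = 1, sd = 0.3) {
  set.seed(seed)
  n <- n_case + n_control
  labels <- c(rep("OC", n_case), rep("HD", n_control))
  p <- n_signal + n_noise
  m <- matrix(abs(rnorm(p * n, sd = sd)), nrow = p)
  if (n_signal > 0) {
    m[seq_len(n_signal), labels == "OC"] <-
      m[seq_len(n_signal), labels == "OC"] + shift
  }
  keys <- c(sprintf("CSIG%02dF", seq_len(n_signal)),
            sprintf("CNSE%02dF", seq_len(n_noise)))[seq_len(p)]
  ids <- sprintf("S%02d", seq_len(n))
  dimnames(m) <- list(keys, ids)
  names(labels) <- ids
  structure(list(values = m, labels = labels), class = "cohort_matrix")
}
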