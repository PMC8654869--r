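# Shared fixtures, built in code at test time.

# tiny expression matrix with known content
tiny_expression <- function() {
  expression_matrix(matrix(c(1.5, 2.25, -0.5,
                             3.125, 0, 4.75), nrow = 3,
                           dimnames = list(c("TP53", "MYC", "EGFR"),
                                           c("S1", "S2"))))
}

# simulate a nonlinear chain A -> B -> C
chain3_data <- function(n = 500, seed = 1, noise = 0.3) {
  set.seed(seed)
  A <- rnorm(n)
  B <- sin(1.5 * A) + rnorm(n, 0, noise)
  C <- tanh(2 * B) + rnorm(n, 0, noise)
  expression_matrix(rbind(A = A, B = B, C = C),
                    c("A", "B", "C"), sprintf("s%04d", seq_len(n)))
}

# a small fitted network on the chain (cheap config for speed)
fast_score_config <- function() score_config(n_basis = 6L)

# survival fixture with hand-computable KM values: 6 records, mixed censoring
km_fixture <- function() {
  data.frame(sample_id = paste0("P", 1:6),
             time = c(1, 2, 2, 3, 4, 5),
             event = c(1, 1, 0, 1, 0, 1),
             stringsAsFactors = FALSE)
}
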