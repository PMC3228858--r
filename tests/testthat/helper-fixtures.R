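# Shared fixtures, all generated in code.

ref_model <- function() taxodium_cot_model()

two_component_model <- function() {
  cot_model(data.frame(fraction = c(0.5, 0.45), rate_k = c(1, 0.001)),
            foldback = 0.02)
}

# a batch of random valid models for property-style loops
random_models <- function(n, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- sample(1:4, 1)
    lk <- sort(runif(m, -5, 2), decreasing = TRUE)
    if (m > 1) while (min(abs(diff(lk))) < 0.4) lk <- sort(runif(m, -5, 2),
                                                           decreasing = TRUE)
    fb <- runif(1, 0, 0.1)
    sh <- rgamma(m, 1) + 0.2
    f <- (runif(1, 0.7, 0.98) - fb) * sh / sum(sh)
    cot_model(data.frame(fraction = f, rate_k = 10^lk), foldback = fb)
  })
}

# repeat-dense read fixture for plant-and-recover suites: fixture i carries
# 1-5 elements with TIR 10-20 nt, DR 2-8 nt, total length 150-400 bp
mite_fixture <- function(i) {
  n_elem <- ((i - 1) %% 5) + 1
  set.seed(1000 + i)
  el <- data.frame(tir_len = sample(10:20, n_elem, TRUE),
                   dr_len = sample(2:8, n_elem, TRUE))
  el$internal_len <- sample(150:400, n_elem, TRUE) - 2 * el$tir_len
  plant_mites(el, n_sequences = 1, seed = 2000 + i)
}
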