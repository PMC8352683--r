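# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no binary data.

# A minimal 2x2x2 taxonomy with 4 symptoms (gender + 3 somatic).
tiny_taxonomy <- function() {
  disease_taxonomy(
    categories = list(
      list(name = "cat_a", subclasses = list(
        list(name = "sub_a1", diseases = c("dis_a11", "dis_a12")),
        list(name = "sub_a2", diseases = c("dis_a21", "dis_a22")))),
      list(name = "cat_b", subclasses = list(
        list(name = "sub_b1", diseases = c("dis_b11", "dis_b12")),
        list(name = "sub_b2", diseases = c("dis_b21", "dis_b22"))))),
    symptom_names = c("gender", "s2", "s3", "s4"),
    code_base = 10)
}

# A random taxonomy with max_b categories, max_j subclasses each, max_t
# diseases each (full tree), used for codec property tests.
full_taxonomy <- function(max_b = 3, max_j = 3, max_t = 3, code_base = 10) {
  disease_taxonomy(
    categories = lapply(seq_len(max_b), function(b) {
      list(name = paste0("c", b), subclasses = lapply(seq_len(max_j), function(j) {
        list(name = paste0("s", b, j),
             diseases = paste0("d", b, j, seq_len(max_t)))
      }))
    }),
    symptom_names = c("gender", paste0("sym", 2:8)),
    code_base = code_base)
}

# Small disjoint-profile generator preset used where the full reference
# preset would be needlessly large: 2x2x2 tree, 20 symptoms.
small_disjoint_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(B = 2, T_b = 2, T_bj = 2, n_symptoms = 20, profile_size = c(2, 2),
         overlap = 0, flip_noise = 0, gender_bias = 0.5, n_per_disease = 6,
         global_disjoint = TRUE, seed = seed),
    list(...))
  do.call(generator_config, args)
}

small_disjoint_data <- function(seed = 1, ...) {
  cfg <- small_disjoint_config(seed = seed, ...)
  tp <- generate_taxonomy(cfg)
  list(config = cfg, taxonomy = tp$taxonomy, profiles = tp$profiles,
       records = generate_records(tp$taxonomy, tp$profiles, cfg))
}

# Straight-transcription oracle for the forward pass: explicit per-unit
# loops, independent of the package's vectorised/compiled implementations.
naive_forward <- function(W_in, W_out, x) {
  N <- length(x); Y <- ncol(W_in); G <- ncol(W_out)
  hn <- numeric(Y); ho <- numeric(Y)
  for (p in seq_len(Y)) {
    s <- 0
    for (n in seq_len(N)) s <- s + W_in[n, p] * x[n]
    hn[p] <- s - W_in[N + 1, p]          # threshold b_p via -1 bias unit
    ho[p] <- 1 / (1 + exp(-hn[p]))
  }
  yn <- numeric(G)
  for (q in seq_len(G)) {
    s <- 0
    for (p in seq_len(Y)) s <- s + W_out[p, q] * ho[p]
    yn[q] <- s - W_out[Y + 1, q]         # threshold theta_q
  }
  yo <- exp(yn) / sum(exp(yn))
  list(hn = hn, ho = ho, yn = yn, yo = yo)
}

# Central finite differences of the weighted cross-entropy loss with respect
# to every parameter of the network, at step h.
fd_gradients <- function(net, x, d, weight = 1, h = 1e-5) {
  loss_at <- function(net) nn_loss(nn_forward(net, x)$yo, d, weight)
  g_in <- net$W_in * 0
  for (i in seq_along(net$W_in)) {
    np <- net; np$W_in[i] <- np$W_in[i] + h
    nm <- net; nm$W_in[i] <- nm$W_in[i] - h
    g_in[i] <- (loss_at(np) - loss_at(nm)) / (2 * h)
  }
  g_out <- net$W_out * 0
  for (i in seq_along(net$W_out)) {
    np <- net; np$W_out[i] <- np$W_out[i] + h
    nm <- net; nm$W_out[i] <- nm$W_out[i] - h
    g_out[i] <- (loss_at(np) - loss_at(nm)) / (2 * h)
  }
  list(dW_in = g_in, dW_out = g_out)
}

# Random separable 2-D binary instance: two unit-variance clusters whose
# centres are at least `gap` apart along a random direction.
random_separable_2d <- function(n = 20, gap = 4) {
  dir <- stats::rnorm(2); dir <- dir / sqrt(sum(dir^2))
  n1 <- sample(2:(n - 2), 1)
  X <- rbind(
    matrix(stats::rnorm(n1 * 2, sd = 0.5), ncol = 2) +
      matrix(rep(dir * gap / 2, each = n1), ncol = 2),
    matrix(stats::rnorm((n - n1) * 2, sd = 0.5), ncol = 2) -
      matrix(rep(dir * gap / 2, each = n - n1), ncol = 2))
  list(X = X, y = c(rep(1, n1), rep(-1, n - n1)))
}
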