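# Shared generators for the test suite. Everything is built in code at
# test time; sizes are kept small so the default run stays fast.

# A small labeled synthetic recording (defaults: 8 channels, 7 classes,
# planted informative channels 3/5/8).
small_recording <- function(seed = 1, trial_duration = 0.5,
                            trials_per_class = 6, ...) {
  generate_recording(sim_config(trial_duration = trial_duration,
                                trials_per_class = trials_per_class, ...),
                     seed = seed)
}

# A random MTSR instance (dense X, one-hot Y).
random_mtsr_instance <- function(seed, d = 10, n = 30, c = 3) {
  set.seed(seed)
  X <- matrix(rnorm(d * n), d, n)
  Y <- class_indicator(sample(seq_len(c), n, replace = TRUE),
                       classes = seq_len(c))
  list(X = X, Y = Y)
}

# An MTSR instance whose response is driven by a known set of rows.
planted_mtsr_instance <- function(seed, d = 12, n = 60, c = 3,
                                  support = 1:3, snr = 8) {
  set.seed(seed)
  X <- matrix(rnorm(d * n), d, n)
  W <- matrix(0, d, c)
  W[support, ] <- snr * matrix(rnorm(length(support) * c), length(support))
  Y <- crossprod(W, X) + 0.1 * matrix(rnorm(c * n), c, n)
  list(X = X, Y = Y, support = sort(support))
}

# Independent mutual information via the entropy identity
# I = H(A) + H(B) - H(A,B); used by the brute-force mRMR oracle so the
# oracle shares no code path with mutual_information().
mi_entropy <- function(a, b) {
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  H(a) + H(b) - H(paste(a, b))
}

# Brute-force incremental mRMR (difference criterion), recomputing the
# full MI tables from scratch at every step.
mrmr_bruteforce <- function(states, labels, m) {
  d <- nrow(states)
  sel <- integer(0)
  for (step in seq_len(m)) {
    best <- -Inf; pick <- NA_integer_
    for (j in setdiff(seq_len(d), sel)) {
      rel <- mi_entropy(states[j, ], labels)
      red <- if (length(sel) == 0) 0
             else mean(vapply(sel, function(i)
               mi_entropy(states[j, ], states[i, ]), numeric(1)))
      score <- rel - red
      if (score > best + 1e-12) { best <- score; pick <- j }
    }
    sel <- c(sel, pick)
  }
  sel
}
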