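test_that("mean +/- 0.5 SD discretization codes rows into at most three states", {
  m <- matrix(c(-10, 0, 10, 0), 1, 4)
  d <- discretize(m)
  # mean 0, sd = sqrt(200/3) ~ 8.16; thresholds at -/+ 4.08
  expect_equal(as.integer(d$states), c(-1L, 0L, 1L, 0L))

  dc <- discretize(matrix(7, 1, 5))
  expect_true(all(dc$states == 0L))

  set.seed(41)
  dr <- discretize(matrix(rnorm(300), 3, 100))
  expect_true(all(dr$alphabet_sizes <= 3))
  expect_true(all(dr$states %in% c(-1L, 0L, 1L)))

  dq <- discretize(matrix(runif(100), 1, 100), scheme = "equalfreq", bins = 4)
  expect_equal(sort(unique(as.integer(dq$states))), 1:4)
})

test_that("mutual information matches hand-computed values and is a proper MI", {
  a <- rep(c(0, 1), 8)
  expect_equal(mutual_information(a, a), 1)     # H(X) of a uniform bit

  # independence by construction: all four joint cells equally frequent
  x <- c(0, 0, 1, 1); y <- c(0, 1, 0, 1)
  expect_equal(mutual_information(x, y), 0)

  # joint counts [[2,1],[1,2]] over n = 6: direct four-term sum
  a2 <- c(0, 0, 0, 1, 1, 1)
  b2 <- c(0, 0, 1, 0, 1, 1)
  p <- c(2, 1, 1, 2) / 6
  marg <- c(0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5)
  expect_equal(mutual_information(a2, b2), sum(p * log2(p / marg)),
               tolerance = 1e-12)

  expect_error(mutual_information(1:3, 1:4), "equal length")

  set.seed(42)
  for (i in 1:10) {
    u <- sample(0:2, 50, replace = TRUE)
    v <- sample(0:3, 50, replace = TRUE)
    expect_gte(mutual_information(u, v), -1e-12)
    expect_lt(abs(mutual_information(u, v) - mutual_information(v, u)), 1e-12)
    # MI(a, a) equals the empirical entropy of a
    pu <- table(u) / length(u)
    expect_equal(mutual_information(u, u), -sum(pu * log2(pu)))
    # bijective recoding of states changes nothing
    expect_equal(mutual_information(u, v),
                 mutual_information(c(9, 5, 7)[u + 1], v))
  }
})

test_that("greedy ranking matches the brute-force incremental oracle", {
  set.seed(43)
  for (trial in 1:8) {
    d <- sample(5:8, 1); n <- 40
    labels <- sample(letters[1:3], n, replace = TRUE)
    states <- matrix(sample(-1:1, d * n, replace = TRUE), d, n)
    # give some rows label structure so relevance varies
    for (r in 1:2) states[r, labels == "a"] <- sample(0:1, sum(labels == "a"),
                                                      replace = TRUE)
    disc <- structure(list(states = states,
                           scheme = list(method = "given"),
                           alphabet_sizes = rep(3L, d)),
                      class = "semg_disc")
    m <- sample(seq_len(d), 1)
    got <- attr(mrmr_rank(disc, labels, m), "order")
    expect_equal(got, mrmr_bruteforce(states, labels, m))
  }
})

test_that("mRMR prefers a non-redundant variable over a duplicate and honors m", {
  n <- 20
  labels <- rep(0:1, 10)
  flip <- function(x, at) { x[at] <- 1 - x[at]; x }
  x1 <- flip(labels, 1:2)     # noisy copy of the label
  x2 <- x1                    # exact duplicate: redundancy is maximal
  x3 <- flip(labels, 3:4)     # equally relevant (same flip pattern), not a duplicate
  disc <- structure(list(states = rbind(x1, x2, x3),
                         scheme = list(method = "given"),
                         alphabet_sizes = rep(2L, 3)),
                    class = "semg_disc")
  idx <- data.frame(channel = c("c1", "c1", "c2"),
                    feature = c("f1", "f2", "f3"))
  vs <- mrmr_rank(disc, labels, m = 2, row_index = idx)
  ord <- attr(vs, "order")
  expect_equal(ord[1], 1)      # ties on relevance break to the lower index
  expect_equal(ord[2], 3)      # the duplicate is never preferred
  expect_error(mrmr_rank(disc, labels, m = 4), "between 1")
  expect_equal(nrow(mrmr_rank(disc, labels, m = 1)), 1)
})

test_that("ranking is invariant to sample-order permutation", {
  set.seed(45)
  n <- 50; d <- 6
  labels <- sample(letters[1:3], n, replace = TRUE)
  states <- matrix(sample(-1:1, d * n, replace = TRUE), d, n)
  disc <- structure(list(states = states, scheme = list(method = "given"),
                         alphabet_sizes = rep(3L, d)),
                    class = "semg_disc")
  perm <- sample(n)
  disc_p <- disc
  disc_p$states <- states[, perm]
  expect_equal(attr(mrmr_rank(disc, labels, 4), "order"),
               attr(mrmr_rank(disc_p, labels[perm], 4), "order"))
})
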