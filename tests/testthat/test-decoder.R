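mk_maps <- function(rate, bin_cm = 10) {
  structure(list(rate = rate, occupancy_s = rep(1, ncol(rate)),
                 bin_cm = bin_cm, edges = seq(0, ncol(rate) * bin_cm, bin_cm),
                 track_length = ncol(rate) * bin_cm, smoothed = FALSE,
                 direction = "both"), class = "rk_ratemaps")
}

test_that("posterior peaks at the active field and is uniform without evidence", {
  r <- matrix(0.01, 1, 5, dimnames = list("1", NULL))
  r[1, 3] <- 20
  counts <- matrix(1, 1, 1, dimnames = list("1", NULL))
  post <- decode_posterior(counts, list(`1` = mk_maps(r)), tau = 0.02)
  expect_equal(which.max(post$prob[, 1]), 3)

  flat <- matrix(2, 3, 5, dimnames = list(1:3, NULL))
  zeros <- matrix(0, 3, 2, dimnames = list(1:3, NULL))
  post2 <- decode_posterior(zeros, list(`1` = mk_maps(flat)), tau = 0.02)
  expect_equal(post2$prob, matrix(0.2, 5, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(colSums(post2$prob) - 1) < 1e-12))
})

test_that("the decoder matches the direct product-form evaluation", {
  # the hand-set 2-unit x 3-bin instance
  r <- matrix(c(1, 5, 0.2, 3, 0.5, 8), 2, 3, dimnames = list(1:2, NULL))
  counts <- matrix(c(1, 2), 2, 1, dimnames = list(1:2, NULL))
  post <- decode_posterior(counts, list(`1` = mk_maps(r)), tau = 0.02)
  expect_equal(post$prob, decode_oracle(counts, r, 0.02), tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(4)
  for (k in 1:25) {
    N <- sample(2:6, 1); nb <- sample(3:8, 1); nt <- sample(1:6, 1)
    r <- matrix(rexp(N * nb, 1 / 5), N, nb, dimnames = list(1:N, NULL))
    r[runif(N * nb) < 0.2] <- 0
    counts <- matrix(rpois(N * nt, 1), N, nt, dimnames = list(1:N, NULL))
    tau <- runif(1, 0.01, 0.3)
    post <- decode_posterior(counts, list(`1` = mk_maps(r)), tau)
    expect_equal(post$prob, decode_oracle(counts, r, tau), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("decoding is invariant to unit relabeling and joint rate/time scaling", {
  set.seed(5)
  r <- matrix(rexp(4 * 6, 1 / 5), 4, 6, dimnames = list(1:4, NULL))
  counts <- matrix(rpois(4 * 3, 1.5), 4, 3, dimnames = list(1:4, NULL))
  p1 <- decode_posterior(counts, list(`1` = mk_maps(r)), 0.02)
  perm <- c(3, 1, 4, 2)
  r2 <- r[perm, ]; rownames(r2) <- as.character(perm)
  c2 <- counts[perm, ]; rownames(c2) <- as.character(perm)
  p2 <- decode_posterior(c2, list(`1` = mk_maps(r2)), 0.02)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)

  # scaling rates by c and tau by 1/c leaves the argmax unchanged
  p3 <- decode_posterior(counts, list(`1` = mk_maps(3 * r)), 0.02 / 3,
                         rate_floor = 0.03)
  expect_equal(apply(p1$prob, 2, which.max), apply(p3$prob, 2, which.max))

  bad <- counts; rownames(bad) <- as.character(5:8)
  expect_error(decode_posterior(bad, list(`1` = mk_maps(r)), 0.02),
               "mismatched unit sets")
})

test_that("two-track normalization sums each column to one across both tracks", {
  set.seed(6)
  r1 <- matrix(rexp(5 * 4), 5, 4, dimnames = list(1:5, NULL))
  r2 <- matrix(rexp(5 * 4), 5, 4, dimnames = list(1:5, NULL))
  counts <- matrix(rpois(5 * 3, 1), 5, 3, dimnames = list(1:5, NULL))
  post <- decode_posterior(counts, list(`1` = mk_maps(r1), `2` = mk_maps(r2)), 0.02)
  expect_equal(colSums(post$prob), rep(1, 3))
  expect_equal(post$track, rep(c(1L, 2L), each = 4))
})

test_that("decoding QC passes on the synthetic re-exposures", {
  ss <- small_session()
  beh <- small_behavior()
  roster <- small_roster()
  pu <- roster$unit_id[roster$place_t1 | roster$place_t2]
  qc <- decoding_qc(ss$session, beh$linpos, small_decode_maps(2), pu)
  expect_true(all(qc$median_error_cm <= 15))
  expect_true(qc$pass)
  expect_true(all(unlist(qc$errors) >= 0))
  expect_error(decoding_qc(ss$session, beh$linpos, small_decode_maps(2), pu,
                           epochs = "RUN9_T1"), "no run windows")
})
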