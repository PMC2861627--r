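test_that("distance is a pseudometric that neglects x and positive self-feedback", {
  d <- drosophila_network(TRUE, TRUE)
  expect_equal(network_distance(d, d), 0L)
  k <- knockout(d, "Kr", "pdm")
  expect_equal(network_distance(d, k), 1L)
  # positive self-feedback on the diagonal is invisible
  dself <- unclass(d); dself["Kr", "Kr"] <- 1L
  expect_equal(network_distance(d, sign_network(dself)), 0L)
  # but a negative self-slot counts
  dneg <- unclass(d); dneg["Kr", "Kr"] <- -5L
  expect_equal(network_distance(d, sign_network(dneg)), 1L)
  # x-column differences are never counted
  dx <- unclass(d); dx["pdm", "x"] <- 1L
  expect_equal(network_distance(d, sign_network(dx)), 0L)
  # symmetry and triangle inequality on random triples
  set.seed(606)
  for (i in 1:100) {
    abc <- random_codes(3, include_x = TRUE)
    expect_equal(network_distance(abc[1], abc[2]), network_distance(abc[2], abc[1]))
    expect_lte(network_distance(abc[1], abc[3]),
               network_distance(abc[1], abc[2]) + network_distance(abc[2], abc[3]))
  }
})

test_that("the analytic all-networks distance oracle matches sampled enumeration", {
  oracle <- all_networks_distance_oracle()
  expect_equal(sum(oracle$pmf), 1, tolerance = 1e-12)
  set.seed(707)
  codes <- random_codes(40000, include_x = TRUE)
  ed <- ensemble_distances(codes)
  expect_equal(ed$mean, oracle$mean, tolerance = 4 * oracle$sd / sqrt(40000) / oracle$mean)
  expect_equal(ed$sd, oracle$sd, tolerance = 0.05)
  # distribution-level agreement
  emp <- as.numeric(ed$histogram) / ed$n
  expect_lt(max(abs(emp - oracle$pmf)), 0.01)
})

test_that("reconnection preserves the sign-count multiset and fixes x slots", {
  d <- drosophila_network(TRUE, TRUE)
  set.seed(808)
  r <- reconnect_network(d)
  expect_equal(sort(as.vector(unclass(r)[, 1:4])), sort(as.vector(unclass(d)[, 1:4])))
  expect_equal(unclass(r)[, "x"], unclass(d)[, "x"])
  # the all-zero network is a fixed point of reconnection
  z <- decode_network(0, include_x = TRUE)
  expect_equal(unclass(reconnect_network(z)), unclass(z))
  # ensemble version: per-network value multisets preserved
  codes <- c(encode_network(d), encode_network(minimum_network()))
  ens <- reconnect_ensemble(codes, per_network = 5, n_iter = 100)
  expect_equal(length(ens), 10L)
  digs_src <- nbcascade:::slot_digits12(codes, neglect_self_activation = FALSE)
  digs_out <- nbcascade:::slot_digits12(ens, neglect_self_activation = FALSE)
  for (i in 1:10) {
    src <- digs_src[ceiling(i / 5), ]
    expect_equal(sort(digs_out[i, ]), sort(src))
  }
  # reproducibility under a fixed seed
  set.seed(42); e1 <- reconnect_ensemble(codes, 5, 100)
  set.seed(42); e2 <- reconnect_ensemble(codes, 5, 100)
  expect_identical(e1, e2)
})

test_that("collapsing positive self-feedback deduplicates, never grows the set", {
  d <- encode_network(drosophila_network(TRUE, TRUE))
  dself <- d + 3^1          # add Kr self-activation (digit 0 -> 1 at slot 1)
  out <- collapse_self_feedback(c(d, dself))
  expect_equal(out, d)
  # a set without self-feedback is untouched
  m <- encode_network(minimum_network())
  expect_equal(collapse_self_feedback(c(d, m)), sort(c(d, m)))
  set.seed(909)
  codes <- random_codes(200, include_x = TRUE)
  expect_lte(length(collapse_self_feedback(codes)), 200L)
})
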