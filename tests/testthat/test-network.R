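test_that("the reference network carries the literature regulations", {
  J <- drosophila_network(include_hb_cas = TRUE, include_x = FALSE)
  expect_equal(J["Kr", "hb"], 1L)
  expect_equal(J["pdm", "hb"], -5L)
  expect_equal(J["cas", "hb"], -5L)
  expect_equal(J["pdm", "Kr"], 1L)
  expect_equal(J["cas", "Kr"], -5L)
  expect_equal(J["Kr", "pdm"], -5L)
  expect_equal(J["cas", "pdm"], 1L)
  expect_equal(J["pdm", "cas"], -5L)
  expect_equal(unname(unclass(J)[cbind(c("Kr", "pdm", "cas"),
                                       c("Kr", "pdm", "cas"))]),
               c(0L, 0L, 0L))
  expect_equal(drosophila_network(FALSE, FALSE)["cas", "hb"], 0L)
  Jx <- drosophila_network(TRUE, TRUE)
  expect_equal(Jx["Kr", "x"], 1L)
  expect_equal(Jx["cas", "x"], -5L)
  expect_equal(Jx["pdm", "x"], 0L)
})

test_that("base-3 codes round-trip and cover the enumeration space", {
  expect_equal(encode_network(decode_network(0, FALSE)), 0)
  all_rep <- decode_network(3^12 - 1, include_x = FALSE)
  expect_true(all(all_rep == -5L))   # highest digit maps to the repression level
  set.seed(101)
  for (inc in c(FALSE, TRUE)) {
    codes <- random_codes(100, inc)
    rt <- vapply(codes, function(cd) encode_network(decode_network(cd, inc)), 0)
    expect_identical(rt, codes)
  }
  expect_error(decode_network(3^12, FALSE), "range")
  expect_error(decode_network(-1, TRUE), "range")
})

test_that("12- and 15-slot variants interconvert", {
  d <- drosophila_network(TRUE, FALSE)
  dx <- with_x(d)
  expect_true(attr(dx, "include_x"))
  expect_equal(unname(dx[, "x"]), c(0L, 0L, 0L))
  expect_equal(without_x(dx), d)
  expect_error(without_x(drosophila_network(TRUE, TRUE)), "x regulations")
})

test_that("knockout removes exactly one slot and rejects absent regulations", {
  d <- drosophila_network(TRUE, TRUE)
  k <- knockout(d, "Kr", "pdm")
  expect_equal(k["pdm", "Kr"], 0L)
  expect_equal(sum(unclass(k) != unclass(d)), 1L)
  expect_equal(network_distance(d, k), 1L)
  expect_error(knockout(d, "x", "pdm"), "absent")
  # removing the three non-minimum regulations recovers the minimum network
  m <- knockout(knockout(knockout(d, "Kr", "pdm"), "pdm", "cas"), "hb", "cas")
  expect_equal(unclass(m), unclass(minimum_network()))
})

test_that("edge-list and JSON serialization round-trip", {
  d <- drosophila_network(TRUE, TRUE)
  el <- as_edgelist(d)
  expect_equal(nrow(el), 10L)
  expect_equal(unclass(network_from_edgelist(el)), unclass(d))
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(d, path)
  expect_equal(unclass(read_network_json(path)), unclass(d))
})

test_that("edge-list CSV serialization round-trips", {
  d <- drosophila_network(TRUE, TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(d, path)
  expect_equal(unclass(read_network_csv(path)), unclass(d))
})
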