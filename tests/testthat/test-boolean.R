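mk_state <- function(...) {
  st <- setNames(integer(6), c("hb", "Kr", "pdm", "cas", "svp", "x"))
  args <- list(...)
  st[names(args)] <- as.integer(unlist(args))
  st
}

test_that("the update rule follows sign, repressor dominance and defaults", {
  dx <- drosophila_network(TRUE, TRUE)
  zeros <- c(Kr = 0L, pdm = 0L, cas = 0L)
  # hand evaluation: hb and x ON -> Kr sum +2, pdm sum -5, cas sum -10
  nxt <- boolean_step(mk_state(hb = 1, x = 1), dx, zeros)
  expect_equal(unname(nxt[c("Kr", "pdm", "cas")]), c(1L, 0L, 0L))
  # zero network: every sum is 0, defaults apply
  z <- decode_network(0, include_x = TRUE)
  nxt <- boolean_step(mk_state(hb = 1), z, c(Kr = 1L, pdm = 0L, cas = 1L))
  expect_equal(unname(nxt[c("Kr", "pdm", "cas")]), c(1L, 0L, 1L))
  # overexpression clamp wins over any input
  nxt <- boolean_step(mk_state(pdm = 1), dx, zeros, genotype("Kr", "overexpression"))
  expect_equal(unname(nxt["Kr"]), 1L)
})

test_that("a single active repressor silences a fully activated target", {
  # property: with at most four +1 activators, one -5 repressor dominates
  set.seed(202)
  for (i in 1:200) {
    net <- decode_network(random_codes(1, TRUE), include_x = TRUE)
    st <- mk_state(hb = 1, Kr = 1, pdm = 1, cas = 1, x = 1)
    nxt <- boolean_step(st, net, c(Kr = 1L, pdm = 1L, cas = 1L))
    for (tg in c("Kr", "pdm", "cas"))
      if (any(unclass(net)[tg, ] == -5L)) expect_equal(unname(nxt[tg]), 0L)
  }
})

test_that("simulated trajectories honour inputs, clamps and determinism", {
  dx <- drosophila_network(TRUE, TRUE)
  sch <- input_schedule(10, 6)
  tr <- simulate_boolean(dx, "wt", c(Kr = 0L, pdm = 1L, cas = 1L), sch)
  expect_equal(dim(tr), c(6L, 11L))
  expect_equal(unname(tr["hb", 1:3]), c(1L, 1L, 0L))   # svp pulse switches hb off
  expect_equal(unname(tr["svp", ]), c(0L, 1L, rep(0L, 9)))
  expect_equal(unname(tr["x", ]), c(rep(1L, 6), rep(0L, 5)))
  tr2 <- simulate_boolean(dx, "wt", c(Kr = 0L, pdm = 1L, cas = 1L), sch)
  expect_identical(tr, tr2)
  # hb loss: hb row identically zero for any network
  set.seed(303)
  for (cd in random_codes(20, TRUE)) {
    trm <- simulate_boolean(decode_network(cd, TRUE), "hb-",
                            c(Kr = 0L, pdm = 0L, cas = 0L), sch)
    expect_true(all(trm["hb", ] == 0L))
  }
  # clamp dominance at every step
  tro <- simulate_boolean(dx, "cas++", c(Kr = 0L, pdm = 0L, cas = 0L), sch)
  expect_true(all(tro["cas", ] == 1L))
  trl <- simulate_boolean(dx, "Kr-", c(Kr = 1L, pdm = 0L, cas = 0L), sch)
  expect_true(all(trl["Kr", ] == 0L))
})

test_that("the wild-type cascade passes through the four pure phases in order", {
  dx <- drosophila_network(TRUE, TRUE)
  tr <- simulate_boolean(dx, "wt", c(Kr = 0L, pdm = 1L, cas = 1L),
                         input_schedule(10, 6))
  comp <- compress_trajectory(tr)
  keys <- apply(comp, 2, paste, collapse = "")
  pure <- c("1000", "0100", "0010", "0001")   # hb, Kr, pdm, cas alone
  pos <- match(pure, keys)
  expect_false(anyNA(pos))
  expect_true(all(diff(pos) > 0))
})

test_that("compression removes duplicates and is idempotent", {
  const <- matrix(1L, 6, 5, dimnames = list(c("hb", "Kr", "pdm", "cas", "svp", "x"), 0:4))
  expect_equal(ncol(compress_trajectory(const)), 1L)
  dx <- drosophila_network(TRUE, TRUE)
  tr <- simulate_boolean(dx, "wt", c(Kr = 1L, pdm = 0L, cas = 0L),
                         input_schedule(10, 4))
  c1 <- compress_trajectory(tr)
  expect_identical(compress_trajectory(c1), c1)
})

test_that("expression windows summarize onsets, offsets and segments", {
  m <- matrix(0L, 6, 6, dimnames = list(c("hb", "Kr", "pdm", "cas", "svp", "x"), 0:5))
  m["hb", 1:2] <- 1L
  m["Kr", c(2, 3, 5, 6)] <- 1L
  w <- expression_windows(m)
  expect_equal(w$onset[w$gene == "hb"], 0)
  expect_equal(w$offset[w$gene == "hb"], 1)
  expect_equal(w$segments[w$gene == "Kr"], 2L)
  expect_true(is.na(w$onset[w$gene == "cas"]))
})
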