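# Architecture statistics: distances to the reference network, ensemble
# distributions, sign-preserving reconnection nulls, self-feedback collapse.
#
# Distance convention: only the 12 non-x slots are compared; positive
# self-feedback (a +1 on the diagonal) is neglected, i.e. mapped to 0 in
# both operands before counting differing sign classes.  x regulations are
# never counted.

# 12-slot digit matrix (n x 12) from 15-slot codes, self +1 mapped to 0.
# Slot order: target-major (Kr,pdm,cas) x regulator (hb,Kr,pdm,cas).
slot_digits12 <- function(codes, neglect_self_activation = TRUE) {
  out <- matrix(0L, length(codes), 12L)
  for (i in 1:3) for (j in 1:4) {
    k <- (i - 1L) * 5L + (j - 1L)
    out[, (i - 1L) * 4L + j] <- as.integer((codes %/% 3^k) %% 3)
  }
  if (neglect_self_activation) {
    for (i in 1:3) {
      sp <- (i - 1L) * 4L + i + 1L   # Kr<-Kr at col 2, pdm<-pdm col 7, cas<-cas col 12
      out[, sp] <- ifelse(out[, sp] == 1L, 0L, out[, sp])
    }
  }
  out
}

code15_of <- function(network) encode_network(with_x(network))

#' Distance between two sign networks
#'
#' Number of regulations (out of the 12 non-x slots) whose sign class
#' differs, after neglecting positive self-feedback in both networks.  x
#' regulations are excluded from the count.
#'
#' @param a,b `sign_network`s or 15-slot integer codes.
#' @return integer distance in `[0, 12]`.
#' @export
network_distance <- function(a, b) {
  ca <- if (inherits(a, "sign_network")) code15_of(a) else a
  cb <- if (inherits(b, "sign_network")) code15_of(b) else b
  sum(slot_digits12(ca) != slot_digits12(cb))
}

#' Distance statistics of a network ensemble
#'
#' @param codes integer vector of 15-slot codes (an ensemble).
#' @param reference reference `sign_network` (default: the Drosophila network
#'   with the hb-|cas repression and the x regulations).
#' @return a `distance_report`: per-network distances, mean, sd, histogram.
#' @export
ensemble_distances <- function(codes, reference = drosophila_network(TRUE, TRUE)) {
  ref <- slot_digits12(code15_of(reference))
  digs <- slot_digits12(codes)
  d <- rowSums(digs != matrix(ref, nrow(digs), 12L, byrow = TRUE))
  structure(list(distances = d, mean = mean(d), sd = sd(d),
                 histogram = table(factor(d, levels = 0:12)), n = length(d)),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("ensemble of %d networks: mean distance %.2f (sd %.2f)\n",
              x$n, x$mean, x$sd))
  print(x$histogram)
  invisible(x)
}

#' Analytic distance distribution over the full network space
#'
#' Closed-form oracle for the distance of a uniformly random network to the
#' reference, under the same counting convention.  Each of the 12 slots is
#' independent and uniform over the three levels; on diagonal slots the +1
#' level is folded into 0.  The per-slot mismatch probabilities are convolved
#' exactly.
#'
#' @param reference reference network.
#' @return list: probability vector over distances 0..12, mean, sd.
#' @export
all_networks_distance_oracle <- function(reference = drosophila_network(TRUE, TRUE)) {
  ref <- slot_digits12(code15_of(reference))
  pmf <- 1
  for (s in 1:12) {
    selfslot <- s %in% c(2L, 7L, 12L)
    if (selfslot) {
      lv <- c(0L, 0L, 2L)   # +1 folded into 0
    } else lv <- c(0L, 1L, 2L)
    p_mis <- mean(lv != ref[s])
    pmf <- c(pmf * (1 - p_mis), 0) + c(0, pmf * p_mis)
  }
  d <- 0:12
  list(pmf = pmf, mean = sum(d * pmf),
       sd = sqrt(sum(d^2 * pmf) - sum(d * pmf)^2))
}

#' Sign-count-preserving reconnection of a network
#'
#' Randomly reshuffles the values of the 12 non-x slots by iterated pairwise
#' swaps (default 1,000 iterations), preserving the numbers of positive and
#' negative regulations.  x regulations are held fixed.
#'
#' @param network a `sign_network`.
#' @param n_iter number of swap iterations.
#' @return a reconnected `sign_network`.
#' @export
reconnect_network <- function(network, n_iter = 1000L) {
  network <- with_x(network)
  J <- unclass(network)
  vals <- as.vector(J[, 1:4])
  for (i in seq_len(n_iter)) {
    p <- sample.int(12L, 2L, replace = TRUE)
    vals[p] <- vals[c(p[2], p[1])]
  }
  J[, 1:4] <- vals
  sign_network(J)
}

#' Reconnection null ensemble
#'
#' Generates `per_network` reconnected draws from each network of an
#' ensemble (vectorized across all draws).
#'
#' @param codes 15-slot codes of the source ensemble.
#' @param per_network draws per source network (default 100).
#' @param n_iter swap iterations per draw (default 1000).
#' @return integer vector of 15-slot codes of the reconnected ensemble.
#' @export
reconnect_ensemble <- function(codes, per_network = 100L, n_iter = 1000L) {
  digs <- slot_digits12(codes, neglect_self_activation = FALSE)
  E <- digs[rep(seq_along(codes), each = per_network), , drop = FALSE]
  NE <- nrow(E)
  idx <- seq_len(NE)
  for (i in seq_len(n_iter)) {
    p1 <- sample.int(12L, NE, replace = TRUE)
    p2 <- sample.int(12L, NE, replace = TRUE)
    v1 <- E[cbind(idx, p1)]
    E[cbind(idx, p1)] <- E[cbind(idx, p2)]
    E[cbind(idx, p2)] <- v1
  }
  # rebuild 15-slot codes: x digits inherited from the source networks
  xd <- matrix(0, length(codes), 3L)
  for (i in 1:3) xd[, i] <- (codes %/% 3^((i - 1L) * 5L + 4L)) %% 3
  xd <- xd[rep(seq_along(codes), each = per_network), , drop = FALSE]
  out <- numeric(NE)
  for (i in 1:3) for (j in 1:4)
    out <- out + E[, (i - 1L) * 4L + j] * 3^((i - 1L) * 5L + (j - 1L))
  for (i in 1:3) out <- out + xd[, i] * 3^((i - 1L) * 5L + 4L)
  out
}

#' Collapse positive self-feedback and deduplicate
#'
#' Maps every +1 diagonal entry (Kr->Kr, pdm->pdm, cas->cas) to 0 in each
#' network of the set and returns the distinct resulting networks.
#'
#' @param codes 15-slot codes.
#' @return sorted integer vector of distinct collapsed codes.
#' @export
collapse_self_feedback <- function(codes) {
  out <- codes
  for (i in 1:3) {
    k <- (i - 1L) * 5L + (i - 1L) + 1L   # self slot exponent: Kr 1, pdm 7, cas 13
    dig <- (out %/% 3^k) %% 3
    out <- out - (dig == 1) * 3^k
  }
  sort(unique(out))
}
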