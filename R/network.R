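#' @useDynLib nbcascade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd cor setNames convolve
#' @importFrom utils write.csv read.csv
NULL

# Gene sets.  svp is implicit: its only action, the pulse that switches hb
# off, is hard-wired into the input schedule (J[hb, svp] = -5, everything
# else involving svp is structurally zero).
GENES      <- c("hb", "Kr", "pdm", "cas", "svp", "x")
TARGETS    <- c("Kr", "pdm", "cas")
REGULATORS <- c("hb", "Kr", "pdm", "cas", "x")

# Three-level regulation values and their frozen base-3 digit encoding.
# digit 0 <-> 0 (absent), digit 1 <-> +1 (activation), digit 2 <-> -5
# (repression; dominant over any sum of activations).
J_LEVELS <- c(0L, 1L, -5L)

#' Construct a sign network
#'
#' A sign network is the integer matrix `J[target, regulator]` of three-level
#' regulation values over targets Kr, pdm, cas and regulators hb, Kr, pdm,
#' cas and (optionally) the presumptive extra factor x.  Entries must be one
#' of `0` (no regulation), `+1` (activation) or `-5` (repression).  The
#' repression level is large in magnitude so that a single active repressor
#' dominates any attainable sum of activations.
#'
#' @param values integer matrix with rownames `c("Kr","pdm","cas")` and
#'   colnames `c("hb","Kr","pdm","cas")` or `c("hb","Kr","pdm","cas","x")`.
#' @return an object of class `sign_network`.
#' @export
sign_network <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- TARGETS
  include_x <- ncol(values) == 5L
  if (is.null(colnames(values)))
    colnames(values) <- if (include_x) REGULATORS else REGULATORS[1:4]
  stopifnot(identical(rownames(values), TARGETS),
            identical(colnames(values), if (include_x) REGULATORS else REGULATORS[1:4]),
            all(values %in% J_LEVELS))
  storage.mode(values) <- "integer"
  structure(values, class = "sign_network", include_x = include_x)
}

#' @export
print.sign_network <- function(x, ...) {
  sym <- matrix(c("0", "+", "-")[match(unclass(x), J_LEVELS)],
                nrow(x), ncol(x), dimnames = dimnames(x))
  cat("sign network (rows: targets, columns: regulators)\n")
  print(sym, quote = FALSE)
  cat("code:", encode_network(x), if (attr(x, "include_x")) "(15-slot)" else "(12-slot)", "\n")
  invisible(x)
}

#' The reconstructed Drosophila temporal-patterning network
#'
#' Activations hb->Kr, Kr->pdm, pdm->cas; repressions hb-|pdm, Kr-|cas,
#' pdm-|Kr, cas-|pdm; the literature-suggested (but unverified) repression
#' hb-|cas optionally; and, when `include_x` is set, the two regulations of
#' the predicted extra factor x: x->Kr and x-|cas.  The svp-|hb pulse is
#' implicit in the input schedule.
#'
#' @param include_hb_cas include the hb-|cas repression (default TRUE; this
#'   is the variant meant when "the Drosophila network" is invoked).
#' @param include_x add the x column with x->Kr and x-|cas.
#' @return a `sign_network`.
#' @export
drosophila_network <- function(include_hb_cas = TRUE, include_x = FALSE) {
  J <- matrix(0L, 3, 5, dimnames = list(TARGETS, REGULATORS))
  J["Kr",  "hb"]  <- 1L
  J["pdm", "Kr"]  <- 1L
  J["cas", "pdm"] <- 1L
  J["pdm", "hb"]  <- -5L
  J["cas", "Kr"]  <- -5L
  J["Kr",  "pdm"] <- -5L
  J["pdm", "cas"] <- -5L
  if (include_hb_cas) J["cas", "hb"] <- -5L
  if (include_x) {
    J["Kr",  "x"] <- 1L
    J["cas", "x"] <- -5L
  } else {
    J <- J[, 1:4]
  }
  sign_network(J)
}

#' The minimum functional network
#'
#' The regulations shared by every functional network found in the exhaustive
#' screen: hb->Kr, hb-|pdm, Kr-|cas, pdm-|Kr, cas-|pdm plus x->Kr and x-|cas.
#' Sufficient for sequential expression, but much less robust than the full
#' Drosophila network.
#'
#' @return a `sign_network` (15-slot).
#' @export
minimum_network <- function() {
  J <- matrix(0L, 3, 5, dimnames = list(TARGETS, REGULATORS))
  J["Kr", "hb"] <- 1L
  J["pdm", "hb"] <- -5L
  J["cas", "Kr"] <- -5L
  J["Kr", "pdm"] <- -5L
  J["pdm", "cas"] <- -5L
  J["Kr", "x"] <- 1L
  J["cas", "x"] <- -5L
  sign_network(J)
}

#' Convert between 12-slot and 15-slot networks
#'
#' @param network a `sign_network`.
#' @return `with_x()` zero-fills the x column; `without_x()` drops it (an
#'   error if any x regulation is nonzero).
#' @export
with_x <- function(network) {
  if (attr(network, "include_x")) return(network)
  J <- cbind(unclass(network), x = 0L)
  sign_network(J)
}

#' @rdname with_x
#' @export
without_x <- function(network) {
  if (!attr(network, "include_x")) return(network)
  if (any(network[, "x"] != 0L))
    stop("network has nonzero x regulations; cannot drop the x column")
  sign_network(unclass(network)[, 1:4])
}

#' Encode a sign network as a base-3 integer code
#'
#' Slots are ordered target-major (Kr, pdm, cas) and regulator-minor (hb, Kr,
#' pdm, cas, then x for 15-slot networks), with the first slot as the least
#' significant digit.  Digits map 0 -> J = 0, 1 -> J = +1, 2 -> J = -5.
#' Codes run in `[0, 3^12)` for 12-slot networks and `[0, 3^15)` with x.
#'
#' @param network a `sign_network`.
#' @return integer code.
#' @export
encode_network <- function(network) {
  digs <- match(as.vector(t(unclass(network))), J_LEVELS) - 1L
  sum(digs * 3L^(seq_along(digs) - 1L))
}

#' @rdname encode_network
#' @param code integer code in range for the chosen slot count.
#' @param include_x whether the code indexes the 15-slot space.
#' @export
decode_network <- function(code, include_x = FALSE) {
  nslot <- if (include_x) 15L else 12L
  if (length(code) != 1L || is.na(code) || code < 0 || code >= 3^nslot)
    stop("code out of range [0, 3^", nslot, ")")
  code <- as.numeric(code)
  digs <- (code %/% 3^(seq_len(nslot) - 1)) %% 3
  J <- matrix(J_LEVELS[digs + 1L], nrow = 3, byrow = TRUE,
              dimnames = list(TARGETS, if (include_x) REGULATORS else REGULATORS[1:4]))
  sign_network(J)
}

#' Remove one regulation from a network
#'
#' @param network a `sign_network`.
#' @param regulator,target gene names of the regulation to delete.
#' @return the network with that slot set to 0.
#' @export
knockout <- function(network, regulator, target) {
  stopifnot(target %in% TARGETS, regulator %in% colnames(network))
  if (network[target, regulator] == 0L)
    stop("regulation ", regulator, " -> ", target, " is absent")
  network[target, regulator] <- 0L
  sign_network(unclass(network))
}

#' Edge-list and JSON serialization
#'
#' `as_edgelist()` returns a data.frame (regulator, target, sign) of the
#' nonzero regulations; `network_from_edgelist()` inverts it.
#' `write_network_json()` / `read_network_json()` round-trip the full matrix.
#'
#' @param network a `sign_network`.
#' @return see details.
#' @export
as_edgelist <- function(network) {
  idx <- which(unclass(network) != 0L, arr.ind = TRUE)
  data.frame(regulator = colnames(network)[idx[, 2]],
             target    = rownames(network)[idx[, 1]],
             sign      = unclass(network)[idx],
             stringsAsFactors = FALSE)
}

#' @rdname as_edgelist
#' @param edges data.frame with columns regulator, target, sign.
#' @param include_x build a 15-slot network.
#' @export
network_from_edgelist <- function(edges, include_x = any(edges$regulator == "x")) {
  J <- matrix(0L, 3, if (include_x) 5 else 4,
              dimnames = list(TARGETS, if (include_x) REGULATORS else REGULATORS[1:4]))
  for (i in seq_len(nrow(edges)))
    J[edges$target[i], edges$regulator[i]] <- as.integer(edges$sign[i])
  sign_network(J)
}

#' @rdname as_edgelist
#' @param path file path.
#' @export
write_network_json <- function(network, path) {
  obj <- list(include_x = attr(network, "include_x"),
              J = as.data.frame(unclass(network)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname as_edgelist
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  J <- as.matrix(obj$J)
  rownames(J) <- TARGETS
  sign_network(J)
}

#' @rdname as_edgelist
#' @export
write_network_csv <- function(network, path) {
  write.csv(as_edgelist(network), path, row.names = FALSE)
  invisible(path)
}

#' @rdname as_edgelist
#' @export
read_network_csv <- function(path, include_x = FALSE) {
  edges <- read.csv(path, stringsAsFactors = FALSE)
  network_from_edgelist(edges, include_x = include_x || any(edges$regulator == "x"))
}
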