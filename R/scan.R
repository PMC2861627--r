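# Exhaustive screens over the candidate network space.
#
# The screens never loop over networks one by one.  Each target gene's next
# state depends only on its own regulator row (5 three-level values) plus its
# default state, so every (row, default) pair reduces to a truth table over
# the 32 joint states of (hb, Kr, pdm, cas, x).  Networks collapse to
# triples of table ids; dynamics are simulated once per triple and mapped
# back to network codes through the preimages of the tables.  A scalar
# reference path (simulate_boolean + matches_criterion) is kept for oracle
# testing.

scan_env <- new.env(parent = emptyenv())

# truth tables for all 243 regulator rows x 2 default states
row_tables <- function() {
  if (!is.null(scan_env$tt)) return(scan_env$tt)
  rr <- 0:242
  cfm <- cbind(J_LEVELS[rr %% 3 + 1], J_LEVELS[(rr %/% 3) %% 3 + 1],
               J_LEVELS[(rr %/% 9) %% 3 + 1], J_LEVELS[(rr %/% 27) %% 3 + 1],
               J_LEVELS[(rr %/% 81) %% 3 + 1])           # hb,Kr,pdm,cas,x
  inp <- 0:31
  bits <- cbind(inp %% 2, (inp %/% 2) %% 2, (inp %/% 4) %% 2,
                (inp %/% 8) %% 2, (inp %/% 16) %% 2)
  S <- cfm %*% t(bits)
  tab0 <- ifelse(S > 0, 1L, 0L)
  tab1 <- ifelse(S > 0, 1L, ifelse(S < 0, 0L, 1L))
  allt <- rbind(tab0, tab1)                               # (row, s0) stacked
  key <- apply(allt, 1, paste, collapse = "")
  uk <- unique(key)
  tid <- match(key, uk)                                   # (s0*243 + row + 1) -> tid
  TTf <- as.integer(t(allt[match(uk, key), , drop = FALSE]))
  pre <- list(split(0:242, tid[1:243]), split(0:242, tid[244:486]))
  scan_env$tt <- list(D = length(uk), tid = tid, TTf = TTf, pre = pre)
  scan_env$tt
}

# genotype -> input mode and clamp, mirroring simulate_boolean
geno_modes <- function() {
  list("wt"    = list(hb = "pulse", clamp = 0L, cv = 0L),
       "hb-"   = list(hb = "off",   clamp = 0L, cv = 0L),
       "Kr-"   = list(hb = "pulse", clamp = 1L, cv = 0L),
       "pdm-"  = list(hb = "pulse", clamp = 2L, cv = 0L),
       "cas-"  = list(hb = "pulse", clamp = 3L, cv = 0L),
       "hb++"  = list(hb = "on",    clamp = 0L, cv = 1L),
       "Kr++"  = list(hb = "pulse", clamp = 1L, cv = 1L),
       "pdm++" = list(hb = "pulse", clamp = 2L, cv = 1L),
       "cas++" = list(hb = "pulse", clamp = 3L, cv = 1L))
}

# window stats of Kr/pdm/cas for a vector of class ids (0-based triples of
# table ids) under one genotype and x schedule
sim_class_windows <- function(idx0, glabel, t_x, t_end, polarity) {
  tt <- row_tables(); D <- tt$D; TTf <- tt$TTf
  tK <- idx0 %% D; tP <- (idx0 %/% D) %% D; tC <- idx0 %/% (D * D)
  nn <- length(idx0)
  gd <- geno_modes()[[glabel]]
  hbtraj <- switch(gd$hb,
    pulse = c(1L, 1L, rep(0L, t_end - 1L)),
    off   = rep(0L, t_end + 1L),
    on    = rep(1L, t_end + 1L))
  tseq <- 0:t_end
  xtraj <- if (is.na(t_x)) rep(0L, t_end + 1L)
           else if (polarity == "on_off") as.integer(tseq < t_x)
           else as.integer(tseq >= t_x)
  K <- integer(nn); P <- integer(nn); C <- integer(nn)
  if (gd$clamp == 1L) K[] <- gd$cv
  if (gd$clamp == 2L) P[] <- gd$cv
  if (gd$clamp == 3L) C[] <- gd$cv
  fK <- rep(-1L, nn); lK <- rep(-1L, nn); nK <- integer(nn)
  fP <- fK; lP <- lK; nP <- nK; fC <- fK; lC <- lK; nC <- nK
  bK <- 32L * tK; bP <- 32L * tP; bC <- 32L * tC
  for (t in tseq) {
    if (t > 0) {
      ii <- hbtraj[t] + 2L * K + 4L * P + 8L * C + 16L * xtraj[t] + 1L
      Kn <- if (gd$clamp == 1L) K else TTf[ii + bK]
      Pn <- if (gd$clamp == 2L) P else TTf[ii + bP]
      Cn <- if (gd$clamp == 3L) C else TTf[ii + bC]
      nK <- nK + (Kn & !K); nP <- nP + (Pn & !P); nC <- nC + (Cn & !C)
      K <- Kn; P <- Pn; C <- Cn
    } else { nK <- nK + K; nP <- nP + P; nC <- nC + C }
    on <- K == 1L; fK[fK < 0L & on] <- t; lK[on] <- t
    on <- P == 1L; fP[fP < 0L & on] <- t; lP[on] <- t
    on <- C == 1L; fC[fC < 0L & on] <- t; lC[on] <- t
  }
  list(fK = fK, lK = lK, nK = nK, fP = fP, lP = lP, nP = nP,
       fC = fC, lC = lC, nC = nC)
}

# vectorized criterion: same rule as matches_criterion, specialized to the
# class-space stats (hb's window is fixed by the genotype's input mode)
crit_pass_vec <- function(st, glabel, t_end) {
  crit <- criterion_for(glabel)
  gd <- geno_modes()[[glabel]]
  n <- length(st$fK)
  ok <- rep(TRUE, n)
  key <- c(Kr = "K", pdm = "P", cas = "C")
  for (a in setdiff(crit$absent, "hb"))
    ok <- ok & (st[[paste0("f", key[[a]])]] < 0L)
  dyn <- setdiff(crit$order, "hb")
  fs <- list(); ls <- list()
  for (g in dyn) {
    kk <- key[[g]]
    ok <- ok & st[[paste0("f", kk)]] >= 0L & st[[paste0("n", kk)]] == 1L
    fs[[g]] <- st[[paste0("f", kk)]]; ls[[g]] <- st[[paste0("l", kk)]]
  }
  if ("hb" %in% crit$order) {
    hbw <- switch(gd$hb, pulse = c(0L, 1L), on = c(0L, t_end), off = NULL)
    fs <- c(list(hb = rep(hbw[1], n)), fs)
    ls <- c(list(hb = rep(hbw[2], n)), ls)
  }
  ord <- names(fs)
  if (length(ord) >= 2) {
    for (i in 2:length(ord))
      ok <- ok & ls[[ord[i - 1]]] <= ls[[ord[i]]]
    for (i in 2:length(ord)) for (j in 1:(i - 1))
      ok <- ok & !(fs[[ord[i]]] == fs[[ord[j]]] & ls[[ord[i]]] == ls[[ord[j]]])
  }
  if (crit$persist && length(ord))
    ok <- ok & ls[[ord[length(ord)]]] == t_end
  ok
}

# class id of a network code under one default combination d (0..7)
class_of <- function(codes, d) {
  tt <- row_tables(); D <- tt$D; tid <- tt$tid
  rowK <- codes %% 243; rowP <- (codes %/% 243) %% 243; rowC <- codes %/% 59049
  dK <- d %% 2L; dP <- (d %/% 2L) %% 2L; dC <- (d %/% 4L) %% 2L
  (tid[dK * 243 + rowK + 1] - 1) +
    D * (tid[dP * 243 + rowP + 1] - 1) +
    D * D * (tid[dC * 243 + rowC + 1] - 1)
}

#' Screen the twelve-slot networks of the known factors
#'
#' Enumerates all 3^12 = 531,441 sign networks over hb, Kr, pdm, cas (svp
#' implicit, no x) and counts how many reproduce the wild-type sequential
#' profile for at least one of the 8 default-state combinations, and how many
#' additionally satisfy all eight mutant criteria (with one shared default
#' choice).
#'
#' @param t_end simulation horizon (default 10).
#' @param keep_flags also return the per-network WT-compatibility flags.
#' @return a `scan_report` list: totals, counts, configuration.
#' @export
scan_known_factors <- function(t_end = 10L, keep_flags = FALSE) {
  t_end <- as.integer(t_end)
  N <- 3L^12L
  codes15 <- (0:(N - 1L)) %% 81L + 243 * (((0:(N - 1L)) %/% 81L) %% 81L) +
    59049 * ((0:(N - 1L)) %/% 6561L)
  wt_flag <- rep(FALSE, N)
  pair_count <- 0L
  surv <- vector("list", 8L)   # per-default indices passing WT
  for (d in 0:7) {
    cls <- class_of(codes15, d)
    ucls <- unique(cls)
    st <- sim_class_windows(ucls, "wt", NA_integer_, t_end, "on_off")
    okc <- crit_pass_vec(st, "wt", t_end)
    ok <- okc[match(cls, ucls)]
    wt_flag <- wt_flag | ok
    pair_count <- pair_count + sum(ok)
    surv[[d + 1]] <- which(ok)
  }
  # full nine-genotype check on the WT survivors, per default combination
  func_flag <- rep(FALSE, N)
  for (d in 0:7) {
    idx <- surv[[d + 1]]
    if (!length(idx)) next
    cls <- class_of(codes15[idx], d)
    keep <- rep(TRUE, length(idx))
    for (g in setdiff(names(nine_genotypes()), "wt")) {
      if (!any(keep)) break
      st <- sim_class_windows(cls[keep], g, NA_integer_, t_end, "on_off")
      keep[keep] <- crit_pass_vec(st, g, t_end)
    }
    func_flag[idx[keep]] <- TRUE
  }
  rep <- structure(list(scan = "known_factors", total = N,
                        wt_compatible = sum(wt_flag),
                        wt_compatible_pairs = pair_count,
                        functional = sum(func_flag),
                        t_end = t_end, t_x_grid = NA, polarity = NA),
                   class = "scan_report")
  if (keep_flags) rep$wt_flags <- wt_flag
  rep
}

#' Screen all fifteen-slot networks with the presumptive factor x
#'
#' Enumerates all 3^15 = 14,348,907 sign networks including the three x
#' regulations, over every x switching step t_x in `[1, t_end]`, and returns
#' the networks whose dynamics satisfy all nine genotype criteria for at
#' least one shared witness (default states, t_x).
#'
#' @param polarity x switching polarity, `"on_off"` (ON at t = 0, switches
#'   OFF at t_x) or `"off_on"`.
#' @param t_end simulation horizon (default 10).
#' @param chunk class-space chunk size (memory/time trade-off).
#' @param progress print progress lines.
#' @return list with elements `report` (a `scan_report`) and `records`, a
#'   data.frame of functional network codes with one witness each
#'   (s0_Kr, s0_pdm, s0_cas, t_x).
#' @export
scan_with_x <- function(polarity = c("on_off", "off_on"), t_end = 10L,
                        chunk = 2000000L, progress = FALSE) {
  polarity <- match.arg(polarity)
  t_end <- as.integer(t_end)
  tt <- row_tables(); D <- tt$D
  NC <- D^3
  wt_classes <- vector("list", t_end)
  for (i0 in seq(1, NC, by = chunk)) {
    i1 <- min(i0 + chunk - 1, NC)
    idx0 <- (i0:i1) - 1
    for (t_x in 1:t_end) {
      st <- sim_class_windows(idx0, "wt", t_x, t_end, polarity)
      ok <- crit_pass_vec(st, "wt", t_end)
      wt_classes[[t_x]] <- c(wt_classes[[t_x]], which(ok) + i0 - 1)
    }
    if (progress) message("wt screen: ", format(i1), "/", format(NC), " classes")
  }
  rec_code <- integer(0); rec_d <- integer(0); rec_tx <- integer(0)
  for (t_x in 1:t_end) {
    cls <- wt_classes[[t_x]]
    if (!length(cls)) next
    keep <- rep(TRUE, length(cls))
    for (g in setdiff(names(nine_genotypes()), "wt")) {
      if (!any(keep)) break
      st <- sim_class_windows(cls[keep] - 1, g, t_x, t_end, polarity)
      keep[keep] <- crit_pass_vec(st, g, t_end)
    }
    good <- cls[keep]
    if (progress) message("t_x = ", t_x, ": ", length(good), " passing classes")
    if (!length(good)) next
    idx0 <- good - 1
    cK <- idx0 %% D + 1; cP <- (idx0 %/% D) %% D + 1; cC <- idx0 %/% (D * D) + 1
    for (i in seq_along(good)) for (d in 0:7) {
      rk <- tt$pre[[d %% 2 + 1]][[as.character(cK[i])]]
      rp <- tt$pre[[(d %/% 2) %% 2 + 1]][[as.character(cP[i])]]
      rc <- tt$pre[[(d %/% 4) %% 2 + 1]][[as.character(cC[i])]]
      if (is.null(rk) || is.null(rp) || is.null(rc)) next
      grid <- expand.grid(rk = rk, rp = rp, rc = rc)
      rec_code <- c(rec_code, grid$rk + 243 * grid$rp + 59049 * grid$rc)
      rec_d <- c(rec_d, rep(d, nrow(grid)))
      rec_tx <- c(rec_tx, rep(t_x, nrow(grid)))
    }
  }
  first <- !duplicated(rec_code)
  records <- data.frame(code = rec_code[first],
                        s0_Kr = rec_d[first] %% 2L,
                        s0_pdm = (rec_d[first] %/% 2L) %% 2L,
                        s0_cas = (rec_d[first] %/% 4L) %% 2L,
                        t_x = rec_tx[first])
  records <- records[order(records$code), , drop = FALSE]
  rownames(records) <- NULL
  rep <- structure(list(scan = "with_x", total = 3^15,
                        wt_compatible = NA_integer_,
                        functional = nrow(records),
                        t_end = t_end, t_x_grid = paste0("1..", t_end),
                        polarity = polarity),
                   class = "scan_report")
  list(report = rep, records = records)
}

#' @export
print.scan_report <- function(x, ...) {
  cat("scan:", x$scan, " total networks:", format(x$total), "\n")
  if (!is.na(x$wt_compatible)) cat("  WT-compatible:", x$wt_compatible, "\n")
  cat("  fully functional:", x$functional, "\n")
  cat("  t_end:", x$t_end,
      if (!is.na(x$t_x_grid)) paste0(" t_x grid: ", x$t_x_grid, " polarity: ", x$polarity),
      "\n")
  invisible(x)
}

#' Regulations common to a set of networks
#'
#' Slotwise comparison across networks: slots that carry the same value in
#' every network are reported as that value's sign; the rest as "varies".
#'
#' @param codes integer vector of 15-slot network codes.
#' @return character matrix targets x regulators with entries
#'   "+", "-", "0" or "varies".
#' @export
common_regulations <- function(codes) {
  if (!length(codes)) stop("empty network set")
  out <- matrix("varies", 3, 5, dimnames = list(TARGETS, REGULATORS))
  for (i in 1:3) for (j in 1:5) {
    k <- (i - 1L) * 5L + (j - 1L)
    digs <- unique((codes %/% 3^k) %% 3)
    if (length(digs) == 1L) out[i, j] <- c("0", "+", "-")[digs + 1]
  }
  out
}
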