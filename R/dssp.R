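#' Assign secondary structure (Kabsch-Sander hydrogen-bond criterion)
#'
#' A compact implementation of the DSSP assignment on backbone geometry.
#' The amide hydrogen is placed 1.0 A from N along the preceding residue's
#' C=O direction (residue 1 gets no H). A hydrogen bond from CO(i) to NH(j)
#' exists when the Kabsch-Sander electrostatic energy
#' \deqn{E = 0.084 \cdot 332 (1/d_{ON} + 1/d_{CH} - 1/d_{OH} - 1/d_{CN})}
#' (kcal/mol) is below -0.5. Helix (H) requires two consecutive i -> i+4
#' turns; strand/bridge (E/B) follows the parallel/antiparallel bridge rules;
#' hydrogen-bonded turns (T) cover the residues spanned by 3-, 4- or 5-turns.
#' Priority H > E > B > T. Percentages report only these classes:
#' `ss_alpha` = \%H, `ss_beta` = \%(E+B), `ss_turn` = \%T, and `ss_total`
#' their sum (components rounded to 0.1\%).
#'
#' @param x A `conformer` with backbone N, CA, C, O atoms (run
#'   [backbone_from_ca()] first for CA-only traces).
#' @return List with `codes` (per-residue character: "H", "E", "B", "T", "-")
#'   and numeric `ss_alpha`, `ss_beta`, `ss_turn`, `ss_total` (percent).
#' @export
assign_secondary_structure <- function(x) {
  stopifnot(inherits(x, "conformer"))
  n <- n_residues(x)
  get_atoms <- function(name) {
    sel <- x$atoms[x$atoms$elety == name, ]
    if (!identical(sort(sel$resid), seq_len(n)))
      stop("missing backbone atom '", name, "' in residue ",
           setdiff(seq_len(n), sel$resid)[1])
    sel <- sel[order(sel$resid), ]
    as.matrix(sel[, c("x", "y", "z")])
  }
  Nm <- get_atoms("N"); Cm <- get_atoms("C"); Om <- get_atoms("O")

  # amide H: 1.0 A from N, parallel to the previous carbonyl C=O vector
  Hm <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    d <- Cm[i - 1, ] - Om[i - 1, ]
    Hm[i, ] <- Nm[i, ] + d / sqrt(sum(d^2))
  }

  hbond <- matrix(FALSE, n, n)   # hbond[i, j]: CO(i) -> NH(j)
  q <- 0.084 * 332
  for (j in 2:n) {
    if (anyNA(Hm[j, ])) next
    d_on <- sqrt(rowSums(sweep(Om, 2, Nm[j, ])^2))
    d_ch <- sqrt(rowSums(sweep(Cm, 2, Hm[j, ])^2))
    d_oh <- sqrt(rowSums(sweep(Om, 2, Hm[j, ])^2))
    d_cn <- sqrt(rowSums(sweep(Cm, 2, Nm[j, ])^2))
    e <- q * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn)
    ok <- e < -0.5
    ok[j] <- FALSE
    if (j > 1) ok[j - 1] <- FALSE     # the shared peptide bond is not an H-bond
    hbond[, j] <- ok
  }

  turn_at <- function(k) {
    t <- rep(FALSE, n)
    idx <- seq_len(max(n - k, 0))
    t[idx] <- hbond[cbind(idx, idx + k)]
    t
  }
  t3 <- turn_at(3); t4 <- turn_at(4); t5 <- turn_at(5)

  codes <- rep("-", n)

  # alpha helix: two consecutive 4-turns at i-1 and i mark residues i..i+3
  for (i in 2:max(n - 4, 1)) {
    if (t4[i - 1] && t4[i]) codes[i:(i + 3)] <- "H"
  }

  # beta bridges
  bridge <- rep(FALSE, n)
  hb <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && hbond[i, j]
  for (i in 2:(n - 1)) {
    for (j in (i + 3):n) {
      if (j > n - 1) next
      para <- (hb(i - 1, j) && hb(j, i + 1)) || (hb(j - 1, i) && hb(i, j + 1))
      anti <- (hb(i, j) && hb(j, i)) || (hb(i - 1, j + 1) && hb(j - 1, i + 1))
      if (para || anti) bridge[c(i, j)] <- TRUE
    }
  }
  ladder <- bridge & (c(FALSE, bridge[-n]) | c(bridge[-1], FALSE))
  codes[bridge & codes == "-"] <- "B"
  codes[ladder & codes %in% c("-", "B")] <- "E"

  # hydrogen-bonded turns: interior residues of any k-turn
  turn_mask <- rep(FALSE, n)
  for (k in 3:5) {
    tk <- get(paste0("t", k))
    for (i in which(tk)) {
      span <- (i + 1):(i + k - 1)
      turn_mask[span[span <= n]] <- TRUE
    }
  }
  codes[turn_mask & codes == "-"] <- "T"

  pct <- function(m) round(100 * sum(m) / n, 1)
  ss_alpha <- pct(codes == "H")
  ss_beta <- pct(codes %in% c("E", "B"))
  ss_turn <- pct(codes == "T")
  list(codes = codes, ss_alpha = ss_alpha, ss_beta = ss_beta,
       ss_turn = ss_turn, ss_total = ss_alpha + ss_beta + ss_turn)
}
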