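# Kabsch-Sander backbone hydrogen-bond secondary-structure assignment.
#
# Hydrogen bonds are detected with the electrostatic model
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# and accepted below -0.5 kcal/mol.  Amide hydrogens are reconstructed
# 1.01 A from N, anti-parallel to the preceding carbonyl (O -> C direction);
# the first residue and prolines donate no hydrogen bond.
# n-turns (n = 3, 4, 5) arise from a CO(i) -> NH(i+n) bond; helices from two
# consecutive n-turns; parallel/antiparallel bridges from the classic bond
# patterns, extended to strands (E) when bridges stack into ladders; hydrogen-
# bonded turns give T, bends (CA virtual-bond angle > 70 deg) give S, the
# remainder coil (C).  Priority: H > E > B > G > I > T > S > C.  Chain
# termini are never assigned helix or strand.

HB_CUTOFF <- -0.5
HB_COUPLING <- 0.084 * 332

# hb[i, j] = TRUE when CO of residue i accepts a bond from NH of residue j
ks_hbond_matrix <- function(N, CA, C, O, donor_ok) {
  n <- nrow(N)
  H <- matrix(NA_real_, n, 3)
  if (n >= 2) {
    d <- C[-n, , drop = FALSE] - O[-n, , drop = FALSE]
    d <- d / sqrt(rowSums(d^2))
    H[-1, ] <- N[-1, , drop = FALSE] + 1.01 * d
  }
  pdist <- function(A, B) {
    # n x n matrix of distances between rows of A (acceptor side) and B
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
    sqrt(pmax(d2, 0))
  }
  r_on <- pdist(O, N); r_cn <- pdist(C, N)
  r_oh <- pdist(O, H); r_ch <- pdist(C, H)
  E <- HB_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  E[r_on < 0.5 | r_ch < 0.5 | r_oh < 0.5 | r_cn < 0.5] <- -9.9
  E[is.na(E)] <- 0
  hb <- E < HB_CUTOFF
  hb[, !donor_ok] <- FALSE
  offset <- abs(outer(seq_len(n), seq_len(n), "-"))
  hb[offset < 2] <- FALSE
  hb
}

ks_assign_chain <- function(N, CA, C, O, donor_ok) {
  n <- nrow(N)
  if (n < 3) return(rep("C", n))
  hb <- ks_hbond_matrix(N, CA, C, O, donor_ok)

  turn_at <- function(k) {
    i <- seq_len(max(0, n - k))
    i[hb[cbind(i, i + k)]]
  }
  t3 <- turn_at(3); t4 <- turn_at(4); t5 <- turn_at(5)

  run_members <- function(starts, k) {
    # residues covered by two consecutive k-turns starting at i-1 and i
    s <- starts[(starts - 1) %in% starts]
    unique(unlist(lapply(s, function(i) i:(i + k - 1))))
  }
  h_set <- run_members(t4, 4)
  g_set <- run_members(t3, 3)
  i_set <- run_members(t5, 5)

  # bridges
  HB <- function(i, j) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    out <- logical(length(i))
    out[ok] <- hb[cbind(i[ok], j[ok])]
    out
  }
  bridges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 2) next
      par <- (HB(i - 1, j) && HB(j, i + 1)) || (HB(j - 1, i) && HB(i, j + 1))
      anti <- (HB(i, j) && HB(j, i)) || (HB(i - 1, j + 1) && HB(j - 1, i + 1))
      if (par || anti) {
        bridges[[length(bridges) + 1]] <- c(i, j, if (par) 1L else -1L)
      }
    }
  }
  b_set <- integer(0); e_set <- integer(0)
  if (length(bridges) > 0) {
    bm <- do.call(rbind, bridges)
    in_ladder <- rep(FALSE, nrow(bm))
    for (k in seq_len(nrow(bm))) {
      i <- bm[k, 1]; j <- bm[k, 2]; s <- bm[k, 3]
      nbr <- (bm[, 1] == i + 1 & bm[, 2] == j + s & bm[, 3] == s) |
             (bm[, 1] == i - 1 & bm[, 2] == j - s & bm[, 3] == s)
      if (any(nbr)) in_ladder[k] <- TRUE
    }
    e_set <- unique(as.vector(bm[in_ladder, 1:2]))
    b_set <- setdiff(unique(as.vector(bm[!in_ladder, 1:2, drop = FALSE])),
                     e_set)
  }

  # hydrogen-bonded turns: interior residues of any n-turn
  t_set <- unique(unlist(c(
    lapply(t3, function(i) (i + 1):(i + 2)),
    lapply(t4, function(i) (i + 1):(i + 3)),
    lapply(t5, function(i) (i + 1):(i + 4))
  )))

  # bends
  s_set <- integer(0)
  if (n >= 5) {
    for (i in 3:(n - 2)) {
      u <- unitv(CA[i, ] - CA[i - 2, ])
      v <- unitv(CA[i + 2, ] - CA[i, ])
      ang <- rad2deg(acos(pmin(1, pmax(-1, sum(u * v)))))
      if (ang > 70) s_set <- c(s_set, i)
    }
  }

  state <- rep("C", n)
  state[s_set] <- "S"
  state[t_set] <- "T"
  state[i_set] <- "I"
  state[g_set] <- "G"
  state[b_set] <- "B"
  state[e_set] <- "E"
  state[h_set] <- "H"
  # termini lack the context for helix/strand calls
  for (i in c(1L, n)) {
    if (state[i] %in% c("H", "G", "I", "E", "B")) {
      state[i] <- if (i %in% t_set) "T" else "C"
    }
  }
  state
}

#' Map detailed secondary-structure states to four categories
#'
#' Extended strands and beta-bridges map to `Beta`; alpha-, 3-10- and
#' pi-helices to `Helix`; hydrogen-bonded turns and bends to `Turn`; the
#' remainder to `Coil`.
#'
#' @param state Character vector of detailed states
#'   (`H,G,I,E,B,T,S,C`).
#' @return Character vector of categories.
#' @export
ss_category <- function(state) {
  map <- c(E = "Beta", B = "Beta", H = "Helix", G = "Helix", I = "Helix",
           T = "Turn", S = "Turn", C = "Coil")
  bad <- setdiff(unique(state), names(map))
  if (length(bad) > 0) {
    abort(sprintf("unknown detailed state(s): %s", paste(bad, collapse = ", ")),
          class = "abloopr_input_error")
  }
  unname(map[state])
}

#' Assign secondary structure over a conformational ensemble
#'
#' Runs the Kabsch-Sander hydrogen-bond assignment on every frame of an
#' ensemble and maps the eight detailed states to the four summary
#' categories Beta / Helix / Turn / Coil.
#'
#' @param ensemble A `loop_ensemble` with backbone atoms N, CA, C, O.
#' @return An object of class `ss_assignment`: list with `detailed` and
#'   `category` (frame x residue character matrices) and `residues` (roster
#'   tibble, one row per residue).
#' @examples
#' hx <- build_ideal_backbone("helix", 12)
#' assign_secondary_structure(hx)
#' @export
assign_secondary_structure <- function(ensemble) {
  stopifnot(inherits(ensemble, "loop_ensemble"))
  atoms <- ensemble$atoms
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  res_keys <- unique(res_key)
  n_res <- length(res_keys)
  residues <- atoms[match(res_keys, res_key),
                    c("chain", "resno", "insert", "resid")]
  sel <- function(elety) {
    i <- which(atoms$elety == elety)
    i[match(res_keys, res_key[i])]
  }
  iN <- sel("N"); iCA <- sel("CA"); iC <- sel("C"); iO <- sel("O")
  if (any(is.na(c(iN, iCA, iC, iO)))) {
    abort("every residue needs backbone atoms N, CA, C, O",
          class = "abloopr_format_error")
  }
  donor_ok <- residues$resid != "PRO"
  donor_ok[1] <- FALSE
  chains <- unique(residues$chain)
  nf <- n_frames(ensemble)
  detailed <- matrix("C", nf, n_res)
  for (f in seq_len(nf)) {
    fr <- matrix(ensemble$xyz[f, , ], ncol = 3)
    for (ch in chains) {
      ridx <- which(residues$chain == ch)
      d_ok <- residues$resid[ridx] != "PRO"
      d_ok[1] <- FALSE
      detailed[f, ridx] <- ks_assign_chain(
        fr[iN[ridx], , drop = FALSE], fr[iCA[ridx], , drop = FALSE],
        fr[iC[ridx], , drop = FALSE], fr[iO[ridx], , drop = FALSE], d_ok)
    }
  }
  category <- matrix(ss_category(detailed), nf, n_res)
  structure(list(detailed = detailed, category = category,
                 residues = residues),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(sprintf("<ss_assignment> %d frame(s) x %d residues\n",
              nrow(x$detailed), ncol(x$detailed)))
  invisible(x)
}

#' Per-frame secondary-structure states as a tibble
#'
#' @param x An `ss_assignment`.
#' @param ... Unused.
#' @return A tibble with `frame`, residue roster columns, `state`,
#'   `category`.
#' @method tidy ss_assignment
#' @export
tidy.ss_assignment <- function(x, ...) {
  nf <- nrow(x$detailed)
  nr <- ncol(x$detailed)
  tibble(
    frame = rep(seq_len(nf), times = nr),
    bind_rows(purrr::map(seq_len(nr), function(r)
      x$residues[rep(r, nf), ])),
    state = as.vector(x$detailed),
    category = as.vector(x$category)
  ) |> arrange(.data$frame)
}
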