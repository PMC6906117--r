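# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: the titration oracle tracks moles in the
# cell and solves each injection's binding equilibrium numerically; the
# energy oracle is a naive double loop over atom pairs.

# Stepwise mass-balance titration simulator. Per injection: apply the
# displaced-volume concentration update, find the equilibrium complex
# concentration b from Ka (nM - b)(X - b) = b by root bracketing, and book
# the heat as dH * V0 * db plus the heat carried by complex displaced from
# the overflow cell during the injection (trapezoid in Q).
oracle_itc_heats <- function(n, Ka, dH_kJmol, tg) {
  V0 <- tg$cell_volume_ul * 1e-6
  dV <- tg$injection_volumes_ul * 1e-6
  v <- cumsum(dV)
  dH <- dH_kJmol * 1000
  Qprev <- 0
  out <- numeric(length(dV))
  for (i in seq_along(dV)) {
    Mi <- tg$cell_conc_M * (1 - v[i] / (2 * V0))
    Xi <- tg$syringe_conc_M * (v[i] / V0) * (1 - v[i] / (2 * V0))
    hi <- min(n * Mi, Xi)
    b <- if (hi <= 0) 0 else
      uniroot(function(b) Ka * (n * Mi - b) * (Xi - b) - b,
              c(0, hi), tol = 1e-16)$root
    Q <- dH * V0 * b
    out[i] <- Q - Qprev + (dV[i] / V0) * (Q + Qprev) / 2
    Qprev <- Q
  }
  out * 1e6   # microjoule
}

# Naive pairwise nonbonded energy: LJ (Lorentz-Berthelot) + Coulomb with a
# plain cutoff, written as an explicit double loop over atom rows.
oracle_pair_u <- function(ri, rj, qi, qj, si, sj, ei, ej, coul, cutoff) {
  r <- sqrt(sum((ri - rj)^2))
  if (r > cutoff) return(0)
  sig <- (si + sj) / 2
  eps <- sqrt(ei * ej)
  sr6 <- (sig / r)^6
  4 * eps * (sr6^2 - sr6) + coul * qi * qj / r
}

# total interaction energy between two disjoint atom index sets (each pair
# once), or within one set if set_b is NULL
oracle_group_energy <- function(frame, params, set_a, set_b = NULL) {
  p <- resolve_params(frame, params)
  xyz <- coords(frame)
  a <- frame$atoms
  res_id <- paste(a$chain, a$resno, a$resname)
  tot <- 0
  if (is.null(set_b)) {
    for (i in set_a) for (j in set_a) {
      if (j <= i || res_id[i] == res_id[j]) next
      tot <- tot + oracle_pair_u(xyz[i, ], xyz[j, ], p$charge_e[i],
                                 p$charge_e[j], p$sigma_A[i], p$sigma_A[j],
                                 p$epsilon_kJmol[i], p$epsilon_kJmol[j],
                                 params$coulomb_constant, params$cutoff_A)
    }
  } else {
    for (i in set_a) for (j in set_b) {
      if (res_id[i] == res_id[j]) next
      tot <- tot + oracle_pair_u(xyz[i, ], xyz[j, ], p$charge_e[i],
                                 p$charge_e[j], p$sigma_A[i], p$sigma_A[j],
                                 p$epsilon_kJmol[i], p$epsilon_kJmol[j],
                                 params$coulomb_constant, params$cutoff_A)
    }
  }
  tot
}

# Exhaustive water matching: over all injective assignments of set A
# oxygens to set B oxygens within the radius, maximize the number of
# matches, then minimize total distance. Feasible for <= 8 waters.
oracle_water_matching <- function(pa, pb, radius) {
  na <- nrow(pa); nb <- nrow(pb)
  dmat <- outer(seq_len(na), seq_len(nb), Vectorize(function(i, j)
    sqrt(sum((pa[i, ] - pb[j, ])^2))))
  best <- list(count = -1, dist = Inf, pairs = NULL)
  recurse <- function(i, used_b, pairs, dist) {
    if (i > na) {
      cnt <- nrow(pairs) %||% 0L
      if (cnt > best$count || (cnt == best$count && dist < best$dist))
        best <<- list(count = cnt, dist = dist, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1L, used_b, pairs, dist)          # leave i unmatched
    for (j in seq_len(nb)) {
      if (used_b[j] || dmat[i, j] > radius) next
      recurse(i + 1L, replace(used_b, j, TRUE),
              rbind(pairs, c(i, j)), dist + dmat[i, j])
    }
  }
  recurse(1L, logical(nb), NULL, 0)
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
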