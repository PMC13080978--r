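# Independent reference implementations used as oracles. Deliberately
# naive and structured differently from the package code paths they check.

# Base frame by explicit Gram-Schmidt on the three ring atoms.
oracle_frame <- function(c2, c4, c6) {
  o <- (c2 + c4 + c6) / 3
  x <- (c2 - o) / sqrt(sum((c2 - o)^2))
  y0 <- (c4 - o) - sum((c4 - o) * x) * x
  y <- y0 / sqrt(sum(y0^2))
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  list(origin = o, x = x, y = y, z = z)
}

# Scalar g-vector evaluation straight from the defining formula.
oracle_gvector <- function(r_local, a = 5, b = 3, r_cut = 2.4) {
  gamma <- pi / r_cut
  rt <- c(r_local[1] / a, r_local[2] / a, r_local[3] / b)
  rho <- sqrt(sum(rt^2))
  if (rho >= r_cut) return(c(0, 0, 0, 0))
  c(sin(gamma * rho) * rt / rho, 1 + cos(gamma * rho))
}

# Monolithic eRMSD between two models: recompute frames, local
# separations, g-vectors and the pair sum in one unoptimized pass.
oracle_ermsd <- function(model_a, model_b, a = 5, b = 3, r_cut = 2.4) {
  frames_of <- function(model) {
    res <- sort(unique(model$atoms$residue_index))
    lapply(res, function(ri) {
      at <- model$atoms[model$atoms$residue_index == ri, ]
      pick <- function(nm) {
        r <- at[at$atom_name == nm, ][1, ]
        c(r$x, r$y, r$z)
      }
      oracle_frame(pick("C2"), pick("C4"), pick("C6"))
    })
  }
  fa <- frames_of(model_a)
  fb <- frames_of(model_b)
  n <- length(fa)
  total <- 0
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) next
      g_of <- function(fr) {
        d <- fr[[k]]$origin - fr[[j]]$origin
        r_local <- c(sum(d * fr[[j]]$x), sum(d * fr[[j]]$y),
                     sum(d * fr[[j]]$z))
        oracle_gvector(r_local, a, b, r_cut)
      }
      total <- total + sum((g_of(fa) - g_of(fb))^2)
    }
  }
  sqrt(total / n)
}

# Optimal-superposition RMSD via the Horn quaternion method.
oracle_quaternion_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  M <- crossprod(Bc, Ac)
  S <- matrix(0, 4, 4)
  tr <- sum(diag(M))
  S[1, 1] <- tr
  S[1, 2:4] <- S[2:4, 1] <- c(M[2, 3] - M[3, 2], M[3, 1] - M[1, 3],
                              M[1, 2] - M[2, 1])
  S[2:4, 2:4] <- M + t(M) - diag(tr, 3)
  lam <- max(eigen(S, symmetric = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# Exhaustive maximum subset with diameter <= thr (DP over subsets).
oracle_max_diameter_subset <- function(D, thr) {
  n <- nrow(D)
  stopifnot(n <= 16)
  ok <- logical(2^n)
  best <- 1L
  for (S in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(S, 2^(0:(n - 1))) > 0)
    if (length(idx) == 1L) {
      ok[S + 1] <- TRUE
      next
    }
    last <- idx[length(idx)]
    rest <- S - 2^(last - 1)
    ok[S + 1] <- ok[rest + 1] &&
      all(D[last, idx[-length(idx)]] <= thr)
    if (ok[S + 1] && length(idx) > best) best <- length(idx)
  }
  best
}

# Direct minimum-over-permutations scaffold RMSD.
oracle_min_sym_rmsd <- function(A, B, perms) {
  best <- Inf
  for (p in perms) {
    s <- 0
    for (i in seq_len(nrow(A))) {
      s <- s + sum((A[i, ] - B[p[i], ])^2)
    }
    best <- min(best, sqrt(s / nrow(A)))
  }
  best
}

random_dist_matrix <- function(n, lo = 0, hi = 1) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, lo, hi)
  D + t(D)
}
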