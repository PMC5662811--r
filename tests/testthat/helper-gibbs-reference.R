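# Pure-R reference implementation of the collapsed Gibbs sampler, written
# directly from the conditional formulas. Used to cross-check the
# compiled sampler trajectory at equal seed.

refGibbs <- function(corpus, pairTable, config, nIter) {
  K <- nLabels(corpus); V <- nHerbs(corpus)
  plist <- prescriptions(corpus)
  N <- length(plist)
  alpha <- if (is.null(config$alpha)) 50 / K else config$alpha
  eta <- config$eta

  # unit decomposition: pair emitted at its first member's position
  h1 <- integer(); h2 <- integer(); pres <- integer()
  for (pi in seq_along(plist)) {
    p <- plist[[pi]]
    pa <- assignPairs(p, pairTable)
    for (i in seq_along(p$herbIds)) {
      if (pa$x[i] == 1L && pa$partner[i] < i) next
      h1 <- c(h1, p$herbIds[i])
      h2 <- c(h2, if (pa$x[i] == 1L) p$herbIds[pa$partner[i]]
              else NA_integer_)
      pres <- c(pres, pi)
    }
  }
  active <- lapply(plist, function(p) as.integer(sort(unique(p$labels))))

  set.seed(config$seed)
  z <- vapply(seq_along(h1), function(u) {
    A <- active[[pres[u]]]
    A[sample.int(length(A), 1L)]
  }, 0L)

  nkh <- matrix(0L, K, V); nk <- integer(K)
  npk <- matrix(0L, N, K); np <- integer(N)
  for (u in seq_along(z)) {
    s <- if (is.na(h2[u])) 1L else 2L
    nkh[z[u], h1[u]] <- nkh[z[u], h1[u]] + 1L
    if (s == 2L) nkh[z[u], h2[u]] <- nkh[z[u], h2[u]] + 1L
    nk[z[u]] <- nk[z[u]] + s
    npk[pres[u], z[u]] <- npk[pres[u], z[u]] + s
    np[pres[u]] <- np[pres[u]] + s
  }

  for (it in seq_len(nIter)) {
    for (u in seq_along(z)) {
      p <- pres[u]; A <- active[[p]]; Kp <- length(A)
      s <- if (is.na(h2[u])) 1L else 2L
      kO <- z[u]
      nkh[kO, h1[u]] <- nkh[kO, h1[u]] - 1L
      if (s == 2L) nkh[kO, h2[u]] <- nkh[kO, h2[u]] - 1L
      nk[kO] <- nk[kO] - s
      npk[p, kO] <- npk[p, kO] - s

      lw <- numeric(Kp)
      den <- log(np[p] - s + alpha * Kp)
      for (a in seq_len(Kp)) {
        k <- A[a]
        w <- log(nkh[k, h1[u]] + eta)
        if (s == 2L) w <- w + log(nkh[k, h2[u]] + eta)
        w <- w - log(nk[k] + eta * V)
        w <- w + log(npk[p, k] + alpha) - den
        lw[a] <- w
      }
      mx <- max(lw)
      wts <- numeric(Kp); tot <- 0
      for (a in seq_len(Kp)) { wts[a] <- exp(lw[a] - mx); tot <- tot + wts[a] }
      r <- runif(1) * tot
      pick <- Kp; acc <- 0
      for (a in seq_len(Kp)) {
        acc <- acc + wts[a]
        if (r <= acc) { pick <- a; break }
      }
      kN <- A[pick]
      z[u] <- kN
      nkh[kN, h1[u]] <- nkh[kN, h1[u]] + 1L
      if (s == 2L) nkh[kN, h2[u]] <- nkh[kN, h2[u]] + 1L
      nk[kN] <- nk[kN] + s
      npk[p, kN] <- npk[p, kN] + s
    }
  }
  list(z = z, nkh = nkh, nk = nk, npk = npk, np = np)
}
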