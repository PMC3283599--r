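# Independent brute-force oracles used across the test files.

BASES <- c("A", "C", "G", "T")

# random DNA string
rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# mutate a string at k distinct positions (to a different base)
mutate_at <- function(seq, positions) {
  x <- strsplit(seq, "")[[1]]
  for (p in positions) x[p] <- sample(setdiff(BASES, x[p]), 1)
  paste(x, collapse = "")
}

# --- damage oracle: enumerate distinct (position, change) pairs by hand ----
oracle_spectrum <- function(clones, consensus) {
  cons <- strsplit(consensus, "")[[1]]
  seen <- character()
  for (cl in clones) {
    x <- strsplit(cl, "")[[1]]
    for (j in seq_along(cons)) {
      if (cons[j] %in% BASES && x[j] != cons[j]) {
        seen <- c(seen, paste(j, cons[j], x[j]))
      }
    }
  }
  seen <- unique(seen)
  types <- vapply(strsplit(seen, " "), function(z) paste0(z[2], ">", z[3]), "")
  table(types)
}

# --- likelihood oracle: exhaustive enumeration over internal states --------
# Uses ape::matexpo for transition probabilities, independent of the
# package's eigendecomposition path.
oracle_site_loglik <- function(tree, chars, mod) {
  pi <- mod$base_freqs
  s <- mod$exchangeabilities
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  pr <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pr[k, 1]; j <- pr[k, 2]
    Q[i, j] <- s[k] * pi[j]; Q[j, i] <- s[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  k <- mod$n_gamma_cat
  gr <- discrete_gamma_rates(mod$alpha, k)
  rates <- c(0, gr / (1 - mod$p_inv))
  w <- c(mod$p_inv, rep((1 - mod$p_inv) / k, k))
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  states <- as.matrix(expand.grid(rep(list(1:4), nn)))
  vapply(seq_len(ncol(chars)), function(site) {
    tip_state <- match(chars[tree$tip.label, site], BASES)
    tot <- 0
    for (ci in seq_along(rates)) {
      if (w[ci] == 0) next
      P <- lapply(tree$edge.length * rates[ci],
                  function(t) ape::matexpo(Q * t))
      lik <- 0
      for (r in seq_len(nrow(states))) {
        st <- c(tip_state, states[r, ])
        pr1 <- pi[st[root]]
        for (e in seq_len(nrow(tree$edge))) {
          pr1 <- pr1 * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
        }
        lik <- lik + pr1
      }
      tot <- tot + w[ci] * lik
    }
    log(tot)
  }, 0)
}

rand_gtrig <- function() {
  f <- runif(4, 0.1, 1); f <- f / sum(f)
  gtrig_model(exchangeabilities = runif(6, 0.2, 3), base_freqs = f,
              alpha = runif(1, 0.3, 2), p_inv = runif(1, 0, 0.4),
              n_gamma_cat = sample(2:4, 1))
}

rand_tree <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, tip.label = letters[seq_len(ntaxa)])
  tr$edge.length <- runif(nrow(tr$edge), 0, 0.5)
  tr
}
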