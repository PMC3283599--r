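# Likelihood-based topology confidence on FIXED trees. Branch lengths and
# model parameters are inputs, never optimised here: the package computes
# partitioned GTR+I+Gamma site log-likelihoods by Felsenstein pruning and
# feeds them to RELL-based SH and AU tests; marginal likelihoods for Bayes
# factors come from posterior log-likelihood traces via the harmonic mean.
# All log-likelihoods are natural logs.

#' Construct a partitioned alignment
#'
#' @param seqs Named character vector of equal-length aligned sequences, or
#'   a character matrix (taxa x sites, single letters).
#' @param labels Per-site partition labels; alternatively supply `gene` and
#'   `codon_pos` vectors and labels become `"<gene>.<codon_pos>"`. Default:
#'   one partition `"all"`.
#' @param gene,codon_pos Optional per-site vectors.
#' @return Object of class `partitioned_alignment`: `taxa`, `chars`
#'   (taxa x sites matrix), `labels`.
#' @export
partitioned_alignment <- function(seqs, labels = NULL, gene = NULL,
                                  codon_pos = NULL) {
  if (is.matrix(seqs)) {
    chars <- toupper(seqs)
  } else {
    if (length(unique(nchar(seqs))) != 1L) {
      stop("aligned sequences must have equal length")
    }
    chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(chars) <- names(seqs)
  }
  if (is.null(rownames(chars))) stop("sequences must be named")
  n_sites <- ncol(chars)
  if (is.null(labels)) {
    labels <- if (!is.null(gene)) {
      paste(gene, codon_pos, sep = ".")
    } else {
      rep("all", n_sites)
    }
  }
  if (length(labels) != n_sites) {
    stop("need exactly one partition label per site")
  }
  structure(list(taxa = rownames(chars), chars = chars,
                 labels = as.character(labels)),
            class = "partitioned_alignment")
}

#' Read an aligned FASTA or relaxed PHYLIP file
#'
#' @param path File path.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @param labels Optional per-site partition labels.
#' @return A [partitioned_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           labels = NULL) {
  format <- match.arg(format)
  m <- if (format == "fasta") {
    ape::read.dna(path, format = "fasta", as.character = TRUE,
                  as.matrix = TRUE)
  } else {
    ape::read.dna(path, format = "sequential", as.character = TRUE)
  }
  partitioned_alignment(toupper(m), labels = labels)
}

#' Parse NEXUS-like charset ranges into per-site labels
#'
#' Accepts lines of the form `charset name = 1-992;`,
#' `charset name = 2-992\3;` (codon step) or comma-separated ranges; the
#' `charset` keyword and trailing `;` are optional.
#'
#' @param text Character vector of lines (or a file path).
#' @param n_sites Alignment length.
#' @return Character vector of per-site labels (NA where unassigned).
#' @export
parse_charsets <- function(text, n_sites) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  labels <- rep(NA_character_, n_sites)
  for (line in text) {
    line <- trimws(sub(";\\s*$", "", sub("^\\s*charset\\s+", "", line,
                                         ignore.case = TRUE)))
    if (!nzchar(line) || !grepl("=", line, fixed = TRUE)) next
    parts <- strsplit(line, "=", fixed = TRUE)[[1L]]
    name <- trimws(parts[1L])
    for (rng in strsplit(trimws(parts[2L]), "[ ,]+")[[1L]]) {
      step <- 1L
      if (grepl("\\\\", rng)) {
        bits <- strsplit(rng, "\\", fixed = TRUE)[[1L]]
        step <- as.integer(bits[2L]); rng <- bits[1L]
      }
      ends <- as.integer(strsplit(rng, "-", fixed = TRUE)[[1L]])
      if (length(ends) == 1L) ends <- c(ends, ends)
      sites <- seq(ends[1L], ends[2L], by = step)
      sites <- sites[sites >= 1L & sites <= n_sites]
      labels[sites] <- name
    }
  }
  labels
}

#' GTR+I+Gamma substitution model for one partition
#'
#' @param exchangeabilities Six non-negative rates in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param base_freqs Four frequencies (A, C, G, T) summing to 1.
#' @param alpha Gamma shape (> 0).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @param n_gamma_cat Number of discrete Gamma categories (default 4).
#' @return Object of class `gtrig_model`.
#' @export
gtrig_model <- function(exchangeabilities = rep(1, 6),
                        base_freqs = rep(0.25, 4),
                        alpha = 1, p_inv = 0, n_gamma_cat = 4L) {
  stopifnot(length(exchangeabilities) == 6L, all(exchangeabilities >= 0),
            length(base_freqs) == 4L, all(base_freqs > 0),
            alpha > 0, p_inv >= 0, p_inv < 1, n_gamma_cat >= 1L)
  if (abs(sum(base_freqs) - 1) > 1e-12) {
    stop("base_freqs must sum to 1 (got ", sum(base_freqs), ")")
  }
  structure(list(exchangeabilities = as.numeric(exchangeabilities),
                 base_freqs = stats::setNames(as.numeric(base_freqs), .BASES),
                 alpha = alpha, p_inv = p_inv,
                 n_gamma_cat = as.integer(n_gamma_cat)),
            class = "gtrig_model")
}

#' Mean-per-category discrete Gamma rates
#'
#' The convention of standard maximum-likelihood programs: K equiprobable
#' categories, each represented by its conditional mean; the rates average
#' exactly 1.
#'
#' @param alpha Gamma shape.
#' @param k Number of categories.
#' @return Numeric vector of k rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha,
                          rate = alpha)
  # E[X | a < X < b] for Gamma(alpha, alpha) via the incomplete-gamma identity
  upper <- stats::pgamma(breaks[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(breaks[-(k + 1L)], shape = alpha + 1, rate = alpha)
  rates <- k * (upper - lower)
  rates / mean(rates)   # guard tiny numerical drift; mean is 1 analytically
}

# normalised GTR rate matrix and its symmetric eigendecomposition
.gtr_eigen <- function(model) {
  pi <- model$base_freqs
  s <- model$exchangeabilities
  Q <- matrix(0, 4L, 4L, dimnames = list(.BASES, .BASES))
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                 c(2L, 3L), c(2L, 4L), c(3L, 4L))
  for (k in seq_len(6L)) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    Q[i, j] <- s[k] * pi[j]
    Q[j, i] <- s[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q / mu
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values, right = diag(1 / d) %*% e$vectors,
       left = t(e$vectors) %*% diag(d), pi = pi, Q = Q)
}

.pmatrix <- function(eig, t) {
  eig$right %*% (exp(eig$values * t) * eig$left)
}

# tip partial-likelihood matrix: 4 x n_sites indicators; gap/?/N = all ones
.tip_partials <- function(chars) {
  codes <- toupper(chars)
  codes[codes %in% c("-", "?", ".")] <- "N"
  bits <- .iupac_bits(codes)
  rbind(A = as.numeric(bitwAnd(bits, 1L) > 0L),
        C = as.numeric(bitwAnd(bits, 2L) > 0L),
        G = as.numeric(bitwAnd(bits, 4L) > 0L),
        T = as.numeric(bitwAnd(bits, 8L) > 0L))
}

# Felsenstein pruning for one tree / one model / one set of sites.
# Returns per-site likelihoods (not logs) for each rate category, already
# mixed over categories.
.prune_sites <- function(tree, chars, model) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  missing_taxa <- setdiff(tree$tip.label, rownames(chars))
  if (length(missing_taxa)) {
    stop("taxa absent from alignment: ", paste(missing_taxa, collapse = ", "))
  }
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  n_sites <- ncol(chars)
  eig <- .gtr_eigen(model)
  k <- model$n_gamma_cat
  gr <- discrete_gamma_rates(model$alpha, k)
  rates <- c(0, gr / (1 - model$p_inv))
  weights <- c(model$p_inv, rep((1 - model$p_inv) / k, k))
  keep <- weights > 0
  rates <- rates[keep]; weights <- weights[keep]
  tips <- lapply(tree$tip.label, function(tx) .tip_partials(chars[tx, ]))
  mix <- matrix(0, nrow = 1L, ncol = n_sites)
  log_scale_total <- NULL
  site_lik <- numeric(n_sites)
  for (ci in seq_along(rates)) {
    partials <- vector("list", n_tip + n_node)
    partials[seq_len(n_tip)] <- tips
    log_scale <- numeric(n_sites)
    pm <- lapply(tree$edge.length * rates[ci], function(t) .pmatrix(eig, t))
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      contrib <- pm[[e]] %*% partials[[child]]
      if (is.null(partials[[parent]])) {
        partials[[parent]] <- contrib
      } else {
        partials[[parent]] <- partials[[parent]] * contrib
        mx <- apply(partials[[parent]], 2L, max)
        mx[mx <= 0] <- 1
        partials[[parent]] <- sweep(partials[[parent]], 2L, mx, "/")
        log_scale <- log_scale + log(mx)
      }
    }
    root <- tree$edge[nrow(tree$edge), 1L]
    lik_c <- as.numeric(eig$pi %*% partials[[root]]) * exp(log_scale)
    site_lik <- site_lik + weights[ci] * lik_c
  }
  site_lik
}

#' Site-wise log-likelihoods of fixed trees
#'
#' Felsenstein pruning per site under a partitioned GTR+I+Gamma model:
#' a mixture over mean-per-category discrete Gamma rates plus an invariant
#' class of weight `p_inv`; IUPAC ambiguity codes enter as partial
#' likelihoods over their base sets, gaps and missing data as all-ones
#' vectors. Branch lengths and parameters are taken as given.
#'
#' @param tree A `phylo` tree with branch lengths (taxa a subset of the
#'   alignment's taxa).
#' @param aln A [partitioned_alignment()].
#' @param models A single [gtrig_model()] applied to every site, or a named
#'   list keyed by partition label.
#' @return Numeric vector of natural-log site likelihoods (one per site).
#' @export
site_loglik <- function(tree, aln, models) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  chars <- aln$chars[tree$tip.label, , drop = FALSE]
  if (inherits(models, "gtrig_model")) {
    models <- stats::setNames(rep(list(models), length(unique(aln$labels))),
                              unique(aln$labels))
  }
  out <- numeric(ncol(chars))
  for (lab in unique(aln$labels)) {
    if (is.null(models[[lab]])) stop("no model for partition ", lab)
    idx <- which(aln$labels == lab)
    out[idx] <- log(.prune_sites(tree, chars[, idx, drop = FALSE],
                                 models[[lab]]))
  }
  out
}

#' Site log-likelihood matrix for a set of candidate trees
#'
#' @param trees A `multiPhylo`, list of `phylo`, or single `phylo`.
#' @param aln A [partitioned_alignment()].
#' @param models As in [site_loglik()].
#' @return Matrix (trees x sites) of natural-log site likelihoods; row
#'   names are tree names or `tree1`, `tree2`, ...
#' @export
site_loglik_matrix <- function(trees, aln, models) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  M <- do.call(rbind, lapply(trees, site_loglik, aln = aln, models = models))
  rownames(M) <- if (!is.null(names(trees))) names(trees) else
    paste0("tree", seq_along(trees))
  M
}

#' Restrict an alignment to sites covered by a focal taxon
#'
#' Keeps only the columns where the focal taxon is not missing (`-`, `N`,
#' `?`), carrying partition labels along — the "limited to the data
#' available" re-analysis for a partially sequenced taxon.
#'
#' @param aln A [partitioned_alignment()].
#' @param focal_taxon Taxon name.
#' @return A [partitioned_alignment()] with the retained columns.
#' @export
restrict_to_covered <- function(aln, focal_taxon) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  if (!focal_taxon %in% aln$taxa) stop("taxon not in alignment: ", focal_taxon)
  row <- toupper(aln$chars[focal_taxon, ])
  keep <- !(row %in% c("-", "N", "?", "."))
  if (!any(keep)) warning("focal taxon has no covered sites")
  partitioned_alignment(aln$chars[, keep, drop = FALSE],
                        labels = aln$labels[keep])
}

#' RELL bootstrap of site log-likelihoods
#'
#' Resampling estimated log-likelihoods: each replicate draws
#' `ceiling(r * n_sites)` site columns with replacement (the same columns
#' for every tree) and sums the site log-likelihoods per tree.
#'
#' @param M Site log-likelihood matrix (trees x sites).
#' @param B Number of replicates.
#' @param seed RNG seed.
#' @param scale Resampling scale r > 0 (default 1; the multiscale values
#'   used by the AU test are < 1 and > 1).
#' @return Matrix (trees x B) of replicate log-likelihood totals.
#' @export
rell_bootstrap <- function(M, B, seed = 1L, scale = 1) {
  M <- rbind(M)
  if (ncol(M) == 0L) stop("empty site log-likelihood matrix")
  if (B < 1L) stop("B must be >= 1")
  if (scale <= 0) stop("scale must be > 0")
  m <- ceiling(scale * ncol(M))
  .run_seeded(seed, function() {
    counts <- stats::rmultinom(B, size = m, prob = rep(1, ncol(M)))
    M %*% counts
  })
}

#' Shimodaira-Hasegawa test from site log-likelihoods
#'
#' Observed statistic `T_i = max_j L_j - L_i` on the row totals; the null
#' distribution comes from RELL replicates centred per tree (each tree's
#' replicate mean subtracted), `T_ib = max_j C_jb - C_ib`;
#' `p_i = fraction(T_ib >= T_i)`.
#'
#' @param M Site log-likelihood matrix (trees x sites), >= 2 rows.
#' @param B Number of RELL replicates (default 10000; a warning is issued
#'   below 100).
#' @param seed RNG seed.
#' @return Data frame: `tree`, `lnL`, `delta_lnL`, `p_sh`.
#' @export
sh_test <- function(M, B = 10000L, seed = 1L) {
  if (nrow(M) < 2L) stop("SH test needs at least two trees")
  if (B < 100L) warning("B < 100 gives unstable SH p-values")
  L <- rowSums(M)
  T_obs <- max(L) - L
  reps <- rell_bootstrap(M, B, seed = seed)
  C <- reps - rowMeans(reps)
  maxC <- apply(C, 2L, max)
  p <- vapply(seq_len(nrow(M)),
              function(i) mean(maxC - C[i, ] >= T_obs[i]), 0)
  data.frame(tree = rownames(M), lnL = L, delta_lnL = T_obs, p_sh = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Approximately unbiased (AU) test via multiscale RELL bootstrap
#'
#' For each tree, the bootstrap proportion `BP(r)` of replicates in which
#' the tree attains the maximal total is computed at each scale r;
#' `z(r) = qnorm(1 - BP(r))` is fitted by weighted least squares to
#' `d*sqrt(r) + c/sqrt(r)` with binomial-variance weights, and
#' `p_AU = 1 - pnorm(d - c)`. Proportions of exactly 0 or 1 at a scale get
#' a continuity correction `1/(2B)`; a tree at 0 (or 1) across *all* scales
#' is reported p = 0 (or 1) directly, since the signed-distance fit is
#' degenerate there.
#'
#' @param M Site log-likelihood matrix (trees x sites), >= 2 rows.
#' @param scales Resampling scales, spanning values below and above 1
#'   (default 0.5 to 1.4 by 0.1).
#' @param B Replicates per scale (default 10000).
#' @param seed RNG seed.
#' @return Data frame: `tree`, `p_au`, `d`, `c`, plus the per-scale
#'   bootstrap proportions as attribute `"bp"`.
#' @export
au_test <- function(M, scales = seq(0.5, 1.4, by = 0.1), B = 10000L,
                    seed = 1L) {
  if (nrow(M) < 2L) stop("AU test needs at least two trees")
  if (length(scales) < 2L) {
    stop("AU test needs at least two usable scales")
  }
  bp <- matrix(NA_real_, nrow = nrow(M), ncol = length(scales),
               dimnames = list(rownames(M), paste0("r", scales)))
  for (si in seq_along(scales)) {
    reps <- rell_bootstrap(M, B, seed = .stream_seed(seed, si),
                           scale = scales[si])
    top <- apply(reps, 2L, max)
    bp[, si] <- rowMeans(reps >= rep(top, each = nrow(M)) - 1e-9)
  }
  p_au <- d_hat <- c_hat <- rep(NA_real_, nrow(M))
  for (i in seq_len(nrow(M))) {
    raw <- bp[i, ]
    if (all(raw <= 0)) { p_au[i] <- 0; next }
    if (all(raw >= 1)) { p_au[i] <- 1; next }
    bpc <- pmin(pmax(raw, 1 / (2 * B)), 1 - 1 / (2 * B))
    z <- stats::qnorm(1 - bpc)
    w <- B * stats::dnorm(z)^2 / (bpc * (1 - bpc))
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    fit <- stats::lm.wfit(X, z, w)
    d_hat[i] <- fit$coefficients[1L]
    c_hat[i] <- fit$coefficients[2L]
    p_au[i] <- 1 - stats::pnorm(d_hat[i] - c_hat[i])
  }
  out <- data.frame(tree = rownames(M), p_au = p_au, d = d_hat, c = c_hat,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "bp") <- bp
  out
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Posterior log-likelihood sample
#'
#' @param lnl_trace Numeric vector of sampled log-likelihoods.
#' @param burnin Number of leading samples to discard (must be smaller than
#'   the trace length).
#' @param run_id Optional identifier.
#' @return Object of class `posterior_sample`.
#' @export
posterior_sample <- function(lnl_trace, burnin = 0L, run_id = "run1") {
  if (burnin >= length(lnl_trace)) stop("burnin >= trace length")
  structure(list(run_id = run_id, lnl_trace = as.numeric(lnl_trace),
                 burnin = as.integer(burnin)),
            class = "posterior_sample")
}

#' Read a posterior trace TSV (generation, lnL)
#'
#' @param path TSV with columns `generation` and `lnL` (natural log).
#' @param burnin Samples to discard.
#' @return A [posterior_sample()].
#' @export
read_posterior_trace <- function(path, burnin = 0L) {
  d <- .read_tsv(path)
  posterior_sample(d$lnL, burnin = burnin,
                   run_id = basename(path))
}

#' Harmonic-mean estimate of the log marginal likelihood
#'
#' `ln m = -(logsumexp(-lnL) - ln n)` over the pooled post-burn-in samples
#' (the numerically stabilised harmonic mean of the likelihoods) — the rough
#' marginal-likelihood estimator classically applied to posterior samples.
#'
#' @param x A [posterior_sample()], a list of them (pooled), or a numeric
#'   vector of log-likelihoods.
#' @param burnin Burn-in to apply when `x` is a bare numeric vector.
#' @return The natural-log marginal likelihood estimate.
#' @export
harmonic_mean_lnl <- function(x, burnin = 0L) {
  drop_burnin <- function(v, b) if (b > 0L) v[-seq_len(b)] else v
  pooled <- if (inherits(x, "posterior_sample")) {
    drop_burnin(x$lnl_trace, x$burnin)
  } else if (is.list(x)) {
    unlist(lapply(x, function(ps) drop_burnin(ps$lnl_trace, ps$burnin)))
  } else {
    drop_burnin(x, burnin)
  }
  if (length(pooled) < 1L) stop("empty post-burn-in trace")
  -(.logsumexp(-pooled) - log(length(pooled)))
}

#' Bayes factor between two marginal likelihoods
#'
#' `2 ln BF = 2 (ln m1 - ln m0)`; positive values favour model 1. Verbal
#' categories follow the Kass-Raftery scale: above 10 "very strong", above
#' 6 "strong", above 2 "positive", otherwise "weak".
#'
#' @param lnm1,lnm0 Natural-log marginal likelihoods.
#' @return List: `two_ln_bf`, `category`, `favours` (1 or 0).
#' @export
bayes_factor <- function(lnm1, lnm0) {
  stopifnot(is.finite(lnm1), is.finite(lnm0))
  v <- 2 * (lnm1 - lnm0)
  category <- if (v > 10) "very strong" else if (v > 6) "strong" else
    if (v > 2) "positive" else "weak"
  list(two_ln_bf = v, category = category,
       favours = if (v >= 0) 1L else 0L)
}
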