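test_that("discrete Gamma rates use the mean-per-category convention", {
  expect_equal(discrete_gamma_rates(0.7, 1), 1)
  for (a in c(0.3, 1, 5)) {
    r <- discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_true(all(diff(r) > 0))
  }
  # very large shape: rates collapse to 1 (no heterogeneity)
  expect_equal(discrete_gamma_rates(1e6, 4), rep(1, 4), tolerance = 1e-2)
})

test_that("zero-length branches give ln(base frequency) for identical tips", {
  tr <- ape::read.tree(text = "(x:0,y:0);")
  mod <- gtrig_model(base_freqs = c(0.3, 0.2, 0.25, 0.25), alpha = 0.7,
                     p_inv = 0.2)
  for (b in c("A", "C", "G", "T")) {
    aln <- partitioned_alignment(setNames(c(b, b), c("x", "y")))
    expect_equal(site_loglik(tr, aln, mod),
                 log(mod$base_freqs[[b]]), tolerance = 1e-12)
  }
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(401)
  for (rep in 1:6) {
    ntaxa <- sample(4:5, 1)
    tr <- rand_tree(ntaxa)
    mod <- rand_gtrig()
    chars <- matrix(sample(BASES, ntaxa * 6, replace = TRUE), nrow = ntaxa,
                    dimnames = list(letters[seq_len(ntaxa)], NULL))
    aln <- partitioned_alignment(chars)
    got <- site_loglik(tr, aln, mod)
    want <- oracle_site_loglik(tr, chars, mod)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("ambiguity codes and gaps enter as partial likelihoods", {
  set.seed(402)
  tr <- rand_tree(4)
  mod <- rand_gtrig()
  # an N/gap tip column must equal the sum over its base resolutions
  chars <- matrix(c("A", "C", "G", "N",
                    "A", "C", "G", "-"), nrow = 4,
                  dimnames = list(letters[1:4], NULL))
  aln <- partitioned_alignment(chars)
  got <- site_loglik(tr, aln, mod)
  per_base <- vapply(BASES, function(b) {
    ch <- chars; ch[4, ] <- b
    exp(site_loglik(tr, partitioned_alignment(ch), mod))
  }, c(0, 0))
  expect_equal(exp(got), rowSums(per_base), tolerance = 1e-10)
  # R = A or G
  chR <- matrix(c("A", "C", "G", "R"), nrow = 4,
                dimnames = list(letters[1:4], NULL))
  gotR <- site_loglik(tr, partitioned_alignment(chR), mod)
  wantR <- log(sum(vapply(c("A", "G"), function(b) {
    ch <- chR; ch[4, ] <- b
    exp(site_loglik(tr, partitioned_alignment(ch), mod))
  }, 0)))
  expect_equal(gotR, wantR, tolerance = 1e-10)
})

test_that("alpha -> Inf converges to the single-rate likelihood", {
  set.seed(403)
  tr <- rand_tree(5)
  chars <- matrix(sample(BASES, 5 * 20, replace = TRUE), nrow = 5,
                  dimnames = list(letters[1:5], NULL))
  aln <- partitioned_alignment(chars)
  f <- c(0.3, 0.2, 0.3, 0.2)
  m_inf <- gtrig_model(base_freqs = f, alpha = 1e7, p_inv = 0, n_gamma_cat = 4)
  m_one <- gtrig_model(base_freqs = f, alpha = 1, p_inv = 0, n_gamma_cat = 1)
  expect_equal(site_loglik(tr, aln, m_inf), site_loglik(tr, aln, m_one),
               tolerance = 1e-4)
})

test_that("total log-likelihood is invariant to re-rooting", {
  set.seed(404)
  tr <- ape::unroot(rand_tree(6))
  chars <- matrix(sample(BASES, 6 * 30, replace = TRUE), nrow = 6,
                  dimnames = list(letters[1:6], NULL))
  aln <- partitioned_alignment(chars)
  mod <- rand_gtrig()
  base_ll <- sum(site_loglik(tr, aln, mod))
  for (og in c("b", "e")) {
    rerooted <- ape::root(tr, outgroup = og, resolve.root = FALSE)
    expect_equal(sum(site_loglik(rerooted, aln, mod)), base_ll,
                 tolerance = 1e-8)
  }
})

test_that("partitioned models apply per site label", {
  set.seed(405)
  tr <- rand_tree(4)
  chars <- matrix(sample(BASES, 4 * 12, replace = TRUE), nrow = 4,
                  dimnames = list(letters[1:4], NULL))
  labels <- rep(c("cytb.1", "cytb.2"), each = 6)
  aln <- partitioned_alignment(chars, labels = labels)
  m1 <- rand_gtrig(); m2 <- rand_gtrig()
  got <- site_loglik(tr, aln, list(cytb.1 = m1, cytb.2 = m2))
  a1 <- partitioned_alignment(chars[, 1:6])
  a2 <- partitioned_alignment(chars[, 7:12])
  expect_equal(got, c(site_loglik(tr, a1, m1), site_loglik(tr, a2, m2)),
               tolerance = 1e-12)
  expect_error(site_loglik(tr, aln, list(cytb.1 = m1)), "no model")
})

test_that("site likelihoods agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(406)
  tr <- rand_tree(5)
  chars <- matrix(sample(BASES, 5 * 40, replace = TRUE), nrow = 5,
                  dimnames = list(letters[1:5], NULL))
  aln <- partitioned_alignment(chars)
  f <- c(0.28, 0.22, 0.27, 0.23)
  ex <- c(1.2, 3.1, 0.8, 1.1, 4.0, 1)
  mod <- gtrig_model(exchangeabilities = ex, base_freqs = f, alpha = 0.9,
                     p_inv = 0, n_gamma_cat = 4)
  pd <- phangorn::phyDat(chars, type = "DNA")
  fit <- phangorn::pml(tr, pd, bf = f, Q = ex, k = 4, shape = 0.9)
  expect_equal(sum(site_loglik(tr, aln, mod)), as.numeric(stats::logLik(fit)),
               tolerance = 1e-6)
})

test_that("alignment restriction keeps covered sites and labels", {
  chars <- matrix(c("A", "C", "G",
                    "-", "C", "G",
                    "A", "N", "G",
                    "A", "C", "G"), nrow = 4, byrow = TRUE,
                  dimnames = list(c("full", "gapped", "focal", "other"), NULL))
  aln <- partitioned_alignment(chars, labels = c("g.1", "g.2", "g.3"))
  r <- restrict_to_covered(aln, "focal")
  expect_equal(ncol(r$chars), 2)
  expect_equal(r$labels, c("g.1", "g.3"))
  same <- restrict_to_covered(aln, "full")
  expect_equal(ncol(same$chars), 3)
  chars2 <- chars; chars2["focal", ] <- "-"
  expect_warning(empty <- restrict_to_covered(
    partitioned_alignment(chars2), "focal"), "no covered")
  expect_equal(ncol(empty$chars), 0)
  expect_error(restrict_to_covered(aln, "nobody"), "not in alignment")
})

test_that("RELL replicates resample columns jointly and reproducibly", {
  M1 <- matrix(c(-3.2), nrow = 1, dimnames = list("t1", NULL))
  expect_equal(as.numeric(rell_bootstrap(M1, B = 1, seed = 5)), -3.2)
  set.seed(407)
  M <- matrix(rnorm(2 * 50, mean = -4), nrow = 2,
              dimnames = list(c("t1", "t2"), NULL))
  r1 <- rell_bootstrap(M, B = 200, seed = 9)
  r2 <- rell_bootstrap(M, B = 200, seed = 9)
  expect_identical(r1, r2)
  # CLT: the replicate mean approximates the observed totals
  big <- rell_bootstrap(M, B = 10000, seed = 10)
  site_var <- apply(M, 1, function(x) sum((x - mean(x))^2))
  se <- sqrt(site_var) / sqrt(10000)
  expect_true(all(abs(rowMeans(big) - rowSums(M)) < 3 * se + 1e-9))
  # scale r resamples ceiling(r * n) columns
  half <- rell_bootstrap(M, B = 500, seed = 11, scale = 0.5)
  expect_true(all(abs(rowMeans(half) - 0.5 * rowSums(M)) <
                    3 * sqrt(0.5 * site_var) / sqrt(500) + 0.5))
  expect_error(rell_bootstrap(M[, 0, drop = FALSE], B = 10), "empty")
})

test_that("SH test: ties give p = 1, dominated trees give tiny p", {
  M <- matrix(rnorm(100, -5), nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), NULL))
  M[2, ] <- M[1, ]
  res <- sh_test(M, B = 2000, seed = 12)
  expect_equal(res$p_sh, c(1, 1))

  M2 <- rbind(t1 = rnorm(100, -5, 0.3), t2 = rnorm(100, -5, 0.3) - 10)
  res2 <- sh_test(M2, B = 5000, seed = 13)
  expect_lt(res2$p_sh[2], 0.001)
  expect_gt(res2$p_sh[1], 0.5)
  expect_true(all(res2$p_sh >= 0 & res2$p_sh <= 1))
  expect_identical(sh_test(M2, B = 500, seed = 3)$p_sh,
                   sh_test(M2, B = 500, seed = 3)$p_sh)
  expect_warning(sh_test(M2, B = 50, seed = 1), "unstable")
})

test_that("AU test rejects dominated trees and tracks SH on 2-tree problems", {
  set.seed(408)
  M <- rbind(t1 = rnorm(150, -5, 0.5), t2 = rnorm(150, -5, 0.5) - 3)
  au <- au_test(M, B = 2000, seed = 14)
  expect_true(all(au$p_au >= 0 & au$p_au <= 1))
  expect_lt(au$p_au[2], 0.01)          # dominated: BP = 0 at every scale
  expect_gt(au$p_au[1], 0.9)

  # moderate signal: AU and SH p-values agree within 0.05
  M2 <- rbind(t1 = rnorm(200, -5, 1), t2 = rnorm(200, -5, 1))
  M2[2, ] <- M2[2, ] - rnorm(200, 0.05, 0.02)
  au2 <- au_test(M2, B = 5000, seed = 15)
  sh2 <- sh_test(M2, B = 5000, seed = 15)
  expect_lt(abs(au2$p_au[2] - sh2$p_sh[2]), 0.05)
  expect_error(au_test(M2, scales = 1, B = 100), "two usable scales")
})

test_that("harmonic-mean marginal likelihood is exact on known cases", {
  expect_equal(harmonic_mean_lnl(rep(-100, 50)), -100)
  expect_equal(harmonic_mean_lnl(c(log(1), log(3))), log(1.5))
  set.seed(409)
  tr <- rnorm(500, -300, 5)
  expect_equal(harmonic_mean_lnl(tr), harmonic_mean_lnl(sample(tr)))
  # pooling runs equals the concatenated trace
  p1 <- posterior_sample(tr[1:250], burnin = 50, run_id = "r1")
  p2 <- posterior_sample(tr[251:500], burnin = 50, run_id = "r2")
  pooled <- harmonic_mean_lnl(list(p1, p2))
  concat <- harmonic_mean_lnl(c(tr[51:250], tr[301:500]))
  expect_equal(pooled, concat)
  expect_error(posterior_sample(c(-1, -2), burnin = 5), "burnin")
})

test_that("Bayes factor categories follow the Kass-Raftery bands", {
  expect_equal(bayes_factor(-10, -10)$two_ln_bf, 0)
  expect_equal(bayes_factor(-10, -10)$category, "weak")
  bf <- bayes_factor(-100, -105.76)
  expect_equal(bf$two_ln_bf, 11.52)
  expect_equal(bf$category, "very strong")
  expect_equal(bayes_factor(-100, -104)$category, "strong")
  expect_equal(bayes_factor(-100, -101.5)$category, "positive")
  # antisymmetry
  expect_equal(bayes_factor(-3, -9)$two_ln_bf,
               -bayes_factor(-9, -3)$two_ln_bf)
})

test_that("charset ranges parse into per-site labels", {
  lab <- parse_charsets(c("charset cytb.1 = 1-6\\3;",
                          "charset cytb.2 = 2-6\\3;",
                          "cytb.3 = 3-6\\3"), 6)
  expect_equal(lab, rep(c("cytb.1", "cytb.2", "cytb.3"), 2))
  lab2 <- parse_charsets("irbp = 1-4", 6)
  expect_equal(lab2, c(rep("irbp", 4), NA, NA))
})
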