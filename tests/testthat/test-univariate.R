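test_that("voxelwise GLM t reproduces the closed-form two-sample t", {
  # scalar engine must reproduce the clinical-table case:
  # 29.75 (16.53, n=24) vs 68.55 (15.89, n=20) -> |t| = 7.889, df = 42
  set.seed(71)
  g1 <- drop(scale(rnorm(24))) * 16.53 + 29.75
  g2 <- drop(scale(rnorm(20))) * 15.89 + 68.55
  y <- matrix(c(g1, g2), ncol = 1)
  des <- glm_design(rep(c("responder", "non-responder"), c(24, 20)))
  tv <- glm_tstat_map(y, des$design, des$contrast)
  expect_equal(attr(tv, "df"), 42)
  expect_lt(abs(abs(tv[1]) - 7.889), 5e-4)

  # equal group means with covariates -> t = 0
  age <- rnorm(44)
  des2 <- glm_design(rep(c("responder", "non-responder"), c(24, 20)),
                     data.frame(age = age))
  y0 <- matrix(rep(1, 44) + 0 * age, ncol = 1)
  expect_equal(glm_tstat_map(y0, des2$design, des2$contrast)[1], 0)

  # closed-form pooled-t oracle on 50 random scalar datasets
  set.seed(72)
  for (i in 1:50) {
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    x1 <- rnorm(n1); x2 <- rnorm(n2, mean = runif(1, -1, 1))
    des3 <- glm_design(rep(c("responder", "non-responder"), c(n1, n2)))
    tv3 <- glm_tstat_map(matrix(c(x1, x2), ncol = 1), des3$design, des3$contrast)
    sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
    t_ref <- (mean(x2) - mean(x1)) / (sp * sqrt(1 / n1 + 1 / n2))
    expect_equal(tv3[1], t_ref, tolerance = 1e-10)
  }
})

test_that("TFCE matches its discrete definition and stays monotone", {
  mask <- array(TRUE, dim = c(5, 5, 5))
  zero <- array(0, dim = c(5, 5, 5))
  expect_true(all(tfce(zero, mask) == 0))
  expect_error(tfce(zero, array(FALSE, c(5, 5, 5))), "empty mask")

  # hand-computed single-voxel case: sum over h in {0.5,1,1.5,2} of h^2*0.5
  s <- zero; s[3, 3, 3] <- 2
  e <- tfce(s, mask, tfce_params(dh = 0.5))
  expect_equal(e[as.vector(s) == 2], 3.75)
  expect_equal(e[as.vector(s) == 2],
               tfce_brute(s, mask, dh = 0.5)[as.vector(s) == 2])

  # scaling the map never decreases any enhanced value
  set.seed(73)
  m <- array(abs(rnorm(125)), dim = c(5, 5, 5))
  e1 <- tfce(m, mask)
  e2 <- tfce(2 * m, mask)
  expect_true(all(e2 >= e1 - 1e-12))

  # two-tailed rule is the voxelwise max of both tails
  tt <- tfce_two_tailed(m - mean(m), mask)
  expect_equal(tt, pmax(tfce(m - mean(m), mask), tfce(mean(m) - m, mask)))
})

test_that("C++ component labelling agrees with an R flood fill", {
  set.seed(74)
  for (conn in c(6L, 18L, 26L)) {
    bin <- array(runif(6 * 5 * 4) > 0.6, dim = c(6, 5, 4))
    fast <- array(rsnpredict:::label_components_cpp(as.vector(bin),
                                                    dim(bin), conn), dim(bin))
    ref <- label_brute(bin, conn)
    # same partition (labels may be permuted)
    expect_equal(fast > 0, ref > 0)
    for (l in unique(ref[ref > 0])) {
      members <- fast[ref == l]
      expect_equal(length(unique(members)), 1L)
    }
    expect_equal(max(fast), max(ref))
  }
})

test_that("pooled permutation FWE respects its p-value contract", {
  nf <- cohort_network_features(81, effect_size = 2.5, n_responders = 8,
                                n_nonresponders = 8, n_timepoints = 30)
  des <- glm_design(nf$y, data.frame(age = nf$age))
  r <- permutation_fwe(nf$families, des$design, des$contrast, nf$mask,
                       n_perm = 99, seed = 4)
  expect_equal(min(unlist(r$p_fwe)), 1 / 100) # strong effect hits the floor
  expect_true(all(unlist(r$p_fwe) >= 1 / 100 & unlist(r$p_fwe) <= 1))

  # pooling monotonicity: joint correction is never more liberal
  r1 <- permutation_fwe(nf$families[1], des$design, des$contrast, nf$mask,
                        n_perm = 99, seed = 4)
  expect_true(all(r$p_fwe[[1]] >= r1$p_fwe[[1]] - 1e-12))

  # exchangeability: permuting subject order (and design rows) is a no-op
  set.seed(99)
  pi <- sample(length(nf$y))
  fam_p <- lapply(nf$families, function(f) f[pi, , drop = FALSE])
  des_p <- glm_design(nf$y[pi], data.frame(age = nf$age[pi]))
  rp <- permutation_fwe(fam_p, des_p$design, des_p$contrast, nf$mask,
                        n_perm = 99, seed = 4)
  expect_equal(rp$tstat, r$tstat, tolerance = 1e-9)
  expect_equal(rp$enhanced, r$enhanced, tolerance = 1e-9)

  expect_error(permutation_fwe(nf$families, des$design, des$contrast,
                               nf$mask, n_perm = 99), "seed")
  expect_error(permutation_fwe(nf$families, des$design, des$contrast,
                               nf$mask, n_perm = 10, seed = 1), ">= 99")
})
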