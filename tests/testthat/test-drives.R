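test_that("dense drive unrolls delayed dendrites with causal zero-padding", {
  # single zero-delay dendrite reduces to the classic drive
  set.seed(1)
  S <- random_spike_matrix(6, 3, 11)
  W <- array(rnorm(3 * 2), c(3, 2, 1))
  kd <- dense_delay_kernel(W, 0L)
  expect_equal(dense_delay_drive(S, kd), S %*% W[, , 1])
  # hand unrolling: delays {0,1}, weights 0.3 / 0.7, S = 1,0,1
  kd <- dense_delay_kernel(array(c(0.3, 0.7), c(1, 1, 2)), c(0, 1))
  expect_equal(dense_delay_drive(matrix(c(1, 0, 1)), kd)[, 1],
               c(0.3, 0.7, 0.3))
  expect_equal(dense_delay_drive(matrix(0, 3, 1), kd), matrix(0, 3, 1))
  expect_error(dense_delay_kernel(array(1, c(1, 1, 2)), c(0, -1)), "nonnegative")
  expect_error(dense_delay_kernel(array(1, c(1, 1, 2)), c(1, 0)), "ascending")
})

test_that("factorized drive equals the dense drive on rank-1 kernels", {
  k <- delay_kernel(matrix(0.5), c(1, 2), delays = c(0, 1))
  expect_equal(factorized_delay_drive(matrix(c(1, 0, 1)), k)[, 1],
               c(0.5, 1.0, 0.5))
  # null temporal taps kill the drive
  k0 <- delay_kernel(matrix(rnorm(6), 3, 2), c(0, 0), delays = c(0, 2))
  expect_equal(factorized_delay_drive(random_spike_matrix(5, 3, 2), k0),
               matrix(0, 5, 2))
  # algebraic identity against the expanded dense kernel
  for (s in 1:25) {
    set.seed(s)
    Ni <- sample(1:4, 1); Nj <- sample(1:4, 1); Nk <- sample(1:4, 1)
    Tn <- sample(2:8, 1)
    kern <- delay_kernel(matrix(rnorm(Ni * Nj), Ni, Nj), rnorm(Nk),
                         delays = sort(sample(0:(Tn + 2), Nk)))
    S <- random_spike_matrix(Tn, Ni, 100 + s)
    expect_equal(factorized_delay_drive(S, kern),
                 dense_delay_drive(S, as_dense_kernel(kern)),
                 tolerance = 1e-12)
  }
})

test_that("factorized kernel stores Ni*Nj + Nk weights", {
  kern <- delay_kernel(matrix(0, 5, 7), numeric(3), delays = c(0, 1, 4))
  expect_identical(length(kern$W1) + length(kern$w2),
                   parameter_count(5, 7, 3, factorized = TRUE))
  expect_identical(length(as_dense_kernel(kern)$W),
                   parameter_count(5, 7, 3, factorized = FALSE))
})

test_that("segment drive aggregates windows and is constant within them", {
  k <- delay_kernel(matrix(1), c(0.5, 0.5))
  expect_equal(segment_drive(matrix(c(1, 0, 0, 1)), k, 2)[, 1],
               rep(0.5, 4))
  # mem_len = 1 reduces to the classic drive
  k1 <- delay_kernel(matrix(rnorm(8), 4, 2), 1)
  S <- random_spike_matrix(6, 4, 3)
  expect_equal(segment_drive(S, k1, 1), S %*% k1$W1)
  # strict divisibility
  k2 <- delay_kernel(matrix(1), c(1, 1, 1))
  expect_error(segment_drive(matrix(c(1, 0, 0, 1)), k2, 3), "divisible")
  # permissive zero-padding: final short window aggregates what exists
  I <- segment_drive(matrix(c(1, 0, 0, 1)), k2, 3, pad = "zero")
  expect_equal(I[, 1], c(1, 1, 1, 1))
  expect_error(segment_drive(S, k1, 2), "length\\(w2\\)")
})

test_that("uniform taps make segment drive permutation-invariant within windows", {
  set.seed(5)
  for (rep in 1:20) {
    Tn <- 12L; L <- sample(c(2L, 3L, 4L), 1)
    Ni <- sample(2:4, 1); Nj <- sample(1:3, 1)
    k <- delay_kernel(matrix(rnorm(Ni * Nj), Ni, Nj), rep(1 / L, L))
    S <- random_spike_matrix(Tn, Ni, 300 + rep)
    Sp <- S
    for (m in seq_len(Tn / L) - 1L) {
      rows <- m * L + sample(L)   # permute spike times inside each window
      Sp[m * L + seq_len(L), ] <- S[rows, ]
    }
    expect_equal(segment_drive(Sp, k, L), segment_drive(S, k, L),
                 tolerance = 1e-12)
  }
})

test_that("segment drive in a window depends only on that window's spikes", {
  set.seed(9)
  k <- delay_kernel(matrix(rnorm(6), 3, 2), rnorm(4))
  S <- random_spike_matrix(12, 3, 4)
  I <- segment_drive(S, k, 4)
  S2 <- S
  S2[9:12, ] <- random_spike_matrix(4, 3, 5)  # perturb the last window only
  I2 <- segment_drive(S2, k, 4)
  expect_equal(I2[1:8, ], I[1:8, ])
  expect_false(isTRUE(all.equal(I2[9:12, ], I[9:12, ])))
})

test_that("temporal fusion is a static weighted readout of all timesteps", {
  h <- fusion_head(matrix(1), c(0.2, 0.3, 0.5))
  expect_equal(temporal_fusion(matrix(c(1, 0, 1)), h), 0.7)
  expect_equal(temporal_fusion(matrix(0, 3, 1), h), 0)
  # all-ones head counts spikes
  S <- random_spike_matrix(7, 4, 8)
  hc <- fusion_head(matrix(1, 4, 1), rep(1, 7))
  expect_equal(temporal_fusion(S, hc), sum(S))
  # uniform taps: invariant under any permutation of timesteps
  hu <- fusion_head(matrix(rnorm(8), 4, 2), rep(1 / 7, 7))
  set.seed(10)
  expect_equal(temporal_fusion(S[sample(7), ], hu), temporal_fusion(S, hu))
  expect_error(temporal_fusion(random_spike_matrix(6, 4, 1), hu), "length|match")
})

test_that("all drive operations are linear in the spike train", {
  set.seed(12)
  Tn <- 8L; Ni <- 3L
  S <- random_spike_matrix(Tn, Ni, 20, p = 0.7)
  mask <- random_spike_matrix(Tn, Ni, 21, p = 0.5)
  S1 <- S * mask; S2 <- S * (1 - mask)    # disjoint decomposition
  k <- delay_kernel(matrix(rnorm(6), Ni, 2), rnorm(2), delays = c(0, 2))
  ks <- delay_kernel(matrix(rnorm(6), Ni, 2), rnorm(4))
  h <- fusion_head(matrix(rnorm(6), Ni, 2), rnorm(Tn))
  expect_equal(factorized_delay_drive(S1, k) + factorized_delay_drive(S2, k),
               factorized_delay_drive(S, k), tolerance = 1e-12)
  expect_equal(segment_drive(S1, ks, 4) + segment_drive(S2, ks, 4),
               segment_drive(S, ks, 4), tolerance = 1e-12)
  expect_equal(temporal_fusion(S1, h) + temporal_fusion(S2, h),
               temporal_fusion(S, h), tolerance = 1e-12)
})

test_that("layer_forward dispatches on mode and matches drive + lif_run", {
  set.seed(14)
  lif <- lif_params(tau = 2, theta = 0.8)
  S <- random_spike_matrix(8, 3, 30)
  # classic dispatch identity
  kc <- delay_kernel(matrix(rnorm(6), 3, 2), 1, delays = 0L)
  spec <- layer_spec(kc, lif, wm_config("classic"))
  tr <- layer_forward(S, spec)
  expect_identical(tr$V, lif_run(S %*% kc$W1, lif)$V)
  expect_identical(tr$spikes, lif_run(S %*% kc$W1, lif)$spikes)
  # overlap causality: future spikes cannot change the present
  ko <- delay_kernel(matrix(rnorm(6), 3, 2), rnorm(3), delays = 0:2)
  so <- layer_spec(ko, lif, wm_config("overlap"))
  tr1 <- layer_forward(S, so)
  S2 <- S; S2[7:8, ] <- 1 - S2[7:8, ]
  tr2 <- layer_forward(S2, so)
  expect_identical(tr2$spikes[1:6, ], tr1$spikes[1:6, ])
  expect_identical(tr2$V[1:6, ], tr1$V[1:6, ])
  # classic mode constructor enforces its delay/tap invariant
  expect_error(layer_spec(ko, lif, wm_config("classic")), "classic")
  expect_error(layer_spec(ko, lif, wm_config("fusion")), "head")
})
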