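test_that("task generators are balanced, deterministic pure functions of the spec", {
  spec <- task_spec("order", n_samples = 10, seed = 5)
  d <- make_order_task(spec)
  expect_equal(dim(d$spikes), c(10L, 32L, 16L))
  expect_equal(sum(d$labels == 0), 5L)
  expect_equal(sum(d$labels == 1), 5L)
  expect_true(all(d$spikes %in% c(0, 1)))
  expect_identical(make_order_task(spec), d)
  expect_false(identical(make_order_task(task_spec("order", n_samples = 10,
                                                   seed = 6)), d))
  spec2 <- task_spec("density", n_samples = 11, seed = 2)
  d2 <- make_density_task(spec2)
  expect_lte(abs(sum(d2$labels == 0) - sum(d2$labels == 1)), 1L)
  expect_identical(make_density_task(spec2), d2)
  expect_identical(make_task(spec2), d2)
  expect_error(task_spec("order", T = 16, motif_len = 8, jitter = 2),
               "2\\*motif_len")
})

test_that("noise-free order samples contain both motifs in opposite order", {
  spec <- task_spec("order", n_samples = 40, jitter = 0, noise_rate = 0,
                    seed = 9)
  d <- make_order_task(spec)
  half <- spec$T %/% 2L
  base <- (half - spec$motif_len) %/% 2L
  rows1 <- base + seq_len(spec$motif_len)
  rows2 <- half + base + seq_len(spec$motif_len)
  s0 <- d$spikes[which(d$labels == 0)[1], , ]
  s1 <- d$spikes[which(d$labels == 1)[1], , ]
  # the two classes carry the same motifs, swapped between halves
  expect_equal(s0[rows1, ], s1[rows2, ])  # motif A
  expect_equal(s0[rows2, ], s1[rows1, ])  # motif B
  # nothing outside the motif slots
  expect_equal(sum(s0[-c(rows1, rows2), ]), 0)
  # time-reversing a class-0 sample puts (reversed) B first, as in class 1
  rev0 <- s0[spec$T:1, ]
  expect_equal(rev0[rows1, ], s1[rows1, ][spec$motif_len:1, ])
})

test_that("density samples confine all informative spikes to one window", {
  spec <- task_spec("density", n_samples = 30, noise_rate = 0, jitter = 0,
                    seed = 4)
  d <- make_density_task(spec)
  L <- spec$motif_len
  for (s in seq_len(30)) {
    x <- d$spikes[s, , ]
    occupied <- which(vapply(seq_len(spec$T / L) - 1L, function(m) {
      sum(x[m * L + seq_len(L), ]) > 0
    }, TRUE))
    expect_lte(length(occupied), 1L)
  }
  # classes differ only in motif identity: window positions span the train
  expect_error(make_density_task(task_spec("order", seed = 1)), "density")
})

test_that("order-task per-neuron spike counts are class-exchangeable", {
  spec <- task_spec("order", n_samples = 2000, seed = 13)
  d <- make_order_task(spec)
  counts <- apply(d$spikes, 1, sum)  # total spikes per sample
  ks <- suppressWarnings(stats::ks.test(counts[d$labels == 0],
                                        counts[d$labels == 1]))
  expect_gt(ks$p.value, 0.01)
  # and per neuron
  per_neuron <- apply(d$spikes, c(1, 3), sum)
  pvals <- vapply(seq_len(spec$n_in), function(i) {
    suppressWarnings(stats::ks.test(per_neuron[d$labels == 0, i],
                                    per_neuron[d$labels == 1, i]))$p.value
  }, 0)
  expect_gt(min(pvals), 0.01 / spec$n_in)  # Bonferroni-adjusted floor
})

test_that("stratified split is exact, disjoint and reproducible", {
  spec <- task_spec("order", n_samples = 100, seed = 8)
  d <- make_order_task(spec)
  parts <- split_dataset(d, c(0.8, 0.2), seed = 3)
  expect_equal(length(parts$train$labels), 80L)
  expect_equal(length(parts$test$labels), 20L)
  expect_equal(sum(parts$train$labels == 0), 40L)
  expect_equal(sum(parts$test$labels == 1), 10L)
  # union of the splits is the original multiset of samples
  expect_equal(sum(parts$train$spikes) + sum(parts$test$spikes),
               sum(d$spikes))
  expect_identical(split_dataset(d, c(0.8, 0.2), seed = 3), parts)
  expect_error(split_dataset(d, c(0.999, 0.001), seed = 1), "empty")
  expect_error(split_dataset(d, c(0.5, 0.6), seed = 1), "summing")
})

test_that("datasets round-trip through plain-text persistence", {
  spec <- task_spec("density", n_samples = 12, T = 16, n_in = 4,
                    motif_len = 4, jitter = 0, seed = 21)
  d <- make_density_task(spec)
  dir <- withr::local_tempdir()
  save_dataset(d, dir)
  d2 <- load_dataset(dir)
  expect_equal(d2$spikes, d$spikes)
  expect_equal(d2$labels, d$labels)
  expect_equal(d2$spec$seed, d$spec$seed)
})
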