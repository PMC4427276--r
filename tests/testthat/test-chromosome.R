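# Binary encoding: decode map, crossover, mutation, cooperative assembly.

test_that("decode hits the bounds exactly and follows the affine map", {
  expect_identical(decode_bits(rep(0L, 16), 0, 50), 0)
  expect_identical(decode_bits(rep(1L, 16), 0, 50), 50)
  expect_equal(decode_bits(c(1L, 0L, 0L, 0L), 0, 50), 8 / 15 * 50)
  # monotone in the integer value, image within bounds (full enumeration)
  vals <- vapply(0:63, function(i) {
    bits <- as.integer(intToBits(i)[6:1])
    decode_bits(bits, -2, 3)
  }, 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= -2 & vals <= 3))
})

test_that("gray decoding is available behind a flag", {
  # gray 1000 -> binary 1111 -> upper bound
  expect_identical(decode_bits(c(1L, 0L, 0L, 0L), 0, 50, gray = TRUE), 50)
  expect_identical(decode_bits(c(0L, 0L, 0L, 0L), 0, 50, gray = TRUE), 0)
})

test_that("k-point crossover swaps alternating segments", {
  set.seed(5)
  a <- rep(0L, 4); b <- rep(1L, 4)
  ch <- k_point_crossover(a, b, 3)  # cuts at every boundary
  expect_identical(ch$a, c(0L, 1L, 0L, 1L))
  expect_identical(ch$b, c(1L, 0L, 1L, 0L))

  for (rep in 1:20) {
    L <- sample(4:20, 1)
    k <- sample(seq_len(L - 1L), 1)
    pa <- sample(0:1, L, replace = TRUE)
    pb <- sample(0:1, L, replace = TRUE)
    ch <- k_point_crossover(pa, pb, k)
    # children stay 0/1 of the same length
    expect_length(ch$a, L); expect_length(ch$b, L)
    expect_true(all(ch$a %in% 0:1) && all(ch$b %in% 0:1))
    # position-wise XOR is preserved by segment swapping
    expect_identical(bitwXor(ch$a, ch$b), bitwXor(pa, pb))
    # identical parents reproduce themselves
    same <- k_point_crossover(pa, pa, k)
    expect_identical(same$a, pa)
    expect_identical(same$b, pa)
  }
})

test_that("mutation flips at most one uniformly chosen bit per individual", {
  set.seed(8)
  bits <- sample(0:1, 16, replace = TRUE)
  expect_identical(mutate_chromosome(bits, 0), bits)
  for (rep in 1:20) {
    out <- mutate_chromosome(bits, 1)
    expect_identical(sum(out != bits), 1L)
  }
  # empirical mutation frequency at rate 0.3 over 10,000 trials
  set.seed(99)
  B <- matrix(sample(0:1, 10000 * 8, replace = TRUE), 10000, 8)
  M <- ncga:::mutate_pop(B, 0.3)
  freq <- mean(rowSums(M != B) > 0)
  expect_lt(abs(freq - 0.3), 0.02)
})

test_that("stochastic operators are reproducible from the RNG seed", {
  pa <- sample(0:1, 16, replace = TRUE)
  pb <- sample(0:1, 16, replace = TRUE)
  set.seed(123); c1 <- k_point_crossover(pa, pb, 2); m1 <- mutate_chromosome(pa, 0.5)
  set.seed(123); c2 <- k_point_crossover(pa, pb, 2); m2 <- mutate_chromosome(pa, 0.5)
  expect_identical(c1, c2)
  expect_identical(m1, m2)
})

test_that("cooperative assembly and decomposition are inverse", {
  p1 <- build_case1()
  set.seed(2)
  algo <- init_ncga(p1, modify_config_for_test(p1$preset, 10L))
  subpops <- algo$subpops
  for (rep in 1:100) {
    chosen <- sample.int(10L, length(subpops), replace = TRUE)
    coop <- assemble_cooperative(subpops, chosen)
    back <- decompose_cooperative(coop)
    for (j in seq_along(subpops)) {
      expect_identical(back[[j]]$member, chosen[j])
      expect_identical(back[[j]]$bits, subpops[[j]]$bits[chosen[j], ])
    }
    # decoded values are within bounds by construction
    for (j in seq_along(subpops)) {
      b <- subpops[[j]]$bounds
      v <- coop$decoded_state[[j]]
      expect_true(v >= b[1] && v <= b[2])
    }
  }
  expect_error(assemble_cooperative(subpops, c(1L, 2L)), "one chosen member")
})

test_that("benchmark presets decompose into the published sub-population counts", {
  p1 <- build_case1(); p2 <- build_case2()
  a1 <- init_ncga(p1, modify_config_for_test(p1$preset, 4L))
  a2 <- init_ncga(p2, modify_config_for_test(p2$preset, 4L))
  c1 <- assemble_cooperative(a1$subpops, rep(1L, length(a1$subpops)))
  c2 <- assemble_cooperative(a2$subpops, rep(1L, length(a2$subpops)))
  expect_length(c1$decoded_state, 11)
  expect_length(c2$decoded_state, 7)
})
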