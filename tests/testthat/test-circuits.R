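test_that("svd_unitarize factors contractions exactly", {
  set.seed(2)
  U <- random_unitary(3)
  f <- svd_unitarize(U)
  expect_equal(f$sigma, rep(1, 3), tolerance = 1e-12)
  f0 <- svd_unitarize(matrix(0i, 2, 2))
  expect_equal(f0$sigma, c(0, 0))
  for (r in 1:5) {
    M <- random_contraction(2)
    f <- svd_unitarize(M)
    expect_lt(max(Mod(f$U %*% diag(f$sigma) %*% f$Vdag - M)), 1e-12)
    expect_true(all(diff(f$sigma) <= 0))
    expect_true(all(f$sigma >= 0 & f$sigma <= 1))
  }
  expect_error(svd_unitarize(2 * diag(2)), "contraction")
})

test_that("dilation phases place diag(sigma) in the ancilla-0 block", {
  expect_equal(dilation_phases(c(1, 1)), rep(0, 4))
  expect_equal(dilation_phases(c(0, 0)), c(pi / 2, pi / 2, -pi / 2, -pi / 2))
  expect_error(dilation_phases(c(0.5, 1.2)))
  set.seed(3)
  for (r in 1:5) {
    sigma <- sort(stats::runif(4), decreasing = TRUE)
    f <- dilation_phases(sigma)
    D <- diag(exp(1i * f))
    Hf <- kronecker(matrix(c(1, 1, 1, -1), 2) / sqrt(2), diag(4))
    blk <- (Hf %*% D %*% Hf)[1:4, 1:4]
    expect_lt(max(Mod(blk - diag(sigma))), 1e-12)
  }
})

test_that("Walsh series is an exact involutive transform", {
  ## constant phase vector: only the global-phase coefficient survives
  ws <- walsh_coefficients(rep(0.37, 8))
  expect_equal(ws$coefficients, c(0.37, rep(0, 7)), tolerance = 1e-14)
  ## a single Walsh-function row maps to one unit coefficient
  W <- krausdyn:::walsh_matrix(3)
  ws2 <- walsh_coefficients(W[6, ])
  expect_equal(ws2$coefficients, as.numeric(seq_len(8) == 6),
               tolerance = 1e-14)
  ## random round trips
  set.seed(4)
  for (n in 1:3) {
    f <- stats::runif(2^n, -pi, pi)
    expect_lt(max(abs(walsh_reconstruct(walsh_coefficients(f)) - f)), 1e-12)
  }
  expect_error(walsh_coefficients(stats::runif(3)), "power of two")
})

test_that("Gray-code synthesis is exact with the expected gate counts", {
  set.seed(6)
  ## 1-qubit diagonal: one RZ, no CNOT
  c1 <- synthesize_diagonal(walsh_coefficients(c(0.3, -0.8)))
  m1 <- circuit_metrics(c1)
  expect_equal(m1$cnot_count, 0L)
  expect_equal(m1$gate_counts$RZ, 1L)
  ## exactness including the tracked global phase, n = 1, 2, 3
  for (n in 1:3) {
    f <- stats::runif(2^n, -pi, pi)
    circ <- synthesize_diagonal(walsh_coefficients(f))
    expect_lt(max(Mod(circuit_unitary(circ) - diag(exp(1i * f)))), 1e-10)
    ## full series on full connectivity never exceeds 2^n - 2 CNOTs
    expect_lte(circuit_metrics(circ)$cnot_count, 2^n - 2)
  }
  ## full 3-qubit series: exactly 6 CNOTs under Gray-cycle construction
  f3 <- stats::runif(8, -1, 1)
  expect_equal(circuit_metrics(synthesize_diagonal(
    walsh_coefficients(f3)))$cnot_count, 6L)
})

test_that("the dilated 2-qubit diagonal costs depth 4 and 2 CNOTs", {
  ## generic singular-value pair (ancilla-odd symmetry zeroes half the
  ## Walsh coefficients; the Gray walk still needs both CNOTs)
  sigma <- c(0.93, 0.41)
  circ <- synthesize_diagonal(walsh_coefficients(dilation_phases(sigma)))
  m <- circuit_metrics(circ)
  expect_equal(m$depth, 4L)
  expect_equal(m$cnot_count, 2L)
})

test_that("Kraus circuits expose the operator in the ancilla-0 block", {
  set.seed(12)
  ## M = identity: ancilla-0 probability 1, outcomes |<i|psi>|^2
  cI <- build_kraus_circuit(diag(2) + 0i)
  UI <- circuit_unitary(cI)
  expect_lt(max(Mod(UI[1:2, 1:2] - diag(2))), 1e-10)
  ## random 2 x 2 contractions, native single-qubit decomposition
  for (r in 1:5) {
    M <- random_contraction(2)
    circ <- build_kraus_circuit(M)
    expect_lt(max(Mod(circuit_unitary(circ)[1:2, 1:2] - M)), 1e-10)
    expect_equal(circuit_metrics(circ)$cnot_count, 2L)
    expect_false(circuit_metrics(circ)$contains_opaque)
  }
  ## 4 x 4 contraction: opaque U/V, exact block, flagged metrics
  M4 <- random_contraction(4)
  c4 <- build_kraus_circuit(M4)
  expect_lt(max(Mod(circuit_unitary(c4)[1:4, 1:4] - M4)), 1e-10)
  expect_true(circuit_metrics(c4)$contains_opaque)
  expect_error(build_kraus_circuit(random_contraction(3)), "2\\^n_sys")
})

test_that("native single-qubit decomposition reproduces the unitary", {
  set.seed(13)
  for (r in 1:10) {
    U <- random_unitary(2)
    dec <- krausdyn:::decompose_1q(U, 1L)
    circ <- circuit_ir(1L, dec$gates, phase = dec$phase)
    expect_lt(max(Mod(circuit_unitary(circ) - U)), 1e-12)
    expect_equal(vapply(dec$gates, `[[`, "", "name"),
                 c("RZ", "SX", "RZ", "SX", "RZ"))
  }
  ## diagonal and antidiagonal edge cases
  for (U in list(diag(c(1, 1i)) + 0i,
                 matrix(c(0, 1i, 1, 0), 2, 2))) {
    dec <- krausdyn:::decompose_1q(U, 1L)
    circ <- circuit_ir(1L, dec$gates, phase = dec$phase)
    expect_lt(max(Mod(circuit_unitary(circ) - U)), 1e-12)
  }
})

test_that("circuit metrics implement greedy ASAP layering", {
  empty <- circuit_ir(2L)
  expect_equal(circuit_metrics(empty)$depth, 0L)
  expect_equal(circuit_metrics(empty)$cnot_count, 0L)
  hch <- circuit_ir(2L, list(gate("H", 1L), gate("CNOT", c(1L, 2L)),
                             gate("H", 1L)))
  m <- circuit_metrics(hch)
  expect_equal(m$depth, 3L)
  expect_equal(m$cnot_count, 1L)
  ## disjoint single-qubit gates share a layer
  par <- circuit_ir(2L, list(gate("H", 1L), gate("X", 2L)))
  expect_equal(circuit_metrics(par)$depth, 1L)
})

test_that("QASM export lists the native gates", {
  circ <- build_kraus_circuit(random_contraction(2))
  txt <- export_qasm(circ)
  expect_true(any(grepl("^OPENQASM", txt)))
  expect_equal(sum(grepl("^cx", txt)), 2L)
  expect_true(any(grepl("^rz", txt)))
})
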