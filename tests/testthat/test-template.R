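test_that("median binarization is balanced, affine-invariant, and guarded", {
  expect_identical(binarize(c(0.2, -0.5, 0.7, -0.1)), c(1L, 0L, 1L, 0L))
  y <- rnorm(10000)
  expect_identical(binarize(3 * y + 7), binarize(y))
  bal <- mean(binarize(y))
  expect_gte(bal, 0.5 - 2 / sqrt(10000))
  expect_lte(bal, 0.5 + 2 / sqrt(10000))
  expect_error(binarize(rep(1, 100)), "constant")
})

test_that("key generation is seeded and distinct seeds give distant keys", {
  k1 <- generate_key(10000, seed = 1)
  expect_identical(k1$bits, generate_key(10000, seed = 1)$bits)
  expect_true(all(k1$bits %in% c(0L, 1L)))
  k2 <- generate_key(10000, seed = 2)
  hd <- sum(k1$bits != k2$bits)
  expect_gte(hd, 5000 - 300)
  expect_lte(hd, 5000 + 300)
  expect_true(generate_key(1, seed = 3)$bits %in% c(0L, 1L))
  expect_error(generate_key(0, seed = 1), "n must be >= 1")
})

test_that("XOR encryption satisfies the truth table and is an involution", {
  expect_identical(xor_encrypt(c(1L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L)),
                   c(0L, 1L, 1L, 0L))
  b <- c(1L, 0L, 1L, 1L)
  expect_identical(xor_encrypt(b, c(0L, 0L, 0L, 0L)), b)
  # property: encrypt twice with the same key restores the input
  withr::with_seed(21, {
    for (rep in 1:25) {
      n <- sample(2:500, 1)
      bits <- sample(c(0L, 1L), n, replace = TRUE)
      key <- generate_key(n, seed = rep)
      expect_identical(xor_encrypt(xor_encrypt(bits, key), key), bits)
    }
  })
  expect_error(xor_encrypt(c(1L, 0L), c(1L, 0L, 1L)), "lengths differ")
})

test_that("template generation is deterministic end to end", {
  pair <- ecg_audio_pair(n = 4000L)
  key <- generate_key(4000, seed = 5)
  cfg <- bss_config(q = 2, l1 = -10, l2 = 10)
  t1 <- generate_template(pair$ecg, pair$audio, key, cfg, subject_id = "A")
  t2 <- generate_template(pair$ecg, pair$audio, key, cfg, subject_id = "A")
  expect_identical(t1$bits, t2$bits)
  expect_length(t1$bits, 4000L)
  expect_true(isTRUE(t1$provenance$converged))
})

test_that("independent keys whiten templates (revocability statistics)", {
  n <- 10000L
  pair <- ecg_audio_pair(n = n)
  cfg <- bss_config(q = 2, l1 = -10, l2 = 10)
  ta <- generate_template(pair$ecg, pair$audio, generate_key(n, seed = 31),
                          cfg, subject_id = "A")
  tb <- generate_template(pair$ecg, pair$audio, generate_key(n, seed = 32),
                          cfg, subject_id = "A")
  nhd <- mean(ta$bits != tb$bits)
  expect_gte(nhd, 0.5 - 3 / sqrt(n))
  expect_lte(nhd, 0.5 + 3 / sqrt(n))
  expect_lt(abs(correlation_score(ta, tb)), 3 / sqrt(n))
  # non-invertibility proxy: encrypted bits carry no correlation with the
  # binarized raw ECG
  raw_bits <- binarize(pair$ecg)
  expect_lt(abs(correlation_score(ta$bits, raw_bits)), 0.05)
})

test_that("revocation rejects seed collisions and decorrelates reissues", {
  n <- 10000L
  pair <- ecg_audio_pair(n = n)
  cfg <- bss_config(q = 2, l1 = -10, l2 = 10)
  old <- generate_template(pair$ecg, pair$audio, generate_key(n, seed = 41),
                           cfg, subject_id = "A")
  expect_error(revoke_template(pair$ecg, pair$audio, old, new_seed = 41),
               "different seed")
  new <- revoke_template(pair$ecg, pair$audio, old, new_seed = 42)
  expect_lt(abs(correlation_score(old, new)), 0.05)
  # an old probe no longer verifies against the reissued enrollment
  expect_false(verify_template(old, new, threshold = 0.5)$match)
})

test_that("template store round-trips bit-exactly as JSON lines", {
  pair <- ecg_audio_pair(n = 2000L)
  cfg <- bss_config(q = 1, l1 = -5, l2 = 5)
  tps <- list(
    generate_template(pair$ecg, pair$audio, generate_key(2000, seed = 1),
                      cfg, subject_id = "A"),
    generate_template(pair$ecg, pair$audio, generate_key(2000, seed = 2),
                      cfg, subject_id = "B", output_choice = "y2")
  )
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_template_store(tps, p)
  expect_length(readLines(p), 2L)
  back <- read_template_store(p)
  expect_identical(back[[1]]$bits, tps[[1]]$bits)
  expect_identical(back[[2]]$bits, tps[[2]]$bits)
  expect_identical(back[[2]]$subject_id, "B")
  expect_identical(back[[2]]$provenance$output_choice, "y2")
})

test_that("hex packing is little-endian within bytes and length-exact", {
  bits <- c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L)  # 9 bits -> 0x01, 0x01
  hex <- cancellableECG:::bits_to_hex(bits)
  expect_identical(hex, "0101")
  expect_identical(cancellableECG:::hex_to_bits(hex, 9L), bits)
  withr::with_seed(9, {
    for (n in c(1L, 8L, 13L, 256L)) {
      b <- sample(c(0L, 1L), n, replace = TRUE)
      expect_identical(
        cancellableECG:::hex_to_bits(cancellableECG:::bits_to_hex(b), n), b)
    }
  })
})
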