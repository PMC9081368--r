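test_that("descriptor dimensions follow the closed forms", {
  withr::local_seed(42)
  s <- rand_seq(80)
  expect_length(encode_188d(s), 188)
  expect_length(encode_apaac(s, lambda = 1), 22)
  expect_length(encode_paac(s, lambda = 3), 23)
  expect_length(encode_ksctriad(s, kmax = 0), 343)
  expect_length(encode_ksctriad(s, kmax = 2), 1029)
  expect_length(encode_cksaagp(s, kmax = 4), 125)
  expect_length(encode_cksaap(s, kmax = 0), 400)

  for (rep in 1:20) {
    cfg <- encoder_config(
      lambda_apaac = sample(1:8, 1), lambda_paac = sample(1:8, 1),
      kmax_ksctriad = sample(0:3, 1), kmax_cksaagp = sample(0:5, 1)
    )
    v <- encode_mixed(rand_seq(sample(30:90, 1)), cfg)
    expect_length(v, config_dimension(cfg))
    expect_true(all(is.finite(v)))
    expect_equal(length(unique(names(v))), length(v))  # labels unique
  }
})

test_that("each CTD property contributes 21 features with the C/T/D layout", {
  v <- encode_188d("ACDEFGHIKLMNPQRSTVWYAC")
  for (prop in c("hydrophobicity", "charge", "solventaccess")) {
    block <- v[grepl(paste0("^d188\\.", prop, "\\."), names(v))]
    expect_length(block, 21)
    expect_length(grep("\\.comp\\.", names(block)), 3)
    expect_length(grep("\\.tran\\.", names(block)), 3)
    expect_length(grep("\\.dist\\.", names(block)), 15)
  }
})

test_that("homopolymer composition is a point mass and AAC sums to 1", {
  v <- encode_188d("AAAA")
  expect_equal(unname(v["d188.AAC.A"]), 1)
  expect_equal(sum(v[1:20]), 1, tolerance = 1e-12)
  expect_equal(unname(v[setdiff(paste0("d188.AAC.", AA_ABC), "d188.AAC.A")]),
               rep(0, 19))
})

test_that("a single adjacent class crossing gives transition 1/(L-1)", {
  # A (neutral) and C (hydrophobic) are in hydrophobicity classes 2 and 3
  v <- encode_188d("AC")
  expect_equal(unname(v["d188.hydrophobicity.tran.23"]), 1)
  expect_equal(unname(v["d188.hydrophobicity.tran.12"]), 0)
  expect_equal(unname(v["d188.hydrophobicity.tran.13"]), 0)
})

test_that("distribution block reports occurrence positions as percent of length", {
  # K is hydrophobicity class 1 (polar); in "KAAAAAAAAK" its occurrences
  # sit at positions 1 and 10 of L = 10
  v <- encode_188d("KAAAAAAAAK")
  d <- unname(v[paste0("d188.hydrophobicity.dist.1.",
                       c("first", "p25", "p50", "p75", "p100"))])
  expect_equal(d, c(10, 10, 10, 100, 100))
  # absent class (class 3, hydrophobic) is all zeros
  expect_equal(unname(v[grepl("dist\\.3\\.", names(v)) &
                        grepl("hydrophobicity", names(v))]), rep(0, 5))
})

test_that("APAAC correlation factors reduce to squared scale values on homopolymers", {
  tbl <- aa_property_tables()
  v <- encode_apaac("AAAAAA", lambda = 2, w = 0.05)
  denom <- 1 + 0.05 * 2 * (tbl$scales$h1[["A"]]^2 + tbl$scales$h2[["A"]]^2)
  expect_equal(unname(v["apaac.tau.1"]), 0.05 * tbl$scales$h1[["A"]]^2 / denom,
               tolerance = 1e-12)
  expect_equal(unname(v["apaac.tau.2"]), 0.05 * tbl$scales$h2[["A"]]^2 / denom,
               tolerance = 1e-12)
  expect_equal(unname(v["apaac.tau.1"]), unname(v["apaac.tau.3"]), tolerance = 1e-12)
  expect_equal(unname(v["apaac.tau.2"]), unname(v["apaac.tau.4"]), tolerance = 1e-12)
})

test_that("PAAC on a homopolymer equals plain AAC with zero correlation tail", {
  v <- encode_paac("GGGGGGGG", lambda = 3, w = 0.05)
  expect_equal(unname(v["paac.f.G"]), 1)
  expect_equal(unname(v[paste0("paac.theta.", 1:3)]), rep(0, 3))
})

test_that("pseudo-composition vectors sum to 1 and pair blocks are distributions", {
  withr::local_seed(7)
  for (rep in 1:100) {
    s <- rand_seq(sample(12:60, 1))
    expect_equal(sum(encode_188d(s)[1:20]), 1, tolerance = 1e-9)
    expect_equal(sum(encode_apaac(s, lambda = 4)), 1, tolerance = 1e-9)
    expect_equal(sum(encode_paac(s, lambda = 4)), 1, tolerance = 1e-9)
    kmax <- sample(0:3, 1)
    for (enc in list(encode_cksaagp(s, kmax), encode_cksaap(s, kmax))) {
      per_k <- split(enc, sub("^[a-z]+\\.(k[0-9]+)\\..*$", "\\1", names(enc)))
      for (block in per_k) {
        expect_equal(sum(block), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("single-pair and single-window examples count correctly", {
  # G aliphatic, F aromatic
  v <- encode_cksaagp("GF", kmax = 0)
  expect_equal(unname(v["cksaagp.k0.aliphatic|aromatic"]), 1)
  expect_equal(sum(v), 1)

  v2 <- encode_cksaap("ACA", kmax = 0)
  expect_equal(unname(v2["cksaap.k0.AC"]), 0.5)
  expect_equal(unname(v2["cksaap.k0.CA"]), 0.5)

  # A is triad class 1; the only raw triple in "AAA" is (1,1,1)
  v3 <- encode_ksctriad("AAA", kmax = 0, norm = "window")
  expect_equal(unname(v3["ksctriad.k0.111"]), 1)
  expect_equal(sum(v3 != 0), 1)
})

test_that("every encoder matches its brute-force oracle within 1e-9", {
  withr::local_seed(101)
  for (rep in 1:20) {
    L <- sample(15:30, 1)
    s <- rand_seq(L)
    lam <- sample(1:5, 1)
    kt <- sample(0:2, 1)
    kg <- sample(0:3, 1)
    expect_equal(unname(encode_188d(s)), oracle_188d(s), tolerance = 1e-9)
    expect_equal(unname(encode_apaac(s, lam, 0.05)), oracle_apaac(s, lam, 0.05),
                 tolerance = 1e-9)
    expect_equal(unname(encode_paac(s, lam, 0.05)), oracle_paac(s, lam, 0.05),
                 tolerance = 1e-9)
    expect_equal(unname(encode_ksctriad(s, kt)), oracle_ksctriad(s, kt),
                 tolerance = 1e-9)
    expect_equal(unname(encode_ksctriad(s, kt, norm = "window")),
                 oracle_ksctriad(s, kt, norm = "window"), tolerance = 1e-9)
    expect_equal(unname(encode_cksaagp(s, kg)), oracle_cksaagp(s, kg),
                 tolerance = 1e-9)
    expect_equal(unname(encode_cksaap(s, kg)), oracle_cksaap(s, kg),
                 tolerance = 1e-9)
  }
})

test_that("composition blocks are permutation invariant; order-sensitive blocks are not", {
  withr::local_seed(13)
  s <- rand_seq(50)
  sh <- paste(sample(chars_of(s)), collapse = "")
  v1 <- encode_188d(s)
  v2 <- encode_188d(sh)
  expect_equal(v1[1:20], v2[1:20], tolerance = 1e-12)
  comp <- grepl("\\.comp\\.", names(v1))
  expect_equal(v1[comp], v2[comp], tolerance = 1e-12)

  p1 <- encode_paac(s, lambda = 3)
  p2 <- encode_paac(sh, lambda = 3)
  expect_false(isTRUE(all.equal(unname(p1), unname(p2), tolerance = 1e-9)))
})

test_that("self-concatenation leaves the composition block unchanged", {
  withr::local_seed(29)
  s <- rand_seq(40)
  v1 <- encode_188d(s)[1:20]
  v2 <- encode_188d(paste0(s, s))[1:20]
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("length preconditions produce clear errors", {
  expect_error(encode_188d(""), "empty")
  expect_error(encode_apaac("ACD", lambda = 3), "too short")
  expect_error(encode_paac("ACD", lambda = 5), "too short")
  expect_error(encode_ksctriad("ACDE", kmax = 1), "too short")
  expect_error(encode_cksaagp("AC", kmax = 1), "too short")
  expect_error(encode_mixed("ACDEF", encoder_config(lambda_apaac = 10)),
               "apaac")
  expect_error(encode_188d("ACXDE"), "non-standard")
})

test_that("mixed encoding concatenates independent blocks in fixed order", {
  withr::local_seed(3)
  s <- rand_seq(40)
  cfg_all <- encoder_config(lambda_apaac = 1, lambda_paac = 1,
                            kmax_ksctriad = 0, kmax_cksaagp = 0)
  v <- encode_mixed(s, cfg_all)
  expect_length(v, 188 + 22 + 343 + 25 + 21)
  expect_equal(unique(sub("\\..*$", "", names(v))),
               c("d188", "apaac", "ksctriad", "cksaagp", "paac"))

  # single-block identity
  cfg_one <- encoder_config(blocks = "d188")
  expect_identical(encode_mixed(s, cfg_one), encode_188d(s))

  # dropping a block leaves the others' values untouched
  cfg_sub <- encoder_config(lambda_apaac = 1, lambda_paac = 1,
                            kmax_ksctriad = 0, kmax_cksaagp = 0,
                            blocks = c("d188", "cksaagp", "paac"))
  vs <- encode_mixed(s, cfg_sub)
  expect_identical(vs, v[names(vs)])
})

test_that("encode_dataset builds aligned rows and refuses bad input", {
  withr::local_seed(5)
  cfg <- encoder_config(lambda_apaac = 1, lambda_paac = 1,
                        kmax_ksctriad = 0, kmax_cksaagp = 0)
  ds <- tibble::tibble(
    id = paste0("s", 1:5),
    residues = vapply(rep(30, 5), rand_seq, character(1)),
    label = c(1L, 1L, 1L, 0L, 0L)
  )
  enc <- encode_dataset(ds, cfg)
  expect_equal(dim(enc), c(5, 2 + 599))
  expect_equal(enc$label, ds$label)
  expect_equal(unlist(enc[3, -(1:2)]), encode_mixed(ds$residues[3], cfg),
               tolerance = 1e-15)

  expect_error(encode_dataset(ds[0, ], cfg), "empty")
  ds$residues[2] <- "AC"
  expect_error(encode_dataset(ds, cfg), "s2")
})
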