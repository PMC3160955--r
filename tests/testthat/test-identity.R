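test_that("textbook pairs give the classic condensed coefficients", {
  ic <- condensed_identity(ped_fullsibs())
  # parent-offspring: one allele transmitted with certainty, no other path
  expect_equal(ic_pair(ic, "a", "x"), c(0, 0, 0, 0, 0, 0, 0, 1, 0))
  # full sibs: (d7, d8, d9) = (1/4, 1/2, 1/4)
  expect_equal(ic_pair(ic, "x", "y"), c(0, 0, 0, 0, 0, 0, 1 / 4, 1 / 2, 1 / 4))
  # non-inbred self pair: d7 = 1
  expect_equal(ic_pair(ic, "x", "x"), c(0, 0, 0, 0, 0, 0, 1, 0, 0))
  # unrelated founders: d9 = 1
  expect_equal(ic_pair(ic, "a", "b"), c(0, 0, 0, 0, 0, 0, 0, 0, 1))

  # half sibs and first cousins against the enumeration oracle
  hs <- ped_halfsibs()
  expect_equal(ic_pair(condensed_identity(hs), "x", "y"),
    enumerate_ibd_oracle(hs, "x", "y")$delta,
    tolerance = 1e-14
  )
  cz <- ped_cousins()
  expect_equal(ic_pair(condensed_identity(cz), "c1", "c2"),
    enumerate_ibd_oracle(cz, "c1", "c2")$delta,
    tolerance = 1e-14
  )

  # inbred self pair: d1 = f, d7 = 1 - f
  icz <- condensed_identity(ped_sibmating())
  expect_equal(ic_pair(icz, "z", "z"), c(1 / 4, 0, 0, 0, 0, 0, 3 / 4, 0, 0))
})

test_that("condensed identity equals the exact oracle on random pedigrees", {
  worst <- 0
  for (seed in 1:8) {
    ped <- rand_ped(nf = sample(2:4, 1), m = sample(3:6, 1), seed = seed)
    ic <- condensed_identity(ped)
    for (r in seq_len(nrow(ic))) {
      o <- enumerate_ibd_oracle(ped, ic$id1[r], ic$id2[r])
      worst <- max(worst, max(abs(unlist(ic[r, paste0("d", 1:9)]) - o$delta)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("identity coefficients satisfy their structural invariants", {
  for (seed in 11:14) {
    ped <- rand_ped(3, 6, seed)
    ic <- condensed_identity(ped)
    d <- delta_cols(ic)
    expect_true(all(d >= -1e-13))
    expect_equal(rowSums(d), rep(1, nrow(d)), tolerance = 1e-12)

    # marginal inbreeding consistency for every pair
    f <- attr(ic, "f")
    f1 <- f$f[match(ic$id1, f$id)]
    f2 <- f$f[match(ic$id2, f$id)]
    expect_equal(d[, 1] + d[, 2] + d[, 3] + d[, 4], f1, tolerance = 1e-12)
    expect_equal(d[, 1] + d[, 2] + d[, 5] + d[, 6], f2, tolerance = 1e-12)

    # kinship identity against the tabular kinship matrix
    phi_ic <- d[, 1] + (d[, 3] + d[, 5] + d[, 7]) / 2 + d[, 8] / 4
    phi <- kinship_matrix(ped)
    expect_equal(phi_ic, phi[cbind(ic$id1, ic$id2)], tolerance = 1e-12)
    expect_equal(f$f, inbreeding(ped)$f[match(f$id, inbreeding(ped)$id)],
      tolerance = 1e-12
    )
  }
})

test_that("evaluation strategies agree exactly", {
  sim <- small_ail(seed = 21, n_generations = 6, n_per_generation = 40)
  targets <- sample(last_gen_ids(sim$ped), 12)
  bu <- condensed_identity(sim$ped, targets, strategy = "bottom_up")
  td <- condensed_identity(sim$ped, targets, strategy = "top_down")
  hy <- condensed_identity(sim$ped, targets, strategy = "hybrid", split_generation = 2)
  expect_equal(delta_cols(bu), delta_cols(td), tolerance = 1e-12)
  expect_equal(delta_cols(bu), delta_cols(hy), tolerance = 1e-12)
})

test_that("target validation and hybrid split bounds are enforced", {
  ped <- ped_trio()
  expect_error(condensed_identity(ped, c("kid", "ghost")), "ghost")
  expect_error(
    condensed_identity(ped, strategy = "hybrid", split_generation = 99),
    "split_generation"
  )
})

test_that("genetic matrices obey the diagonal and outbred identities", {
  # outbred family: HH = AD = MH = 0, AA/DD diagonals 1
  gm <- genetic_matrices(ped_fullsibs())
  expect_equal(unname(gm$AA["x", "y"]), 1 / 2)
  expect_equal(unname(gm$DD["x", "y"]), 1 / 4)
  expect_equal(unname(diag(gm$AA)), rep(1, 4))
  expect_equal(unname(diag(gm$DD)), rep(1, 4))
  expect_true(all(gm$HH == 0) && all(gm$AD == 0) && all(gm$MH == 0))

  # unrelated non-inbred founders: AA = DD = I
  gmf <- genetic_matrices(ped_trio(), ids = c("pa", "ma"))
  expect_equal(unname(gmf$AA), diag(2))
  expect_equal(unname(gmf$DD), diag(2))

  # inbred pedigree: diagonal identities in terms of f
  ped <- ped_sibmating()
  gm2 <- genetic_matrices(ped)
  f <- inbreeding(ped)
  expect_equal(unname(diag(gm2$AA)), 1 + f$f)
  expect_equal(unname(diag(gm2$DD)), 1 - f$f)
  expect_equal(unname(diag(gm2$HH)), f$f)
  expect_equal(unname(diag(gm2$AD)), 4 * f$f)
  expect_equal(unname(diag(gm2$MH)), f$f * (1 - f$f))
  for (nm in names(gm2)) expect_true(isSymmetric(gm2[[nm]]))

  # AA is twice the kinship matrix everywhere
  phi <- kinship_matrix(ped)
  expect_equal(gm2$AA, 2 * phi, tolerance = 1e-12)
})

test_that("identity output round-trips to TSV", {
  ic <- condensed_identity(ped_fullsibs())
  path <- withr::local_tempfile(fileext = ".tsv")
  fpath <- withr::local_tempfile(fileext = ".tsv")
  write_identity(ic, path, fpath)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(ic))
  expect_equal(back$d8[back$id1 == "a" & back$id2 == "x"], 1)
  fback <- readr::read_tsv(fpath, show_col_types = FALSE)
  expect_equal(fback$f, rep(0, 4))
})
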