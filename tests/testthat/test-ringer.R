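test_that("the swung gamma position reproduces the requested chi1 geometry", {
  st <- toy_structure()
  mp <- toy_map()
  cv <- ringer_curve(mp, st, 2)   # SER 2
  at <- polymer_atoms_of(st)
  res <- at[at$resno == 2, ]
  n <- get_atom_coord(res, "N"); ca <- get_atom_coord(res, "CA")
  cb <- get_atom_coord(res, "CB"); og <- get_atom_coord(res, "OG")
  chi_now <- dihedral(n, ca, cb, og)
  u <- cb - ca; u <- u / sqrt(sum(u^2))
  for (th in c(0, 60, 150, 290)) {
    g <- rotate_about_axis(og, cb, u, th - chi_now)
    dd <- (dihedral(n, ca, cb, g) - th) %% 360
    expect_lt(min(dd, 360 - dd), 1e-3)
    # bond length and bond angle preserved
    expect_equal(sqrt(sum((g - cb)^2)), sqrt(sum((og - cb)^2)),
                 tolerance = 1e-9)
    ang <- function(p) acos(sum((ca - cb) * (p - cb)) /
                              (sqrt(sum((ca - cb)^2)) * sqrt(sum((p - cb)^2))))
    expect_equal(ang(g), ang(og), tolerance = 1e-9)
  }
})

test_that("the Ringer maximum sits at the modeled chi1", {
  st <- toy_structure()
  mp <- toy_map()
  for (resno in c(2, 5, 7)) {      # SER, CYS, THR
    at <- polymer_atoms_of(st)
    res <- at[at$resno == resno, ]
    gname <- intersect(c("OG", "SG", "OG1"), res$name)[1]
    chi_true <- dihedral(get_atom_coord(res, "N"), get_atom_coord(res, "CA"),
                         get_atom_coord(res, "CB"),
                         get_atom_coord(res, gname)) %% 360
    cv <- ringer_curve(mp, st, resno)
    peak <- cv$angle[which.max(cv$density)]
    d <- abs(peak - chi_true) %% 360
    expect_lte(min(d, 360 - d), 10)   # within one angular step
  }
})

test_that("a constant map yields a flat curve and an undefined CC", {
  st <- toy_structure()
  flat <- density_map(array(1, c(32, 32, 32)), st$cell)
  cv <- ringer_curve(flat, st, 2, scale = "raw")
  expect_equal(diff(range(cv$density)), 0)
  cc <- curve_cc(cv, cv)
  expect_true(is.na(cc))
  expect_true(attr(cc, "undefined"))
})

test_that("a two-conformer side chain produces two Ringer peaks", {
  st <- toy_structure()
  at <- st$atoms
  og_row <- which(at$kind == "polymer" & at$resno == 2 & at$name == "OG")
  res <- at[at$kind == "polymer" & at$resno == 2, ]
  n <- get_atom_coord(res, "N"); ca <- get_atom_coord(res, "CA")
  cb <- get_atom_coord(res, "CB"); og <- get_atom_coord(res, "OG")
  chi_true <- dihedral(n, ca, cb, og)
  u <- cb - ca; u <- u / sqrt(sum(u^2))
  og2 <- rotate_about_axis(og, cb, u, 120)
  a1 <- at[og_row, ]; a1$altloc <- "A"; a1$occ <- 0.5
  a2 <- at[og_row, ]; a2$altloc <- "B"; a2$occ <- 0.5
  a2[, c("x", "y", "z")] <- og2
  dual <- crystal_structure(rbind(at[-og_row, ], a1, a2), st$cell,
                            st$spacegroup)
  mp <- simulate_map(dual, grid = 0.25)
  cv <- ringer_curve(mp, strip_to_single_conformer(dual), 2)
  pk <- find_peaks(cv, min_sigma = 0.3)
  expect_gte(nrow(pk), 2)
  expected <- sort(c(chi_true, chi_true + 120) %% 360)
  got <- sort(pk$angle[1:2])
  d <- abs(got - expected) %% 360
  expect_true(all(pmin(d, 360 - d) <= 10))
})

test_that("curve_cc matches the direct Pearson formula and its trivial values", {
  mk <- function(v) structure(list(angle = seq(0, 350, 10), density = v),
                              class = "ringer_curve")
  set.seed(5)
  a <- mk(rnorm(36)); b <- mk(rnorm(36))
  num <- sum((a$density - mean(a$density)) * (b$density - mean(b$density)))
  den <- sqrt(sum((a$density - mean(a$density))^2) *
                sum((b$density - mean(b$density))^2))
  expect_equal(curve_cc(a, b), num / den, tolerance = 1e-12)
  expect_equal(curve_cc(a, a), 1, tolerance = 1e-12)
  neg <- mk(-a$density)
  expect_equal(curve_cc(a, neg), -1, tolerance = 1e-12)
  coarse <- structure(list(angle = seq(0, 340, 20), density = rnorm(18)),
                      class = "ringer_curve")
  expect_error(curve_cc(a, coarse), "different angle grids")
})

test_that("CC is invariant under affine rescaling of one map", {
  st <- toy_structure()
  mp <- toy_map()
  scaled <- density_map(3 * mp$values + 7, st$cell)
  c1 <- ringer_curves(mp, st)
  c2 <- ringer_curves(scaled, st)
  for (k in names(c1))
    expect_equal(curve_cc(c1[[k]], c2[[k]]), 1, tolerance = 1e-9)
})

test_that("flagged-residue accounting and range exclusion are exact", {
  st <- toy_structure()
  mp <- toy_map()
  pr <- perturb(st, list(list(kind = "rotamer-flip", resno = 2,
                              target_chi1 = 180),
                         list(kind = "rotamer-flip", resno = 9,
                              target_chi1 = toy_flip_target(9))),
                seed = 6)$structure
  mp2 <- simulate_map(pr, grid = 0.25)
  ca <- ringer_curves(mp, st)
  cb <- ringer_curves(mp2, pr)
  cmp <- flag_changed_residues(ca, cb, threshold = 0.5)
  expect_setequal(cmp$flagged$resno, c(2, 9))
  expect_equal(cmp$count, 2L)
  expect_equal(cmp$percent,
               round(100 * cmp$count / cmp$n_evaluated, 1))
  # excluding residue 9's range removes it from both count and denominator
  cmp_ex <- flag_changed_residues(ca, cb, threshold = 0.5, exclude = "8-10")
  expect_equal(cmp_ex$flagged$resno, 2)
  expect_equal(cmp_ex$n_evaluated, cmp$n_evaluated - sum(
    cmp$table$resno %in% 8:10))
})

test_that("find_peaks agrees with a brute-force circular scan", {
  st <- toy_structure()
  cv <- ringer_curve(toy_map(), st, 11)   # ILE
  pk <- find_peaks(cv, min_sigma = 0.2)
  v <- cv$density; n <- length(v)
  brute <- which(vapply(seq_len(n), function(i) {
    p <- if (i == 1) n else i - 1
    q <- if (i == n) 1 else i + 1
    v[i] > v[p] && v[i] >= v[q] && v[i] >= 0.2
  }, logical(1)))
  expect_setequal(pk$angle, cv$angle[brute])
  expect_true(all(diff(pk$height) <= 1e-12))
})

test_that("GLY/ALA and step validation behave as documented", {
  st <- toy_structure()
  at <- st$atoms
  at$resid[at$kind == "polymer" & at$resno == 3] <- "ALA"
  ala <- crystal_structure(at, st$cell, st$spacegroup)
  expect_message(out <- ringer_curve(toy_map(), ala, 3), "no chi1")
  expect_null(out)
  expect_error(ringer_curve(toy_map(), st, 2, step = 7), "divide 360")
})
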