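test_that("dihedral matches hand-constructed reference angles", {
  # +60 degree torsion built by explicit rotation about the central bond
  p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 0, 1)
  th <- 60 * pi / 180
  p4 <- p3 + c(cos(th), sin(th), 0)
  expect_equal(dihedral(p1, p2, p3, p4), 60, tolerance = 1e-9)
  p4m <- p3 + c(cos(th), -sin(th), 0)
  expect_equal(dihedral(p1, p2, p3, p4m), -60, tolerance = 1e-9)
  # cis and trans
  expect_equal(dihedral(p1, p2, p3, p3 + c(1, 0, 0)), 0, tolerance = 1e-9)
  expect_equal(dihedral(p1, p2, p3, p3 + c(-1, 0, 0)), 180, tolerance = 1e-9)
})

test_that("dihedral agrees with the independent projection oracle", {
  set.seed(17)
  for (i in 1:25) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    got <- try(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]), silent = TRUE)
    if (inherits(got, "try-error")) next
    want <- dihedral_oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    d <- abs(got - want) %% 360
    expect_lt(min(d, 360 - d), 1e-9)
  }
})

test_that("dihedral obeys reversal and sign symmetries", {
  set.seed(23)
  pts <- matrix(rnorm(12), 4, 3)
  a <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  # reversing atom order preserves the angle
  expect_equal(dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ]), a,
               tolerance = 1e-9)
  # mirror reflection negates it
  m <- pts; m[, 3] <- -m[, 3]
  expect_equal(dihedral(m[1, ], m[2, ], m[3, ], m[4, ]), -a, tolerance = 1e-9)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("place_atom and dihedral are mutually consistent", {
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(3); b <- a + rnorm(3); c <- b + rnorm(3)
    tor <- runif(1, -179, 179)
    d <- place_atom(a, b, c, 1.5, 111, tor)
    expect_equal(dihedral(a, b, c, d), tor, tolerance = 1e-6)
    expect_equal(sqrt(sum((d - c)^2)), 1.5, tolerance = 1e-9)
  }
})

test_that("chi1 classes cover their documented intervals", {
  expect_equal(chi1_class(62), "p")
  expect_equal(chi1_class(180), "t")
  expect_equal(chi1_class(-65), "m")
  expect_equal(chi1_class(0), "p")
  expect_equal(chi1_class(119.9), "p")
  expect_equal(chi1_class(120), "t")
  expect_equal(chi1_class(239.9), "t")
  expect_equal(chi1_class(240), "m")
  expect_equal(chi1_class(-0.1), "m")
})

test_that("rotamer naming is exact at modes and invariant to +/-360", {
  expect_equal(as.character(name_rotamer("SER", 64)), "p")
  expect_equal(as.character(name_rotamer("SER", 64 - 360)), "p")
  expect_equal(as.character(name_rotamer("SER", 178 + 360)), "t")
  expect_equal(as.character(name_rotamer("LEU", c(-65, 175))), "mt")
  expect_equal(as.character(name_rotamer("MET", c(180, 180, -75))), "ttm")
  # symmetric terminal torsion: chi2 and chi2 + 180 are the same rotamer
  expect_equal(as.character(name_rotamer("ASP", c(62, -10))),
               as.character(name_rotamer("ASP", c(62, 170))))
  expect_equal(as.character(name_rotamer("PHE", c(177, 80))),
               as.character(name_rotamer("PHE", c(177, -100))))
  expect_equal(as.character(name_rotamer("SER", 130)), "OUTLIER")
  expect_error(name_rotamer("SER", c(64, 80)), "expects 1")
  expect_error(name_rotamer("XYZ", 64), "no rotamer table")
})

test_that("naming matches an exhaustive nearest-mode oracle", {
  nearest_oracle <- function(restype, chis, cut = 40) {
    modes <- perturbxtal:::.rotamer_modes[[restype]]
    symm <- isTRUE(perturbxtal:::.chi_symm_last[restype])
    wrap <- function(a, b) {
      d <- abs((a - b) %% 360); pmin(d, 360 - d)
    }
    devs <- vapply(modes, function(m) {
      d <- wrap(chis, m)
      if (symm) {
        k <- length(chis)
        d[k] <- min(wrap(chis[k], m[k]), wrap(chis[k], m[k] + 180))
      }
      max(d)
    }, numeric(1))
    if (min(devs) > cut) "OUTLIER" else names(modes)[which.min(devs)]
  }
  set.seed(41)
  for (restype in c("SER", "LEU", "ILE", "ASP", "PHE", "MET", "LYS")) {
    k <- n_chi(restype)
    for (i in 1:40) {
      chis <- runif(k, -180, 180)
      expect_equal(as.character(name_rotamer(restype, chis)),
                   nearest_oracle(restype, chis),
                   info = paste(restype, paste(round(chis), collapse = ",")))
    }
  }
})

test_that("small perturbations of a mode are never called OUTLIER", {
  set.seed(43)
  for (restype in names(perturbxtal:::.rotamer_modes)) {
    modes <- perturbxtal:::.rotamer_modes[[restype]]
    for (nm in names(modes)) {
      chis <- modes[[nm]] + runif(length(modes[[nm]]), -5, 5)
      got <- as.character(name_rotamer(restype, chis))
      expect_false(got == "OUTLIER", info = paste(restype, nm))
    }
  }
})

test_that("toy-structure assignments recover the generator's chi choices", {
  st <- toy_structure()
  ra <- rotamer_assignments(st)
  expect_equal(nrow(ra), 14)   # every residue has a side chain
  for (i in seq_len(nrow(ra))) {
    want <- st$assigned_chis[[ra$resno[i]]]
    got <- c(ra$chi1[i], ra$chi2[i], ra$chi3[i], ra$chi4[i])[seq_along(want)]
    d <- abs(got - want) %% 360
    expect_lt(max(pmin(d, 360 - d)), 1e-6)
    expect_false(ra$rotamer[i] == "OUTLIER")
  }
})

test_that("rotamer_diff finds planted flips and honors exclusion", {
  st <- toy_structure()
  pr <- perturb(st, list(list(kind = "rotamer-flip", resno = 2,
                              target_chi1 = 180),
                         list(kind = "rotamer-flip", resno = 9,
                              target_chi1 = toy_flip_target(9))),
                seed = 2)$structure
  rd <- rotamer_diff(pr, st)
  expect_setequal(rd$changed$resno, c(2, 9))
  expect_equal(rd$count, 2L)
  expect_equal(rd$n_evaluated, 14L)
  expect_equal(rd$percent, round(100 * 2 / 14, 1))
  # symmetric in its arguments
  rd2 <- rotamer_diff(st, pr)
  expect_setequal(rd2$changed$resno, rd$changed$resno)
  # exclusion removes residue 9 from numerator and denominator
  rd3 <- rotamer_diff(pr, st, exclude = "9-9")
  expect_equal(rd3$changed$resno, 2)
  expect_equal(rd3$n_evaluated, 13L)
  # no perturbation, no changes
  expect_equal(rotamer_diff(st, st)$count, 0L)
})

test_that("any-match vs primary policies differ for split conformers", {
  st <- toy_structure()
  at <- st$atoms
  og <- which(at$kind == "polymer" & at$resno == 2 & at$name == "OG")
  res <- at[at$kind == "polymer" & at$resno == 2, ]
  cb <- get_atom_coord(res, "CB"); ca <- get_atom_coord(res, "CA")
  u <- cb - ca; u <- u / sqrt(sum(u^2))
  # altloc A keeps the original (m); altloc B rotated to t
  a1 <- at[og, ]; a1$altloc <- "A"; a1$occ <- 0.4
  a2 <- at[og, ]; a2$altloc <- "B"; a2$occ <- 0.6
  a2[, c("x", "y", "z")] <- rotate_about_axis(
    get_atom_coord(res, "OG"), cb, u, -115)   # -65 -> -180 == t
  dual <- crystal_structure(rbind(at[-og, ], a1, a2), st$cell, st$spacegroup)
  any_match <- rotamer_diff(dual, st, policy = "any-match")
  expect_false(2 %in% any_match$changed$resno)   # conformer A still matches
  primary <- rotamer_diff(dual, st, policy = "primary")
  expect_true(2 %in% primary$changed$resno)      # highest-occ conformer is t
  expect_equal(unname(any_match$multi_rotamer[1]), 1)
})

test_that("residue range parsing accepts strings, pairs and singletons", {
  expect_equal(parse_residue_ranges("375-383"), list(c(375L, 383L)))
  expect_equal(parse_residue_ranges(list(c(5, 9))), list(c(5, 9)))
  expect_equal(parse_residue_ranges("7"), list(c(7L, 7L)))
  expect_equal(in_ranges(c(4, 7, 10), parse_residue_ranges("5-9")),
               c(FALSE, TRUE, FALSE))
  expect_equal(in_ranges(1:3, parse_residue_ranges(NULL)), rep(FALSE, 3))
})
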