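test_that("planar quadruples give exact cis/trans/perpendicular values", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_identical(torsion_angle(p1, p2, p3, c(1, -1, 0)), 180)
  expect_identical(torsion_angle(p1, p2, p3, c(1, 1, 0)), 0)
  expect_equal(torsion_angle(p1, p2, p3, c(1, 0, 1)), 90)
  expect_equal(torsion_angle(p1, p2, p3, c(1, 0, -1)), -90)
})

test_that("the sign convention matches an independent torsion routine", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  for (k in 1:20) {
    pts <- matrix(rnorm(12, sd = 2), 4L, byrow = TRUE)
    mine <- tryCatch(torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                     error = function(e) NA_real_)
    skip_if(is.na(mine))
    ref <- bio3d::torsion.xyz(as.vector(t(pts)), atm.inc = 4)
    expect_equal(circ_dist(mine, ref), 0, tolerance = 1e-6)
  }
})

test_that("torsions are invariant under rigid motion of all four points", {
  set.seed(11)
  for (k in 1:25) {
    pts <- matrix(rnorm(12, sd = 3), 4L, byrow = TRUE)
    base <- tryCatch(torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                     error = function(e) NA_real_)
    if (is.na(base)) next
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    moved <- pts %*% t(R) + matrix(t, 4L, 3L, byrow = TRUE)
    expect_equal(circ_dist(base, torsion_angle(moved[1, ], moved[2, ],
                                               moved[3, ], moved[4, ])),
                 0, tolerance = 1e-9)
  }
})

# Under the IUPAC sign convention (fixed by the worked cis/trans/+90
# examples above) a dihedral is invariant under reversing the quadruple
# and changes sign under mirror reflection of the coordinates.
test_that("torsion symmetry: reversal-invariant, sign-flipped by mirrors", {
  set.seed(13)
  for (k in 1:25) {
    pts <- matrix(rnorm(12, sd = 3), 4L, byrow = TRUE)
    fwd <- tryCatch(torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                    error = function(e) NA_real_)
    if (is.na(fwd) || abs(abs(fwd) - 180) < 1e-6) next
    rev <- torsion_angle(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    expect_equal(rev, fwd, tolerance = 1e-9)
    mir <- pts %*% diag(c(1, 1, -1))
    expect_equal(torsion_angle(mir[1, ], mir[2, ], mir[3, ], mir[4, ]),
                 -fwd, tolerance = 1e-9)
  }
})

test_that("degenerate quadruples are rejected", {
  p <- c(0, 0, 0)
  expect_error(torsion_angle(p, p, c(1, 0, 0), c(2, 0, 0)), "degenerate")
  expect_error(torsion_angle(c(-1, 0, 0), p, c(1, 0, 0), c(2, 1, 0)),
               "collinear")
})

test_that("built chains round-trip their backbone targets", {
  phi <- c(NA, -139, -57, -75, 60)[c(2:5, 2)]  # arbitrary defined targets
  psi <- c(135, -47, 140, 40, -60)
  s <- build_chain("AGFSY", phi = phi, psi = psi, omega = 180)
  m <- strucstats:::torsion_matrix(s)
  expect_equal(m[2:5, "phi"], phi[2:5], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(m[1:4, "psi"], psi[1:4], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(m[1:4, "omega"], rep(180, 4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("chain termini have undefined phi / psi / omega", {
  s <- build_chain("AGFSY")
  m <- strucstats:::torsion_matrix(s)
  expect_true(is.na(m[1L, "phi"]))
  expect_true(is.na(m[5L, "psi"]))
  expect_true(is.na(m[5L, "omega"]))
  expect_false(anyNA(m[2:5, "phi"]))
})

test_that("an engineered chain break propagates undefined angles", {
  s <- build_chain("AGFSY", break_after = 2L)  # C(2)-N(3) at 4 A
  m <- strucstats:::torsion_matrix(s)
  expect_true(is.na(m[3L, "phi"]))   # N-terminal side of the break
  expect_true(is.na(m[2L, "psi"]))   # C-terminal side
  expect_true(is.na(m[2L, "omega"]))
  expect_false(is.na(m[2L, "phi"]))
  expect_false(is.na(m[3L, "psi"]))
})

test_that("phi-undefined count equals chain starts plus breaks", {
  s <- build_chain("AGFSYAGFSY", break_after = c(3L, 7L))
  m <- strucstats:::torsion_matrix(s)
  expect_equal(sum(is.na(m[, "phi"])), 1L + 2L)
})

test_that("chi angles follow the residue-type table", {
  s <- build_chain("GAKRM",
                   chi = list(NULL, NULL, c(-60, 180, 180, 60),
                              c(-170, 75, -160, 100), c(-65, 175, 70)))
  m <- strucstats:::torsion_matrix(s)
  expect_true(all(is.na(m[1L, c("chi1", "chi2", "chi3", "chi4")])))  # Gly
  expect_true(all(is.na(m[2L, c("chi1", "chi2", "chi3", "chi4")])))  # Ala
  expect_equal(m[3L, 4:7], c(-60, 180, 180, 60), tolerance = 1e-6,
               ignore_attr = TRUE)  # Lys
  expect_equal(m[4L, 4:7], c(-170, 75, -160, 100), tolerance = 1e-6,
               ignore_attr = TRUE)  # Arg
  expect_equal(m[5L, 4:6], c(-65, 175, 70), tolerance = 1e-6,
               ignore_attr = TRUE)  # Met: chi1-chi3 only
  expect_true(is.na(m[5L, "chi4"]))
})

test_that("chi values agree with an independent torsion implementation", {
  skip_if_not_installed("bio3d")
  s <- build_chain("KLS", chi = list(c(-60, 170, -175, 65),
                                     c(-70, 165), 60))
  path <- tempfile(fileext = ".pdb")
  write_pdb(s, path)
  tor <- suppressWarnings(bio3d::torsion.pdb(bio3d::read.pdb(path)))
  m <- strucstats:::torsion_matrix(read_pdb(path))  # same rounded coords
  expect_equal(unname(circ_dist(m[1L, "chi1"], tor$tbl[1L, "chi1"])), 0,
               tolerance = 1e-4)
  expect_equal(unname(circ_dist(m[2L, "phi"], tor$tbl[2L, "phi"])), 0,
               tolerance = 1e-4)
  expect_equal(unname(circ_dist(m[2L, "psi"], tor$tbl[2L, "psi"])), 0,
               tolerance = 1e-4)
})

test_that("missing atoms make the affected angles undefined", {
  s <- build_chain("AKA", chi = list(NULL, c(-60, 180, 180, 60), NULL))
  s$atoms <- s$atoms[!(s$atoms$ridx == 2L & s$atoms$name == "CD"), ]
  m <- strucstats:::torsion_matrix(s)
  expect_false(is.na(m[2L, "chi1"]))
  expect_true(all(is.na(m[2L, c("chi2", "chi3", "chi4")])))
})

test_that("the long-format tables cover every residue and angle", {
  s <- build_chain("AGF", label = "t")
  bb <- backbone_torsions(s)
  sc <- sidechain_torsions(s)
  expect_equal(nrow(bb), 3L * 3L)
  expect_equal(nrow(sc), 3L * 4L)
  all7 <- ensemble_torsions(list(s))
  expect_equal(nrow(all7), 3L * 7L)
  expect_setequal(unique(all7$angle),
                  c("phi", "psi", "omega", "chi1", "chi2", "chi3", "chi4"))
  defined <- all7$value[!is.na(all7$value)]
  expect_true(all(defined > -180 & defined <= 180))
})
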