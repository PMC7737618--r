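# Shrake-Rupley surfaces, buried interface areas, contact networks.

test_that("an isolated sphere has its full analytic extended surface", {
  one <- make_atoms(list(list(chain = "A", resno = 1, resname = "GLY",
                              atom = "O", element = "O", xyz = c(3, -2, 7))))
  s <- sasa(one)
  want <- 4 * pi * (1.52 + 1.4)^2
  expect_equal(s$total, want, tolerance = 0.01 * want)
  # zero-probe variant uses the bare vdW sphere
  expect_equal(sasa(one, probe = 0)$total, 4 * pi * 1.52^2,
               tolerance = 0.01 * 4 * pi * 1.52^2)
})

test_that("two overlapping spheres match a Monte-Carlo oracle within 2%", {
  centers <- matrix(c(0, 0, 0, 2.5, 0, 0), ncol = 3, byrow = TRUE)
  two <- make_atoms(list(
    list(chain = "A", resno = 1, resname = "GLY", atom = "C", element = "C",
         xyz = centers[1, ]),
    list(chain = "A", resno = 2, resname = "GLY", atom = "N", element = "N",
         xyz = centers[2, ])))
  s <- sasa(two)
  want <- mc_sasa(centers, c(1.70, 1.55) + 1.4)
  expect_equal(s$total, want, tolerance = 0.02 * want)
  # per-residue areas sum to the total
  expect_equal(sum(s$residue_area), s$total, tolerance = 1e-10)
})

test_that("a fully engulfed atom contributes no area", {
  pair <- make_atoms(list(
    list(chain = "A", resno = 1, resname = "GLY", atom = "H", element = "H",
         xyz = c(0, 0, 0)),
    list(chain = "A", resno = 2, resname = "CU", atom = "X", element = "S",
         xyz = c(0, 0, 0.1))))
  # H sphere (1.2 + 1.4 = 2.6) sits inside the S sphere (1.8 + 1.4 = 3.2)
  s <- sasa(pair)
  expect_equal(s$atom_area[1], 0)
  expect_gt(s$atom_area[2], 0)
})

test_that("unknown elements are rejected unless a radius is supplied", {
  odd <- make_atoms(list(list(chain = "A", resno = 1, resname = "UNK",
                              atom = "FE", element = "FE", xyz = c(0, 0, 0))))
  expect_error(sasa(odd), "FE", class = "elevator_unknown_element")
  s <- sasa(odd, radii = c(FE = 2))
  expect_equal(s$total, 4 * pi * 3.4^2, tolerance = 0.5)
})

test_that("buried area follows the half-sum interface convention", {
  # two identical spheres far apart bury nothing; touching spheres bury
  # an amount equal on both conventions up to the factor of two
  far <- make_atoms(list(
    list(chain = "A", resno = 1, resname = "GLY", atom = "C", element = "C",
         xyz = c(0, 0, 0)),
    list(chain = "B", resno = 1, resname = "GLY", atom = "C", element = "C",
         xyz = c(50, 0, 0))))
  expect_equal(buried_area(far, "A", "B"), 0, tolerance = 1e-9)

  near <- make_atoms(list(
    list(chain = "A", resno = 1, resname = "GLY", atom = "C", element = "C",
         xyz = c(0, 0, 0)),
    list(chain = "B", resno = 1, resname = "GLY", atom = "C", element = "C",
         xyz = c(3, 0, 0))))
  bsa_i <- buried_area(near, "A", "B")
  bsa_t <- buried_area(near, "A", "B", convention = "total")
  expect_gt(bsa_i, 0)
  expect_equal(bsa_t, 2 * bsa_i, tolerance = 1e-10)
  # analytic: each extended sphere (R = 3.1) loses a cap of height
  # h = R - d/2; buried total = 2 * 2*pi*R*h
  R <- 1.7 + 1.4; h <- R - 1.5
  expect_equal(bsa_t, 2 * 2 * pi * R * h, tolerance = 0.02 * bsa_t)

  expect_error(buried_area(near, "A", "A"), class = "elevator_validation")
  expect_error(buried_area(near, "A", "Z"), class = "elevator_empty_selection")
})

test_that("buried area between residue groups works on data-frame selectors", {
  m <- make_atoms(list(
    list(chain = "A", resno = 1, resname = "LEU", atom = "C", element = "C",
         xyz = c(0, 0, 0)),
    list(chain = "A", resno = 2, resname = "LEU", atom = "C", element = "C",
         xyz = c(3, 0, 0)),
    list(chain = "A", resno = 3, resname = "LEU", atom = "C", element = "C",
         xyz = c(60, 0, 0))))
  g1 <- data.frame(chain = "A", resno = 1)
  bsa <- buried_area(m, g1, data.frame(chain = "A", resno = 2:3))
  expect_gt(bsa, 0)
  # the distant residue 3 adds nothing to the interface
  expect_equal(bsa, buried_area(m, g1, data.frame(chain = "A", resno = 2)),
               tolerance = 1e-9)
})

test_that("contact networks apply distance and conservation filters", {
  # core residue 1 contacts dimer residue 11 (3.5 A) but not 12 (20 A);
  # residue 13 is close but poorly conserved; residue 14 close but absent
  # from the conservation table (grade 0)
  m <- make_atoms(list(
    list(chain = "A", resno = 1, resname = "LEU", atom = "CA", element = "C",
         xyz = c(0, 0, 5)),
    list(chain = "A", resno = 11, resname = "PHE", atom = "CA", element = "C",
         xyz = c(3.5, 0, 5)),
    list(chain = "A", resno = 12, resname = "SER", atom = "CA", element = "C",
         xyz = c(20, 0, 0)),
    list(chain = "A", resno = 13, resname = "VAL", atom = "CA", element = "C",
         xyz = c(0, 3.5, 5)),
    list(chain = "A", resno = 14, resname = "ILE", atom = "CA", element = "C",
         xyz = c(-3.5, 0, 5)),
    # hydrogens never count as contact atoms
    list(chain = "A", resno = 12, resname = "SER", atom = "H", element = "H",
         xyz = c(1, 0, 5))))
  dom <- domain_definition(
    domains = list(core_domain = data.frame(chain = "A", resno = 1),
                   dimer_domain = data.frame(chain = "A", resno = 11:14)),
    binding_site = data.frame(chain = "A", resno = 1),
    membrane_normal = c(0, 0, 1))
  cons <- data.frame(chain = "A", resno = c(1, 11, 12, 13),
                     grade = c(9, 9, 9, 4))
  net <- interdomain_contacts(m, dom, cons)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$residue_a, "A 1")
  expect_equal(net$edges$residue_b, "A 11")
  expect_equal(net$edges$distance, 3.5, tolerance = 1e-10)
  expect_equal(net$site_normal_coord, 5)
  gates <- gate_residues(net)
  expect_setequal(gates$key, c("A 1", "A 11"))
  expect_true(all(gates$side == "extracellular"))
  expect_error(interdomain_contacts(m, dom, data.frame(chain = "A")),
               class = "elevator_schema")
})

test_that("gate residues split by side of the binding site", {
  m <- make_atoms(list(
    list(chain = "A", resno = 1, resname = "GLY", atom = "CA", element = "C",
         xyz = c(0, 0, 0)),                      # binding site at z = 0
    list(chain = "A", resno = 2, resname = "LEU", atom = "CA", element = "C",
         xyz = c(0, 0, 8)),                      # core, above
    list(chain = "A", resno = 11, resname = "PHE", atom = "CA", element = "C",
         xyz = c(3, 0, 8)),                      # dimer, above
    list(chain = "A", resno = 3, resname = "VAL", atom = "CA", element = "C",
         xyz = c(0, 0, -8)),                     # core, below
    list(chain = "A", resno = 12, resname = "ILE", atom = "CA", element = "C",
         xyz = c(3, 0, -8))))                    # dimer, below
  dom <- domain_definition(
    domains = list(core_domain = data.frame(chain = "A", resno = c(2, 3)),
                   dimer_domain = data.frame(chain = "A", resno = c(11, 12))),
    binding_site = data.frame(chain = "A", resno = 1),
    membrane_normal = c(0, 0, 1))
  cons <- data.frame(chain = "A", resno = c(1, 2, 3, 11, 12), grade = 9)
  gates <- gate_residues(interdomain_contacts(m, dom, cons))
  expect_equal(sort(unique(gates$side)),
               c("extracellular", "intracellular"))
  expect_equal(gates$side[gates$key == "A 2"], "extracellular")
  expect_equal(gates$side[gates$key == "A 3"], "intracellular")
})
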