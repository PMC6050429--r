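test_that("mass-action flux follows kf*prod(reactants) - kr*prod(products)", {
  # zero substrate -> zero flux
  r <- reaction("r1", c(S = 1), c(P = 1), kf = 3)
  expect_identical(mass_action_flux(r, c(S = 0, P = 5)), 0)

  # symmetric reversible equilibrium: k1[Akt][PIP3] = kr1[Aktm]
  r <- reaction("akt", c(Akt = 1, PIP3 = 1), c(Aktm = 1), kf = 1, kr = 1)
  expect_equal(mass_action_flux(r, c(Akt = 1, PIP3 = 1, Aktm = 1)), 0)

  # bimolecular hand evaluation: v = k2 [S][R] = 0.5 * 2 * 3
  r <- reaction("bi", c(S = 1, R = 1), c(P = 1), kf = 0.5)
  expect_equal(mass_action_flux(r, c(S = 2, R = 3, P = 0)), 3.0)

  # stoichiometry 2 raises concentration to the power
  r <- reaction("dim", c(A = 2), c(B = 1), kf = 1)
  expect_equal(mass_action_flux(r, c(A = 3, B = 0)), 9)

  expect_error(mass_action_flux(r, c(B = 1)), "missing species")
  expect_error(mass_action_flux(r, c(A = -1, B = 0)), "negative")
})

test_that("stoichiometry matrix holds net product-minus-reactant coefficients", {
  m <- sig_model("toy",
                 list(species("S", initial_concentration = 1), species("P")),
                 list(reaction("r", c(S = 1), c(P = 1), kf = 1)))
  expect_equal(unname(stoichiometry_matrix(m)[, 1]), c(-1, 1))

  m <- sig_model("akt",
                 list(species("Akt", initial_concentration = 1),
                      species("PIP3", initial_concentration = 1),
                      species("Aktm")),
                 list(reaction("r", c(Akt = 1, PIP3 = 1), c(Aktm = 1),
                               kf = 1, kr = 1)))
  expect_equal(unname(stoichiometry_matrix(m)[, 1]), c(-1, -1, 1))

  m <- sig_model("dimer",
                 list(species("A", initial_concentration = 1), species("B")),
                 list(reaction("r", c(A = 2), c(B = 1), kf = 1)))
  expect_equal(unname(stoichiometry_matrix(m)[, 1]), c(-2, 1))
})

test_that("ode_rhs matches hand-derived derivatives and respects boundaries", {
  m <- decay_model(k1 = 0.5, s0 = 2)
  d <- ode_rhs(m, initial_state(m))
  expect_equal(unname(d), c(-1, 1))

  # all concentrations zero, no zeroth-order inputs -> all derivatives zero
  d0 <- ode_rhs(m, c(S = 0, P = 0))
  expect_equal(unname(d0), c(0, 0))

  # boundary species derivative is pinned at zero
  mb <- sig_model("b",
                  list(species("S", initial_concentration = 2, is_boundary = TRUE),
                       species("P")),
                  list(reaction("r", c(S = 1), c(P = 1), kf = 0.5)))
  db <- ode_rhs(mb, initial_state(mb))
  expect_equal(unname(db), c(0, 1))

  expect_error(ode_rhs(m, c(S = Inf, P = 0)), "non-finite")
  expect_error(ode_rhs(m, c(S = 1)), "does not match species count")
})

test_that("ode_rhs equals the brute-force per-reaction oracle on 100 random networks", {
  set.seed(42)
  worst <- 0
  for (seed in 1:100) {
    net <- random_network(n_species = sample(3:15, 1), n_reactions = sample(2:20, 1),
                          frac_reversible = runif(1), seed = seed)
    st <- initial_state(net$model)
    d_impl <- ode_rhs(net$model, st)
    d_oracle <- rhs_bruteforce(net$model, st)
    worst <- max(worst, max(abs(d_impl - d_oracle[names(d_impl)])))
  }
  expect_lt(worst, 1e-12)
})

test_that("species with zero concentration never have negative derivatives", {
  for (seed in 1:25) {
    net <- random_network(n_species = 6, n_reactions = 10,
                          frac_reversible = 0.5, seed = seed)
    st <- initial_state(net$model)
    zero_out <- seq(1, length(st), by = 2)
    st[zero_out] <- 0
    d <- ode_rhs(net$model, st)
    expect_true(all(d[zero_out] >= -1e-12))
  }
})

test_that("conserved moieties are exact left null vectors", {
  # closed two-state cycle
  m <- sig_model("iso",
                 list(species("S", initial_concentration = 1), species("P")),
                 list(reaction("r", c(S = 1), c(P = 1), kf = 1, kr = 0.5)))
  cm <- conserved_moieties(m)
  expect_length(cm, 1)
  expect_equal(unname(cm[[1]]), c(1, 1))

  # receptor cycle R -> Rp -> Rint -> R
  m <- sig_model("cycle",
                 list(species("R", initial_concentration = 1), species("Rp"),
                      species("Rint")),
                 list(reaction("a", c(R = 1), c(Rp = 1), kf = 1),
                      reaction("b", c(Rp = 1), c(Rint = 1), kf = 1),
                      reaction("c", c(Rint = 1), c(R = 1), kf = 1)))
  cm <- conserved_moieties(m)
  expect_length(cm, 1)
  expect_equal(unname(cm[[1]]), c(1, 1, 1))

  # random networks: every returned c satisfies t(c) %*% N == 0 exactly
  for (seed in 1:30) {
    net <- random_network(n_species = 8, n_reactions = 6,
                          frac_reversible = 0.3, seed = seed)
    N <- stoichiometry_matrix(net$model)
    for (v in conserved_moieties(net$model)) {
      expect_true(all(as.vector(v %*% N) == 0))
    }
  }
})

test_that("validate_model reports structural, value and units problems", {
  ok <- decay_model()
  expect_identical(nrow(validate_model(ok)), 0L)

  bad <- sig_model("bad", list(species("S", initial_concentration = 1)),
                   list(reaction("r", c(S = 1), c(Ghost = 1), kf = 1)),
                   validate = FALSE)
  rep <- validate_model(bad)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$type, "structural")

  # kf order 1 on a bimolecular reaction is a units error
  r <- reaction("r", c(A = 1, B = 1), c(C = 1),
                kf = rate_constant("k", 1, order = 2))
  r$kf <- rate_constant("k", 1, order = 1)
  m <- sig_model("units", list(species("A", initial_concentration = 1),
                               species("B", initial_concentration = 1),
                               species("C")),
                 list(r), validate = FALSE)
  rep <- validate_model(m)
  expect_identical(rep$type, "units")
})

test_that("reaction constructor enforces mass-action invariants", {
  expect_error(reaction("r", c(A = 3), c(B = 1), kf = 1), "stoichiometry")
  expect_error(reaction("r", c(A = 1), c(B = 1), kf = 1, reversible = TRUE),
               "requires kr")
  expect_error(reaction("r", c(A = 1), c(B = 1, C = 1, D = 1), kf = 1, kr = 1),
               "product stoichiometry")
  expect_error(rate_constant("k", -1), "non-negative")
  expect_error(species("s", initial_concentration = -0.1), "non-negative")
})
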