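model_signature <- function(m) {
  list(
    species = lapply(m$species, function(s) {
      s[c("id", "initial_concentration", "is_boundary")]
    }),
    N = stoichiometry_matrix(m),
    k = lapply(m$reactions, function(r) {
      c(kf = r$kf$value, kr = if (!is.null(r$kr)) r$kr$value else NA_real_)
    }),
    rules = lapply(m$rules, function(rl) rl[c("kind", "target")]),
    params = m$parameters
  )
}

test_that("a toy model survives a write/read round trip", {
  m <- sig_model(
    "toy_rt",
    list(species("A", initial_concentration = 1.5, tags = "observable:A"),
         species("B", is_boundary = TRUE, initial_concentration = 0.2),
         species("C")),
    list(reaction("r1", c(A = 1, B = 1), c(C = 1), kf = 0.7, kr = 0.05),
         reaction("r2", c(C = 1), c(A = 1), kf = 0.01)),
    rules = list(rule("rr", "rate", "C", "0.001 * A")),
    parameters = c(theta = 2))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  rt <- read_sbml(path)
  expect_equal(model_signature(rt$model), model_signature(m))
  expect_identical(rt$info$level, 3L)
  # a rule element is carried exactly once
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  expect_length(xml2::xml_find_all(doc, "//listOfRules/*"), 1)
  # one kinetic law per reaction
  expect_length(xml2::xml_find_all(doc, "//kineticLaw"), 2)
  # tags survive
  expect_identical(rt$model$species[[1]]$tags, "observable:A")
})

test_that("100 random synthetic models round-trip up to ordering", {
  path <- withr::local_tempfile(fileext = ".xml")
  for (seed in 1:100) {
    net <- random_network(n_species = 5, n_reactions = 6,
                          frac_reversible = 0.4, seed = seed)
    write_sbml(net$model, path)
    rt <- read_sbml(path)
    expect_equal(model_signature(rt$model), model_signature(net$model))
  }
})

test_that("ode_rhs of an SBML-loaded model matches the programmatic model", {
  net <- random_network(n_species = 10, n_reactions = 14,
                        frac_reversible = 0.5, seed = 7)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net$model, path)
  rt <- read_sbml(path)
  ids <- vapply(net$model$species, `[[`, character(1), "id")
  set.seed(11)
  for (i in 1:20) {
    st <- stats::setNames(runif(length(ids), 0, 2), ids)
    d1 <- ode_rhs(net$model, st)
    d2 <- ode_rhs(rt$model, st[vapply(rt$model$species, `[[`, character(1), "id")])
    expect_lt(max(abs(d1[names(d2)] - d2)), 1e-10)
  }
})

test_that("non-mass-action kinetic laws are rejected with a diagnostic", {
  # hand-written SBML with a Michaelis-Menten law
  mm <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="mm"><listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="S" compartment="c" initialConcentration="1" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>',
    '<species id="P" compartment="c" initialConcentration="0" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>',
    '</listOfSpecies>',
    '<listOfReactions><reaction id="enz" reversible="false">',
    '<listOfReactants><speciesReference species="S" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="P" stoichiometry="1" constant="true"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><divide/><apply><times/><ci>Vmax</ci><ci>S</ci></apply>',
    '<apply><plus/><ci>Km</ci><ci>S</ci></apply></apply>',
    '</math><listOfLocalParameters>',
    '<localParameter id="Vmax" value="1"/><localParameter id="Km" value="0.5"/>',
    '</listOfLocalParameters></kineticLaw></reaction></listOfReactions>',
    '</model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(mm, path)
  expect_error(read_sbml(path), "enz.*not.*mass action")
})

test_that("SBML Level 2 documents with legacy parameter lists are accepted", {
  l2 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="l2toy"><listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="S" compartment="c" initialConcentration="2"/>',
    '<species id="P" compartment="c" initialConcentration="0"/>',
    '</listOfSpecies>',
    '<listOfReactions><reaction id="conv" reversible="false">',
    '<listOfReactants><speciesReference species="S"/></listOfReactants>',
    '<listOfProducts><speciesReference species="P"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>k1</ci><ci>S</ci></apply>',
    '</math><listOfParameters><parameter id="k1" value="0.5"/></listOfParameters>',
    '</kineticLaw></reaction></listOfReactions>',
    '</model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, path)
  rt <- read_sbml(path)
  expect_identical(rt$info$level, 2L)
  expect_equal(rt$model$reactions[[1]]$kf$value, 0.5)
  expect_equal(unname(initial_state(rt$model)), c(2, 0))
})

test_that("malformed XML raises a parse error", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><unclosed>", path)
  expect_error(read_sbml(path))
})
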