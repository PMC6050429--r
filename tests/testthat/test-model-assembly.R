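write_toy_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("reaction_id\treactants\tproducts\treversible\tkf\tkr\tnotes",
               lines), path)
  path
}

test_that("reaction-table parser handles the documented dialect", {
  path <- write_toy_table(c(
    "R1\tA + B\tC\t1\t0.5\t0.1\tbinding",
    "R2\tC\tA + B\t0\t0.2\t\tunbinding",
    "R3\t2 A\tD\t0\t0.3\t\tdimer"
  ))
  rows <- parse_reaction_table(path)
  expect_length(rows, 3)
  expect_true(rows[[1]]$reversible)
  expect_false(rows[[2]]$reversible)
  expect_false(rows[[3]]$reversible)
  expect_equal(rows[[3]]$reactants, c(A = 2L))

  # the reversible Akt membrane-recruitment row
  path <- write_toy_table("R1\tAkt + PIP3\tAktm\t1\t0.5\t0.1\t")
  rows <- parse_reaction_table(path)
  expect_equal(sort(names(rows[[1]]$reactants)), c("Akt", "PIP3"))
  expect_equal(names(rows[[1]]$products), "Aktm")
  expect_true(rows[[1]]$reversible)

  # empty table warns and returns an empty list
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), path)
  expect_warning(rows <- parse_reaction_table(path), "empty")
  expect_length(rows, 0)
})

test_that("malformed rows are reported with line numbers", {
  path <- write_toy_table(c(
    "R1\tA\tB\t0\t0.5\t\tok",
    "R2\tA\tB\t0\tnot_a_number\t\tbad kf",
    "R3\tA\tB\t1\t0.5\t\tmissing kr"
  ))
  expect_error(parse_reaction_table(path), "line 3.*line 4")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("reaction_id\treactants\tproducts", path)
  expect_error(parse_reaction_table(path), "missing column")
})

test_that("assembled models contain exactly the referenced species", {
  path <- write_toy_table(c(
    "R1\tA + B\tC\t1\t0.5\t0.1\t",
    "R2\tC\tD\t0\t0.2\t\t",
    "R3\tD\tA + B\t0\t0.1\t\t"
  ))
  rows <- parse_reaction_table(path)
  m <- assemble_model(rows, condition_spec("untreated"), name = "toy")
  expect_setequal(vapply(m$species, `[[`, character(1), "id"),
                  c("A", "B", "C", "D"))
  expect_equal(unname(model_counts(m)), c(4L, 3L, 4L, 0L))

  # duplicate reaction ids are rejected
  path <- write_toy_table(c("R1\tA\tB\t0\t1\t\t", "R1\tB\tA\t0\t1\t\t"))
  expect_error(assemble_model(parse_reaction_table(path),
                              condition_spec("untreated")),
               "duplicate reaction ids")
})

test_that("full network assembles to 128 species, 143 reactions, 213 parameters, 1 rule", {
  m <- build_full_model("treated")
  expect_equal(unname(model_counts(m)),
               c(128L, 143L, 213L, 1L))
  expect_identical(nrow(validate_model(m)), 0L)
})

test_that("treated and untreated models differ only in ligand inputs", {
  m_t <- build_full_model("treated", tam_dose = 1)
  m_u <- build_full_model("untreated")
  expect_identical(stoichiometry_matrix(m_t), stoichiometry_matrix(m_u))
  init_t <- initial_state(m_t)
  init_u <- initial_state(m_u)
  changed <- names(init_t)[init_t != init_u]
  expect_identical(changed, "Tam")
  expect_equal(m_t$parameters[["Tam_dose"]], 1)
  expect_equal(m_u$parameters[["Tam_dose"]], 0)
  # assembly is deterministic
  m_t2 <- build_full_model("treated", tam_dose = 1)
  ids <- function(m) vapply(m$species, `[[`, character(1), "id")
  expect_identical(ids(m_t), ids(m_t2))
  expect_identical(initial_state(m_t), initial_state(m_t2))
})

test_that("submodels are valid and the internalization motif conserves its receptor", {
  for (nm in c("egfr_activation", "ras_raf_mek_erk", "pi3k_akt_pten",
               "jak_stat", "gpr30_plc_pkc", "src_mmp_hbegf",
               "gpcr_internalization")) {
    m <- build_submodel(nm)
    expect_identical(nrow(validate_model(m)), 0L)
  }
  expect_error(build_submodel("nope"), "unknown submodel")

  m <- build_submodel("gpcr_internalization")
  cm <- conserved_moieties(m)
  sids <- vapply(m$species, `[[`, character(1), "id")
  receptor <- as.integer(sids %in% c("R", "R_p", "R_p_bArr", "R_i_bArr", "R_i"))
  # the total-receptor vector is a conserved quantity spanned by the basis
  N <- stoichiometry_matrix(m)
  expect_true(all(receptor %*% N == 0))
  expect_true(in_span(receptor, cm))
})

test_that("MAPK motif produces a transient ppERK pulse under a decaying input", {
  m <- build_submodel("ras_raf_mek_erk")
  tr <- integrate_model(m, t_end = 7200, n_points = 1200)
  y <- observable_timecourse(tr, observable_from_tags(m, "ppERK"))
  ipk <- which.max(y)
  expect_gt(ipk, 3)                 # rises first
  expect_lt(ipk, length(y))         # then declines
  expect_lt(y[length(y)], 0.5 * max(y))  # decays toward baseline
})

test_that("PIP3 rises monotonically when PTEN is disabled", {
  m <- build_submodel("pi3k_akt_pten")
  m0 <- m
  for (j in seq_along(m0$reactions)) {
    if (m0$reactions[[j]]$id == "pip3_deg") m0$reactions[[j]]$kf$value <- 0
  }
  tr <- integrate_model(m0, t_end = 600, n_points = 200)
  pip3 <- tr$concentrations[, "PIP3"]
  expect_true(all(diff(pip3) >= -1e-8))
})
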