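# Species enumeration and reaction generation of the random-order
# scaffold-assembly scheme, checked against an independent brute-force
# graph-growing oracle and the published network sizes.

test_that("species and reaction counts match the brute-force oracle for 0-3 ligands", {
  for (n in 0:3) {
    net <- generate_network(n)
    orc <- oracle_network(n)
    expect_identical(net$counts$n_species, orc$n_species)
    expect_identical(net$counts$n_reversible_pairs, orc$n_forward)
    expect_identical(net$counts$n_reversible_pairs, orc$n_reverse)
    # closed forms for the rule grammar
    expect_identical(net$counts$n_species,
                     as.integer(n + 2^(n + 1) + 4^n - 3^n))
    if (n > 0)
      expect_identical(net$counts$n_reversible_pairs,
                       as.integer(n * (2^n + 4^n - 2 * 3^(n - 1))))
  }
})

test_that("the 4-ligand expansion reproduces the published network sizes", {
  net <- generate_network(4)
  expect_identical(net$counts$n_species, 211L)
  expect_identical(net$counts$n_reversible_pairs, 872L)
  expect_identical(net$counts$n_irreversible, 1744L)
  tallies <- table(net$reactions$class)
  expect_identical(as.integer(tallies[["bind_free_to_G"]]), 180L)
  expect_identical(as.integer(tallies[["bind_free_to_R"]]), 180L)
  expect_identical(as.integer(tallies[["bridge_association"]]), 216L)
  expect_identical(as.integer(tallies[["ring_closure"]]), 296L)
})

test_that("every reaction is molecule-balanced and reversibly paired", {
  net <- toy_network_staged(2)
  expect_true(all(check_balance(net)))
  rx <- net$reactions
  bind <- which(!is.na(rx$reverse_of))
  expect_true(all(rx$reverse_of[rx$reverse_of[bind]] == bind))
  # stage reactions are irreversible
  expect_identical(sum(is.na(rx$reverse_of)), 2L)
})

test_that("every species is reachable as the product of some reaction", {
  net <- generate_network(3)
  produced <- sort(unique(unlist(net$reactions$products)))
  monomers <- which(vapply(net$species, function(s)
    (s$g + s$r + length(s$lig)) == 1L, logical(1)))
  expect_setequal(union(produced, monomers), seq_along(net$species))
})

test_that("canonical labels follow the grammar and are injective", {
  net <- add_translation_stage(generate_network(4))
  expect_identical(net$labels[1:2], c("G()", "R()"))
  expect_true("G.R.E(gr)" %in% net$labels)
  expect_false(anyDuplicated(net$labels) > 0)
  expect_identical(length(net$labels), 215L)
  # identical structure built in a different insertion order -> same label
  s1 <- list(g = TRUE, r = TRUE, lig = c(E = "gr", A = "g"))
  s2 <- list(g = TRUE, r = TRUE, lig = c(A = "g", E = "gr"))
  expect_identical(canonical_label(s1), canonical_label(s2))
})

test_that("translation-stage augmentation adds 4 species and 2 reactions once", {
  net <- generate_network(4)
  staged <- add_translation_stage(net)
  expect_identical(staged$counts$n_species, 215L)
  expect_identical(staged$counts$n_irreversible, 1746L)
  expect_error(add_translation_stage(staged), "already present")

  toy <- add_translation_stage(generate_network(1))
  expect_identical(toy$counts$n_species, 10L)
  expect_identical(toy$counts$n_irreversible, 10L)
  # the 43S substrate is the all-bridged full complex
  expect_identical(staged$labels[staged$idx_full],
                   "G.R.A(gr).E(gr).D(gr).P(gr)")
})

test_that("unsupported constraint configurations are rejected", {
  expect_error(cap_constraints(single_copy = FALSE), "unsupported constraint")
  expect_error(cap_constraints(scaffold_scaffold_bond = TRUE), "unsupported constraint")
  expect_error(generate_network(7), "unsupported constraint")
})

test_that("SBML export round-trips through re-import", {
  toy <- toy_network_staged(1)
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(toy, cap_params(n_ligands = 1), cap_totals(n_ligands = 1), path)
  back <- read_sbml_counts(path)
  expect_identical(back$n_species, 10L)
  expect_identical(back$n_reactions, 10L)
  expect_identical(back$n_parameters, 9L)  # 7 per ligand + 2 stage rates
  expect_setequal(back$boundary_ids, c("S43", "S40"))

  full <- toy_network_staged(4)
  path2 <- withr::local_tempfile(fileext = ".xml")
  export_sbml(full, cap_params(), cap_totals(), path2)
  back2 <- read_sbml_counts(path2)
  expect_identical(back2$n_species, 215L)
  expect_identical(back2$n_reactions, 1746L)
  expect_identical(back2$n_parameters, 30L)
})

test_that("network summary table reports membership and bond counts", {
  net <- generate_network(1)
  s <- network_summary(net)
  expect_identical(s$n_bonds[s$label == "G.R.A(gr)"], 2L)
  expect_identical(s$n_members[s$label == "G.R.A(gr)"], 3L)
  expect_identical(s$n_bonds[s$label == "A()"], 0L)
})
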