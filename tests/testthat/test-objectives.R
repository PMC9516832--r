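# Descriptors, desirability predicates and structural variance

test_that("descriptors of hand-checkable molecules match chemistry", {
  d <- compute_descriptors(c("CCO", "c1ccccc1", "Nc1cccc2ncccc12"))
  ethanol <- d[1, ]
  expect_equal(ethanol$hbd, 1L)
  expect_equal(ethanol$hba, 1L)
  expect_equal(ethanol$rot_bonds, 0L)
  expect_equal(ethanol$aromatic_rings, 0L)
  expect_true(ethanol$fg_oh)
  expect_lt(ethanol$logp, 3)

  benzene <- d[2, ]
  expect_equal(benzene$aromatic_rings, 1L)
  expect_equal(benzene$non_aromatic_rings, 0L)
  expect_false(any(benzene$fg_oh, benzene$fg_ester, benzene$fg_cooh,
                   benzene$fg_nh2))

  aminoquinoline <- d[3, ]
  expect_true(aminoquinoline$fg_nh2)
  expect_equal(aminoquinoline$aromatic_rings, 2L)
})

test_that("descriptor computation rejects invalid SMILES by name", {
  expect_error(compute_descriptors(c("CCO", "C(")), "C\\(")
})

# a descriptor row builder for predicate logic tests
drow <- function(logp = 1, mol_weight = 100, hba = 1, hbd = 1, rot_bonds = 1,
                 aromatic_rings = 2L, non_aromatic_rings = 1L,
                 fg_oh = TRUE, fg_ester = FALSE, fg_cooh = FALSE,
                 fg_nh2 = FALSE, r_value = 0.3) {
  tibble::tibble(logp = logp, mol_weight = mol_weight, hba = hba, hbd = hbd,
                 rot_bonds = rot_bonds, aromatic_rings = aromatic_rings,
                 non_aromatic_rings = non_aromatic_rings, fg_oh = fg_oh,
                 fg_ester = fg_ester, fg_cooh = fg_cooh, fg_nh2 = fg_nh2,
                 r_value = r_value, heavy_atoms = 10L)
}

test_that("objective 1 boundary is inclusive", {
  expect_true(objective_1(drow(logp = 3.0)))
  expect_false(objective_1(drow(logp = 3.01)))
})

test_that("objective 2 requires exact ring counts, a group and the R window", {
  expect_true(objective_2(drow()))
  expect_false(objective_2(drow(aromatic_rings = 3L)))
  expect_false(objective_2(drow(non_aromatic_rings = 0L)))
  expect_false(objective_2(drow(fg_oh = FALSE)))
  expect_true(objective_2(drow(fg_oh = FALSE, fg_nh2 = TRUE)))
  expect_false(objective_2(drow(r_value = 0.51)))
  expect_true(objective_2(drow(r_value = 0.50)))   # closed interval
  expect_true(objective_2(drow(r_value = 0.51), use_r_value = FALSE))
})

test_that("objective 3 is the five-clause rule of three with a veto", {
  expect_true(objective_3(drow(rot_bonds = 3)))
  expect_false(objective_3(drow(mol_weight = 481)))
  expect_false(objective_3(drow(hba = 4)))
  expect_false(objective_3(drow(hbd = 4)))
  expect_false(objective_3(drow(rot_bonds = 4)))
})

test_that("objective 4 is the conjunction and implies 2 and 3", {
  expect_true(objective_4(drow()))
  withr::with_seed(11, {
    for (i in 1:50) {
      d <- drow(
        logp = stats::runif(1, -1, 5), mol_weight = stats::runif(1, 50, 600),
        hba = sample(0:6, 1), hbd = sample(0:6, 1),
        rot_bonds = sample(0:6, 1), aromatic_rings = sample(0:3, 1),
        non_aromatic_rings = sample(0:2, 1),
        fg_oh = sample(c(TRUE, FALSE), 1), fg_nh2 = sample(c(TRUE, FALSE), 1),
        r_value = stats::runif(1)
      )
      if (objective_4(d)) {
        expect_true(objective_2(d))
        expect_true(objective_3(d))
      }
    }
  })
})

test_that("objective 5 needs every functional group; its group clause is stricter", {
  all_groups <- drow(fg_oh = TRUE, fg_ester = TRUE, fg_cooh = TRUE,
                     fg_nh2 = TRUE)
  expect_true(objective_5(all_groups))
  expect_false(objective_5(drow()))  # only -OH present
  # anything passing objective 5's group clause passes objective 2's
  expect_true(objective_2(all_groups))
})

test_that("structural variance reproduces the worked examples", {
  expect_equal(structural_variance("Nc1cccc2ncccc12"), 0.05)
  expect_equal(structural_variance("CC"), 0.01)
  expect_equal(structural_variance("COc1ccccc1CCN"), 0.05)
  expect_equal(structural_variance_per_length("Nc1cccc2ncccc12"), 5 / 15)
  expect_equal(round(structural_variance_per_length("Nc1cccc2ncccc12"), 2),
               0.33)
})

test_that("structural variance strips whitespace and rejects empty input", {
  expect_equal(structural_variance("(= O)C"), structural_variance("(=O)C"))
  expect_error(structural_variance(""), "empty")
  expect_error(structural_variance_per_length("  "), "empty")
})

test_that("SV responds only to novel characters", {
  base <- structural_variance("CCO")
  expect_equal(structural_variance("CCOC"), base)         # duplicate: no change
  expect_equal(structural_variance("CCON"), base + 0.01)  # novel: +1/100
  # per-length variant always >= global variant for strings under the cap
  for (s in c("CC", "CCO", "Nc1cccc2ncccc12")) {
    expect_gte(structural_variance_per_length(s), structural_variance(s))
  }
  expect_equal(structural_variance_per_length("CCCC"), 1 / 4)
})

test_that("bracket/charge-decorated molecules have higher mean SV than plain aromatics", {
  decorated <- c("[K+].[O-]S(=O)(=O)c1ccccc1",
                 "CC(=O)O[C@H]1CC[NH+](C)C1",
                 "[Na+].[O-]C(=O)c1ccc(F)cc1",
                 "C[N+](C)(C)CCO")
  plain <- c("c1ccccc1", "c1ccc(C)cc1", "c1ccncc1", "Cc1ccccc1C")
  expect_gt(mean(structural_variance(decorated)),
            mean(structural_variance(plain)))
})

test_that("objectives load from YAML clause lists", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "name: custom",
    "description: logP window plus a group",
    "clauses:",
    "  - {descriptor: logp, op: between, value: [-1, 3]}",
    "  - {descriptor: rot_bonds, op: le, value: 3}",
    "  - op: any_flag",
    "    value: [fg_oh, fg_nh2]"
  ), path)
  obj <- objective_from_yaml(path)
  expect_s3_class(obj, "smi_objective")
  expect_true(obj$predicate(drow()))
  expect_false(obj$predicate(drow(logp = 5)))
  expect_false(obj$predicate(drow(fg_oh = FALSE)))
})

test_that("satisfies_objective treats invalid molecules as undesirable", {
  hits <- satisfies_objective(c("CCO", "C(", "c1ccccc1"), obj_no_aromatic())
  expect_identical(hits, c(TRUE, FALSE, FALSE))
  expect_identical(satisfies_objective(character(), obj_no_aromatic()),
                   logical())
})
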