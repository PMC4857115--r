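# build a network from a designed bipartite edge plan: each plant gets
# compounds that are exact copies of the drugs it should connect to, so
# every planned edge appears with Tc = 1 and no others (drug scaffolds are
# mutually dissimilar aromatic cores)
planned_network <- function(edge_plan, drug_smiles) {
  plant_ids <- sort(unique(edge_plan$plant))
  drugs <- data.frame(drug_id = names(drug_smiles), smiles = drug_smiles,
                      stage = "approved", row.names = NULL)
  comp <- data.frame(compound_id = sprintf("c%02d", seq_len(nrow(edge_plan))),
                     smiles = drug_smiles[edge_plan$drug],
                     plant = edge_plan$plant)
  plants <- data.frame(plant_id = plant_ids, plant_name = plant_ids,
                       family = "F")
  plants$compound_ids <- lapply(plant_ids, function(p)
    comp$compound_id[comp$plant == p])
  enr <- data.frame(plant_id = plant_ids, plant_name = plant_ids,
                    family = "F", significant = TRUE)
  fps <- maccs_fingerprint(comp$smiles, comp$compound_id)
  build_network(enr, plants, fps, drugs)
}

drug_pool <- c(d1 = "c1ccc2ncccc2c1", d2 = "O=S(=O)(N)c1ccccc1",
               d3 = "c1ccc2c(c1)cc[nH]2", d4 = "C(=C/c1ccccc1)\\c1ccccn1",
               d5 = "O=c1ccc2ccccc2o1")

test_that("an exact compound-drug match yields one edge with full evidence", {
  net <- planned_network(data.frame(plant = "P1", drug = "d1"), drug_pool["d1"])
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$max_tc, 1)
  comps <- connected_components(net)
  expect_identical(length(comps), 1L)
  expect_identical(comps[[1]], c("P1", "d1"))
})

test_that("two compounds hitting the same drug collapse into one edge", {
  net <- planned_network(data.frame(plant = c("P1", "P1"), drug = c("d1", "d1")),
                         drug_pool["d1"])
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$n_evidence, 2L)
  expect_identical(nrow(net$evidence), 2L)
})

test_that("disjoint plant-drug pairs form separate components", {
  net <- planned_network(data.frame(plant = c("P1", "P2"), drug = c("d1", "d2")),
                         drug_pool[c("d1", "d2")])
  comps <- connected_components(net)
  expect_identical(length(comps), 2L)
  expect_identical(comps[[1]], c("P1", "d1"))  # size tie: smallest member first
})

test_that("components match a brute-force union-find oracle on random graphs", {
  for (seed in 1:5) {
    plan <- withr::with_seed(seed, {
      n_edge <- sample(3:8, 1)
      data.frame(plant = sprintf("P%d", sample(1:4, n_edge, replace = TRUE)),
                 drug = sample(names(drug_pool), n_edge, replace = TRUE))
    })
    net <- planned_network(plan, drug_pool[sort(unique(plan$drug))])
    got <- connected_components(net)
    want <- union_find_components(net$edges$plant_id, net$edges$drug_id)
    expect_identical(got, want)
  }
})

test_that("restricting to fewer plants never adds edges", {
  plan <- data.frame(plant = c("P1", "P1", "P2", "P3"),
                     drug = c("d1", "d2", "d2", "d3"))
  full <- planned_network(plan, drug_pool[c("d1", "d2", "d3")])
  sub <- planned_network(plan[plan$plant != "P1", ],
                         drug_pool[c("d1", "d2", "d3")])
  key <- function(net) paste(net$edges$plant_id, net$edges$drug_id)
  expect_true(all(key(sub) %in% key(full)))
  expect_lte(nrow(sub$edges), nrow(full$edges))
})

test_that("edges are invariant to compound iteration order", {
  plan <- data.frame(plant = c("P1", "P2", "P2"), drug = c("d1", "d2", "d3"))
  a <- planned_network(plan, drug_pool[c("d1", "d2", "d3")])
  b <- planned_network(plan[c(3, 1, 2), ], drug_pool[c("d1", "d2", "d3")])
  expect_identical(a$edges[c("plant_id", "drug_id", "n_evidence")],
                   b$edges[c("plant_id", "drug_id", "n_evidence")])
})

test_that("a drug in several stages takes its most advanced stage label", {
  smi <- drug_pool[["d1"]]
  panels <- data.frame(drug_id = "dX", smiles = smi,
                       stage = c("preclinical", "approved"))
  plants <- data.frame(plant_id = "P1", plant_name = "P1", family = "F")
  plants$compound_ids <- list("c1")
  enr <- data.frame(plant_id = "P1", plant_name = "P1", family = "F",
                    significant = TRUE)
  net <- build_network(enr, plants, maccs_fingerprint(smi, "c1"), panels)
  expect_identical(net$drug_nodes$stage, "approved")
})
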