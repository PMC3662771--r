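test_that("validation partitions every record with machine-readable reasons", {
  part <- validate_records(toy_records(), toy_checklist(), toy_taxonomy(),
                           toy_plant_orders())
  expect_equal(nrow(part$valid) + nrow(part$nonplant) + nrow(part$discarded),
               nrow(toy_records()))
  # family-rank name resolves through the taxonomy map
  fab <- part$valid[part$valid$host_name == "Fabaceae", ]
  expect_equal(fab$host_order, "Fabales")
  # genus-rank resolution
  pip <- part$valid[part$valid$host_name == "Piper", ]
  expect_equal(pip$host_order, "Piperales")
  # stop-list term discarded as generic
  expect_equal(part$discarded$reason[part$discarded$host_name == "grasses"],
               "generic_term")
  # animal and detritus go to the non-plant partition
  expect_setequal(part$nonplant$host_name, c("animal", "detritus"))
  # unknown butterfly and unresolvable host are discarded with reasons
  expect_equal(
    part$discarded$reason[part$discarded$butterfly_species == "Unknown species"],
    "unknown_butterfly")
  expect_equal(part$discarded$reason[part$discarded$host_name == "Mysteryplant"],
               "unresolved_host")

  expect_error(validate_records(toy_records()[0, ], toy_checklist(),
                                toy_taxonomy(), toy_plant_orders()),
               "no records")
  dup <- rbind(toy_checklist(), toy_checklist()[1, ])
  expect_error(validate_records(toy_records(), dup, toy_taxonomy(),
                                toy_plant_orders()), "duplicate")
})

test_that("partition property holds on random synthetic inputs", {
  for (s in 1:3) {
    d <- simulate_dataset(synthetic_config(n_orders = 10, n_subfamilies = 8,
                                           beta0 = 2, seed = s))
    recs <- d$records
    # inject junk rows
    junk <- data.frame(butterfly_species = c("Nobody", recs$butterfly_species[1]),
                       host_name = c(recs$host_name[1], "grasses"),
                       host_rank = "order", source = "junk")
    recs <- rbind(recs, junk)
    part <- suppressWarnings(
      validate_records(recs, d$checklist, NULL, d$plant_tree$tip.label))
    expect_equal(nrow(part$valid) + nrow(part$nonplant) + nrow(part$discarded),
                 nrow(recs))
  }
})

test_that("matrices match hand counts on the three-species toy", {
  cl <- toy_checklist()
  # 3 Papilioninae species: two on Piperales only, one on Piperales + Fabales
  recs <- data.frame(
    butterfly_species = c("Papilio alpha", "Papilio beta", "Graphium gamma",
                          "Graphium gamma"),
    host_name = c("Piperales", "Piperales", "Piperales", "Fabales"),
    host_rank = "order", source = "toy")
  part <- validate_records(recs, cl, NULL, toy_plant_orders())
  tab <- suppressWarnings(build_matrices(part$valid, cl))
  expect_equal(tab$C["Piperales", "Papilioninae"], 3L)
  expect_equal(tab$C["Fabales", "Papilioninae"], 1L)
  expect_equal(tab$S[["Papilioninae"]], 3L)
  expect_equal(tab$Z["Piperales", "Papilioninae"], 1)
  expect_equal(tab$Z["Fabales", "Papilioninae"], 1 / 3)
  expect_equal(tab$X["Piperales", "Papilioninae"], 1)
  expect_equal(tab$X["Fabales", "Papilioninae"], 1)
  # subfamilies without records are retained, flagged, all-zero
  expect_true(all(c("Miletinae", "Poritiinae") %in% tab$flagged))
  expect_true(all(tab$C[, "Miletinae"] == 0))
  expect_equal(tab$R[["Papilioninae"]], 3L)

  # duplicates collapse: adding repeated records changes nothing
  part2 <- validate_records(rbind(recs, recs), cl, NULL, toy_plant_orders())
  tab2 <- suppressWarnings(build_matrices(part2$valid, cl))
  expect_identical(tab$C, tab2$C)
  expect_identical(tab$S, tab2$S)
})

test_that("matrix invariants hold on random synthetic record sets", {
  for (s in 4:6) {
    d <- simulate_dataset(synthetic_config(n_orders = 12, n_subfamilies = 10,
                                           beta0 = 2.5, seed = s))
    part <- suppressWarnings(
      validate_records(d$records, d$checklist, NULL, d$plant_tree$tip.label))
    tab <- suppressWarnings(build_matrices(part$valid, d$checklist))
    expect_identical(tab$A, (tab$C > 0) + 0L)
    expect_equal(tab$Z %*% diag(pmax(tab$S, 1L)), tab$C,
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_identical(tab$X, (tab$Z > 0.1) + 0L)
    expect_true(all(apply(tab$Z, 2, max) <= 1))
    expect_true(all(colSums(tab$Z) >= apply(tab$Z, 2, max)))
    expect_true(all(tab$C <= matrix(tab$S, nrow(tab$C), ncol(tab$C),
                                    byrow = TRUE)))
    expect_true(all(tab$S <= tab$R))
  }
})

test_that("resource classification applies strict thresholds and tie rules", {
  cl <- data.frame(species = paste0("s", 1:20), genus = "G",
                   subfamily = "Sub1", family = "F", region = "OR")
  # 20 recorded species: all on OrdA, 2 on OrdB (z = 0.1 exactly),
  # 3 on OrdC (z = 0.15)
  recs <- data.frame(
    butterfly_species = c(paste0("s", 1:20), "s1", "s2", "s3", "s4", "s5"),
    host_name = c(rep("OrdA", 20), rep("OrdB", 2), rep("OrdC", 3)),
    host_rank = "order", source = "t")
  part <- validate_records(recs, cl, NULL, c("OrdA", "OrdB", "OrdC"))
  tab <- build_matrices(part$valid, cl)
  cls <- classify_resources(tab)
  expect_equal(cls$most_important, "OrdA")
  expect_equal(cls$primary, "OrdA")                 # 19/20 > 0.9
  imp <- strsplit(cls$important, ",")[[1]]
  expect_true("OrdC" %in% imp)                      # 0.15 > 0.1
  expect_false("OrdB" %in% imp)                     # exactly 0.1: strict
  # tie for argmax is broken lexicographically with a warning
  tabT <- tab
  tabT$Z["OrdB", 1] <- tabT$Z["OrdA", 1]
  expect_warning(clsT <- classify_resources(tabT), "tie")
  expect_equal(clsT$most_important, "OrdA")
  expect_true(clsT$tie)
})

test_that("representativeness proportions and totals are conserved", {
  cl <- data.frame(species = paste0("sp", 1:10), genus = "G",
                   subfamily = "SubA", family = "FamA",
                   region = rep(c("OR", "NT"), each = 5))
  recs <- data.frame(butterfly_species = paste0("sp", 1:4),
                     host_name = "OrdA", host_rank = "order", source = "t")
  part <- validate_records(recs, cl, NULL, "OrdA")
  rep_sum <- representativeness_summary(cl, part$valid)
  tot <- rep_sum$region_family[rep_sum$region_family$region == "Total", ]
  expect_equal(tot$n_species, 10L)
  expect_equal(tot$n_with_records, 4L)
  expect_equal(tot$proportion, 0.4)
  body <- rep_sum$region_family[rep_sum$region_family$region != "Total", ]
  expect_equal(sum(body$n_species), tot$n_species)
  expect_equal(sum(body$n_with_records), tot$n_with_records)

  # a Megathyminae-shaped row: 39 worldwide, 36 with records -> 0.923
  cl2 <- data.frame(species = paste0("m", 1:39), genus = "Megathymus",
                    subfamily = "Megathyminae", family = "Hesperiidae",
                    region = "NC")
  recs2 <- data.frame(butterfly_species = paste0("m", 1:36),
                      host_name = "OrdA", host_rank = "order", source = "t")
  part2 <- validate_records(recs2, cl2, NULL, "OrdA")
  sf <- representativeness_summary(cl2, part2$valid)$subfamily
  expect_equal(round(sf$species_proportion, 3), 0.923)
})

test_that("usage frequencies count distinct species and match a brute tally", {
  part <- validate_records(toy_records(), toy_checklist(), toy_taxonomy(),
                           toy_plant_orders())
  uf <- usage_frequency_summary(part$valid)
  # Piperales used by Papilio alpha (twice -> once) and Graphium gamma
  expect_equal(uf$order$n_species[uf$order$name == "Piperales"], 2L)
  expect_equal(uf$family$n_species[uf$family$name == "Fabaceae"], 1L)

  # brute-force recount on a random synthetic set
  d <- simulate_dataset(synthetic_config(n_orders = 10, n_subfamilies = 6,
                                         beta0 = 2.5, seed = 9))
  part2 <- suppressWarnings(
    validate_records(d$records, d$checklist, NULL, d$plant_tree$tip.label))
  uf2 <- usage_frequency_summary(part2$valid)
  for (k in seq_len(nrow(uf2$order))) {
    ord <- uf2$order$name[k]
    manual <- length(unique(part2$valid$butterfly_species[
      part2$valid$host_order == ord]))
    expect_equal(uf2$order$n_species[k], manual)
  }
})
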