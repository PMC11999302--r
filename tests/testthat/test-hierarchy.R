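test_that("shipped presets load with the documented structure", {
  cork <- svi_preset("cork_flood")
  expect_equal(nrow(cork$dimensions), 3)
  expect_equal(nrow(cork$domains), 11)
  expect_equal(nrow(cork$indicators), 27)
  expect_equal(sum(cork$domains$designed_size), 27)

  logrono <- svi_preset("logrono_heat")
  expect_equal(nrow(logrono$dimensions), 3)
  expect_equal(sum(!logrono$indicators$collected), 1)
  expect_equal(logrono$domains$designed_size[logrono$domains$domain_id == "health"], 2L)

  milan <- svi_preset("milan_heat")
  expect_equal(nrow(milan$dimensions), 3)
  expect_equal(sum(milan$domains$dimension_id == "sensitivity"), 1)
})

test_that("validation flags structural problems at the right severity", {
  expect_identical(nrow(validate_hierarchy(svi_preset("cork_flood"))), 0L)

  # Milan-shaped: single-domain dimensions warn, never error
  rep <- validate_hierarchy(svi_preset("milan_heat"))
  expect_true(all(rep$severity == "warning"))
  expect_true(any(grepl("sensitivity", rep$message)))

  # a dimension absent from the canonical three is an error-severity finding
  doc <- yaml::yaml.load(minimal_yaml())
  doc$dimensions <- doc$dimensions[1:2]
  doc$domains <- doc$domains[1:2]
  doc$indicators <- doc$indicators[1:2]
  cfg2 <- load_hierarchy(yaml::as.yaml(doc))
  rep2 <- validate_hierarchy(cfg2)
  expect_true(any(rep2$rule == "dimension_absent" & rep2$severity == "error"))
})

test_that("loading rejects dangling references and malformed documents", {
  bad <- sub("domain: income", "domain: wealth", minimal_yaml())
  expect_error(load_hierarchy(bad), "wealth", class = "svi_linkage_error")
  expect_error(load_hierarchy("dimensions:\n  - {id: sensitivity}\n"),
               "missing top-level key", class = "svi_config_error")
  dup <- sub("id: unemployment", "id: over_75", minimal_yaml())
  expect_error(load_hierarchy(dup), "duplicate", class = "svi_config_error")
})

test_that("a minimal configuration round-trips through save/load unchanged", {
  cfg <- load_hierarchy(minimal_yaml())
  path <- tempfile(fileext = ".yaml")
  save_hierarchy(cfg, path)
  expect_equal(load_hierarchy(path), cfg)
})

test_that("availability profiling counts per design and flags depletion", {
  cfg <- fixture_hierarchy()
  tab <- fixture_table()
  prof <- availability_profile(cfg, tab)
  expect_identical(prof$depleted_domains, character(0))
  expect_equal(prof$domains$available_count,
               prof$domains$designed_size)

  # drop a required age indicator -> age depleted (1 of 2 designed)
  tab2 <- degrade_table(tab, cfg, "tier2_deplete", "a2")
  prof2 <- availability_profile(cfg, tab2)
  expect_identical(prof2$depleted_domains, "age")
  expect_true(prof2$domains$missing_required[prof2$domains$domain_id == "age"])

  # a constant column carries no rankable information: unavailable
  v <- tab$values; v[, "h1"] <- 7
  prof3 <- availability_profile(cfg, indicator_table(v, tab$area_ids))
  expect_equal(prof3$domains$available_count[prof3$domains$domain_id == "health"], 0L)

  # dropping a whole dimension's columns zeroes its domain count
  tab4 <- degrade_table(tab, cfg, "tier4_drop_dimension", "enhanced_exposure")
  prof4 <- availability_profile(cfg, tab4)
  expect_equal(prof4$dimensions$available_domain_count[
    prof4$dimensions$dimension_id == "enhanced_exposure"], 0L)

  expect_error(availability_profile(cfg,
                 indicator_table(matrix(1:10, 5, dimnames = list(NULL, c("x", "y"))),
                                 paste0("a", 1:5))),
               class = "svi_consistency_error")
})

test_that("availability profile is invariant to row and column permutations", {
  cfg <- fixture_hierarchy()
  tab <- fixture_table()
  ref <- availability_profile(cfg, tab)
  set.seed(11)
  for (k in 1:5) {
    v <- tab$values[sample(nrow(tab$values)), sample(ncol(tab$values)), drop = FALSE]
    perm <- availability_profile(cfg, indicator_table(v, rownames(v)))
    expect_equal(perm$domains, ref$domains)
    expect_equal(perm$dimensions, ref$dimensions)
  }
})

test_that("removing a column never increases availability; adding it back restores", {
  cfg <- svi_preset("cork_flood")
  sim <- simulate_indicators(simulation_spec(30, cfg, seed = 3))
  ref <- availability_profile(cfg, sim$table)
  for (col in sample(colnames(sim$table$values), 6)) {
    keep <- setdiff(colnames(sim$table$values), col)
    less <- availability_profile(cfg,
      indicator_table(sim$table$values[, keep, drop = FALSE], sim$table$area_ids))
    expect_true(all(less$domains$available_count <= ref$domains$available_count))
    back <- availability_profile(cfg,
      indicator_table(sim$table$values[, c(keep, col)][, colnames(sim$table$values)],
                      sim$table$area_ids))
    expect_equal(back$domains, ref$domains)
  }
})

test_that("the three presets against their own full tables match the case studies", {
  # Cork: ideal scenario, no depleted domains
  cork <- svi_preset("cork_flood")
  pc <- availability_profile(cork, simulate_indicators(simulation_spec(50, cork, seed = 1))$table)
  expect_length(pc$depleted_domains, 0)

  # Logrono: Health depleted, but every dimension keeps >=2 domains
  log <- svi_preset("logrono_heat")
  pl <- availability_profile(log, simulate_indicators(simulation_spec(50, log, seed = 1))$table)
  expect_true(length(pl$depleted_domains) >= 1)
  expect_true("health" %in% pl$depleted_domains)
  expect_true(all(pl$dimensions$available_domain_count >= 2))

  # Milan: sensitivity rests on exactly one available domain
  mil <- svi_preset("milan_heat")
  pm <- availability_profile(mil, simulate_indicators(simulation_spec(50, mil, seed = 1))$table)
  expect_equal(pm$dimensions$available_domain_count[
    pm$dimensions$dimension_id == "sensitivity"], 1L)
})
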