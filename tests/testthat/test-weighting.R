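test_that("tier classification reproduces the four case-study situations", {
  cork <- svi_preset("cork_flood")
  sim <- simulate_indicators(simulation_spec(40, cork, seed = 2))
  expect_equal(classify_tier(availability_profile(cork, sim$table))$tier, 1L)

  log <- svi_preset("logrono_heat")
  tl <- classify_tier(availability_profile(
    log, simulate_indicators(simulation_spec(40, log, seed = 2))$table))
  expect_equal(tl$tier, 2L)
  expect_true(any(grepl("health", tl$reasons)))

  mil <- svi_preset("milan_heat")
  tm <- classify_tier(availability_profile(
    mil, simulate_indicators(simulation_spec(40, mil, seed = 2))$table))
  expect_equal(tm$tier, 3L)
  expect_true(length(tm$caveats) > 0)

  t4 <- classify_tier(availability_profile(
    cork, degrade_table(sim$table, cork, "tier4_drop_dimension", "enhanced_exposure")))
  expect_equal(t4$tier, 4L)
  expect_true(length(t4$caveats) > 0)
})

test_that("weight construction follows the tiered rules exactly", {
  cfg <- fixture_hierarchy()
  tab <- fixture_table()
  prof <- availability_profile(cfg, tab)

  # complete domains: equal split, domain sums exactly 1
  w1 <- build_weights(prof, 1L)
  inc <- w1$weights[w1$weights$domain_id == "income", ]
  expect_equal(inc$weight, c(0.5, 0.5))
  expect_true(all(abs(w1$domain_weight_sums - 1) < 1e-12))

  # depleted domain with m = 1: weight halved to 1/2
  tab2 <- degrade_table(tab, cfg, "tier2_deplete", "a2")
  prof2 <- availability_profile(cfg, tab2)
  tier2 <- classify_tier(prof2)
  w2 <- build_weights(prof2, tier2)
  expect_equal(w2$weights$weight[w2$weights$indicator_id == "a1"], 0.5)
  expect_equal(unname(w2$domain_weight_sums["age"]), 0.5)
  expect_equal(unname(w2$domain_weight_sums["income"]), 1)
  expect_equal(w2$weights$weight[w2$weights$indicator_id == "a2"], 0)

  # depleted domain with m = 2 of designed 3: each 1/(2m) = 0.25, sum 0.5
  cfg3 <- fixture_hierarchy()
  cfg3$indicators <- rbind(cfg3$indicators,
    data.frame(indicator_id = "i3", label = "third", domain_id = "income",
               direction = "vulnerability_increasing", required = TRUE,
               sub_ability = NA_character_, collected = TRUE))
  cfg3$domains$designed_size[cfg3$domains$domain_id == "income"] <- 3L
  prof3 <- availability_profile(cfg3, tab)  # i3 column absent
  expect_true("income" %in% prof3$depleted_domains)
  w3 <- build_weights(prof3, classify_tier(prof3))
  inc3 <- w3$weights[w3$weights$domain_id == "income" & w3$weights$weight > 0, ]
  expect_equal(inc3$weight, c(0.25, 0.25))
  expect_equal(unname(w3$domain_weight_sums["income"]), 0.5)

  # tier 4 routes away from hierarchical weights
  expect_error(build_weights(prof, 4L), class = "svi_tier_routing_error")
})

test_that("weighted aggregation matches hand evaluation", {
  # one area, one domain, weights 0.5/0.5 over z = (2, -1)
  z <- structure(list(
    area_ids = "a1",
    values = matrix(c(2, -1), 1, dimnames = list("a1", c("x", "y"))),
    params = NULL, aligned = TRUE, flipped = character()),
    class = "svi_zscores")
  w <- structure(list(
    weights = data.frame(domain_id = "d", indicator_id = c("x", "y"),
                         weight = 0.5),
    tier = structure(list(tier = 1L, reasons = character(),
                          caveats = character()), class = "svi_tier"),
    domain_weight_sums = c(d = 1)), class = "svi_weights")
  sc <- apply_weights(z, w)
  expect_equal(unname(sc$domain_scores[, "d"]), 0.5)
  expect_equal(unname(sc$svi), 0.5)

  # all-zero z -> zero index
  z0 <- z; z0$values[] <- 0
  expect_equal(unname(apply_weights(z0, w)$svi), 0)

  # svi is the row sum across domains
  cfg <- fixture_hierarchy()
  sc2 <- package_svi(fixture_table(), cfg)
  expect_equal(sc2$svi, rowSums(sc2$domain_scores), tolerance = 1e-12)
})

test_that("per-area weight renormalization preserves the domain weight sum", {
  cfg <- fixture_hierarchy()
  tab <- fixture_table()
  v <- tab$values
  v[2, "i1"] <- NA  # one missing cell inside the two-indicator income domain
  tabna <- indicator_table(v, tab$area_ids)
  prof <- availability_profile(cfg, tabna)
  z <- align_direction(zscore_normalize(tabna), cfg)
  sc <- apply_weights(z, build_weights(prof, classify_tier(prof)),
                      missing_policy = "renormalize_weights")
  # area 2's income score now uses the full domain weight on i2 alone
  expect_equal(unname(sc$domain_scores[2, "income"]),
               unname(z$values[2, "i2"]) * 1)
  expect_false(anyNA(sc$svi))
  expect_error(apply_weights(z, build_weights(prof, classify_tier(prof)),
                             missing_policy = "error"),
               class = "svi_data_error")
})

test_that("index is strictly monotone in any positively weighted indicator", {
  cfg <- fixture_hierarchy()
  sc <- package_svi(fixture_table(), cfg)
  z <- align_direction(zscore_normalize(fixture_table()), cfg)
  w <- sc$weights
  for (j in c("a1", "i2", "e1")) {
    z2 <- z
    z2$values[3, j] <- z2$values[3, j] + 0.7  # frozen params, perturb one cell
    sc2 <- apply_weights(z2, w)
    expect_gt(sc2$svi[3], sc$svi[3])
    expect_equal(sc2$svi[-3], sc$svi[-3])
  }
})

test_that("tier is non-decreasing under nested degradation", {
  cfg <- svi_preset("cork_flood")
  tab <- simulate_indicators(simulation_spec(30, cfg, seed = 9))$table
  tier_of <- function(t) classify_tier(availability_profile(cfg, t))$tier
  expect_equal(tier_of(tab), 1L)
  t2 <- degrade_table(tab, cfg, "tier2_deplete", "persons_poor_health")
  expect_equal(tier_of(t2), 2L)
  t3 <- degrade_table(t2, cfg, "tier3_single_domain_dimension",
                      "enhanced_exposure", keep = "physical_environment")
  expect_equal(tier_of(t3), 3L)
  t4 <- degrade_table(t3, cfg, "tier4_drop_dimension", "enhanced_exposure")
  expect_equal(tier_of(t4), 4L)
})

test_that("aggregation matches the naive double-loop oracle", {
  cfg <- fixture_hierarchy()
  tab <- fixture_table()
  oracle <- naive_svi(tab$values, cfg)
  sc <- package_svi(tab, cfg)
  expect_equal(oracle$tier, sc$weights$tier$tier)
  expect_lt(max(abs(unname(sc$svi) - oracle$svi)), 1e-12)
})
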