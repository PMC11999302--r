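# Hand-written fixtures and an independent oracle used across the suite.

# Minimal valid configuration: 3 dimensions, 3 domains, 3 indicators.
minimal_yaml <- function() {
  '
hazard: flood
city: Testville
dimensions:
  - {id: sensitivity, label: Sensitivity}
  - {id: adaptive_capacity, label: Adaptive Capacity}
  - {id: enhanced_exposure, label: Enhanced Exposure}
domains:
  - {id: age, label: Age, dimension: sensitivity}
  - {id: income, label: Income, dimension: adaptive_capacity}
  - {id: environment, label: Environment, dimension: enhanced_exposure}
indicators:
  - {id: over_75, label: Over 75, domain: age, direction: vulnerability_increasing, required: true}
  - {id: unemployment, label: Unemployment, domain: income, direction: vulnerability_increasing, required: true}
  - {id: tree_cover, label: Tree cover, domain: environment, direction: vulnerability_reducing, required: true}
'
}

# Fixed 5-area x 6-indicator fixture: two multi-indicator domains so the
# within-domain weight split is exercised, one vulnerability-reducing
# column so alignment is exercised. Sensitivity holds two domains; adaptive
# capacity and enhanced exposure hold one each, so the full table is a
# Tier 3 situation, and dropping a2 depletes the age domain.
fixture_hierarchy <- function() {
  load_hierarchy('
hazard: flood
city: Fixtureton
dimensions:
  - {id: sensitivity, label: S}
  - {id: adaptive_capacity, label: AC}
  - {id: enhanced_exposure, label: EE}
domains:
  - {id: age, label: Age, dimension: sensitivity}
  - {id: health, label: Health, dimension: sensitivity}
  - {id: income, label: Income, dimension: adaptive_capacity}
  - {id: environment, label: Environment, dimension: enhanced_exposure}
indicators:
  - {id: a1, label: under 5, domain: age, direction: vulnerability_increasing, required: true}
  - {id: a2, label: over 75, domain: age, direction: vulnerability_increasing, required: true}
  - {id: h1, label: poor health, domain: health, direction: vulnerability_increasing, required: true}
  - {id: i1, label: unemployment, domain: income, direction: vulnerability_increasing, required: true}
  - {id: i2, label: renting, domain: income, direction: vulnerability_increasing, required: true}
  - {id: e1, label: tree cover, domain: environment, direction: vulnerability_reducing, required: true}
')
}

fixture_table <- function() {
  v <- matrix(c(
    # a1    a2    h1    i1    i2    e1
    12,   8,  20,   6,  30,  40,
    4,  15,  10,  12,  55,  10,
    9,   5,  35,   3,  22,  65,
    20,  11,  15,   9,  48,  25,
    7,   2,   8,   5,  18,  80
  ), nrow = 5, byrow = TRUE,
  dimnames = list(NULL, c("a1", "a2", "h1", "i1", "i2", "e1")))
  indicator_table(v, paste0("area", 1:5))
}

# Independent oracle: explicit double-loop evaluation of the tiered
# weighted-sum model, recomputing availability, depletion, tier, z-scores
# and weights from scratch. Complete data assumed. Returns NULL for tier 4.
naive_svi <- function(values, cfg) {
  ind <- cfg$indicators
  usable <- character()
  for (j in colnames(values)) {
    x <- values[, j]
    if (sum(!is.na(x)) >= 2 && stats::sd(x, na.rm = TRUE) > 0)
      usable <- c(usable, j)
  }
  dom_ids <- cfg$domains$domain_id
  m <- integer(); depleted <- logical(); dim_of <- character()
  for (d in dom_ids) {
    declared <- ind$indicator_id[ind$domain_id == d]
    avail <- declared[declared %in% usable]
    designed <- length(declared)
    req <- ind$indicator_id[ind$domain_id == d & ind$required]
    miss_req <- any(!req %in% avail)
    m[d] <- length(avail)
    depleted[d] <- (length(avail) < designed && miss_req) ||
      (length(avail) == 1 && designed > 1)
    dim_of[d] <- cfg$domains$dimension_id[cfg$domains$domain_id == d]
  }
  dim_counts <- sapply(cfg$dimensions$dimension_id,
                       function(dd) sum(m[dom_ids[dim_of[dom_ids] == dd]] > 0))
  tier <- if (any(dim_counts == 0)) 4L
  else if (any(dim_counts == 1)) 3L
  else if (any(depleted)) 2L
  else 1L
  if (tier == 4L) return(NULL)

  svi <- numeric(nrow(values))
  for (d in dom_ids) {
    declared <- ind$indicator_id[ind$domain_id == d]
    avail <- declared[declared %in% usable]
    if (!length(avail)) next
    w <- if (tier >= 2L && depleted[d]) 1 / (2 * length(avail)) else 1 / length(avail)
    for (j in avail) {
      x <- values[, j]
      z <- (x - mean(x)) / stats::sd(x)
      if (ind$direction[ind$indicator_id == j] == "vulnerability_reducing")
        z <- -z
      for (i in seq_len(nrow(values)))
        svi[i] <- svi[i] + w * z[i]
    }
  }
  list(tier = tier, svi = svi)
}

# Random complete fixture on the flood preset: <=20 areas, a random column
# subset that keeps every dimension represented (tiers 1-3 only).
random_fixture <- function(seed) {
  set.seed(seed)
  cfg <- svi_preset("cork_flood")
  repeat {
    n <- sample(5:20, 1)
    cols <- sample(cfg$indicators$indicator_id,
                   sample(6:12, 1))
    v <- matrix(rnorm(n * length(cols)), n,
                dimnames = list(NULL, cols))
    tab <- indicator_table(v, sprintf("r%03d", seq_len(n)))
    oracle <- naive_svi(tab$values, cfg)
    if (!is.null(oracle)) return(list(cfg = cfg, table = tab, oracle = oracle))
  }
}

# Run the package path (profile -> tier -> weights -> z -> svi) on a table.
package_svi <- function(table, cfg) {
  prof <- availability_profile(cfg, table)
  tier <- classify_tier(prof)
  z <- align_direction(zscore_normalize(table), cfg)
  apply_weights(z, build_weights(prof, tier))
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

run_cli <- function(args, env = character()) {
  cli <- system.file("cli", "svi.R", package = "svindex")
  out <- tempfile(); err <- tempfile()
  status <- system2(rscript_bin(), c(cli, args), stdout = out, stderr = err,
                    env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  list(status = status, stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
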