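make_pool <- function() {
  data.frame(
    stand_id = c("u_near", "u_far", "u_othercls", "u_remote1", "u_remote2"),
    role = "intact",
    latitude = c(1.02, 1.07, 1.03, 2.5, 2.51),
    longitude = c(103.50, 103.50, 103.50, 103.6, 103.61),
    site_id = c("siteA", "siteA", "siteB", "siteC", "siteC"),
    geomorphic_class = c("delta", "delta", "lagoon", "delta", "delta"),
    agb_c_mgha = c(100, 120, 80, 90, 110),
    bgb_c_mgha = c(50, 60, 40, 45, 55),
    soil_c_mgha = c(280, 300, 250, 260, 270),
    study_id = "s9",
    stringsAsFactors = FALSE)
}

planted_at <- function(lat, lon, class = "delta") {
  data.frame(stand_id = "p", role = "planted", latitude = lat,
             longitude = lon, site_id = "siteP", geomorphic_class = class,
             age_yr = 10, composition = "Rhizophora",
             agb_c_mgha = 55, bgb_c_mgha = 27.5, soil_c_mgha = 140,
             study_id = "s1", stringsAsFactors = FALSE)
}

test_that("haversine distances match closed-form arc lengths", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 6371.0088 * pi / 180,
               tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088,
               tolerance = 1e-6)
  expect_equal(haversine_km(5, 10, 40, 60), haversine_km(40, 60, 5, 10))
})

test_that("local matching uses all same-class intact stands within 10 km", {
  p <- planted_at(1.0, 103.5)
  m <- match_references(p, make_pool())
  expect_identical(m$match_mode, "local")
  expect_setequal(m$reference_ids, c("u_near", "u_far"))
  expect_lte(m$distance_km, 10)
  # a nearer stand of the wrong class is never used
  expect_false("u_othercls" %in% m$reference_ids)
})

test_that("remote fallback picks the nearest same-class, same-band cluster", {
  p <- planted_at(2.0, 103.6)   # ~56 km from siteA, ~56 km from siteC
  pool <- make_pool()
  pool <- pool[pool$site_id != "siteA", ]   # leave only remote candidates
  m <- match_references(p, pool)
  expect_identical(m$match_mode, "remote")
  expect_setequal(m$reference_ids, c("u_remote1", "u_remote2"))
  expect_lte(m$distance_km, 400)
  # outside the remote cap: unmatched
  cfg <- pairing_config(remote_max_km = 10)
  expect_null(match_references(p, pool, cfg))
  # different climatic band: unmatched
  p_far <- planted_at(15, 103.6)
  expect_null(match_references(p_far, pool))
})

test_that("matching is deterministic and invariant to pool ordering", {
  p <- planted_at(1.0, 103.5)
  pool <- make_pool()
  m1 <- match_references(p, pool)
  m2 <- match_references(p, pool[rev(seq_len(nrow(pool))), ])
  expect_identical(m1, m2)
})

test_that("ratios divide by the mean reference stock per compartment", {
  p <- planted_at(1.0, 103.5)
  refs <- make_pool()[1:2, ]
  r <- compute_ratio(p, refs, "agb")
  expect_equal(r$ratio, 55 / 110)
  expect_equal(r$n_refs, 2)
  # single reference, ratio 1
  p1 <- p; p1$agb_c_mgha <- 100
  expect_equal(compute_ratio(p1, refs[1, ], "agb")$ratio, 1)
  # missing compartment on the planted side: no observation
  p2 <- p; p2$bgb_c_mgha <- NA
  expect_null(compute_ratio(p2, refs, "bgb"))
  # zero mean reference: undefined
  refs0 <- refs; refs0$soil_c_mgha <- 0
  expect_error(compute_ratio(p, refs0, "soil"), "undefined ratio")
})

test_that("ratios are scale invariant", {
  p <- planted_at(1.0, 103.5)
  refs <- make_pool()[1:2, ]
  base <- compute_ratio(p, refs, "soil")$ratio
  for (c in c(0.1, 3, 1000)) {
    ps <- p; ps$soil_c_mgha <- p$soil_c_mgha * c
    rs <- refs; rs$soil_c_mgha <- refs$soil_c_mgha * c
    expect_equal(compute_ratio(ps, rs, "soil")$ratio, base,
                 tolerance = 1e-12)
  }
})

test_that("strata below the data floor are excluded, counts reconcile", {
  withr::with_seed(5, {
    obs <- data.frame(
      planted_id = sprintf("p%03d", 1:127),
      compartment = "soil",
      ratio = runif(127, 0.3, 1.2),
      age_yr = runif(127, 1, 40),
      composition_group = c(rep("Avicennia", 27), rep("Rhizophora", 100)),
      study_id = c(sprintf("st%d", rep(1:5, length.out = 27)),
                   sprintf("st%d", rep(6:17, length.out = 100))),
      stringsAsFactors = FALSE)
  })
  st <- build_strata(obs)
  # 27 observations from 5 studies: excluded under the defaults
  expect_false("soil:Avicennia" %in% names(st$strata))
  expect_true("soil:Rhizophora" %in% names(st$strata))
  expect_true("soil:all" %in% names(st$strata))
  rep <- st$report
  av <- rep[rep$stratum == "soil:Avicennia", ]
  expect_equal(av$n_obs, 27); expect_equal(av$n_studies, 5)
  expect_false(av$retained)
  # genus strata partition the compartment's observations
  genus <- rep[rep$stratum != "soil:all", ]
  expect_equal(sum(genus$n_obs), nrow(obs))
  # empty input
  empty <- build_strata(obs[0, ])
  expect_length(empty$strata, 0)
})

test_that("build_ratios drops unmatched planted stands with a log", {
  stands <- rbind(
    cbind(planted_at(1.0, 103.5), origin = "restored",
          soil_depth_cm = 100, n_samples = 3L),
    cbind(planted_at(30, 50), origin = "restored",
          soil_depth_cm = 100, n_samples = 3L))
  stands$stand_id <- c("pA", "pB")
  pool <- make_pool()
  pool$origin <- "intact"; pool$age_yr <- NA; pool$composition <- "mixed"
  pool$soil_depth_cm <- 100; pool$n_samples <- 3L
  all <- rbind(stands[, names(pool)], pool)
  obs <- build_ratios(structure(all, class = c("stand_dataset",
                                               "data.frame")))
  expect_setequal(unique(obs$planted_id), "pA")
  expect_identical(attr(obs, "unmatched"), "pB")
  expect_true(all(obs$reference_distance_km <= 10))
})
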