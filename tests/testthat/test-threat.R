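test_that("three-generation decline: closed forms", {
  expect_equal(decline_over_3gen(0), 0)
  expect_equal(decline_over_3gen(0.02), 0)
  expect_equal(decline_over_3gen(log(0.7) / 75, 25), 0.30, tolerance = 1e-12)
  expect_equal(decline_over_3gen(-0.01, 25), 1 - exp(-0.75),
               tolerance = 1e-12)
  expect_true(is.na(decline_over_3gen(NA)))
  expect_error(decline_over_3gen(-0.01, 0), "positive")
})

test_that("size criteria trigger without growth data; A3 needs growth", {
  expect_equal(classify_language(19, 10000)$category, "VU")        # D2
  expect_equal(classify_language(19, 10000)$criteria_met, "D2:VU")
  expect_equal(classify_language(1e6, 900)$category, "VU")         # D1
  expect_equal(classify_language(1e6, 200)$category, "EN")         # D1 EN
  expect_equal(classify_language(1e6, 30)$category, "CR")          # D1 CR
  ## 35% three-generation decline triggers A3 VU; exactly 30% does not
  r35 <- log(0.65) / 75
  expect_equal(classify_language(1e6, 1e6, r35)$category, "VU")
  expect_equal(classify_language(1e6, 1e6, r35)$criteria_met, "A3:VU")
  expect_equal(classify_language(1e6, 1e6, log(0.7) / 75)$category,
               "not_threatened")
  ## no data at all: data deficient
  expect_equal(classify_language(NA, NA)$category, "data_deficient")
  expect_error(classify_language(-1, 10), "negative")
})

test_that("boundary truth table: just-below / at / just-above per criterion", {
  th <- iucn_thresholds()
  eps <- 1e-6
  r_dec <- -0.05    # strong continuing decline (satisfies all C1 rates)
  ## D1 population thresholds: strict <
  for (lev in c("CR", "EN", "VU")) {
    lim <- th$d1_population[[lev]]
    expect_equal(classify_language(1e6, lim - 1)$category, lev)
    got_at <- classify_language(1e6, lim)$criteria_met
    expect_false(paste0("D1:", lev) %in% got_at)
    expect_false(paste0("D1:", lev) %in%
                   classify_language(1e6, lim + 1)$criteria_met)
  }
  ## D2 range threshold: strict <
  expect_equal(classify_language(20 - eps, 1e6)$category, "VU")
  expect_equal(classify_language(20, 1e6)$category, "not_threatened")
  ## B1 range thresholds require decline
  for (lev in c("CR", "EN", "VU")) {
    lim <- th$b1_range_km2[[lev]]
    expect_true(paste0("B1:", lev) %in%
                  classify_language(lim - eps, 1e6, r_dec)$criteria_met)
    expect_false(paste0("B1:", lev) %in%
                   classify_language(lim, 1e6, r_dec)$criteria_met)
    expect_false(paste0("B1:", lev) %in%
                   classify_language(lim - eps, 1e6, 0)$criteria_met)
  }
  ## C1 population thresholds with sufficient decline rate
  for (lev in c("CR", "EN", "VU")) {
    lim <- th$c1_population[[lev]]
    expect_true(paste0("C1:", lev) %in%
                  classify_language(1e6, lim - 1, r_dec)$criteria_met)
    expect_false(paste0("C1:", lev) %in%
                   classify_language(1e6, lim, r_dec)$criteria_met)
  }
  ## A3 decline thresholds: strict >
  for (lev in c("CR", "EN", "VU")) {
    frac <- th$a3_decline[[lev]]
    r_at <- log(1 - frac) / 75
    r_above <- log(1 - frac - 0.01) / 75
    expect_false(paste0("A3:", lev) %in%
                   classify_language(1e6, 1e6, r_at)$criteria_met)
    expect_true(paste0("A3:", lev) %in%
                  classify_language(1e6, 1e6, r_above)$criteria_met)
  }
})

test_that("category is the most severe trigger; CR nests EN and VU", {
  ## tiny population and tiny range with steep decline: everything fires
  cl <- classify_language(10, 30, -0.1)
  expect_equal(cl$category, "CR")
  expect_true(all(c("D1:CR", "D2:VU", "B1:CR", "C1:CR", "A3:CR")
                  %in% cl$criteria_met))
  ## monotonicity: worsening r never improves the category
  rank_of <- function(cat) c(not_threatened = 0, VU = 1, EN = 2, CR = 3)[cat]
  rates <- c(0.01, 0, -0.002, -0.01, -0.03, -0.1)
  cats <- vapply(rates, function(r)
    classify_language(3e4, 3000, r)$category, character(1))
  expect_true(all(diff(unname(rank_of(cats))) >= 0))
  ## monotonicity: loosening a threshold never decreases the count
  comp <- data.frame(language_id = paste0("l", 1:50),
                     area_km2 = 10^runif(50, 0, 6),
                     population = round(10^runif(50, 0, 6)),
                     rate = rnorm(50, 0, 0.02))
  n1 <- assess_all(comp, iucn_thresholds())$summary$n_threatened
  th2 <- iucn_thresholds(d1_population = c(CR = 50, EN = 250, VU = 2000))
  n2 <- assess_all(comp, th2)$summary$n_threatened
  expect_gte(n2, n1)
})

test_that("a hand-built panel spanning all five criteria is classified exactly", {
  panel <- data.frame(
    language_id = c("a3", "b1", "c1", "d1", "d2", "ok"),
    area_km2 = c(1e6, 15000, 1e6, 1e6, 15, 1e6),
    population = c(1e6, 1e6, 8000, 800, 1e6, 1e6),
    rate = c(log(0.4) / 75, -0.001, log(0.8) / 75, NA, NA, 0.01))
  got <- assess_all(panel)
  expect_equal(got$assessments$category,
               c("EN", "VU", "VU", "VU", "VU", "not_threatened"))
  expect_equal(got$assessments$criteria_met[1], "A3:EN")
  expect_equal(got$assessments$criteria_met[2], "B1:VU")
  expect_equal(got$assessments$criteria_met[3], "C1:VU")
  expect_equal(got$assessments$criteria_met[4], "D1:VU")
  expect_equal(got$assessments$criteria_met[5], "D2:VU")
  expect_equal(got$summary$n_threatened, 5)
  expect_equal(unname(got$summary$by_criterion),
               c(1L, 1L, 1L, 1L, 1L))
})

test_that("threat maps: proportions, classes, brute-force recount", {
  g <- build_grid(c(0, 4e5, 0, 2e5), cell_size = 2e5)  # 2 x 1
  mem <- data.frame(cell_id = c(1, 1, 1, 1, 2, 2),
                    language_id = c("a", "b", "c", "d", "a", "e"))
  assess <- data.frame(language_id = letters[1:5],
                       category = c("VU", "CR", rep("not_threatened", 3)),
                       criteria_met = c("D1:VU", "D1:CR", "", "", ""),
                       threatened = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  tm <- threat_maps(g, mem, assess, extinct_points = NULL)
  expect_equal(tm$extant_richness, c(4L, 2L))
  expect_equal(tm$threatened_richness, c(2L, 1L))
  expect_equal(tm$prop_threatened, c(0.5, 0.5))
  expect_equal(tm$prop_extinct, c(0, 0))
  expect_equal(tm$filter_class, rep("high-threat-low-extinction", 2))
  ## brute-force recount over membership pairs
  for (cid in 1:2) {
    ids <- mem$language_id[mem$cell_id == cid]
    expect_equal(tm$threatened_richness[cid],
                 sum(assess$threatened[match(ids, assess$language_id)]))
  }
  ## extinct points land in the right cells; zero-extant flag
  ext <- data.frame(language_id = "z",
                    lon = behrmann_unproject(3e5, 1e5)[, "lon"],
                    lat = behrmann_unproject(3e5, 1e5)[, "lat"])
  tm2 <- threat_maps(g, mem[mem$cell_id == 1, ], assess, ext)
  expect_equal(tm2$extinct_richness, c(0L, 1L))
  expect_true(tm2$undefined_extant[2])
  expect_equal(tm2$filter_class[1], "high-threat-low-extinction")
})
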