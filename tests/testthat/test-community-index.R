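# Affinity classes, CTI and community-survey assembly.

test_that("affinity classification partitions the indicator grid", {
  grid <- seq(1, 5, by = 0.5)
  cls <- classify_affinity(grid)
  expect_equal(as.character(cls),
               c(rep("cryophilic", 4),   # 1, 1.5, 2, 2.5
                 "mesophilic",           # 3
                 rep("thermophilic", 4)))# 3.5, 4, 4.5, 5
  # every grid value maps to exactly one of the three classes
  expect_false(any(cls == "unclassified"))
  expect_equal(as.character(classify_affinity(NA)), "unclassified")
  expect_error(classify_affinity(2.7), "grid")
  expect_error(classify_affinity(5.5), "grid")
})

test_that("CTI is the unweighted mean, undefined on an empty set", {
  expect_equal(compute_cti(3), 3)
  expect_equal(compute_cti(c(2, 4)), 3)
  expect_equal(compute_cti(c(1, 2, 3, 3.5)), 2.375)
  expect_true(is.na(compute_cti(numeric(0))))
  expect_true(is.na(compute_cti(c(NA, NA))))
  expect_error(compute_cti(2.2), "grid")
})

test_that("CTI obeys the reflection symmetry of the unweighted mean", {
  grid <- seq(1, 5, by = 0.5)
  set.seed(1)
  for (i in 1:20) {
    v <- sample(grid, sample(1:12, 1), replace = TRUE)
    expect_equal(compute_cti(6 - v), 6 - compute_cti(v))
  }
})

test_that("surveys split by lineage and handle missing indicator values", {
  tt <- tiny_tables()
  sv <- build_surveys(tt$plots, tt$traits, tt$occurrences, verbose = FALSE)
  # p1 in 2001 hosts both lineages -> two surveys
  p1 <- sv[sv$plot_id == "p1" & sv$year == 2001, ]
  expect_equal(nrow(p1), 2L)
  b <- p1[p1$lineage == "bryophyte", ]
  expect_equal(b$n_species, 2L)
  expect_equal(b$cti, 3)  # mean of 2 and 4
  expect_equal(c(b$n_cryo, b$n_meso, b$n_thermo), c(1L, 0L, 1L))
  v <- p1[p1$lineage == "vascular", ]
  expect_equal(v$n_species, 3L)
  expect_equal(v$n_with_t, 2L)  # v3 has no indicator value
  expect_equal(v$cti, 2)  # mean of 1 and 3

  # a survey whose only species lacks a value: present, CTI undefined
  occ <- data.frame(plot_id = "p1", year = 2006, species_id = "v3")
  sv2 <- build_surveys(tt$plots, tt$traits, occ, verbose = FALSE)
  expect_equal(nrow(sv2), 1L)
  expect_true(is.na(sv2$cti))
  expect_equal(c(sv2$n_cryo, sv2$n_meso, sv2$n_thermo), c(0L, 0L, 0L))
})

test_that("presence semantics: duplicated occurrences change nothing", {
  tt <- tiny_tables()
  sv1 <- build_surveys(tt$plots, tt$traits, tt$occurrences, verbose = FALSE)
  dup <- rbind(tt$occurrences, tt$occurrences)
  sv2 <- build_surveys(tt$plots, tt$traits, dup, verbose = FALSE)
  expect_equal(sv1, sv2)
})

test_that("affinity counts add up to the number of classified species", {
  dat <- small_scenario(n_plots = 60, seed = 17)
  sv <- build_surveys(dat$plots, dat$traits, dat$occurrences, verbose = FALSE)
  expect_true(all(sv$n_cryo + sv$n_meso + sv$n_thermo == sv$n_with_t))
  expect_true(all(sv$n_with_t <= sv$n_species))
  ok <- !is.na(sv$cti)
  expect_true(all(sv$cti[ok] >= 1 & sv$cti[ok] <= 5))
  # lineage subsetting partitions the occurrence records
  expect_equal(sum(sv$n_species),
               nrow(dat$occurrences))
})

test_that("longevity filtering restricts members before CTI computation", {
  tt <- tiny_tables()
  sv <- build_surveys(tt$plots, tt$traits, tt$occurrences,
                      longevity = "short_lived", verbose = FALSE)
  # p1/2001: short-lived members are b1 (colonist, T=2) and v1 (rrr, T=1)
  b <- sv[sv$plot_id == "p1" & sv$lineage == "bryophyte", ]
  expect_equal(b$cti, 2)
  v <- sv[sv$plot_id == "p1" & sv$lineage == "vascular", ]
  expect_equal(v$cti, 1)
})

test_that("life-strategy codes map to longevity classes as published", {
  expect_equal(as.character(classify_life_strategy("colonist", "bryophyte")),
               "short_lived")
  expect_equal(as.character(classify_life_strategy(
    c("fugitive", "annual_shuttle", "ephemeral_colonist", "pioneer_colonist",
      "short_lived_shuttle"), "bryophyte")),
    rep("short_lived", 5))
  expect_equal(as.character(classify_life_strategy(
    c("long_lived_shuttle", "perennial", "competitive_perennial",
      "stress_tolerant_perennial", "dominant"), "bryophyte")),
    rep("long_lived", 5))
  expect_equal(as.character(classify_life_strategy(c("rrr", "rrs", "crr"), "vascular")),
               rep("short_lived", 3))
  expect_equal(as.character(classify_life_strategy(c("ccc", "ccs", "ccr"), "vascular")),
               rep("long_lived", 3))
  # stress-tolerant and crs codes have no defined longevity
  expect_equal(as.character(classify_life_strategy(c("sss", "css", "rss", "crs"),
                                                   "vascular")),
               rep("unclassified", 4))
  expect_equal(as.character(classify_life_strategy(c(NA, "mystery"), "bryophyte")),
               rep("unclassified", 2))
  # a bryophyte code means nothing for a vascular plant
  expect_equal(as.character(classify_life_strategy("colonist", "vascular")),
               "unclassified")
})
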