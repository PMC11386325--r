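test_that("generations in the 100-year horizon are horizon / t", {
  expect_equal(generations_in_horizon(2), 50)    # antelope-like
  expect_equal(generations_in_horizon(20), 5)    # whale-like
  expect_equal(generations_in_horizon(100), 1)
  expect_error(generations_in_horizon(0), "positive")
})

test_that("drift projection matches closed form and limits", {
  p <- project_heterozygosity(0.5, 50, 10)
  expect_equal(p$ratio, 0.99^10, tolerance = 1e-12)
  expect_equal(round(p$ratio, 6), 0.904382)
  expect_equal(project_heterozygosity(0.5, 50, 0)$ratio, 1)
  expect_equal(project_heterozygosity(0.5, 1e12, 5)$ratio, 1,
               tolerance = 1e-10)
  expect_error(project_heterozygosity(0.5, 0.4, 5), "Ne")
})

test_that("log-space projection matches naive evaluation to 12 digits", {
  set.seed(2)
  for (rep in 1:30) {
    Ne <- 10^runif(1, 1, 9)
    T <- 10^runif(1, -1, 3)
    naive <- (1 - 1 / (2 * Ne))^T
    expect_equal(project_heterozygosity(0.1, Ne, T)$ratio, naive,
                 tolerance = 1e-12)
  }
})

test_that("Ne derivations follow their defining identities", {
  expect_equal(ne_from_nc(6517, 1.0), 6517)
  expect_equal(ne_from_nc(6517, 0.10), 651.7)
  expect_equal(ne_from_nc(123, 1), 123)
  expect_equal(ne_from_theta(0.002, 1e-8), 50000)
  expect_equal(ne_from_theta(0, 1e-8), 0)
  expect_error(ne_from_theta(0.002, 0), "positive")
})

test_that("theta-based Ne inverts the simulator configuration", {
  # simulate at per-site theta 4 Ne mu = 0.002; recover Ne for a chosen mu
  sp <- simulate_population(10, 100, 5e4, 60, seed = 31)
  ws <- window_stats(sp$table, make_windows(sp$index, 5e4))
  theta_hat <- mean(ws$theta_w)
  se <- sd(ws$theta_w) / sqrt(nrow(ws))
  mu <- 1e-8
  expect_equal(ne_from_theta(theta_hat, mu), 0.002 / (4 * mu),
               tolerance = 3 * se / 0.002)
})

test_that("relative-H_O threshold is the threatened maximum", {
  ref <- data.frame(
    label = c("tiger", "wolf", "otter", "bear"),
    H_O = c(0.00118, 0.00090, 0.00200, 0.00250),
    category = c("EN", "VU", "LC", "LC"),
    taxon_order = "Carnivora", taxon_family = NA,
    stringsAsFactors = FALSE)
  expect_equal(relative_ho_threshold(ref, "Carnivora"), 0.00118)
  expect_equal(relative_ho_threshold(ref[1, ], "Carnivora"), 0.00118)
  # adding a lower threatened H_O leaves the maximum unchanged
  ref2 <- rbind(ref, data.frame(label = "mink", H_O = 0.0005,
                                category = "CR", taxon_order = "Carnivora",
                                taxon_family = NA))
  expect_equal(relative_ho_threshold(ref2, "Carnivora"), 0.00118)
  # no threatened reference at either level: undefined
  expect_true(is.na(relative_ho_threshold(ref[3:4, ], "Carnivora")))
})

cheetah <- function(ratio) {
  species_profile("cheetah", H_O = 0.00041, generation_time_years = 6,
                  taxon_order = "Carnivora", Nc = 6517,
                  ne_nc_ratio = ratio)
}

carnivora_ref <- data.frame(
  label = "Panthera tigris jacksoni", H_O = 0.00118, category = "EN",
  taxon_order = "Carnivora", taxon_family = "Felidae",
  stringsAsFactors = FALSE)

test_that("the decision tree reproduces the cheetah walk-through", {
  at10 <- assign_genetic_category(cheetah(0.10), reference = carnivora_ref)
  expect_equal(at10$category, "VU")          # Ne = 651.7 < 1000 floor
  expect_match(at10$provenance, "Ne")
  expect_equal(round(at10$ratio, 3), 0.987)

  at100 <- assign_genetic_category(cheetah(1.0), reference = carnivora_ref)
  expect_equal(at100$category, "Threatened") # LC by tree, relative H_O fires
  expect_match(at100$provenance, "relative H_O")
  expect_equal(as_redlist(at100$category), "VU")
})

test_that("no rule fires for large, diverse populations", {
  p <- species_profile("ok", H_O = 0.005, generation_time_years = 5,
                       taxon_order = "Carnivora", Ne = 1e6)
  out <- assign_genetic_category(p, reference = carnivora_ref)
  expect_equal(out$category, "LC")
})

test_that("ratio rules assign CR / EN / VU at their bounds", {
  # choose Ne so the 100-year ratio lands in each band (t = 1 => T = 100)
  mk <- function(Ne) species_profile("x", H_O = 0.01,
                                     generation_time_years = 1, Ne = Ne)
  r <- function(Ne) project_heterozygosity(0.01, Ne, 100)$ratio
  # Ne = 400 -> ratio ~0.882 (CR); Ne = 700 -> ~0.931 (EN);
  # Ne = 1500 -> ~0.967 (VU); all floors are weaker or equal
  expect_equal(assign_genetic_category(mk(400))$category, "CR")
  expect_equal(assign_genetic_category(mk(700))$category, "EN")
  expect_equal(assign_genetic_category(mk(1500))$category, "VU")
  expect_true(r(400) <= 0.90 && r(700) <= 0.95 && r(1500) <= 0.975)
})

test_that("decreasing Ne never yields a less-threatened category", {
  rank <- c(LC = 1, VU = 3, EN = 4, CR = 5)
  ne_grid <- c(1e6, 1e5, 1e4, 2000, 900, 400, 150, 80, 20, 5)
  cats <- vapply(ne_grid, function(Ne) {
    assign_genetic_category(
      species_profile("x", H_O = 0.01, generation_time_years = 2,
                      Ne = Ne))$category
  }, "")
  expect_true(all(diff(rank[cats]) >= 0))
})

test_that("long generation time or missing Ne routes to relative H_O", {
  whale <- species_profile("whale", H_O = 0.0008,
                           generation_time_years = 20,
                           taxon_order = "Carnivora", Ne = 1e6)
  out <- assign_genetic_category(whale, reference = carnivora_ref)
  expect_equal(out$category, "Threatened")
  expect_match(out$provenance, "relative H_O")

  no_ne <- species_profile("mystery", H_O = 0.005,
                           generation_time_years = 3,
                           taxon_order = "Carnivora")
  out2 <- assign_genetic_category(no_ne, reference = carnivora_ref)
  expect_equal(out2$category, "LC")  # H_O above threatened maximum

  out3 <- assign_genetic_category(no_ne)  # no reference either
  expect_true(is.na(out3$category))
  expect_match(out3$provenance, "no route")
})

test_that("exactly one provenance rule is recorded per assignment", {
  profiles <- list(cheetah(0.10), cheetah(1.0),
                   species_profile("x", 0.01, 1, Ne = 400))
  for (p in profiles) {
    out <- assign_genetic_category(p, reference = carnivora_ref)
    expect_length(out$provenance, 1)
    expect_false(is.na(out$provenance))
  }
})

test_that("binary collapse follows the Threatened definition", {
  expect_equal(collapse_binary(c("VU", "EN", "CR")), rep("Threatened", 3))
  expect_equal(collapse_binary(c("LC", "NT")), rep("Non-Threatened", 2))
  expect_equal(collapse_binary("Threatened"), "Threatened")
})

test_that("table-level categorization runs the two-pass procedure", {
  species <- data.frame(
    label = c("tiger", "cheetah", "mouse"),
    H_O = c(0.00118, 0.00041, 0.006),
    generation_time_years = c(8, 6, 0.5),
    taxon_order = "Carnivora_or_Rodentia",
    Nc = c(400, 6517, 1e7),
    stringsAsFactors = FALSE)
  species$taxon_order <- c("Carnivora", "Carnivora", "Rodentia")
  out <- genetic_categories(species, ne_nc_ratio = 1.0)
  # tiger: Ne = 400 < 500 floor -> EN; becomes the Carnivora reference
  expect_equal(out$category[1], "EN")
  # cheetah: tree LC, then relative H_O against tiger -> Threatened/VU
  expect_equal(out$category[2], "Threatened")
  expect_equal(out$redlist[2], "VU")
  expect_equal(out$binary[2], "Threatened")
  # mouse: huge Ne, high H_O, different Order -> LC
  expect_equal(out$category[3], "LC")
})
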