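# A small genotype table used repeatedly below: 2 individuals (4
# chromosomes), three segregating sites with derived counts {1, 2, 2}.
toy_table <- function() {
  geno <- rbind(c(1L, 0L),   # x = 1
                c(1L, 1L),   # x = 2
                c(2L, 0L))   # x = 2
  colnames(geno) <- c("a", "b")
  suppressWarnings(variant_table(rep("s1", 3), c(10, 20, 30), geno))
}

test_that("folded SFS counts minor alleles and folds symmetrically", {
  sfs <- folded_sfs(toy_table())
  expect_equal(sfs$n_chromosomes, 4)
  expect_equal(sfs$counts, c(1L, 2L))
  expect_equal(sum(sfs$counts), 3)  # = S

  # monomorphic table: S = 0
  mono <- suppressWarnings(variant_table("s1", 5, matrix(c(0L, 0L), 1, 2)))
  expect_equal(sum(folded_sfs(mono)$counts), 0)

  # counts k and n - k land in the same bin
  g1 <- suppressWarnings(variant_table("s1", 5, matrix(c(1L, 0L), 1, 2)))
  g3 <- suppressWarnings(variant_table("s1", 5, matrix(c(1L, 2L), 1, 2)))
  expect_equal(folded_sfs(g1)$counts, folded_sfs(g3)$counts)
})

test_that("Watterson's theta follows S / a1(n) / L_eff", {
  expect_equal(watterson_theta(3, 4, 100), 3 / sum(1 / (1:3)) / 100)
  expect_equal(watterson_theta(0, 4, 100), 0)
  expect_equal(watterson_theta(3, 4, 200), watterson_theta(3, 4, 100) / 2)
  expect_true(is.na(watterson_theta(3, 4, 0)))
})

test_that("nucleotide diversity matches the counting formula", {
  one <- suppressWarnings(variant_table("s1", 5, matrix(c(1L, 1L), 1, 2)))
  expect_equal(nucleotide_diversity(one, L_eff = 100),
               2 * 2 * 2 / (4 * 3) / 100)  # x=2, n=4
  mono <- suppressWarnings(variant_table("s1", 5, matrix(c(2L, 2L), 1, 2)))
  expect_equal(nucleotide_diversity(mono, L_eff = 100), 0)
  expect_true(is.na(nucleotide_diversity(one, L_eff = 0)))
})

test_that("pi equals brute-force all-pairs differences on random toys", {
  set.seed(20)
  for (rep in 1:25) {
    n_hap <- 2 * sample(2:4, 1)      # up to 8 haplotypes
    m <- sample(3:20, 1)             # up to 20 sites
    hap <- matrix(rbinom(m * n_hap, 1, runif(1, 0.2, 0.8)), m, n_hap)
    tab <- geno_from_haplotypes(hap)
    got <- nucleotide_diversity(tab, L_eff = 1)
    expect_equal(got, brute_pi_abs(hap), tolerance = 1e-12)
  }
})

test_that("Tajima's D matches independent constant-by-constant evaluation", {
  n <- 4; S <- 3; pi_abs <- 2.0
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (pi_abs - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(S, pi_abs, n), expected, tolerance = 1e-12)
  expect_equal(round(expected, 2), 2.01)

  expect_equal(tajimas_d(3, 3 / a1, 4), 0)      # numerator zero
  expect_true(is.na(tajimas_d(0, 0, 4)))        # undefined at S = 0
})

test_that("window statistics compose the per-window estimators", {
  idx <- genome_index("s1", 100)
  w <- make_windows(idx, 100)
  ws <- window_stats(toy_table(), w)
  expect_equal(ws$S, 3L)
  expect_equal(ws$theta_w, 3 / sum(1 / (1:3)) / 100)
  expect_equal(ws$pi, (2 * 1 * 3 + 2 * 2 * 2 + 2 * 2 * 2) / 12 / 100)
  expect_equal(ws$tajimas_d, tajimas_d(3, ws$pi_abs, 4))
})

test_that("windows without sites or without callable bp behave", {
  idx <- genome_index("s1", 200)
  w <- make_windows(idx, 100)
  tab <- toy_table()  # sites all in [0, 100)
  ws <- window_stats(tab, w)
  expect_equal(ws$S[2], 0L)
  expect_equal(ws$theta_w[2], 0)
  expect_equal(ws$pi[2], 0)
  expect_true(is.na(ws$tajimas_d[2]))

  w$effective_sites[1] <- 0
  ws0 <- window_stats(tab, w)
  expect_true(is.na(ws0$theta_w[1]))
})

test_that("splitting a scaffold into windows conserves total S", {
  sp <- simulate_population(5, 20, 2e4, 1, seed = 9)
  one <- window_stats(sp$table, make_windows(sp$index, 2e4))
  two <- window_stats(sp$table, make_windows(sp$index, 1e4))
  expect_equal(sum(two$S), sum(one$S))
})

test_that("individual heterozygosity counts het sites over callable bp", {
  geno <- rbind(c(1L, 0L), c(1L, 2L), c(1L, 0L), c(0L, NA))
  colnames(geno) <- c("a", "b")
  tab <- suppressWarnings(variant_table(rep("s1", 4), 1:4 * 10, geno))
  expect_equal(individual_heterozygosity(tab, "a", 1000)$H, 0.003)
  expect_equal(individual_heterozygosity(tab, "b", 1000)$H, 0)
  expect_true(is.na(individual_heterozygosity(tab, "b", 0)$H))
  expect_error(individual_heterozygosity(tab, "zz", 1000), "no such sample")
})

test_that("population summary averages windows and individuals", {
  ws <- data.frame(partial = c(FALSE, FALSE), theta_w = c(0.01, 0.03),
                   pi = c(0.01, 0.02), tajimas_d = c(NA, 0.5))
  het <- data.frame(sample = c("a", "b"), H = c(0.002, 0.004))
  out <- population_summary(ws, het, label = "sp")
  expect_equal(out$mean_theta_w, 0.02)
  expect_equal(out$mean_pi, 0.015)
  expect_equal(out$mean_H, 0.003)
  expect_equal(out$mean_D, 0.5)  # undefined windows excluded

  expect_warning(population_summary(ws, het[1, , drop = FALSE]),
                 "fewer than 2")
  ws$theta_w <- NA_real_
  expect_error(suppressWarnings(population_summary(ws, het)), "no windows")
})

test_that("window means are invariant to scaffold ordering", {
  sp <- simulate_population(4, 10, 1e4, 4, seed = 15)
  tab <- sp$table
  w <- make_windows(sp$index, 1e4)
  ws <- window_stats(tab, w)
  # shuffle window order; the mean over windows must not change
  ws_shuf <- ws[sample(nrow(ws)), ]
  het <- individual_heterozygosity(tab, tab$samples[1], 4e4)
  s1 <- suppressWarnings(population_summary(ws, het))
  s2 <- suppressWarnings(population_summary(ws_shuf, het))
  expect_equal(s1$mean_theta_w, s2$mean_theta_w)
  expect_equal(s1$mean_D, s2$mean_D)
})
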